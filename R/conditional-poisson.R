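#' Natural cubic spline basis with df columns
#'
#' Wraps [splines::ns()] with the package's pinned convention: `df`
#' columns, interior knots at the covariate's equally spaced quantiles
#' (33.3rd/66.7th percentiles for df = 3) and boundary knots at the
#' observed min and max, so the fitted curve is linear beyond the data.
#' Bases are computed from the covariate values of the subset actually
#' being fitted (e.g. a season stratum), mirroring a per-model formula.
#'
#' @param values Numeric covariate series, no missing values.
#' @param df Degrees of freedom (columns); default 3.
#' @return Matrix with `df` columns and attributes `knots`,
#'   `Boundary.knots` as set by [splines::ns()].
#' @export
natural_spline_basis <- function(values, df = 3) {
  if (anyNA(values)) stop("natural_spline_basis: missing values")
  if (length(unique(values)) < df + 2) {
    stop("natural_spline_basis: need at least df + 2 distinct values")
  }
  splines::ns(values, df = df)
}

#' Conditional Poisson log-likelihood, gradient and Hessian
#'
#' For counts y_i in clusters C with linear predictor eta_i = x_i' beta,
#' conditioning on each cluster's total N_C eliminates the cluster
#' intercepts and leaves the multinomial log-likelihood
#' \deqn{\ell(\beta) = \sum_i y_i \eta_i - \sum_C N_C \log \sum_{j \in C}
#' e^{\eta_j},}
#' dropping the beta-free multinomial coefficient (so at beta = 0 with
#' equal cluster sizes |C|, ell = -sum_C N_C log |C|). The within-cluster
#' log-sum-exp is computed after subtracting the cluster max, so large
#' linear predictors do not overflow. Clusters with N_C = 0 contribute
#' nothing.
#'
#' @param beta Coefficient vector, length ncol(X).
#' @param X Design matrix (no intercept; cluster effects are conditioned
#'   out, and any cluster-constant column is non-identified).
#' @param y Non-negative integer counts.
#' @param cluster Cluster id per row (any atomic type).
#' @return List with `loglik`, `gradient` (length p), `hessian` (p x p,
#'   negative semidefinite) and `mu` (fitted means N_C * pi_i).
#' @export
conditional_loglik <- function(beta, X, y, cluster) {
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(length(beta) == p, length(y) == nrow(X),
            length(cluster) == nrow(X))
  cl <- as.integer(factor(cluster))
  eta <- drop(X %*% beta)
  if (any(!is.finite(eta))) {
    stop("conditional_loglik: non-finite linear predictor at row ",
         which(!is.finite(eta))[1])
  }
  mC <- as.numeric(tapply(eta, cl, max))   # per-cluster max, order 1..K
  w <- exp(eta - mC[cl])
  sw <- rowsum(w, cl)                      # sum_j exp(eta_j - m_C)
  lse <- log(drop(sw)) + mC                # log sum_j exp(eta_j)
  N <- drop(rowsum(y, cl))
  pi_i <- w / drop(sw)[cl]
  mu <- N[cl] * pi_i
  ll <- sum(y * eta) - sum(N * lse)
  grad <- drop(crossprod(X, y - mu))
  # Hessian: -(X' diag(mu) X - sum_C N_C xbar_C xbar_C'), xbar_C = sum pi x
  Xpi <- rowsum(pi_i * X, cl)              # per-cluster sum of pi_j x_j
  H <- -(crossprod(X, mu * X) - crossprod(sqrt(N) * Xpi))
  list(loglik = ll, gradient = grad, hessian = H, mu = mu)
}

#' Fit a conditional quasi-Poisson model
#'
#' Maximises the conditional (cluster-total-conditioned) Poisson
#' likelihood by Newton iteration with step halving, started at beta = 0
#' (the objective is concave, so the start is benign). Convergence is
#' declared when the gradient max-norm on the internally standardised
#' covariate scale falls below `tol`. Overdispersion is absorbed
#' quasi-Poisson style: the dispersion is the Pearson chi-square over the
#' residual degrees of freedom n - k - p, where n counts days in clusters
#' with positive totals and k counts those clusters (mirroring the
#' fixed-effects-Poisson equivalence, in which each cluster absorbs one
#' intercept); standard errors are sqrt(dispersion x diag of the inverse
#' observed information).
#'
#' @param X Design matrix (exposure first column by convention of the
#'   callers; no intercept, no cluster-constant columns).
#' @param y Non-negative integer counts per day.
#' @param cluster Cluster identifier per day.
#' @param tol Gradient max-norm tolerance on the standardised scale.
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `ccfit`: list with `beta`, `se_beta` (both on
#'   the original covariate scale), `vcov`, `dispersion`, `loglik`,
#'   `converged`, `n_iter`, `n_days`, `n_clusters` (days and clusters with
#'   positive totals), `fitted`.
#' @export
conditional_poisson_fit <- function(X, y, cluster, tol = 1e-8,
                                    max_iter = 50L) {
  X <- as.matrix(X)
  p <- ncol(X)
  n <- nrow(X)
  stopifnot(length(y) == n, length(cluster) == n)
  if (any(y < 0) || any(y != round(y))) {
    stop("conditional_poisson_fit: counts must be non-negative integers")
  }
  cl <- as.integer(factor(cluster))
  N <- drop(rowsum(y, cl))
  # identifiability: some cluster with positive total must show
  # within-cluster variation in each column
  active <- N[cl] > 0
  if (!any(active)) {
    stop("conditional_poisson_fit: all cluster totals are zero")
  }
  ca <- cl[active]
  for (j in seq_len(p)) {
    dev <- X[active, j] - stats::ave(X[active, j], ca)
    if (all(abs(dev) < 1e-12)) {
      stop("conditional_poisson_fit: column ", j,
           " is constant within every informative cluster; ",
           "the coefficient is not identified")
    }
  }
  # standardise columns for numerics; beta_orig = beta_std / scale
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(X, 2, scl, "/")
  beta <- rep(0, p)
  state <- conditional_loglik(beta, Xs, y, cluster)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(state$gradient)) < tol) {
      converged <- TRUE
      break
    }
    step <- tryCatch(
      solve(state$hessian + diag(-1e-10, p), -state$gradient),
      error = function(e) NULL
    )
    if (is.null(step)) break
    # step halving on the concave objective
    ok <- FALSE
    for (h in 0:30) {
      cand <- beta + step / 2^h
      new_state <- tryCatch(conditional_loglik(cand, Xs, y, cluster),
                            error = function(e) NULL)
      if (!is.null(new_state) && is.finite(new_state$loglik) &&
          new_state$loglik >= state$loglik - 1e-12) {
        beta <- cand
        state <- new_state
        ok <- TRUE
        break
      }
    }
    if (!ok) break
  }
  if (!converged && max(abs(state$gradient)) < tol) converged <- TRUE
  info_s <- -state$hessian
  vcov_s <- tryCatch(solve(info_s), error = function(e) matrix(NA_real_, p, p))
  mu <- state$mu
  use <- N[cl] > 0
  n_eff <- sum(use)
  k_eff <- sum(N > 0)
  df_resid <- n_eff - k_eff - p
  pearson <- sum((y[use] - mu[use])^2 / mu[use])
  dispersion <- if (df_resid > 0) pearson / df_resid else NA_real_
  # back-transform to the original covariate scale
  beta_o <- beta / scl
  vcov_o <- vcov_s / tcrossprod(scl)
  disp_used <- if (is.finite(dispersion)) dispersion else 1
  se_o <- sqrt(pmax(disp_used * diag(vcov_o), 0))
  structure(
    list(beta = beta_o, se_beta = se_o, vcov = disp_used * vcov_o,
         dispersion = dispersion, loglik = state$loglik,
         converged = converged, n_iter = iter, n_days = n_eff,
         n_clusters = k_eff, fitted = mu),
    class = "ccfit"
  )
}

#' @export
print.ccfit <- function(x, ...) {
  cat("Conditional quasi-Poisson fit:", x$n_days, "days in", x$n_clusters,
      "clusters;", if (x$converged) "converged" else "NOT converged",
      "in", x$n_iter, "iterations\n")
  cat("  exposure beta =", format(x$beta[1], digits = 4),
      " se =", format(x$se_beta[1], digits = 4),
      " dispersion =", format(x$dispersion, digits = 4), "\n")
  invisible(x)
}

#' Fit one case-crossover model from a model-ready table
#'
#' Builds the design matrix — the lagged exposure plus natural splines
#' (3 df each) of temperature and relative humidity, computed from this
#' table's own covariate values — assigns days to their year-month-weekday
#' clusters, and calls [conditional_poisson_fit()].
#'
#' @param model_data Tibble with columns `date`, `count`, `exposure`,
#'   `temperature`, `humidity` (as produced by [attach_lags()]).
#' @param spline_df Degrees of freedom for each weather spline; 0 drops
#'   weather adjustment.
#' @param ... Passed to [conditional_poisson_fit()].
#' @return A `ccfit` object; `beta[1]` is the exposure coefficient per
#'   native unit.
#' @export
fit_model <- function(model_data, spline_df = 3, ...) {
  stopifnot(all(c("date", "count", "exposure") %in% names(model_data)))
  des <- build_clusters(min(model_data$date), max(model_data$date))
  cluster <- des$days$cluster[match(model_data$date, des$days$date)]
  X <- matrix(model_data$exposure, ncol = 1,
              dimnames = list(NULL, "exposure"))
  if (spline_df > 0) {
    stopifnot(all(c("temperature", "humidity") %in% names(model_data)))
    bt <- natural_spline_basis(model_data$temperature, spline_df)
    bh <- natural_spline_basis(model_data$humidity, spline_df)
    colnames(bt) <- paste0("ns_temp", seq_len(spline_df))
    colnames(bh) <- paste0("ns_hum", seq_len(spline_df))
    X <- cbind(X, bt, bh)
  }
  conditional_poisson_fit(X, model_data$count, cluster, ...)
}

#' Relative risk per exposure increment
#'
#' RR = exp(beta * delta) with the Wald interval
#' exp((beta +/- z * se) * delta); `delta` is typically the exposure's
#' interquartile range, so the RR is reported per IQR increase.
#'
#' @param fit A `ccfit` object (must have converged).
#' @param delta Exposure increment in native units, > 0.
#' @param level Confidence level, default 0.95 (two-tailed 0.05).
#' @return Tibble with `rr`, `lower`, `upper`, `delta`, `level`.
#' @export
rr_from_fit <- function(fit, delta, level = 0.95) {
  stopifnot(inherits(fit, "ccfit"))
  if (!fit$converged) {
    stop("rr_from_fit: model did not converge")
  }
  stopifnot(delta > 0, level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  b <- fit$beta[1]
  se <- fit$se_beta[1]
  tibble::tibble(
    rr = exp(b * delta),
    lower = exp((b - z * se) * delta),
    upper = exp((b + z * se) * delta),
    delta = delta,
    level = level
  )
}
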
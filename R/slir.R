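#' Lag-embedded design matrix
#'
#' For every requested sample time `t` the design row holds, for each
#' feature, its values at `t, t - dt, ..., t - (m-1) dt`.  Lags may reach
#' back across trial boundaries into the continuous recording (inter-trial
#' rest) but never off the recording start: rows whose full lag window is
#' not available are excluded and reported.
#'
#' @param ft A `feature_tensor` (or bare features x samples matrix sampled
#'   at `fs`).
#' @param rows Integer sample indices (into the feature time axis) at which
#'   to build rows; default all samples.
#' @param m Number of lags per feature.
#' @param dt_s Lag spacing in seconds; `dt_s * fs` must be an integer
#'   number of samples.
#' @param fs Sampling rate of the feature series (taken from `ft` when it
#'   is a `feature_tensor`).
#' @return List of class `lagged_design` with `X` (rows x features*m),
#'   `rows` (the retained sample indices), `m`, `dt_s`, `column_key`
#'   (data.frame `feature`, `lag` per column) and `n_dropped`.
#' @export
build_lagged_design <- function(ft, rows = NULL, m = 100L, dt_s = 0.01,
                                fs = NULL) {
  if (inherits(ft, "feature_tensor")) {
    vals <- ft$values; fs <- ft$fs
  } else {
    vals <- ft
    if (is.null(fs)) stop_invalid("`fs` required for a bare feature matrix")
  }
  m <- as.integer(m)
  if (m < 1L) stop_invalid("m must be >= 1")
  step <- dt_s * fs
  if (abs(step - round(step)) > 1e-9)
    stop_invalid("dt_s * fs must be an integer number of samples")
  step <- as.integer(round(step))
  n_s <- ncol(vals)
  if (is.null(rows)) rows <- seq_len(n_s)
  min_row <- (m - 1L) * step + 1L
  dropped <- sum(rows < min_row)
  rows <- rows[rows >= min_row & rows <= n_s]
  if (!length(rows)) stop_invalid("no rows have a complete lag window")
  p <- nrow(vals)
  X <- matrix(0, length(rows), p * m)
  for (j in seq_len(m) - 1L) {
    cols <- seq_len(p) * m - (m - 1L) + j     # feature-major, lag runs fastest
    X[, cols] <- t(vals[, rows - j * step, drop = FALSE])
  }
  key <- data.frame(feature = rep(seq_len(p), each = m),
                    lag = rep(seq_len(m) - 1L, times = p))
  structure(list(X = X, rows = rows, m = m, dt_s = dt_s, fs = fs,
                 column_key = key, n_dropped = dropped),
            class = "lagged_design")
}

#' Sparse Bayesian linear regression (automatic relevance determination)
#'
#' Fits `y = w0 + X w + e` with an independent zero-mean Gaussian prior
#' per weight, `w_j ~ N(0, 1/alpha_j)`, and Gaussian noise of precision
#' `beta`.  Hyperparameters are updated by evidence maximization: the
#' posterior mean and covariance of the weights are computed in closed
#' form, then `alpha_j <- gamma_j / mu_j^2` with
#' `gamma_j = 1 - alpha_j Sigma_jj`, then
#' `beta <- (n - sum(gamma)) / ||y - X mu||^2`, iterated until the largest
#' relative weight change falls below `tol`.  Weights whose `alpha`
#' exceeds `prune_alpha` are pruned to exactly zero and leave the active
#' set permanently.  The bias `w0` is unpenalized (the fit is performed on
#' centred data and `w0` recovered as `mean(y) - colMeans(X) %*% w`).
#'
#' @param design A `lagged_design`, or a bare numeric design matrix.
#' @param y Numeric response aligned with the design rows.
#' The response is standardized internally (weights are refit on
#' `y / sd(y)` and rescaled afterwards), which makes the relevance
#' precisions dimensionless: `prune_alpha` therefore has the same meaning
#' for a target measured in millimetres as for one in arbitrary units.
#' The default threshold 1e3 prunes weights smaller than about 3% of a
#' response standard deviation (per unit of a z-scored feature); spurious
#' features under a pure-noise residual reach stable precisions of about
#' 1e4 and above, so the threshold separates the two regimes by an order
#' of magnitude on each side.
#'
#' @param tol Convergence threshold on the relative weight change; the
#'   relevance precisions must also be stable (default 1e-6).
#' @param max_iter Maximum number of update sweeps (default 500).
#' @param prune_alpha Dimensionless precision (standardized-response
#'   scale) above which a weight is pruned (default 1e3).
#' @param alpha0 Initial per-weight precision on the scale of the
#'   original response; the default (`NULL`) initializes all precisions
#'   at 1 on the standardized scale, which keeps the fit exactly
#'   equivariant under rescaling of `y`.
#' @param beta0 Initial noise precision, original response scale; the
#'   default (`NULL`) corresponds to `1/var(y)`.
#' @param update_alpha,update_beta Disable the hyperparameter updates to
#'   obtain a fixed-ridge fit (used for cross-checks).
#' @return List of class `slir_model`: `w0`, `w` (length-p, pruned entries
#'   exactly 0), `alpha`, `beta`, `active` (logical mask), `iterations`,
#'   `converged`, `column_key` (when available) and `fingerprint`.
#' @export
fit_slir <- function(design, y, tol = 1e-6, max_iter = 500L,
                     prune_alpha = 1e3, alpha0 = NULL, beta0 = NULL,
                     update_alpha = TRUE, update_beta = TRUE) {
  key <- NULL
  if (inherits(design, "lagged_design")) {
    X <- design$X; key <- design$column_key
  } else X <- as.matrix(design)
  if (nrow(X) != length(y)) stop_invalid("y must align with the design rows")
  if (nrow(X) < 10L) stop_invalid("need at least 10 rows to fit")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop_invalid("non-finite values in the design or response")
  n <- nrow(X); p <- ncol(X)
  xbar <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2L, xbar, "-")
  yc <- y - ybar
  vy <- sum(yc^2) / max(1L, n - 1L)
  if (vy <= 0) {                      # constant response: intercept only
    return(new_slir_model(numeric(p), ybar, rep(Inf, p), Inf, key,
                          iterations = 0L, converged = TRUE))
  }
  yc <- yc / sqrt(vy)                 # standardized response
  XtX <- crossprod(Xc)
  Xty <- drop(crossprod(Xc, yc))
  yty <- sum(yc^2)
  # user-supplied precisions are on the original response scale
  beta <- if (is.null(beta0)) 1 else beta0 * vy
  alpha <- rep(if (is.null(alpha0)) 1 else alpha0 * vy, p)
  active <- rep(TRUE, p)
  w_full <- numeric(p)
  it <- 0L; converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    a <- which(active)
    if (!length(a)) { converged <- TRUE; break }
    H <- beta * XtX[a, a, drop = FALSE]
    diag(H) <- diag(H) + alpha[a]
    ch <- tryCatch(chol(H), error = function(e) NULL)
    if (is.null(ch)) {                # stabilize a near-singular system
      diag(H) <- diag(H) * (1 + 1e-10) + 1e-12
      ch <- chol(H)
    }
    mu <- beta * backsolve(ch, forwardsolve(t(ch), Xty[a]))
    Sdiag <- diag(chol2inv(ch))
    gam <- 1 - alpha[a] * Sdiag
    gam <- pmin(pmax(gam, 1e-12), 1)
    w_new <- numeric(p)
    w_new[a] <- mu
    delta <- max(abs(w_new - w_full)) / max(max(abs(w_new)), 1e-12)
    w_full <- w_new
    delta_logalpha <- 0
    if (update_alpha) {
      alpha_new <- gam / pmax(mu^2, 1e-300)
      # hyperparameters must also be stable: weights on their way out have
      # geometrically growing alpha and must be pruned, not frozen by an
      # early weight-change stop
      delta_logalpha <- max(abs(log(alpha_new) - log(alpha[a])))
      alpha[a] <- alpha_new
      newly_pruned <- a[alpha[a] > prune_alpha]
      if (length(newly_pruned)) {
        active[newly_pruned] <- FALSE
        w_full[newly_pruned] <- 0
      }
    }
    if (update_beta) {
      rss <- yty - 2 * sum(mu * Xty[a]) +
        drop(crossprod(mu, XtX[a, a, drop = FALSE] %*% mu))
      beta <- (n - sum(gam)) / max(rss, 1e-300)
    }
    if (delta < tol && delta_logalpha < 1e-3) { converged <- TRUE; break }
  }
  w_full <- w_full * sqrt(vy)         # back to the original response scale
  w0 <- ybar - sum(xbar * w_full)
  new_slir_model(w_full, w0, alpha / vy, beta / vy, key, iterations = it,
                 converged = converged)
}

new_slir_model <- function(w, w0, alpha, beta, column_key, iterations,
                           converged) {
  structure(list(w0 = w0, w = w, alpha = alpha, beta = beta,
                 active = w != 0, column_key = column_key,
                 fit_log = list(iterations = iterations,
                                converged = converged,
                                n_active = sum(w != 0)),
                 fingerprint = NULL),
            class = "slir_model")
}

#' @export
print.slir_model <- function(x, ...) {
  cat(sprintf("slir_model: %d/%d active weights, w0 = %.4g, %d iterations (%s)\n",
              sum(x$active), length(x$w), x$w0, x$fit_log$iterations,
              if (x$fit_log$converged) "converged" else "not converged"))
  invisible(x)
}

#' Predict from a fitted SLiR model
#'
#' Pure linear evaluation
#' `Y_p(t) = w0 + sum_ij w_ij z_i(t - j dt)`.
#'
#' @param object A `slir_model`.
#' @param design A `lagged_design` (its `column_key` must match the
#'   model's) or a bare matrix with as many columns as the model has
#'   weights.
#' @param ... Unused.
#' @return Numeric vector of predictions, one per design row.
#' @export
predict.slir_model <- function(object, design, ...) {
  if (inherits(design, "lagged_design")) {
    if (!is.null(object$column_key) &&
        !identical(dim(object$column_key), dim(design$column_key)))
      stop_invalid("design columns are incompatible with the model")
    X <- design$X
  } else X <- as.matrix(design)
  if (ncol(X) != length(object$w))
    stop_invalid("design has %d columns but the model has %d weights",
                 ncol(X), length(object$w))
  a <- which(object$w != 0)
  pred <- rep(object$w0, nrow(X))
  if (length(a)) pred <- pred + drop(X[, a, drop = FALSE] %*% object$w[a])
  pred
}
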
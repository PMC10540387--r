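#' Fit a PLS1 regression by NIPALS
#'
#' Classical NIPALS partial least squares for a single response. `X` and `y`
#' are centered internally; for each component the weight is
#' `w = X'y / ||X'y||`, the score `t = X w`, the x-loading `p = X't / t't`,
#' the y-loading `q = y't / t't`, and `X` is deflated by `t p'`. The
#' regression vector is `W (P'W)^{-1} q`, expressed in the centered variable
#' space. PLS1 is deterministic: no random initialization is involved.
#'
#' @param X Numeric matrix `n x p` of (pretreated) spectral variables.
#' @param y Numeric response vector of length `n`.
#' @param rank Number of latent variables, between 1 and `min(n - 1, p)`.
#' @return An object of class `pls_fit`: `rank`, `x_mean`, `y_mean`,
#'   `weights` (p x rank), `x_loadings` (p x rank), `y_loadings` (rank),
#'   `scores` (n x rank), `coefficients` (p), `fitted`.
#' @seealso [pls_coefficients()] for truncated-rank coefficient vectors.
#' @export
fit_pls <- function(X, y, rank) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("X and y sizes do not match")
  rank <- as.integer(rank)
  if (rank < 1L || rank > min(n - 1L, p)) {
    stop("rank must be between 1 and min(n - 1, p) = ", min(n - 1L, p))
  }
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2L, x_mean)
  yc <- y - y_mean
  W <- matrix(0, p, rank)
  P <- matrix(0, p, rank)
  Tm <- matrix(0, n, rank)
  q <- numeric(rank)
  Xd <- Xc
  yd <- yc
  for (a in seq_len(rank)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sum(yd^2)))) {
      stop("rank exceeds data rank: zero-norm weight at component ", a)
    }
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    if (tt < 1e-24) stop("rank exceeds data rank: zero-variance score at component ", a)
    pv <- crossprod(Xd, t) / tt
    qa <- sum(yd * t) / tt
    Xd <- Xd - t %*% t(pv)
    yd <- yd - qa * t
    W[, a] <- w; P[, a] <- pv; Tm[, a] <- t; q[a] <- qa
  }
  beta <- as.numeric(W %*% solve(crossprod(P, W), q))
  fitted <- y_mean + as.numeric(Xc %*% beta)
  structure(list(rank = rank, x_mean = x_mean, y_mean = y_mean,
                 weights = W, x_loadings = P, y_loadings = q, scores = Tm,
                 coefficients = beta, fitted = fitted),
            class = "pls_fit")
}

#' @export
print.pls_fit <- function(x, ...) {
  cat(sprintf("<pls_fit> rank %d, %d variables\n", x$rank,
              length(x$coefficients)))
  invisible(x)
}

#' Regression vector of a NIPALS fit truncated to a lower rank
#'
#' @param fit A [fit_pls()] object.
#' @param rank Number of components to use, at most `fit$rank`.
#' @return The regression vector in centered variable space.
#' @export
pls_coefficients <- function(fit, rank = fit$rank) {
  stopifnot(inherits(fit, "pls_fit"))
  rank <- as.integer(rank)
  if (rank < 1L || rank > fit$rank) stop("rank out of range")
  a <- seq_len(rank)
  as.numeric(fit$weights[, a, drop = FALSE] %*%
               solve(crossprod(fit$x_loadings[, a, drop = FALSE],
                               fit$weights[, a, drop = FALSE]),
                     fit$y_loadings[a]))
}

#' @param object A [fit_pls()] object.
#' @param newdata Numeric matrix with the same variables the fit used.
#' @param rank Components to use; defaults to the fitted rank.
#' @param ... Ignored.
#' @return Numeric vector of predictions.
#' @rdname fit_pls
#' @export
predict.pls_fit <- function(object, newdata, rank = object$rank, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_mean)) {
    stop("newdata has ", ncol(newdata), " variables; model expects ",
         length(object$x_mean))
  }
  beta <- if (rank == object$rank) object$coefficients else
    pls_coefficients(object, rank)
  object$y_mean + as.numeric(sweep(newdata, 2L, object$x_mean) %*% beta)
}

#' Regression performance metrics
#'
#' RMSE, coefficient of determination, RPD and bias for a set of predictions.
#' `R2 = 1 - SS_res / SS_tot` against the observed values of the stage being
#' scored; `RPD = sd_ref / RMSE`, conventionally the calibration-set
#' reference SD over the stage RMSE. A perfect fit (RMSE = 0) reports
#' `RPD = Inf` rather than an error.
#'
#' @param y_obs Observed reference values (length >= 2).
#' @param y_hat Predictions, same length.
#' @param sd_ref Reference-value standard deviation used as the RPD
#'   numerator; defaults to `sd(y_obs)`.
#' @return A list with `RMSE`, `R2`, `RPD`, `bias`, `n`.
#' @export
metrics <- function(y_obs, y_hat, sd_ref = stats::sd(y_obs)) {
  y_obs <- as.numeric(y_obs); y_hat <- as.numeric(y_hat)
  if (length(y_obs) != length(y_hat)) stop("length mismatch")
  if (length(y_obs) < 2L) stop("metrics need at least 2 observations")
  if (!is.finite(sd_ref) || sd_ref <= 0) stop("sd_ref must be positive")
  res <- y_hat - y_obs
  rmse <- sqrt(mean(res^2))
  ss_tot <- sum((y_obs - mean(y_obs))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(res^2) / ss_tot
  rpd <- if (rmse == 0) Inf else sd_ref / rmse
  list(RMSE = rmse, R2 = r2, RPD = rpd, bias = mean(res), n = length(y_obs))
}

#' Ratio of (reference) deviation to prediction error
#'
#' @param sd_ref Reference-value standard deviation.
#' @param rmse Stage RMSE.
#' @return `sd_ref / rmse` (`Inf` for a zero RMSE).
#' @export
rpd <- function(sd_ref, rmse) {
  if (!is.finite(sd_ref) || sd_ref <= 0) stop("sd_ref must be positive")
  if (rmse < 0) stop("rmse must be nonnegative")
  if (rmse == 0) Inf else sd_ref / rmse
}

#' Calibrate a frozen PLS model on spectra
#'
#' Bundles the full prediction transform — window selection, fitted
#' pretreatment (with any MSC reference frozen on the calibration set),
#' centering and the NIPALS regression vector — into one artifact that can
#' be serialized and applied to new spectra.
#'
#' @param s Calibration [spectra_set()].
#' @param ref Matching [reference_table()].
#' @param pretreat A [pretreatment()] (or method name string).
#' @param windows A [window_set()] or `NULL` for the full range.
#' @param rank Number of latent variables.
#' @return An object of class `pls_model`.
#' @export
calibrate_model <- function(s, ref, pretreat = pretreatment("NONE"),
                            windows = NULL, rank = 10L) {
  stopifnot(inherits(s, "spectra_set"))
  if (is.character(pretreat)) pretreat <- pretreatment(pretreat)
  y <- align_reference(s, ref)
  sw <- apply_windows(s, windows)
  pretreat <- fit_pretreatment(sw, pretreat)
  X <- pretreat_matrix(sw$values, sw$grid, pretreat, ids = sw$sample_ids)
  fit <- fit_pls(X, y, rank)
  structure(list(fit = fit, pretreatment = pretreat, windows = windows,
                 grid = sw$grid, full_grid = s$grid,
                 trait_name = ref$trait[1L], units = ref$units[1L],
                 calibration_ids = s$sample_ids,
                 y_mean = mean(y), sd_ref = stats::sd(y), rank = rank),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %s [%s], rank %d, %s %s, %d calibration samples\n",
              x$trait_name, x$units, x$rank, x$pretreatment$method,
              format_windows(x$windows), length(x$calibration_ids)))
  invisible(x)
}

#' Predict trait values from spectra with a frozen model
#'
#' Applies windows, the frozen pretreatment statistics and the centered
#' regression vector; no statistic is re-estimated from `newdata`.
#'
#' @param object A [calibrate_model()] model.
#' @param newdata A [spectra_set()] whose grid covers the model's windows.
#' @param ... Ignored.
#' @return Named numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "spectra_set"))
  sw <- apply_windows(newdata, object$windows)
  if (length(sw$grid) != length(object$grid) ||
      max(abs(sw$grid - object$grid)) > 1e-8 * max(abs(object$grid))) {
    stop("spectra grid does not cover the model's windows (",
         format_windows(object$windows), ")")
  }
  X <- pretreat_matrix(sw$values, sw$grid, object$pretreatment,
                       ids = sw$sample_ids)
  stats::setNames(predict(object$fit, X), newdata$sample_ids)
}
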
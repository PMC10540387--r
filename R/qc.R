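#' Principal-component model of a spectral population
#'
#' PCA on the column-centered (but unscaled: spectral variables share units)
#' spectral matrix, used to characterize population structure and to screen
#' outliers via the GH distance. Loadings carry a deterministic sign
#' convention: the largest-magnitude element of each component is positive.
#'
#' @param s A [spectra_set()] with at least 3 samples.
#' @param k Number of retained components, at most `min(n - 1, p)`.
#'   Default 10, the customary depth for NIR population characterization.
#' @return An object of class `pca_model` with fields `center`, `loadings`
#'   (p x k, orthonormal columns), `explained_variance_ratio`, `k`, `grid`,
#'   and `score_cov` (k x k covariance of the fitting-set scores, n-1
#'   denominator).
#' @export
fit_pca <- function(s, k = 10L) {
  stopifnot(inherits(s, "spectra_set"))
  n <- nrow(s$values); p <- ncol(s$values)
  if (n < 3L) stop("PCA needs at least 3 samples")
  k <- as.integer(k)
  if (k < 1L || k > min(n - 1L, p)) {
    stop("k must be between 1 and min(n - 1, p) = ", min(n - 1L, p))
  }
  pc <- stats::prcomp(s$values, center = TRUE, scale. = FALSE)
  evr_all <- pc$sdev^2 / sum(pc$sdev^2)
  load <- pc$rotation[, seq_len(k), drop = FALSE]
  # sign convention: largest-magnitude loading element positive
  for (j in seq_len(k)) {
    m <- which.max(abs(load[, j]))
    if (load[m, j] < 0) load[, j] <- -load[, j]
  }
  sc <- sweep(s$values, 2L, pc$center) %*% load
  structure(list(center = as.numeric(pc$center), loadings = unname(load),
                 explained_variance_ratio = evr_all[seq_len(k)], k = k,
                 grid = s$grid, score_cov = stats::cov(sc), n_fit = n),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("<pca_model> k = %d components, %.1f%% variance explained\n",
              x$k, 100 * sum(x$explained_variance_ratio)))
  invisible(x)
}

#' Project spectra onto a fitted PCA model
#'
#' @param m A [fit_pca()] model.
#' @param s A [spectra_set()] on the same wavenumber grid.
#' @return An `n x k` score matrix (rows named by sample id).
#' @export
pca_scores <- function(m, s) {
  stopifnot(inherits(m, "pca_model"), inherits(s, "spectra_set"))
  if (length(s$grid) != length(m$grid) ||
      max(abs(s$grid - m$grid)) > 1e-8 * max(abs(m$grid))) {
    stop("spectra grid does not match the grid the PCA model was fitted on")
  }
  sc <- sweep(s$values, 2L, m$center) %*% m$loadings
  rownames(sc) <- s$sample_ids
  sc
}

#' GH (global distance) outlier screen
#'
#' The GH statistic of each spectrum is its squared Mahalanobis distance in
#' the retained k-component score space, divided by k. The score covariance
#' is that of the fitting set (n-1 denominator), so the mean GH over the
#' fitting set is exactly `(n - 1) / n`. Samples with `GH > threshold` are
#' flagged, not removed; removal is an explicit pipeline option.
#'
#' @param m A [fit_pca()] model with `k >= 2`.
#' @param s A [spectra_set()] to screen (typically the fitting set itself).
#' @param threshold Flagging cutoff on GH; default 3, standard NIRS practice.
#' @return A `data.frame` of class `gh_report` with columns `sample_id`,
#'   `GH`, `flag`; the threshold is stored as an attribute.
#' @export
gh_distance <- function(m, s, threshold = 3) {
  stopifnot(inherits(m, "pca_model"))
  if (m$k < 2L) stop("GH screening needs a PCA model with k >= 2")
  if (rcond(m$score_cov) < 1e-12) stop("singular score covariance")
  sc <- pca_scores(m, s)
  d2 <- stats::mahalanobis(sc, center = rep(0, m$k), cov = m$score_cov)
  gh <- d2 / m$k
  structure(data.frame(sample_id = s$sample_ids, GH = as.numeric(gh),
                       flag = as.numeric(gh) > threshold,
                       stringsAsFactors = FALSE),
            class = c("gh_report", "data.frame"), threshold = threshold)
}
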
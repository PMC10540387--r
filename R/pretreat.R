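#' Pretreatment methods
#'
#' The ten per-spectrum transforms offered before PLS calibration, plus
#' `NONE`. Combination methods apply the first derivative before the scatter
#' step (so `FD_SNV` is "first derivative, then SNV"), matching the usual
#' "FD + SNV" naming.
#'
#' @format Character vector of method names.
#' @export
PRETREATMENT_METHODS <- c("NONE", "COE", "SSL", "SNV", "MMN", "MSC",
                          "FD", "SED", "FD_SSL", "FD_SNV", "FD_MSC")

#' Specify a spectral pretreatment
#'
#' @param method One of [PRETREATMENT_METHODS]: constant offset elimination
#'   (`COE`), straight-line subtraction (`SSL`), standard normal variate
#'   (`SNV`), min-max normalization (`MMN`), multiplicative scatter
#'   correction (`MSC`), Savitzky-Golay first/second derivative
#'   (`FD`/`SED`), first-derivative combinations (`FD_SSL`, `FD_SNV`,
#'   `FD_MSC`), or `NONE`.
#' @param sg_window Savitzky-Golay window length in grid points; odd,
#'   at least 5, larger than `sg_polyorder`. Default 17.
#' @param sg_polyorder Savitzky-Golay polynomial order. Default 2.
#' @return An object of class `pretreatment`. MSC-containing methods gain an
#'   `msc_reference` field once fitted with [fit_pretreatment()].
#' @export
pretreatment <- function(method = PRETREATMENT_METHODS, sg_window = 17L,
                         sg_polyorder = 2L) {
  method <- match.arg(method)
  sg_window <- as.integer(sg_window)
  sg_polyorder <- as.integer(sg_polyorder)
  if (sg_window %% 2L == 0L || sg_window < 5L) {
    stop("sg_window must be odd and at least 5")
  }
  if (sg_polyorder >= sg_window) stop("sg_window must exceed sg_polyorder")
  if (method == "SED" && sg_polyorder < 2L) {
    stop("second derivative needs sg_polyorder >= 2")
  }
  structure(list(method = method, sg_window = sg_window,
                 sg_polyorder = sg_polyorder, msc_reference = NULL),
            class = "pretreatment")
}

#' @export
print.pretreatment <- function(x, ...) {
  cat(sprintf("<pretreatment> %s (SG window %d, polyorder %d)%s\n",
              x$method, x$sg_window, x$sg_polyorder,
              if (!is.null(x$msc_reference)) ", MSC reference fitted" else ""))
  invisible(x)
}

uses_msc <- function(spec) spec$method %in% c("MSC", "FD_MSC")
uses_fd <- function(spec) spec$method %in% c("FD", "FD_SSL", "FD_SNV", "FD_MSC")

#' Fit pretreatment statistics on a calibration set
#'
#' Most pretreatments are stateless and are returned unchanged. The
#' MSC-containing methods freeze the correction reference: the column mean of
#' the calibration spectra (taken after the derivative step for `FD_MSC`), so
#' that prediction-time correction never peeks at new-data statistics.
#'
#' @param s A [spectra_set()] (the calibration set).
#' @param spec A [pretreatment()].
#' @return The (possibly fitted) `pretreatment`.
#' @export
fit_pretreatment <- function(s, spec) {
  stopifnot(inherits(s, "spectra_set"), inherits(spec, "pretreatment"))
  if (!uses_msc(spec)) return(spec)
  if (nrow(s$values) < 2L) stop("MSC needs at least 2 calibration samples")
  v <- s$values
  if (uses_fd(spec)) {
    v <- t(apply(v, 1L, sg_derivative, grid = s$grid, order = 1L,
                 window = spec$sg_window, polyorder = spec$sg_polyorder))
  }
  spec$msc_reference <- colMeans(v)
  spec
}

#' Apply a pretreatment to every spectrum
#'
#' Combination methods apply the first derivative, then the scatter step on
#' the derivative spectra. `NONE` is the identity. Errors raised by the
#' per-spectrum operators are annotated with the offending sample id.
#'
#' @param s A [spectra_set()].
#' @param spec A [pretreatment()]; MSC-containing methods must be fitted
#'   first with [fit_pretreatment()].
#' @return A `spectra_set` of transformed values on the same grid.
#' @export
apply_pretreatment <- function(s, spec) {
  stopifnot(inherits(s, "spectra_set"), inherits(spec, "pretreatment"))
  out <- pretreat_matrix(s$values, s$grid, spec, ids = s$sample_ids)
  spectra_set(out, s$grid, sample_ids = s$sample_ids, mode = s$mode)
}

# matrix-level worker shared by apply_pretreatment and the CV refitter
pretreat_matrix <- function(v, grid, spec, ids = rownames(v)) {
  if (spec$method == "NONE") return(v)
  if (uses_msc(spec) && is.null(spec$msc_reference)) {
    stop("MSC reference not fitted; call fit_pretreatment() on the calibration set first")
  }
  if (uses_fd(spec)) {
    v <- t(apply(v, 1L, sg_derivative, grid = grid, order = 1L,
                 window = spec$sg_window, polyorder = spec$sg_polyorder))
  }
  step <- sub("^FD_?", "", spec$method)
  if (step == "") return(v)
  out <- v
  for (i in seq_len(nrow(v))) {
    out[i, ] <- tryCatch(
      switch(step,
             COE = coe(v[i, ]),
             SSL = ssl(v[i, ], grid),
             SNV = snv(v[i, ]),
             MMN = mmn(v[i, ]),
             MSC = msc(v[i, ], spec$msc_reference),
             SED = sg_derivative(v[i, ], grid, order = 2L,
                                 window = spec$sg_window,
                                 polyorder = spec$sg_polyorder)),
      error = function(e) {
        stop("pretreatment ", spec$method, " failed for sample ",
             if (is.null(ids)) i else ids[i], ": ", conditionMessage(e),
             call. = FALSE)
      })
  }
  out
}

#' Standard normal variate
#'
#' Per-spectrum standardization: subtract the mean, divide by the sample
#' standard deviation (n-1 denominator). Output has mean 0 and SD 1.
#'
#' @param x Numeric spectrum of at least 3 points with nonzero variance.
#' @return The standardized spectrum.
#' @export
snv <- function(x) {
  if (length(x) < 3L) stop("SNV needs at least 3 points")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero-variance spectrum in SNV")
  (x - mean(x)) / s
}

#' Multiplicative scatter correction
#'
#' Least-squares fit `x ~ a + b * reference`, then return `(x - a) / b`.
#' Inverts per-sample affine scatter distortion relative to the reference.
#'
#' @param x Numeric spectrum.
#' @param reference Reference spectrum of the same length, non-constant.
#' @return The corrected spectrum.
#' @export
msc <- function(x, reference) {
  if (length(x) != length(reference)) stop("spectrum/reference length mismatch")
  rc <- reference - mean(reference)
  den <- sum(rc^2)
  if (den == 0) stop("constant MSC reference")
  b <- sum(rc * (x - mean(x))) / den
  if (abs(b) < 1e-12) stop("degenerate scatter fit: slope ~ 0")
  a <- mean(x) - b * mean(reference)
  (x - a) / b
}

#' Constant offset elimination
#'
#' Subtracts the spectrum minimum, so the output minimum is 0.
#'
#' @param x Numeric spectrum.
#' @return The offset-corrected spectrum.
#' @export
coe <- function(x) x - min(x)

#' Straight-line subtraction
#'
#' Removes the least-squares straight line in wavenumber, leaving a residual
#' orthogonal to both the constant and the linear trend. Idempotent.
#'
#' @param x Numeric spectrum.
#' @param grid Wavenumbers, same length as `x`.
#' @return The detrended spectrum.
#' @export
ssl <- function(x, grid) {
  if (length(x) != length(grid)) stop("spectrum/grid length mismatch")
  g <- grid - mean(grid)
  b <- sum(g * x) / sum(g^2)
  x - mean(x) - b * g
}

#' Min-max normalization
#'
#' Rescales the spectrum linearly so its range is exactly `[0, 1]`.
#'
#' @param x Numeric, non-constant spectrum.
#' @return The normalized spectrum.
#' @export
mmn <- function(x) {
  r <- max(x) - min(x)
  if (r == 0) stop("constant spectrum in min-max normalization")
  (x - min(x)) / r
}

#' Savitzky-Golay derivative
#'
#' Smoothed derivative with respect to wavenumber, computed by local
#' polynomial regression over a moving window and scaled by the grid spacing
#' (units per cm^-1). Exact for polynomials of degree at most `polyorder`;
#' boundary points use the polynomial fit on the edge window, so the grid
#' length is preserved.
#'
#' @param x Numeric spectrum.
#' @param grid Uniformly spaced wavenumbers (relative tolerance 1e-6).
#' @param order Derivative order, 1 or 2.
#' @param window Odd window length in points, at most `length(x)`.
#' @param polyorder Local polynomial order, at least `order`.
#' @return The derivative spectrum, same length as `x`.
#' @export
sg_derivative <- function(x, grid, order = 1L, window = 17L, polyorder = 2L) {
  order <- as.integer(order)
  if (!order %in% c(1L, 2L)) stop("derivative order must be 1 or 2")
  if (length(x) != length(grid)) stop("spectrum/grid length mismatch")
  if (window > length(x)) stop("SG window larger than spectrum")
  if (polyorder < order) stop("polyorder must be at least the derivative order")
  h <- diff(grid)
  if (max(abs(h - h[1L])) > 1e-6 * abs(h[1L])) {
    stop("Savitzky-Golay derivative requires a uniform grid")
  }
  as.numeric(signal::sgolayfilt(x, p = polyorder, n = window, m = order,
                                ts = h[1L]))
}
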
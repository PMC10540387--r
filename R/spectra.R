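#' Construct a spectra set
#'
#' A `spectra_set` holds a wide spectral matrix: one row per sample, one
#' column per wavenumber. The wavenumber grid is always stored strictly
#' ascending in cm^-1; readers reorder descending instrument exports at the
#' boundary so everything downstream can assume one convention.
#'
#' @param values Numeric matrix, `n_samples x n_wavenumbers`, no missing
#'   values.
#' @param grid Numeric vector of wavenumbers in cm^-1, strictly increasing,
#'   length equal to `ncol(values)`.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to `rownames(values)`.
#' @param mode Either `"reflectance"` or `"absorbance"`.
#' @return An object of class `spectra_set` with fields `sample_ids`, `grid`,
#'   `values` and `mode`.
#' @examples
#' s <- spectra_set(matrix(runif(12), 3, 4), grid = c(4000, 5000, 6000, 7000),
#'                  sample_ids = c("A", "B", "C"))
#' s
#' @export
spectra_set <- function(values, grid, sample_ids = rownames(values),
                        mode = c("reflectance", "absorbance")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  sample_ids <- as.character(sample_ids)
  grid <- as.numeric(grid)
  if (nrow(values) < 1L) stop("spectra_set needs at least one sample")
  if (length(grid) != ncol(values)) {
    stop("grid length (", length(grid), ") does not match number of columns (",
         ncol(values), ")")
  }
  if (anyNA(values) || anyNA(grid)) stop("spectra_set does not allow missing values")
  if (length(grid) > 1L && any(diff(grid) <= 0)) {
    stop("wavenumber grid must be strictly increasing")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (length(sample_ids) != nrow(values)) {
    stop("sample_ids length does not match number of rows")
  }
  dimnames(values) <- list(sample_ids, NULL)
  structure(list(sample_ids = sample_ids, grid = grid, values = values,
                 mode = mode),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d wavenumbers (%s)\n",
              length(x$sample_ids), length(x$grid), x$mode))
  cat(sprintf("  grid: %.1f .. %.1f cm^-1\n", min(x$grid), max(x$grid)))
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$values)

#' Subset samples of a spectra set
#'
#' @param x A [spectra_set()].
#' @param i Row (sample) index: integer, logical, or sample-id character
#'   vector.
#' @param ... Ignored.
#' @return A `spectra_set` with the selected samples.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  if (is.character(i)) {
    idx <- match(i, x$sample_ids)
    if (anyNA(idx)) stop("unknown sample ids: ",
                         paste(i[is.na(idx)], collapse = ", "))
    i <- idx
  }
  spectra_set(x$values[i, , drop = FALSE], x$grid,
              sample_ids = x$sample_ids[i], mode = x$mode)
}

#' Read spectra from a wide CSV file
#'
#' Expected layout: first column `sample_id`, remaining column names are
#' wavenumbers in cm^-1. Files exported with a descending wavenumber axis
#' (common for FT-NIR instruments) are reordered to ascending on read.
#'
#' @param path Path to a CSV file.
#' @param mode Either `"reflectance"` or `"absorbance"`.
#' @return A [spectra_set()].
#' @seealso [write_spectra()]
#' @export
read_spectra <- function(path, mode = c("reflectance", "absorbance")) {
  mode <- match.arg(mode)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("spectra CSV needs a sample_id column plus spectral columns")
  ids <- as.character(df[[1L]])
  grid <- suppressWarnings(as.numeric(names(df)[-1L]))
  if (anyNA(grid)) stop("malformed grid: non-numeric wavenumber header")
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric spectral value in ", path)
  if (anyNA(vals)) stop("missing or non-numeric spectral value in ", path)
  ord <- order(grid)
  grid <- grid[ord]
  if (any(diff(grid) <= 0)) stop("malformed grid: duplicate wavenumbers in header")
  spectra_set(vals[, ord, drop = FALSE], grid, sample_ids = ids, mode = mode)
}

#' Write spectra to a wide CSV file
#'
#' Round-trips bit-identically with [read_spectra()] on values.
#'
#' @param s A [spectra_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(s, path) {
  stopifnot(inherits(s, "spectra_set"))
  # %.17g keeps doubles lossless through the text round trip
  vals <- apply(s$values, 2L, function(col) sprintf("%.17g", col))
  vals <- matrix(vals, nrow = nrow(s$values))
  lines <- c(paste(c("sample_id", sprintf("%.17g", s$grid)), collapse = ","),
             paste(s$sample_ids, apply(vals, 1L, paste, collapse = ","),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Convert reflectance spectra to absorbance
#'
#' Applies the usual `A = log10(1/R)` transform. The calibration pipeline is
#' agnostic to the representation; this is offered so reflectance exports can
#' be modeled on an absorbance scale when preferred.
#'
#' @param s A [spectra_set()] in reflectance mode with strictly positive
#'   values.
#' @return A `spectra_set` in absorbance mode.
#' @export
to_absorbance <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  if (s$mode != "reflectance") stop("spectra are already in absorbance mode")
  if (any(s$values <= 0)) stop("nonpositive reflectance cannot be converted to absorbance")
  spectra_set(log10(1 / s$values), s$grid, sample_ids = s$sample_ids,
              mode = "absorbance")
}

#' Define a set of wavenumber windows
#'
#' A `window_set` is a list of closed `[lo, hi]` intervals in cm^-1 used to
#' select spectral variables, in the style of range labels such as
#' "5669.7-9626.9, 10406-11200.6".
#'
#' @param intervals A list of length-2 numeric vectors `c(lo, hi)`, or a
#'   two-column matrix with one interval per row.
#' @return An object of class `window_set`.
#' @export
window_set <- function(intervals) {
  if (is.matrix(intervals)) {
    intervals <- lapply(seq_len(nrow(intervals)), function(i) intervals[i, ])
  }
  if (is.numeric(intervals) && length(intervals) == 2L) {
    intervals <- list(intervals)
  }
  intervals <- lapply(intervals, as.numeric)
  if (length(intervals) < 1L) stop("window_set needs at least one interval")
  for (iv in intervals) {
    if (length(iv) != 2L) stop("each interval must be a c(lo, hi) pair")
    if (!(iv[1L] < iv[2L])) stop("interval lower bound must be below upper bound")
  }
  o <- order(vapply(intervals, `[`, numeric(1), 1L))
  intervals <- intervals[o]
  if (length(intervals) > 1L) {
    his <- vapply(intervals, `[`, numeric(1), 2L)
    los <- vapply(intervals, `[`, numeric(1), 1L)
    if (any(los[-1L] <= his[-length(his)])) {
      stop("window intervals must be pairwise disjoint")
    }
  }
  structure(list(intervals = intervals), class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat("<window_set>", format_windows(x), "\n")
  invisible(x)
}

#' Format a window set as a range label
#'
#' @param w A [window_set()] or `NULL` (formatted as `"full"`).
#' @return A single string like `"5669.7-9626.9, 10406-11200.6"`.
#' @export
format_windows <- function(w) {
  if (is.null(w)) return("full")
  paste(vapply(w$intervals, function(iv)
    paste0(format(iv[1L], trim = TRUE), "-", format(iv[2L], trim = TRUE)),
    character(1)), collapse = ", ")
}

#' Restrict spectra to a set of wavenumber windows
#'
#' Keeps exactly the grid points falling inside some closed interval of `w`;
#' column order is preserved. Idempotent for a fixed window set.
#'
#' @param s A [spectra_set()].
#' @param w A [window_set()], or `NULL` for the identity.
#' @return A `spectra_set` on the restricted grid.
#' @export
apply_windows <- function(s, w) {
  stopifnot(inherits(s, "spectra_set"))
  if (is.null(w)) return(s)
  stopifnot(inherits(w, "window_set"))
  keep <- window_mask(s$grid, w)
  if (!any(keep)) {
    stop("empty selection: no grid point falls inside ", format_windows(w))
  }
  spectra_set(s$values[, keep, drop = FALSE], s$grid[keep],
              sample_ids = s$sample_ids, mode = s$mode)
}

window_mask <- function(grid, w) {
  keep <- rep(FALSE, length(grid))
  for (iv in w$intervals) {
    keep <- keep | (grid >= iv[1L] & grid <= iv[2L])
  }
  keep
}

#' Construct a reference trait table
#'
#' Holds per-sample laboratory reference values for one trait: rind
#' penetrometer resistance (RPR, N/mm^2) or breaking force (N).
#'
#' @param sample_ids Character vector of unique sample identifiers.
#' @param value Strictly positive numeric vector of trait values.
#' @param trait `"RPR"` or `"breaking_force"`.
#' @param units Measurement units; defaults to the conventional unit for the
#'   trait (`"N/mm^2"` for RPR, `"N"` for breaking force).
#' @return A `data.frame` of class `reference_table` with columns
#'   `sample_id`, `trait`, `value`, `units`.
#' @export
reference_table <- function(sample_ids, value,
                            trait = c("RPR", "breaking_force"),
                            units = NULL) {
  trait <- match.arg(trait)
  if (is.null(units)) units <- if (trait == "RPR") "N/mm^2" else "N"
  sample_ids <- as.character(sample_ids)
  value <- as.numeric(value)
  if (length(sample_ids) != length(value)) stop("ids and values differ in length")
  if (anyNA(value)) stop("reference values must not be missing")
  if (any(value <= 0)) stop("reference values must be strictly positive")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids in reference table")
  structure(data.frame(sample_id = sample_ids, trait = trait, value = value,
                       units = units, stringsAsFactors = FALSE),
            class = c("reference_table", "data.frame"))
}

#' Read a reference trait table from CSV
#'
#' Expected columns: `sample_id,trait,value,units`.
#'
#' @param path Path to a CSV file.
#' @return A [reference_table()].
#' @export
read_reference <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "trait", "value")
  if (!all(need %in% names(df))) {
    stop("reference CSV needs columns: ", paste(need, collapse = ", "))
  }
  trait <- unique(df$trait)
  if (length(trait) != 1L) stop("reference CSV must contain a single trait")
  reference_table(df$sample_id, df$value, trait = trait,
                  units = if ("units" %in% names(df)) df$units[1L] else NULL)
}

#' Write a reference trait table to CSV
#'
#' @param ref A [reference_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  utils::write.csv(as.data.frame(ref), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# align a reference table to a spectra set, erroring on mismatch;
# returns the numeric y in spectra order
align_reference <- function(s, ref) {
  idx <- match(s$sample_ids, ref$sample_id)
  if (anyNA(idx)) {
    stop("reference table is missing samples: ",
         paste(utils::head(s$sample_ids[is.na(idx)], 5L), collapse = ", "))
  }
  ref$value[idx]
}
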
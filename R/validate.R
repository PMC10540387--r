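#' Split samples into calibration and validation sets
#'
#' Seeded uniform split at the given ratio, after which the samples carrying
#' the global minimum and maximum reference values are swapped into the
#' calibration set (exchanging with randomly chosen non-extreme calibration
#' members so the counts are preserved). This keeps every prediction on the
#' validation set an interpolation: the validation range is contained in the
#' calibration range.
#'
#' @param ref A [reference_table()] with at least 10 samples.
#' @param ratio Calibration fraction in (0, 1); default 0.8 (a 4:1 split).
#' @param seed Integer seed; the split is reproducible given the seed.
#' @return An object of class `split_spec` with fields `calibration`,
#'   `validation` (id vectors), `ratio`, `seed`.
#' @export
split_calibration_validation <- function(ref, ratio = 0.8, seed = 1L) {
  stopifnot(inherits(ref, "data.frame"))
  n <- nrow(ref)
  if (n < 10L) stop("need at least 10 samples to split")
  if (!(ratio > 0 && ratio < 1)) stop("ratio must be strictly between 0 and 1")
  n_cal <- round(ratio * n)
  if (n_cal < 2L || n_cal > n - 1L) stop("ratio leaves an empty set")
  set.seed(as.integer(seed))
  ids <- ref$sample_id
  cal <- sort(sample.int(n, n_cal))
  val <- setdiff(seq_len(n), cal)
  extremes <- c(which.min(ref$value), which.max(ref$value))
  for (e in unique(extremes)) {
    if (e %in% val) {
      pool <- setdiff(cal, extremes)
      swap <- pool[sample.int(length(pool), 1L)]
      cal <- sort(c(setdiff(cal, swap), e))
      val <- sort(c(setdiff(val, e), swap))
    }
  }
  structure(list(calibration = ids[cal], validation = ids[val],
                 ratio = ratio, seed = as.integer(seed)),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %d calibration / %d validation (ratio %.2f, seed %d)\n",
              length(x$calibration), length(x$validation), x$ratio, x$seed))
  invisible(x)
}

# seeded contiguous segmentation of a permuted index; returns integer
# segment id per sample
cv_segments <- function(n, n_segments, seed) {
  n_segments <- as.integer(n_segments)
  if (n_segments < 2L || n_segments > n) {
    stop("n_segments must be between 2 and n")
  }
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  bounds <- floor(seq(0, n, length.out = n_segments + 1L))
  seg <- integer(n)
  for (g in seq_len(n_segments)) {
    seg[perm[(bounds[g] + 1L):bounds[g + 1L]]] <- g
  }
  seg
}

# one CV pass fitting each fold once at max_rank and reading off pooled
# held-out predictions for every lower rank; pretreatment statistics (MSC
# reference) are refit inside each fold when a stateful pretreatment is given
cv_curve <- function(X, y, max_rank, n_segments, seed,
                     pretreat = NULL, grid = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop("X and y sizes do not match")
  seg <- cv_segments(n, n_segments, seed)
  stateful <- !is.null(pretreat) && uses_msc(pretreat)
  if (!is.null(pretreat) && !stateful && pretreat$method != "NONE") {
    X <- pretreat_matrix(X, grid, pretreat)
    pretreat <- NULL
  }
  max_fold <- max(table(seg))
  cap <- min(max_rank, n - max_fold - 1L, ncol(X))
  if (cap < 1L) stop("too few samples per fold for even one component")
  pred <- matrix(NA_real_, n, cap)
  for (g in sort(unique(seg))) {
    tr <- seg != g
    Xtr <- X[tr, , drop = FALSE]
    Xte <- X[!tr, , drop = FALSE]
    if (stateful) {
      sp <- pretreat
      v <- Xtr
      if (uses_fd(sp)) {
        v <- t(apply(v, 1L, sg_derivative, grid = grid, order = 1L,
                     window = sp$sg_window, polyorder = sp$sg_polyorder))
      }
      sp$msc_reference <- colMeans(v)
      Xtr <- pretreat_matrix(Xtr, grid, sp)
      Xte <- pretreat_matrix(Xte, grid, sp)
    }
    fit <- fit_pls(Xtr, y[tr], cap)
    for (a in seq_len(cap)) {
      pred[!tr, a] <- predict(fit, Xte, rank = a)
    }
  }
  rmsecv <- sqrt(colMeans((pred - y)^2))
  ss_tot <- sum((y - mean(y))^2)
  r2cv <- 1 - colSums((pred - y)^2) / ss_tot
  list(predictions = pred, segments = seg, rmsecv = rmsecv, r2cv = r2cv,
       max_rank = cap)
}

#' Segmented internal cross-validation of a PLS calibration
#'
#' The calibration samples are shuffled (seeded) and divided into
#' `n_segments` contiguous near-equal groups; each group is predicted by a
#' model refit on the remaining groups — including any fold-local
#' pretreatment statistics such as the MSC reference, so no information
#' leaks into the held-out segment. Held-out predictions are pooled into
#' RMSECV and R2cv.
#'
#' @param X Numeric matrix of spectral variables (raw if `pretreat` is
#'   given, otherwise already pretreated).
#' @param y Reference values.
#' @param rank Number of latent variables.
#' @param n_segments Number of CV segments (default 10); `n_segments = n`
#'   gives leave-one-out.
#' @param seed Integer seed for the segment shuffle.
#' @param pretreat Optional [pretreatment()] refit inside each fold.
#' @param grid Wavenumber grid (required when `pretreat` needs it).
#' @return A list: `RMSECV`, `R2cv`, `predictions` (pooled, original
#'   order), `segments`.
#' @export
cross_validate <- function(X, y, rank, n_segments = 10L, seed = 1L,
                           pretreat = NULL, grid = NULL) {
  cv <- cv_curve(X, y, rank, n_segments, seed, pretreat, grid)
  if (cv$max_rank < rank) {
    stop("rank ", rank, " not reachable with these fold sizes (max ",
         cv$max_rank, ")")
  }
  list(RMSECV = cv$rmsecv[rank], R2cv = cv$r2cv[rank],
       predictions = cv$predictions[, rank], segments = cv$segments)
}

#' Choose the PLS rank by cross-validation
#'
#' Computes RMSECV for every rank up to `max_rank` in a single segmented CV
#' pass and returns, by default, the smallest rank whose RMSECV is within 2%
#' of the minimum (a parsimony rule guarding against overfitting the CV
#' curve); `parsimony = FALSE` gives the plain argmin.
#'
#' @inheritParams cross_validate
#' @param max_rank Largest rank to consider.
#' @param parsimony Apply the 2% parsimony rule (default `TRUE`).
#' @param tol Parsimony slack as a fraction of the minimum RMSECV.
#' @return The selected rank (integer) with the RMSECV curve attached as
#'   attribute `"rmsecv"`.
#' @export
select_rank <- function(X, y, max_rank, n_segments = 10L, seed = 1L,
                        pretreat = NULL, grid = NULL, parsimony = TRUE,
                        tol = 0.02) {
  cv <- cv_curve(X, y, max_rank, n_segments, seed, pretreat, grid)
  best <- if (parsimony) {
    min(which(cv$rmsecv <= (1 + tol) * min(cv$rmsecv)))
  } else {
    which.min(cv$rmsecv)
  }
  structure(as.integer(best), rmsecv = cv$rmsecv, r2cv = cv$r2cv)
}

#' External validation of a frozen PLS model
#'
#' Predictions come from the frozen model only; the validation samples must
#' be disjoint from the calibration set (an overlap signals leakage and is
#' an error). RPD uses the calibration-set reference SD stored in the model.
#'
#' @param m A [calibrate_model()] model.
#' @param s_val Validation [spectra_set()].
#' @param ref_val Matching [reference_table()].
#' @return A list: `RMSEP`, `R2ev`, `RPD`, `bias`, `n`, `predictions`.
#' @export
external_validate <- function(m, s_val, ref_val) {
  stopifnot(inherits(m, "pls_model"), inherits(s_val, "spectra_set"))
  if (length(s_val$sample_ids) < 2L) {
    stop("validation set too small: need at least 2 samples")
  }
  overlap <- intersect(s_val$sample_ids, m$calibration_ids)
  if (length(overlap) > 0L) {
    stop("leakage: validation samples also in the calibration set: ",
         paste(utils::head(overlap, 5L), collapse = ", "))
  }
  y <- align_reference(s_val, ref_val)
  pred <- predict(m, s_val)
  mt <- metrics(y, pred, sd_ref = m$sd_ref)
  list(RMSEP = mt$RMSE, R2ev = mt$R2, RPD = mt$RPD, bias = mt$bias,
       n = mt$n, predictions = pred)
}

#' Default window candidates for the model search
#'
#' Splits the grid span into `n_blocks` equal blocks and enumerates every
#' union of at most `max_runs` non-adjacent runs of consecutive blocks
#' (adjacent runs would merge into one). Covers the common one- and
#' two-interval range selections.
#'
#' @param grid Wavenumber grid.
#' @param n_blocks Number of equal blocks (default 10).
#' @param max_runs Maximum number of disjoint intervals (1 or 2).
#' @return A list of [window_set()] objects, first element the full range.
#' @export
default_window_candidates <- function(grid, n_blocks = 10L, max_runs = 2L) {
  b <- seq(min(grid), max(grid), length.out = n_blocks + 1L)
  runs <- list()
  for (i in seq_len(n_blocks)) {
    for (j in i:n_blocks) runs[[length(runs) + 1L]] <- c(i, j)
  }
  out <- list()
  for (r in runs) {
    out[[length(out) + 1L]] <- window_set(list(c(b[r[1L]], b[r[2L] + 1L])))
  }
  if (max_runs >= 2L) {
    for (r1 in runs) {
      for (r2 in runs) {
        if (r2[1L] >= r1[2L] + 2L) {
          out[[length(out) + 1L]] <- window_set(list(
            c(b[r1[1L]], b[r1[2L] + 1L]), c(b[r2[1L]], b[r2[2L] + 1L])))
        }
      }
    }
  }
  # put the full range first
  full <- which(vapply(out, function(w) length(w$intervals) == 1L &&
                         w$intervals[[1L]][1L] == b[1L] &&
                         w$intervals[[1L]][2L] == b[n_blocks + 1L],
                       logical(1)))
  c(out[full], out[-full])
}

# one leaderboard row: calibration + CV statistics for a fitted combination
stage_report <- function(model, y, cvres, rank, pretreat_label, window_label) {
  tr <- metrics(y, model$fit$fitted, sd_ref = stats::sd(y))
  data.frame(pretreatment = pretreat_label, windows = window_label,
             rank = rank, N = length(y), mean = mean(y), SD = stats::sd(y),
             RMSEC = tr$RMSE, R2 = tr$R2, RPD_cal = tr$RPD,
             RMSECV = cvres$RMSECV, R2cv = cvres$R2cv,
             RPD_cv = rpd(stats::sd(y), cvres$RMSECV),
             stringsAsFactors = FALSE)
}

#' Search pretreatment-by-window model combinations
#'
#' Evaluates every pretreatment x window-set pair by segmented
#' cross-validation with rank selection, and returns the full leaderboard
#' ranked by RMSECV (ties broken by higher R2cv, then lower rank). The best
#' model — high R2/R2cv, low RMSE, high RPD — is the first row.
#'
#' @param s Calibration [spectra_set()].
#' @param ref Matching [reference_table()].
#' @param candidate_pretreatments Character vector of method names or list
#'   of [pretreatment()] objects.
#' @param candidate_windows List of [window_set()] objects (`NULL` entries
#'   mean the full range).
#' @param max_rank Largest rank considered (default 15).
#' @param n_segments CV segments (default 10).
#' @param seed Integer seed governing segmentation.
#' @return An object of class `calibration_search`: `leaderboard`
#'   (data.frame), `models` (list of [calibrate_model()] fits in leaderboard
#'   order), `seed`, `settings`.
#' @export
grid_search <- function(s, ref, candidate_pretreatments = "NONE",
                        candidate_windows = list(NULL), max_rank = 15L,
                        n_segments = 10L, seed = 1L) {
  stopifnot(inherits(s, "spectra_set"))
  if (length(candidate_pretreatments) == 0L || length(candidate_windows) == 0L) {
    stop("candidate lists must be non-empty")
  }
  if (is.character(candidate_pretreatments)) {
    candidate_pretreatments <- lapply(candidate_pretreatments, pretreatment)
  }
  y <- align_reference(s, ref)
  rows <- list(); models <- list(); failures <- character()
  for (pt in candidate_pretreatments) {
    for (w in candidate_windows) {
      label <- paste(pt$method, format_windows(w))
      res <- tryCatch({
        sw <- apply_windows(s, w)
        rank <- select_rank(sw$values, y, max_rank = max_rank,
                            n_segments = n_segments, seed = seed,
                            pretreat = pt, grid = sw$grid)
        cvres <- list(RMSECV = attr(rank, "rmsecv")[rank],
                      R2cv = attr(rank, "r2cv")[rank])
        model <- calibrate_model(s, ref, pretreat = pt, windows = w,
                                 rank = as.integer(rank))
        list(row = stage_report(model, y, cvres, as.integer(rank),
                                pt$method, format_windows(w)),
             model = model)
      }, error = function(e) conditionMessage(e))
      if (is.character(res)) {
        failures <- c(failures, paste0(label, ": ", res))
      } else {
        rows[[length(rows) + 1L]] <- res$row
        models[[length(models) + 1L]] <- res$model
      }
    }
  }
  if (length(rows) == 0L) {
    stop("all candidate combinations failed:\n  ",
         paste(failures, collapse = "\n  "))
  }
  lb <- do.call(rbind, rows)
  o <- order(lb$RMSECV, -lb$R2cv, lb$rank)
  lb <- lb[o, , drop = FALSE]
  rownames(lb) <- NULL
  structure(list(leaderboard = lb, models = models[o], seed = as.integer(seed),
                 settings = list(max_rank = max_rank, n_segments = n_segments),
                 failures = failures),
            class = "calibration_search")
}

#' @export
print.calibration_search <- function(x, ...) {
  cat(sprintf("<calibration_search> %d combinations (seed %d)\n",
              nrow(x$leaderboard), x$seed))
  print(utils::head(x$leaderboard, 10L), digits = 4)
  invisible(x)
}

#' Recalibrate on the merged calibration + validation set
#'
#' Merges both halves of a split into one integrated calibration set and
#' reruns rank selection and cross-validation with the chosen pretreatment
#' and windows — the "global modeling" step after external validation.
#'
#' @param split A [split_calibration_validation()] split.
#' @param s Full [spectra_set()].
#' @param ref Full [reference_table()].
#' @param pretreat A [pretreatment()] or method name.
#' @param windows A [window_set()] or `NULL`.
#' @param max_rank,n_segments,seed As in [grid_search()].
#' @return A list of class `global_report`: `stage = "global"`, leaderboard
#'   row `report`, and the refitted `model`.
#' @export
global_recalibrate <- function(split, s, ref, pretreat = pretreatment("NONE"),
                               windows = NULL, max_rank = 15L,
                               n_segments = 10L, seed = 1L) {
  stopifnot(inherits(split, "split_spec"))
  if (is.character(pretreat)) pretreat <- pretreatment(pretreat)
  ids <- c(split$calibration, split$validation)
  su <- s[ids]
  refu <- ref[match(ids, ref$sample_id), , drop = FALSE]
  y <- refu$value
  sw <- apply_windows(su, windows)
  rank <- select_rank(sw$values, y, max_rank = max_rank,
                      n_segments = n_segments, seed = seed,
                      pretreat = pretreat, grid = sw$grid)
  cvres <- list(RMSECV = attr(rank, "rmsecv")[rank],
                R2cv = attr(rank, "r2cv")[rank])
  model <- calibrate_model(su, refu, pretreat = pretreat, windows = windows,
                           rank = as.integer(rank))
  structure(list(stage = "global",
                 report = stage_report(model, y, cvres, as.integer(rank),
                                       pretreat$method, format_windows(windows)),
                 model = model),
            class = "global_report")
}
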
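#' Build a replicate-level measurement table
#'
#' One row per biological replicate. RPR replicates carry five position peak
#' readings (five puncture positions per internode); breaking-force
#' replicates carry a single peak force in `p1`.
#'
#' @param genotype Genotype id per row.
#' @param trait `"RPR"` or `"breaking_force"` per row.
#' @param replicate Replicate index (1-6) per row.
#' @param peaks Numeric matrix of peak readings: 5 columns for RPR rows
#'   (`p1..p5`), breaking-force rows use `p1` with `p2..p5` as `NA`.
#' @param internode Optional internode index per row.
#' @return A `data.frame` of class `replicate_records` with columns
#'   `genotype`, `trait`, `internode`, `replicate`, `p1..p5`.
#' @export
replicate_records <- function(genotype, trait, replicate, peaks,
                              internode = NA_integer_) {
  peaks <- as.matrix(peaks)
  if (ncol(peaks) > 5L) stop("at most 5 position peaks per replicate")
  if (ncol(peaks) < 5L) {
    peaks <- cbind(peaks, matrix(NA_real_, nrow(peaks), 5L - ncol(peaks)))
  }
  colnames(peaks) <- paste0("p", 1:5)
  df <- data.frame(genotype = as.character(genotype), trait = as.character(trait),
                   internode = internode, replicate = as.integer(replicate),
                   peaks, stringsAsFactors = FALSE)
  bad <- df$trait == "RPR" & rowSums(!is.na(peaks)) != 5L
  if (any(bad)) stop("RPR replicates need exactly 5 position peaks")
  bad <- df$trait == "breaking_force" & rowSums(!is.na(peaks)) != 1L
  if (any(bad)) stop("breaking-force replicates carry a single peak reading")
  if (any(peaks <= 0, na.rm = TRUE)) stop("peak readings must be positive")
  structure(df, class = c("replicate_records", "data.frame"))
}

#' Reduce five RPR position readings to one internode value
#'
#' The internode RPR is the mean of the three readings that remain after
#' eliminating the maximum and the minimum. Under ties exactly one instance
#' of each is removed, so the result always equals the 3-point trimmed mean
#' and lies within the range of the inputs.
#'
#' @param peaks Numeric vector of exactly 5 peak readings.
#' @return The trimmed-mean internode value.
#' @export
reduce_rpr_positions <- function(peaks) {
  peaks <- as.numeric(peaks)
  if (length(peaks) != 5L || anyNA(peaks)) {
    stop("RPR position reduction needs exactly 5 readings")
  }
  mean(sort(peaks)[2:4])
}

# replicate-level value: trimmed mean for RPR, single peak otherwise
replicate_value <- function(rec) {
  if (rec$trait[1L] == "RPR") {
    apply(as.matrix(rec[, paste0("p", 1:5)]), 1L, reduce_rpr_positions)
  } else {
    rec$p1
  }
}

#' Summarize replicates per genotype
#'
#' Reduces each replicate to one value (trimmed mean of positions for RPR,
#' the single peak for breaking force), then reports the replicate mean,
#' sample SD, standard error `SE = SD / sqrt(n)`, and the relative deviation
#' `SD / mean * 100` (the replicate coefficient of variation, in %) per
#' genotype. All rows must share one trait.
#'
#' @param records A [replicate_records()] table for one trait (any number
#'   of genotypes, each with at least 2 replicates).
#' @return A `data.frame` of class `genotype_summary` with columns
#'   `genotype`, `trait`, `mean`, `sd`, `se`, `relative_deviation`,
#'   `n_replicates`.
#' @export
aggregate_genotype <- function(records) {
  stopifnot(inherits(records, "data.frame"))
  if (length(unique(records$trait)) != 1L) {
    stop("aggregate one trait at a time")
  }
  vals <- replicate_value(records)
  out <- lapply(split(seq_len(nrow(records)), records$genotype), function(i) {
    v <- vals[i]
    if (length(v) < 2L) {
      stop("genotype ", records$genotype[i[1L]], " has fewer than 2 replicates")
    }
    m <- mean(v); s <- stats::sd(v)
    data.frame(genotype = records$genotype[i[1L]], trait = records$trait[1L],
               mean = m, sd = s, se = s / sqrt(length(v)),
               relative_deviation = 100 * s / m, n_replicates = length(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("genotype_summary", "data.frame"))
}

#' Pearson correlation between two trait summaries
#'
#' Pairs genotypes by id (intersection only) and reports the Pearson
#' correlation with a two-sided t-test significance flag at `alpha`.
#'
#' @param a,b [aggregate_genotype()] summaries (or data.frames with
#'   `genotype` and `mean` columns) sharing at least 3 genotypes.
#' @param alpha Significance level for the flag (default 0.01).
#' @return A list: `r`, `n`, `p_value`, `significant`.
#' @export
trait_correlation <- function(a, b, alpha = 0.01) {
  shared <- intersect(a$genotype, b$genotype)
  if (length(shared) < 3L) stop("need at least 3 shared genotypes")
  x <- a$mean[match(shared, a$genotype)]
  y <- b$mean[match(shared, b$genotype)]
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), n = length(shared), p_value = ct$p.value,
       significant = ct$p.value < alpha)
}

#' Descriptive distribution summary
#'
#' Min/max/mean/SD plus a fixed-width histogram, for population variation
#' reporting.
#'
#' @param values Non-empty numeric vector.
#' @param bins Number of fixed-width bins (default 20).
#' @return A list: `min`, `max`, `mean`, `sd`, `n`, `breaks`, `counts`.
#' @export
descriptive_distribution <- function(values, bins = 20L) {
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values)) {
    stop("values must be non-empty and complete")
  }
  if (min(values) == max(values)) {
    breaks <- min(values) + c(-0.5, 0.5)
    counts <- length(values)
  } else {
    breaks <- seq(min(values), max(values), length.out = bins + 1L)
    h <- graphics::hist(values, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE)
    counts <- h$counts
  }
  list(min = min(values), max = max(values), mean = mean(values),
       sd = stats::sd(values), n = length(values),
       breaks = breaks, counts = counts)
}
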
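#' Configure the synthetic spectra/reference generator
#'
#' The generator emulates the statistical structure of a stalk-strength NIRS
#' study: reference traits follow a truncated normal with the population
#' mean/SD/range reported for each trait; absorbance spectra are sums of
#' Gaussian bands whose informative-band concentrations are affine in the
#' latent trait, with independent interferent bands, per-sample scatter
#' distortion (multiplicative slope, baseline offset, linear tilt) and
#' additive spectral noise; measured reference values add an independent
#' laboratory measurement error. The latent trait is returned alongside the
#' noisy observables, so the pipeline's irreducible error floor is known
#' exactly in tests.
#'
#' Trait defaults: RPR mean 42.0, SD 7.62, range 22.8-79.7 N/mm^2,
#' reference-error SD 0.94; breaking force mean 20.3, SD 6.08, range
#' 6.6-32.8 N, reference-error SD 1.15.
#'
#' @param trait `"RPR"` or `"breaking_force"`.
#' @param n_samples Number of samples (default 500).
#' @param seed Integer master seed.
#' @param trait_mean,trait_sd,trait_min,trait_max Population parameters;
#'   defaults depend on `trait` (above).
#' @param reference_error_sd SD of the lab measurement error added to the
#'   latent trait.
#' @param grid Wavenumber grid; default 4000-12000 cm^-1 in 1038 points.
#' @param n_informative_bands,n_interferent_bands Gaussian band counts
#'   (defaults 5 and 8).
#' @param band_width Gaussian band SD in cm^-1 (default 350).
#' @param trait_band_amplitude Informative-band concentration change per SD
#'   of the latent trait (default 0.15, against a baseline concentration of
#'   1): compositional variation stays a modest fraction of total intensity,
#'   so per-sample scatter — not chemistry — dominates amplitude variation,
#'   the regime scatter-corrective pretreatment addresses.
#' @param interferent_mean,interferent_sd Interferent-band concentration
#'   distribution (defaults 0.3 and 0.08).
#' @param scatter_mult_sd,scatter_offset_sd,scatter_tilt_sd Per-sample
#'   scatter coefficients: multiplicative slope `1 + N(0, mult_sd)`,
#'   baseline offset `N(0, offset_sd)`, linear tilt `N(0, tilt_sd)` across
#'   the grid span. Defaults 0.10 / 0.05 / 0.05.
#' @param noise_sd Additive per-point spectral noise SD (default 0.002
#'   absorbance units).
#' @param replicate_sd Between-replicate biological SD for
#'   [gen_replicates()]; default 2.1 (RPR) / 2.82 (breaking force), sized so
#'   6-replicate genotype standard errors land in the reported 0.57-1.19 /
#'   0.37-1.37 bands.
#' @param position_sd Within-internode position-to-position SD for RPR
#'   (default 2.0).
#' @param outlier_fraction Fraction of spectra corrupted by
#'   [inject_outliers()] when the simulation writer is asked for outliers.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(trait = c("RPR", "breaking_force"),
                             n_samples = 500L, seed = 1L,
                             trait_mean = NULL, trait_sd = NULL,
                             trait_min = NULL, trait_max = NULL,
                             reference_error_sd = NULL,
                             grid = seq(4000, 12000, length.out = 1038L),
                             n_informative_bands = 5L,
                             n_interferent_bands = 8L,
                             band_width = 350,
                             trait_band_amplitude = 0.15,
                             interferent_mean = 0.3,
                             interferent_sd = 0.08,
                             scatter_mult_sd = 0.10,
                             scatter_offset_sd = 0.05,
                             scatter_tilt_sd = 0.05,
                             noise_sd = 0.002,
                             replicate_sd = NULL,
                             position_sd = 2.0,
                             outlier_fraction = 0) {
  trait <- match.arg(trait)
  def <- if (trait == "RPR") {
    list(mean = 42.0, sd = 7.62, min = 22.8, max = 79.7, err = 0.94,
         rep = 2.1)
  } else {
    list(mean = 20.3, sd = 6.08, min = 6.6, max = 32.8, err = 1.15,
         rep = 2.82)
  }
  cfg <- list(
    trait = trait, n_samples = as.integer(n_samples), seed = as.integer(seed),
    trait_mean = trait_mean %||% def$mean, trait_sd = trait_sd %||% def$sd,
    trait_min = trait_min %||% def$min, trait_max = trait_max %||% def$max,
    reference_error_sd = reference_error_sd %||% def$err,
    grid = as.numeric(grid),
    n_informative_bands = as.integer(n_informative_bands),
    n_interferent_bands = as.integer(n_interferent_bands),
    band_width = band_width,
    trait_band_amplitude = trait_band_amplitude,
    interferent_mean = interferent_mean, interferent_sd = interferent_sd,
    scatter_mult_sd = scatter_mult_sd, scatter_offset_sd = scatter_offset_sd,
    scatter_tilt_sd = scatter_tilt_sd, noise_sd = noise_sd,
    replicate_sd = replicate_sd %||% def$rep, position_sd = position_sd,
    outlier_fraction = outlier_fraction)
  if (!(cfg$trait_min < cfg$trait_mean && cfg$trait_mean < cfg$trait_max)) {
    stop("trait bounds must satisfy min < mean < max")
  }
  sds <- c(cfg$trait_sd, cfg$reference_error_sd, cfg$scatter_mult_sd,
           cfg$scatter_offset_sd, cfg$scatter_tilt_sd, cfg$noise_sd,
           cfg$replicate_sd, cfg$position_sd)
  if (any(sds < 0)) stop("all SD parameters must be nonnegative")
  if (cfg$trait_sd == 0) stop("trait_sd must be positive")
  # fixed band layout: informative bands evenly spaced inside the grid,
  # widths constant; interferent centers interleaved deterministically
  span <- range(cfg$grid)
  cfg$informative_centers <- seq(span[1L] + 0.1 * diff(span),
                                 span[2L] - 0.1 * diff(span),
                                 length.out = cfg$n_informative_bands)
  cfg$interferent_centers <- if (cfg$n_interferent_bands > 0L) {
    seq(span[1L] + 0.05 * diff(span), span[2L] - 0.05 * diff(span),
        length.out = cfg$n_interferent_bands)
  } else numeric(0)
  if (any(c(cfg$informative_centers, cfg$interferent_centers) < span[1L] |
          c(cfg$informative_centers, cfg$interferent_centers) > span[2L])) {
    stop("band centers must lie inside the grid")
  }
  structure(cfg, class = "generator_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate reference trait values
#'
#' Latent trait values are drawn from a normal truncated to
#' `[trait_min, trait_max]` (inverse-CDF sampling); the measured reference
#' adds independent lab error of SD `reference_error_sd`, floored at a
#' small positive value so the table stays physically valid.
#'
#' @param cfg A [generator_config()].
#' @return A list: `reference` (a [reference_table()] of measured values)
#'   and `latent` (named numeric vector of noiseless trait values).
#' @export
gen_reference <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  if (cfg$trait_min >= cfg$trait_max) stop("degenerate truncation range")
  set.seed(cfg$seed)
  n <- cfg$n_samples
  lo <- stats::pnorm(cfg$trait_min, cfg$trait_mean, cfg$trait_sd)
  hi <- stats::pnorm(cfg$trait_max, cfg$trait_mean, cfg$trait_sd)
  u <- stats::runif(n, lo, hi)
  latent <- stats::qnorm(u, cfg$trait_mean, cfg$trait_sd)
  measured <- latent + stats::rnorm(n, 0, cfg$reference_error_sd)
  measured <- pmax(measured, 1e-6)
  ids <- sprintf("G%04d", seq_len(n))
  names(latent) <- ids
  list(reference = reference_table(ids, measured, trait = cfg$trait),
       latent = latent)
}

gauss_bands <- function(grid, centers, width) {
  vapply(centers, function(mu) exp(-0.5 * ((grid - mu) / width)^2),
         numeric(length(grid)))
}

#' Generate absorbance spectra from latent trait values
#'
#' Each pure spectrum is a sum of Gaussian bands: informative-band
#' concentrations are affine in the standardized latent trait (alternating
#' signs across bands), interferent-band concentrations are independent
#' noise. Scatter distortion `m_i * A_i + o_i + t_i * nu` and additive
#' spectral noise are then applied per sample (all seeded).
#'
#' @param truth Named latent trait vector from [gen_reference()].
#' @param cfg The same [generator_config()].
#' @param seed Seed for the spectral randomness; defaults to `cfg$seed + 1`
#'   so spectra noise is independent of the reference draw.
#' @return A [spectra_set()] in absorbance mode.
#' @export
gen_spectra <- function(truth, cfg, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(as.integer(seed))
  n <- length(truth)
  grid <- cfg$grid
  z <- (truth - cfg$trait_mean) / cfg$trait_sd
  B_info <- gauss_bands(grid, cfg$informative_centers, cfg$band_width)
  k <- cfg$n_informative_bands
  base <- rep(1, k)
  slope <- cfg$trait_band_amplitude * (-1)^(seq_len(k) - 1L)  # alternating band response
  conc_info <- outer(z, slope) + matrix(base, n, k, byrow = TRUE)
  A <- conc_info %*% t(B_info)
  if (cfg$n_interferent_bands > 0L) {
    B_int <- gauss_bands(grid, cfg$interferent_centers, cfg$band_width)
    conc_int <- matrix(stats::rnorm(n * cfg$n_interferent_bands,
                                    cfg$interferent_mean, cfg$interferent_sd),
                       n, cfg$n_interferent_bands)
    A <- A + conc_int %*% t(B_int)
  }
  m <- 1 + stats::rnorm(n, 0, cfg$scatter_mult_sd)
  m <- pmax(m, 0.2)
  o <- stats::rnorm(n, 0, cfg$scatter_offset_sd)
  t <- stats::rnorm(n, 0, cfg$scatter_tilt_sd)
  nu <- (grid - mean(grid)) / diff(range(grid))   # in [-0.5, 0.5]
  A <- A * m + outer(o, rep(1, length(grid))) + outer(t, nu)
  if (cfg$noise_sd > 0) {
    A <- A + matrix(stats::rnorm(n * length(grid), 0, cfg$noise_sd),
                    n, length(grid))
  }
  spectra_set(A, grid, sample_ids = names(truth), mode = "absorbance")
}

#' Export absorbance spectra as reflectance
#'
#' `R = 10^(-A)`; exercises the reflectance input path of the pipeline.
#'
#' @param s A [spectra_set()] in absorbance mode.
#' @return A `spectra_set` in reflectance mode.
#' @export
as_reflectance <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  if (s$mode != "absorbance") stop("spectra are not in absorbance mode")
  spectra_set(10^(-s$values), s$grid, sample_ids = s$sample_ids,
              mode = "reflectance")
}

#' Generate replicate-level laboratory records
#'
#' Per genotype, 6 biological replicates. RPR replicates expand into 5
#' position peak readings (replicate effect SD `replicate_sd`, position
#' noise SD `position_sd`); breaking-force replicates carry one peak with SD
#' `replicate_sd`. With the defaults, 6-replicate genotype standard errors
#' fall in the reported measurement-error bands.
#'
#' @param truth Named latent trait vector.
#' @param cfg A [generator_config()].
#' @param seed Seed; defaults to `cfg$seed + 2`.
#' @return A [replicate_records()] table with `6 * length(truth)` rows.
#' @export
gen_replicates <- function(truth, cfg, seed = cfg$seed + 2L) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(as.integer(seed))
  n <- length(truth); n_rep <- 6L
  geno <- rep(names(truth), each = n_rep)
  repl <- rep(seq_len(n_rep), times = n)
  rep_eff <- stats::rnorm(n * n_rep, 0, cfg$replicate_sd)
  center <- rep(truth, each = n_rep) + rep_eff
  if (cfg$trait == "RPR") {
    peaks <- matrix(rep(center, 5L), ncol = 5L) +
      matrix(stats::rnorm(n * n_rep * 5L, 0, cfg$position_sd), ncol = 5L)
    peaks <- pmax(peaks, 1e-6)
  } else {
    peaks <- cbind(pmax(center, 1e-6),
                   matrix(NA_real_, n * n_rep, 4L))
  }
  replicate_records(geno, cfg$trait, repl, peaks)
}

#' Inject gross scatter outliers into a spectra set
#'
#' Corrupted samples receive a gross baseline artifact — an offset, a linear
#' tilt and a quadratic bow across the grid, each of amplitude `magnitude`
#' with a sign pattern cycled over all eight combinations (in seeded random
#' order) — heterogeneous gross scatter defects of the kind a GH screen is
#' meant to catch. Spreading the corruption over the three-shape space
#' keeps a group of outliers from collapsing onto a single score direction,
#' which would otherwise mask them from a Mahalanobis screen fitted with
#' the outliers included.
#' Returns the corrupted spectra and the ground-truth flags for recall
#' scoring.
#'
#' @param s A [spectra_set()].
#' @param fraction Fraction of samples to corrupt; `round(fraction * n)`
#'   samples are chosen.
#' @param magnitude Corruption amplitude in absorbance units.
#' @param seed Integer seed.
#' @return A list: `spectra` (corrupted `spectra_set`) and `truth` (logical
#'   vector, `TRUE` for corrupted samples).
#' @export
inject_outliers <- function(s, fraction, magnitude, seed = 1L) {
  stopifnot(inherits(s, "spectra_set"))
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  n <- nrow(s$values)
  n_out <- round(fraction * n)
  truth <- rep(FALSE, n)
  if (n_out == 0L) return(list(spectra = s, truth = truth))
  set.seed(as.integer(seed))
  idx <- sample.int(n, n_out)
  truth[idx] <- TRUE
  nu <- (s$grid - mean(s$grid)) / diff(range(s$grid))
  shapes <- cbind(1, nu, nu^2 - mean(nu^2))
  v <- s$values
  patterns <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  patterns <- patterns[sample.int(8L), , drop = FALSE]
  coefs <- patterns[((seq_len(n_out) - 1L) %% 8L) + 1L, , drop = FALSE] *
    magnitude
  for (j in seq_along(idx)) {
    v[idx[j], ] <- v[idx[j], ] + as.numeric(shapes %*% coefs[j, ])
  }
  list(spectra = spectra_set(v, s$grid, sample_ids = s$sample_ids,
                             mode = s$mode),
       truth = truth)
}

#' Simulate a complete synthetic study and write its files
#'
#' Writes the spectra CSV, reference CSV, replicate CSV and a truth JSON
#' (latent values, outlier flags, config echo, seed) to a directory.
#'
#' @param cfg A [generator_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
simulate_dataset <- function(cfg, dir) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  gr <- gen_reference(cfg)
  sp <- gen_spectra(gr$latent, cfg)
  flags <- rep(FALSE, cfg$n_samples)
  if (cfg$outlier_fraction > 0) {
    out <- inject_outliers(sp, cfg$outlier_fraction,
                           magnitude = 10 * cfg$scatter_offset_sd,
                           seed = cfg$seed + 3L)
    sp <- out$spectra
    flags <- out$truth
  }
  reps <- gen_replicates(gr$latent, cfg)
  paths <- list(spectra = file.path(dir, "spectra.csv"),
                reference = file.path(dir, "reference.csv"),
                replicates = file.path(dir, "replicates.csv"),
                truth = file.path(dir, "truth.json"))
  write_spectra(sp, paths$spectra)
  write_reference(gr$reference, paths$reference)
  utils::write.csv(as.data.frame(reps), paths$replicates, row.names = FALSE)
  cfg_echo <- unclass(cfg)
  cfg_echo$grid <- NULL
  cfg_echo$grid_span <- range(cfg$grid)
  cfg_echo$grid_points <- length(cfg$grid)
  jsonlite::write_json(
    list(seed = cfg$seed, latent = as.list(gr$latent),
         outlier_flags = flags, config = cfg_echo),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(spectra = sp, reference = gr$reference, latent = gr$latent,
                 replicates = reps, outlier_flags = flags, paths = paths))
}
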
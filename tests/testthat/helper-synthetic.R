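# shared fixture builders; everything is generated in code at test time

toy_grid <- function(p = 20, from = 4000, by = 100) {
  seq(from, by = by, length.out = p)
}

toy_spectra <- function(n = 5, p = 20, seed = 1) {
  set.seed(seed)
  spectra_set(matrix(stats::runif(n * p, 0.1, 1), n, p), toy_grid(p),
              sample_ids = sprintf("S%02d", seq_len(n)),
              mode = "absorbance")
}

# desk-scale generator: fewer samples and a coarser grid than the defaults,
# all other structure identical
small_config <- function(seed, n = 120, p = 200, ...) {
  generator_config(n_samples = n, seed = seed,
                   grid = seq(4000, 12000, length.out = p), ...)
}

small_dataset <- function(seed, n = 120, p = 200, ...) {
  cfg <- small_config(seed, n = n, p = p, ...)
  gr <- gen_reference(cfg)
  list(cfg = cfg, reference = gr$reference, latent = gr$latent,
       spectra = gen_spectra(gr$latent, cfg))
}

ref_subset <- function(ref, ids) ref[match(ids, ref$sample_id), , drop = FALSE]
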
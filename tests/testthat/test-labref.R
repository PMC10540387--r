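test_that("RPR position reduction is the 3-point trimmed mean", {
  expect_equal(reduce_rpr_positions(c(40, 42, 45, 38, 50)),
               mean(c(40, 42, 45)))
  expect_equal(reduce_rpr_positions(rep(10, 5)), 10)  # ties
  expect_error(reduce_rpr_positions(c(40, 42, 45, 38)), "exactly 5")
  set.seed(71)
  for (i in 1:25) {
    peaks <- runif(5, 10, 80)
    got <- reduce_rpr_positions(peaks)
    expect_equal(got, mean(sort(peaks)[2:4]))  # independent sort oracle
    expect_gte(got, min(peaks))
    expect_lte(got, max(peaks))
  }
})

test_that("genotype aggregation computes mean, SD, SE and relative deviation", {
  rec <- replicate_records(rep("G1", 6), "RPR", 1:6,
                           matrix(42, 6, 5))
  out <- aggregate_genotype(rec)
  expect_equal(out$mean, 42)
  expect_equal(out$se, 0)
  expect_equal(out$relative_deviation, 0)
  # two replicates with values 40 and 44: closed form
  rec2 <- replicate_records(rep("G2", 2), "breaking_force", 1:2,
                            matrix(c(40, 44), 2, 1))
  out2 <- aggregate_genotype(rec2)
  expect_equal(out2$mean, 42)
  expect_equal(out2$sd, 2 * sqrt(2))
  expect_equal(out2$se, 2)
  expect_equal(out2$relative_deviation, 100 * 2 * sqrt(2) / 42)
  expect_equal(out2$se, out2$sd / sqrt(out2$n_replicates))
  # mixed traits in one call are rejected
  mixed <- rbind(as.data.frame(rec), as.data.frame(rec2))
  expect_error(aggregate_genotype(mixed), "one trait")
})

test_that("replicate_records validates peak structure", {
  expect_error(replicate_records("G1", "RPR", 1, matrix(1, 1, 4)),
               "exactly 5")
  expect_error(replicate_records("G1", "breaking_force", 1, matrix(1, 1, 5)),
               "single peak")
  expect_error(replicate_records("G1", "breaking_force", 1,
                                 matrix(-3, 1, 1)), "positive")
})

test_that("synthetic replicate errors land in the reported SE band", {
  cfg <- generator_config(n_samples = 200, seed = 72)
  gr <- gen_reference(cfg)
  rec <- gen_replicates(gr$latent, cfg)
  expect_equal(nrow(rec), 200 * 6)
  summ <- aggregate_genotype(rec)
  expect_equal(nrow(summ), 200)
  # pooled standard error inside the reported 0.57-1.19 band for RPR
  expect_gt(mean(summ$se), 0.57)
  expect_lt(mean(summ$se), 1.19)
  # median replicate-level relative deviation in the plausible 2-10% range
  expect_gt(median(summ$relative_deviation), 2)
  expect_lt(median(summ$relative_deviation), 10)
})

test_that("genotype SE scales as 1/sqrt(n) on resampled replicates", {
  set.seed(73)
  n_geno <- 100
  se_for <- function(n_rep) {
    vals <- matrix(50 + rnorm(n_geno * n_rep, sd = 2), n_geno, n_rep)
    rec <- replicate_records(rep(sprintf("G%03d", 1:n_geno), each = n_rep),
                             "breaking_force",
                             rep(1:n_rep, n_geno),
                             matrix(as.numeric(t(vals)), ncol = 1))
    mean(aggregate_genotype(rec)$se)
  }
  ratio <- se_for(24) / se_for(6)
  expect_equal(ratio, 0.5, tolerance = 0.1)
})

test_that("trait correlation pairs genotypes and tests significance", {
  a <- data.frame(genotype = sprintf("G%02d", 1:20), mean = 1:20)
  b <- data.frame(genotype = sprintf("G%02d", 1:20), mean = 2 * (1:20) + 1)
  expect_equal(trait_correlation(a, b)$r, 1, tolerance = 1e-12)
  b$mean <- -a$mean
  expect_equal(trait_correlation(a, b)$r, -1, tolerance = 1e-12)
  # only the intersection of genotypes is used
  b2 <- data.frame(genotype = sprintf("G%02d", 11:30), mean = rnorm(20))
  expect_equal(trait_correlation(a, b2)$n, 10)
  expect_error(trait_correlation(a[1:2, ], b[1:2, ]), "3 shared")
})

test_that("independent traits rarely show spurious correlation at n = 245", {
  set.seed(74)
  small <- replicate(100, {
    x <- rnorm(245); y <- rnorm(245)
    abs(cor(x, y)) < 0.2
  })
  expect_gte(mean(small), 0.95)
})

test_that("descriptive distribution summarizes range, moments and bins", {
  d <- descriptive_distribution(c(1, 2, 3))
  expect_equal(d$min, 1); expect_equal(d$max, 3); expect_equal(d$mean, 2)
  dc <- descriptive_distribution(rep(5, 10))
  expect_equal(dc$sd, 0)
  expect_equal(sum(dc$counts > 0), 1)
  expect_error(descriptive_distribution(numeric(0)), "non-empty")
  # synthetic RPR population matches the configured moments
  cfg <- generator_config(n_samples = 500, seed = 75)
  gr <- gen_reference(cfg)
  ds <- descriptive_distribution(gr$reference$value)
  expect_lt(abs(ds$mean - 42.0), 1.0)
  expect_lt(abs(ds$sd - 7.62), 1.0)
  expect_equal(sum(ds$counts), 500)
})
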
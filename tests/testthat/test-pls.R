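test_that("rank-1 PLS is exact when y is proportional to one variable", {
  set.seed(41)
  X <- matrix(rnorm(60), 20, 3)
  y <- 2.5 * X[, 2]
  X[, c(1, 3)] <- 0
  fit <- fit_pls(X, y, rank = 1)
  expect_equal(fit$fitted, y, tolerance = 1e-10)
  expect_equal(metrics(y, fit$fitted)$RMSE, 0, tolerance = 1e-10)
})

test_that("a small exact system is solved at full rank", {
  X <- rbind(c(1, 0), c(0, 1), c(1, 1))
  y <- c(1, 2, 3)  # y = x1 + 2*x2
  fit <- fit_pls(X, y, rank = 2)
  expect_equal(fit$fitted, y, tolerance = 1e-10)
  # normal-equations oracle on the centered system
  Xc <- scale(X, scale = FALSE)
  beta <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  expect_equal(fit$coefficients, as.numeric(beta), tolerance = 1e-8)
})

test_that("full-rank PLS equals the OLS solution on random instances", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(10:50, 1)
    p <- sample(2:min(20, n - 1), 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    fit <- fit_pls(X, y, rank = p)
    Xc <- scale(X, scale = FALSE)
    beta <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
    expect_equal(fit$coefficients, as.numeric(beta), tolerance = 1e-6)
  }
})

test_that("NIPALS scores are mutually orthogonal and RMSEC is monotone", {
  set.seed(43)
  X <- matrix(rnorm(200), 20, 10)
  y <- rnorm(20)
  fit <- fit_pls(X, y, rank = 8)
  G <- crossprod(fit$scores)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / max(diag(G)), 1e-8)
  rmsec <- sapply(1:8, function(a) {
    sqrt(mean((predict(fit, X, rank = a) - y)^2))
  })
  expect_true(all(diff(rmsec) <= 1e-10))
})

test_that("degenerate ranks are rejected with the failing component named", {
  set.seed(44)
  X <- matrix(rnorm(30), 10, 3)
  X[, 3] <- X[, 1] + X[, 2]  # data rank 2
  y <- rnorm(10)
  expect_error(fit_pls(X, y, rank = 3), "component 3")
  expect_error(fit_pls(X, y, rank = 0), "between")
  expect_error(fit_pls(X, y, rank = 4), "between")
})

test_that("prediction on the calibration set reproduces fitted values", {
  d <- small_dataset(45, n = 40, p = 60)
  m <- calibrate_model(d$spectra, d$reference, pretreat = "SNV", rank = 4)
  pred <- predict(m, d$spectra)
  expect_equal(unname(pred), m$fit$fitted, tolerance = 1e-12)
  # centering identity: mean prediction over the calibration set is y_mean
  expect_equal(mean(pred), m$y_mean, tolerance = 1e-10)
})

test_that("metrics reproduce the published worked RPD examples", {
  # RPR cross-validation row: SD 7.62, RMSECV 0.74 -> RPD 10.30
  y_obs <- c(40, 44)
  y_hat <- y_obs + c(0.74, -0.74)   # RMSE exactly 0.74
  m1 <- metrics(y_obs, y_hat, sd_ref = 7.62)
  expect_equal(m1$RMSE, 0.74, tolerance = 1e-12)
  expect_equal(round(m1$RPD, 2), 10.30)
  # breaking-force cross-validation row: SD 6.08, RMSECV 2.51 -> RPD 2.42
  m2 <- metrics(c(18, 22), c(18, 22) + c(2.51, -2.51), sd_ref = 6.08)
  expect_equal(round(m2$RPD, 2), 2.42)
})

test_that("metrics handle edge cases as declared", {
  y <- c(1, 2, 3, 4)
  expect_equal(metrics(y, rep(mean(y), 4))$R2, 0)
  perfect <- metrics(y, y, sd_ref = 1)
  expect_identical(perfect$RPD, Inf)
  expect_equal(perfect$RMSE, 0)
  expect_error(metrics(y, y[1:3]), "mismatch")
  expect_error(metrics(y, y, sd_ref = 0), "positive")
})

test_that("leave-one-out CV equals the brute-force refitting oracle", {
  set.seed(46)
  n <- 20
  X <- matrix(rnorm(n * 8), n, 8)
  y <- X %*% rnorm(8) + rnorm(n, sd = 0.3)
  cv <- cross_validate(X, y, rank = 3, n_segments = n, seed = 47)
  oracle <- sapply(seq_len(n), function(i) {
    fit <- fit_pls(X[-i, ], y[-i], rank = 3)
    predict(fit, X[i, , drop = FALSE])
  })
  expect_equal(cv$predictions, oracle, tolerance = 1e-12)
  expect_equal(cv$RMSECV, sqrt(mean((oracle - y)^2)), tolerance = 1e-12)
})

test_that("cross-validation is deterministic and exact on noiseless data", {
  set.seed(48)
  X <- matrix(rnorm(200), 40, 5)
  y <- as.numeric(X %*% c(1, -2, 0.5, 3, 1)) + 7
  cv <- cross_validate(X, y, rank = 5, n_segments = 8, seed = 49)
  expect_lt(cv$RMSECV, 1e-8)
  cv2 <- cross_validate(X, y, rank = 5, n_segments = 8, seed = 49)
  expect_identical(cv$segments, cv2$segments)
  expect_identical(cv$predictions, cv2$predictions)
  expect_error(cross_validate(X, y, rank = 5, n_segments = 1, seed = 1),
               "n_segments")
})

test_that("rank selection follows the CV curve with the parsimony rule", {
  # three latent factors, low noise: selected rank stays small
  set.seed(50)
  n <- 80; p <- 40
  L <- matrix(rnorm(3 * p), 3, p)
  f <- matrix(rnorm(n * 3), n, 3)
  X <- f %*% L + matrix(rnorm(n * p, sd = 0.01), n, p)
  y <- as.numeric(f %*% c(2, -1, 0.5)) + rnorm(n, sd = 0.05)
  r <- select_rank(X, y, max_rank = 10, n_segments = 5, seed = 51)
  expect_lte(as.integer(r), 5)
  expect_lt(attr(r, "rmsecv")[r], 0.1)
  # pure-noise response: no overfitting escape
  y_noise <- rnorm(n)
  rn <- select_rank(X, y_noise, max_rank = 10, n_segments = 5, seed = 52)
  expect_lte(attr(rn, "r2cv")[rn], 0.2)
  # max_rank 1 returns 1
  expect_equal(as.integer(select_rank(X, y, max_rank = 1, n_segments = 5,
                                      seed = 53)), 1L)
  # argmin mode never selects a higher-RMSECV rank than the parsimony rule
  ra <- select_rank(X, y, max_rank = 10, n_segments = 5, seed = 51,
                    parsimony = FALSE)
  expect_lte(attr(ra, "rmsecv")[ra], attr(r, "rmsecv")[r])
})

test_that("calibration/validation splits respect ratio, extremes and seed", {
  ref <- reference_table(sprintf("S%02d", 1:10), 1:10 + 20, trait = "RPR")
  sp <- split_calibration_validation(ref, ratio = 0.8, seed = 54)
  expect_equal(length(sp$calibration), 8)
  expect_equal(length(sp$validation), 2)
  expect_setequal(c(sp$calibration, sp$validation), ref$sample_id)
  expect_true(all(c("S01", "S10") %in% sp$calibration))
  # n = 526 at 4:1 gives 421/105 by the rounding rule
  ref2 <- reference_table(sprintf("G%03d", 1:526), runif(526, 20, 80),
                          trait = "RPR")
  sp2 <- split_calibration_validation(ref2, ratio = 0.8, seed = 55)
  expect_equal(length(sp2$calibration), 421)
  expect_equal(length(sp2$validation), 105)
  # determinism
  sp3 <- split_calibration_validation(ref2, ratio = 0.8, seed = 55)
  expect_identical(sp2$calibration, sp3$calibration)
  expect_error(split_calibration_validation(ref, ratio = 1.2), "between")
  expect_error(split_calibration_validation(ref[1:5, ], ratio = 0.8),
               "at least 10")
})

test_that("external validation guards against leakage and small sets", {
  d <- small_dataset(56, n = 60, p = 80)
  sp <- split_calibration_validation(d$reference, 0.8, seed = 57)
  m <- calibrate_model(d$spectra[sp$calibration],
                       ref_subset(d$reference, sp$calibration),
                       pretreat = "SNV", rank = 5)
  ev <- external_validate(m, d$spectra[sp$validation],
                          ref_subset(d$reference, sp$validation))
  expect_true(ev$RMSEP >= 0)
  expect_lte(ev$R2ev, 1)
  expect_equal(ev$n, length(sp$validation))
  expect_error(external_validate(m, d$spectra[sp$calibration[1:5]],
                                 d$reference), "leakage")
  expect_error(external_validate(m, d$spectra[sp$validation[1]],
                                 d$reference), "too small")
})

test_that("grid search ranks combinations by RMSECV with full bookkeeping", {
  d <- small_dataset(58, n = 80, p = 120)
  gs <- grid_search(d$spectra, d$reference,
                    candidate_pretreatments = c("NONE", "SNV"),
                    candidate_windows = list(NULL,
                                             window_set(c(5000, 11000))),
                    max_rank = 8, n_segments = 5, seed = 59)
  lb <- gs$leaderboard
  expect_equal(nrow(lb), 4)
  expect_true(all(diff(lb$RMSECV) >= 0))
  expect_equal(lb$RPD_cv, lb$SD / lb$RMSECV, tolerance = 1e-12)
  expect_equal(lb$RPD_cal, lb$SD / lb$RMSEC, tolerance = 1e-12)
  expect_true(all(lb$N == 80))
  # single-candidate search yields a single-row leaderboard
  gs1 <- grid_search(d$spectra, d$reference, "NONE", list(NULL),
                     max_rank = 5, n_segments = 5, seed = 59)
  expect_equal(nrow(gs1$leaderboard), 1)
  # every candidate failing raises an aggregate error
  expect_error(grid_search(d$spectra, d$reference, "NONE",
                           list(window_set(c(1, 2))),
                           max_rank = 5, n_segments = 5, seed = 59),
               "all candidate")
})

test_that("the default window candidates enumerate block runs", {
  g <- seq(4000, 12000, length.out = 100)
  cands <- default_window_candidates(g, n_blocks = 10, max_runs = 2)
  # 55 single runs + 330 disjoint pairs
  expect_equal(length(cands), 385)
  n_int <- vapply(cands, function(w) length(w$intervals), integer(1))
  expect_true(all(n_int <= 2))
  expect_equal(cands[[1]]$intervals[[1]], c(4000, 12000))
  # every candidate selects at least one grid point
  for (w in cands[seq(1, 385, by = 40)]) {
    expect_gt(ncol(apply_windows(toy_spectra(2, 100), w)$values), 0)
  }
})

test_that("global recalibration merges both sets and reports the union", {
  d <- small_dataset(60, n = 60, p = 80)
  sp <- split_calibration_validation(d$reference, 0.8, seed = 61)
  g <- global_recalibrate(sp, d$spectra, d$reference, pretreat = "SNV",
                          max_rank = 6, n_segments = 5, seed = 61)
  expect_identical(g$stage, "global")
  expect_equal(g$report$N, length(sp$calibration) + length(sp$validation))
  expect_equal(length(g$model$calibration_ids), 60)
})
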
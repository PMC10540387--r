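test_that("SNV standardizes to mean 0 and sample SD 1", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  expect_equal(snv(c(2, 4, 6)), c(-1, 0, 1))  # scale invariance
  expect_error(snv(c(5, 5, 5)), "zero-variance")
  expect_error(snv(c(1, 2)), "3 points")
  set.seed(11)
  for (i in 1:20) {
    x <- rnorm(sample(10:200, 1)) * runif(1, 0.01, 100) + runif(1, -50, 50)
    out <- snv(x)
    expect_lt(abs(mean(out)), 1e-10)
    expect_lt(abs(sd(out) - 1), 1e-10)
  }
})

test_that("MSC inverts affine scatter distortion", {
  set.seed(12)
  ref <- rnorm(50)
  expect_equal(msc(1 + 2 * ref, ref), ref)
  expect_equal(msc(ref, ref), ref)
  expect_error(msc(rnorm(50), rep(1, 50)), "constant")
  expect_error(msc(ref + 1e-15 * rnorm(50) - ref + 0.5, ref), "degenerate")
  # invariance under x -> a*x + b for a > 0
  for (i in 1:20) {
    x <- rnorm(80)
    a <- runif(1, 0.1, 5); b <- runif(1, -3, 3)
    expect_equal(msc(a * x + b, ref[1:80 %% 50 + 1]),
                 msc(x, ref[1:80 %% 50 + 1]), tolerance = 1e-8)
  }
})

test_that("COE subtracts the minimum and is offset invariant", {
  expect_equal(coe(c(0.5, 0.2, 0.9)), c(0.3, 0.0, 0.7))
  expect_equal(coe(rep(0, 5)), rep(0, 5))
  set.seed(13)
  x <- rnorm(40)
  expect_equal(coe(x + 7.3), coe(x))
})

test_that("SSL removes the least-squares line and is idempotent", {
  g <- toy_grid(25)
  expect_equal(ssl(3 * g + 7, g), rep(0, 25))
  set.seed(14)
  x <- rnorm(25)
  once <- ssl(x, g)
  expect_equal(ssl(once, g), once)
  # orthogonal to {1, grid}
  expect_lt(abs(sum(once)), 1e-8)
  expect_lt(abs(sum(once * (g - mean(g)))), 1e-6)
  # quadratic on a symmetric grid: line fit is flat, residual = g^2 - mean
  gs <- seq(-10, 10, by = 1)
  expect_equal(ssl(gs^2, gs), gs^2 - mean(gs^2))
  # general oracle: lm residuals
  x <- rnorm(25, sd = 3)
  expect_equal(ssl(x, g), unname(residuals(lm(x ~ g))), tolerance = 1e-10)
})

test_that("MMN maps the range to [0, 1] and ignores positive affine maps", {
  expect_equal(mmn(c(0.2, 0.6, 1.0)), c(0, 0.5, 1))
  set.seed(15)
  x <- rnorm(30)
  expect_equal(mmn(2.7 * x + 11), mmn(x))
  expect_equal(range(mmn(x)), c(0, 1))
  expect_error(mmn(rep(2, 5)), "constant")
})

test_that("SG derivatives are exact on polynomials at every point", {
  g <- toy_grid(60, by = 8)
  expect_equal(sg_derivative(3 * g + 7, g, order = 1, window = 17,
                             polyorder = 2),
               rep(3, 60))
  expect_equal(sg_derivative(g^2, g, order = 2, window = 17, polyorder = 2),
               rep(2, 60))
  set.seed(16)
  for (i in 1:10) {
    co <- rnorm(4)  # random cubic, polyorder 3
    x <- co[1] + co[2] * g + co[3] * g^2 + co[4] * g^3
    d1 <- co[2] + 2 * co[3] * g + 3 * co[4] * g^2
    got <- sg_derivative(x, g, order = 1, window = 9, polyorder = 3)
    expect_equal(got, d1, tolerance = 1e-8)
  }
})

test_that("SG derivative matches the analytic derivative of a smooth signal", {
  g <- seq(4000, 12000, by = 10)
  x <- sin(g / 500)
  d <- sg_derivative(x, g, order = 1, window = 9, polyorder = 2)
  truth <- cos(g / 500) / 500
  interior <- 5:(length(g) - 4)
  expect_lt(max(abs(d[interior] - truth[interior]) / max(abs(truth))), 1e-3)
})

test_that("SG derivative rejects invalid grids and windows", {
  g <- c(toy_grid(10), 20000)
  expect_error(sg_derivative(rnorm(11), g, window = 5), "uniform")
  expect_error(sg_derivative(rnorm(5), toy_grid(5), window = 7), "larger")
  expect_error(pretreatment("FD", sg_window = 4), "odd")
  expect_error(pretreatment("FD", sg_window = 3, sg_polyorder = 2), "odd")
  expect_error(pretreatment("FD", sg_window = 5, sg_polyorder = 5), "exceed")
})

test_that("MSC fitting freezes the calibration mean spectrum", {
  one <- rnorm(15)
  s <- spectra_set(rbind(one, one, one), toy_grid(15), mode = "absorbance",
                   sample_ids = c("a", "b", "c"))
  spec <- fit_pretreatment(s, pretreatment("MSC"))
  expect_equal(spec$msc_reference, one, ignore_attr = TRUE)
  # stateless methods return unchanged
  expect_identical(fit_pretreatment(s, pretreatment("SNV")),
                   pretreatment("SNV"))
  s1 <- spectra_set(matrix(rnorm(15), 1), toy_grid(15), mode = "absorbance")
  expect_error(fit_pretreatment(s1, pretreatment("MSC")), "2 calibration")
  expect_error(apply_pretreatment(s, pretreatment("MSC")), "not fitted")
})

test_that("apply_pretreatment transforms per row with the declared order", {
  s <- toy_spectra(n = 6, p = 80, seed = 17)
  expect_identical(apply_pretreatment(s, pretreatment("NONE"))$values,
                   s$values)
  # FD_SNV: SNV postcondition holds on the derivative spectra
  out <- apply_pretreatment(s, pretreatment("FD_SNV", sg_window = 9))
  expect_equal(unname(rowMeans(out$values)), rep(0, 6), tolerance = 1e-10)
  expect_equal(unname(apply(out$values, 1, sd)), rep(1, 6), tolerance = 1e-10)
  # FD_SNV equals derivative followed by SNV, confirming the combination order
  d <- t(apply(s$values, 1, sg_derivative, grid = s$grid, order = 1,
               window = 9, polyorder = 2))
  expect_equal(unname(out$values), unname(t(apply(d, 1, snv))),
               tolerance = 1e-12)
  # MSC applied to its own reference returns the reference
  spec <- fit_pretreatment(s, pretreatment("MSC"))
  sref <- spectra_set(matrix(spec$msc_reference, 1), s$grid,
                      mode = "absorbance")
  expect_equal(unname(apply_pretreatment(sref, spec)$values[1, ]),
               spec$msc_reference, tolerance = 1e-12)
  # errors carry the sample id
  bad <- s
  bad$values[3, ] <- 5
  expect_error(apply_pretreatment(bad, pretreatment("SNV")), "S03")
})

test_that("all pretreatments preserve sample count and grid length", {
  s <- toy_spectra(n = 4, p = 60, seed = 18)
  for (m in setdiff(PRETREATMENT_METHODS, "NONE")) {
    spec <- fit_pretreatment(s, pretreatment(m, sg_window = 9))
    out <- apply_pretreatment(s, spec)
    expect_identical(dim(out$values), dim(s$values))
    expect_identical(out$grid, s$grid)
  }
})
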
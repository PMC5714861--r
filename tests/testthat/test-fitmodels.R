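marker_grid <- c(200, 500, 1000, 2000, 5000, 7500, 10000)

test_that("noise-free power laws are recovered to machine-level accuracy", {
  d <- tibble::tibble(x = marker_grid, y = 26.60 * x^0.34)
  fit <- fit_power_law(d, x, y)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)["m"] - 26.60), 1e-6)
  expect_lt(abs(coef(fit)["n"] - 0.34), 1e-6)

  d2 <- tibble::tibble(x = marker_grid, y = 250.04 * x^-0.51)
  fit2 <- fit_power_law(d2, x, y)
  expect_lt(abs(coef(fit2)["m"] - 250.04), 1e-6)
  expect_lt(abs(coef(fit2)["n"] + 0.51), 1e-6)
})

test_that("degenerate and equivariant cases behave: constant y and scaled y", {
  d <- tibble::tibble(x = c(10, 100, 1000), y = rep(7, 3))
  fit <- fit_power_law(d, x, y)
  expect_lt(abs(coef(fit)["n"]), 1e-8)
  expect_lt(abs(coef(fit)["m"] - 7), 1e-8)

  d1 <- tibble::tibble(x = marker_grid, y = 5 * x^0.4 * exp(rnorm(7, sd = 0.02)))
  f1 <- fit_power_law(d1, x, y)
  d2 <- dplyr::mutate(d1, y = y * 3)
  f2 <- fit_power_law(d2, x, y)
  expect_equal(unname(coef(f2)["m"]), unname(3 * coef(f1)["m"]), tolerance = 1e-6)
  expect_equal(unname(coef(f2)["n"]), unname(coef(f1)["n"]), tolerance = 1e-6)
})

test_that("the fitter agrees with an independent Levenberg-Marquardt oracle on noisy data", {
  set.seed(5)
  d <- tibble::tibble(x = marker_grid,
                      y = 20 * x^0.45 * exp(rnorm(7, sd = 0.05)))
  fit <- fit_power_law(d, x, y)
  init <- coef(lm(log(y) ~ log(x), data = d))
  oracle <- minpack.lm::nlsLM(y ~ m * x^n, data = d,
                              start = list(m = exp(init[1]), n = init[2]),
                              control = minpack.lm::nls.lm.control(ftol = 1e-12))
  expect_equal(unname(coef(fit)), unname(coef(oracle)), tolerance = 1e-5)
  ose <- summary(oracle)$coefficients[, "Std. Error"]
  expect_equal(unname(fit$std_error), unname(ose), tolerance = 1e-3)
})

test_that("tidy/glance/predict expose the fit in broom style", {
  d <- tibble::tibble(x = marker_grid, y = 26.60 * x^0.34)
  fit <- fit_power_law(d, x, y)
  td <- tidy(fit)
  expect_equal(td$term, c("m", "n"))
  expect_equal(td$estimate, c(26.60, 0.34), tolerance = 1e-6)
  gl <- glance(fit)
  expect_lt(gl$rss, 1e-10)
  expect_true(gl$converged)
  expect_equal(predict(fit, tibble::tibble(x = 100)), 26.60 * 100^0.34,
               tolerance = 1e-6)
})

test_that("power-law preconditions are enforced", {
  expect_error(fit_power_law(tibble::tibble(x = c(1, 2), y = c(1, 2)), x, y),
               "3 distinct")
  expect_error(fit_power_law(tibble::tibble(x = c(1, 2, 3), y = c(1, -2, 3)), x, y),
               "strictly positive")
  expect_error(fit_power_law(tibble::tibble(x = c(0, 2, 3), y = c(1, 2, 3)), x, y),
               "strictly positive")
})

test_that("coefficient recovery under 5% lognormal noise tracks the estimator's information", {
  # with 7 grid points the exponent is well identified; the prefactor is an
  # extrapolation to x = 1 and carries several-fold larger sampling error
  set.seed(17)
  rel_err <- replicate(200, {
    y <- 26.60 * marker_grid^0.34 * exp(rnorm(7, sd = 0.05))
    fit <- fit_power_law(tibble::tibble(x = marker_grid, y = y), x, y)
    abs(coef(fit) - c(26.60, 0.34)) / c(26.60, 0.34)
  })
  expect_lt(median(rel_err[2, ]), 0.05)   # exponent n
  expect_lt(median(rel_err[1, ]), 0.15)   # prefactor m
})

test_that("resolution theory: bin number, bin size and their algebraic identity", {
  expect_equal(theoretical_bin_number(16, 200), 3200)
  expect_equal(theoretical_bin_number(86, 1), 86)
  expect_equal(theoretical_bin_number(16, 0), 0)
  expect_equal(theoretical_bin_size(16, 1), 143.75)
  for (a in c(16, 41, 72, 86)) {
    x <- c(1, 10, 469, 2522)
    expect_equal(theoretical_bin_size(a, x) * theoretical_bin_number(a, x),
                 rep(2300, length(x)))
  }
  expect_error(theoretical_bin_size(16, 0), "nonzero")
})

test_that("required_lines inverts the size formula and round-trips integer line counts", {
  for (a in c(16, 41, 72, 86)) {
    for (x in c(1, 7, 200, 469)) {
      expect_equal(required_lines(a, theoretical_bin_size(a, x)), x)
    }
    expect_equal(required_lines(a, 2300 / a), 1)
  }
})

test_that("required_markers inverts a bin-size power law", {
  expect_equal(required_markers(c(m = 250.04, n = -0.51), 250.04), 1)
  # halving the target multiplies the marker requirement by 2^(1/|n|)
  x1 <- required_markers(c(m = 400, n = -0.5), 2)
  x2 <- required_markers(c(m = 400, n = -0.5), 1)
  expect_equal(x2 / x1, 2^(1 / 0.5), tolerance = 1e-3)
  # closed-form evaluation, computed independently on the log scale
  expected <- round(exp(log(390.24 / 0.057) / 0.64))
  expect_equal(required_markers(c(m = 390.24, n = -0.64), 0.057), expected)
  expect_gt(expected, 9.5e5)
  expect_lt(expected, 1.05e6)

  d <- tibble::tibble(x = c(100, 1000, 10000), y = 250 * x^-0.5)
  expect_equal(required_markers(fit_power_law(d, x, y), 250), 1)
  expect_error(required_markers(c(m = 10, n = 0.3), 1), "n < 0")
})

test_that("the gene-density bin target is 57 Kb truncated from 57.5", {
  expect_equal(gene_density_bin_kb(), 57)
  expect_equal(gene_density_bin_kb(truncate = FALSE), 57.5)
})

test_that("resolution_summary tabulates theory for named populations", {
  out <- resolution_summary(c(dh = 16, ril = 41, ibm = 72, magic = 86))
  expect_equal(nrow(out), 16)
  row <- out[out$population == "dh" & out$n_lines == 200, ]
  expect_equal(row$bin_number, 3200)
  expect_equal(row$lines_for_gene_target, 2522)
})
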
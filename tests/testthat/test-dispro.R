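test_that("ROR point estimate and Woolf CI match closed-form arithmetic", {
  r <- ror_with_ci(10, 90, 100, 9900)
  expect_equal(r$ror, 11.0)
  expect_equal(r$ror_lo, 5.56, tolerance = 0.005)
  expect_equal(r$ror_hi, 21.77, tolerance = 0.005)
  # independence: a*d == b*c
  expect_equal(ror_with_ci(5, 50, 10, 100)$ror, 1)
  # zero cells: undefined without a correction, finite with Haldane
  z <- ror_with_ci(0, 90, 100, 9900)
  expect_true(is.na(z$ror_lo))
  zh <- ror_with_ci(0, 90, 100, 9900, correction = "haldane")
  expect_true(is.finite(zh$ror) && is.finite(zh$ror_lo))
})

test_that("PRR and Yates chi-squared match the standard test", {
  p <- prr_with_chi2(10, 90, 100, 9900)
  expect_equal(p$prr, 10.0)
  oracle <- unname(suppressWarnings(stats::chisq.test(matrix(c(10, 90, 100, 9900), 2,
                                            byrow = TRUE),
                                     correct = TRUE))$statistic)
  expect_equal(p$chi2, oracle, tolerance = 1e-10)
  # proportional table: PRR exactly 1
  expect_equal(prr_with_chi2(10, 90, 100, 900)$prr, 1)
  # c = 0: undefined with a reasoned NA
  expect_true(is.na(prr_with_chi2(10, 90, 0, 9900)$prr))
  # uncorrected variant agrees with Pearson
  p2 <- prr_with_chi2(10, 90, 100, 9900, correction = "none")
  oracle2 <- unname(suppressWarnings(stats::chisq.test(matrix(c(10, 90, 100, 9900), 2,
                                             byrow = TRUE),
                                      correct = FALSE))$statistic)
  expect_equal(p2$chi2, oracle2, tolerance = 1e-10)
})

test_that("information component: shrunk O/E form and its gamma lower bound", {
  ic <- bcpnn_ic(10, 90, 100, 9900)
  E <- 100 * 110 / 10100
  expect_equal(E, 1.0891, tolerance = 1e-4)
  expect_equal(ic$ic, log2(10.5 / (E + 0.5)))
  expect_equal(ic$ic025, ic025_quadrature(10, E), tolerance = 1e-3)
  # independence limit: a == E, large
  big <- bcpnn_ic(1000, 9000, 10000, 90000)
  expect_lt(abs(big$ic), 0.01)
  # defined at a = 0
  expect_true(is.finite(bcpnn_ic(0, 100, 100, 9900)$ic))
})

test_that("the Bate closed-form IC variant tracks the default at scale", {
  for (cells in list(c(659, 5000, 30000, 900000), c(50, 500, 5000, 90000))) {
    noren <- bcpnn_ic(cells[1], cells[2], cells[3], cells[4])
    bate <- bcpnn_ic(cells[1], cells[2], cells[3], cells[4],
                     variant = "bate")
    expect_lt(abs(noren$ic - bate$ic), 0.05)
    expect_lt(bate$ic025, bate$ic)
  }
})

test_that("signal criteria implement the conventional thresholds", {
  row <- data.table::data.table(
    n = 659L, ror = 2.62, ror_lo = 2.41, ror_hi = 2.84, prr = 2.36,
    chi2 = 554.70, ic = 1.24, ic025 = 1.14, ebgm = 2.36, ebgm05 = 2.17)
  f <- apply_signal_criteria(row)
  expect_true(f$flag_ror && f$flag_prr && f$flag_ic && f$flag_ebgm &&
                f$flag_all)
  # n >= 3 gates ROR and PRR regardless of magnitude
  small <- data.table::copy(row)[, n := 2L]
  fs <- apply_signal_criteria(small)
  expect_false(fs$flag_ror || fs$flag_prr)
  expect_true(fs$flag_ic)
  # strict inequality at IC025 = 0
  edge <- data.table::copy(row)[, ic025 := 0]
  expect_false(apply_signal_criteria(edge)$flag_ic)
  # undefined statistics yield FALSE flags
  und <- data.table::copy(row)[, `:=`(ror_lo = NA_real_, prr = NA_real_)]
  fu <- apply_signal_criteria(und)
  expect_false(fu$flag_ror || fu$flag_prr || fu$flag_all)
})

test_that("ROR, PRR and 1 are always ordered consistently", {
  withr::with_seed(77, {
    a <- sample(1:500, 1000, TRUE); b <- sample(1:5000, 1000, TRUE)
    cc <- sample(1:5000, 1000, TRUE); d <- sample(1:50000, 1000, TRUE)
  })
  ror <- ror_with_ci(a, b, cc, d)$ror
  prr <- prr_with_chi2(a, b, cc, d)$prr
  expect_equal(ror > 1, prr > 1)
  expect_equal(ror > 1, ror > prr)
  expect_equal(ror < 1, prr < 1)
  expect_equal(ror < 1, ror < prr)
})

test_that("point statistics are nondecreasing in a for fixed b, c, d", {
  a <- 1:60
  prior <- structure(list(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4,
                          P = 1 / 3), class = "mgps_prior")
  ror <- ror_with_ci(a, 100, 200, 20000)$ror
  prr <- prr_with_chi2(a, 100, 200, 20000)$prr
  ic <- bcpnn_ic(a, 100, 200, 20000)$ic
  N <- a + 100 + 200 + 20000
  E <- (a + 100) * (a + 200) / N
  eb <- mgps_ebgm(a, E, prior)$ebgm
  for (v in list(ror, prr, ic, eb)) expect_true(all(diff(v) > -1e-12))
})
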
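test_that("noiseless decays are recovered exactly on both delay schedules", {
  cases <- list(list(sched = "R1", i0 = 100, rate = 1.0),
                list(sched = "R2", i0 = 50, rate = 22))
  for (cs in cases) {
    t <- delay_schedule(cs$sched)
    y <- cs$i0 * exp(-cs$rate * t)
    fit <- fit_exponential(t, y)
    expect_true(fit$ok)
    expect_equal(fit$rate, cs$rate, tolerance = 1e-6)
    expect_equal(fit$i0, cs$i0, tolerance = 1e-6)
    # identical to the closed-form log-linear solution
    oracle <- loglinear_fit(t, y)
    expect_equal(fit$rate, oracle$rate, tolerance = 1e-6)
    expect_equal(fit$i0, oracle$i0, tolerance = 1e-6)
    # near-zero errors on exact data
    expect_lt(fit$rate_error / fit$rate, 1e-6)
  }
})

test_that("fit outputs are invariant to row order and intensity scale", {
  t <- delay_schedule("R2")
  set.seed(31)
  y <- 80 * exp(-18 * t) + rnorm(length(t), 0, 1.6)
  f0 <- fit_exponential(t, y)
  perm <- sample(length(t))
  f1 <- fit_exponential(t[perm], y[perm])
  expect_equal(f1$rate, f0$rate, tolerance = 1e-9)
  expect_equal(f1$rate_error, f0$rate_error, tolerance = 1e-9)

  f2 <- fit_exponential(t, 1000 * y)
  expect_equal(f2$rate, f0$rate, tolerance = 1e-8)
  expect_equal(f2$rate_error, f0$rate_error, tolerance = 1e-8)
  expect_equal(f2$i0 / f0$i0, 1000, tolerance = 1e-8)
  expect_equal(f2$i0_error / f0$i0_error, 1000, tolerance = 1e-6)
})

test_that("degenerate series raise or flag instead of crashing", {
  expect_error(fit_exponential(c(0.1, 0.2), c(10, 5)), "insufficient")
  # rising 'decay' has no positive-rate optimum: flagged, not an error
  f <- fit_exponential(c(0.1, 0.5, 1, 2), c(1, 5, 20, 90))
  expect_false(f$ok)
  expect_true(is.na(f$rate))
})

test_that("covariance errors are calibrated at the few-percent noise level", {
  t <- delay_schedule("R2")
  rate <- 22; i0 <- 100; nf <- 0.02
  set.seed(7)
  fits <- replicate(300, {
    y <- i0 * exp(-rate * t) + rnorm(length(t), 0, nf * i0)
    f <- fit_exponential(t, y)
    c(f$rate, f$rate_error)
  })
  rates <- fits[1, ]; errs <- fits[2, ]
  expect_lt(abs(mean(rates) - rate) / rate, 0.01)
  # reported error tracks the empirical scatter
  expect_lt(abs(sd(rates) - mean(errs)) / mean(errs), 0.25)
  cover <- mean(abs(rates - rate) < errs)
  expect_gt(cover, 0.58); expect_lt(cover, 0.78)
})

test_that("jackknife errors agree with covariance errors within a factor of two", {
  t <- delay_schedule("R2")
  y0 <- 100 * exp(-22 * t)
  expect_lt(as.numeric(jackknife_rate_error(t, y0)), 1e-6)

  # Monte-Carlo comparison: on average the two error estimates agree
  set.seed(7)
  ratios <- replicate(50, {
    y <- y0 + rnorm(length(t), 0, 2)
    as.numeric(jackknife_rate_error(t, y)) / fit_exponential(t, y)$rate_error
  })
  expect_gt(mean(ratios), 0.5)
  expect_lt(mean(ratios), 2)

  # n = 4 series: exactly four leave-one-out refits
  t4 <- t[1:4]; y4 <- 100 * exp(-10 * t4)
  expect_length(attr(jackknife_rate_error(t4, y4), "rates"), 4)
  expect_error(jackknife_rate_error(t4[1:3], y4[1:3]), "at least 4")
})

test_that("hnNOE values and errors follow the propagation formula", {
  expect_equal(compute_hnnoe(50, 50, 1, 1)$value, 1.0)
  v <- compute_hnnoe(30, 100, 2, 2)
  expect_equal(v$value, 0.300, tolerance = 1e-12)
  expect_equal(v$error, 0.0209, tolerance = 1e-3)
  expect_equal(v$error, 0.3 * sqrt((2 / 30)^2 + (2 / 100)^2),
               tolerance = 1e-12)
  expect_equal(compute_hnnoe(-5, 100, 2, 2)$value, -0.05)
  expect_equal(compute_hnnoe(0, 100, 2, 2)$error, 2 / 100)  # limit form
  expect_error(compute_hnnoe(30, 0, 2, 2), "reference")
  expect_error(compute_hnnoe(30, 100, -1, 2), "noise")
})

test_that("R2/R1 combines rates with quadrature error propagation", {
  r <- compute_r2_over_r1(1.07, 22, 0, 0)
  expect_equal(r$value, 22 / 1.07, tolerance = 1e-12)
  expect_equal(round(r$value, 2), 20.56)
  expect_equal(r$error, 0)

  r2 <- compute_r2_over_r1(2, 2, 0.1, 0.1)
  expect_equal(r2$value, 1.0)
  expect_equal(r2$error, 1.0 * sqrt(2) * 0.05, tolerance = 1e-12)

  bad <- structure(list(rate = NA, rate_error = NA, ok = FALSE), class = "rate_fit")
  good <- fit_exponential(delay_schedule("R1"),
                          100 * exp(-1.2 * delay_schedule("R1")))
  expect_equal(compute_r2_over_r1(bad, good)$reason, "not-fit")
})

test_that("profiles account for every residue and region averages behave", {
  tab <- simulate_peak_table("WT", 0, seed = 3)
  r1p <- relaxation_profile(tab, "R1")
  expect_setequal(union(r1p$residue[r1p$status == "ok"],
                        r1p$residue[r1p$status != "ok"]), 1:36)
  expect_equal(r1p$status[r1p$residue == 16], "invisible")
  expect_equal(r1p$status[r1p$residue == 20], "omitted")
  expect_true(all(r1p$value[r1p$status == "ok"] > 0))

  noe <- noe_profile(tab)
  expect_equal(sum(noe$residue == 36), 2)  # K36 doublet: two peaks

  # doublets contribute their mean as one observation
  ra36 <- region_average(noe, "K36", "K36")
  k36 <- noe$value[noe$residue == 36]
  expect_equal(ra36$mean, mean(k36))
  expect_equal(ra36$n, 1)

  const <- make_profile(rep(0.5, 36))
  ra <- region_average(const, "T3", "K36")
  expect_equal(ra$mean, 0.5)
  expect_equal(ra$sd, 0)
  expect_equal(ra$n, 34)

  gap <- make_profile(c(rep(0.5, 15), NA, rep(0.5, 20)))
  expect_error(region_average(gap, "P16", "P16"), "empty region")

  # hinge contrast reproduced on calibrated synthetic data
  expect_lt(region_average(noe, "S28", "K36")$mean,
            region_average(noe, "T3", "K27")$mean)
})

test_that("R2/R1 profiles combine matching peaks and flag partial fits", {
  tab <- simulate_peak_table("R17Q", 0, seed = 8)
  r1 <- relaxation_profile(tab, "R1")
  r2 <- relaxation_profile(tab, "R2")
  rr <- ratio_profile(r1, r2)
  ok <- rr[rr$status == "ok", ]
  for (i in seq_len(3)) {
    a <- r1[r1$residue == ok$residue[i] & r1$peak_id == ok$peak_id[i], ]
    b <- r2[r2$residue == ok$residue[i] & r2$peak_id == ok$peak_id[i], ]
    expect_equal(ok$value[i], b$value / a$value, tolerance = 1e-12)
  }
  expect_error(ratio_profile(r2, r1), "R1")
})
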
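test_that("difference profiles use the WT-minus-mutant convention", {
  profs <- sim_noe_profiles(17, constructs = c("WT", "R26Q"))
  self <- delta_profile(profs$WT, profs$WT)
  expect_true(all(self$delta[self$status == "ok"] == 0))
  expect_equal(self$error[self$status == "ok"],
               sqrt(2) * self$sigma_wt[self$status == "ok"],
               tolerance = 1e-12)

  dp <- delta_profile(profs$WT, profs$R26Q)
  # mutant more mobile near the mutation: positive hnNOE delta
  near <- dp$residue %in% 24:28 & dp$status == "ok"
  expect_true(all(dp$delta[near] > 0))
  # quadrature and sum errors both present, sum >= quadrature
  ok <- dp$status == "ok"
  expect_true(all(dp$error_sum[ok] >= dp$error[ok]))

  r1 <- relaxation_profile(simulate_peak_table("WT", 0, seed = 1), "R1")
  expect_error(delta_profile(profs$WT, r1), "observable mismatch")
})

test_that("WT-singlet versus mutant-doublet residues carry two deltas", {
  profs <- sim_noe_profiles(6, constructs = c("WT", "R8Q"))
  dp <- delta_profile(profs$WT, profs$R8Q)
  # Q5 is a singlet in WT and a doublet in R8Q
  expect_equal(dp$pairing[dp$residue == 5 & dp$status == "ok"],
               c("1-1", "1-2"))
})

test_that("summed delta is simple arithmetic over per-residue means", {
  d <- rep(NA_real_, 36); e <- rep(0.01, 36)
  d[c(5, 10, 15)] <- 0.1; d[20] <- -0.05
  dp <- make_delta_profile(d, e)
  expect_equal(summed_delta(dp), 0.25, tolerance = 1e-12)

  zero <- make_delta_profile(rep(0, 36), e)
  expect_equal(summed_delta(zero), 0)

  # linear in the profile and invariant to residue order (shuffle rows)
  expect_equal(summed_delta(make_delta_profile(2 * d, e)), 0.5,
               tolerance = 1e-12)
  shuffled <- dp[sample(nrow(dp)), ]
  attributes(shuffled)[c("observable", "salt_mM")] <- list("hnNOE", 0)
  class(shuffled) <- c("delta_profile", "data.frame")
  expect_equal(summed_delta(shuffled), 0.25, tolerance = 1e-12)
})

test_that("mutant ranking is deterministic and flags ties", {
  d1 <- rep(NA_real_, 36); d1[3:10] <- 0.2
  d2 <- rep(NA_real_, 36); d2[3:10] <- 0.1
  e <- rep(0.01, 36)
  p1 <- make_delta_profile(d1, e, mut = "R26Q")
  p2 <- make_delta_profile(d2, e, mut = "R2Q")
  rk <- rank_mutants(list(R26Q = p1, R2Q = p2))
  expect_equal(rk$construct, c("R26Q", "R2Q"))
  expect_false(any(rk$tie))

  single <- rank_mutants(list(R26Q = p1))
  expect_equal(nrow(single), 1)

  tied <- rank_mutants(list(B = p1, A = p1))
  expect_true(all(tied$tie))
  expect_equal(tied$construct, c("A", "B"))  # name order breaks the tie

  other <- make_delta_profile(d1, e, observable = "R2R1")
  expect_error(rank_mutants(list(p1, other)), "mix observables")
})

test_that("region detection reproduces the published breadth patterns", {
  e <- rep(0.02, 36)
  # qualifying 22-27 and 29-35, interrupted only at 28; P30 missing
  d <- rep(0, 36)
  d[c(22:27, 29, 31:35)] <- 0.1
  d[c(1, 16, 30)] <- NA
  regs <- detect_affected_regions(make_delta_profile(d, e))
  expect_equal(nrow(regs), 1)
  expect_equal(regs$start_label, "T22")
  expect_equal(regs$end_label, "V35")
  expect_equal(regs$residue_count, 14L)
  expect_equal(regs$interruptions, "28")

  # two disjoint segments: 15-20 and 24-26 with a two-residue break
  d2 <- rep(0, 36); d2[c(15, 17:20, 24:26)] <- 0.1
  d2[c(1, 16, 30)] <- NA
  regs2 <- detect_affected_regions(make_delta_profile(d2, e))
  expect_equal(nrow(regs2), 2)
  expect_equal(regs2$residue_count, c(6L, 3L))
  expect_equal(regs2$start_label, c("A15", "A24"))

  # all-null profile: no regions
  expect_equal(nrow(detect_affected_regions(
    make_delta_profile(rep(0, 36), e))), 0)

  # endpoints must qualify: trailing non-qualifier is not absorbed
  d3 <- rep(0, 36); d3[10:13] <- 0.1; d3[14] <- 0.01
  regs3 <- detect_affected_regions(make_delta_profile(d3, e))
  expect_equal(regs3$end, 13)
})

test_that("region detection equals the exhaustive oracle on random profiles", {
  set.seed(99)
  for (i in 1:300) {
    d <- rnorm(36, 0, 1)
    e <- runif(36, 0.4, 1.6)
    miss <- unique(c(1, 16, 30, sample(36, sample(0:6, 1))))
    d[miss] <- NA
    dp <- make_delta_profile(d, e)
    got <- detect_affected_regions(dp)
    q <- ifelse(is.na(d), NA, abs(d) > e)
    want <- oracle_regions(q)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("inflating all deltas never shrinks detected regions", {
  set.seed(123)
  for (i in 1:50) {
    d <- rnorm(36, 0, 1); e <- runif(36, 0.5, 1.5)
    d[c(1, 16, 30)] <- NA
    base <- detect_affected_regions(make_delta_profile(d, e))
    big <- detect_affected_regions(make_delta_profile(1.7 * d, e))
    if (nrow(base)) {
      covered <- vapply(seq_len(nrow(base)), function(r) {
        any(big$start <= base$start[r] & big$end >= base$end[r])
      }, logical(1))
      expect_true(all(covered))
    }
  }
})

test_that("truth-level additivity is exact and WT substitution recovers the sum", {
  profs <- sim_noe_profiles(1, noise_fraction = 0)
  singles <- lapply(c("R2Q", "R8Q", "R17Q", "R26Q"),
                    function(cn) delta_profile(profs$WT, profs[[cn]]))
  quad <- delta_profile(profs$WT, profs$`R2/8/17/26Q`)
  # zero-noise errors are zero: compare discrepancy values directly
  ad <- suppressWarnings(additivity_discrepancy(singles, quad))
  expect_true(all(abs(ad$discrepancy) < 1e-10))
  expect_lt(attr(ad, "mean_abs_discrepancy"), 1e-10)

  # replacing the quadruple by WT leaves the sum of singles
  null_quad <- delta_profile(profs$WT, profs$WT)
  ad2 <- suppressWarnings(additivity_discrepancy(singles, null_quad))
  sum_singles <- Reduce(`+`, lapply(singles, function(s) {
    v <- s$delta[s$status == "ok"][match(ad2$residue,
                                         s$residue[s$status == "ok"])]
    v
  }))
  expect_equal(ad2$discrepancy, sum_singles, tolerance = 1e-10)

  expect_error(additivity_discrepancy(singles[1:3], quad), "four")
})

test_that("percent changes render the published headline numbers", {
  expect_equal(percent_change(1.07, 1.25), 100 * 0.18 / 1.07,
               tolerance = 1e-12)
  expect_equal(render_percent_change(percent_change(1.07, 1.25)),
               "17% increase")
  expect_equal(render_percent_change(percent_change(21, 8)), "62% decrease")
  expect_equal(percent_change(5, 5), 0)
  expect_equal(render_percent_change(0), "0% increase")
  expect_error(percent_change(0, 1), "reference")
})

test_that("mean breadths over replicates order as R26Q > {R8Q, R17Q} > R2Q", {
  cons <- c("R2Q", "R8Q", "R17Q", "R26Q")
  breadths <- sapply(1:50, function(seed) {
    profs <- sim_noe_profiles(seed, constructs = c("WT", cons))
    vapply(cons, function(cn) {
      dp <- delta_profile(profs$WT, profs[[cn]])
      sum(detect_affected_regions(dp)$residue_count)
    }, numeric(1))
  })
  mb <- rowMeans(breadths)
  expect_gt(mb[["R26Q"]], mb[["R8Q"]])
  expect_gt(mb[["R26Q"]], mb[["R17Q"]])
  expect_gt(mb[["R8Q"]], mb[["R2Q"]])
  expect_gt(mb[["R17Q"]], mb[["R2Q"]])
  # R8Q and R17Q are statistically indistinguishable in breadth
  expect_lt(abs(mb[["R8Q"]] - mb[["R17Q"]]), 5)
})
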
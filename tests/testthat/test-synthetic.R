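test_that("wild-type truth is calibrated to the baseline tail averages", {
  tr <- generate_truth("WT", 0, seed = 1)
  obs <- observable_positions("WT", 0)
  expect_lt(abs(mean(tr$hnnoe[obs]) - 0.34), 0.03)
  hinge <- intersect(obs, 28:36)
  nterm <- intersect(obs, 3:27)
  expect_lt(mean(tr$hnnoe[hinge]), mean(tr$hnnoe[nterm]))
  expect_lt(abs(mean(tr$hnnoe[hinge]) - 0.16), 0.03)
  expect_lt(abs(mean(tr$r1[obs]) - 1.07), 0.03)
  expect_lt(abs(mean(tr$r2[obs]) - 22), 0.5)
  expect_true(all(tr$r1 > 0 & tr$r2 > 0))
  expect_true(all(tr$hnnoe > -0.2 & tr$hnnoe <= 1))
})

test_that("mutant truth differs from WT only via additive local kernels", {
  wt <- generate_truth("WT", 0, seed = 1)
  singles <- lapply(c("R2Q", "R8Q", "R17Q", "R26Q"),
                    function(cn) generate_truth(cn, 0, seed = 1))
  quad <- generate_truth("R2/8/17/26Q", 0, seed = 1)

  # additivity holds exactly, for every observable
  for (col in c("strength", "hnnoe", "r1", "r2")) {
    sum_deltas <- Reduce(`+`, lapply(singles, function(s) wt[[col]] - s[[col]]))
    expect_equal(wt[[col]] - quad[[col]], sum_deltas, tolerance = 1e-12)
  }

  # single-mutant effect is largest at/near the mutated site and one-signed
  r26 <- wt$hnnoe - singles[[4]]$hnnoe
  expect_true(all(r26 > 0))
  expect_equal(which.max(r26), 26L)
})

test_that("salt scaling and site strengths act monotonically on the truth", {
  t0 <- generate_truth("WT", 0, seed = 1)
  t150 <- generate_truth("WT", 150, seed = 1)
  expect_true(all(t150$r2 < t0$r2))
  expect_true(all(t150$hnnoe < t0$hnnoe))
  expect_true(all(t150$r1 > t0$r1))  # faster motion raises R1 here

  # weakening lysine anchors never decreases true R1 anywhere
  weak <- anchor_params(site_strengths = c(R = 1.0, K = 0.4))
  tw <- generate_truth("WT", 0, params = weak, seed = 1)
  expect_true(all(tw$r1 >= t0$r1))

  expect_error(anchor_params(f_salt = 0), "f_salt")
  expect_error(anchor_params(lambda_N = 6, lambda_C = 3), "lambda_C")
  expect_error(anchor_params(site_strengths = c(R = 1.2, K = 0.7)),
               "site strengths")
})

test_that("simulated tables are deterministic given (construct, salt, seed)", {
  a <- simulate_peak_table("R17Q", 0, seed = 11)
  b <- simulate_peak_table("R17Q", 0, seed = 11)
  expect_identical(a, b)
  f1 <- tempfile(); f2 <- tempfile()
  write_peak_table(a, f1); write_peak_table(b, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  c2 <- simulate_peak_table("R17Q", 0, seed = 12)
  expect_false(identical(a$intensity, c2$intensity))
})

test_that("zero noise reproduces the model exactly", {
  tr <- generate_truth("WT", 0, seed = 5)
  rel <- simulate_relaxation_series(tr, "R1", noise_fraction = 0, seed = 5,
                                    residues = c(3L, 10L))
  for (r in unique(rel$residue)) {
    g <- rel[rel$residue == r, ]
    i0 <- tr$i0[tr$residue == r]
    expect_equal(g$intensity, i0 * exp(-tr$r1[tr$residue == r] * g$delay_s),
                 tolerance = 1e-12)
  }
  noe <- simulate_noe_pair(tr, noise_fraction = 0, seed = 5, residues = 3L)
  sat <- noe$intensity[noe$experiment == "hnNOE-sat"]
  ref <- noe$intensity[noe$experiment == "hnNOE-ref"]
  expect_equal(sat / ref, tr$hnnoe[3], tolerance = 1e-12)

  # negative true hnNOE passes through as a negative saturated intensity
  quad150 <- generate_truth("R2/8/17/26Q", 150, seed = 5)
  stopifnot(any(quad150$hnnoe < 0))
  rneg <- quad150$residue[which.min(quad150$hnnoe)]
  noeneg <- simulate_noe_pair(quad150, noise_fraction = 0, seed = 5,
                              residues = rneg)
  expect_lt(noeneg$intensity[noeneg$experiment == "hnNOE-sat"], 0)

  expect_error(simulate_noe_pair(tr, noise_fraction = -0.1), ">= 0")
})

test_that("delay schedules carry the duplicated points as independent rows", {
  expect_equal(sum(delay_schedule("R1") == 0.390), 2)
  expect_equal(sum(delay_schedule("R2") == 0.110), 2)
  expect_length(delay_schedule("R2", "wt150"), 8)
  tr <- generate_truth("WT", 0, seed = 1)
  rel <- simulate_relaxation_series(tr, "R1", seed = 1, residues = 5L)
  expect_equal(sum(rel$delay_s == 0.390), 2)
  expect_false(identical(rel$intensity[rel$delay_s == 0.390][1],
                         rel$intensity[rel$delay_s == 0.390][2]))
})

test_that("shift tables obey the CSP envelope and the doublet rules", {
  wt <- simulate_shift_table("WT", 0, seed = 9)
  # WT doublets at R2 and K36; two peaks with distinct shifts
  expect_equal(sort(unique(wt$residue[wt$peak_id == 2])), c(2L, 36L))
  r2pk <- wt[wt$residue == 2, ]
  expect_false(identical(r2pk$dH_ppm[1], r2pk$dH_ppm[2]))

  # same seed, no mutations: identical shifts, all CSPs zero
  wt2 <- simulate_shift_table("WT", 0, seed = 9)
  expect_identical(wt, wt2)

  mut <- simulate_shift_table("R8Q", 0, seed = 9)
  both <- merge(wt[wt$peak_id == 1, c("residue", "dH_ppm", "dN_ppm")],
                mut[mut$peak_id == 1, c("residue", "dH_ppm", "dN_ppm")],
                by = "residue")
  csp <- compute_csp(both$dH_ppm.y - both$dH_ppm.x,
                     both$dN_ppm.y - both$dN_ppm.x)
  non_mut <- both$residue != 8
  expect_true(all(csp[non_mut] <= 0.1))
  expect_true(all(csp[non_mut & abs(both$residue - 8) > 5] <= 0.04))
  expect_gt(max(csp[both$residue == 8], csp[abs(both$residue - 8) == 1]),
            max(csp[abs(both$residue - 8) > 5]))

  # 150 mM: all singlets
  wt150 <- simulate_shift_table("R17Q", 150, seed = 9)
  expect_true(all(wt150$peak_id == 1))
})

test_that("the assembled table applies omission and visibility rules", {
  tab <- simulate_peak_table("WT", 0, seed = 2)
  rel <- tab[tab$experiment == "R1", ]
  expect_false(any(rel$residue %in% c(1, 2, 16, 20, 30)))
  hsqc <- tab[tab$experiment == "HSQC", ]
  expect_true(2 %in% hsqc$residue)     # R2 visible in HSQC at 0 mM
  expect_false(any(hsqc$residue %in% c(1, 16, 30)))
  expect_setequal(unique(tab$experiment),
                  c("R1", "R2", "hnNOE-ref", "hnNOE-sat", "HSQC"))

  full <- simulate_peak_table("WT", 0, seed = 2, apply_omissions = FALSE)
  expect_true(all(c(2, 20) %in% full$residue[full$experiment == "R1"]))
})
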
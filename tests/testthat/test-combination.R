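test_that("surface margins reproduce the single-drug curves", {
  sys <- toy_two_arm()
  grid_a <- c(0, 10^seq(0, 2.5, length.out = 5))
  grid_b <- c(0, 10^seq(0, 2.5, length.out = 5))
  surf <- dose_response_surface(sys$net, sys$aff, "dA", "dB",
                                grid_a, grid_b)
  curve_a <- predict_curve(sys$net, sys$aff, "dA", grid_a[-1])
  curve_b <- predict_curve(sys$net, sys$aff, "dB", grid_b[-1])
  expect_equal(surf$response[-1, 1], curve_a$responses)
  expect_equal(surf$response[1, -1], curve_b$responses)
  expect_equal(surf$response[1, 1], 0)
})

test_that("surfaces are monotone along both axes", {
  sys <- toy_two_arm()
  surf <- dose_response_surface(sys$net, sys$aff, "dA", "dB",
                                c(0, 10^seq(-1, 3, length.out = 7)),
                                c(0, 10^seq(-1, 3, length.out = 7)))
  expect_true(all(apply(surf$response, 2, function(col) all(diff(col) >= -1e-9))))
  expect_true(all(apply(surf$response, 1, function(row) all(diff(row) >= -1e-9))))
})

test_that("sham self-combination surface depends only on the summed dose", {
  net <- lps_pge2_fixture()
  aff <- affinity_table(data.frame(
    compound_id = "drug", target_node = c("TAK1", "COX2"), pki = c(5, 5.2)))
  both <- sham_affinity(aff, "drug", "drug2")
  f <- nef_evaluator(net, both)
  single <- nef_evaluator(net, aff)
  for (d in c(2, 20, 80)) {
    expect_equal(f(dose_scenario(drug = d * 0.4, drug2 = d * 0.6)),
                 single(dose_scenario(drug = d)))
  }
})

test_that("single_dose_for_effect inverts the model curve", {
  sys <- toy_two_arm()
  f <- nef_evaluator(sys$net, sys$aff)
  for (probe in c(5, 40, 200)) {
    eff <- f(dose_scenario(dA = probe))
    d <- single_dose_for_effect(sys$net, sys$aff, "dA", eff, evaluator = f)
    expect_equal(d, probe, tolerance = 1e-4)
  }
  # brute-force cross-check at the 50% level
  d50 <- single_dose_for_effect(sys$net, sys$aff, "dA", 50, evaluator = f)
  grid <- 10^seq(-2, 4, length.out = 10000)
  scan <- grid[which.min(abs(vapply(grid, function(c0)
    f(dose_scenario(dA = c0)), numeric(1)) - 50))]
  expect_equal(d50, scan, tolerance = 2e-3)
  # unattainable levels are refused
  expect_error(
    single_dose_for_effect(sys$net, sys$aff, "dA", 99.9, evaluator = f),
    class = "pathdose_attainability_error")
  expect_error(single_dose_for_effect(sys$net, sys$aff, "dA", 0),
               class = "pathdose_domain_error")
})

test_that("a drug alone has combination index exactly 1", {
  sys <- toy_two_arm()
  ci <- combination_index(sys$net, sys$aff, "dA", "dB",
                          dose_a = 25, dose_b = 0)
  expect_equal(ci$ci, 1, tolerance = 1e-9)
})

test_that("sham combinations are Loewe-additive (CI = 1)", {
  net <- lps_pge2_fixture()
  aff <- affinity_table(data.frame(
    compound_id = "drug", target_node = c("TAK1", "NFKB", "P38"),
    pki = c(5, 4.6, 5.3)))
  both <- sham_affinity(aff, "drug", "drug2")
  f <- nef_evaluator(net, both)
  for (split in c(0.2, 0.5, 0.8)) {
    total <- 40
    ci <- combination_index(net, both, "drug", "drug2",
                            dose_a = total * split,
                            dose_b = total * (1 - split), evaluator = f)
    expect_equal(ci$ci, 1, tolerance = 1e-6)
  }
})

test_that("isobole points all reproduce the target effect", {
  sys <- toy_two_arm()
  f <- nef_evaluator(sys$net, sys$aff)
  iso <- isobologram(sys$net, sys$aff, "dA", "dB", effect = 50,
                     n_points = 9)
  expect_equal(nrow(iso), 9)
  # axis intercepts are the single-drug equivalent doses
  expect_equal(iso$dose_a[1], 0)
  expect_equal(iso$dose_b[nrow(iso)], 0, tolerance = 1e-6)
  expect_equal(iso$dose_b[1], attr(iso, "dx_b"), tolerance = 1e-6)
  for (k in seq_len(nrow(iso))) {
    doses <- c(iso$dose_a[k], iso$dose_b[k])
    ids <- c("dA", "dB")[doses > 0]
    doses <- doses[doses > 0]
    expect_equal(f(dose_scenario(setNames(doses, ids))), 50,
                 tolerance = 0.1)
  }
  # endpoints are single-drug points, hence CI = 1 there
  expect_equal(iso$ci[1], 1, tolerance = 1e-6)
  expect_equal(iso$ci[nrow(iso)], 1, tolerance = 1e-6)
})

test_that("a sham isobole is the straight line d_a + d_b = const", {
  net <- lps_pge2_fixture()
  aff <- affinity_table(data.frame(
    compound_id = "drug", target_node = c("IKK", "COX2"), pki = c(5, 5.4)))
  both <- sham_affinity(aff, "drug", "drug2")
  iso <- isobologram(net, both, "drug", "drug2", effect = 40, n_points = 7)
  expect_equal(iso$dose_a + iso$dose_b,
               rep(attr(iso, "dx_a"), 7), tolerance = 1e-5)
  expect_equal(iso$ci, rep(1, 7), tolerance = 1e-6)
})

test_that("optimal combination beats the endpoints and matches a dense scan", {
  sys <- toy_two_arm()
  opt <- optimal_combination(sys$net, sys$aff, "dA", "dB", effect = 50,
                             n_scan = 21)
  expect_false(opt$flat)
  expect_lte(opt$ci, 1 + 1e-9)  # endpoints are single-drug points with CI 1
  dense <- isobologram(sys$net, sys$aff, "dA", "dB", effect = 50,
                       n_points = 1001)
  expect_lte(opt$ci, min(dense$ci) + 1e-6)
  expect_gte(opt$ci, min(dense$ci) - 1e-4)
})

test_that("a sham optimal combination reports a flat landscape", {
  net <- lps_pge2_fixture()
  aff <- affinity_table(data.frame(
    compound_id = "drug", target_node = c("TAK1", "COX2"), pki = c(5, 5.2)))
  both <- sham_affinity(aff, "drug", "drug2")
  opt <- optimal_combination(net, both, "drug", "drug2", effect = 30,
                             n_scan = 11)
  expect_true(opt$flat)
  expect_equal(opt$ci, 1, tolerance = 1e-6)
})

test_that("combination index is invariant under a consistent unit rescale", {
  sys <- toy_two_arm()
  ci1 <- combination_index(sys$net, sys$aff, "dA", "dB", 1, 1.5)
  # express all concentrations in units 10x smaller: pKi shifts by -1,
  # doses scale by 10
  aff10 <- affinity_table(within(as.data.frame(sys$aff)[
    c("compound_id", "target_node", "pki")], pki <- pki - 1))
  ci2 <- combination_index(sys$net, aff10, "dA", "dB", 10, 15)
  expect_equal(ci2$ci, ci1$ci, tolerance = 1e-9)
  expect_equal(ci2$effect, ci1$effect, tolerance = 1e-9)
})

test_that("min-CI dose ratio tracks the EC50 ratio on the fixture (diagnostic)", {
  net <- lps_pge2_fixture()
  aff <- affinity_table(data.frame(
    compound_id = c("ca", "ca", "ca", "sc", "sc", "sc"),
    target_node = c("TAK1", "NFKB", "COX2", "TAK1", "P38", "COX2"),
    pki = c(5.4, 4.9, 5.1, 4.9, 5.2, 4.7)))
  opt <- optimal_combination(net, aff, "ca", "sc", effect = 50)
  ratio <- opt$dose_ratio / opt$ec50_ratio
  # soft, reported property: optimal ratio within a factor of 2 of the
  # EC50 ratio for multi-shared-target compounds
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})
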
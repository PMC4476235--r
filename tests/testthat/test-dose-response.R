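test_that("hill_eval hits its limits and midpoint", {
  fit <- list(e_max = 100, e_min = 0, ec50 = 30, n = 1.2)
  expect_equal(hill_eval(30, fit), 50)
  expect_equal(hill_eval(0, fit), 0)
  expect_equal(hill_eval(1e12, fit), 100, tolerance = 1e-6)
  fit2 <- list(e_max = 90, e_min = 10, ec50 = 5, n = 2)
  expect_equal(hill_eval(5, fit2), 50)   # (e_max + e_min) / 2
})

test_that("fit_hill recovers generating parameters from noiseless data", {
  theta <- list(e_max = 100, e_min = 0, ec50 = 30, n = 1)
  conc <- 10^seq(log10(0.3), log10(3000), length.out = 12)
  curve <- dose_response_curve("syn", conc, hill_eval(conc, theta),
                               "experimental")
  fit <- fit_hill(curve)
  expect_equal(fit$ec50, 30, tolerance = 1e-6)
  expect_equal(fit$e_max, 100, tolerance = 1e-6)
  expect_equal(fit$e_min, 0, tolerance = 1e-4)  # absolute scale ~100
  expect_equal(fit$n, 1, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("parameter recovery holds across a spread of true parameters", {
  grid <- expand.grid(ec50 = c(3, 45), n = c(0.6, 1.3), e_max = c(95, 110))
  for (k in seq_len(nrow(grid))) {
    theta <- list(e_max = grid$e_max[k], e_min = -2, ec50 = grid$ec50[k],
                  n = grid$n[k])
    conc <- 10^seq(log10(theta$ec50 / 100), log10(theta$ec50 * 100),
                   length.out = 12)
    fit <- fit_hill(dose_response_curve("syn", conc, hill_eval(conc, theta),
                                        "experimental"))
    expect_equal(fit$ec50, theta$ec50, tolerance = 1e-4)
    expect_equal(fit$n, theta$n, tolerance = 1e-4)
  }
})

test_that("EC50 recovery survives 1% additive noise", {
  theta <- list(e_max = 100, e_min = 0, ec50 = 30, n = 1)
  conc <- 10^seq(log10(0.3), log10(3000), length.out = 12)
  set.seed(101)
  y <- hill_eval(conc, theta) + rnorm(length(conc), sd = 1)
  fit <- fit_hill(dose_response_curve("syn", conc, y, "experimental"))
  expect_equal(fit$ec50, 30, tolerance = 0.05)
})

test_that("degenerate inputs are rejected with fit errors", {
  expect_error(
    fit_hill(dose_response_curve("c", c(1, 2, 3, 4), rep(0, 4),
                                 "experimental")),
    class = "pathdose_fit_error")
  expect_error(
    fit_hill(dose_response_curve("c", 1:10, rep(5, 10), "experimental")),
    class = "pathdose_fit_error")
})

test_that("predicted curves are monotone, start at zero and fit the Hill model", {
  net <- lps_pge2_fixture()
  aff <- affinity_table(data.frame(
    compound_id = "cmpd", target_node = c("TAK1", "IKK", "COX2", "P38"),
    pki = c(5.1, 4.8, 5.4, 5.0)))
  zero <- predict_curve(net, aff, "cmpd", c(0, 1, 10))
  expect_equal(zero$responses[1], 0)
  cur <- predict_curve(net, aff, "cmpd")  # default 12-point grid
  expect_length(cur$concentrations, 12)
  expect_true(all(diff(cur$responses) >= -1e-9))
  fit <- fit_hill(cur)
  expect_gte(fit$r2, 0.999)
  # measure variants stay ordered as a geometric mean
  nef <- predict_curve(net, aff, "cmpd", cur$concentrations, measure = "nef")
  ned <- predict_curve(net, aff, "cmpd", cur$concentrations, measure = "ned")
  nfd <- predict_curve(net, aff, "cmpd", cur$concentrations, measure = "nfd")
  expect_true(all(nef$responses >= pmin(ned$responses, nfd$responses) - 1e-9))
  expect_true(all(nef$responses <= pmax(ned$responses, nfd$responses) + 1e-9))
})

test_that("predict_curve validates its inputs", {
  net <- make_chain()
  aff <- affinity_table(data.frame(compound_id = "d", target_node = "A",
                                   pki = 5))
  expect_error(predict_curve(net, aff, "nope"),
               class = "pathdose_validation_error")
  expect_error(predict_curve(net, aff, "d", numeric(0)),
               class = "pathdose_validation_error")
})

test_that("curve files round-trip", {
  cur <- dose_response_curve("c", c(1, 10, 100), c(5, 50, 95),
                             "experimental")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_curve(cur, path)
  back <- read_curve(path, "c")
  expect_equal(back$concentrations, cur$concentrations)
  expect_equal(back$responses, cur$responses)
})

test_that("ec50_correlation matches a closed-form least-squares oracle", {
  # hand least squares: r2 = 1 - SS_res/SS_tot for y ~ a + b x
  r2_hand <- function(x, y) {
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    a <- mean(y) - b * mean(x)
    1 - sum((y - a - b * x)^2) / sum((y - mean(y))^2)
  }
  x <- c(1, 2, 4, 8, 9); y <- c(10, 7, 6, 3, 1)   # anti-correlated
  res <- ec50_correlation(x, y)
  expect_equal(res$r2_ordinary, r2_hand(x, y))
  expect_equal(res$r2_adjusted,
               1 - (1 - r2_hand(x, y)) * (5 - 1) / (5 - 2))
  # perfect linearity and symmetry of ordinary r2 under swapping
  expect_equal(suppressWarnings(ec50_correlation(x, 2 * x + 1)$r2_ordinary), 1)
  expect_equal(ec50_correlation(y, x)$r2_ordinary, res$r2_ordinary)
  expect_error(ec50_correlation(1:2, 1:2),
               class = "pathdose_validation_error")
})

test_that("reference EC50 table reproduces the published agreement", {
  ref <- pge2_reference_fits()
  expect_equal(nrow(ref), 5)
  res <- ec50_correlation(ref$ec50_pred, ref$ec50_exp)
  expect_equal(res$r2_adjusted, 0.93, tolerance = 0.005 / 0.93)
  expect_equal(res$r2_ordinary, 0.94, tolerance = 0.01 / 0.94)
})
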
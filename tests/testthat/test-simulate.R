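test_that("the generator is deterministic and arm substreams are independent", {
  cfg <- simulation_config(n_dq = 50, n_ecwm1 = 40, n_ecwm2 = 30, seed = 9)
  s1 <- simulate_survey(cfg)
  s2 <- simulate_survey(cfg)
  expect_identical(s1, s2)
  # resizing one arm leaves the other arms' draws untouched
  cfg_big <- simulation_config(n_dq = 200, n_ecwm1 = 40, n_ecwm2 = 30,
                               seed = 9)
  s3 <- simulate_survey(cfg_big)
  unrowname <- function(x) { rownames(x) <- NULL; x }
  expect_identical(unrowname(s1[s1$arm == "ECWM1", ]),
                   unrowname(s3[s3$arm == "ECWM1", ]))
  expect_identical(unrowname(s1[s1$arm == "ECWM2", ]),
                   unrowname(s3[s3$arm == "ECWM2", ]))
})

test_that("responses respect each arm's alphabet", {
  svy <- simulate_survey(simulation_config(n_dq = 80, n_ecwm1 = 80,
                                           n_ecwm2 = 80, seed = 2))
  for (it in c("FB1", "FB2", "FB3", "FB4")) {
    expect_true(all(svy[[it]][svy$arm == "DQ"] %in% c("Yes", "No")))
    expect_true(all(svy[[it]][svy$arm != "DQ"] %in% c("A", "B")))
  }
})

test_that("config validation catches bad fields", {
  expect_error(simulation_config(p1 = 0.5), "not 0.5")
  expect_error(simulation_config(n_dq = -1), "non-negative")
  expect_error(simulation_config(dq_misreport_rate = 1.2), "probability")
  expect_error(simulation_config(items = list(FB1 = 2)), "\\[0, 1\\]")
  expect_error(simulation_config(
    items = list(FB1 = list(intercept = -1, slopes = c(x = 0.5)))),
    "covariate")
  expect_error(simulation_config(
    option_preference = list(arm = "DQ", rate = 0.3, option = "B")),
    "ECWM1")
  expect_error(simulation_config(
    option_preference = list(arm = "ECWM1", rate = 0.3, option = "B",
                             items = "FB9")),
    "declared item")
})

test_that("with full adherence both questioning formats recover the truth", {
  cfg <- simulation_config(
    n_dq = 2e5, n_ecwm1 = 2e5, n_ecwm2 = 2e5,
    items = list(FB1 = 0.1), dq_misreport_rate = 0, seed = 3)
  svy <- simulate_survey(cfg)
  dq <- estimate_dq(response_counts(
    sum(svy$FB1[svy$arm == "DQ"] == "Yes"), 2e5))
  a1 <- response_counts(sum(svy$FB1[svy$arm == "ECWM1"] == "A"), 2e5)
  a2 <- response_counts(sum(svy$FB1[svy$arm == "ECWM2"] == "A"), 2e5)
  pl <- pool_ecwm(a1, d_ecwm1, a2, d_ecwm2, check_adherence = FALSE)
  expect_lt(abs(dq$pi_hat - 0.1), 0.005)
  expect_lt(abs(pl$pi_hat - 0.1), 0.005)
  # marginal option-A share sits within 3 MC SEs of lambda_expected
  lam <- lambda_expected(0.1, d_ecwm1)
  expect_lt(abs(a1$lambda_hat - lam), 3 * sqrt(lam * (1 - lam) / 2e5))
})

test_that("one-sided DQ misreporting deflates only the DQ estimate", {
  cfg <- simulation_config(
    n_dq = 1e5, n_ecwm1 = 1e5, n_ecwm2 = 1e5,
    items = list(FB1 = 0.2), dq_misreport_rate = 0.7, seed = 4)
  svy <- simulate_survey(cfg)
  dq_hat <- mean(svy$FB1[svy$arm == "DQ"] == "Yes")
  a1 <- response_counts(sum(svy$FB1[svy$arm == "ECWM1"] == "A"), 1e5)
  a2 <- response_counts(sum(svy$FB1[svy$arm == "ECWM2"] == "A"), 1e5)
  pl <- pool_ecwm(a1, d_ecwm1, a2, d_ecwm2, check_adherence = FALSE)
  expect_lt(abs(dq_hat - 0.3 * 0.2), 0.005)     # carriers answer Yes at 0.3
  expect_lt(abs(pl$pi_hat - 0.2), 0.01)
})

test_that("fully careless arms drive both group estimates to the lambda=1/2 value", {
  cfg <- simulation_config(
    n_dq = 0, n_ecwm1 = 5e4, n_ecwm2 = 5e4,
    items = list(FB1 = 0.05), careless_rate = 1, seed = 5)
  svy <- simulate_survey(cfg)
  a1 <- response_counts(sum(svy$FB1[svy$arm == "ECWM1"] == "A"), 5e4)
  a2 <- response_counts(sum(svy$FB1[svy$arm == "ECWM2"] == "A"), 5e4)
  target <- (0.5 + 0.256 - 1) / (2 * 0.256 - 1)   # = 0.5
  e1 <- estimate_ecwm_group(a1, d_ecwm1)
  e2 <- estimate_ecwm_group(a2, d_ecwm2)
  expect_lt(abs(e1$pi_hat - target), 0.01)
  expect_lt(abs(e2$pi_hat - target), 0.01)
})

test_that("the count-level margin matches the respondent-level generator", {
  # same mechanism composition: preference overrides careless overrides the
  # adherent crosswise response
  cfg <- simulation_config(
    n_dq = 0, n_ecwm1 = 2e5, n_ecwm2 = 0,
    items = list(FB1 = 0.15), careless_rate = 0.2,
    option_preference = list(arm = "ECWM1", rate = 0.25, option = "B"),
    seed = 6)
  svy <- simulate_survey(cfg)
  obs <- mean(svy$FB1 == "A")
  lam <- lambda_expected(0.15, d_ecwm1)
  expected <- 0.25 * 0 + 0.2 * (1 - 0.25) / 2 + (1 - 0.25) * (1 - 0.2) * lam
  expect_lt(abs(obs - expected), 3 * sqrt(expected * (1 - expected) / 2e5))
  set.seed(7)
  cnt <- simulate_ecwm_counts(200, 2e5, 0.15, 0.256, careless_rate = 0.2,
                              pref_rate = 0.25, pref_option = "B")
  expect_lt(abs(mean(cnt) / 2e5 - expected), 3 * sqrt(expected / (200 * 2e5)))
})

test_that("logistic item links produce covariate-dependent prevalence", {
  cfg <- simulation_config(
    n_dq = 4e4, n_ecwm1 = 0, n_ecwm2 = 0,
    items = list(FB1 = list(intercept = -2, slopes = c(x = 1))),
    covariates = list(list(name = "x", type = "normal")),
    dq_misreport_rate = 0, seed = 8)
  svy <- simulate_survey(cfg)
  hi <- mean(svy$FB1[svy$x > 0] == "Yes")
  lo <- mean(svy$FB1[svy$x < 0] == "Yes")
  expect_gt(hi, lo + 0.05)
  p_hi <- mean(plogis(-2 + svy$x[svy$x > 0]))
  expect_lt(abs(hi - p_hi), 0.02)
})

test_that("the study-scale fixture has the right shape", {
  svy <- study_scale_fixture()
  expect_equal(nrow(svy), 1577)
  expect_equal(as.vector(table(svy$arm)[c("DQ", "ECWM1", "ECWM2")]),
               c(530, 523, 524))
  expect_true(all(svy$FB1[svy$arm == "ECWM1"] %in% c("A", "B")))
  expect_true(all(c("moral_norm", "male") %in% names(svy)))
  expect_identical(svy, study_scale_fixture())
})
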
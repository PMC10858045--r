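# helper: survey with a logistic covariate link and truthful DQ responses
sim_link_survey <- function(n_dq, n1, n2, b0 = -1.5,
                            slopes = c(moral_norm = -0.6), seed = 1,
                            misreport = 0) {
  simulate_survey(simulation_config(
    n_dq = n_dq, n_ecwm1 = n1, n_ecwm2 = n2,
    items = list(FB1 = list(intercept = b0, slopes = slopes)),
    covariates = lapply(names(slopes), function(nm)
      list(name = nm, type = "normal")),
    dq_misreport_rate = misreport, seed = seed))
}

test_that("an all-DQ fit reproduces standard logistic regression", {
  svy <- sim_link_survey(2000, 0, 0, seed = 71)
  fit <- fit_rr_logistic(svy, "FB1", "moral_norm", default_designs())
  ref <- glm(I(FB1 == "Yes") ~ moral_norm, binomial(), data = svy)
  expect_true(fit$converged)
  expect_true(fit$format_dropped)
  expect_equal(fit$coefficients$beta, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-5)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
})

test_that("an intercept-only single-arm fit matches the closed-form estimator", {
  svy <- sim_link_survey(0, 3000, 0, b0 = -1.2, seed = 72)
  fit <- fit_rr_logistic(svy, "FB1", character(0), default_designs())
  cnt <- response_counts(sum(svy$FB1 == "A"), nrow(svy))
  grp <- estimate_ecwm_group(cnt, d_ecwm1)
  expect_true(fit$converged)
  expect_equal(plogis(fit$coefficients$beta[1]), grp$pi_hat,
               tolerance = 1e-6)
})

test_that("the likelihood is invariant to which ECWM arm is the reference", {
  svy <- sim_link_survey(500, 500, 500, seed = 73)
  ds <- default_designs()
  fit_a <- fit_rr_logistic(svy, "FB1", "moral_norm", ds)
  # reorder so ECWM2 becomes the reference design; ECWM1 gets flipped
  fit_b <- fit_rr_logistic(svy, "FB1", "moral_norm",
                           ds[c("DQ", "ECWM2", "ECWM1")])
  expect_identical(fit_a$flipped_arms, "ECWM2")
  expect_identical(fit_b$flipped_arms, "ECWM1")
  expect_equal(fit_a$loglik, fit_b$loglik, tolerance = 1e-8)
  expect_equal(fit_a$coefficients$beta, fit_b$coefficients$beta,
               tolerance = 1e-6)
})

test_that("the fitted model nests the intercept-only model", {
  svy <- sim_link_survey(400, 400, 400, seed = 74)
  ds <- default_designs()
  full <- fit_rr_logistic(svy, "FB1", "moral_norm", ds)
  null <- fit_rr_logistic(svy, "FB1", character(0), ds)
  expect_gte(full$loglik, null$loglik - 1e-10)
  expect_false(full$format_dropped)
  expect_true("format" %in% full$coefficients$term)
})

test_that("degenerate inputs are reported, not silently fixed", {
  svy <- sim_link_survey(300, 300, 300, seed = 75)
  svy$flat <- 1
  expect_error(fit_rr_logistic(svy, "FB1", "flat", default_designs()),
               "zero variance")
  svy$bad <- "x"
  expect_error(fit_rr_logistic(svy, "FB1", "bad", default_designs()),
               "numeric")
  expect_error(fit_rr_logistic(svy, "FB9", "moral_norm", default_designs()),
               "not in data")
  # mismatched randomisation probability is caught
  ds <- default_designs()
  ds$ECWM2 <- ecwm_design(0.3, "ECWM2")
  expect_error(fit_rr_logistic(svy, "FB1", "moral_norm", ds),
               "complementary")
})

test_that("complete-case filtering drives n_used", {
  svy <- sim_link_survey(300, 300, 300, seed = 76)
  svy$FB1[1:10] <- NA
  svy$moral_norm[11:15] <- NA
  fit <- fit_rr_logistic(svy, "FB1", "moral_norm", default_designs())
  expect_equal(fit$n_used, nrow(svy) - 15)
})

test_that("a negative covariate effect is recovered through both formats", {
  svy <- sim_link_survey(2000, 2000, 2000, b0 = -1.5,
                         slopes = c(moral_norm = -0.6), seed = 77)
  fit <- fit_rr_logistic(svy, "FB1", "moral_norm", default_designs())
  tab <- fit$coefficients
  b <- tab$beta[tab$term == "moral_norm"]
  expect_lt(b, 0)
  expect_lt(abs(b - (-0.6)), 0.2)
  expect_lt(tab$odds_ratio[tab$term == "moral_norm"], 1)
  expect_true(all(tab$ci_low < tab$odds_ratio & tab$odds_ratio < tab$ci_high))
})

test_that("format moderation: null calibration and power", {
  ds <- default_designs()
  # null: identical covariate effect in both formats, truthful DQ
  set.seed(78)
  seeds <- sample.int(1e6, 300)
  rej <- vapply(seeds, function(s) {
    svy <- sim_link_survey(220, 220, 220, seed = s)
    fit <- test_format_moderation(svy, "FB1", "moral_norm", designs = ds)
    fit$moderation$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)

  # power: the covariate effect exists only in the latent status of ECWM
  # respondents' observations; DQ answers are generated without it, the
  # signature of social desirability suppressing an association under DQ
  sim_suppressed <- function(n_per_arm, seed) {
    set.seed(seed)
    make_arm <- function(arm, p) {
      x <- rnorm(n_per_arm)
      if (arm == "DQ") {
        y <- rbinom(n_per_arm, 1, plogis(-1.5))          # no x effect
        resp <- ifelse(y == 1, "Yes", "No")
      } else {
        z <- rbinom(n_per_arm, 1, plogis(-1.5 - 0.8 * x))
        r <- rbinom(n_per_arm, 1, p)
        resp <- ifelse(z == r, "A", "B")
      }
      data.frame(id = paste0(arm, seq_len(n_per_arm)), arm = arm,
                 FB1 = resp, moral_norm = x, stringsAsFactors = FALSE)
    }
    rbind(make_arm("DQ", NA), make_arm("ECWM1", 0.256),
          make_arm("ECWM2", 0.744))
  }
  set.seed(79)
  seeds2 <- sample.int(1e6, 60)
  hit <- vapply(seeds2, function(s) {
    svy <- sim_suppressed(1667, s)                       # ~5,000 in total
    fit <- test_format_moderation(svy, "FB1", "moral_norm", designs = ds)
    fit$moderation$p_value < 0.05
  }, logical(1))
  expect_gt(mean(hit), 0.8)
})
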
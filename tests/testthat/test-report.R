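write_fixture_files <- function(dir, records = study_scale_fixture(),
                                p1 = 0.256) {
  csv <- file.path(dir, "survey.csv")
  cfg <- file.path(dir, "design.yaml")
  write_survey_csv(records, csv)
  writeLines(c(sprintf("p1: %s", p1),
               "items: [FB1, FB2, FB3, FB4]",
               "covariates: [moral_norm, male]"), cfg)
  list(csv = csv, cfg = cfg)
}

test_that("a simulated survey round-trips through CSV and config", {
  td <- withr::local_tempdir()
  fx <- write_fixture_files(td)
  svy <- load_survey(fx$csv, fx$cfg)
  expect_s3_class(svy, "ecwm_survey")
  expect_equal(nrow(svy$records), 1577)
  expect_identical(svy$items, c("FB1", "FB2", "FB3", "FB4"))
  expect_equal(svy$designs$ECWM2$p, 0.744)
  expect_identical(svy$provenance$csv, fx$csv)
})

test_that("schema and value violations are distinct, row-numbered errors", {
  td <- withr::local_tempdir()
  rec <- study_scale_fixture()

  bad <- rec; bad$FB1[3] <- "Maybe"
  fx <- write_fixture_files(td, bad)
  expect_error(load_survey(fx$csv, fx$cfg), "invalid response.*3")

  bad2 <- rec; bad2$arm[1] <- "ECWM3"
  fx2 <- write_fixture_files(td, bad2)
  expect_error(load_survey(fx2$csv, fx2$cfg), "no design")

  bad3 <- rec; bad3$id[2] <- bad3$id[1]
  fx3 <- write_fixture_files(td, bad3)
  expect_error(load_survey(fx3$csv, fx3$cfg), "duplicate")

  fx4 <- write_fixture_files(td, rec, p1 = 0.5)
  expect_error(load_survey(fx4$csv, fx4$cfg), "unidentified")

  writeLines("p1: 0.256", file.path(td, "empty.yaml"))
  expect_error(load_survey(fx$csv, file.path(td, "empty.yaml")), "items")
})

test_that("missing responses are preserved and excluded per item", {
  rec <- study_scale_fixture()
  rec$FB1[rec$arm == "DQ"][1:20] <- NA
  rep <- run_full_pipeline(as_ecwm_survey(
    rec, items = c("FB1", "FB2", "FB3", "FB4"),
    covariates = c("moral_norm", "male")))
  expect_equal(rep$dq$n[rep$dq$item == "FB1"], 510)
  expect_equal(rep$dq$n[rep$dq$item == "FB2"], 530)
})

test_that("the pipeline reproduces the blocked-item pattern end to end", {
  rep <- run_full_pipeline(study_scale_fixture())
  adh <- rep$adherence
  expect_false(adh$pooled_valid[adh$item == "FB4"])
  expect_identical(adh$preferred_option[adh$item == "FB4"], "B")
  expect_true(all(adh$pooled_valid[adh$item != "FB4"]))
  # the non-adherent item is never pooled or compared
  expect_false("FB4" %in% rep$ecwm$item[rep$ecwm$group == "Pooled"])
  expect_false("FB4" %in% rep$comparison$item)
  # the adherent items show the DQ-deflation signature
  expect_true(all(rep$comparison$ecwm_pct > rep$comparison$dq_pct))
  expect_true(any(grepl("pooling blocked", rep$log)))
})

test_that("empty ECWM arms degrade to a DQ-only report", {
  rec <- study_scale_fixture()
  rec <- rec[rec$arm == "DQ", ]
  rep <- run_full_pipeline(as_ecwm_survey(
    rec, items = c("FB1", "FB2", "FB3", "FB4"),
    covariates = c("moral_norm", "male")))
  expect_false(is.null(rep$dq))
  expect_null(rep$ecwm)
  expect_null(rep$comparison)
  expect_true(any(grepl("DQ-only", rep$log)))
})

test_that("identical inputs give identical reports, and tables match their JSON twins", {
  svy <- as_ecwm_survey(study_scale_fixture(),
                        items = c("FB1", "FB2", "FB3", "FB4"),
                        covariates = c("moral_norm", "male"))
  r1 <- run_full_pipeline(svy)
  r2 <- run_full_pipeline(svy)
  expect_identical(r1[setdiff(names(r1), "provenance")],
                   r2[setdiff(names(r2), "provenance")])

  td <- withr::local_tempdir()
  write_report(r1, td)
  expect_true(all(file.exists(file.path(td, c("dq.csv", "ecwm.csv",
                                              "adherence.csv",
                                              "comparison.csv",
                                              "report.json", "run.log")))))
  js <- jsonlite::read_json(file.path(td, "report.json"),
                            simplifyVector = TRUE)
  for (it in r1$comparison$item) {
    expect_equal(round(js$items[[it]]$pooled$pi_hat, 3),
                 r1$ecwm$estimate[r1$ecwm$item == it &
                                    r1$ecwm$group == "Pooled"])
    expect_equal(round(js$items[[it]]$comparison$z, 3),
                 r1$comparison$z[r1$comparison$item == it])
    expect_equal(round(100 * js$items[[it]]$dq$pi_hat, 3),
                 r1$dq$prevalence_pct[r1$dq$item == it])
  }
})

test_that("the pipeline can carry the measurement-model regression", {
  svy <- simulate_survey(simulation_config(
    n_dq = 400, n_ecwm1 = 400, n_ecwm2 = 400,
    items = list(FB1 = list(intercept = -1.5,
                            slopes = c(moral_norm = -0.6))),
    covariates = list(list(name = "moral_norm", type = "normal")),
    dq_misreport_rate = 0, seed = 91))
  rep <- run_full_pipeline(as_ecwm_survey(svy, items = "FB1",
                                          covariates = "moral_norm"),
                           regression_terms = "moral_norm")
  expect_false(is.null(rep$regression))
  expect_true(all(c("item", "term", "beta", "odds_ratio") %in%
                    names(rep$regression)))
  expect_true("moral_norm" %in% rep$regression$term)
})

test_that("a report plot is produced without error", {
  rep <- run_full_pipeline(study_scale_fixture())
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(rep))
})
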
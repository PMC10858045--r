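## Survey container, CSV/config I/O, and the table-producing pipeline:
## DQ prevalences -> ECWM group estimates -> adherence tests -> pooling of
## adherent items -> DQ-vs-ECWM comparison -> optional measurement-model
## regression.  Items whose adherence test fails are never pooled, compared
## or regressed.

DQ_ALPHABET <- c("Yes", "No")
ECWM_ALPHABET <- c("A", "B")

#' Assemble a survey dataset from respondent records
#'
#' Validates respondent-level records against the per-arm questioning
#' designs: every arm must have a design, and every non-missing response
#' must belong to its arm's response alphabet (\code{Yes}/\code{No} for DQ,
#' \code{A}/\code{B} for crosswise arms).  Invalid values are reported with
#' their row numbers, never coerced.
#'
#' @param records data frame with columns \code{id}, \code{arm}, one
#'   response column per item, and any covariate columns.
#' @param designs named list of \code{"ecwm_design"}s covering every arm
#'   value in \code{records$arm}.
#' @param items character vector of item (response) column names.
#' @param covariates character vector of covariate column names (optional).
#' @param provenance optional list recorded verbatim (input paths, hashes).
#' @return An object of class \code{"ecwm_survey"}.
#' @export
as_ecwm_survey <- function(records, designs = default_designs(),
                           items, covariates = character(0),
                           provenance = list()) {
  stopifnot(is.data.frame(records))
  need <- c("id", "arm", items, covariates)
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(records$id))
    stop("duplicate respondent id(s): ",
         paste(utils::head(unique(records$id[duplicated(records$id)]), 5),
               collapse = ", "))
  arms <- unique(as.character(records$arm))
  unknown <- setdiff(arms, names(designs))
  if (length(unknown))
    stop("arm(s) with no design in the config: ",
         paste(unknown, collapse = ", "))
  for (it in items) {
    v <- as.character(records[[it]])
    alphabet <- ifelse(
      vapply(as.character(records$arm),
             function(a) is_dq_design(designs[[a]]), logical(1)),
      "DQ", "ECWM")
    ok <- is.na(v) | (alphabet == "DQ" & v %in% DQ_ALPHABET) |
      (alphabet == "ECWM" & v %in% ECWM_ALPHABET)
    if (!all(ok))
      stop("item '", it, "': invalid response value(s) in row(s) ",
           paste(utils::head(which(!ok), 10), collapse = ", "),
           " (e.g. '", v[which(!ok)[1]], "'); DQ responses must be Yes/No ",
           "and ECWM responses A/B")
  }
  structure(
    list(records = records, designs = designs, items = items,
         covariates = covariates, provenance = provenance),
    class = "ecwm_survey"
  )
}

#' Load a respondent CSV and a design config into a survey dataset
#'
#' The CSV must have columns \code{id}, \code{arm}, one response column per
#' item and any covariate columns; empty cells are missing responses.  The
#' config (YAML or JSON) declares \code{p1} (ECWM group-1 randomisation
#' probability; group 2 is complementary), \code{items} (response column
#' names) and optionally \code{covariates}.  A config with \code{p1 = 0.5}
#' is rejected at load time because the crosswise estimator is then
#' unidentified.
#'
#' @param csv_path path to the respondent-level CSV.
#' @param config_path path to the YAML/JSON design config.
#' @return An \code{"ecwm_survey"}; provenance records both paths, the
#'   config's MD5 hash, and the load timestamp.
#' @export
load_survey <- function(csv_path, config_path) {
  cfg <- if (grepl("\\.json$", config_path, ignore.case = TRUE))
    jsonlite::read_json(config_path, simplifyVector = TRUE)
  else yaml::read_yaml(config_path)
  if (is.null(cfg$p1) || is.null(cfg$items))
    stop("config must declare 'p1' and 'items'")
  designs <- default_designs(cfg$p1)   # errors on p1 = 0.5 or out of range
  records <- utils::read.csv(csv_path, stringsAsFactors = FALSE,
                             na.strings = c("", "NA"))
  as_ecwm_survey(
    records, designs, items = as.character(cfg$items),
    covariates = as.character(cfg$covariates %||% character(0)),
    provenance = list(csv = csv_path, config = config_path,
                      config_md5 = unname(tools::md5sum(config_path)),
                      loaded = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  )
}

#' Write respondent records as CSV in the dialect \code{load_survey} reads
#'
#' @param records respondent data frame (e.g. from
#'   \code{\link{simulate_survey}}).
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_survey_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

arm_item_counts <- function(records, arm, item) {
  v <- as.character(records[[item]][records$arm == arm])
  v <- v[!is.na(v)]
  if (!length(v)) return(NULL)
  response_counts(sum(v %in% c("Yes", "A")), length(v))
}

#' Run the full DQ / ECWM analysis pipeline
#'
#' Orchestrates every analysis stage in its natural order: per-item DQ
#' prevalences; per-group crosswise estimates; the G2 adherence test between
#' the two ECWM groups; joint-ML pooling for items whose adherence test is
#' non-significant; the two-proportion Z comparison of DQ against the
#' pooled crosswise estimate for those items; and, when covariate terms are
#' supplied, the measurement-model logistic regression per adherent item.
#' An item that fails the adherence test is flagged and excluded from
#' pooling, comparison and regression.  With no ECWM respondents the
#' pipeline degrades to a DQ-only report.
#'
#' @param survey an \code{"ecwm_survey"} (or a respondent data frame, in
#'   which case \code{designs}/\code{items} are taken from the defaults and
#'   the data's columns).
#' @param alpha significance level for the adherence decision and the
#'   comparison flag.
#' @param regression_terms optional character vector of covariate columns;
#'   when supplied, the measurement-model regression is fitted for each
#'   adherent item.
#' @return An object of class \code{"ecwm_report"}: list of tidy tables
#'   (\code{dq}, \code{ecwm}, \code{adherence}, \code{comparison},
#'   \code{regression}), the full-precision \code{estimates} list, a
#'   \code{log} of stage lines, and \code{alpha}.  Table proportions are
#'   rounded to 3 decimals (DQ prevalences printed as percentages);
#'   full precision is retained in \code{estimates} and the JSON bundle.
#' @seealso \code{\link{write_report}}
#' @export
run_full_pipeline <- function(survey, alpha = 0.05,
                              regression_terms = NULL) {
  if (is.data.frame(survey)) {
    designs <- default_designs()
    items <- setdiff(names(survey),
                     c("id", "arm", regression_terms %||% character(0)))
    items <- items[vapply(survey[items], function(v)
      all(is.na(v) | v %in% c(DQ_ALPHABET, ECWM_ALPHABET)), logical(1))]
    survey <- as_ecwm_survey(survey, designs, items,
                             covariates = regression_terms %||% character(0))
  }
  stopifnot(inherits(survey, "ecwm_survey"))
  rec <- survey$records
  designs <- survey$designs
  items <- survey$items
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  arms_present <- function(a) any(rec$arm == a)
  has_dq <- arms_present("DQ")
  has_ecwm <- arms_present("ECWM1") && arms_present("ECWM2")
  note("pipeline start: %d records, %d items, arms: %s", nrow(rec),
       length(items), paste(unique(rec$arm), collapse = ", "))
  if (!has_ecwm)
    note("ECWM arm(s) empty: producing a DQ-only report")

  est <- list()
  dq_rows <- list(); ecwm_rows <- list(); adh_rows <- list()
  cmp_rows <- list(); reg_rows <- list()

  for (it in items) {
    est[[it]] <- list()
    if (has_dq) {
      cnt <- arm_item_counts(rec, "DQ", it)
      if (!is.null(cnt)) {
        e <- estimate_dq(cnt)
        est[[it]]$dq <- e
        dq_rows[[it]] <- data.frame(
          item = it, n = cnt$n_total, n_yes = cnt$n_a,
          prevalence_pct = round(100 * e$pi_hat, 3))
        note("%s: DQ prevalence %.3f%% (n = %d)", it, 100 * e$pi_hat,
             cnt$n_total)
      }
    }
    if (!has_ecwm) next
    c1 <- arm_item_counts(rec, "ECWM1", it)
    c2 <- arm_item_counts(rec, "ECWM2", it)
    if (is.null(c1) || is.null(c2)) {
      note("%s: missing ECWM responses in one group; skipping ECWM stages", it)
      next
    }
    d1 <- designs$ECWM1; d2 <- designs$ECWM2
    e1 <- estimate_ecwm_group(c1, d1)
    e2 <- estimate_ecwm_group(c2, d2)
    adh <- adherence_lr_test(c1, d1, c2, d2, alpha = alpha)
    est[[it]]$ecwm1 <- e1
    est[[it]]$ecwm2 <- e2
    est[[it]]$adherence <- adh
    grp_row <- function(e, g) data.frame(
      item = it, group = g, estimate = round(e$pi_hat, 3),
      se = round(e$se, 3), truncated = e$truncated)
    ecwm_rows[[paste0(it, "_1")]] <- grp_row(e1, "ECWM1")
    ecwm_rows[[paste0(it, "_2")]] <- grp_row(e2, "ECWM2")
    adh_rows[[it]] <- data.frame(
      item = it, g2 = round(adh$g2, 3), df = adh$df,
      p_value = round(adh$p_value, 3), pooled_valid = adh$pooled_valid,
      preferred_option = adh$preferred_option)
    if (!adh$pooled_valid) {
      note("%s: pooling blocked, G2 = %.3f (p = %.4g < %g); systematic preference for option %s",
           it, adh$g2, adh$p_value, alpha, adh$preferred_option)
      next
    }
    pooled <- pool_ecwm(c1, d1, c2, d2, check_adherence = FALSE)
    est[[it]]$pooled <- pooled
    ecwm_rows[[paste0(it, "_p")]] <- grp_row(pooled, "Pooled")
    note("%s: adherence ok (G2 = %.3f, p = %.3f); pooled estimate %.3f (SE %.3f)",
         it, adh$g2, adh$p_value, pooled$pi_hat, pooled$se)
    if (has_dq && !is.null(est[[it]]$dq)) {
      cmp <- compare_dq_ecwm(est[[it]]$dq, pooled, alpha = alpha, item = it)
      est[[it]]$comparison <- cmp
      cmp_rows[[it]] <- data.frame(
        item = it, dq_pct = round(100 * cmp$est_dq, 3),
        ecwm_pct = round(100 * cmp$est_ecwm, 3),
        z = round(cmp$z, 3), p_value = round(cmp$p_value, 3),
        significant = cmp$significant)
      note("%s: DQ vs ECWM z = %.3f (p = %.4g)", it, cmp$z, cmp$p_value)
    }
    if (!is.null(regression_terms)) {
      fit <- fit_rr_logistic(rec, it, regression_terms, designs)
      est[[it]]$regression <- fit
      tab <- fit$coefficients
      tab <- cbind(item = it, tab)
      reg_rows[[it]] <- tab
      note("%s: measurement-model regression on %s (n = %d, converged: %s)",
           it, paste(regression_terms, collapse = ", "), fit$n_used,
           fit$converged)
    }
  }

  bind <- function(rows) if (length(rows)) {
    out <- do.call(rbind, rows); rownames(out) <- NULL; out
  } else NULL
  structure(
    list(dq = bind(dq_rows), ecwm = bind(ecwm_rows),
         adherence = bind(adh_rows), comparison = bind(cmp_rows),
         regression = bind(reg_rows), estimates = est, log = log,
         alpha = alpha, items = items,
         provenance = survey$provenance),
    class = "ecwm_report"
  )
}

#' @export
print.ecwm_report <- function(x, ...) {
  show <- function(tab, title) {
    if (is.null(tab)) return(invisible())
    cat("\n== ", title, " ==\n", sep = "")
    print(tab, row.names = FALSE)
  }
  show(x$dq, "Direct questioning prevalence (%)")
  show(x$ecwm, "ECWM group and pooled estimates")
  show(x$adherence, "Instruction-adherence tests")
  show(x$comparison, "DQ vs ECWM comparison (two-proportion Z)")
  show(x$regression, "Measurement-model logistic regression")
  invisible(x)
}

report_json_payload <- function(report) {
  num <- function(e) if (is.null(e)) NULL else
    list(pi_hat = e$pi_hat, se = e$se, ci_low = e$ci_low,
         ci_high = e$ci_high, method = e$method, truncated = e$truncated,
         raw = e$raw, n = e$n)
  items <- lapply(report$estimates, function(st) {
    out <- list(dq = num(st$dq), ecwm1 = num(st$ecwm1),
                ecwm2 = num(st$ecwm2), pooled = num(st$pooled))
    if (!is.null(st$adherence))
      out$adherence <- list(g2 = st$adherence$g2, df = st$adherence$df,
                            p_value = st$adherence$p_value,
                            pooled_valid = st$adherence$pooled_valid,
                            preferred_option = st$adherence$preferred_option)
    if (!is.null(st$comparison))
      out$comparison <- list(z = st$comparison$z,
                             p_value = st$comparison$p_value,
                             significant = st$comparison$significant)
    if (!is.null(st$regression))
      out$regression <- st$regression$coefficients
    out[!vapply(out, is.null, logical(1))]
  })
  list(alpha = report$alpha, items = items, log = report$log,
       provenance = report$provenance)
}

#' Write a report bundle to disk
#'
#' Writes each tidy table as CSV, the full-precision machine-readable
#' bundle as JSON, and the stage log as plain text.
#'
#' @param report an \code{"ecwm_report"}.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ecwm_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("dq", "ecwm", "adherence", "comparison", "regression")) {
    if (!is.null(report[[nm]]))
      utils::write.csv(report[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  jsonlite::write_json(report_json_payload(report),
                       file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' Plot DQ and pooled ECWM prevalence estimates with 95\% intervals
#'
#' @param x an \code{"ecwm_report"}.
#' @param ... passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.ecwm_report <- function(x, ...) {
  items <- names(x$estimates)
  pick <- function(it, which) x$estimates[[it]][[which]]
  has <- vapply(items, function(it)
    !is.null(pick(it, "dq")) || !is.null(pick(it, "pooled")), logical(1))
  items <- items[has]
  if (!length(items)) stop("no estimates to plot")
  k <- length(items)
  xs <- seq_len(k)
  ymax <- 0
  for (it in items) for (w in c("dq", "pooled")) {
    e <- pick(it, w); if (!is.null(e)) ymax <- max(ymax, e$ci_high)
  }
  graphics::plot(NA, xlim = c(0.5, k + 0.5), ylim = c(0, ymax * 1.05),
                 xaxt = "n", xlab = "", ylab = "Prevalence",
                 main = "DQ vs pooled ECWM prevalence (95% CI)", ...)
  graphics::axis(1, at = xs, labels = items)
  off <- 0.12
  for (i in seq_len(k)) {
    for (w in c("dq", "pooled")) {
      e <- pick(items[i], w)
      if (is.null(e)) next
      xx <- i + if (w == "dq") -off else off
      pch <- if (w == "dq") 19 else 17
      graphics::points(xx, e$pi_hat, pch = pch)
      graphics::arrows(xx, e$ci_low, xx, e$ci_high, angle = 90, code = 3,
                       length = 0.04)
    }
  }
  graphics::legend("topright", pch = c(19, 17),
                   legend = c("DQ", "ECWM pooled"), bty = "n")
  invisible(x)
}
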
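#' Default arm designs for a three-arm DQ / ECWM survey
#'
#' @param p1 randomisation probability of ECWM group 1; group 2 receives the
#'   complementary probability \eqn{1 - p_1}.  The default 0.256 is the
#'   birth-month randomisation probability used throughout this package's
#'   worked examples (three consecutive months of England live births).
#' @return Named list of \code{"ecwm_design"} objects for arms \code{DQ},
#'   \code{ECWM1}, \code{ECWM2}.
#' @export
default_designs <- function(p1 = 0.256) {
  list(DQ = dq_design(),
       ECWM1 = ecwm_design(p1, "ECWM1"),
       ECWM2 = ecwm_design(1 - p1, "ECWM2"))
}

#' Configuration for the synthetic survey generator
#'
#' Collects and validates every knob of the respondent-level simulator.
#' The defaults describe the survey conditions this package is built
#' around: three arms of 530 / 523 / 524 respondents, four sensitive items
#' with prevalences between 0.06 and 0.18, randomisation probability
#' \eqn{p_1 = 0.256}, and strong one-sided under-reporting (rate 0.7) of
#' carriers under direct questioning.
#'
#' Items are given either as a plain prevalence (latent status drawn
#' \code{Bernoulli(pi)}) or as a logistic link
#' \code{list(intercept =, slopes = c(name = beta, ...))} over the declared
#' covariates (latent status \code{Bernoulli(plogis(intercept + x'slopes))}).
#'
#' Two non-adherence mechanisms are available for the ECWM arms, matching
#' the two failure modes that matter for the crosswise design:
#' \emph{careless} responding (a respondent picks A or B uniformly at
#' random, item by item) and \emph{systematic option preference} (a
#' respondent always gives one fixed option on the affected items).  A
#' respondent flagged for both follows the preference.
#'
#' @param n_dq,n_ecwm1,n_ecwm2 arm sizes (non-negative integers).
#' @param items named list (or numeric vector) of item specifications; see
#'   Details.
#' @param p1 ECWM group-1 randomisation probability, in (0,1), not 0.5.
#' @param dq_misreport_rate probability that a carrier answers "No" under
#'   DQ (one-sided social desirability; non-carriers never false-confess).
#' @param careless_rate probability that an ECWM respondent is careless.
#' @param option_preference \code{NULL}, or
#'   \code{list(arm =, rate =, option = "A"|"B", items = NULL)}: in the
#'   named arm a fraction \code{rate} of respondents always answer
#'   \code{option} on \code{items} (default: all items).
#' @param covariates \code{NULL}, or a list of
#'   \code{list(name =, type = "normal"|"bernoulli", prob = 0.5)};
#'   normal covariates are standard-normal (standardised psychological
#'   scales), bernoulli covariates are 0/1 demographics.
#' @param seed integer seed; identical seed and config give byte-identical
#'   surveys.  Each arm draws from its own substream (derived from
#'   \code{seed}), so changing one arm's size does not reshuffle the others.
#' @return A validated list of class \code{"ecwm_sim_config"}.
#' @export
simulation_config <- function(n_dq = 530, n_ecwm1 = 523, n_ecwm2 = 524,
                              items = list(FB1 = 0.18, FB2 = 0.11,
                                           FB3 = 0.06, FB4 = 0.18),
                              p1 = 0.256,
                              dq_misreport_rate = 0.7,
                              careless_rate = 0,
                              option_preference = NULL,
                              covariates = NULL,
                              seed = 1L) {
  chk_n <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
        x != floor(x))
      stop("'", nm, "' must be a single non-negative integer")
  }
  chk_rate <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
      stop("'", nm, "' must be a single probability in [0, 1]")
  }
  chk_n(n_dq, "n_dq"); chk_n(n_ecwm1, "n_ecwm1"); chk_n(n_ecwm2, "n_ecwm2")
  chk_rate(dq_misreport_rate, "dq_misreport_rate")
  chk_rate(careless_rate, "careless_rate")
  if (!is.numeric(p1) || length(p1) != 1L || p1 <= 0 || p1 >= 1 ||
      abs(p1 - 0.5) < 1e-9)
    stop("'p1' must be in (0, 1) and not 0.5")
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != floor(seed) || abs(seed) >= 2^31 - 1000)
    stop("'seed' must be a single integer below 2^31 - 1000 in magnitude")

  if (is.numeric(items)) items <- as.list(items)
  if (!is.list(items) || is.null(names(items)) || any(names(items) == ""))
    stop("'items' must be a named list of prevalences or logistic links")
  cov_names <- vapply(covariates, function(cv) cv$name %||% "",
                      character(1))
  for (nm in names(items)) {
    it <- items[[nm]]
    if (is.numeric(it) && length(it) == 1L) {
      if (is.na(it) || it < 0 || it > 1)
        stop("item '", nm, "': prevalence must be in [0, 1]")
    } else if (is.list(it)) {
      if (is.null(it$intercept) || !is.numeric(it$intercept))
        stop("item '", nm, "': logistic link needs a numeric 'intercept'")
      sl <- it$slopes %||% numeric(0)
      if (length(sl) && (is.null(names(sl)) ||
                         !all(names(sl) %in% cov_names)))
        stop("item '", nm, "': every slope must be named after a declared ",
             "covariate")
    } else stop("item '", nm, "': must be a prevalence or a logistic link")
  }
  if (!is.null(covariates)) {
    if (!is.list(covariates)) stop("'covariates' must be a list")
    for (cv in covariates) {
      if (is.null(cv$name) || !nzchar(cv$name))
        stop("each covariate needs a 'name'")
      if (!(cv$type %||% "normal") %in% c("normal", "bernoulli"))
        stop("covariate '", cv$name, "': type must be 'normal' or 'bernoulli'")
      chk_rate(cv$prob %||% 0.5, paste0("covariates$", cv$name, "$prob"))
    }
  }
  if (!is.null(option_preference)) {
    op <- option_preference
    if (!is.list(op) || is.null(op$arm) || is.null(op$rate) ||
        is.null(op$option))
      stop("'option_preference' must be list(arm =, rate =, option =, items =)")
    if (!op$arm %in% c("ECWM1", "ECWM2"))
      stop("option_preference$arm must be 'ECWM1' or 'ECWM2'")
    chk_rate(op$rate, "option_preference$rate")
    if (!op$option %in% c("A", "B"))
      stop("option_preference$option must be 'A' or 'B'")
    if (!is.null(op$items) && !all(op$items %in% names(items)))
      stop("option_preference$items must be declared item names")
  }
  structure(
    list(n_dq = n_dq, n_ecwm1 = n_ecwm1, n_ecwm2 = n_ecwm2,
         items = items, p1 = p1,
         dq_misreport_rate = dq_misreport_rate,
         careless_rate = careless_rate,
         option_preference = option_preference,
         covariates = covariates, seed = as.integer(seed)),
    class = "ecwm_sim_config"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a generator configuration from a YAML or JSON file
#'
#' @param path file path; format chosen by extension (\code{.yaml} /
#'   \code{.yml} / \code{.json}).
#' @return A validated \code{"ecwm_sim_config"}.
#' @export
read_simulation_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  if (!is.null(raw$items)) raw$items <- as.list(raw$items)
  do.call(simulation_config, raw)
}

draw_covariates <- function(n, covariates) {
  out <- list()
  for (cv in covariates) {
    out[[cv$name]] <- switch(
      cv$type %||% "normal",
      normal = stats::rnorm(n),
      bernoulli = stats::rbinom(n, 1, cv$prob %||% 0.5)
    )
  }
  out
}

latent_status <- function(n, item_spec, covs) {
  if (is.numeric(item_spec)) return(stats::rbinom(n, 1, item_spec))
  eta <- rep(item_spec$intercept, n)
  for (nm in names(item_spec$slopes %||% numeric(0)))
    eta <- eta + item_spec$slopes[[nm]] * covs[[nm]]
  stats::rbinom(n, 1, stats::plogis(eta))
}

simulate_arm <- function(arm, n, config) {
  if (n == 0L) return(NULL)
  covs <- draw_covariates(n, config$covariates)
  resp <- list()
  if (arm == "DQ") {
    for (nm in names(config$items)) {
      z <- latent_status(n, config$items[[nm]], covs)
      hide <- stats::rbinom(n, 1, config$dq_misreport_rate)
      resp[[nm]] <- ifelse(z == 1 & hide == 0, "Yes", "No")
    }
  } else {
    p_arm <- if (arm == "ECWM1") config$p1 else 1 - config$p1
    careless <- stats::rbinom(n, 1, config$careless_rate) == 1
    op <- config$option_preference
    prefers <- if (!is.null(op) && op$arm == arm)
      stats::rbinom(n, 1, op$rate) == 1 else rep(FALSE, n)
    for (nm in names(config$items)) {
      z <- latent_status(n, config$items[[nm]], covs)
      r <- stats::rbinom(n, 1, p_arm)          # randomiser answers "Yes"
      ans <- ifelse(z == r, "A", "B")          # adherent crosswise response
      cl <- careless
      ans[cl] <- c("A", "B")[1 + stats::rbinom(sum(cl), 1, 0.5)]
      if (!is.null(op) && op$arm == arm &&
          (is.null(op$items) || nm %in% op$items))
        ans[prefers] <- op$option              # preference overrides careless
      resp[[nm]] <- ans
    }
  }
  out <- data.frame(id = sprintf("%s_%05d", arm, seq_len(n)), arm = arm,
                    stringsAsFactors = FALSE)
  for (nm in names(resp)) out[[nm]] <- resp[[nm]]
  for (nm in names(covs)) out[[nm]] <- covs[[nm]]
  out
}

#' Simulate a respondent-level DQ / ECWM survey
#'
#' Generates one survey with the data-generating process the analysis
#' pipeline assumes: covariates are drawn per respondent; each item's latent
#' carrier status is Bernoulli (constant prevalence or logistic in the
#' covariates); DQ respondents answer "Yes" iff they are carriers and do not
#' misreport (non-carriers never false-confess); ECWM respondents answer
#' option A iff their sensitive answer matches their randomiser draw, unless
#' overridden by the careless or option-preference mechanisms.
#'
#' Each arm is generated from its own seed substream, so arm outputs are
#' reproducible independently of the other arms' sizes.
#'
#' @param config an \code{"ecwm_sim_config"} from
#'   \code{\link{simulation_config}}.
#' @return A data frame with columns \code{id}, \code{arm}, one response
#'   column per item (\code{Yes}/\code{No} in the DQ arm, \code{A}/\code{B}
#'   in the ECWM arms), and one column per covariate.
#' @examples
#' svy <- simulate_survey(simulation_config(seed = 1))
#' table(svy$arm)
#' @export
simulate_survey <- function(config) {
  stopifnot(inherits(config, "ecwm_sim_config"))
  offsets <- c(DQ = 101L, ECWM1 = 202L, ECWM2 = 303L)
  sizes <- c(DQ = config$n_dq, ECWM1 = config$n_ecwm1, ECWM2 = config$n_ecwm2)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  parts <- list()
  for (arm in names(sizes)) {
    set.seed(config$seed + offsets[[arm]])   # per-arm substream
    parts[[arm]] <- simulate_arm(arm, sizes[[arm]], config)
  }
  out <- do.call(rbind, parts[!vapply(parts, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Study-scale fixture survey
#'
#' A fixed-seed survey at the scale of the motivating study: arms of
#' 530 (DQ), 523 (ECWM1) and 524 (ECWM2) respondents — 1577 in all — with
#' four falsification-behaviour items whose true prevalences (0.18, 0.11,
#' 0.06, 0.18) sit near the pooled crosswise estimates that scale of survey
#' produces, carrier under-reporting at rate 0.7 in the DQ arm, and a
#' synthetic non-adherence pattern on the fourth item: 30\% of ECWM1
#' respondents always answer option B on \code{FB4}.  The fixture exercises
#' the full pipeline — DQ deflation on every item, valid pooling on three
#' items, and a blocked, non-adherent fourth item.
#'
#' @param seed integer seed (fixed default so the fixture is stable).
#' @return A respondent data frame as from \code{\link{simulate_survey}}.
#' @export
study_scale_fixture <- function(seed = 4242L) {
  cfg <- simulation_config(
    option_preference = list(arm = "ECWM1", rate = 0.3, option = "B",
                             items = "FB4"),
    covariates = list(list(name = "moral_norm", type = "normal"),
                      list(name = "male", type = "bernoulli", prob = 0.49)),
    seed = seed
  )
  simulate_survey(cfg)
}

#' Count-level simulation of arm totals
#'
#' The option-A (or DQ "Yes") count in an arm is a sufficient statistic, and
#' under the respondent-level mechanism of \code{\link{simulate_survey}} it
#' is exactly binomial.  These draws reproduce that marginal directly —
#' including the careless / option-preference / misreporting mechanisms —
#' which makes large calibration studies (bias, test size, power) cheap.
#'
#' For an ECWM arm the success probability is
#' \deqn{P(A) = r\,[opt = A] + c(1 - r)/2 + (1 - r)(1 - c)\,\lambda(\pi, p),}
#' with preference rate \eqn{r}, careless rate \eqn{c} and the adherent
#' option-A probability \eqn{\lambda}; for a DQ arm it is
#' \eqn{\pi(1 - m)} with misreporting rate \eqn{m}.
#'
#' @param n_reps number of replicate arms to draw.
#' @param n respondents per arm.
#' @param pi true prevalence.
#' @param p randomisation probability of the arm.
#' @param careless_rate,pref_rate,pref_option non-adherence mechanism rates
#'   as in \code{\link{simulation_config}}.
#' @param misreport_rate DQ carrier under-reporting rate.
#' @return Integer vector of length \code{n_reps}: option-A ("Yes") counts.
#' @export
simulate_ecwm_counts <- function(n_reps, n, pi, p, careless_rate = 0,
                                 pref_rate = 0, pref_option = "B") {
  stopifnot(pi >= 0, pi <= 1, careless_rate >= 0, pref_rate >= 0,
            careless_rate <= 1, pref_rate <= 1)
  lam <- (1 - p) + (2 * p - 1) * pi
  pa <- pref_rate * (pref_option == "A") +
    careless_rate * (1 - pref_rate) / 2 +
    (1 - pref_rate) * (1 - careless_rate) * lam
  stats::rbinom(n_reps, n, pa)
}

#' @rdname simulate_ecwm_counts
#' @export
simulate_dq_counts <- function(n_reps, n, pi, misreport_rate = 0) {
  stopifnot(pi >= 0, pi <= 1, misreport_rate >= 0, misreport_rate <= 1)
  stats::rbinom(n_reps, n, pi * (1 - misreport_rate))
}
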
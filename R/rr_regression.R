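## Measurement-model ("randomized response") logistic regression.
##
## The latent sensitive status follows a logistic model
##   P(carrier | x) = sigma(x'beta),
## but the status is observed only through the questioning design of each
## respondent's arm: the observed binary response (Yes/A coded 1) has
##   P(y = 1 | x) = q = c + d * sigma(x'beta),
## with (c, d) = (0, 1) under DQ and (1 - p, 2p - 1) under a crosswise
## design with randomisation probability p.  For any beta, q stays inside
## [min(c, c + d), max(c, c + d)], a closed subinterval of (0, 1) for
## interior crosswise designs, so the log-likelihood is evaluable
## everywhere and DQ is the degenerate case of ordinary logistic
## regression.

rr_loglik_parts <- function(beta, X, y, cc, dd) {
  eta <- drop(X %*% beta)
  s <- stats::plogis(eta)
  q <- cc + dd * s
  q <- pmin(pmax(q, 1e-300), 1 - 1e-16)
  ll <- sum(y * log(q) + (1 - y) * log(1 - q))
  r <- y / q - (1 - y) / (1 - q)
  u <- dd * s * (1 - s)                      # dq/deta
  grad <- drop(crossprod(X, r * u))
  h <- (-y / q^2 - (1 - y) / (1 - q)^2) * u^2 + r * u * (1 - 2 * s)
  H <- crossprod(X, X * h)                   # d2 loglik / dbeta dbeta'
  list(ll = ll, grad = grad, H = H)
}

#' Logistic regression of a latent sensitive status observed through
#' heterogeneous questioning designs
#'
#' Fits, by maximum likelihood, the logistic model
#' \eqn{P(\mathrm{carrier}\mid x) = \sigma(x'\beta)} when the carrier status
#' is observed through the questioning design of each respondent's arm:
#' direct questioning observes the status itself, while a crosswise (ECWM)
#' arm observes option A with probability
#' \eqn{q = (1 - p) + (2p - 1)\,\sigma(x'\beta)}.  Responses from any
#' crosswise arm whose randomisation probability is complementary to the
#' reference arm's are first re-coded with the flip transformation (A/B
#' swapped, \eqn{p \to 1 - p}) so that all crosswise respondents share one
#' design; the likelihood is invariant to which arm is flipped.
#'
#' The linear predictor always contains an intercept and — when both
#' questioning formats are present — the effect-coded format
#' (\eqn{-1} = DQ, \eqn{+1} = ECWM) as a control term, followed by the
#' requested covariates.  Estimation is damped Newton--Raphson with analytic
#' gradient and Hessian from a fixed zero start, so fits are deterministic;
#' convergence requires the gradient norm to fall below \code{grad_tol}.
#' Wald standard errors come from the observed information at the optimum.
#'
#' @param data data frame of respondent records with columns \code{arm},
#'   one response column per item (\code{Yes}/\code{No} for DQ arms,
#'   \code{A}/\code{B} for ECWM arms), and numeric covariate columns.
#' @param item name of the item (response column) to analyse.
#' @param terms character vector of covariate column names (possibly empty).
#' @param designs named list of \code{"ecwm_design"} objects, one per arm
#'   value occurring in \code{data$arm}.
#' @param interaction optional name of one covariate in \code{terms} whose
#'   format-moderation interaction (covariate \eqn{\times} effect-coded
#'   format) is added to the model; see
#'   \code{\link{test_format_moderation}}.
#' @param max_iter,grad_tol Newton iteration cap and convergence tolerance
#'   on the Euclidean gradient norm.
#' @return An object of class \code{"ecwm_rr_fit"}: list with
#'   \code{coefficients} (data frame: \code{term}, \code{beta}, \code{se},
#'   \code{odds_ratio}, \code{ci_low}, \code{ci_high}, \code{p_value}),
#'   \code{loglik}, \code{converged}, \code{n_used}, \code{gradient_norm},
#'   \code{iterations}, \code{vcov}, and notes on dropped terms.
#'   Inference is Wald-based with no multiple-testing correction across
#'   terms or items.
#' @examples
#' cfg <- simulation_config(n_dq = 300, n_ecwm1 = 300, n_ecwm2 = 300,
#'   items = list(FB1 = list(intercept = -2, slopes = c(moral_norm = -0.6))),
#'   covariates = list(list(name = "moral_norm", type = "normal")),
#'   seed = 7)
#' svy <- simulate_survey(cfg)
#' fit_rr_logistic(svy, "FB1", "moral_norm", default_designs())
#' @export
fit_rr_logistic <- function(data, item, terms = character(), designs,
                            interaction = NULL,
                            max_iter = 100L, grad_tol = 1e-8) {
  stopifnot(is.data.frame(data), is.character(item), length(item) == 1L)
  if (!item %in% names(data)) stop("item column '", item, "' not in data")
  if (!all(terms %in% names(data)))
    stop("covariate column(s) not in data: ",
         paste(setdiff(terms, names(data)), collapse = ", "))
  if (!"arm" %in% names(data)) stop("data must have an 'arm' column")
  arms <- unique(as.character(data$arm))
  if (!all(arms %in% names(designs)))
    stop("no design supplied for arm(s): ",
         paste(setdiff(arms, names(designs)), collapse = ", "))
  for (a in arms) stopifnot(inherits(designs[[a]], "ecwm_design"))
  if (!is.null(interaction)) {
    stopifnot(length(interaction) == 1L)
    if (!interaction %in% terms)
      stop("'interaction' must name one of the covariates in 'terms'")
  }

  keep <- stats::complete.cases(data[, c(item, terms), drop = FALSE])
  df <- data[keep, , drop = FALSE]
  n_used <- nrow(df)
  if (n_used < length(terms) + 2L)
    stop("too few complete cases (", n_used, ") to fit the model")

  arm <- as.character(df$arm)
  resp <- as.character(df[[item]])
  y <- ifelse(resp %in% c("Yes", "A"), 1,
              ifelse(resp %in% c("No", "B"), 0, NA_real_))
  if (anyNA(y))
    stop("item responses must be Yes/No (DQ) or A/B (ECWM)")

  is_dq <- vapply(arm, function(a) is_dq_design(designs[[a]]), logical(1))
  # reference crosswise design: first ECWM arm in `designs` order
  ecwm_arms <- names(designs)[!vapply(designs, is_dq_design, logical(1))]
  ecwm_arms <- ecwm_arms[ecwm_arms %in% arms]
  p_ref <- if (length(ecwm_arms)) designs[[ecwm_arms[1]]]$p else NA_real_
  flipped <- character(0)
  for (a in ecwm_arms) {
    pa <- designs[[a]]$p
    if (abs(pa - p_ref) < 1e-9) next
    if (abs(pa - (1 - p_ref)) < 1e-9) {
      sel <- arm == a
      y[sel] <- 1 - y[sel]                   # swap A/B, use p' = 1 - p
      flipped <- c(flipped, a)
    } else {
      stop("arm '", a, "' has randomisation probability ", pa,
           ", neither equal nor complementary to the reference ", p_ref)
    }
  }

  cc <- ifelse(is_dq, 0, 1 - p_ref)
  dd <- ifelse(is_dq, 1, 2 * p_ref - 1)
  fmt <- ifelse(is_dq, -1, 1)                # effect-coded questioning format

  Xcols <- list(`(Intercept)` = rep(1, n_used))
  dropped_format <- length(unique(fmt)) < 2L
  if (!dropped_format) Xcols$format <- fmt
  for (tm in terms) {
    v <- df[[tm]]
    if (!is.numeric(v)) stop("covariate '", tm, "' must be numeric")
    if (stats::var(v) == 0)
      stop("covariate '", tm, "' has zero variance among complete cases")
    Xcols[[tm]] <- v
  }
  if (!is.null(interaction)) {
    if (dropped_format)
      stop("format-moderation requires both questioning formats in the data")
    Xcols[[paste0(interaction, ":format")]] <- df[[interaction]] * fmt
  }
  X <- do.call(cbind, Xcols)
  colnames(X) <- names(Xcols)
  k <- ncol(X)

  beta <- rep(0, k)                          # fixed deterministic start
  parts <- rr_loglik_parts(beta, X, y, cc, dd)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    gnorm <- sqrt(sum(parts$grad^2))
    if (gnorm < grad_tol) { converged <- TRUE; break }
    step <- tryCatch(solve(-parts$H, parts$grad), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    # damped update: halve until the log-likelihood does not decrease
    ok <- FALSE
    for (h in 0:30) {
      cand <- beta + step / 2^h
      pc <- rr_loglik_parts(cand, X, y, cc, dd)
      if (is.finite(pc$ll) && pc$ll >= parts$ll - 1e-12) {
        beta <- cand; parts <- pc; ok <- TRUE; break
      }
    }
    if (!ok) break
  }
  gnorm <- sqrt(sum(parts$grad^2))
  converged <- converged || gnorm < grad_tol
  separated <- max(abs(beta)) > 30
  if (separated)
    warning("possible separation: a coefficient exceeded 30 on the log-odds ",
            "scale; estimates and standard errors are unreliable")
  if (!converged && !separated)
    warning("Newton iteration did not reach gradient tolerance ", grad_tol,
            " (final gradient norm ", format(gnorm), ")")

  vc <- tryCatch(solve(-parts$H), error = function(e)
    matrix(NA_real_, k, k))
  se <- sqrt(pmax(diag(vc), 0))
  zq <- stats::qnorm(0.975)
  coef_tab <- data.frame(
    term = colnames(X), beta = beta, se = se,
    odds_ratio = exp(beta),
    ci_low = exp(beta - zq * se), ci_high = exp(beta + zq * se),
    p_value = 2 * stats::pnorm(-abs(beta / se)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(coefficients = coef_tab, loglik = parts$ll, converged = converged,
         n_used = n_used, gradient_norm = gnorm, iterations = it,
         vcov = vc, item = item, p_ref = p_ref,
         flipped_arms = flipped, format_dropped = dropped_format,
         separation = separated),
    class = "ecwm_rr_fit"
  )
}

#' @export
print.ecwm_rr_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Measurement-model logistic regression for item '%s' (n = %d)\n",
              x$item, x$n_used))
  if (length(x$flipped_arms))
    cat("  response codes flipped for arm(s): ",
        paste(x$flipped_arms, collapse = ", "),
        " (reference p = ", format(x$p_ref), ")\n", sep = "")
  if (x$format_dropped)
    cat("  single questioning format: format control term dropped\n")
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], function(v) signif(v, digits))
  print(tab, row.names = FALSE)
  cat(sprintf("  log-likelihood %.4f; converged: %s (gradient norm %.2e, %d iterations)\n",
              x$loglik, x$converged, x$gradient_norm, x$iterations))
  invisible(x)
}

#' Test whether a covariate effect is moderated by the questioning format
#'
#' Refits the measurement-model logistic regression with an added
#' covariate-by-format interaction, where format is effect-coded
#' (\eqn{-1} = DQ, \eqn{+1} = ECWM), and reports the interaction's Wald
#' test.  A significant interaction indicates that the covariate's
#' association with the sensitive behaviour differs between direct and
#' crosswise questioning — the signature of social desirability distorting
#' the directly-questioned responses.
#'
#' @inheritParams fit_rr_logistic
#' @param term name of the covariate whose moderation is tested; added to
#'   \code{terms} if absent.
#' @return The \code{"ecwm_rr_fit"} for the interaction model, with an
#'   extra element \code{moderation}: a one-row data frame holding the
#'   interaction term's coefficient and Wald test.
#' @export
test_format_moderation <- function(data, item, term, terms = term, designs,
                                   max_iter = 100L, grad_tol = 1e-8) {
  stopifnot(length(term) == 1L)
  terms <- union(terms, term)
  fit <- fit_rr_logistic(data, item, terms, designs, interaction = term,
                         max_iter = max_iter, grad_tol = grad_tol)
  iname <- paste0(term, ":format")
  fit$moderation <- fit$coefficients[fit$coefficients$term == iname, ,
                                     drop = FALSE]
  fit
}
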
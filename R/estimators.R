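#' Expected option-A probability under a questioning design
#'
#' Forward branch of the crosswise measurement model.  A carrier produces
#' option A with probability \code{a_carrier} and a non-carrier with
#' probability \code{a_noncarrier}, so the marginal option-A probability at
#' prevalence \eqn{\pi} is
#' \deqn{\lambda(\pi) = a_{nc} + (a_c - a_{nc})\,\pi,}
#' which for a CWM design with randomisation probability \eqn{p} reduces to
#' \eqn{\lambda = (1 - p) + (2p - 1)\pi} and for DQ to \eqn{\lambda = \pi}.
#'
#' @param pi prevalence of the sensitive behaviour, in \code{[0, 1]}
#'   (vectorised).
#' @param design an \code{"ecwm_design"}.
#' @return Option-A probability, same length as \code{pi}.
#' @examples
#' d <- ecwm_design(0.256)
#' lambda_expected(0, d)      # 0.744: non-carriers answer A iff randomiser "No"
#' lambda_expected(0.214, d)  # 0.639568
#' @export
lambda_expected <- function(pi, design) {
  stopifnot(inherits(design, "ecwm_design"))
  if (!is.numeric(pi) || anyNA(pi) || any(pi < 0 | pi > 1))
    stop("'pi' must be in [0, 1]")
  design$a_noncarrier + (design$a_carrier - design$a_noncarrier) * pi
}

new_estimate <- function(pi_hat, se, method, n, raw = pi_hat,
                         truncated = FALSE) {
  z <- stats::qnorm(0.975)
  structure(
    list(pi_hat = pi_hat, se = se,
         ci_low = max(0, pi_hat - z * se),
         ci_high = min(1, pi_hat + z * se),
         method = method, truncated = truncated, raw = raw, n = n),
    class = "ecwm_estimate"
  )
}

#' @export
print.ecwm_estimate <- function(x, digits = 3, ...) {
  cat(sprintf("%s prevalence estimate: %.*f (SE %.*f, 95%% CI %.*f-%.*f, n = %s)%s\n",
              x$method, digits, x$pi_hat, digits, x$se, digits, x$ci_low,
              digits, x$ci_high, format(x$n),
              if (isTRUE(x$truncated))
                sprintf(" [raw %.*f truncated]", digits, x$raw) else ""))
  invisible(x)
}

#' Direct-questioning prevalence estimate
#'
#' The DQ prevalence is the proportion of "Yes" responses,
#' \eqn{\hat\pi = n_{yes}/n}, with binomial standard error
#' \eqn{\sqrt{\hat\pi(1-\hat\pi)/n}} and a 95\% Wald interval clamped to
#' \code{[0, 1]}.
#'
#' @param counts an \code{"ecwm_counts"} object (for DQ, \code{n_a} is the
#'   "Yes" count).
#' @return An \code{"ecwm_estimate"} with \code{method = "DQ"}.
#' @examples
#' estimate_dq(response_counts(30, 523))
#' @export
estimate_dq <- function(counts) {
  stopifnot(inherits(counts, "ecwm_counts"))
  ph <- counts$lambda_hat
  new_estimate(ph, sqrt(ph * (1 - ph) / counts$n_total), "DQ", counts$n_total)
}

#' Crosswise-model prevalence estimate for one ECWM group
#'
#' Inverts the measurement model at the observed option-A proportion:
#' \deqn{\hat\pi = \frac{\hat\lambda + p - 1}{2p - 1},}
#' with standard error
#' \eqn{\sqrt{\hat\lambda(1-\hat\lambda)/n}\,/\,|2p - 1|} (the binomial SE of
#' \eqn{\hat\lambda} inflated by the randomisation procedure).  The raw
#' estimate can fall outside \code{[0, 1]} when \eqn{\hat\lambda <
#' \min(p, 1-p)} or \eqn{\hat\lambda > \max(p, 1-p)}; it is then clamped and
#' flagged, with the raw value kept in \code{$raw} for diagnostics.
#'
#' @param counts an \code{"ecwm_counts"} object.
#' @param design the group's \code{"ecwm_design"} (must not be DQ).
#' @return An \code{"ecwm_estimate"} with \code{method = "ECWM_GROUP"}.
#' @examples
#' estimate_ecwm_group(response_counts(334.49, 523), ecwm_design(0.256))
#' @export
estimate_ecwm_group <- function(counts, design) {
  stopifnot(inherits(counts, "ecwm_counts"), inherits(design, "ecwm_design"))
  if (is_dq_design(design))
    stop("use estimate_dq() for direct questioning")
  p <- design$p
  lh <- counts$lambda_hat
  raw <- (lh + p - 1) / (2 * p - 1)
  se <- sqrt(lh * (1 - lh) / counts$n_total) / abs(2 * p - 1)
  # tolerance keeps exact-boundary cases (lambda_hat = p or 1 - p) from
  # being flagged through floating-point round-off alone
  new_estimate(min(1, max(0, raw)), se, "ECWM_GROUP", counts$n_total,
               raw = raw, truncated = (raw < -1e-12 || raw > 1 + 1e-12))
}

## Vectorised maximiser of the joint two-group binomial log-likelihood over
## the admissible interval (both group lambdas strictly inside (0,1)).
## The log-likelihood is concave in pi (binomial log-likelihood is concave
## in the mean and lambda_g is affine in pi), so a safeguarded Newton on the
## score with a shrinking bracket converges to the unique maximiser.
## Returns the *raw* maximiser, possibly outside [0,1].
pool_raw_mle <- function(lh1, n1, p1, lh2, n2, p2,
                         tol = 1e-12, maxit = 200L) {
  d1 <- 2 * p1 - 1
  d2 <- 2 * p2 - 1
  eps <- 1e-10
  # pi-interval on which both lambdas lie in (eps, 1 - eps)
  b1 <- sort(c((eps - (1 - p1)) / d1, ((1 - eps) - (1 - p1)) / d1))
  b2 <- sort(c((eps - (1 - p2)) / d2, ((1 - eps) - (1 - p2)) / d2))
  lo0 <- max(b1[1], b2[1])
  hi0 <- min(b1[2], b2[2])

  score <- function(pi) {
    l1 <- (1 - p1) + d1 * pi
    l2 <- (1 - p2) + d2 * pi
    n1 * d1 * (lh1 - l1) / (l1 * (1 - l1)) +
      n2 * d2 * (lh2 - l2) / (l2 * (1 - l2))
  }
  info <- function(pi) {  # minus the score derivative; > 0 by concavity
    l1 <- (1 - p1) + d1 * pi
    l2 <- (1 - p2) + d2 * pi
    t1 <- n1 * d1^2 * (lh1 * (1 - l1)^2 + (1 - lh1) * l1^2) /
      (l1 * (1 - l1))^2
    t2 <- n2 * d2^2 * (lh2 * (1 - l2)^2 + (1 - lh2) * l2^2) /
      (l2 * (1 - l2))^2
    t1 + t2
  }

  m <- max(length(lh1), length(lh2), length(n1), length(n2))
  lh1 <- rep_len(lh1, m); lh2 <- rep_len(lh2, m)
  n1 <- rep_len(n1, m);   n2 <- rep_len(n2, m)
  lo <- rep_len(lo0, m);  hi <- rep_len(hi0, m)

  # boundary cases: score single-signed on the whole interval
  s_lo <- score(lo); s_hi <- score(hi)
  pi <- (lo + hi) / 2
  at_lo <- s_lo <= 0
  at_hi <- s_hi >= 0
  pi[at_lo] <- lo[at_lo]
  pi[at_hi] <- hi[at_hi]
  active <- !(at_lo | at_hi)

  for (it in seq_len(maxit)) {
    if (!any(active)) break
    s <- score(pi)
    pos <- active & s > 0
    neg <- active & s <= 0
    lo[pos] <- pi[pos]
    hi[neg] <- pi[neg]
    step <- s / info(pi)
    cand <- pi + step
    bad <- active & (cand <= lo | cand >= hi | !is.finite(cand))
    cand[bad] <- (lo[bad] + hi[bad]) / 2
    conv <- active & (abs(cand - pi) < tol)
    pi[active] <- cand[active]
    active <- active & !conv
  }
  pi
}

#' Pooled ECWM prevalence estimate from two complementary groups
#'
#' When the adherence test gives no evidence that the two groups' implied
#' prevalences differ, a single pooled prevalence is estimated by maximising
#' the joint two-group binomial log-likelihood
#' \deqn{\ell(\pi) = \sum_{g=1}^{2} n_g\left[\hat\lambda_g \log
#'   \lambda_g(\pi) + (1 - \hat\lambda_g)\log(1 - \lambda_g(\pi))\right]}
#' over the common prevalence \eqn{\pi \in [0, 1]}, where
#' \eqn{\lambda_g(\pi)} is the group's expected option-A probability.  The
#' pooled standard error is the inverse-variance combination
#' \eqn{(1/se_1^2 + 1/se_2^2)^{-1/2}} of the two group standard errors.
#'
#' The likelihood is concave in \eqn{\pi}, so the maximiser is unique; it
#' always lies weakly between the two group estimates.  A raw maximiser
#' outside \code{[0, 1]} (possible when both group estimates are truncated on
#' the same side) is clamped and flagged.
#'
#' @param counts1,counts2 \code{"ecwm_counts"} for the two groups.
#' @param design1,design2 the groups' complementary \code{"ecwm_design"}s.
#' @param check_adherence if \code{TRUE} (default), run
#'   \code{\link{adherence_lr_test}} on the same inputs first and warn when
#'   it is significant at \code{alpha} — a pooled estimate is then not
#'   interpretable.
#' @param alpha significance level for the adherence warning.
#' @return An \code{"ecwm_estimate"} with \code{method = "ECWM_POOLED"}.
#' @examples
#' d1 <- ecwm_design(0.256, "ECWM1"); d2 <- ecwm_design(0.744, "ECWM2")
#' c1 <- response_counts(lambda_expected(0.214, d1) * 523, 523)
#' c2 <- response_counts(lambda_expected(0.154, d2) * 524, 524)
#' pool_ecwm(c1, d1, c2, d2)   # 0.184
#' @export
pool_ecwm <- function(counts1, design1, counts2, design2,
                      check_adherence = TRUE, alpha = 0.05) {
  stopifnot(inherits(counts1, "ecwm_counts"), inherits(counts2, "ecwm_counts"))
  stop_if_not_complementary(design1, design2)
  if (isTRUE(check_adherence)) {
    adh <- adherence_lr_test(counts1, design1, counts2, design2,
                             alpha = alpha, pool = FALSE)
    if (!adh$pooled_valid)
      warning(sprintf(paste0("adherence test significant (G2 = %.3f, p = %.4g): ",
                             "the two groups imply different prevalences; ",
                             "the pooled estimate is not interpretable"),
                      adh$g2, adh$p_value))
  }
  raw <- pool_raw_mle(counts1$lambda_hat, counts1$n_total, design1$p,
                      counts2$lambda_hat, counts2$n_total, design2$p)
  e1 <- estimate_ecwm_group(counts1, design1)
  e2 <- estimate_ecwm_group(counts2, design2)
  se <- if (e1$se == 0 || e2$se == 0) 0
        else 1 / sqrt(1 / e1$se^2 + 1 / e2$se^2)
  new_estimate(min(1, max(0, raw)), se, "ECWM_POOLED",
               counts1$n_total + counts2$n_total,
               raw = raw, truncated = (raw < -1e-12 || raw > 1 + 1e-12))
}
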
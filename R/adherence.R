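#' Likelihood-ratio test for instruction non-adherence in the ECWM
#'
#' If respondents follow the crosswise instructions, the two complementary
#' ECWM groups measure the same prevalence and their group-specific estimates
#' differ only by chance.  A systematic preference for one response option
#' pushes the two implied prevalences apart (in opposite directions, because
#' the randomisation probabilities are mirrored), so comparing the groups
#' detects this form of non-adherence.  The test is the likelihood-ratio
#' G-statistic
#' \deqn{G^2 = 2\,[\ell_{sep} - \ell_{common}],}
#' where \eqn{\ell_{sep}} evaluates each group's binomial log-likelihood at
#' its own MLE (\eqn{\lambda = \hat\lambda_g}) and \eqn{\ell_{common}} at the
#' option-A probabilities implied by the joint maximum-likelihood common
#' prevalence.  Under adherence \eqn{G^2 \sim \chi^2_1}.
#'
#' When the test is significant, the direction of the violation is
#' diagnosed: in the group with the larger absolute deviation between
#' observed and expected option-A counts, \code{preferred_option} is
#' \code{"A"} if option A was observed more often than the common-prevalence
#' model expects, \code{"B"} otherwise.
#'
#' @param counts1,counts2 \code{"ecwm_counts"} for the two groups.
#' @param design1,design2 complementary \code{"ecwm_design"}s.
#' @param alpha significance level for the pooling decision (default 0.05);
#'   a significant test blocks pooling and any downstream comparison.
#' @param pool if \code{TRUE} (default) attach the two group estimates.
#' @return An object of class \code{"ecwm_adherence"}: list with \code{g2},
#'   \code{df} (1), \code{p_value}, \code{group_estimates} (the two group
#'   \code{"ecwm_estimate"}s, when \code{pool}), \code{pooled_valid}
#'   (\code{p_value >= alpha}), \code{preferred_option} (\code{"A"},
#'   \code{"B"} or \code{"none"}) and \code{alpha}.
#' @examples
#' d1 <- ecwm_design(0.256, "ECWM1"); d2 <- ecwm_design(0.744, "ECWM2")
#' adherence_lr_test(response_counts(334, 523), d1,
#'                   response_counts(174, 524), d2)
#' @export
adherence_lr_test <- function(counts1, design1, counts2, design2,
                              alpha = 0.05, pool = TRUE) {
  stopifnot(inherits(counts1, "ecwm_counts"), inherits(counts2, "ecwm_counts"))
  stop_if_not_complementary(design1, design2)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single number in (0, 1)")

  lh <- c(counts1$lambda_hat, counts2$lambda_hat)
  n <- c(counts1$n_total, counts2$n_total)
  p <- c(design1$p, design2$p)

  xlogy <- function(x, y) ifelse(x == 0, 0, x * log(y))  # 0 log 0 = 0
  ll_sep <- sum(n * (xlogy(lh, pmin(lh, 1)) + xlogy(1 - lh, pmin(1 - lh, 1))))

  pi_common <- pool_raw_mle(lh[1], n[1], p[1], lh[2], n[2], p[2])
  lam_common <- (1 - p) + (2 * p - 1) * pi_common
  ll_common <- sum(n * (xlogy(lh, lam_common) + xlogy(1 - lh, 1 - lam_common)))

  g2 <- max(0, 2 * (ll_sep - ll_common))
  p_value <- stats::pchisq(g2, df = 1, lower.tail = FALSE)
  valid <- p_value >= alpha

  preferred <- "none"
  if (!valid) {
    dev <- n * lh - n * lam_common           # observed minus expected A count
    g <- which.max(abs(dev))
    preferred <- if (dev[g] > 0) "A" else "B"
  }

  structure(
    list(g2 = g2, df = 1L, p_value = p_value,
         group_estimates = if (pool)
           list(estimate_ecwm_group(counts1, design1),
                estimate_ecwm_group(counts2, design2)) else NULL,
         pooled_valid = valid, preferred_option = preferred,
         pi_common = pi_common, alpha = alpha),
    class = "ecwm_adherence"
  )
}

#' @export
print.ecwm_adherence <- function(x, digits = 3, ...) {
  cat(sprintf("ECWM instruction-adherence test: G2 = %.*f, df = %d, p = %.4g\n",
              digits, x$g2, x$df, x$p_value))
  if (!is.null(x$group_estimates)) {
    cat(sprintf("  group estimates: %.*f, %.*f\n", digits,
                x$group_estimates[[1]]$pi_hat, digits,
                x$group_estimates[[2]]$pi_hat))
  }
  if (x$pooled_valid) {
    cat(sprintf("  no evidence of non-adherence at alpha = %g; pooling valid\n",
                x$alpha))
  } else {
    cat(sprintf("  non-adherence detected (alpha = %g): systematic preference for option %s; do not pool\n",
                x$alpha, x$preferred_option))
  }
  invisible(x)
}
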
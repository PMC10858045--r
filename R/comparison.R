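#' Two-proportion Z comparison of DQ and ECWM prevalence estimates
#'
#' Social desirability pushes direct-questioning (DQ) prevalence estimates of
#' stigmatised behaviours downwards; a crosswise estimate that is
#' significantly higher than its DQ counterpart is the expected signature of
#' that bias.  With the large samples typical of these surveys the normal
#' approximation to the binomial applies, so the comparison uses the
#' two-proportion Z statistic with unpooled, model-based standard errors
#' \deqn{z = \frac{\hat\pi_{ECWM} - \hat\pi_{DQ}}
#'   {\sqrt{se_{DQ}^2 + se_{ECWM}^2}},}
#' with a two-sided p-value from the standard normal.  The ECWM standard
#' error already carries the variance inflation of the randomisation
#' procedure, which is why the unpooled form is used.
#'
#' @param est_dq an \code{"ecwm_estimate"} with \code{method = "DQ"}.
#' @param est_ecwm an \code{"ecwm_estimate"} with method
#'   \code{"ECWM_GROUP"} or \code{"ECWM_POOLED"}.
#' @param alpha significance level for the \code{significant} flag.
#' @param item optional item label carried into the result.
#' @return An object of class \code{"ecwm_comparison"}: list with
#'   \code{item}, \code{est_dq}, \code{est_ecwm} (the two proportions),
#'   \code{z}, \code{p_value} and \code{significant}.
#' @examples
#' dq <- estimate_dq(response_counts(30, 523))
#' d1 <- ecwm_design(0.256); d2 <- ecwm_design(0.744, "ECWM2")
#' ec <- pool_ecwm(response_counts(334, 523), d1,
#'                 response_counts(174, 524), d2)
#' compare_dq_ecwm(dq, ec)
#' @export
compare_dq_ecwm <- function(est_dq, est_ecwm, alpha = 0.05, item = NA_character_) {
  stopifnot(inherits(est_dq, "ecwm_estimate"), inherits(est_ecwm, "ecwm_estimate"))
  if (est_dq$method != "DQ")
    stop("'est_dq' must be a DQ estimate")
  if (!est_ecwm$method %in% c("ECWM_GROUP", "ECWM_POOLED"))
    stop("'est_ecwm' must be an ECWM group or pooled estimate")
  v <- est_dq$se^2 + est_ecwm$se^2
  if (v <= 0)
    stop("both standard errors are zero: the Z statistic is undefined")
  z <- (est_ecwm$pi_hat - est_dq$pi_hat) / sqrt(v)
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(item = item, est_dq = est_dq$pi_hat, est_ecwm = est_ecwm$pi_hat,
         z = z, p_value = p, significant = p < alpha, alpha = alpha),
    class = "ecwm_comparison"
  )
}

#' @export
print.ecwm_comparison <- function(x, digits = 3, ...) {
  cat(sprintf("DQ vs ECWM two-proportion Z test%s\n",
              if (is.na(x$item)) "" else paste0(" (", x$item, ")")))
  cat(sprintf("  DQ %.*f vs ECWM %.*f: z = %.3f, p = %.4g%s\n",
              digits, x$est_dq, digits, x$est_ecwm, x$z, x$p_value,
              if (x$significant) " *" else ""))
  invisible(x)
}
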
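#' Sampling variance of the crosswise prevalence estimator
#'
#' The crosswise estimator \eqn{\hat\pi = (\hat\lambda + p - 1)/(2p - 1)}
#' has variance
#' \deqn{\mathrm{Var}(\hat\pi) = \frac{\lambda(1 - \lambda)}{n\,(2p - 1)^2},
#'   \qquad \lambda = (1 - p) + (2p - 1)\pi,}
#' which exceeds the direct-questioning variance \eqn{\pi(1-\pi)/n} at equal
#' \eqn{n}: the randomisation question injects noise, and the closer \eqn{p}
#' is to 0.5, the larger the inflation.  At \eqn{p = 1} the formula reduces
#' exactly to the DQ variance.
#'
#' @param pi planning prevalence, in (0, 1) (vectorised).
#' @param p randomisation probability, in (0, 1) and not 0.5; \code{p = 1}
#'   is allowed as the DQ limit.
#' @param n sample size, at least 1.
#' @return The estimator variance (same length as \code{pi}).
#' @examples
#' variance_cwm(0.1, 0.256, 523)
#' variance_cwm(0.1, 1, 523)      # = 0.1 * 0.9 / 523, the DQ variance
#' design_effect(0.1, 0.256)
#' @export
variance_cwm <- function(pi, p, n) {
  if (!is.numeric(pi) || any(pi <= 0 | pi >= 1))
    stop("'pi' must be in (0, 1)")
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1)
    stop("'p' must be in (0, 1]")
  if (abs(p - 0.5) < 1e-9)
    stop("p = 0.5 makes the crosswise estimator unidentified")
  if (!is.numeric(n) || any(n < 1)) stop("'n' must be >= 1")
  lam <- (1 - p) + (2 * p - 1) * pi
  lam * (1 - lam) / (n * (2 * p - 1)^2)
}

#' @rdname variance_cwm
#' @description \code{design_effect} is the ratio of the crosswise variance
#'   to the DQ variance at equal \eqn{n} — the factor by which the sample
#'   must grow to recover DQ precision.
#' @export
design_effect <- function(pi, p) {
  variance_cwm(pi, p, 1) / (pi * (1 - pi))
}

#' Sample sizes for a two-arm DQ versus ECWM comparison
#'
#' Normal-approximation sample sizes for detecting a difference
#' \code{detectable_difference} between the DQ prevalence (assumed
#' \eqn{\pi}, the value depressed by social desirability) and the crosswise
#' prevalence (assumed \eqn{\pi + \delta}) with a two-sided two-proportion Z
#' test.  Model-based per-observation variances are used:
#' \eqn{v_{DQ} = \pi(1-\pi)} and \eqn{v_{ECWM} =
#' \lambda(1-\lambda)/(2p-1)^2} evaluated at \eqn{\pi + \delta}.  The DQ arm
#' size solves
#' \deqn{n_{DQ} = \frac{(z_{1-\alpha/2} + z_{power})^2\,
#'   (v_{DQ} + v_{ECWM}/r)}{\delta^2},}
#' with \eqn{r} the ECWM-to-DQ allocation ratio; the ECWM total
#' \eqn{r\,n_{DQ}} is split equally between the two complementary groups.
#' The default \code{allocation_ratio = 2} compensates the crosswise
#' variance inflation by allocating about twice as many respondents to the
#' ECWM condition as to DQ.  No continuity correction is applied, consistent
#' with the normal-approximation analysis the sizes are planned for.
#'
#' @param pi planning prevalence in the DQ arm, in (0, 1).
#' @param p randomisation probability of ECWM group 1 (group 2 uses
#'   \eqn{1 - p}); the result is symmetric in \eqn{p \leftrightarrow 1 - p}.
#' @param detectable_difference prevalence difference \eqn{\delta > 0} to
#'   detect (ECWM minus DQ); \eqn{\pi + \delta} must stay below 1.
#' @param alpha two-sided significance level.
#' @param power target power, in (0, 1).
#' @param allocation_ratio ECWM-to-DQ allocation ratio \eqn{r > 0}.
#' @param worst_case if \code{TRUE}, replace \eqn{\lambda(1-\lambda)} by its
#'   maximum 1/4 (most conservative crosswise variance).
#' @return A list with per-arm sizes \code{n_dq}, \code{n_ecwm} (total),
#'   \code{n_per_ecwm_group}, \code{n_total}, the variances used and the
#'   inputs echoed.  Sizes are rounded up to whole respondents.
#' @examples
#' required_n(0.06, 0.256, detectable_difference = 0.12)
#' @export
required_n <- function(pi, p, detectable_difference, alpha = 0.05,
                       power = 0.8, allocation_ratio = 2,
                       worst_case = FALSE) {
  if (!is.numeric(pi) || length(pi) != 1L || pi <= 0 || pi >= 1)
    stop("'pi' must be a single number in (0, 1)")
  if (abs(p - 0.5) < 1e-9) stop("p = 0.5 is unidentified")
  if (p <= 0 || p >= 1) stop("'p' must be in (0, 1)")
  if (!is.numeric(detectable_difference) || detectable_difference <= 0)
    stop("'detectable_difference' must be > 0")
  if (pi + detectable_difference >= 1)
    stop("infeasible: pi + detectable_difference must be below 1")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("'alpha' and 'power' must be in (0, 1)")
  if (allocation_ratio <= 0) stop("'allocation_ratio' must be > 0")

  pi_ecwm <- pi + detectable_difference
  v_dq <- pi * (1 - pi)
  lam <- (1 - p) + (2 * p - 1) * pi_ecwm
  num <- if (worst_case) 0.25 else lam * (1 - lam)
  v_ecwm <- num / (2 * p - 1)^2

  zq <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  n_dq <- ceiling(zq^2 * (v_dq + v_ecwm / allocation_ratio) /
                    detectable_difference^2)
  n_grp <- ceiling(allocation_ratio * n_dq / 2)
  list(n_dq = n_dq, n_ecwm = 2 * n_grp, n_per_ecwm_group = n_grp,
       n_total = n_dq + 2 * n_grp,
       v_dq = v_dq, v_ecwm = v_ecwm,
       design_effect = v_ecwm / (pi_ecwm * (1 - pi_ecwm)),
       pi = pi, p = p, detectable_difference = detectable_difference,
       alpha = alpha, power = power, allocation_ratio = allocation_ratio,
       worst_case = worst_case)
}
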
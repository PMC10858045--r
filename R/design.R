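#' Questioning designs for sensitive-item surveys
#'
#' A questioning design describes how a respondent's latent sensitive status
#' (carrier / non-carrier) maps to the observed binary response.  Under
#' direct questioning (DQ) a carrier who answers truthfully says "Yes" and a
#' non-carrier says "No".  Under the crosswise model (CWM) the sensitive
#' question is paired with an unrelated non-sensitive question whose "Yes"
#' probability \eqn{p} (the randomisation probability) is known; respondents
#' report only whether the two answers match (option A) or differ (option B),
#' so that \eqn{P(A \mid carrier) = p} and \eqn{P(A \mid non\mbox{-}carrier)
#' = 1 - p}.  The extended crosswise model (ECWM) fields two CWM groups with
#' complementary randomisation probabilities \eqn{p} and \eqn{1 - p}.
#'
#' @param p randomisation probability, in (0, 1) and different from 0.5
#'   (at \eqn{p = 0.5} the crosswise estimator is unidentified because
#'   \eqn{2p - 1 = 0}).
#' @param label design label, e.g. \code{"ECWM1"} or \code{"ECWM2"}.
#'
#' @return An object of class \code{"ecwm_design"}: a list with elements
#'   \code{label}, \code{p}, \code{a_carrier} (probability of option A /
#'   "Yes" given carrier) and \code{a_noncarrier}.
#'
#' @examples
#' d1 <- ecwm_design(0.256, "ECWM1")
#' d2 <- complement_design(d1)
#' d2$p   # 0.744
#' dq_design()
#' @export
ecwm_design <- function(p, label = "ECWM1") {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1)
    stop("randomisation probability 'p' must be a single number in (0, 1)")
  if (abs(p - 0.5) < 1e-9)
    stop("p = 0.5 makes the crosswise estimator unidentified (2p - 1 = 0)")
  structure(
    list(label = as.character(label), p = p,
         a_carrier = p, a_noncarrier = 1 - p),
    class = "ecwm_design"
  )
}

#' @rdname ecwm_design
#' @export
dq_design <- function() {
  structure(
    list(label = "DQ", p = 1, a_carrier = 1, a_noncarrier = 0),
    class = "ecwm_design"
  )
}

#' @rdname ecwm_design
#' @param design an \code{"ecwm_design"} object.
#' @export
complement_design <- function(design) {
  stopifnot(inherits(design, "ecwm_design"))
  if (is_dq_design(design)) stop("a DQ design has no complementary design")
  lab <- if (design$label == "ECWM1") "ECWM2"
         else if (design$label == "ECWM2") "ECWM1"
         else paste0(design$label, "_flipped")
  ecwm_design(1 - design$p, lab)
}

is_dq_design <- function(design) {
  design$a_carrier == 1 && design$a_noncarrier == 0
}

#' @export
print.ecwm_design <- function(x, ...) {
  if (is_dq_design(x)) {
    cat("Direct questioning design (", x$label, ")\n", sep = "")
  } else {
    cat("Crosswise design ", x$label, ": p = ", format(x$p),
        "  [P(A|carrier) = ", format(x$a_carrier),
        ", P(A|non-carrier) = ", format(x$a_noncarrier), "]\n", sep = "")
  }
  invisible(x)
}

#' Check that two crosswise designs form a complementary ECWM pair
#'
#' Two ECWM groups are complementary when their randomisation probabilities
#' sum to one, i.e. \eqn{p_2 = 1 - p_1}.
#'
#' @param design1,design2 \code{"ecwm_design"} objects.
#' @param tol numeric tolerance on \eqn{p_1 + p_2 - 1}.
#' @return Logical scalar.
#' @export
is_complementary_pair <- function(design1, design2, tol = 1e-9) {
  inherits(design1, "ecwm_design") && inherits(design2, "ecwm_design") &&
    !is_dq_design(design1) && !is_dq_design(design2) &&
    abs(design1$p + design2$p - 1) <= tol
}

# An ECWM group pair is analysable when the two randomisation probabilities
# are complementary (p2 = 1 - p1) or equal (one group already re-coded via
# flip_group_coding); anything else is a design mismatch.
stop_if_not_complementary <- function(design1, design2) {
  ok <- is_complementary_pair(design1, design2) ||
    (inherits(design1, "ecwm_design") && inherits(design2, "ecwm_design") &&
       !is_dq_design(design1) && !is_dq_design(design2) &&
       abs(design1$p - design2$p) <= 1e-9)
  if (!ok)
    stop("the two designs must be a complementary ECWM pair (p2 = 1 - p1), ",
         "or share one p after flip_group_coding")
  invisible(TRUE)
}

#' Observed response counts for one arm and one item
#'
#' The sufficient statistic for all prevalence work: the number of option-A
#' (or, under DQ, "Yes") responses among the non-missing responses to one
#' item in one arm.  \code{n_a} may be fractional: arm-level counts
#' reconstructed from a published proportion (e.g. inverting a printed
#' prevalence estimate back to an option-A proportion) need not be whole
#' numbers, and every estimator here depends on the counts only through
#' \code{lambda_hat = n_a / n_total}.
#'
#' @param n_a number of option-A / "Yes" responses, \code{0 <= n_a <= n_total}.
#' @param n_total number of non-missing responses, at least 1.
#' @return An object of class \code{"ecwm_counts"} with elements \code{n_a},
#'   \code{n_total} and \code{lambda_hat}.
#' @examples
#' response_counts(30, 523)
#' @export
response_counts <- function(n_a, n_total) {
  if (!is.numeric(n_total) || length(n_total) != 1L || is.na(n_total) ||
      n_total < 1)
    stop("'n_total' must be a single number >= 1")
  if (!is.numeric(n_a) || length(n_a) != 1L || is.na(n_a) ||
      n_a < 0 || n_a > n_total)
    stop("'n_a' must be a single number in [0, n_total]")
  structure(
    list(n_a = n_a, n_total = n_total, lambda_hat = n_a / n_total),
    class = "ecwm_counts"
  )
}

#' @export
print.ecwm_counts <- function(x, ...) {
  cat("Response counts: ", format(x$n_a), " option-A of ", format(x$n_total),
      " (lambda_hat = ", format(x$lambda_hat, digits = 6), ")\n", sep = "")
  invisible(x)
}

#' Flip the response coding of one ECWM group
#'
#' Because the two ECWM groups use complementary randomisation probabilities,
#' either group can be re-expressed on the other group's scale by swapping
#' its A/B codes and replacing \eqn{p} with \eqn{1 - p}.  The crosswise
#' prevalence estimator is invariant under this transformation, which is what
#' justifies merging the two groups into a single arm (e.g. before the
#' measurement-model regression).
#'
#' @param counts an \code{"ecwm_counts"} object.
#' @param design the group's \code{"ecwm_design"} (must not be DQ).
#' @return A list with elements \code{counts} (codes swapped:
#'   \code{n_a' = n_total - n_a}) and \code{design} (with \eqn{p' = 1 - p}).
#' @examples
#' f <- flip_group_coding(response_counts(334, 523), ecwm_design(0.744, "ECWM2"))
#' f$counts$n_a     # 189
#' f$design$p       # 0.256
#' @export
flip_group_coding <- function(counts, design) {
  stopifnot(inherits(counts, "ecwm_counts"), inherits(design, "ecwm_design"))
  if (is_dq_design(design))
    stop("flip_group_coding applies to crosswise (ECWM) designs only")
  list(
    counts = response_counts(counts$n_total - counts$n_a, counts$n_total),
    design = complement_design(design)
  )
}
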
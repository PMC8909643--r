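#' Gaussian (delta-method) error propagation
#'
#' First-order standard errors for products, quotients and sums or
#' differences of independent Gaussian estimates:
#' * product a*b: sqrt(a^2 se_b^2 + b^2 se_a^2)
#' * quotient num/den: |num/den| * sqrt((se_num/num)^2 + (se_den/den)^2),
#'   with the num = 0 limit se_num / |den|
#' * sum or difference: sqrt(se_1^2 + se_2^2)
#'
#' Independence of the two estimates is assumed; in the two-sample setting
#' the step-1 and step-2 coefficients come from non-overlapping datasets.
#'
#' @param a,b,num,den Point estimates.
#' @param se_a,se_b,se_num,se_den,se_1,se_2 Non-negative standard errors.
#' @return The propagated standard error.
#' @export
se_product <- function(a, se_a, b, se_b) {
  stopifnot(se_a >= 0, se_b >= 0)
  sqrt(a^2 * se_b^2 + b^2 * se_a^2)
}

#' @rdname se_product
#' @export
se_quotient <- function(num, se_num, den, se_den) {
  if (den == 0) stop("quotient SE undefined for zero denominator", call. = FALSE)
  stopifnot(se_num >= 0, se_den >= 0)
  if (num == 0) return(se_num / abs(den))
  abs(num / den) * sqrt((se_num / num)^2 + (se_den / den)^2)
}

#' @rdname se_product
#' @export
se_sum <- function(se_1, se_2) {
  stopifnot(se_1 >= 0, se_2 >= 0)
  sqrt(se_1^2 + se_2^2)
}

#' Product-method indirect effect of one mediator
#'
#' Multiplies the step-1 effect of the exposure on the mediator (`a`, SD
#' of mediator per unit exposure) by the step-2 direct effect of the
#' mediator on the outcome adjusted for the exposure (`b`, log-odds of
#' outcome per SD mediator) to obtain the mediated (indirect) effect, with
#' a delta-method standard error and a two-sided z-test.
#'
#' @param a,se_a Step-1 effect and SE.
#' @param b,se_b Step-2 adjusted effect and SE.
#' @return List with `indirect`, `se`, `pval`, `ci_low`, `ci_high`.
#' @export
indirect_effect <- function(a, se_a, b, se_b) {
  ind <- a * b
  se <- se_product(a, se_a, b, se_b)
  z <- stats::qnorm(0.975)
  p <- if (se > 0) 2 * stats::pnorm(abs(ind / se), lower.tail = FALSE) else
    as.numeric(ind == 0)
  list(indirect = ind, se = se, pval = p,
       ci_low = ind - z * se, ci_high = ind + z * se)
}

#' Proportion of the total effect that is mediated
#'
#' Divides the indirect effect by the total effect; the SE follows the
#' quotient propagation rule and the 95% CI is proportion +/- 1.96 SE.
#' A proportion outside \[0, 1\] (inconsistent mediation, e.g. when direct
#' and indirect effects have opposite signs) raises a warning flag, not an
#' error.
#'
#' @param indirect,se_indirect Indirect effect and SE.
#' @param total,se_total Total effect (nonzero) and SE.
#' @return List with `proportion`, `se`, `ci_low`, `ci_high`, `percent`
#'   (proportion x 100) and logical `inconsistent`.
#' @export
proportion_mediated <- function(indirect, se_indirect, total, se_total) {
  if (total == 0) stop("proportion undefined for zero total effect",
                       call. = FALSE)
  prop <- indirect / total
  se <- se_quotient(indirect, se_indirect, total, se_total)
  z <- stats::qnorm(0.975)
  inconsistent <- prop < 0 || prop > 1
  if (inconsistent)
    warning("proportion mediated outside [0, 1]: inconsistent mediation",
            call. = FALSE)
  list(proportion = prop, se = se,
       ci_low = prop - z * se, ci_high = prop + z * se,
       percent = 100 * prop, inconsistent = inconsistent)
}

#' Mediation summary for a single mediator
#'
#' Bundles the step-1 coefficient, the step-2 adjusted coefficient, the
#' total effect, the product-method indirect effect and the proportion
#' mediated into one record with the eligibility flag used by the
#' two-step workflow: a mediator must pass p < `gate_p` at step 1
#' (exposure causally shifts the mediator) and at step 2 (the mediator
#' causally shifts the outcome, adjusted for the exposure) to contribute a
#' mediation estimate.
#'
#' @param mediator_name Label.
#' @param a,se_a,p_a Step-1 effect, SE, p-value.
#' @param b,se_b,p_b Step-2 adjusted effect, SE, p-value.
#' @param total,se_total Total effect of the exposure on the outcome and
#'   its SE.
#' @param gate_p Eligibility threshold applied to both steps (default
#'   0.05).
#' @return An object of class `mediation_result`: list with the inputs
#'   plus `indirect`, `se_indirect`, `p_indirect`, `proportion`, `se_prop`,
#'   `ci_low`, `ci_high`, `percent` and `flag` (one of `"ok"`,
#'   `"excluded_step1"`, `"excluded_step2"`).
#' @export
mediation_result <- function(mediator_name, a, se_a, p_a, b, se_b, p_b,
                             total, se_total, gate_p = 0.05) {
  flag <- if (is.na(p_a) || p_a >= gate_p) "excluded_step1"
          else if (is.na(p_b) || p_b >= gate_p) "excluded_step2"
          else "ok"
  out <- list(mediator_name = mediator_name,
              a = a, se_a = se_a, p_a = p_a,
              b = b, se_b = se_b, p_b = p_b,
              total = total, se_total = se_total,
              indirect = NA_real_, se_indirect = NA_real_,
              p_indirect = NA_real_,
              proportion = NA_real_, se_prop = NA_real_,
              ci_low = NA_real_, ci_high = NA_real_, percent = NA_real_,
              flag = flag)
  if (flag == "ok") {
    ie <- indirect_effect(a, se_a, b, se_b)
    pm <- suppressWarnings(
      proportion_mediated(ie$indirect, ie$se, total, se_total))
    out$indirect <- ie$indirect; out$se_indirect <- ie$se
    out$p_indirect <- ie$pval
    out$proportion <- pm$proportion; out$se_prop <- pm$se
    out$ci_low <- pm$ci_low; out$ci_high <- pm$ci_high
    out$percent <- pm$percent
    if (pm$inconsistent) out$flag <- "inconsistent"
  }
  structure(out, class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation via %s [%s]\n", x$mediator_name, x$flag))
  if (x$flag %in% c("ok", "inconsistent"))
    cat(sprintf("  indirect = %.4f (SE %.4f), proportion = %.1f%% [%.1f%%, %.1f%%]\n",
                x$indirect, x$se_indirect, x$percent,
                100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}

#' Combined mediation by the difference method
#'
#' The combined indirect effect of a set of mediators is the total effect
#' minus the direct effect of the exposure on the outcome adjusted for all
#' mediators jointly; the combined proportion mediated divides that
#' difference by the total effect. SEs follow the sum and quotient
#' propagation rules.
#'
#' @param total,se_total Total effect (nonzero) and SE.
#' @param direct_adjusted,se_direct Adjusted direct effect and SE.
#' @return An object of class `combined_mediation`: list with `total`,
#'   `se_total`, `direct_adjusted`, `se_direct`, `combined_indirect`,
#'   `se_indirect`, `proportion`, `se_prop`, `ci_low`, `ci_high`,
#'   `percent`.
#' @export
combined_mediation <- function(total, se_total, direct_adjusted, se_direct) {
  if (total == 0) stop("combined proportion undefined for zero total effect",
                       call. = FALSE)
  ci <- total - direct_adjusted
  se_ci <- se_sum(se_total, se_direct)
  pm <- suppressWarnings(proportion_mediated(ci, se_ci, total, se_total))
  structure(list(total = total, se_total = se_total,
                 direct_adjusted = direct_adjusted, se_direct = se_direct,
                 combined_indirect = ci, se_indirect = se_ci,
                 proportion = pm$proportion, se_prop = pm$se,
                 ci_low = pm$ci_low, ci_high = pm$ci_high,
                 percent = pm$percent),
            class = "combined_mediation")
}

#' @export
print.combined_mediation <- function(x, ...) {
  cat(sprintf(
    "Combined mediation: indirect = %.4f (SE %.4f), proportion = %.1f%% [%.1f%%, %.1f%%]\n",
    x$combined_indirect, x$se_indirect, x$percent,
    100 * x$ci_low, 100 * x$ci_high))
  invisible(x)
}
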
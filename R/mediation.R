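# Two-step mediation: total effect, mediator-path effects,
# product-of-coefficients decomposition, Bonferroni families.

#' Total causal effect of the exposure on the outcome
#'
#' Thin wrapper over the headline IVW analysis (fixed effects with
#' escalation to multiplicative random effects under heterogeneity), kept
#' as its own verb because it supplies the denominator `alpha` of the
#' mediation decomposition.
#'
#' @param set Harmonized exposure/outcome set (drug-target instruments).
#' @param q_alpha Heterogeneity escalation level.
#' @return A one-row MR result (log-odds scale for binary outcomes).
#' @export
total_effect <- function(set, q_alpha = 0.05) {
  set <- as_hs(set)
  if (nrow(set) == 1L) {
    return(wald_ratio(set$gamma, set$se_gamma, set$Gamma, set$se_Gamma))
  }
  q <- cochran_q(set, basis = "ivw")
  mode <- if (q$pval < q_alpha) "multiplicative_random" else "fixed"
  mr_ivw(set, mode = mode)
}

#' Exposure-to-mediator and mediator-to-outcome effects
#'
#' `beta1` is estimated with the drug-target instruments against the
#' mediator GWAS; `beta2` with the mediator's own (pQTL) instruments
#' against the outcome. To keep the exposure pathway out of `beta2`,
#' `overlap_policy = "drop-shared"` removes any mediator instrument that is
#' also an exposure instrument or in LD (r2 > `r2_overlap`) with one;
#' `"none"` skips the exclusion.
#'
#' @param exp_med Harmonized set: drug-target instruments vs mediator GWAS.
#' @param med_out Harmonized set: mediator pQTL instruments vs outcome GWAS.
#' @param exposure_snps Character vector of exposure instrument ids
#'   (used by `"drop-shared"`).
#' @param overlap_policy `"drop-shared"` (default) or `"none"`.
#' @param ld Optional LD matrix for the r2-based exclusion.
#' @param r2_overlap LD exclusion threshold (default 0.001).
#' @param q_alpha Heterogeneity escalation level for both IVW fits.
#' @return List with `beta1`, `beta2` (one-row MR results; `beta2` is
#'   `NULL` with `non_estimable = TRUE` when the exclusion empties the
#'   instrument set) and `n_overlap_dropped`.
#' @export
mediator_effects <- function(exp_med, med_out, exposure_snps = NULL,
                             overlap_policy = c("drop-shared", "none"),
                             ld = NULL, r2_overlap = 0.001, q_alpha = 0.05) {
  overlap_policy <- match.arg(overlap_policy)
  exp_med <- as_hs(exp_med)
  med_out <- as_hs(med_out)
  beta1 <- total_effect(exp_med, q_alpha = q_alpha)

  dropped <- character(0)
  if (overlap_policy == "drop-shared" && length(exposure_snps)) {
    shared <- med_out$snp_id %in% exposure_snps
    if (!is.null(ld)) {
      both <- intersect(rownames(ld), med_out$snp_id)
      expo <- intersect(rownames(ld), exposure_snps)
      if (length(both) && length(expo)) {
        linked <- both[apply(ld[both, expo, drop = FALSE] > r2_overlap, 1, any)]
        shared <- shared | med_out$snp_id %in% linked
      }
    }
    dropped <- med_out$snp_id[shared]
    med_out <- med_out[!shared, , drop = FALSE]
  }
  if (nrow(med_out) == 0L) {
    return(list(beta1 = beta1, beta2 = NULL, non_estimable = TRUE,
                n_overlap_dropped = length(dropped),
                overlap_dropped = dropped))
  }
  beta2 <- total_effect(med_out, q_alpha = q_alpha)
  list(beta1 = beta1, beta2 = beta2, non_estimable = FALSE,
       n_overlap_dropped = length(dropped), overlap_dropped = dropped)
}

#' Product-of-coefficients mediation decomposition
#'
#' Indirect effect `beta1 * beta2` with the Sobel standard error
#' `sqrt(beta1^2 se2^2 + beta2^2 se1^2)` (independence across the
#' non-overlapping two-sample fits assumed); proportion mediated
#' `(beta1 * beta2) / alpha` with a first-order delta standard error over
#' `(beta1, beta2, alpha)` treated as independent; direct effect
#' `alpha - beta1 * beta2`. The proportion is undefined (NA, flagged) when
#' `alpha = 0`.
#'
#' @param alpha,alpha_se Total effect and its SE (log scale).
#' @param beta1,beta1_se Exposure-to-mediator effect and SE.
#' @param beta2,beta2_se Mediator-to-outcome effect and SE.
#' @return A `mediation_result` list with the three inputs, `indirect`,
#'   `proportion` (and `proportion_pct`), `direct`, their SEs and 95% CIs.
#' @export
mediate <- function(alpha, alpha_se = NA_real_, beta1, beta1_se = NA_real_,
                    beta2, beta2_se = NA_real_) {
  indirect <- beta1 * beta2
  indirect_se <- sqrt(beta1^2 * beta2_se^2 + beta2^2 * beta1_se^2)
  direct <- alpha - indirect
  if (alpha == 0) {
    proportion <- NA_real_
    proportion_se <- NA_real_
    warning("alpha = 0: proportion mediated undefined", call. = FALSE)
  } else {
    proportion <- indirect / alpha
    proportion_se <- sqrt((beta2 / alpha)^2 * beta1_se^2 +
                            (beta1 / alpha)^2 * beta2_se^2 +
                            (indirect / alpha^2)^2 * alpha_se^2)
  }
  ci <- function(est, se) est + c(-1, 1) * stats::qnorm(0.975) * se
  structure(list(alpha = alpha, alpha_se = alpha_se,
                 beta1 = beta1, beta1_se = beta1_se,
                 beta2 = beta2, beta2_se = beta2_se,
                 indirect = indirect, indirect_se = indirect_se,
                 indirect_ci = ci(indirect, indirect_se),
                 proportion = proportion, proportion_se = proportion_se,
                 proportion_pct = 100 * proportion,
                 direct = direct),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("total effect (alpha):      %.4f (se %.4f)\n", x$alpha, x$alpha_se))
  cat(sprintf("exposure -> mediator (b1): %.4f (se %.4f)\n", x$beta1, x$beta1_se))
  cat(sprintf("mediator -> outcome (b2):  %.4f (se %.4f)\n", x$beta2, x$beta2_se))
  cat(sprintf("indirect effect (b1*b2):   %.4f (se %.4f)\n",
              x$indirect, x$indirect_se))
  cat(sprintf("direct effect:             %.4f\n", x$direct))
  if (is.na(x$proportion)) {
    cat("proportion mediated:       undefined (alpha = 0)\n")
  } else {
    cat(sprintf("proportion mediated:       %.4f (%.2f%%)\n",
                x$proportion, x$proportion_pct))
  }
  invisible(x)
}

#' Bonferroni test family
#'
#' Family-wise threshold `0.05 / m`; a member is significant when its raw
#' p-value is strictly below it. `m` defaults to the number of tests but is
#' caller-controlled because published families sometimes use a different
#' denominator than the member count (a warning is raised when
#' `m < length(pvals)`).
#'
#' @param pvals Named or unnamed numeric vector of raw p-values.
#' @param m Family size for the correction.
#' @param name Optional family label.
#' @param alpha Family-wise error rate (default 0.05).
#' @return A `test_family` list: `name`, `m`, `threshold`, `members`
#'   (data frame of `id`, `pval`, `significant`).
#' @export
bonferroni_family <- function(pvals, m = length(pvals), name = "",
                              alpha = 0.05) {
  stopifnot(m >= 1)
  if (m < length(pvals)) {
    warning(sprintf("family size m = %d is smaller than the %d tests supplied",
                    m, length(pvals)), call. = FALSE)
  }
  threshold <- alpha / m
  ids <- names(pvals) %||% sprintf("test_%d", seq_along(pvals))
  structure(list(name = name, m = m, threshold = threshold,
                 members = data.frame(id = ids, pval = as.numeric(pvals),
                                      significant = as.numeric(pvals) < threshold,
                                      stringsAsFactors = FALSE)),
            class = "test_family")
}

#' Back-calculate a two-sided p-value from an OR and its 95% CI
#'
#' Utility for reconciling printed forest-plot rows:
#' `se = (log(ci_high) - log(ci_low)) / (2 * 1.959964)`,
#' `z = log(or) / se`, two-sided normal p.
#'
#' @param or_point Odds ratio point estimate.
#' @param ci_low,ci_high 95% confidence bounds (must bracket `or_point`).
#' @return Two-sided p-value.
#' @export
pval_from_or_ci <- function(or_point, ci_low, ci_high) {
  if (!(0 < ci_low && ci_low < or_point && or_point < ci_high)) {
    stop("require 0 < ci_low < or_point < ci_high", call. = FALSE)
  }
  se <- (log(ci_high) - log(ci_low)) / (2 * 1.959964)
  z_pval(log(or_point) / se)
}
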
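#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment over one family of tests, delegated to
#' [stats::p.adjust()]. The family size `m` may exceed the number of
#' p-values supplied (exposures never analysed still count toward the
#' family, e.g. a full 91-protein panel of which only some pairs reached
#' the MR stage).
#'
#' @param pvals Numeric vector of raw p-values in (0, 1].
#' @param m Family size (default `length(pvals)`).
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(pvals, m = length(pvals)) {
  if (length(pvals) == 0) stop("no p-values to adjust", call. = FALSE)
  if (any(!is.finite(pvals) | pvals <= 0 | pvals > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  if (m < length(pvals)) stop("family size m cannot be smaller than the number of p-values",
                              call. = FALSE)
  stats::p.adjust(pvals, method = "BH", n = m)
}

#' Two-step mediation arithmetic (product of coefficients)
#'
#' From the total effect of the exposure on the outcome (`beta_total`), the
#' exposure-to-mediator effect (`beta1`) and the mediator-to-outcome effect
#' (`beta2`): indirect effect `beta1 * beta2`; mediated proportion
#' `beta1 * beta2 / beta_total`. Proportions outside [0, 1] are possible in
#' univariable two-step MR (inconsistent mediation) and are reported as-is
#' with a warning.
#'
#' @param beta_total Total exposure -> outcome effect (non-zero).
#' @param beta1 Exposure -> mediator effect.
#' @param beta2 Mediator -> outcome effect.
#' @param exposure,mediator,outcome Optional labels.
#' @return A `mediation_result` one-row data frame with columns `exposure`,
#'   `mediator`, `outcome`, `beta_total`, `beta1`, `beta2`, `indirect`,
#'   `proportion`, `proportion_pct`.
#' @export
mediation_effects <- function(beta_total, beta1, beta2,
                              exposure = "exposure", mediator = "mediator",
                              outcome = "outcome") {
  if (!is.finite(beta_total) || beta_total == 0) {
    stop("mediated proportion is undefined when the total effect is zero",
         call. = FALSE)
  }
  indirect <- beta1 * beta2
  proportion <- indirect / beta_total
  if (proportion < 0 || proportion > 1) {
    warning(sprintf("mediated proportion %.1f%% lies outside [0%%, 100%%] (inconsistent mediation)",
                    100 * proportion), call. = FALSE)
  }
  out <- data.frame(exposure = exposure, mediator = mediator,
                    outcome = outcome, beta_total = beta_total,
                    beta1 = beta1, beta2 = beta2, indirect = indirect,
                    proportion = proportion,
                    proportion_pct = 100 * proportion,
                    stringsAsFactors = FALSE)
  class(out) <- c("mediation_result", "data.frame")
  out
}

#' Annotate a family of MR results with FDR and exclusion flags
#'
#' Joins one IVW row per exposure with its sensitivity report, attaches
#' Benjamini-Hochberg adjusted p-values over the family (all exposures of
#' one panel against one outcome), and applies the exclusion rules: rows
#' whose Steiger direction is wrong are dropped (kept in the audit
#' attribute), and Egger/IVW slope-sign disagreement is flagged. Flags
#' `significant` (pFDR < alpha) and `nominal` (p < alpha).
#'
#' @param estimates Data frame with one IVW row per exposure; must carry
#'   columns `exposure`, `beta`, `pval` (e.g. built by [run_mr_pair()]
#'   callers); an `egger_beta` column enables the sign-consistency flag.
#' @param sensitivity Data frame with one row per exposure carrying
#'   `exposure`, `correct_causal_direction` and optionally
#'   `egger_intercept_p`.
#' @param alpha Significance level for both flags (default 0.05).
#' @param m Family size for the FDR adjustment (default `nrow(estimates)`).
#' @return The annotated and filtered table; dropped rows in
#'   `attr(, "excluded")`.
#' @export
build_result_table <- function(estimates, sensitivity = NULL, alpha = 0.05,
                               m = nrow(estimates)) {
  stopifnot(is.data.frame(estimates), nrow(estimates) > 0)
  tab <- estimates
  if (!is.null(sensitivity)) {
    keep_cols <- intersect(c("exposure", "correct_causal_direction",
                             "egger_intercept_p", "q_p",
                             "presso_global_p"), names(sensitivity))
    tab <- merge(tab, sensitivity[, keep_cols, drop = FALSE],
                 by = "exposure", sort = FALSE)
  }
  tab$pfdr <- bh_fdr(tab$pval, m = max(m, nrow(tab)))
  tab$nominal <- tab$pval < alpha
  tab$significant <- tab$pfdr < alpha
  if ("egger_beta" %in% names(tab)) {
    tab$egger_sign_disagreement <- sign(tab$beta) != sign(tab$egger_beta)
  }
  excluded <- tab[0, , drop = FALSE]
  if ("correct_causal_direction" %in% names(tab)) {
    wrong <- !is.na(tab$correct_causal_direction) &
      !tab$correct_causal_direction
    excluded <- tab[wrong, , drop = FALSE]
    tab <- tab[!wrong, , drop = FALSE]
  }
  rownames(tab) <- NULL
  structure(tab, excluded = excluded)
}
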
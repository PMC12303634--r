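#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_j * (ratio_j - beta_ivw_fe)^2)` with IVW weights
#' `w_j = (gamma_j / se_Gamma_j)^2`, referred to the chi-square distribution
#' with `J - 1` degrees of freedom. A small p indicates heterogeneity among
#' the per-SNP causal estimates (possible pleiotropy or invalid instruments).
#'
#' @param pairs A `harmonized_pairs` object with at least 2 SNPs.
#' @return List with `q_stat`, `q_df`, `q_p`.
#' @export
cochran_q <- function(pairs) {
  J <- nrow(pairs)
  if (J < 2) stop("Cochran's Q is undefined for fewer than 2 instruments",
                  call. = FALSE)
  w <- (pairs$gamma / pairs$se_Gamma)^2
  ratios <- pairs$Gamma / pairs$gamma
  beta <- sum(w * ratios) / sum(w)
  Q <- sum(w * (ratios - beta)^2)
  list(q_stat = Q, q_df = J - 1,
       q_p = stats::pchisq(Q, df = J - 1, lower.tail = FALSE))
}

#' MR-Egger intercept test for horizontal pleiotropy
#'
#' The intercept of the Egger regression ([egger()]) estimates the average
#' direct (pleiotropic) effect of the instruments on the outcome; an
#' intercept p-value above 0.05 is read downstream as evidence against
#' directional pleiotropy.
#'
#' @param pairs A `harmonized_pairs` object with at least 3 SNPs.
#' @return List with `intercept`, `intercept_se`, `intercept_p`.
#' @export
egger_intercept_test <- function(pairs) {
  fit <- egger(pairs)
  list(intercept = fit$intercept, intercept_se = fit$intercept_se,
       intercept_p = fit$intercept_p)
}

#' MR-PRESSO global, outlier, and distortion tests
#'
#' Residual-based outlier detection. The observed residual sum of squares is
#' `RSS = sum_j w_j * (Gamma_j - beta_(-j) * gamma_j)^2`, `w_j =
#' 1/se_Gamma_j^2`, where `beta_(-j)` is the fixed-effects IVW estimate
#' leaving SNP j out. Its null distribution is simulated `n_sim` times by
#' drawing `gamma*_j ~ N(gamma_j, se_gamma_j)` and `Gamma*_j ~
#' N(beta_(-j) * gamma_j, se_Gamma_j)` and recomputing RSS on the simulated
#' data. Empirical p-values use add-one smoothing, so `global_p >=
#' 1/(n_sim + 1)`. Per-SNP outlier p-values are the analogous tails of each
#' SNP's weighted residual, Bonferroni-scaled by J; the distortion test
#' compares the outlier-removed IVW estimate with estimates after removing
#' equally many random SNPs.
#'
#' @param pairs A `harmonized_pairs` object with at least 4 SNPs (fewer
#'   returns `NULL` with a note — the null simulation is not identifiable).
#' @param n_sim Number of null simulations (default 1000).
#' @param outlier_alpha Significance level for the Bonferroni-scaled per-SNP
#'   test (default 0.05).
#' @param seed RNG seed (default 20250721).
#' @param quiet Suppress logging.
#' @return List with `global_p`, `outliers` (rsIDs), `outlier_p` (per SNP,
#'   Bonferroni-scaled), `distortion_p` (`NA` when no outliers), or `NULL`
#'   when skipped.
#' @export
mr_presso <- function(pairs, n_sim = 1000, outlier_alpha = 0.05,
                      seed = 20250721, quiet = FALSE) {
  J <- nrow(pairs)
  if (J < 4) {
    if (!quiet) message("MR-PRESSO skipped: fewer than 4 instruments")
    return(NULL)
  }
  g <- pairs$gamma
  G <- pairs$Gamma
  sg <- pairs$se_gamma
  sG <- pairs$se_Gamma
  w <- 1 / sG^2

  loo_beta <- function(gv, Gv) {
    num <- gv * Gv / sG^2
    den <- gv^2 / sG^2
    (sum(num) - num) / (sum(den) - den)
  }
  b_loo <- loo_beta(g, G)
  res_obs <- w * (G - b_loo * g)^2
  rss_obs <- sum(res_obs)

  sims <- with_seed(seed, {
    gs <- matrix(stats::rnorm(J * n_sim, mean = g, sd = sg), nrow = J)
    Gs <- matrix(stats::rnorm(J * n_sim, mean = b_loo * g, sd = sG),
                 nrow = J)
    num <- gs * Gs / sG^2
    den <- gs^2 / sG^2
    b_star <- (rep(colSums(num), each = J) - num) /
      (rep(colSums(den), each = J) - den)
    res_star <- w * (Gs - b_star * gs)^2
    list(rss = colSums(res_star), res = res_star)
  })

  global_p <- (1 + sum(sims$rss >= rss_obs)) / (n_sim + 1)
  outlier_p_raw <- (1 + rowSums(sims$res >= res_obs)) / (n_sim + 1)
  outlier_p <- pmin(1, outlier_p_raw * J)
  is_out <- outlier_p < outlier_alpha
  outliers <- pairs$rsid[is_out]

  distortion_p <- NA_real_
  if (any(is_out) && sum(!is_out) >= 2) {
    beta_all <- ivw(pairs, model = "fixed", quiet = TRUE)$beta
    keep <- !is_out
    beta_clean <- sum(g[keep] * G[keep] / sG[keep]^2) /
      sum(g[keep]^2 / sG[keep]^2)
    d_obs <- beta_clean - beta_all
    k <- sum(is_out)
    d_null <- with_seed(seed + 1, {
      vapply(seq_len(n_sim), function(i) {
        drop <- sample.int(J, k)
        kk <- setdiff(seq_len(J), drop)
        sum(g[kk] * G[kk] / sG[kk]^2) / sum(g[kk]^2 / sG[kk]^2) - beta_all
      }, numeric(1))
    })
    distortion_p <- (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
  }
  if (!quiet && length(outliers) > 0) {
    message(sprintf("MR-PRESSO flagged %d outlier(s): %s", length(outliers),
                    paste(outliers, collapse = ", ")))
  }
  list(global_p = global_p, outliers = outliers, outlier_p = outlier_p,
       distortion_p = distortion_p)
}

#' Leave-one-out influence analysis
#'
#' Re-estimates IVW (auto error model) J times, dropping one SNP each time.
#' A row is flagged influential when its estimate changes sign relative to
#' the full-set IVW or when dropping the SNP moves the 95% CI across zero
#' (gains or loses overlap with the null).
#'
#' @param pairs A `harmonized_pairs` object with at least 3 SNPs.
#' @return Data frame with one row per left-out SNP: `rsid_left_out`,
#'   `nsnp`, `beta`, `se`, `ci_low`, `ci_high`, `pval`, `influential`.
#' @export
leave_one_out <- function(pairs) {
  J <- nrow(pairs)
  if (J < 3) stop("leave-one-out requires at least 3 instruments",
                  call. = FALSE)
  full <- ivw(pairs, model = "auto", quiet = TRUE)
  full_crosses <- full$ci_low <= 0 && full$ci_high >= 0
  rows <- lapply(seq_len(J), function(j) {
    fit <- ivw(pairs[-j, , drop = FALSE], model = "auto", quiet = TRUE)
    crosses <- fit$ci_low <= 0 && fit$ci_high >= 0
    data.frame(rsid_left_out = pairs$rsid[j], nsnp = J - 1L,
               beta = fit$beta, se = fit$se, ci_low = fit$ci_low,
               ci_high = fit$ci_high, pval = fit$pval,
               influential = sign(fit$beta) != sign(full$beta) ||
                 crosses != full_crosses,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_beta") <- full$beta
  out
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure versus the
#' outcome (per-SNP t-statistic R-squared, summed over instruments). The
#' presumed direction exposure -> outcome is supported
#' (`correct_causal_direction = TRUE`) when the instruments explain more of
#' the exposure. The p-value uses the two-sample Fisher z comparison
#' `z = (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
#' sqrt(1/(n_exp - 3) + 1/(n_out - 3))`, two-sided.
#'
#' The t-statistic R-squared is applied to both trait types (no
#' liability-scale correction for binary traits); for binary outcomes the
#' summed "variance explained" is an approximation on the log-odds scale.
#'
#' @param pairs A `harmonized_pairs` object.
#' @param n_exp,n_out Sample sizes; defaults to the per-SNP values stored in
#'   `pairs` (averaged if they vary).
#' @return List with `r2_exp`, `r2_out`, `correct_causal_direction`,
#'   `steiger_p`.
#' @export
steiger_direction <- function(pairs, n_exp = NULL, n_out = NULL) {
  if (nrow(pairs) < 1) stop("no instruments", call. = FALSE)
  n_exp <- n_exp %||% mean(pairs$n_exp)
  n_out <- n_out %||% mean(pairs$n_out)
  if (!is.finite(n_exp) || !is.finite(n_out) || n_exp <= 3 || n_out <= 3) {
    stop("Steiger test needs sample sizes above 3 for both traits",
         call. = FALSE)
  }
  r2_exp <- sum(snp_r2(pairs$gamma, se = pairs$se_gamma,
                       n = rep_len(n_exp, nrow(pairs)), method = "tstat"))
  r2_out <- sum(snp_r2(pairs$Gamma, se = pairs$se_Gamma,
                       n = rep_len(n_out, nrow(pairs)), method = "tstat"))
  r2_exp <- min(r2_exp, 1 - 1e-12)
  r2_out <- min(r2_out, 1 - 1e-12)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  list(r2_exp = r2_exp, r2_out = r2_out,
       correct_causal_direction = r2_exp > r2_out,
       steiger_p = 2 * stats::pnorm(-abs(z)))
}

#' Full sensitivity battery for one exposure-outcome pair
#'
#' Runs Cochran's Q, the Egger intercept test, MR-PRESSO, leave-one-out and
#' the Steiger directionality test, collecting everything into one report.
#' Components whose instrument minimum is not met are `NA`/`NULL` with a
#' logged note rather than an error.
#'
#' @param pairs A `harmonized_pairs` object.
#' @param presso_nsim,presso_alpha,seed MR-PRESSO controls.
#' @param quiet Suppress logging.
#' @return A `sensitivity_report` list; `as.data.frame()` flattens the
#'   scalar fields to one row.
#' @export
sensitivity_report <- function(pairs, presso_nsim = 1000,
                               presso_alpha = 0.05, seed = 20250721,
                               quiet = FALSE) {
  J <- nrow(pairs)
  q <- if (J >= 2) cochran_q(pairs) else
    list(q_stat = NA_real_, q_df = NA_integer_, q_p = NA_real_)
  eg <- if (J >= 3) egger_intercept_test(pairs) else
    list(intercept = NA_real_, intercept_se = NA_real_,
         intercept_p = NA_real_)
  pr <- mr_presso(pairs, n_sim = presso_nsim, outlier_alpha = presso_alpha,
                  seed = seed, quiet = quiet)
  loo <- if (J >= 3) leave_one_out(pairs) else NULL
  st <- steiger_direction(pairs)
  structure(list(nsnp = J,
                 q_stat = q$q_stat, q_df = q$q_df, q_p = q$q_p,
                 egger_intercept = eg$intercept,
                 egger_intercept_se = eg$intercept_se,
                 egger_intercept_p = eg$intercept_p,
                 presso_global_p = if (is.null(pr)) NA_real_ else pr$global_p,
                 presso_outliers = if (is.null(pr)) character(0)
                                   else pr$outliers,
                 presso_distortion_p = if (is.null(pr)) NA_real_
                                       else pr$distortion_p,
                 loo = loo,
                 steiger_r2_exp = st$r2_exp, steiger_r2_out = st$r2_out,
                 correct_causal_direction = st$correct_causal_direction,
                 steiger_p = st$steiger_p),
            class = "sensitivity_report")
}

#' @export
as.data.frame.sensitivity_report <- function(x, ...) {
  data.frame(nsnp = x$nsnp, q_stat = x$q_stat, q_df = x$q_df, q_p = x$q_p,
             egger_intercept = x$egger_intercept,
             egger_intercept_se = x$egger_intercept_se,
             egger_intercept_p = x$egger_intercept_p,
             presso_global_p = x$presso_global_p,
             presso_n_outliers = length(x$presso_outliers),
             presso_outliers = paste(x$presso_outliers, collapse = ","),
             presso_distortion_p = x$presso_distortion_p,
             steiger_r2_exp = x$steiger_r2_exp,
             steiger_r2_out = x$steiger_r2_out,
             correct_causal_direction = x$correct_causal_direction,
             steiger_p = x$steiger_p, stringsAsFactors = FALSE)
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity report (%d SNPs)\n", x$nsnp))
  cat(sprintf("  Cochran's Q: %.3f (df %d), p = %.3g\n", x$q_stat, x$q_df,
              x$q_p))
  cat(sprintf("  Egger intercept: %.4f (se %.4f), p = %.3g\n",
              x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  cat(sprintf("  MR-PRESSO global p: %.3g; outliers: %s\n",
              x$presso_global_p,
              if (length(x$presso_outliers)) paste(x$presso_outliers,
                                                   collapse = ", ")
              else "none"))
  cat(sprintf("  Steiger: R2(exposure) = %.4g vs R2(outcome) = %.4g; correct direction: %s (p = %.3g)\n",
              x$steiger_r2_exp, x$steiger_r2_out,
              x$correct_causal_direction, x$steiger_p))
  invisible(x)
}
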
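#' Harmonize exposure instruments with outcome summary statistics
#'
#' Aligns each instrument's outcome association to the exposure's effect
#' allele. Matching is by rsID. Per SNP:
#' * outcome alleles identical to the exposure's -> kept as-is;
#' * outcome alleles swapped (ea/oa exchanged) -> outcome beta negated and
#'   eaf complemented (`sign_flipped`);
#' * outcome alleles match only after complementing both to the opposite
#'   strand (A<->T, C<->G) -> complemented then re-tested (`strand_flipped`,
#'   possibly also sign-flipped);
#' * palindromic pairs (A/T, C/G) dropped unconditionally — strand cannot be
#'   resolved from the alleles;
#' * irreconcilable allele sets dropped as mismatches;
#' * instruments absent from the outcome table dropped and logged.
#'
#' @param exposure An `instrument_set` (see [select_instruments()]) or a
#'   `sumstats` object whose rows are the instruments.
#' @param outcome A `sumstats` object for the outcome trait.
#' @param quiet Suppress logging.
#' @return A `harmonized_pairs` object: data frame with columns `rsid`,
#'   `gamma`, `se_gamma`, `Gamma`, `se_Gamma`, `eaf_exp`, `eaf_out`,
#'   `n_exp`, `n_out`, `r2_exp`, `action`; the audit rows for dropped SNPs
#'   are kept in `attr(, "audit")`.
#' @export
harmonize <- function(exposure, outcome, quiet = FALSE) {
  exp_df <- if (inherits(exposure, "instrument_set")) exposure$snps
            else as.data.frame(exposure)
  exp_id <- if (inherits(exposure, "instrument_set")) exposure$trait_id
            else attr(exposure, "trait_id") %||% "exposure"
  out_df <- as.data.frame(outcome)
  out_id <- attr(outcome, "trait_id") %||% "outcome"

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  idx <- match(exp_df$rsid, out_df$rsid)

  n <- nrow(exp_df)
  action <- character(n)
  Gamma <- se_Gamma <- eaf_out <- n_out <- rep(NA_real_, n)

  for (i in seq_len(n)) {
    e_ea <- exp_df$ea[i]
    e_oa <- exp_df$oa[i]
    if (validate_alleles(e_ea, e_oa) == "palindromic") {
      action[i] <- "dropped_palindromic"
      next
    }
    j <- idx[i]
    if (is.na(j)) {
      action[i] <- "dropped_missing"
      next
    }
    o_ea <- out_df$ea[j]
    o_oa <- out_df$oa[j]
    if (validate_alleles(o_ea, o_oa) == "palindromic") {
      action[i] <- "dropped_palindromic"
      next
    }
    b <- out_df$beta[j]
    f <- out_df$eaf[j]
    strand <- FALSE
    if (!(identical(o_ea, e_ea) && identical(o_oa, e_oa)) &&
        !(identical(o_ea, e_oa) && identical(o_oa, e_ea))) {
      # try the opposite strand
      o_ea2 <- unname(comp[o_ea])
      o_oa2 <- unname(comp[o_oa])
      if ((identical(o_ea2, e_ea) && identical(o_oa2, e_oa)) ||
          (identical(o_ea2, e_oa) && identical(o_oa2, e_ea))) {
        o_ea <- o_ea2
        o_oa <- o_oa2
        strand <- TRUE
      } else {
        action[i] <- "dropped_mismatch"
        next
      }
    }
    if (identical(o_ea, e_ea)) {
      action[i] <- if (strand) "strand_flipped" else "kept"
    } else {
      b <- -b
      f <- if (is.na(f)) NA_real_ else 1 - f
      action[i] <- if (strand) "strand_flipped" else "sign_flipped"
    }
    Gamma[i] <- b
    se_Gamma[i] <- out_df$se[j]
    eaf_out[i] <- f
    n_out[i] <- out_df$n[j]
  }

  pairs <- data.frame(rsid = exp_df$rsid,
                      gamma = exp_df$beta,
                      se_gamma = exp_df$se,
                      Gamma = Gamma,
                      se_Gamma = se_Gamma,
                      eaf_exp = exp_df$eaf,
                      eaf_out = eaf_out,
                      n_exp = exp_df$n,
                      n_out = n_out,
                      action = action,
                      stringsAsFactors = FALSE)
  if ("r2" %in% names(exp_df)) pairs$r2_exp <- exp_df$r2
  audit <- pairs[, c("rsid", "action")]
  kept <- pairs[startsWith(pairs$action, "dropped") == FALSE, , drop = FALSE]
  if (nrow(kept) == 0) {
    stop(sprintf("harmonization of '%s' on '%s' kept zero SNPs", exp_id,
                 out_id), call. = FALSE)
  }
  n_drop <- n - nrow(kept)
  if (!quiet && n_drop > 0) {
    tab <- table(pairs$action[startsWith(pairs$action, "dropped")])
    message(sprintf("[%s -> %s] harmonized %d/%d SNPs (%s)", exp_id, out_id,
                    nrow(kept), n,
                    paste(names(tab), tab, sep = ": ", collapse = ", ")))
  }
  rownames(kept) <- NULL
  structure(kept, exposure_id = exp_id, outcome_id = out_id, audit = audit,
            class = c("harmonized_pairs", "data.frame"))
}

#' @export
print.harmonized_pairs <- function(x, ...) {
  cat(sprintf("Harmonized pairs: %s -> %s, %d SNP(s)\n",
              attr(x, "exposure_id"), attr(x, "outcome_id"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Construct harmonized pairs directly from effect vectors
#'
#' Convenience constructor for simulation studies and tests that bypass
#' allele bookkeeping.
#'
#' @param gamma,se_gamma Exposure effects and standard errors.
#' @param Gamma,se_Gamma Outcome effects and standard errors.
#' @param n_exp,n_out GWAS sample sizes (scalar or per-SNP).
#' @param rsid Optional identifiers.
#' @return A `harmonized_pairs` object.
#' @export
harmonized_pairs <- function(gamma, se_gamma, Gamma, se_Gamma,
                             n_exp = NA_real_, n_out = NA_real_,
                             rsid = NULL) {
  J <- length(gamma)
  stopifnot(length(se_gamma) == J, length(Gamma) == J, length(se_Gamma) == J)
  if (any(se_gamma <= 0) || any(se_Gamma <= 0)) {
    stop("standard errors must be positive", call. = FALSE)
  }
  df <- data.frame(rsid = rsid %||% sprintf("rs%d", seq_len(J)),
                   gamma = gamma, se_gamma = se_gamma,
                   Gamma = Gamma, se_Gamma = se_Gamma,
                   eaf_exp = NA_real_, eaf_out = NA_real_,
                   n_exp = rep_len(n_exp, J), n_out = rep_len(n_out, J),
                   action = "kept", stringsAsFactors = FALSE)
  structure(df, exposure_id = "exposure", outcome_id = "outcome",
            audit = df[, c("rsid", "action")],
            class = c("harmonized_pairs", "data.frame"))
}
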
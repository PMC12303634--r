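#' Per-SNP variance explained
#'
#' Two estimators of the fraction of trait variance explained by one SNP.
#' The `tstat` method, `r2 = t^2 / (t^2 + n - 2)` with `t = beta/se`, needs no
#' allele frequency and is the default; the `eaf` method,
#' `r2 = 2 * beta^2 * eaf * (1 - eaf)`, assumes a standardized continuous
#' trait and per-allele effects in SD units.
#'
#' @param beta Per-allele effect estimate.
#' @param se Standard error of `beta` (required for `tstat`).
#' @param n GWAS sample size (required for `tstat`).
#' @param eaf Effect-allele frequency (required for `eaf`).
#' @param method `"tstat"` or `"eaf"`.
#' @return Variance explained, clipped to `[0, 1)`. Vectorized over SNPs.
#' @export
snp_r2 <- function(beta, se = NULL, n = NULL, eaf = NULL,
                   method = c("tstat", "eaf")) {
  method <- match.arg(method)
  if (method == "tstat") {
    stopifnot(!is.null(se), !is.null(n))
    if (any(se <= 0)) stop("se must be positive", call. = FALSE)
    if (any(n <= 2)) stop("n must exceed 2", call. = FALSE)
    t2 <- (beta / se)^2
    r2 <- t2 / (t2 + n - 2)
  } else {
    if (is.null(eaf) || anyNA(eaf)) {
      stop("eaf method requires effect-allele frequencies", call. = FALSE)
    }
    r2 <- 2 * beta^2 * eaf * (1 - eaf)
  }
  pmin(pmax(r2, 0), 1 - 1e-12)
}

#' Per-SNP F-statistic for instrument strength
#'
#' `F = (n - 2) * r2 / (1 - r2)`. Under the `tstat` variance-explained
#' method this is exactly the squared Wald t-statistic `(beta/se)^2`.
#' Instruments with `F <= 10` are conventionally considered weak.
#'
#' @param r2 Variance explained, in `[0, 1)`.
#' @param n GWAS sample size (> 2).
#' @return F value (vectorized).
#' @export
f_statistic <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must lie in [0, 1)", call. = FALSE)
  if (any(n <= 2)) stop("n must exceed 2", call. = FALSE)
  (n - 2) * r2 / (1 - r2)
}

#' Read a square LD matrix from TSV
#'
#' Header row and value rows give squared correlations; row order must match
#' the header. Validated for symmetry, unit diagonal and values in `[0, 1]`.
#'
#' @param path TSV path with rsIDs as header.
#' @return An `ld_matrix`: a named numeric matrix.
#' @export
read_ld_matrix <- function(path) {
  m <- as.matrix(utils::read.delim(path, check.names = FALSE))
  rownames(m) <- colnames(m)
  as_ld_matrix(m)
}

#' Validate an LD r-squared matrix
#'
#' @param m Square numeric matrix with rsID dimnames.
#' @return The matrix with class `ld_matrix`.
#' @export
as_ld_matrix <- function(m) {
  if (is.null(colnames(m)) || nrow(m) != ncol(m)) {
    stop("LD matrix must be square with rsID dimnames", call. = FALSE)
  }
  if (any(m < 0 | m > 1 + 1e-9)) {
    stop("LD r-squared values must lie in [0, 1]", call. = FALSE)
  }
  if (max(abs(m - t(m))) > 1e-8) stop("LD matrix must be symmetric",
                                      call. = FALSE)
  if (max(abs(diag(m) - 1)) > 1e-8) stop("LD matrix diagonal must be 1",
                                         call. = FALSE)
  structure(m, class = c("ld_matrix", class(matrix())))
}

#' Greedy LD clumping
#'
#' Keeps the most significant SNP of every LD-correlated group: candidates
#' are visited in ascending p-value order (ties broken by rsID) and a SNP is
#' retained iff its LD r-squared with every already-retained SNP on the same
#' chromosome within `window_kb` is below `r2_max`. SNPs absent from the LD
#' matrix are treated as independent (logged). Deterministic and invariant to
#' input row order.
#'
#' @param candidates Data frame of SNP records (needs `rsid`, `pval`, and
#'   `chrom`/`pos` when positional windows matter).
#' @param ld An `ld_matrix` of squared correlations, or `NULL` to treat all
#'   SNPs as independent.
#' @param window_kb Clumping window in kilobases (default 10000).
#' @param r2_max LD threshold (default 0.001).
#' @param quiet Suppress logging.
#' @return The retained rows of `candidates`, in ascending p order.
#' @export
clump <- function(candidates, ld = NULL, window_kb = 10000, r2_max = 0.001,
                  quiet = FALSE) {
  if (nrow(candidates) == 0) return(candidates)
  ord <- order(candidates$pval, candidates$rsid)
  cand <- candidates[ord, , drop = FALSE]
  if (is.null(ld)) {
    if (!quiet) message("no LD matrix supplied; SNPs assumed pre-clumped")
    return(cand)
  }
  in_ld <- cand$rsid %in% colnames(ld)
  if (!quiet && any(!in_ld)) {
    message(sprintf("%d SNP(s) absent from LD matrix; treated as independent",
                    sum(!in_ld)))
  }
  keep <- logical(nrow(cand))
  kept_idx <- integer(0)
  for (i in seq_len(nrow(cand))) {
    admissible <- TRUE
    for (j in kept_idx) {
      same_chr <- !is.na(cand$chrom[i]) && !is.na(cand$chrom[j]) &&
        cand$chrom[i] == cand$chrom[j]
      within_win <- is.na(cand$pos[i]) || is.na(cand$pos[j]) ||
        abs(cand$pos[i] - cand$pos[j]) <= window_kb * 1000
      # missing chrom: fall back to LD-only comparison
      positional <- if (is.na(cand$chrom[i]) || is.na(cand$chrom[j])) {
        TRUE
      } else {
        same_chr && within_win
      }
      if (!positional) next
      if (in_ld[i] && in_ld[j]) {
        r2 <- ld[cand$rsid[i], cand$rsid[j]]
        if (r2 >= r2_max) {
          admissible <- FALSE
          break
        }
      }
    }
    if (admissible) {
      keep[i] <- TRUE
      kept_idx <- c(kept_idx, i)
    }
  }
  cand[keep, , drop = FALSE]
}

#' Select instrumental variables for one exposure
#'
#' The full instrument-selection pipeline, applied in order: genome-wide
#' significance filter, confounder exclusion-list removal, palindromic-SNP
#' removal, greedy LD clumping, per-SNP variance-explained and F-statistic
#' computation, weak-instrument (`F <= f_min`) removal. Stage-by-stage
#' removal counts are recorded in the returned provenance.
#'
#' @param stats A `sumstats` object (the exposure GWAS).
#' @param p_threshold Significance threshold for instrument candidacy.
#' @param exclusion Character vector of rsIDs to remove (confounder
#'   blacklist), or `NULL`.
#' @param ld An `ld_matrix`, or `NULL` (SNPs assumed pre-clumped, logged).
#' @param window_kb,r2_max Clumping parameters.
#' @param f_min Weak-instrument F threshold (default 10, i.e. keep `F > 10`).
#' @param r2_method Variance-explained method, see [snp_r2()].
#' @param quiet Suppress logging.
#' @return An `instrument_set`: list with `trait_id`, `snps` (SNP records plus
#'   `r2` and `f_stat` columns), and `provenance` (named stage counts).
#' @export
select_instruments <- function(stats, p_threshold = 5e-8, exclusion = NULL,
                               ld = NULL, window_kb = 10000, r2_max = 0.001,
                               f_min = 10, r2_method = c("tstat", "eaf"),
                               quiet = FALSE) {
  r2_method <- match.arg(r2_method)
  stopifnot(p_threshold > 0, p_threshold < 1)
  trait_id <- attr(stats, "trait_id") %||% "exposure"
  df <- as.data.frame(stats)
  n0 <- nrow(df)

  fail_if_empty <- function(df, stage) {
    if (nrow(df) == 0) {
      stop(sprintf("instrument selection for '%s' exhausted at stage '%s'",
                   trait_id, stage), call. = FALSE)
    }
    df
  }

  df <- fail_if_empty(df[df$pval <= p_threshold, , drop = FALSE],
                      "p_threshold")
  n_p <- nrow(df)

  if (!is.null(exclusion) && length(exclusion) > 0) {
    df <- df[!(df$rsid %in% exclusion), , drop = FALSE]
  }
  df <- fail_if_empty(df, "exclusion_list")
  n_excl <- nrow(df)

  cls <- vapply(seq_len(nrow(df)),
                function(i) validate_alleles(df$ea[i], df$oa[i]),
                character(1))
  df <- fail_if_empty(df[cls == "valid", , drop = FALSE], "palindrome")
  n_pal <- nrow(df)

  df <- fail_if_empty(clump(df, ld = ld, window_kb = window_kb,
                            r2_max = r2_max, quiet = quiet), "clump")
  n_clump <- nrow(df)

  df$r2 <- snp_r2(df$beta, se = df$se, n = df$n, eaf = df$eaf,
                  method = r2_method)
  df$f_stat <- f_statistic(df$r2, df$n)
  df <- fail_if_empty(df[df$f_stat > f_min, , drop = FALSE], "f_filter")
  rownames(df) <- NULL

  provenance <- c(input = n0,
                  removed_p_threshold = n0 - n_p,
                  removed_exclusion = n_p - n_excl,
                  removed_palindromic = n_excl - n_pal,
                  removed_clump = n_pal - n_clump,
                  removed_weak_f = n_clump - nrow(df),
                  retained = nrow(df))
  if (!quiet) {
    message(sprintf("[%s] instruments: %d -> %d (p<=%.3g: -%d, blacklist: -%d, palindromic: -%d, clump: -%d, F<=%g: -%d)",
                    trait_id, n0, nrow(df), p_threshold,
                    provenance[["removed_p_threshold"]],
                    provenance[["removed_exclusion"]],
                    provenance[["removed_palindromic"]],
                    provenance[["removed_clump"]],
                    f_min, provenance[["removed_weak_f"]]))
  }
  structure(list(trait_id = trait_id,
                 trait_type = attr(stats, "trait_type"),
                 snps = df,
                 thresholds = list(p_threshold = p_threshold,
                                   window_kb = window_kb, r2_max = r2_max,
                                   f_min = f_min, r2_method = r2_method),
                 provenance = provenance),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set for %s: %d SNP(s), p <= %.3g, F > %g\n",
              x$trait_id, nrow(x$snps), x$thresholds$p_threshold,
              x$thresholds$f_min))
  invisible(x)
}
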
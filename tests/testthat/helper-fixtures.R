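# small in-code fixtures shared across the suite

write_sumstats_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# a six-SNP exposure table exercising every selection stage
toy_exposure_df <- function() {
  data.frame(
    rsid = sprintf("rs%d", 1:6),
    chrom = c("1", "1", "2", "2", "3", "3"),
    pos = c(1e6, 2e6, 1e6, 2e6, 1e6, 2e6),
    ea = c("A", "C", "A", "G", "A", "C"),
    oa = c("G", "T", "T", "A", "C", "A"),
    eaf = c(0.3, 0.4, 0.2, 0.25, 0.35, 0.45),
    beta = c(0.10, 0.09, 0.11, 0.08, 0.002, 0.12),
    se = c(0.010, 0.011, 0.012, 0.010, 0.010, 0.011),
    pval = c(1e-9, 1e-8, 1e-9, 4e-9, 8e-1, 2e-9),
    n = rep(20000, 6),
    stringsAsFactors = FALSE)
}

toy_sumstats <- function(df = toy_exposure_df(), trait_id = "toy") {
  validate_sumstats(df, trait_id = trait_id, quiet = TRUE)
}

# harmonized pairs whose per-SNP ratios are given exactly
pairs_from_ratios <- function(ratios, gamma = 1, se_gamma = 0.01,
                              se_Gamma = 0.05, n_exp = 1e5, n_out = 1e5) {
  J <- length(ratios)
  g <- rep_len(gamma, J)
  harmonized_pairs(gamma = g, se_gamma = rep_len(se_gamma, J),
                   Gamma = ratios * g, se_Gamma = rep_len(se_Gamma, J),
                   n_exp = n_exp, n_out = n_out)
}

# independent greedy-clumping oracle: straight replay of the definition
clump_oracle <- function(df, ld, window_kb, r2_max) {
  ord <- order(df$pval, df$rsid)
  df <- df[ord, , drop = FALSE]
  kept <- integer(0)
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (j in kept) {
      if (is.na(df$chrom[i]) || is.na(df$chrom[j])) {
        positional <- TRUE
      } else {
        positional <- df$chrom[i] == df$chrom[j] &&
          (is.na(df$pos[i]) || is.na(df$pos[j]) ||
             abs(df$pos[i] - df$pos[j]) <= window_kb * 1000)
      }
      if (!positional) next
      if (df$rsid[i] %in% colnames(ld) && df$rsid[j] %in% colnames(ld) &&
          ld[df$rsid[i], df$rsid[j]] >= r2_max) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  df$rsid[kept]
}
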
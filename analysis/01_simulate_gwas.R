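#!/usr/bin/env Rscript
# Generates the synthetic GWAS summary statistics used throughout the
# analysis: an exposure/outcome pair with a known causal effect, an
# exposure/mediator/outcome triad at the published mediation magnitudes,
# and a block LD matrix for the clumping stage. Everything is written as
# TSV under results/sim_data/ with the ground truth alongside.

suppressMessages(library(mrmediate))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 20250721
out_dir <- "results/sim_data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

message("simulating a clean exposure -> outcome pair (J = 50, beta = 0.3)")
pair <- simulate_sumstats_pair(
  sim_scenario(n_snps = 50, true_beta = 0.3, seed = seed))
write_results(as.data.frame(pair$exposure),
              file.path(out_dir, "exposure.tsv"))
write_results(as.data.frame(pair$outcome),
              file.path(out_dir, "outcome.tsv"))
write_results(pair$truth$per_snp, file.path(out_dir, "pair_truth.tsv"))

message("simulating a mediation triad at the published magnitudes ",
        "(beta = -0.333, beta1 = 0.191, beta2 = -0.124)")
tri <- simulate_mediation_triple(
  sim_scenario(n_snps = 50, true_beta = -0.333, true_beta1 = 0.191,
               true_beta2 = -0.124, seed = seed + 1))
for (tab in c("exposure", "mediator", "outcome")) {
  write_results(as.data.frame(tri[[tab]]),
                file.path(out_dir, paste0("triad_", tab, ".tsv")))
}
write_results(tri$truth$per_snp, file.path(out_dir, "triad_truth.tsv"))

message("writing a 50-SNP block LD matrix (blocks of 5, within-block r2 0.3)")
ld <- simulate_ld_blocks(50, 5, 0.3, rsids = pair$exposure$rsid)
utils::write.table(as.data.frame(unclass(ld)),
                   file.path(out_dir, "ld_blocks.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message("done; tables under ", out_dir)
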
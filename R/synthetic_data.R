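#' Define a simulation scenario
#'
#' Collects the generative assumptions behind the synthetic GWAS
#' summary-statistics generator: instrument count, GWAS sample sizes, the
#' allele-frequency range, the true causal effects (total and the two
#' mediation path coefficients), and the instrument-invalidity mechanisms
#' (directional/balanced pleiotropy on a fraction of instruments, extra
#' heterogeneity). All traits are treated as standardized continuous traits,
#' giving the per-SNP standard error `1/sqrt(2 * n * maf * (1 - maf))`;
#' binary-trait log-odds tables are approximated by the same machinery.
#'
#' @param n_snps Number of exposure instruments J (default 50).
#' @param n_exp,n_med,n_out GWAS sample sizes (default 50000).
#' @param maf_range Minor-allele-frequency interval within (0, 0.5]
#'   (default `c(0.05, 0.5)`).
#' @param true_beta Exposure -> outcome total causal effect (default 0.3).
#' @param true_beta1,true_beta2 Mediation path effects (exposure -> mediator,
#'   mediator -> outcome); defaults 0 (no mediation paths unless asked for).
#' @param pleiotropy_mean,pleiotropy_sd Directional mean and balanced SD of
#'   the pleiotropic direct effects carried by invalid instruments.
#' @param invalid_fraction Share of instruments with pleiotropy, in [0, 1].
#' @param heterogeneity_sd Extra SNP-level noise on the true outcome effect.
#' @param nome When `TRUE` (default) downstream trait effects are anchored
#'   on the realized exposure associations, matching the no-measurement-
#'   error (NOME) assumption under which the first-order MR estimators are
#'   derived, so estimator calibration is exact by construction. With
#'   `FALSE` they are anchored on the latent instrument effects, injecting
#'   exposure-side measurement error into the causal path (the per-SNP
#'   ratio variance inflates by `1 + true_beta^2 * se_gamma^2/se_Gamma^2`,
#'   visibly over-dispersing Cochran's Q).
#' @param seed Mandatory RNG seed.
#' @return A `sim_scenario` list.
#' @export
sim_scenario <- function(n_snps = 50, n_exp = 50000, n_med = 50000,
                         n_out = 50000, maf_range = c(0.05, 0.5),
                         true_beta = 0.3, true_beta1 = 0, true_beta2 = 0,
                         pleiotropy_mean = 0, pleiotropy_sd = 0,
                         invalid_fraction = 0, heterogeneity_sd = 0,
                         nome = TRUE, seed) {
  stopifnot(n_snps >= 1, n_exp > 3, n_med > 3, n_out > 3,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            invalid_fraction >= 0, invalid_fraction <= 1,
            heterogeneity_sd >= 0, pleiotropy_sd >= 0)
  if (missing(seed)) stop("a seed is mandatory in a simulation scenario",
                          call. = FALSE)
  structure(list(n_snps = n_snps, n_exp = n_exp, n_med = n_med,
                 n_out = n_out, maf_range = maf_range,
                 true_beta = true_beta, true_beta1 = true_beta1,
                 true_beta2 = true_beta2,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 invalid_fraction = invalid_fraction,
                 heterogeneity_sd = heterogeneity_sd,
                 nome = isTRUE(nome),
                 seed = as.integer(seed)),
            class = "sim_scenario")
}

# standard error of a per-allele effect on a standardized trait
se_standardized <- function(n, maf) 1 / sqrt(2 * n * maf * (1 - maf))

# draw latent instrument effects from N(0, 0.05), rejected until the
# expected F-statistic (gamma/se)^2 + 1 exceeds 10. Effect alleles are
# oriented to be exposure-increasing (gamma > 0), the convention under
# which directional pleiotropy has a recoverable sign (Egger intercept).
draw_instrument_effects <- function(J, se, effect_sd = 0.05) {
  thresh <- 3 * se
  g <- stats::rnorm(J, 0, effect_sd)
  bad <- abs(g) < thresh
  while (any(bad)) {
    g[bad] <- stats::rnorm(sum(bad), 0, effect_sd)
    bad <- abs(g) < thresh
  }
  abs(g)
}

# non-palindromic allele pairs, cycled deterministically over SNPs
assign_alleles <- function(J) {
  pairs <- matrix(c("A", "G", "C", "T", "G", "A", "T", "C",
                    "A", "C", "G", "T"), ncol = 2, byrow = TRUE)
  idx <- ((seq_len(J) - 1) %% nrow(pairs)) + 1
  list(ea = pairs[idx, 1], oa = pairs[idx, 2])
}

# genome coordinates spaced far beyond any clumping window
assign_positions <- function(J, offset = 0) {
  chrom <- as.character(((seq_len(J) + offset - 1) %% 22) + 1)
  pos <- 1e6 + 25e6 * ((seq_len(J) + offset - 1) %/% 22)
  list(chrom = chrom, pos = pos)
}

build_sumstats_table <- function(rsid, chrom, pos, ea, oa, maf, beta, se,
                                 n, trait_id, trait_type = "continuous") {
  df <- data.frame(rsid = rsid, chrom = chrom, pos = pos, ea = ea, oa = oa,
                   eaf = maf, beta = beta, se = se,
                   pval = 2 * stats::pnorm(-abs(beta / se)), n = n,
                   stringsAsFactors = FALSE)
  validate_sumstats(df, trait_id = trait_id, trait_type = trait_type,
                    quiet = TRUE)
}

#' Simulate an exposure/outcome GWAS summary-statistics pair
#'
#' Per SNP: `maf ~ Uniform(maf_range)`; a latent instrument effect
#' `gamma_j ~ N(0, 0.05)` conditioned to pass the weak-instrument bar
#' (expected F > 10 at `n_exp`); observed exposure effect
#' `N(gamma_j, se_gamma_j)`; outcome effect `true_beta * gamma_j` (anchored
#' on the realized exposure association under the default `nome` scenario,
#' on the latent effect otherwise) plus a pleiotropic direct effect
#' `N(pleiotropy_mean, pleiotropy_sd)` for the invalid fraction of
#' instruments plus `N(0, heterogeneity_sd)` noise; observed outcome effect
#' `N(Gamma_j, se_Gamma_j)`. Standard errors follow the standardized-trait
#' formula `1/sqrt(2 n maf (1 - maf))`; p-values are two-sided normal.
#'
#' @param s A `sim_scenario`.
#' @return List with `exposure` and `outcome` (`sumstats` objects sharing
#'   rsIDs and alleles) and `truth` (scenario plus per-SNP latent values:
#'   `gamma`, `alpha`, `Gamma`, `invalid`).
#' @export
simulate_sumstats_pair <- function(s) {
  stopifnot(inherits(s, "sim_scenario"))
  J <- s$n_snps
  with_seed(s$seed, {
    maf <- stats::runif(J, s$maf_range[1], s$maf_range[2])
    se_g <- se_standardized(s$n_exp, maf)
    se_G <- se_standardized(s$n_out, maf)
    gamma <- draw_instrument_effects(J, se_g)
    n_invalid <- round(s$invalid_fraction * J)
    invalid <- seq_len(J) %in% sample.int(J, n_invalid)
    alpha <- ifelse(invalid,
                    stats::rnorm(J, s$pleiotropy_mean, s$pleiotropy_sd), 0)
    gamma_hat <- stats::rnorm(J, gamma, se_g)
    anchor <- if (s$nome) gamma_hat else gamma
    Gamma_true <- s$true_beta * anchor + alpha +
      stats::rnorm(J, 0, s$heterogeneity_sd)
    Gamma_hat <- stats::rnorm(J, Gamma_true, se_G)

    rsid <- sprintf("rs%05d", seq_len(J))
    al <- assign_alleles(J)
    loc <- assign_positions(J)
    exposure <- build_sumstats_table(rsid, loc$chrom, loc$pos, al$ea, al$oa,
                                     maf, gamma_hat, se_g, s$n_exp,
                                     "sim_exposure")
    outcome <- build_sumstats_table(rsid, loc$chrom, loc$pos, al$ea, al$oa,
                                    maf, Gamma_hat, se_G, s$n_out,
                                    "sim_outcome")
    truth <- list(scenario = s,
                  per_snp = data.frame(rsid = rsid, maf = maf,
                                       gamma = gamma, alpha = alpha,
                                       Gamma = Gamma_true,
                                       invalid = invalid,
                                       stringsAsFactors = FALSE))
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Simulate an exposure/mediator/outcome GWAS triad
#'
#' Builds three summary-statistics tables over a shared rsID namespace.
#' The J exposure instruments carry effects `gamma_j` on the exposure,
#' `true_beta1 * gamma_j` on the mediator, and
#' `true_beta * gamma_j` on the outcome (total effect: direct path
#' `true_beta - true_beta1 * true_beta2` plus the mediated path
#' `true_beta1 * true_beta2`). A further J independent mediator instruments
#' `delta_k` (null on the exposure) carry `delta_k` on the mediator and
#' `true_beta2 * delta_k` on the outcome, enabling the mediator -> outcome
#' MR of step 2.
#'
#' @param s A `sim_scenario` with `true_beta1`/`true_beta2` set.
#' @return List with `exposure`, `mediator`, `outcome` (`sumstats`), and
#'   `truth` (scenario plus per-SNP latent values and roles).
#' @export
simulate_mediation_triple <- function(s) {
  stopifnot(inherits(s, "sim_scenario"))
  J <- s$n_snps
  with_seed(s$seed, {
    maf_e <- stats::runif(J, s$maf_range[1], s$maf_range[2])
    maf_m <- stats::runif(J, s$maf_range[1], s$maf_range[2])
    maf <- c(maf_e, maf_m)
    se_exp <- se_standardized(s$n_exp, maf)
    se_med <- se_standardized(s$n_med, maf)
    se_out <- se_standardized(s$n_out, maf)

    gamma <- draw_instrument_effects(J, se_exp[seq_len(J)])
    delta <- draw_instrument_effects(J, se_med[J + seq_len(J)])

    # effects on each trait, exposure instruments first
    exp_true <- c(gamma, rep(0, J))
    exp_hat <- stats::rnorm(2 * J, exp_true, se_exp)
    g_anchor <- if (s$nome) exp_hat[seq_len(J)] else gamma

    med_true <- c(s$true_beta1 * g_anchor, delta)
    med_hat <- stats::rnorm(2 * J, med_true, se_med)
    d_anchor <- if (s$nome) med_hat[J + seq_len(J)] else delta

    out_true <- c(s$true_beta * g_anchor, s$true_beta2 * d_anchor)
    out_hat <- stats::rnorm(2 * J, out_true, se_out)

    rsid <- sprintf("rs%05d", seq_len(2 * J))
    al <- assign_alleles(2 * J)
    loc <- assign_positions(2 * J)
    truth <- list(scenario = s,
                  per_snp = data.frame(rsid = rsid, maf = maf,
                                       role = rep(c("exposure_iv",
                                                    "mediator_iv"),
                                                  each = J),
                                       beta_exp = exp_true,
                                       beta_med = med_true,
                                       beta_out = out_true,
                                       stringsAsFactors = FALSE))
    list(exposure = build_sumstats_table(rsid, loc$chrom, loc$pos, al$ea,
                                         al$oa, maf, exp_hat, se_exp,
                                         s$n_exp, "sim_exposure"),
         mediator = build_sumstats_table(rsid, loc$chrom, loc$pos, al$ea,
                                         al$oa, maf, med_hat, se_med,
                                         s$n_med, "sim_mediator"),
         outcome = build_sumstats_table(rsid, loc$chrom, loc$pos, al$ea,
                                        al$oa, maf, out_hat, se_out,
                                        s$n_out, "sim_outcome"),
         truth = truth)
  })
}

#' Simulate a block-diagonal LD matrix
#'
#' Squared correlations are `within_r2` inside consecutive blocks of
#' `block_size` SNPs, 0 between blocks, 1 on the diagonal.
#'
#' @param n_snps Total SNP count; must be a multiple of `block_size`.
#' @param block_size SNPs per LD block.
#' @param within_r2 Off-diagonal r-squared inside a block.
#' @param rsids Identifiers (default `rs00001`...); must have length
#'   `n_snps`.
#' @return An `ld_matrix`.
#' @export
simulate_ld_blocks <- function(n_snps, block_size, within_r2,
                               rsids = sprintf("rs%05d", seq_len(n_snps))) {
  if (n_snps %% block_size != 0) {
    stop("block_size must divide n_snps", call. = FALSE)
  }
  stopifnot(within_r2 >= 0, within_r2 <= 1, length(rsids) == n_snps)
  block <- matrix(within_r2, block_size, block_size)
  diag(block) <- 1
  m <- matrix(0, n_snps, n_snps)
  for (b in seq_len(n_snps / block_size)) {
    i <- (b - 1) * block_size + seq_len(block_size)
    m[i, i] <- block
  }
  dimnames(m) <- list(rsids, rsids)
  as_ld_matrix(m)
}

#' Convert a simulated pair to harmonized effect pairs
#'
#' Bypasses instrument selection and allele harmonization (the simulated
#' tables are already aligned), yielding the `harmonized_pairs` the
#' estimators consume. Used to study estimator properties in isolation.
#'
#' @param sim Output of [simulate_sumstats_pair()].
#' @return A `harmonized_pairs` object over all simulated SNPs.
#' @export
sim_to_pairs <- function(sim) {
  e <- sim$exposure
  o <- sim$outcome
  harmonized_pairs(gamma = e$beta, se_gamma = e$se, Gamma = o$beta,
                   se_Gamma = o$se, n_exp = e$n, n_out = o$n,
                   rsid = e$rsid)
}
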
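test_that("scenario validation enforces its invariants", {
  expect_error(sim_scenario(n_snps = 10), "seed")
  expect_error(sim_scenario(invalid_fraction = 1.2, seed = 1))
  expect_error(sim_scenario(maf_range = c(0, 0.5), seed = 1))
  expect_error(sim_scenario(maf_range = c(0.1, 0.6), seed = 1))
})

test_that("standard errors follow the standardized-trait formula", {
  # maf 0.5, n 10000 -> se = 1/sqrt(5000)
  sim <- simulate_sumstats_pair(
    sim_scenario(n_snps = 5, n_exp = 10000, n_out = 10000,
                 maf_range = c(0.5, 0.5), seed = 61))
  expect_equal(sim$exposure$se, rep(1 / sqrt(5000), 5), tolerance = 1e-12)
  expect_equal(sim$outcome$se, rep(1 / sqrt(5000), 5), tolerance = 1e-12)
  # p-values are two-sided normal
  expect_equal(sim$exposure$pval,
               2 * pnorm(-abs(sim$exposure$beta / sim$exposure$se)),
               tolerance = 1e-12)
})

test_that("generation is reproducible and instruments pass the strength bar", {
  s <- sim_scenario(n_snps = 30, seed = 62)
  a <- simulate_sumstats_pair(s)
  b <- simulate_sumstats_pair(s)
  expect_identical(as.data.frame(a$exposure), as.data.frame(b$exposure))
  expect_identical(a$truth$per_snp, b$truth$per_snp)
  # latent effects clear the expected-F bar: (gamma/se)^2 >= 9
  expect_true(all((a$truth$per_snp$gamma / a$exposure$se)^2 >= 9))
})

test_that("observed effects scatter around the latent ones at the stated SE", {
  # SE calibration: empirical SD of gamma_hat - gamma across replicates
  set.seed(63)
  devs <- vapply(1:300, function(i) {
    s <- sim_scenario(n_snps = 1, n_exp = 30000, maf_range = c(0.3, 0.3),
                      seed = 5000 + i)
    sim <- simulate_sumstats_pair(s)
    (sim$exposure$beta - sim$truth$per_snp$gamma) / sim$exposure$se
  }, numeric(1))
  expect_equal(sd(devs), 1, tolerance = 0.15)
  expect_equal(mean(devs), 0, tolerance = 0.15)
})

test_that("exposure-side anchoring controls Cochran's Q dispersion", {
  # with latent anchoring the ratio variance inflates by ~1 + beta^2 at
  # equal sample sizes; the default (NOME) anchoring stays nominal
  set.seed(64)
  rej <- function(nome) {
    mean(vapply(1:200, function(i) {
      p <- sim_to_pairs(simulate_sumstats_pair(
        sim_scenario(n_snps = 40, true_beta = 0.5, nome = nome,
                     seed = 7000 + i)))
      cochran_q(p)$q_p < 0.05
    }, logical(1)))
  }
  expect_lt(rej(TRUE), 0.1)
  expect_gt(rej(FALSE), 0.15)
})

test_that("planted pleiotropy biases IVW upward and is seen by Egger", {
  set.seed(65)
  res <- t(vapply(1:100, function(i) {
    p <- sim_to_pairs(simulate_sumstats_pair(
      sim_scenario(n_snps = 40, invalid_fraction = 1,
                   pleiotropy_mean = 0.02, seed = 9000 + i)))
    c(ivw(p, quiet = TRUE)$beta, egger(p)$intercept)
  }, numeric(2)))
  expect_gt(mean(res[, 1]), 0.3 + 0.05) # IVW biased upward
  expect_lt(abs(mean(res[, 2]) - 0.02), 0.005)
})

test_that("the mediation triad embeds the product-of-coefficients truth", {
  s <- sim_scenario(n_snps = 40, true_beta = -0.333, true_beta1 = 0.191,
                    true_beta2 = -0.124, seed = 66)
  tri <- simulate_mediation_triple(s)
  expect_equal(nrow(tri$exposure), 80) # J exposure + J mediator IVs
  expect_setequal(tri$exposure$rsid, tri$outcome$rsid)
  expect_setequal(tri$mediator$rsid, tri$outcome$rsid)

  roles <- tri$truth$per_snp$role
  exp_iv <- roles == "exposure_iv"
  # step betas recovered by IVW over the role-true instruments
  p_total <- harmonized_pairs(tri$exposure$beta[exp_iv],
                              tri$exposure$se[exp_iv],
                              tri$outcome$beta[exp_iv],
                              tri$outcome$se[exp_iv])
  p_b1 <- harmonized_pairs(tri$exposure$beta[exp_iv],
                           tri$exposure$se[exp_iv],
                           tri$mediator$beta[exp_iv],
                           tri$mediator$se[exp_iv])
  p_b2 <- harmonized_pairs(tri$mediator$beta[!exp_iv],
                           tri$mediator$se[!exp_iv],
                           tri$outcome$beta[!exp_iv],
                           tri$outcome$se[!exp_iv])
  expect_lt(abs(ivw(p_total, quiet = TRUE)$beta - -0.333), 0.05)
  expect_lt(abs(ivw(p_b1, quiet = TRUE)$beta - 0.191), 0.05)
  expect_lt(abs(ivw(p_b2, quiet = TRUE)$beta - -0.124), 0.05)
})

test_that("null and sign-flipped mediation paths behave as constructed", {
  set.seed(67)
  rec <- function(b1, b2, seed) {
    tri <- simulate_mediation_triple(
      sim_scenario(n_snps = 30, true_beta = -0.333, true_beta1 = b1,
                   true_beta2 = b2, seed = seed))
    exp_iv <- tri$truth$per_snp$role == "exposure_iv"
    beta1 <- ivw(harmonized_pairs(tri$exposure$beta[exp_iv],
                                  tri$exposure$se[exp_iv],
                                  tri$mediator$beta[exp_iv],
                                  tri$mediator$se[exp_iv]),
                 quiet = TRUE)$beta
    beta2 <- ivw(harmonized_pairs(tri$mediator$beta[!exp_iv],
                                  tri$mediator$se[!exp_iv],
                                  tri$outcome$beta[!exp_iv],
                                  tri$outcome$se[!exp_iv]),
                 quiet = TRUE)$beta
    beta1 * beta2
  }
  null_ind <- vapply(1:40, function(i) rec(0, -0.124, 300 + i), numeric(1))
  expect_equal(mean(null_ind), 0, tolerance = 0.01)
  pos <- vapply(1:20, function(i) rec(0.191, 0.124, 400 + i), numeric(1))
  neg <- vapply(1:20, function(i) rec(0.191, -0.124, 400 + i), numeric(1))
  expect_gt(mean(pos), 0)
  expect_lt(mean(neg), 0)
})

test_that("block LD matrices drive clumping to one survivor per block", {
  ld <- simulate_ld_blocks(4, 2, 0.5)
  df <- data.frame(rsid = sprintf("rs%05d", 1:4), chrom = "1",
                   pos = c(1e6, 1.1e6, 5e7, 5.01e7), ea = "A", oa = "G",
                   eaf = 0.3, beta = 0.1, se = 0.01,
                   pval = c(1e-9, 1e-8, 1e-9, 1e-8), n = 1e4)
  expect_equal(nrow(clump(df, ld, quiet = TRUE)), 2)

  ld0 <- simulate_ld_blocks(4, 2, 0)
  expect_equal(nrow(clump(df, ld0, quiet = TRUE)), 4)

  ld100 <- simulate_ld_blocks(100, 10, 0.8)
  df100 <- data.frame(rsid = sprintf("rs%05d", 1:100), chrom = "1",
                      pos = seq(1e6, by = 1e5, length.out = 100), ea = "A",
                      oa = "G", eaf = 0.3, beta = 0.1, se = 0.01,
                      pval = seq(1e-12, 1e-6, length.out = 100), n = 1e4)
  expect_equal(nrow(clump(df100, ld100, quiet = TRUE)), 10)
  expect_error(simulate_ld_blocks(10, 3, 0.5), "divide")
})
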
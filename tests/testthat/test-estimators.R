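test_that("Wald ratio follows the first-order delta method", {
  p <- harmonized_pairs(gamma = 1, se_gamma = 0.01, Gamma = 0.5,
                        se_Gamma = 0.05)
  w <- wald_ratio(p)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.05)
  p2 <- harmonized_pairs(gamma = -2, se_gamma = 0.01, Gamma = 1.0,
                         se_Gamma = 0.1)
  w2 <- wald_ratio(p2)
  expect_equal(w2$beta, -0.5)
  expect_equal(w2$se, 0.05)
  expect_error(wald_ratio(harmonized_pairs(0, 0.01, 0.1, 0.1)),
               "degenerate")
})

test_that("IVW reproduces its closed form and falls back to Wald for J=1", {
  p <- harmonized_pairs(gamma = c(1, 2), se_gamma = c(0.01, 0.01),
                        Gamma = c(0.5, 1.0), se_Gamma = c(0.1, 0.1))
  fit <- ivw(p, quiet = TRUE)
  expect_equal(fit$beta, 0.5, tolerance = 1e-12)
  expect_equal(fit$q_stat, 0, tolerance = 1e-12)
  expect_equal(fit$model, "fixed")
  expect_equal(fit$se, 1 / sqrt(100 + 400), tolerance = 1e-12)

  expect_message(one <- ivw(p[1, , drop = FALSE]), "Wald")
  expect_equal(one$beta, wald_ratio(p[1, , drop = FALSE])$beta)
  expect_equal(one$se, wald_ratio(p[1, , drop = FALSE])$se)
})

test_that("IVW equals the explicit weighted mean of Wald ratios", {
  set.seed(21)
  for (rep in 1:5) {
    J <- 7
    p <- harmonized_pairs(gamma = runif(J, 0.02, 0.2),
                          se_gamma = runif(J, 0.005, 0.02),
                          Gamma = rnorm(J, 0.1, 0.2),
                          se_Gamma = runif(J, 0.01, 0.05))
    ratios <- p$Gamma / p$gamma
    w <- (p$gamma / p$se_Gamma)^2
    expect_equal(ivw(p, quiet = TRUE)$beta, sum(w * ratios) / sum(w),
                 tolerance = 1e-12)
  }
})

test_that("random-effects IVW inflates the SE only under heterogeneity", {
  p <- harmonized_pairs(gamma = c(1, 1, 1, 1),
                        se_gamma = rep(0.01, 4),
                        Gamma = c(0.8, -0.4, 0.9, -0.5),
                        se_Gamma = rep(0.05, 4))
  fe <- ivw(p, model = "fixed", quiet = TRUE)
  re <- ivw(p, model = "random", quiet = TRUE)
  auto <- ivw(p, model = "auto", quiet = TRUE)
  expect_gt(re$se, fe$se)
  expect_equal(re$se, fe$se * sqrt(fe$q_stat / 3), tolerance = 1e-12)
  expect_equal(auto$model, "random") # Q is huge here
  # homogeneous ratios: random floors at the fixed SE
  ph <- harmonized_pairs(gamma = c(1, 2, 4), se_gamma = rep(0.01, 3),
                         Gamma = c(0.3, 0.6, 1.2), se_Gamma = rep(0.1, 3))
  expect_equal(ivw(ph, model = "random", quiet = TRUE)$se,
               ivw(ph, model = "fixed", quiet = TRUE)$se)
})

test_that("Egger recovers an exact linear fit and matches normal equations", {
  g <- c(0.5, 1, 1.5)
  p <- harmonized_pairs(gamma = g, se_gamma = rep(0.01, 3),
                        Gamma = 0.1 + 0.4 * g, se_Gamma = rep(0.1, 3))
  fit <- egger(p)
  expect_equal(fit$intercept, 0.1, tolerance = 1e-10)
  expect_equal(fit$beta, 0.4, tolerance = 1e-10)

  set.seed(22)
  J <- 10
  pr <- harmonized_pairs(gamma = runif(J, 0.05, 0.3),
                         se_gamma = runif(J, 0.005, 0.02),
                         Gamma = rnorm(J, 0.05, 0.1),
                         se_Gamma = runif(J, 0.02, 0.08))
  fit2 <- egger(pr)
  # independent oracle: direct 2x2 normal equations on oriented data
  w <- 1 / pr$se_Gamma^2
  sw <- sum(w); swx <- sum(w * pr$gamma); swx2 <- sum(w * pr$gamma^2)
  swy <- sum(w * pr$Gamma); swxy <- sum(w * pr$gamma * pr$Gamma)
  slope <- (sw * swxy - swx * swy) / (sw * swx2 - swx^2)
  intercept <- (swy - slope * swx) / sw
  expect_equal(fit2$beta, slope, tolerance = 1e-10)
  expect_equal(fit2$intercept, intercept, tolerance = 1e-10)
  expect_error(egger(pr[1:2, ]), "at least 3")
})

test_that("Egger orientation makes the fit invariant to per-SNP sign flips", {
  set.seed(23)
  J <- 8
  p <- harmonized_pairs(gamma = runif(J, 0.05, 0.3),
                        se_gamma = rep(0.01, J),
                        Gamma = rnorm(J, 0.05, 0.1),
                        se_Gamma = rep(0.05, J))
  flip <- rep(c(1, -1), length.out = J)
  pf <- harmonized_pairs(gamma = p$gamma * flip, se_gamma = p$se_gamma,
                         Gamma = p$Gamma * flip, se_Gamma = p$se_Gamma)
  expect_equal(egger(pf)$beta, egger(p)$beta, tolerance = 1e-12)
  expect_equal(egger(pf)$intercept, egger(p)$intercept, tolerance = 1e-12)
})

test_that("weighted median interpolates the weighted ratio distribution", {
  p <- pairs_from_ratios(c(0.2, 0.4, 0.6))
  expect_equal(weighted_median(p, n_boot = 50, seed = 1)$beta, 0.4,
               tolerance = 1e-12)
  # hand evaluation: ratios {0,1}, weights {0.75, 0.25}:
  # S = {0.375, 0.875}; at 0.5: 0 + 1*(0.5-0.375)/0.5 = 0.25
  est <- mrmediate:::weighted_median_point(c(0, 1), c(0.75, 0.25))
  expect_equal(est, 0.25, tolerance = 1e-12)
  expect_lt(est, 0.5)
})

test_that("weighted median resists 30% gross contamination where IVW fails", {
  set.seed(24)
  reps <- 40
  res <- t(vapply(seq_len(reps), function(i) {
    J <- 20
    gamma <- runif(J, 0.05, 0.15)
    alpha <- c(rep(0.15, 6), rep(0, 14)) # 30% grossly invalid
    se_G <- rep(0.01, J)
    Gamma <- 0.3 * gamma + alpha + rnorm(J, 0, se_G)
    p <- harmonized_pairs(gamma, rep(0.005, J), Gamma, se_G)
    c(wm = weighted_median(p, n_boot = 20, seed = i)$beta,
      ivw = ivw(p, quiet = TRUE)$beta)
  }, numeric(2)))
  expect_lt(abs(mean(res[, "wm"]) - 0.3), 0.08)
  expect_gt(abs(mean(res[, "ivw"]) - 0.3), 0.2)
  expect_lt(abs(mean(res[, "wm"]) - 0.3), abs(mean(res[, "ivw"]) - 0.3) / 2)
})

test_that("mode estimators find the majority mode and handle degeneracy", {
  # bimodal ratios: 7 SNPs at 0.1, 3 at 0.9 -> majority mode near 0.1
  p <- pairs_from_ratios(c(rep(0.1, 7), rep(0.9, 3)))
  fit <- mr_mode(p, weighted = FALSE, n_boot = 20, seed = 2)
  expect_lt(abs(fit$beta - 0.1), 0.05)
  # dense-grid oracle for the same KDE
  ratios <- p$Gamma / p$gamma
  h <- 0.9 * min(sd(ratios), IQR(ratios) / 1.34) * length(ratios)^(-1 / 5)
  grid <- seq(min(ratios) - 3 * h, max(ratios) + 3 * h, length.out = 20000)
  dens <- vapply(grid, function(x) sum(dnorm((x - ratios) / h)), numeric(1))
  expect_lt(abs(fit$beta - grid[which.max(dens)]), 0.01)

  # all ratios identical: degenerate bandwidth path returns the ratio
  pd <- pairs_from_ratios(rep(0.5, 5))
  fd <- mr_mode(pd, n_boot = 10, seed = 3)
  expect_equal(fd$beta, 0.5)
  expect_equal(fd$se, ivw(pd, model = "fixed", quiet = TRUE)$se)

  # weighted variant with nearly all weight on one SNP returns its ratio
  pw <- harmonized_pairs(gamma = c(5, 0.01, 0.01),
                         se_gamma = rep(0.01, 3),
                         Gamma = c(5 * 0.7, 0.002, 0.009),
                         se_Gamma = c(0.01, 1, 1))
  fw <- mr_mode(pw, weighted = TRUE, n_boot = 10, seed = 4)
  expect_equal(fw$beta, 0.7, tolerance = 0.02)
})

test_that("all estimators are equivariant under a joint sign flip", {
  set.seed(25)
  sim <- simulate_sumstats_pair(sim_scenario(n_snps = 12, seed = 31))
  p <- sim_to_pairs(sim)
  pneg <- harmonized_pairs(gamma = p$gamma, se_gamma = p$se_gamma,
                           Gamma = -p$Gamma, se_Gamma = p$se_Gamma)
  fits <- list(
    list(ivw(p, quiet = TRUE), ivw(pneg, quiet = TRUE), TRUE),
    list(egger(p), egger(pneg), TRUE),
    list(weighted_median(p, n_boot = 30, seed = 9),
         weighted_median(pneg, n_boot = 30, seed = 9), FALSE),
    list(mr_mode(p, n_boot = 10, seed = 9),
         mr_mode(pneg, n_boot = 10, seed = 9), FALSE),
    list(mr_mode(p, weighted = FALSE, n_boot = 10, seed = 9),
         mr_mode(pneg, weighted = FALSE, n_boot = 10, seed = 9), FALSE))
  for (f in fits) {
    expect_equal(f[[2]]$beta, -f[[1]]$beta, tolerance = 1e-9)
    if (f[[3]]) { # analytic SEs are exactly invariant; bootstrap SEs vary
      expect_equal(f[[2]]$se, f[[1]]$se, tolerance = 1e-9)
    } else {
      expect_equal(f[[2]]$se, f[[1]]$se, tolerance = 0.5)
    }
  }
})
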
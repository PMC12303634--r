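test_that("variance explained follows the t-statistic and eaf formulas", {
  expect_equal(snp_r2(0.1, se = 0.01, n = 10002, method = "tstat"),
               100 / (100 + 10000), tolerance = 1e-12)
  expect_equal(snp_r2(0.2, eaf = 0.5, method = "eaf"), 0.02,
               tolerance = 1e-12)
  # monotone decreasing in n, limit 0
  r2 <- snp_r2(0.1, se = 0.01, n = c(1e3, 1e5, 1e9), method = "tstat")
  expect_true(all(diff(r2) < 0))
  expect_lt(r2[3], 1e-6)
  expect_error(snp_r2(0.1, eaf = NULL, method = "eaf"), "eaf")
})

test_that("F-statistic matches (n-2) r2/(1-r2) and the squared Wald t", {
  expect_equal(f_statistic(0.009901, 10002), 100.0, tolerance = 1e-4)
  expect_equal(f_statistic(0, 1000), 0)
  expect_equal(f_statistic(0.01, 1002), 1000 * 0.01 / 0.99,
               tolerance = 1e-12)
  # under the tstat R2, F reproduces (beta/se)^2 exactly
  beta <- 0.07; se <- 0.011; n <- 35000
  expect_equal(f_statistic(snp_r2(beta, se = se, n = n), n),
               (beta / se)^2, tolerance = 1e-9)
  # strictly increasing in r2 and in n
  expect_true(all(diff(f_statistic(c(0.01, 0.02, 0.1), 1000)) > 0))
  expect_true(all(diff(f_statistic(0.05, c(100, 1000, 10000))) > 0))
})

test_that("clumping keeps the most significant SNP of each LD group", {
  df <- data.frame(rsid = c("rs1", "rs2"), chrom = "1",
                   pos = c(1e6, 1e6 + 50e3), ea = "A", oa = "G",
                   eaf = 0.3, beta = 0.1, se = 0.01,
                   pval = c(1e-9, 1e-8), n = 1e4,
                   stringsAsFactors = FALSE)
  ld <- as_ld_matrix(matrix(c(1, 0.5, 0.5, 1), 2,
                            dimnames = list(c("rs1", "rs2"),
                                            c("rs1", "rs2"))))
  kept <- clump(df, ld, quiet = TRUE)
  expect_equal(kept$rsid, "rs1")

  # different chromosomes, no LD entry: both retained
  df2 <- df
  df2$chrom <- c("1", "2")
  ld2 <- as_ld_matrix(matrix(1, 1, 1, dimnames = list("rs1", "rs1")))
  expect_equal(nrow(clump(df2, ld2, quiet = TRUE)), 2)

  # no LD matrix: pre-clumped assumption, logged
  expect_message(clump(df, NULL), "pre-clumped")
})

test_that("clumping agrees with an independent greedy replay on block LD", {
  set.seed(11)
  for (rep in 1:5) {
    J <- 12
    ld <- simulate_ld_blocks(J, block_size = 3, within_r2 = 0.4,
                             rsids = sprintf("rs%d", 1:J))
    df <- data.frame(rsid = sprintf("rs%d", 1:J), chrom = "1",
                     pos = seq(1e6, by = 1e5, length.out = J),
                     ea = "A", oa = "G", eaf = 0.3, beta = 0.1, se = 0.01,
                     pval = runif(J, 1e-12, 1e-6), n = 1e4,
                     stringsAsFactors = FALSE)
    got <- clump(df, ld, window_kb = 10000, r2_max = 0.001, quiet = TRUE)
    expect_equal(got$rsid, clump_oracle(df, ld, 10000, 0.001))
    expect_equal(nrow(got), 4) # one survivor per block
  }
})

test_that("clump output is invariant to input row order", {
  set.seed(12)
  J <- 10
  ld <- simulate_ld_blocks(J, 5, 0.9, rsids = sprintf("rs%d", 1:J))
  df <- data.frame(rsid = sprintf("rs%d", 1:J), chrom = "1",
                   pos = seq(1e6, by = 2e5, length.out = J), ea = "A",
                   oa = "G", eaf = 0.3, beta = 0.1, se = 0.01,
                   pval = rep(1e-8, J), n = 1e4, # all ties: rsid breaks them
                   stringsAsFactors = FALSE)
  base <- clump(df, ld, quiet = TRUE)
  for (perm in list(J:1, sample(J))) {
    expect_equal(clump(df[perm, ], ld, quiet = TRUE)$rsid, base$rsid)
  }
})

test_that("instrument selection applies the stages in order with conserved counts", {
  ss <- toy_sumstats()
  # rs5 fails p; rs4 blacklisted; rs3 palindromic (A/T); others survive
  iv <- select_instruments(ss, p_threshold = 5e-8, exclusion = "rs4",
                           quiet = TRUE)
  expect_s3_class(iv, "instrument_set")
  expect_setequal(iv$snps$rsid, c("rs1", "rs2", "rs6"))
  pr <- iv$provenance
  expect_equal(unname(pr["input"]), 6)
  expect_equal(unname(pr["removed_p_threshold"]), 1)
  expect_equal(unname(pr["removed_exclusion"]), 1)
  expect_equal(unname(pr["removed_palindromic"]), 1)
  expect_equal(unname(pr["input"]),
               unname(pr["retained"]) + sum(pr[grepl("removed", names(pr))]))
  expect_true(all(iv$snps$f_stat > 10))
  expect_true(all(iv$snps$pval <= 5e-8))
})

test_that("selection errors name the stage that exhausted the set", {
  ss <- toy_sumstats()
  expect_error(select_instruments(ss, p_threshold = 1e-15, quiet = TRUE),
               "p_threshold")
  expect_error(select_instruments(ss, p_threshold = 5e-8,
                                  exclusion = sprintf("rs%d", 1:6),
                                  quiet = TRUE),
               "exclusion_list")
  # weak instruments: inflate the SEs so every F <= 10
  df <- toy_exposure_df()
  df$se <- abs(df$beta) # t = 1 -> F ~ 1
  df$pval <- rep(1e-9, 6)
  expect_error(select_instruments(toy_sumstats(df), p_threshold = 5e-8,
                                  quiet = TRUE),
               "f_filter")
})

test_that("LD matrix validation rejects malformed input", {
  m <- matrix(c(1, 0.2, 0.3, 1), 2,
              dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(as_ld_matrix(m), "symmetric")
  m2 <- matrix(c(1, 0.2, 0.2, 0.9), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(as_ld_matrix(m2), "diagonal")
  # TSV round trip
  ok <- simulate_ld_blocks(4, 2, 0.5)
  path <- tempfile(fileext = ".tsv")
  utils::write.table(as.data.frame(unclass(ok)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  expect_equal(unclass(read_ld_matrix(path)), unclass(ok))
})
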
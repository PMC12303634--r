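#' @keywords internal
mr_estimate <- function(method, nsnp, beta, se, pval,
                        ci_low = NULL, ci_high = NULL,
                        intercept = NA_real_, intercept_se = NA_real_,
                        intercept_p = NA_real_, model = NA_character_,
                        q_stat = NA_real_, q_p = NA_real_) {
  z <- stats::qnorm(0.975)
  out <- data.frame(method = method, nsnp = as.integer(nsnp),
                    beta = beta, se = se,
                    ci_low = ci_low %||% (beta - z * se),
                    ci_high = ci_high %||% (beta + z * se),
                    or_value = exp(beta), pval = pval,
                    intercept = intercept, intercept_se = intercept_se,
                    intercept_p = intercept_p, model = model,
                    q_stat = q_stat, q_p = q_p,
                    stringsAsFactors = FALSE)
  out$or_ci_low <- exp(out$ci_low)
  out$or_ci_high <- exp(out$ci_high)
  class(out) <- c("mr_estimate", "data.frame")
  out
}

#' Wald ratio estimate from a single instrument
#'
#' `beta = Gamma / gamma`, with the first-order delta-method standard error
#' `se = se_Gamma / |gamma|` (uncertainty in the exposure association is
#' ignored, the common default). P-value from a two-sided normal test.
#'
#' @param pairs A `harmonized_pairs` object with exactly one row (or a row
#'   index selecting one SNP).
#' @return An `mr_estimate` row (`method = "wald"`).
#' @export
wald_ratio <- function(pairs) {
  if (nrow(pairs) != 1) {
    stop("wald_ratio expects exactly one harmonized SNP", call. = FALSE)
  }
  g <- pairs$gamma[1]
  if (g == 0) stop("degenerate instrument: exposure effect is zero",
                   call. = FALSE)
  beta <- pairs$Gamma[1] / g
  se <- pairs$se_Gamma[1] / abs(g)
  p <- 2 * stats::pnorm(-abs(beta / se))
  mr_estimate("wald", 1L, beta, se, p)
}

#' Inverse-variance weighted estimate
#'
#' Meta-analysis of per-SNP Wald ratios with weights `(gamma/se_Gamma)^2`,
#' equivalently weighted regression of `Gamma` on `gamma` through the origin:
#' `beta = sum(gamma * Gamma / se_Gamma^2) / sum(gamma^2 / se_Gamma^2)`.
#' Under `model = "auto"` Cochran's Q decides the error model: when the Q
#' test does not reject at 0.05 the fixed-effects SE
#' `sqrt(1 / sum(gamma^2 / se_Gamma^2))` is used, otherwise a multiplicative
#' random-effects inflation `se_fixed * sqrt(Q / (J - 1))`, floored at the
#' fixed-effects SE.
#'
#' @param pairs A `harmonized_pairs` object with at least 2 SNPs (one SNP
#'   falls back to [wald_ratio()] with a logged note).
#' @param model `"fixed"`, `"random"`, or `"auto"` (default).
#' @param quiet Suppress logging.
#' @return An `mr_estimate` row carrying the Q statistic and chosen model.
#' @export
ivw <- function(pairs, model = c("auto", "fixed", "random"), quiet = FALSE) {
  model <- match.arg(model)
  J <- nrow(pairs)
  if (J < 2) {
    if (!quiet) message("single instrument: IVW falls back to the Wald ratio")
    return(wald_ratio(pairs))
  }
  w <- pairs$gamma^2 / pairs$se_Gamma^2
  beta <- sum(pairs$gamma * pairs$Gamma / pairs$se_Gamma^2) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  ratios <- pairs$Gamma / pairs$gamma
  Q <- sum(w * (ratios - beta)^2)
  q_p <- stats::pchisq(Q, df = J - 1, lower.tail = FALSE)
  chosen <- switch(model,
                   fixed = "fixed",
                   random = "random",
                   auto = if (q_p >= 0.05) "fixed" else "random")
  se <- if (chosen == "fixed") se_fixed
        else max(se_fixed, se_fixed * sqrt(Q / (J - 1)))
  p <- 2 * stats::pnorm(-abs(beta / se))
  method <- if (chosen == "fixed") "ivw_fe" else "ivw_re"
  mr_estimate(method, J, beta, se, p, model = chosen, q_stat = Q, q_p = q_p)
}

#' MR-Egger regression
#'
#' Weighted least squares of `Gamma` on `gamma` with a free intercept and
#' weights `1/se_Gamma^2`, after orienting every pair so `gamma >= 0`
#' (negating both effects where needed — the estimate must not depend on the
#' arbitrary choice of effect allele). The slope is the causal estimate; the
#' intercept captures directional horizontal pleiotropy. Coefficient
#' standard errors use the estimated residual scale floored at 1, and
#' p-values come from the t distribution with `J - 2` degrees of freedom.
#'
#' @param pairs A `harmonized_pairs` object with at least 3 SNPs.
#' @return An `mr_estimate` row (`method = "egger"`) with `intercept`,
#'   `intercept_se`, `intercept_p` filled.
#' @export
egger <- function(pairs) {
  J <- nrow(pairs)
  if (J < 3) stop("MR-Egger requires at least 3 instruments", call. = FALSE)
  flip <- sign(pairs$gamma)
  flip[flip == 0] <- 1
  g <- pairs$gamma * flip
  G <- pairs$Gamma * flip
  w <- 1 / pairs$se_Gamma^2
  X <- cbind(1, g)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * G)
  coef <- solve(XtWX, XtWy)
  resid <- G - X %*% coef
  sigma2 <- sum(w * resid^2) / (J - 2)
  scale2 <- max(1, sigma2)
  V <- scale2 * solve(XtWX)
  ses <- sqrt(diag(V))
  tvals <- coef / ses
  pvals <- 2 * stats::pt(-abs(tvals), df = J - 2)
  tq <- stats::qt(0.975, df = J - 2)
  mr_estimate("egger", J, beta = coef[2], se = ses[2], pval = pvals[2],
              ci_low = coef[2] - tq * ses[2],
              ci_high = coef[2] + tq * ses[2],
              intercept = coef[1], intercept_se = ses[1],
              intercept_p = pvals[1])
}

# weighted median of ratio estimates at cumulative weight 0.5 with the
# half-weight offset interpolation
weighted_median_point <- function(ratios, w) {
  ord <- order(ratios)
  r <- ratios[ord]
  wn <- w[ord] / sum(w)
  S <- cumsum(wn) - wn / 2
  if (S[1] >= 0.5) return(r[1])
  J <- length(r)
  if (S[J] <= 0.5) return(r[J])
  k <- max(which(S < 0.5))
  r[k] + (r[k + 1] - r[k]) * (0.5 - S[k]) / (S[k + 1] - S[k])
}

#' Weighted median estimate
#'
#' Consistent when instruments carrying at least half of the total weight
#' are valid. Per-SNP ratios `Gamma/gamma` receive weights
#' `(gamma/se_Gamma)^2` (normalized); the estimate interpolates the weighted
#' empirical distribution of ratios at cumulative weight 0.5 (with the
#' standard half-weight offset). The standard error is the SD of the
#' estimate over `n_boot` parametric-bootstrap replicates drawing each ratio
#' from `Normal(ratio_j, se_Gamma_j/|gamma_j|)`.
#'
#' @param pairs A `harmonized_pairs` object with at least 3 SNPs.
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed RNG seed for the bootstrap (default 20250721).
#' @return An `mr_estimate` row (`method = "weighted_median"`).
#' @export
weighted_median <- function(pairs, n_boot = 1000, seed = 20250721) {
  J <- nrow(pairs)
  if (J < 3) stop("weighted median requires at least 3 instruments",
                  call. = FALSE)
  ratios <- pairs$Gamma / pairs$gamma
  w <- (pairs$gamma / pairs$se_Gamma)^2
  est <- weighted_median_point(ratios, w)
  ratio_se <- pairs$se_Gamma / abs(pairs$gamma)
  boots <- with_seed(seed, {
    draws <- matrix(stats::rnorm(J * n_boot, mean = ratios, sd = ratio_se),
                    nrow = J)
    apply(draws, 2, weighted_median_point, w = w)
  })
  se <- stats::sd(boots)
  p <- 2 * stats::pnorm(-abs(est / se))
  mr_estimate("weighted_median", J, est, se, p)
}

# kernel-density mode of ratio estimates; bandwidth rule
# h = phi * 0.9 * min(sd, IQR/1.34) * J^(-1/5)
mode_point <- function(ratios, w, phi) {
  J <- length(ratios)
  s <- stats::sd(ratios)
  iqr <- stats::IQR(ratios) / 1.34
  h <- phi * 0.9 * min(s, iqr) * J^(-1 / 5)
  if (!is.finite(h) || h <= 0) return(list(mode = ratios[1], h = 0))
  d <- stats::density(ratios, weights = w / sum(w), bw = h,
                      kernel = "gaussian", n = 512,
                      from = min(ratios) - 3 * h, to = max(ratios) + 3 * h)
  list(mode = d$x[which.max(d$y)], h = h)
}

#' Mode-based estimate (simple and weighted)
#'
#' The mode of the kernel-smoothed density of per-SNP ratio estimates:
#' consistent when the largest group of instruments sharing one ratio value
#' is valid (zero modal pleiotropy assumption). Normal kernel with bandwidth
#' `phi * 0.9 * min(sd, IQR/1.34) * J^(-1/5)`, density evaluated on a
#' 512-point grid spanning the ratio range plus three bandwidths; the
#' weighted variant weights each kernel by the normalized IVW weight
#' `(gamma/se_Gamma)^2`. SE by parametric bootstrap as in
#' [weighted_median()]. When all ratios coincide the bandwidth degenerates
#' and the common ratio is returned with the fixed-effects IVW SE.
#'
#' @param pairs A `harmonized_pairs` object with at least 3 SNPs.
#' @param weighted Use IVW weights (`TRUE`) or equal weights (`FALSE`).
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed RNG seed (default 20250721).
#' @return An `mr_estimate` row (`method = "weighted_mode"` or
#'   `"simple_mode"`).
#' @export
mr_mode <- function(pairs, weighted = TRUE, phi = 1, n_boot = 1000,
                    seed = 20250721) {
  J <- nrow(pairs)
  if (J < 3) stop("mode-based estimation requires at least 3 instruments",
                  call. = FALSE)
  ratios <- pairs$Gamma / pairs$gamma
  w <- if (weighted) (pairs$gamma / pairs$se_Gamma)^2 else rep(1, J)
  method <- if (weighted) "weighted_mode" else "simple_mode"
  pt <- mode_point(ratios, w, phi)
  if (pt$h == 0) {
    # all ratios identical: the mode is that ratio, spread comes from IVW
    fe <- ivw(pairs, model = "fixed", quiet = TRUE)
    return(mr_estimate(method, J, ratios[1], fe$se,
                       2 * stats::pnorm(-abs(ratios[1] / fe$se))))
  }
  ratio_se <- pairs$se_Gamma / abs(pairs$gamma)
  boots <- with_seed(seed, {
    draws <- matrix(stats::rnorm(J * n_boot, mean = ratios, sd = ratio_se),
                    nrow = J)
    apply(draws, 2, function(r) mode_point(r, w, phi)$mode)
  })
  se <- stats::sd(boots)
  p <- 2 * stats::pnorm(-abs(pt$mode / se))
  mr_estimate(method, J, pt$mode, se, p)
}

#' Run a set of MR estimators on one harmonized pair set
#'
#' @param pairs A `harmonized_pairs` object.
#' @param methods Subset of `c("ivw", "egger", "weighted_median",
#'   "weighted_mode", "simple_mode")`; methods whose instrument minimum is
#'   not met are skipped with a note.
#' @param ivw_model Passed to [ivw()].
#' @param n_boot,seed Bootstrap controls for median/mode SEs.
#' @param quiet Suppress logging.
#' @return An `mr_estimate` data frame, one row per method run.
#' @export
run_estimators <- function(pairs,
                           methods = c("ivw", "egger", "weighted_median",
                                       "weighted_mode", "simple_mode"),
                           ivw_model = "auto", n_boot = 1000,
                           seed = 20250721, quiet = FALSE) {
  methods <- match.arg(methods, several.ok = TRUE)
  J <- nrow(pairs)
  rows <- list()
  for (m in methods) {
    min_j <- if (m == "ivw") 1 else 3
    if (J < min_j) {
      if (!quiet) message(sprintf("skipping %s: %d instrument(s) < %d", m, J,
                                  min_j))
      next
    }
    rows[[m]] <- switch(m,
      ivw = ivw(pairs, model = ivw_model, quiet = quiet),
      egger = egger(pairs),
      weighted_median = weighted_median(pairs, n_boot = n_boot, seed = seed),
      weighted_mode = mr_mode(pairs, weighted = TRUE, n_boot = n_boot,
                              seed = seed),
      simple_mode = mr_mode(pairs, weighted = FALSE, n_boot = n_boot,
                            seed = seed))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# evaluate expr under a local RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
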
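#' Analysis configuration
#'
#' Bundles every tunable of the MR workflow. Role-specific instrument
#' p-value thresholds default to the study design: molecular exposures
#' (cytokines/proteins) 5e-6, immune-cell mediators 1e-5, disease traits
#' used as exposures in the reverse direction 5e-8. Threshold escalation for
#' instrument-poor exposures is never automatic; callers opt in by setting
#' the threshold explicitly.
#'
#' @param p_exposure,p_mediator,p_disease Instrument p-value thresholds per
#'   trait role.
#' @param window_kb,r2_max LD-clumping window (kb) and r-squared threshold.
#' @param f_min Weak-instrument F threshold.
#' @param exclusion Character vector of blacklisted rsIDs (confounder-
#'   associated SNPs), or `NULL`.
#' @param ld An `ld_matrix` or `NULL` (SNPs assumed pre-clumped).
#' @param methods Estimators to run, see [run_estimators()].
#' @param fdr_alpha Significance level for the BH-adjusted IVW p-values.
#' @param presso_nsim MR-PRESSO null simulations.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param seed RNG seed governing every stochastic component.
#' @param out_dir Output directory for result TSVs, or `NULL` to skip
#'   writing.
#' @param quiet Suppress logging.
#' @return An `mr_config` list.
#' @export
mr_config <- function(p_exposure = 5e-6, p_mediator = 1e-5,
                      p_disease = 5e-8, window_kb = 10000, r2_max = 0.001,
                      f_min = 10, exclusion = NULL, ld = NULL,
                      methods = c("ivw", "egger", "weighted_median",
                                  "weighted_mode", "simple_mode"),
                      fdr_alpha = 0.05, presso_nsim = 1000, n_boot = 1000,
                      seed = 20250721, out_dir = NULL, quiet = FALSE) {
  stopifnot(p_exposure > 0, p_exposure < 1, p_mediator > 0, p_mediator < 1,
            p_disease > 0, p_disease < 1, fdr_alpha > 0, fdr_alpha < 1)
  structure(list(p_exposure = p_exposure, p_mediator = p_mediator,
                 p_disease = p_disease, window_kb = window_kb,
                 r2_max = r2_max, f_min = f_min, exclusion = exclusion,
                 ld = ld, methods = methods, fdr_alpha = fdr_alpha,
                 presso_nsim = presso_nsim, n_boot = n_boot,
                 seed = as.integer(seed), out_dir = out_dir,
                 quiet = quiet),
            class = "mr_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Recognised keys match the arguments of [mr_config()]; `exclusion` may be
#' a path to a one-rsID-per-line file, and `ld` a path to an LD-matrix TSV.
#'
#' @param path YAML file path.
#' @return An `mr_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$exclusion) && is.character(raw$exclusion) &&
      length(raw$exclusion) == 1 && file.exists(raw$exclusion)) {
    raw$exclusion <- read_exclusion_list(raw$exclusion)
  }
  if (!is.null(raw$ld) && is.character(raw$ld)) {
    raw$ld <- read_ld_matrix(raw$ld)
  }
  known <- names(formals(mr_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(mr_config, raw)
}

#' Run one exposure -> outcome MR analysis
#'
#' Executes instrument selection, harmonization, the configured estimators
#' and the full sensitivity battery for a single pair of traits. Stage
#' failures are re-raised with the failing stage named.
#'
#' @param exposure,outcome `sumstats` objects.
#' @param cfg An `mr_config`.
#' @param p_threshold Instrument threshold; defaults to `cfg$p_exposure`.
#' @return List with `estimates` (one row per method, labelled with the
#'   trait ids), `sensitivity` (a `sensitivity_report`), `pairs`
#'   (`harmonized_pairs`), and `instruments` (`instrument_set`).
#' @export
run_mr_pair <- function(exposure, outcome, cfg = mr_config(),
                        p_threshold = NULL) {
  p_threshold <- p_threshold %||% cfg$p_exposure
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  iv <- stage("select_instruments",
              select_instruments(exposure, p_threshold = p_threshold,
                                 exclusion = cfg$exclusion, ld = cfg$ld,
                                 window_kb = cfg$window_kb,
                                 r2_max = cfg$r2_max, f_min = cfg$f_min,
                                 quiet = cfg$quiet))
  pairs <- stage("harmonize", harmonize(iv, outcome, quiet = cfg$quiet))
  est <- stage("estimators",
               run_estimators(pairs, methods = cfg$methods,
                              n_boot = cfg$n_boot, seed = cfg$seed,
                              quiet = cfg$quiet))
  sens <- stage("sensitivity",
                sensitivity_report(pairs, presso_nsim = cfg$presso_nsim,
                                   seed = cfg$seed, quiet = cfg$quiet))
  est <- cbind(exposure = attr(pairs, "exposure_id"),
               outcome = attr(pairs, "outcome_id"), est,
               stringsAsFactors = FALSE)
  list(estimates = est, sensitivity = sens, pairs = pairs,
       instruments = iv)
}

#' Bidirectional MR between two traits
#'
#' Runs [run_mr_pair()] in both directions with role-appropriate thresholds
#' and evaluates the Steiger directionality filter in each.
#'
#' @param a,b `sumstats` objects.
#' @param cfg An `mr_config`.
#' @param p_forward,p_reverse Instrument thresholds for the a -> b and
#'   b -> a directions (defaults `cfg$p_exposure` and `cfg$p_disease`).
#' @return List with elements `forward` and `reverse`, each as returned by
#'   [run_mr_pair()] (or `NULL` with a logged note when a stage exhausts the
#'   instrument set in that direction).
#' @export
run_bidirectional <- function(a, b, cfg = mr_config(), p_forward = NULL,
                              p_reverse = NULL) {
  if (identical(attr(a, "trait_id"), attr(b, "trait_id"))) {
    warning("the two traits share one trait_id; bidirectional MR of a trait on itself is degenerate",
            call. = FALSE)
  }
  run_dir <- function(x, y, p) {
    tryCatch(run_mr_pair(x, y, cfg, p_threshold = p),
             error = function(e) {
               if (!cfg$quiet) message("direction skipped: ",
                                       conditionMessage(e))
               NULL
             })
  }
  list(forward = run_dir(a, b, p_forward %||% cfg$p_exposure),
       reverse = run_dir(b, a, p_reverse %||% cfg$p_disease))
}

# one IVW + sensitivity summary row per exposure of a panel against one
# outcome; failed pairs are recorded and skipped
panel_scan <- function(panel, outcome, cfg, p_threshold) {
  rows <- list()
  failures <- character(0)
  for (ex in panel) {
    id <- attr(ex, "trait_id")
    res <- tryCatch(run_mr_pair(ex, outcome, cfg,
                                p_threshold = p_threshold),
                    error = function(e) {
                      failures[[length(failures) + 1]] <<-
                        sprintf("%s: %s", id, conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) next
    ivw_row <- res$estimates[grepl("^ivw", res$estimates$method), ,
                             drop = FALSE]
    eg <- res$estimates[res$estimates$method == "egger", , drop = FALSE]
    sens <- as.data.frame(res$sensitivity)
    row <- data.frame(exposure = id, outcome = attr(outcome, "trait_id"),
                      nsnp = ivw_row$nsnp, beta = ivw_row$beta,
                      se = ivw_row$se, ci_low = ivw_row$ci_low,
                      ci_high = ivw_row$ci_high,
                      or_value = ivw_row$or_value, pval = ivw_row$pval,
                      egger_beta = if (nrow(eg)) eg$beta else NA_real_,
                      stringsAsFactors = FALSE)
    rows[[id]] <- cbind(row, sens[, c("q_stat", "q_p", "egger_intercept",
                                      "egger_intercept_p",
                                      "presso_global_p",
                                      "steiger_r2_exp", "steiger_r2_out",
                                      "correct_causal_direction",
                                      "steiger_p")])
  }
  list(rows = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       failures = failures)
}

#' Two-step MR mediation pipeline
#'
#' The three-step design over an exposure panel, a candidate-mediator panel
#' and one outcome:
#' * Step 1 — each exposure against the outcome (total effects), BH-FDR over
#'   the exposure family; survivors need pFDR < alpha, a correct Steiger
#'   direction and IVW/Egger sign agreement.
#' * Step 2 — each mediator against the outcome, BH-FDR over the mediator
#'   family, same exclusions.
#' * Step 3 — every surviving exposure against every surviving mediator,
#'   BH-FDR over the surviving mediators per exposure; surviving
#'   (exposure, mediator) pairs enter the product-of-coefficients
#'   calculus: indirect = beta1 * beta2, proportion = indirect / beta_total.
#'
#' When `cfg$out_dir` is set, writes `estimates.tsv` (steps 1 and 2 scans),
#' `mediation.tsv` (Table-1-format rows) and `audit.tsv` (exclusions and
#' failures). Deterministic given `cfg$seed`.
#'
#' @param exposures,mediators Lists of `sumstats` objects.
#' @param outcome A `sumstats` object.
#' @param cfg An `mr_config`.
#' @param m_exposures,m_mediators FDR family sizes (default: panel lengths;
#'   set larger when only part of a catalog panel is analysed).
#' @return List with `step1`, `step2`, `step3` annotated scan tables and
#'   `mediation` (a `mediation_result` data frame, zero rows when nothing
#'   survives).
#' @export
run_mediation_pipeline <- function(exposures, mediators, outcome,
                                   cfg = mr_config(),
                                   m_exposures = length(exposures),
                                   m_mediators = length(mediators)) {
  stopifnot(length(exposures) > 0, length(mediators) > 0)
  out_id <- attr(outcome, "trait_id")
  log_msg <- function(...) if (!cfg$quiet) message(sprintf(...))

  s1 <- panel_scan(exposures, outcome, cfg, cfg$p_exposure)
  if (is.null(s1$rows)) stop("step 1: no exposure produced an MR estimate",
                             call. = FALSE)
  step1 <- build_result_table(s1$rows, alpha = cfg$fdr_alpha,
                              m = m_exposures)
  surv1 <- step1[step1$significant &
                   !(step1$egger_sign_disagreement %in% TRUE), ,
                 drop = FALSE]
  log_msg("step 1: %d/%d exposures survive FDR against %s", nrow(surv1),
          length(exposures), out_id)

  s2 <- panel_scan(mediators, outcome, cfg, cfg$p_mediator)
  if (is.null(s2$rows)) stop("step 2: no mediator produced an MR estimate",
                             call. = FALSE)
  step2 <- build_result_table(s2$rows, alpha = cfg$fdr_alpha,
                              m = m_mediators)
  surv2 <- step2[step2$nominal &
                   !(step2$egger_sign_disagreement %in% TRUE), ,
                 drop = FALSE]
  log_msg("step 2: %d/%d mediators survive against %s", nrow(surv2),
          length(mediators), out_id)

  med_rows <- list()
  step3_rows <- list()
  if (nrow(surv1) > 0 && nrow(surv2) > 0) {
    med_by_id <- stats::setNames(mediators,
                                 vapply(mediators, attr, "", "trait_id"))
    exp_by_id <- stats::setNames(exposures,
                                 vapply(exposures, attr, "", "trait_id"))
    for (eid in surv1$exposure) {
      # step 3 runs exposure -> mediator, with the mediator in the outcome
      # role
      s3 <- panel_scan_step3(exp_by_id[[eid]], med_by_id[surv2$exposure],
                             cfg)
      if (is.null(s3$rows)) next
      step3 <- build_result_table(s3$rows, alpha = cfg$fdr_alpha,
                                  m = nrow(surv2))
      step3_rows[[eid]] <- step3
      surv3 <- step3[step3$significant &
                       !(step3$egger_sign_disagreement %in% TRUE), ,
                     drop = FALSE]
      for (mid in surv3$outcome) {
        beta_total <- surv1$beta[surv1$exposure == eid][1]
        beta1 <- surv3$beta[surv3$outcome == mid][1]
        beta2 <- surv2$beta[surv2$exposure == mid][1]
        med_rows[[paste(eid, mid)]] <-
          mediation_effects(beta_total, beta1, beta2, exposure = eid,
                            mediator = mid, outcome = out_id)
      }
    }
  }
  mediation <- if (length(med_rows) > 0) {
    do.call(rbind, c(med_rows, list(make.row.names = FALSE)))
  } else {
    log_msg("no (exposure, mediator) pair survives all three steps")
    mediation_effects(1, 0, 0)[0, , drop = FALSE]
  }

  if (!is.null(cfg$out_dir)) {
    scan_all <- rbind(cbind(step = 1L, as.data.frame(step1)),
                      cbind(step = 2L, as.data.frame(step2)))
    write_results(scan_all, file.path(cfg$out_dir, "estimates.tsv"))
    if (nrow(mediation) > 0) {
      write_results(mediation, file.path(cfg$out_dir, "mediation.tsv"))
    } else {
      dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
      writeLines(paste(names(mediation_effects(1, 0, 0)), collapse = "\t"),
                 file.path(cfg$out_dir, "mediation.tsv"))
    }
    audit <- data.frame(
      note = c(sprintf("step1 failure %s", s1$failures),
               sprintf("step2 failure %s", s2$failures),
               sprintf("step1 direction-excluded %s",
                       attr(step1, "excluded")$exposure),
               sprintf("step2 direction-excluded %s",
                       attr(step2, "excluded")$exposure)),
      stringsAsFactors = FALSE)
    if (nrow(audit) == 0) audit <- data.frame(note = "no exclusions")
    write_results(audit, file.path(cfg$out_dir, "audit.tsv"))
  }
  list(step1 = step1, step2 = step2, step3 = step3_rows,
       mediation = mediation)
}

# exposure -> each mediator scan (step 3); mirrors panel_scan with the
# mediator in the outcome role
panel_scan_step3 <- function(exposure, mediator_panel, cfg) {
  rows <- list()
  failures <- character(0)
  for (md in mediator_panel) {
    mid <- attr(md, "trait_id")
    res <- tryCatch(run_mr_pair(exposure, md, cfg,
                                p_threshold = cfg$p_exposure),
                    error = function(e) {
                      failures[[length(failures) + 1]] <<-
                        sprintf("%s: %s", mid, conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) next
    ivw_row <- res$estimates[grepl("^ivw", res$estimates$method), ,
                             drop = FALSE]
    eg <- res$estimates[res$estimates$method == "egger", , drop = FALSE]
    sens <- as.data.frame(res$sensitivity)
    row <- data.frame(exposure = attr(exposure, "trait_id"), outcome = mid,
                      nsnp = ivw_row$nsnp, beta = ivw_row$beta,
                      se = ivw_row$se, ci_low = ivw_row$ci_low,
                      ci_high = ivw_row$ci_high,
                      or_value = ivw_row$or_value, pval = ivw_row$pval,
                      egger_beta = if (nrow(eg)) eg$beta else NA_real_,
                      stringsAsFactors = FALSE)
    rows[[mid]] <- cbind(row, sens[, c("q_stat", "q_p", "egger_intercept",
                                       "egger_intercept_p",
                                       "presso_global_p",
                                       "steiger_r2_exp", "steiger_r2_out",
                                       "correct_causal_direction",
                                       "steiger_p")])
  }
  list(rows = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       failures = failures)
}
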
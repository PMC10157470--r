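# Study orchestration: Bonferroni thresholds, three-tier significance
# classification, and the exposure x outcome grid runner.

#' Bonferroni-corrected significance threshold
#'
#' @param family_alpha Family-wise error rate, in (0, 1).
#' @param n_tests Number of tests in the family.
#' @return `family_alpha / n_tests`.
#' @export
#' @examples
#' bonferroni_threshold(0.05, 68)  # 7.35e-4, the regional threshold
#' bonferroni_threshold(0.05, 2)   # 0.025, the global threshold
bonferroni_threshold <- function(family_alpha, n_tests) {
  stopifnot(family_alpha > 0, family_alpha < 1)
  if (!is.numeric(n_tests) || length(n_tests) != 1L || n_tests < 1) {
    stopf("n_tests must be a positive integer")
  }
  family_alpha / n_tests
}

#' Study-level configuration
#'
#' Thresholds and settings for [run_study()] and [classify_pair()]. The
#' regional threshold is Bonferroni-corrected for 34 cortical regions x 2
#' measures (surface area, thickness) = 68 tests; the global threshold for
#' the 2 whole-cortex measures.
#'
#' @param family_alpha Family-wise alpha (default 0.05).
#' @param n_regional_tests Regional test count (default 68).
#' @param n_global_tests Global test count (default 2).
#' @param wm_alpha Weighted-median significance requirement inside the
#'   "significant" tier (default 0.05; the weighted median is the more
#'   conservative estimator, so it is held to the nominal level).
#' @param heterogeneity_alpha Cochran's Q gate (default 0.05).
#' @param pleiotropy_alpha Egger-intercept gate (default 0.05).
#' @param loo_threshold Leave-one-out per-refit significance requirement
#'   (default 0.05).
#' @param require_sensitivity_gates Require Q p, intercept p and
#'   leave-one-out to clear their gates for the "significant" tier (default
#'   `TRUE`, the stricter reading; `FALSE` uses only the three consistency
#'   criteria).
#' @param presso Run the MR-PRESSO outlier pre-filter before estimation
#'   (default `TRUE`).
#' @param presso_n_sim,outlier_alpha MR-PRESSO settings.
#' @param n_boot Weighted-median bootstrap resamples.
#' @param seed Integer master seed for all stochastic components; per-pair
#'   seeds are derived deterministically from it.
#' @param selection A [selection_config()], or a named list of them (one
#'   per exposure) for per-exposure thresholds (e.g. the relaxed IL-6
#'   significance cutoff).
#' @param palindrome_eaf_limit Passed to [harmonize()].
#' @param sample_overlap_note Optional free-text note on assumed
#'   exposure-outcome sample overlap, recorded in report metadata only.
#' @return List of class `study_config`, including the derived
#'   `regional_alpha` and `global_alpha`.
#' @export
study_config <- function(family_alpha = 0.05, n_regional_tests = 68,
                         n_global_tests = 2, wm_alpha = 0.05,
                         heterogeneity_alpha = 0.05, pleiotropy_alpha = 0.05,
                         loo_threshold = 0.05,
                         require_sensitivity_gates = TRUE,
                         presso = TRUE, presso_n_sim = 1000,
                         outlier_alpha = 0.05, n_boot = 1000, seed = NULL,
                         selection = selection_config(),
                         palindrome_eaf_limit = 0.42,
                         sample_overlap_note = NULL) {
  structure(list(
    family_alpha = family_alpha,
    regional_alpha = bonferroni_threshold(family_alpha, n_regional_tests),
    global_alpha = bonferroni_threshold(family_alpha, n_global_tests),
    wm_alpha = wm_alpha, heterogeneity_alpha = heterogeneity_alpha,
    pleiotropy_alpha = pleiotropy_alpha, loo_threshold = loo_threshold,
    require_sensitivity_gates = require_sensitivity_gates,
    presso = presso, presso_n_sim = presso_n_sim,
    outlier_alpha = outlier_alpha, n_boot = n_boot, seed = seed,
    selection = selection, palindrome_eaf_limit = palindrome_eaf_limit,
    sample_overlap_note = sample_overlap_note), class = "study_config")
}

.est_table <- function(estimates) {
  if (inherits(estimates, "mr_fit")) return(estimates$estimates)
  if (is.data.frame(estimates)) return(estimates)
  if (is.list(estimates)) {
    return(do.call(rbind, lapply(estimates, function(e) {
      data.frame(method = e$method, beta = e$beta, se = e$se,
                 pvalue = e$pvalue, n_snps = e$n_snps,
                 stringsAsFactors = FALSE)
    })))
  }
  stopf("cannot interpret 'estimates'")
}

.sens_fields <- function(sensitivity) {
  if (is.null(sensitivity)) return(list(q_pvalue = NA_real_,
                                        intercept_pvalue = NA_real_,
                                        loo_pass = NA))
  if (inherits(sensitivity, "mr_sensitivity")) {
    return(list(q_pvalue = sensitivity$q$q_pvalue,
                intercept_pvalue = sensitivity$egger_intercept$pvalue,
                loo_pass = sensitivity$loo$loo_pass))
  }
  list(q_pvalue = sensitivity$q_pvalue %||% NA_real_,
       intercept_pvalue = sensitivity$intercept_pvalue %||% NA_real_,
       loo_pass = sensitivity$loo_pass %||% NA)
}

#' Three-tier significance classification for one pair
#'
#' Classifies an exposure-outcome result as `"significant"`, `"nominal"` or
#' `"null"`. The significant tier requires all consistency criteria: the
#' IVW p-value below the level-specific Bonferroni threshold, the
#' weighted-median p-value below `wm_alpha`, and the weighted-median and
#' MR-Egger estimates pointing in the same direction as the IVW; with
#' `require_sensitivity_gates` (default) it additionally requires no
#' detected heterogeneity (Q p at or above `heterogeneity_alpha`), no
#' detected pleiotropy (intercept p at or above `pleiotropy_alpha`) and a
#' passing leave-one-out analysis. The nominal tier is IVW p below 0.05
#' without meeting the significant tier. Single-instrument (Wald-ratio)
#' pairs can reach at most nominal.
#'
#' @param estimates An [mr_fit()], or a `data.frame` with columns `method`,
#'   `beta`, `pvalue` covering `ivw_mre` (or `ivw_fixed`),
#'   `weighted_median`, `egger_slope`.
#' @param sensitivity An `mr_sensitivity`, or a list with `q_pvalue`,
#'   `intercept_pvalue`, `loo_pass`; `NULL` when unavailable.
#' @param config A [study_config()].
#' @param level `"regional"` or `"global"`: which Bonferroni threshold
#'   applies.
#' @return List `tier` and `reasons` (ordered character vector, one entry
#'   per criterion, each marked satisfied or violated).
#' @export
classify_pair <- function(estimates, sensitivity = NULL,
                          config = study_config(),
                          level = c("regional", "global")) {
  level <- match.arg(level)
  tab <- .est_table(estimates)
  sens <- .sens_fields(sensitivity)
  thr <- if (level == "regional") config$regional_alpha else config$global_alpha

  ivw <- tab[match("ivw_mre", tab$method), ]
  if (is.na(ivw$method)) ivw <- tab[match("ivw_fixed", tab$method), ]
  if (is.na(ivw$method)) stopf("no IVW estimate supplied")
  wm <- tab[match("weighted_median", tab$method), ]
  eg <- tab[match("egger_slope", tab$method), ]
  has_wm <- !is.na(wm$method)
  has_eg <- !is.na(eg$method)
  j <- if ("n_snps" %in% names(tab)) ivw$n_snps else NA_integer_
  if (!is.na(j) && j >= 3L && (!has_wm || !has_eg)) {
    stopf("pair with %d instruments is missing weighted-median or MR-Egger estimates", j)
  }

  ok <- function(cond, what) {
    sprintf("%s: %s", what,
            if (isTRUE(cond)) "satisfied" else "violated")
  }
  crit <- list(
    ivw = ivw$pvalue < thr,
    wm_p = has_wm && wm$pvalue < config$wm_alpha,
    direction = has_wm && has_eg &&
      sign(wm$beta) == sign(ivw$beta) && sign(eg$beta) == sign(ivw$beta)
  )
  reasons <- c(
    ok(crit$ivw, sprintf("IVW p < %s threshold (%.3g)", level, thr)),
    ok(crit$wm_p, sprintf("weighted-median p < %g", config$wm_alpha)),
    ok(crit$direction, "WM and Egger direction concordant with IVW"))
  if (config$require_sensitivity_gates) {
    crit$q <- !is.na(sens$q_pvalue) && sens$q_pvalue >= config$heterogeneity_alpha
    crit$pleio <- !is.na(sens$intercept_pvalue) &&
      sens$intercept_pvalue >= config$pleiotropy_alpha
    crit$loo <- isTRUE(sens$loo_pass)
    reasons <- c(reasons,
                 ok(crit$q, sprintf("no heterogeneity (Q p >= %g)",
                                    config$heterogeneity_alpha)),
                 ok(crit$pleio, sprintf("no pleiotropy (intercept p >= %g)",
                                        config$pleiotropy_alpha)),
                 ok(crit$loo, "leave-one-out stable"))
  }
  tier <- if (all(unlist(crit))) "significant"
          else if (ivw$pvalue < 0.05) "nominal"
          else "null"
  if (tier != "significant") {
    reasons <- c(reasons, ok(ivw$pvalue < 0.05, "IVW p < 0.05 (nominal)"))
  }
  list(tier = tier, reasons = reasons)
}

.as_records <- function(x, what) {
  if (is.character(x) && length(x) == 1L) return(read_summary_stats(x))
  if (is.data.frame(x)) return(x)
  stopf("%s must be a data.frame of summary records or a file path", what)
}

#' Run the full exposure x outcome MR study
#'
#' For every exposure: select instruments ([select_instruments()]); for
#' every outcome: harmonize, optionally pre-filter outliers with MR-PRESSO,
#' fit the estimator battery ([mr_fit()]), run the sensitivity battery, and
#' classify the pair ([classify_pair()]). Pairs that cannot be evaluated
#' (no shared SNPs, too few instruments for classification, selection
#' failure) are reported with tier `"not_evaluable"` and the cause, never
#' silently dropped. Report rows are ordered by exposure then outcome name.
#'
#' @param exposures Named list: exposure name -> summary-record `data.frame`
#'   or file path.
#' @param outcomes Named list: outcome name -> summary-record `data.frame`
#'   or file path.
#' @param ld Pairwise LD table (see [read_ld_table()]) or `NULL`.
#' @param exclusions Confounder exclusion `data.frame(snp_id, reason)`, a
#'   named list of them (one per exposure), or `NULL`.
#' @param config A [study_config()].
#' @param global_outcomes Character vector of outcome names tested at the
#'   global Bonferroni threshold; by default, names beginning with
#'   "global" (case-insensitive).
#' @param outdir Optional directory: writes `results_long.tsv` (all
#'   method-level estimates), `table1_style.tsv` (significant + nominal
#'   rows: exposure, outcome, beta, se, ivw_p, q_p, intercept_p, loo) and
#'   `audit.log`.
#' @return Object of class `mr_study`: `summary` (one row per pair),
#'   `long` (one row per pair x method), `pairs` (per-pair detail: fit,
#'   sensitivity, classification), `instruments` (per-exposure
#'   `instrument_set`), `audit` (character log), `config`.
#' @export
run_study <- function(exposures, outcomes, ld = NULL, exclusions = NULL,
                      config = study_config(), global_outcomes = NULL,
                      outdir = NULL) {
  stopifnot(inherits(config, "study_config"))
  if (is.null(names(exposures)) || is.null(names(outcomes))) {
    stopf("exposures and outcomes must be named lists")
  }
  audit <- character(0)
  log <- function(fmt, ...) audit <<- c(audit, sprintf(fmt, ...))
  if (!is.null(config$sample_overlap_note)) {
    log("assumed sample overlap: %s", config$sample_overlap_note)
  }
  if (is.null(global_outcomes)) {
    global_outcomes <- names(outcomes)[grepl("^global", names(outcomes),
                                             ignore.case = TRUE)]
  }
  ex_names <- sort(names(exposures))
  out_names <- sort(names(outcomes))
  out_recs <- lapply(outcomes, .as_records, what = "outcome")

  instrument_sets <- list()
  pairs <- list()
  rows <- list()
  long <- list()
  pair_idx <- 0L

  for (ex in ex_names) {
    sel_cfg <- if (inherits(config$selection, "selection_config")) config$selection
               else config$selection[[ex]] %||% selection_config()
    excl <- if (is.data.frame(exclusions) || is.null(exclusions)) exclusions
            else exclusions[[ex]]
    if (!is.null(excl)) sel_cfg$exclusions <- excl
    inst <- tryCatch(
      select_instruments(.as_records(exposures[[ex]], "exposure"), ld, sel_cfg),
      error = function(e) e)
    if (inherits(inst, "error")) {
      log("exposure %s: instrument selection failed (%s)", ex,
          conditionMessage(inst))
      for (ou in out_names) {
        rows[[length(rows) + 1L]] <- data.frame(
          exposure = ex, outcome = ou,
          level = if (ou %in% global_outcomes) "global" else "regional",
          n_snps = 0L, beta = NA_real_, se = NA_real_, ivw_p = NA_real_,
          q_p = NA_real_, intercept_p = NA_real_, loo = NA,
          tier = "not_evaluable",
          reason = paste("instrument selection failed:",
                         conditionMessage(inst)),
          stringsAsFactors = FALSE)
      }
      next
    }
    instrument_sets[[ex]] <- inst
    log("exposure %s: %s", ex,
        paste(names(inst$audit), inst$audit, sep = "=", collapse = ", "))

    for (ou in out_names) {
      pair_idx <- pair_idx + 1L
      level <- if (ou %in% global_outcomes) "global" else "regional"
      pair_seed <- if (is.null(config$seed)) NULL
                   else (config$seed + 7L * pair_idx) %% .Machine$integer.max
      res <- tryCatch(
        .run_pair(inst$instruments, out_recs[[ou]],
                  pair_label = paste(ex, "x", ou), level = level,
                  config = config, seed = pair_seed),
        error = function(e) e)
      if (inherits(res, "error")) {
        log("pair %s x %s: not evaluable (%s)", ex, ou, conditionMessage(res))
        rows[[length(rows) + 1L]] <- data.frame(
          exposure = ex, outcome = ou, level = level, n_snps = 0L,
          beta = NA_real_, se = NA_real_, ivw_p = NA_real_, q_p = NA_real_,
          intercept_p = NA_real_, loo = NA, tier = "not_evaluable",
          reason = conditionMessage(res), stringsAsFactors = FALSE)
        next
      }
      pairs[[paste(ex, ou, sep = "|")]] <- res
      prim <- res$primary
      sens <- .sens_fields(res$sensitivity)
      log("pair %s x %s: J=%d, IVW beta=%.4g p=%.3g, tier=%s",
          ex, ou, res$fit$n_snps, prim$beta, prim$pvalue, res$tier)
      rows[[length(rows) + 1L]] <- data.frame(
        exposure = ex, outcome = ou, level = level, n_snps = res$fit$n_snps,
        beta = prim$beta, se = prim$se, ivw_p = prim$pvalue,
        q_p = sens$q_pvalue, intercept_p = sens$intercept_pvalue,
        loo = sens$loo_pass, tier = res$tier,
        reason = paste(res$reasons, collapse = "; "),
        stringsAsFactors = FALSE)
      lt <- res$fit$estimates
      lt <- cbind(data.frame(exposure = ex, outcome = ou,
                             stringsAsFactors = FALSE), lt)
      long[[length(long) + 1L]] <- lt
    }
  }

  summary_df <- do.call(rbind, rows)
  o <- order(summary_df$exposure, summary_df$outcome)
  summary_df <- summary_df[o, , drop = FALSE]
  rownames(summary_df) <- NULL
  long_df <- if (length(long)) do.call(rbind, long) else NULL
  study <- structure(list(summary = summary_df, long = long_df,
                          pairs = pairs, instruments = instrument_sets,
                          audit = audit, config = config),
                     class = "mr_study")
  if (!is.null(outdir)) write_study_reports(study, outdir)
  study
}

# one exposure-outcome pair: harmonize -> PRESSO pre-filter -> fit ->
# sensitivity -> classify
.run_pair <- function(instruments, outcome_records, pair_label, level,
                      config, seed) {
  hs <- harmonize(instruments, outcome_records,
                  palindrome_eaf_limit = config$palindrome_eaf_limit,
                  pair_label = pair_label)
  presso_res <- NULL
  if (config$presso && nrow(hs) >= 4L) {
    presso_res <- mr_presso(hs, n_sim = config$presso_n_sim, seed = seed,
                            outlier_alpha = config$outlier_alpha)
    hs <- presso_res$cleaned
  }
  j <- nrow(hs)
  fit <- mr_fit(hs, n_boot = config$n_boot,
                seed = if (is.null(seed)) NULL else seed + 1L)
  sens <- if (j >= 3L) {
    s <- mr_sensitivity(hs, loo_threshold = config$loo_threshold,
                        heterogeneity_alpha = config$heterogeneity_alpha,
                        presso = FALSE)
    s$presso <- presso_res
    s
  } else NULL
  if (j >= 3L) {
    cls <- classify_pair(fit, sens, config, level)
  } else {
    # Wald-ratio / two-SNP pairs: nominal at best
    ivw_p <- fit$estimates$pvalue[1L]
    cls <- list(tier = if (ivw_p < 0.05) "nominal" else "null",
                reasons = sprintf(
                  "fewer than 3 instruments (J=%d): capped at nominal; IVW p = %.3g",
                  j, ivw_p))
  }
  prim <- fit$estimates[1L, ]
  list(fit = fit, sensitivity = sens, presso = presso_res, primary = prim,
       tier = cls$tier, reasons = cls$reasons, level = level)
}

#' Write study reports to disk
#'
#' @param study An [run_study()] result.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_study_reports <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(study$long)) {
    utils::write.table(study$long, file.path(outdir, "results_long.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tab1 <- study$summary[study$summary$tier %in% c("significant", "nominal"),
                        c("exposure", "outcome", "beta", "se", "ivw_p",
                          "q_p", "intercept_p", "loo")]
  tab1$loo <- ifelse(is.na(tab1$loo), "NA", ifelse(tab1$loo, "Yes", "No"))
  utils::write.table(tab1, file.path(outdir, "table1_style.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(study$audit, file.path(outdir, "audit.log"))
  invisible(outdir)
}

#' @export
print.mr_study <- function(x, ...) {
  tiers <- table(factor(x$summary$tier,
                        levels = c("significant", "nominal", "null",
                                   "not_evaluable")))
  cat(sprintf("MR study: %d exposure-outcome pairs\n", nrow(x$summary)))
  cat(paste(sprintf("  %s: %d", names(tiers), tiers), collapse = "\n"), "\n")
  hits <- x$summary[x$summary$tier == "significant", , drop = FALSE]
  if (nrow(hits)) {
    cat("Significant pairs:\n")
    print.data.frame(hits[, c("exposure", "outcome", "beta", "se", "ivw_p")],
                     row.names = FALSE)
  }
  invisible(x)
}
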
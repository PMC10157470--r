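# Sensitivity battery: Cochran's Q, Egger intercept, MR-PRESSO,
# leave-one-out, funnel data.

#' Cochran's Q heterogeneity test
#'
#' Weighted sum of squared deviations of the per-SNP Wald ratios from the
#' fixed-effects IVW estimate, with weights `beta_x^2 / se_y^2`; equal (by
#' algebra) to the weighted residual sum of squares of the origin-forced
#' regression at the fixed-effects solution. Compared to chi-square on
#' `J - 1` degrees of freedom.
#'
#' @param data A [harmonized_set()] with at least two SNPs.
#' @return List `q_stat`, `q_df`, `q_pvalue`.
#' @export
cochran_q <- function(data) {
  data <- .as_hset(data)
  j <- nrow(data)
  if (j < 2L) stopf("Cochran's Q needs at least 2 instruments, got %d", j)
  core <- .ivw_core(data$beta_x, data$beta_y, data$se_y)
  list(q_stat = core$q, q_df = core$df,
       q_pvalue = stats::pchisq(core$q, df = core$df, lower.tail = FALSE))
}

#' MR-Egger intercept test for horizontal pleiotropy
#'
#' The intercept of the MR-Egger regression estimates the average
#' directional pleiotropic effect of the instruments; an intercept
#' distinguishable from zero (conventionally p < 0.05) flags horizontal
#' pleiotropy. Delegates to [mr_egger()].
#'
#' @param data A [harmonized_set()] with at least three SNPs.
#' @return List `intercept`, `se`, `pvalue`.
#' @export
egger_intercept_test <- function(data) {
  ic <- mr_egger(data)$intercept
  list(intercept = ic$beta, se = ic$se, pvalue = ic$pvalue)
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Simulation-based detection of pleiotropic outlier instruments. The
#' observed global statistic is `RSS = sum_j w_j (beta_yj - b_(-j) *
#' beta_xj)^2` with `w_j = 1 / se_yj^2` and `b_(-j)` the fixed-effects IVW
#' estimate leaving SNP j out. Its null distribution comes from `n_sim`
#' parametric draws: `beta_x* ~ N(beta_x, se_x)` and `beta_y* ~ N(b_(-j) *
#' beta_xj, se_yj)`, re-fitting the leave-one-out estimates per draw. The
#' global p-value is the fraction of simulated RSS at or above the observed
#' one (zero exceedances reported as below `1/n_sim`). Per SNP, the observed
#' residual contribution is compared one-sided to its simulated
#' distribution; Bonferroni correction over J (switchable) and flagging at
#' `outlier_alpha`. When outliers are found, the distortion test compares
#' the outlier-removed IVW estimate with the all-SNP estimate against the
#' distribution obtained by removing equally many SNPs at random.
#'
#' @param data A [harmonized_set()] with at least four SNPs.
#' @param n_sim Null-distribution draws (default 1000; fewer than 100 draws
#'   warn).
#' @param seed Integer seed; fixed seed gives bit-identical output.
#' @param outlier_alpha Flagging threshold on the (corrected) per-SNP
#'   p-value (default 0.05).
#' @param bonferroni Apply Bonferroni correction over J to the per-SNP
#'   p-values before flagging (default `TRUE`).
#' @return List of class `mr_presso`: `global_rss`, `global_pvalue`,
#'   `global_pvalue_floor` (`TRUE` when no simulated RSS reached the
#'   observed one, i.e. p is below `1/n_sim`), `outlier_table`
#'   (`snp_id`, `rss_contribution`, `pvalue`, `pvalue_adj`, `outlier`),
#'   `outliers` (flagged ids), `distortion_pvalue` (`NA` without outliers),
#'   `cleaned` (the harmonized set minus outliers).
#' @export
mr_presso <- function(data, n_sim = 1000, seed = NULL, outlier_alpha = 0.05,
                      bonferroni = TRUE) {
  data <- .as_hset(data)
  j <- nrow(data)
  if (j < 4L) stopf("MR-PRESSO needs at least 4 instruments, got %d", j)
  if (n_sim < 100) warnf("n_sim = %d is small; p-value resolution is 1/%d",
                         n_sim, n_sim)
  bx <- data$beta_x; by <- data$beta_y
  sx <- data$se_x; sy <- data$se_y
  w <- 1 / sy^2
  sxy <- sum(w * bx * by); sxx <- sum(w * bx^2)
  b_loo <- (sxy - w * bx * by) / (sxx - w * bx^2)
  res_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(res_obs)

  sims <- with_seed(seed, {
    bxs <- matrix(stats::rnorm(n_sim * j, rep(bx, each = n_sim),
                               rep(sx, each = n_sim)), n_sim, j)
    bys <- matrix(stats::rnorm(n_sim * j, rep(b_loo * bx, each = n_sim),
                               rep(sy, each = n_sim)), n_sim, j)
    m_xy <- sweep(bxs * bys, 2L, w, `*`)
    m_xx <- sweep(bxs * bxs, 2L, w, `*`)
    b_loo_s <- (rowSums(m_xy) - m_xy) / (rowSums(m_xx) - m_xx)
    res_s <- sweep((bys - b_loo_s * bxs)^2, 2L, w, `*`)
    list(res = res_s, rss = rowSums(res_s))
  })

  exceed <- sum(sims$rss >= rss_obs)
  global_p <- exceed / n_sim
  p_snp <- colMeans(sweep(sims$res, 2L, res_obs, `>=`))
  p_adj <- if (bonferroni) pmin(1, p_snp * j) else p_snp
  is_out <- p_adj < outlier_alpha
  outliers <- data$snp_id[is_out]

  distortion_p <- NA_real_
  cleaned <- data
  if (any(is_out)) {
    keep <- !is_out
    cleaned <- hset_subset(data, keep)
    attr(cleaned, "dropped") <- rbind(
      dropped_snps(data),
      data.frame(snp_id = outliers, reason = "mr-presso outlier",
                 stringsAsFactors = FALSE))
    if (sum(keep) >= 2L) {
      b_all <- .ivw_core(bx, by, sy)$beta
      b_clean <- .ivw_core(bx[keep], by[keep], sy[keep])$beta
      d_obs <- (b_clean - b_all) / abs(b_all)
      n_out <- sum(is_out)
      d_sim <- with_seed(if (is.null(seed)) NULL else seed + 1L, {
        vapply(seq_len(n_sim), function(i) {
          drop <- sample.int(j, n_out)
          (.ivw_core(bx[-drop], by[-drop], sy[-drop])$beta - b_all) / abs(b_all)
        }, numeric(1))
      })
      distortion_p <- mean(abs(d_sim) >= abs(d_obs))
    }
  }

  structure(list(global_rss = rss_obs,
                 global_pvalue = if (exceed == 0) 1 / n_sim else global_p,
                 global_pvalue_floor = exceed == 0,
                 n_sim = n_sim,
                 outlier_table = data.frame(snp_id = data$snp_id,
                                            rss_contribution = res_obs,
                                            pvalue = p_snp,
                                            pvalue_adj = p_adj,
                                            outlier = is_out,
                                            stringsAsFactors = FALSE),
                 outliers = outliers,
                 distortion_pvalue = distortion_p,
                 cleaned = cleaned),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  gp <- if (x$global_pvalue_floor) sprintf("< %g", 1 / x$n_sim)
        else sprintf("= %.3g", x$global_pvalue)
  cat(sprintf("MR-PRESSO: global RSS p %s; %d outlier(s)%s\n", gp,
              length(x$outliers),
              if (length(x$outliers)) paste0(" [",
                paste(x$outliers, collapse = ", "), "]") else ""))
  if (!is.na(x$distortion_pvalue)) {
    cat(sprintf("Distortion test p = %.3g\n", x$distortion_pvalue))
  }
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the multiplicative random-effects IVW estimator on every subset
#' leaving one SNP out. The analysis passes when every leave-one-out
#' p-value stays below `significance_threshold` and every leave-one-out
#' estimate keeps the sign of the full-set estimate, i.e. no single SNP
#' drives the result.
#'
#' @param data A [harmonized_set()] with at least three SNPs.
#' @param significance_threshold Per-refit significance requirement
#'   (default 0.05).
#' @return List: `loo_results` (`data.frame` with one row per left-out SNP:
#'   `snp_id`, `beta`, `se`, `pvalue`), `loo_pass`, `full` (full-set IVW
#'   `mr_estimate`).
#' @export
leave_one_out <- function(data, significance_threshold = 0.05) {
  data <- .as_hset(data)
  j <- nrow(data)
  if (j < 3L) stopf("leave-one-out needs at least 3 instruments, got %d", j)
  full <- mr_ivw(data, "multiplicative_random")
  rows <- lapply(seq_len(j), function(i) {
    e <- mr_ivw(hset_subset(data, -i), "multiplicative_random")
    data.frame(snp_id = data$snp_id[i], beta = e$beta, se = e$se,
               pvalue = e$pvalue, stringsAsFactors = FALSE)
  })
  loo <- do.call(rbind, rows)
  pass <- all(loo$pvalue < significance_threshold) &&
    all(sign(loo$beta) == sign(full$beta))
  list(loo_results = loo, loo_pass = pass, full = full)
}

#' Per-SNP funnel-plot data
#'
#' Wald ratio `beta_y / beta_x` against its precision `|beta_x| / se_y`
#' (the reciprocal of the first-order ratio SE). Asymmetry of the funnel
#' around the pooled estimate indicates directional pleiotropy.
#'
#' @param data A [harmonized_set()]; all `beta_x` must be nonzero.
#' @return `data.frame(snp_id, ratio, precision)`.
#' @export
funnel_data <- function(data) {
  data <- .as_hset(data)
  zero <- data$beta_x == 0
  if (any(zero)) stopf("zero exposure effect for %s: Wald ratio undefined",
                       paste(data$snp_id[zero], collapse = ", "))
  data.frame(snp_id = data$snp_id,
             ratio = data$beta_y / data$beta_x,
             precision = abs(data$beta_x) / data$se_y,
             stringsAsFactors = FALSE)
}

#' Funnel plot of per-SNP causal ratios
#'
#' @param data A [harmonized_set()].
#' @param ... Passed to [graphics::plot()].
#' @export
funnel_plot <- function(data, ...) {
  fd <- funnel_data(data)
  graphics::plot(fd$ratio, fd$precision, pch = 19,
                 xlab = "Wald ratio", ylab = "Precision (|beta_x| / se_y)", ...)
  graphics::abline(v = mr_ivw(data, "fixed")$beta, col = "firebrick", lty = 2)
  invisible(fd)
}

#' Full sensitivity battery for one exposure-outcome pair
#'
#' Runs Cochran's Q, the MR-Egger intercept test, MR-PRESSO (when at least
#' four instruments are available), leave-one-out, and funnel data, and
#' gathers them into one report. When `q_pvalue < heterogeneity_alpha`,
#' heterogeneity is present and only the multiplicative random-effects IVW
#' should be read as primary (`use_mre_only` records this).
#'
#' @param data A [harmonized_set()] with at least three SNPs.
#' @param n_sim,seed,outlier_alpha Passed to [mr_presso()].
#' @param loo_threshold Passed to [leave_one_out()].
#' @param heterogeneity_alpha Threshold on the Q p-value (default 0.05).
#' @param presso Run MR-PRESSO (default `TRUE`; requires `J >= 4`).
#' @return Object of class `mr_sensitivity` with components `q`,
#'   `egger_intercept`, `presso` (or `NULL`), `loo`, `funnel`,
#'   `use_mre_only`, `n_snps`.
#' @export
mr_sensitivity <- function(data, n_sim = 1000, seed = NULL,
                           outlier_alpha = 0.05, loo_threshold = 0.05,
                           heterogeneity_alpha = 0.05, presso = TRUE) {
  data <- .as_hset(data)
  j <- nrow(data)
  if (j < 3L) stopf("sensitivity battery needs at least 3 instruments, got %d", j)
  q <- cochran_q(data)
  structure(list(
    q = q,
    egger_intercept = egger_intercept_test(data),
    presso = if (presso && j >= 4L) mr_presso(data, n_sim = n_sim, seed = seed,
                                              outlier_alpha = outlier_alpha)
             else NULL,
    loo = leave_one_out(data, loo_threshold),
    funnel = funnel_data(data),
    use_mre_only = q$q_pvalue < heterogeneity_alpha,
    n_snps = j), class = "mr_sensitivity")
}

#' @export
print.mr_sensitivity <- function(x, ...) {
  cat(sprintf("Sensitivity report (%d instruments)\n", x$n_snps))
  cat(sprintf("  Cochran's Q: %.3f on %d df, p = %.3g%s\n", x$q$q_stat,
              x$q$q_df, x$q$q_pvalue,
              if (x$use_mre_only) " [heterogeneity: report mRE IVW only]" else ""))
  cat(sprintf("  Egger intercept: %.4g (se %.4g), p = %.3g\n",
              x$egger_intercept$intercept, x$egger_intercept$se,
              x$egger_intercept$pvalue))
  if (!is.null(x$presso)) print(x$presso)
  cat(sprintf("  Leave-one-out: %s\n", if (x$loo$loo_pass) "pass" else "FAIL"))
  invisible(x)
}
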
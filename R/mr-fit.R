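# Causal estimators for two-sample MR: IVW (fixed / multiplicative
# random-effects), weighted median, MR-Egger. All consume a harmonized_set.

.as_hset <- function(data) {
  if (!inherits(data, "harmonized_set")) {
    stopf("'data' must be a harmonized_set (see harmonize())")
  }
  data
}

mr_estimate <- function(method, beta, se, pvalue, n_snps) {
  structure(list(method = method, beta = beta, se = se, pvalue = pvalue,
                 n_snps = n_snps,
                 ci_low = beta - stats::qnorm(0.975) * se,
                 ci_high = beta + stats::qnorm(0.975) * se),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta = %.4g (se %.4g), 95%% CI [%.4g, %.4g], p = %.3g, J = %d\n",
              x$method, x$beta, x$se, x$ci_low, x$ci_high, x$pvalue, x$n_snps))
  invisible(x)
}

# weighted regression of by on bx through the origin, w = 1/sy^2,
# plus Cochran's Q at the fixed-effects solution
.ivw_core <- function(bx, by, sy) {
  w <- 1 / sy^2
  sxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sxx
  se_fixed <- sqrt(1 / sxx)
  q <- sum(w * (by - beta * bx)^2)
  df <- length(bx) - 1L
  phi <- if (df > 0) q / df else NA_real_
  list(beta = beta, se_fixed = se_fixed, q = q, df = df,
       se_mre = se_fixed * sqrt(max(1, phi)))
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted regression of the SNP-outcome effects on the SNP-exposure
#' effects through the origin with weights `1 / se_y^2` — algebraically the
#' inverse-variance-weighted mean of the per-SNP Wald ratios. In
#' `"multiplicative_random"` mode (the primary estimator) the fixed-effects
#' standard error is inflated by `sqrt(max(1, Q / (J - 1)))`, so the
#' estimate is unchanged but its uncertainty absorbs any heterogeneity; the
#' floor at 1 keeps it no smaller than the fixed-effects SE. A single
#' instrument returns the Wald ratio `beta_y / beta_x` with first-order
#' delta-method SE `se_y / |beta_x|`, labelled `ivw_fixed`.
#'
#' @param data A [harmonized_set()] with at least one SNP.
#' @param mode `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_estimate`: `method`, `beta`, `se`, `pvalue` (two-sided
#'   normal), `n_snps`, `ci_low`, `ci_high`.
#' @export
mr_ivw <- function(data, mode = c("multiplicative_random", "fixed")) {
  data <- .as_hset(data)
  mode <- match.arg(mode)
  j <- nrow(data)
  if (j == 0L) stopf("empty harmonized set")
  if (j == 1L) {
    beta <- data$beta_y / data$beta_x
    se <- data$se_y / abs(data$beta_x)
    return(mr_estimate("ivw_fixed", beta, se, z_pvalue(beta / se), 1L))
  }
  core <- .ivw_core(data$beta_x, data$beta_y, data$se_y)
  if (mode == "fixed") {
    mr_estimate("ivw_fixed", core$beta, core$se_fixed,
                z_pvalue(core$beta / core$se_fixed), j)
  } else {
    mr_estimate("ivw_mre", core$beta, core$se_mre,
                z_pvalue(core$beta / core$se_mre), j)
  }
}

# point estimate only; shared by the estimator and its bootstrap
.weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= s[1L]) return(r[1L])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The weighted median of the per-SNP Wald ratios `beta_y / beta_x` with
#' weights `beta_x^2 / se_y^2` (the inverse variance of the first-order
#' ratio). Standardized cumulative weights use the midpoint convention
#' `s_j = (sum_{i<=j} w_i - w_j / 2) / sum(w)` with linear interpolation at
#' `s = 0.5`; outside `[s_1, s_J]` the extreme ratio is returned. The
#' estimator is consistent when instruments carrying at least half the
#' weight are valid. The standard error comes from a parametric bootstrap:
#' `n_boot` resamples of each `(beta_x, beta_y)` from normal distributions
#' with the observed standard errors.
#'
#' @param data A [harmonized_set()] with at least three SNPs and no zero
#'   `beta_x`.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap; `NULL` uses the current RNG
#'   stream.
#' @return An `mr_estimate` with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed = NULL) {
  data <- .as_hset(data)
  j <- nrow(data)
  if (j < 3L) stopf("weighted median needs at least 3 instruments, got %d", j)
  zero <- data$beta_x == 0
  if (any(zero)) stopf("zero exposure effect for %s: Wald ratio undefined",
                       paste(data$snp_id[zero], collapse = ", "))
  r <- data$beta_y / data$beta_x
  w <- data$beta_x^2 / data$se_y^2
  beta <- .weighted_median_point(r, w)
  boot <- with_seed(seed, {
    bx <- matrix(stats::rnorm(n_boot * j, mean = rep(data$beta_x, each = n_boot),
                              sd = rep(data$se_x, each = n_boot)), n_boot, j)
    by <- matrix(stats::rnorm(n_boot * j, mean = rep(data$beta_y, each = n_boot),
                              sd = rep(data$se_y, each = n_boot)), n_boot, j)
    vapply(seq_len(n_boot), function(i) {
      bxi <- bx[i, ]
      bxi[bxi == 0] <- .Machine$double.eps  # measure-zero guard
      .weighted_median_point(by[i, ] / bxi, bxi^2 / data$se_y^2)
    }, numeric(1))
  })
  se <- stats::sd(boot)
  pval <- if (se > 0) z_pvalue(beta / se) else as.numeric(beta == 0)
  est <- mr_estimate("weighted_median", beta, se, pval, j)
  est
}

#' MR-Egger regression
#'
#' Weighted least squares of the SNP-outcome effects on the SNP-exposure
#' effects with an unconstrained intercept, weights `1 / se_y^2`, after
#' orienting every SNP so that `beta_x >= 0` (both effects negated where
#' needed; estimates are invariant to per-SNP sign flips). The slope is the
#' causal estimate under the InSIDE assumption; the intercept estimates the
#' average directional pleiotropy. Standard errors carry a multiplicative
#' overdispersion factor `sqrt(max(1, RSS_w / (J - 2)))`; p-values use the t
#' distribution with `J - 2` degrees of freedom.
#'
#' @param data A [harmonized_set()] with at least three SNPs.
#' @return List with `slope` and `intercept`, each an `mr_estimate`
#'   (methods `"egger_slope"`, `"egger_intercept"`).
#' @export
mr_egger <- function(data) {
  data <- .as_hset(data)
  j <- nrow(data)
  if (j < 3L) stopf("MR-Egger needs at least 3 instruments, got %d", j)
  s <- sign(data$beta_x)
  s[s == 0] <- 1
  bx <- data$beta_x * s
  by <- data$beta_y * s
  w <- 1 / data$se_y^2
  X <- cbind(intercept = 1, slope = bx)
  fit <- stats::lm.wfit(X, by, w)
  coefs <- fit$coefficients
  rss_w <- sum(w * fit$residuals^2)
  disp <- max(1, rss_w / (j - 2))
  xtx_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
  ses <- sqrt(diag(xtx_inv) * disp)
  pvals <- 2 * stats::pt(-abs(coefs / ses), df = j - 2)
  make <- function(tag, i) {
    est <- mr_estimate(tag, coefs[[i]], ses[[i]], pvals[[i]], j)
    tq <- stats::qt(0.975, df = j - 2)
    est$ci_low <- coefs[[i]] - tq * ses[[i]]
    est$ci_high <- coefs[[i]] + tq * ses[[i]]
    est
  }
  list(slope = make("egger_slope", 2L), intercept = make("egger_intercept", 1L))
}

#' Fit the two-sample MR estimator battery
#'
#' The package's central fitting function. From one harmonized
#' exposure-outcome set it computes the multiplicative random-effects IVW
#' estimate (primary), the fixed-effects IVW, the weighted median and the
#' MR-Egger slope and intercept (the latter two require at least three
#' instruments), together with Cochran's Q. With a single instrument only
#' the Wald ratio is available.
#'
#' @param data A [harmonized_set()].
#' @param n_boot Bootstrap resamples for the weighted-median SE.
#' @param seed Seed for the bootstrap.
#' @return Object of class `mr_fit` with components `estimates` (a
#'   `data.frame`, one row per method), `q` (list `q_stat`, `q_df`,
#'   `q_pvalue`), `data`, `n_snps`, `pair_label`. Methods: `print`,
#'   `summary`, `coef`, `confint`, `residuals`, `plot`.
#' @export
#' @examples
#' set.seed(1)
#' bx <- rnorm(10, 0.1, 0.02)
#' by <- 0.2 * bx + rnorm(10, 0, 0.01)
#' d <- harmonized_set(bx, rep(0.005, 10), by, rep(0.01, 10))
#' fit <- mr_fit(d, seed = 1)
#' coef(fit)
mr_fit <- function(data, n_boot = 1000, seed = NULL) {
  data <- .as_hset(data)
  j <- nrow(data)
  ests <- list(mr_ivw(data, "multiplicative_random"))
  if (j >= 2L) ests <- c(ests, list(mr_ivw(data, "fixed")))
  if (j >= 3L) {
    eg <- mr_egger(data)
    ests <- c(ests, list(mr_weighted_median(data, n_boot = n_boot, seed = seed),
                         eg$slope, eg$intercept))
  }
  tab <- do.call(rbind, lapply(ests, function(e) {
    data.frame(method = e$method, beta = e$beta, se = e$se, pvalue = e$pvalue,
               n_snps = e$n_snps, ci_low = e$ci_low, ci_high = e$ci_high,
               stringsAsFactors = FALSE)
  }))
  q <- if (j >= 2L) cochran_q(data) else list(q_stat = NA_real_, q_df = NA_integer_,
                                              q_pvalue = NA_real_)
  structure(list(estimates = tab, q = q, data = data, n_snps = j,
                 pair_label = attr(data, "pair_label")),
            class = "mr_fit")
}

.fit_row <- function(fit, method) {
  i <- match(method, fit$estimates$method)
  if (is.na(i)) NULL else fit$estimates[i, ]
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  lab <- x$pair_label
  cat(sprintf("Two-sample MR fit%s: %d instruments\n",
              if (!is.null(lab) && nzchar(lab)) paste0(" [", lab, "]") else "",
              x$n_snps))
  prim <- .fit_row(x, "ivw_mre") %||% .fit_row(x, "ivw_fixed")
  cat(sprintf("Primary (%s): beta = %s, se = %s, p = %s\n", prim$method,
              signif(prim$beta, digits), signif(prim$se, digits),
              signif(prim$pvalue, 3)))
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  fit <- x$fit
  print(fit)
  tab <- fit$estimates
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print.data.frame(tab, row.names = FALSE)
  if (!is.na(fit$q$q_stat)) {
    cat(sprintf("Cochran's Q = %.3f on %d df, p = %.3g\n",
                fit$q$q_stat, fit$q$q_df, fit$q$q_pvalue))
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$estimates$beta, object$estimates$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  tab <- object$estimates
  if (!missing(parm)) tab <- tab[tab$method %in% parm, , drop = FALSE]
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(tab$beta - z * tab$se, tab$beta + z * tab$se)
  dimnames(out) <- list(tab$method,
                        paste0(format(100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2)), " %"))
  out
}

#' @export
residuals.mr_fit <- function(object, ...) {
  prim <- .fit_row(object, "ivw_mre") %||% .fit_row(object, "ivw_fixed")
  d <- object$data
  stats::setNames((d$beta_y - prim$beta * d$beta_x) / d$se_y, d$snp_id)
}

#' Scatter plot of a two-sample MR fit
#'
#' SNP-outcome against SNP-exposure effects with +/- 1 SE error bars and
#' the fitted IVW (through the origin) and MR-Egger (free intercept) lines.
#'
#' @param x An [mr_fit()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$beta_x, d$beta_y,
                 xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome",
                 pch = 19, ...)
  graphics::segments(d$beta_x, d$beta_y - d$se_y, d$beta_x, d$beta_y + d$se_y,
                     col = "grey60")
  graphics::segments(d$beta_x - d$se_x, d$beta_y, d$beta_x + d$se_x, d$beta_y,
                     col = "grey60")
  ivw <- .fit_row(x, "ivw_mre") %||% .fit_row(x, "ivw_fixed")
  graphics::abline(0, ivw$beta, col = "firebrick", lwd = 2)
  eg <- .fit_row(x, "egger_slope")
  if (!is.null(eg)) {
    graphics::abline(.fit_row(x, "egger_intercept")$beta, eg$beta,
                     col = "steelblue", lwd = 2, lty = 2)
    graphics::legend("topleft", legend = c("IVW", "MR-Egger"), lwd = 2,
                     lty = c(1, 2), col = c("firebrick", "steelblue"),
                     bty = "n")
  }
  invisible(x)
}
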
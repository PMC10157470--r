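test_that("IVW recovers proportional data exactly, with no heterogeneity inflation", {
  d <- harmonized_set(beta_x = c(0.1, 0.2, 0.3), se_x = rep(0.01, 3),
                      beta_y = c(0.02, 0.04, 0.06), se_y = rep(0.01, 3))
  mre <- mr_ivw(d, "multiplicative_random")
  fix <- mr_ivw(d, "fixed")
  expect_equal(mre$beta, 0.2, tolerance = 1e-14)
  expect_equal(fix$beta, 0.2, tolerance = 1e-14)
  expect_equal(mre$se, fix$se)  # Q = 0 so the overdispersion floor binds
  q <- cochran_q(d)
  expect_equal(q$q_stat, 0, tolerance = 1e-20)
  expect_equal(q$q_pvalue, 1)
})

test_that("a single instrument returns the Wald ratio with delta-method SE", {
  d <- harmonized_set(0.1, 0.005, 0.05, 0.01)
  est <- mr_ivw(d)
  expect_equal(est$method, "ivw_fixed")
  expect_equal(est$beta, 0.5, tolerance = 1e-14)
  expect_equal(est$se, 0.1, tolerance = 1e-14)
})

test_that("IVW and Egger match independent weighted-least-squares oracles", {
  set.seed(42)
  for (rep in 1:50) {
    d <- random_hset(10)
    w <- 1 / d$se_y^2
    # IVW oracle: weighted regression through the origin via lm
    o <- lm(beta_y ~ 0 + beta_x, data = d, weights = w)
    fix <- mr_ivw(d, "fixed")
    expect_equal(fix$beta, unname(coef(o)), tolerance = 1e-10)
    se_unscaled <- sqrt(vcov(o)[1, 1]) / summary(o)$sigma
    expect_equal(fix$se, se_unscaled, tolerance = 1e-10)
    # multiplicative random effects: same estimate, floored SE inflation
    mre <- mr_ivw(d, "multiplicative_random")
    q <- cochran_q(d)
    expect_equal(mre$beta, fix$beta)
    expect_equal(mre$se, fix$se * sqrt(max(1, q$q_stat / q$q_df)),
                 tolerance = 1e-12)
    expect_gte(mre$se, fix$se)
    # Egger oracle: explicit normal equations with an intercept
    s <- sign(d$beta_x); s[s == 0] <- 1
    X <- cbind(1, d$beta_x * s)
    yv <- d$beta_y * s
    W <- diag(w)
    ab <- solve(t(X) %*% W %*% X, t(X) %*% W %*% yv)
    eg <- mr_egger(d)
    expect_equal(eg$intercept$beta, ab[1, 1], tolerance = 1e-10)
    expect_equal(eg$slope$beta, ab[2, 1], tolerance = 1e-10)
    rss <- sum(w * (yv - X %*% ab)^2)
    v <- solve(t(X) %*% W %*% X) * max(1, rss / (nrow(d) - 2))
    expect_equal(eg$intercept$se, sqrt(v[1, 1]), tolerance = 1e-10)
    expect_equal(eg$slope$se, sqrt(v[2, 2]), tolerance = 1e-10)
  }
})

test_that("fixed-effects IVW equals the inverse-variance-weighted mean of Wald ratios", {
  set.seed(9)
  for (rep in 1:20) {
    d <- random_hset(12)
    r <- d$beta_y / d$beta_x
    w <- d$beta_x^2 / d$se_y^2
    expect_equal(mr_ivw(d, "fixed")$beta, sum(w * r) / sum(w),
                 tolerance = 1e-12)
  }
})

test_that("weighted median reduces to the sample median for equal weights and odd J", {
  d <- harmonized_set(beta_x = rep(0.1, 3), se_x = rep(0.01, 3),
                      beta_y = c(0.01, 0.02, 0.03), se_y = rep(0.01, 3))
  est <- mr_weighted_median(d, n_boot = 50, seed = 1)
  expect_equal(est$beta, 0.2, tolerance = 1e-12)
  set.seed(2)
  for (rep in 1:10) {
    j <- sample(c(5, 7, 9), 1)
    d <- harmonized_set(rep(0.2, j), rep(0.01, j),
                        0.2 * runif(j, -1, 1), rep(0.02, j))
    est <- mr_weighted_median(d, n_boot = 10, seed = rep)
    expect_equal(est$beta, median(d$beta_y / d$beta_x), tolerance = 1e-12)
  }
})

test_that("weighted median is exact and its bootstrap SE vanishes in the degenerate limit", {
  j <- 5
  d <- harmonized_set(runif(j, 0.1, 0.3), rep(1e-8, j), beta_y = NA,
                      se_y = rep(1e-8, j))
  d$beta_y <- 0.2 * d$beta_x
  est <- mr_weighted_median(d, n_boot = 200, seed = 3)
  expect_equal(est$beta, 0.2, tolerance = 1e-6)
  expect_lt(est$se, 1e-5)
})

test_that("weighted median tolerates a large invalid minority", {
  # 6 valid instruments (ratio ~ 0.2) vs 5 invalid (ratio ~ 1.0), with the
  # valid block carrying > 50% of the weight
  bx <- c(rep(0.2, 6), rep(0.1, 5))
  by <- c(0.2 * bx[1:6], 1.0 * bx[7:11])
  d <- harmonized_set(bx, rep(0.005, 11), by, rep(0.01, 11))
  est <- mr_weighted_median(d, n_boot = 500, seed = 4)
  expect_lt(abs(est$beta - 0.2), 2 * est$se + 1e-8)
  expect_lt(abs(est$beta - 0.2), 0.05)
})

test_that("Egger recovers slope and intercept from pleiotropic data and ignores SNP orientation", {
  set.seed(5)
  j <- 30
  bx <- runif(j, 0.05, 0.3)
  by <- 0.01 + 0.2 * bx + rnorm(j, 0, 1e-4)
  d <- harmonized_set(bx, rep(0.005, j), by, rep(0.01, j))
  eg <- mr_egger(d)
  expect_equal(eg$slope$beta, 0.2, tolerance = 5e-3)
  expect_lt(abs(eg$intercept$beta - 0.01), 4 * eg$intercept$se + 1e-4)
  # flipping the reported allele of any subset of SNPs changes nothing
  flip <- sample(j, 10)
  bx2 <- bx; by2 <- by
  bx2[flip] <- -bx2[flip]; by2[flip] <- -by2[flip]
  d2 <- harmonized_set(bx2, rep(0.005, j), by2, rep(0.01, j))
  eg2 <- mr_egger(d2)
  expect_equal(eg2$slope$beta, eg$slope$beta, tolerance = 1e-12)
  expect_equal(eg2$intercept$beta, eg$intercept$beta, tolerance = 1e-12)
  # proportional data: line through the origin
  d3 <- harmonized_set(c(0.1, 0.2, 0.3), rep(0.01, 3),
                       c(0.02, 0.04, 0.06), rep(0.01, 3))
  eg3 <- mr_egger(d3)
  expect_equal(eg3$slope$beta, 0.2, tolerance = 1e-10)
  expect_equal(eg3$intercept$beta, 0, tolerance = 1e-12)
})

test_that("estimators are invariant to SNP relabeling and reordering", {
  set.seed(6)
  d <- random_hset(15)
  perm <- sample(15)
  d2 <- harmonized_set(d$beta_x[perm], d$se_x[perm], d$beta_y[perm],
                       d$se_y[perm], snp_id = paste0("x", 1:15))
  expect_equal(mr_ivw(d2)$beta, mr_ivw(d)$beta, tolerance = 1e-14)
  expect_equal(mr_egger(d2)$slope$beta, mr_egger(d)$slope$beta,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(d2, n_boot = 10, seed = 1)$beta,
               mr_weighted_median(d, n_boot = 10, seed = 1)$beta,
               tolerance = 1e-12)
})

test_that("mr_fit assembles the estimator battery with working methods", {
  d <- sim_hset(sim_config(n_snps = 20, theta = 0.2, seed = 8))
  fit <- mr_fit(d, n_boot = 100, seed = 1)
  expect_s3_class(fit, "mr_fit")
  expect_setequal(fit$estimates$method,
                  c("ivw_mre", "ivw_fixed", "weighted_median", "egger_slope",
                    "egger_intercept"))
  expect_true(all(fit$estimates$ci_low <= fit$estimates$beta &
                    fit$estimates$beta <= fit$estimates$ci_high))
  expect_named(coef(fit))
  ci <- confint(fit, parm = "ivw_mre")
  expect_equal(dim(ci), c(1, 2))
  expect_length(residuals(fit), 20)
  expect_output(print(summary(fit)), "Cochran")
  # degenerate-ratio guard
  d$beta_x[1] <- 0
  expect_error(mr_weighted_median(d, n_boot = 10, seed = 1),
               "Wald ratio undefined")
})
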
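test_that("p-value filtering keeps strictly significant records in order", {
  rec <- make_records(3, pvalue = c(1e-9, 4e-8, 6e-8))
  expect_equal(filter_by_pvalue(rec, 5e-8)$snp_id, c("rs1", "rs2"))
  # relaxed threshold used for sparsely instrumented exposures
  expect_equal(nrow(filter_by_pvalue(rec, 5e-6)), 3)
  expect_warning(out <- filter_by_pvalue(rec, 1e-20), "no records")
  expect_equal(nrow(out), 0)
})

test_that("greedy clumping keeps the most significant SNP per LD region", {
  rec <- make_records(3, snp_id = c("A", "B", "C"),
                      pos = c(1e6, 1.05e6, 1.08e6),
                      pvalue = c(1e-10, 1e-9, 1e-8))
  ld <- data.frame(snp_a = c("A", "A"), snp_b = c("B", "C"),
                   r2 = c(0.5, 0.0001))
  kept <- ld_clump(rec, ld, clump_r2 = 0.001, clump_kb = 10000)
  expect_setequal(kept$snp_id, c("A", "C"))
  # different chromosomes are never clumped, whatever the r2 entry says
  rec2 <- make_records(2, snp_id = c("A", "B"), chrom = c("1", "2"),
                       pvalue = c(1e-10, 1e-9))
  ld2 <- data.frame(snp_a = "A", snp_b = "B", r2 = 0.99)
  expect_equal(nrow(ld_clump(rec2, ld2)), 2)
  expect_error(ld_clump(rec, data.frame(snp_a = "A", snp_b = "B", r2 = 1.2)),
               "\\[0, 1\\]")
})

test_that("clumping satisfies the independence and attribution properties on block-structured LD", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 20
    rec <- make_records(n, snp_id = sprintf("rs%02d", sample(n)),
                        chrom = as.character(rep(1:2, each = 10)),
                        pos = rep(sort(sample(1e6:6e6, 10)), 2),
                        pvalue = 10^-runif(n, 5, 20))
    pairs <- t(combn(rec$snp_id, 2))
    same_chr <- rec$chrom[match(pairs[, 1], rec$snp_id)] ==
      rec$chrom[match(pairs[, 2], rec$snp_id)]
    ld <- data.frame(snp_a = pairs[same_chr, 1], snp_b = pairs[same_chr, 2],
                     r2 = sample(c(0, 0.3), sum(same_chr), replace = TRUE,
                                 prob = c(0.5, 0.5)))
    kept <- ld_clump(rec, ld, clump_r2 = 0.001, clump_kb = 10000)
    r2_of <- function(a, b) {
      hit <- (ld$snp_a == a & ld$snp_b == b) | (ld$snp_a == b & ld$snp_b == a)
      if (any(hit)) ld$r2[which(hit)[1]] else 0
    }
    conflict <- function(a, b) {
      ra <- rec[rec$snp_id == a, ]; rb <- rec[rec$snp_id == b, ]
      ra$chrom == rb$chrom && abs(ra$pos - rb$pos) <= 1e7 &&
        r2_of(a, b) >= 0.001
    }
    # no retained pair violates the independence rule
    if (nrow(kept) > 1) {
      for (i in 1:(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
        expect_false(conflict(kept$snp_id[i], kept$snp_id[j]))
      }
    }
    # every removed SNP is attributable to a retained index with smaller p
    removed <- setdiff(rec$snp_id, kept$snp_id)
    for (snp in removed) {
      p_snp <- rec$pvalue[rec$snp_id == snp]
      culprits <- kept$snp_id[vapply(kept$snp_id, conflict, logical(1), b = snp)]
      expect_true(any(rec$pvalue[match(culprits, rec$snp_id)] <= p_snp))
    }
    # input order never matters
    shuffled <- rec[sample(nrow(rec)), ]
    expect_equal(ld_clump(shuffled, ld)$snp_id, kept$snp_id)
  }
})

test_that("instrument strength matches the two printed formulas", {
  # frequency-based formula
  st <- compute_strength(make_records(1, eaf = 0.5, beta = 0.1, nn = 10000), k = 1)
  expect_equal(st$r2, 0.005, tolerance = 1e-12)
  expect_equal(st$f_stat, (0.005 / 0.995) * 9998, tolerance = 1e-12)
  expect_equal(st$formula_used, "maf_formula")
  # standard-error fallback when the frequency is missing
  st <- compute_strength(make_records(1, eaf = NA, beta = 0.1, se = 0.01,
                                      nn = 1000), k = 1)
  expect_equal(st$r2, 0.01 / (0.01 + 0.0001 * 1000), tolerance = 1e-12)
  expect_equal(st$f_stat, (st$r2 / (1 - st$r2)) * 998, tolerance = 1e-10)
  expect_equal(st$formula_used, "se_formula")
  # zero effect explains nothing
  st <- compute_strength(make_records(1, eaf = 0.3, beta = 0), k = 1)
  expect_equal(st$r2, 0)
  expect_equal(st$f_stat, 0)
  # MAF is the minor-allele frequency whichever allele is modelled
  hi <- compute_strength(make_records(1, eaf = 0.8, beta = 0.1), k = 1)
  lo <- compute_strength(make_records(1, eaf = 0.2, beta = 0.1), k = 1)
  expect_equal(hi$r2, lo$r2)
  expect_error(compute_strength(make_records(1, nn = 2), k = 1),
               "sample size")
})

test_that("F increases with |beta| under both formulas", {
  betas <- seq(0.05, 0.5, by = 0.05)
  f_maf <- compute_strength(make_records(length(betas), beta = betas,
                                         eaf = 0.3), k = 1)$f_stat
  f_se <- compute_strength(make_records(length(betas), beta = betas,
                                        eaf = NA, se = 0.01), k = 1)$f_stat
  expect_true(all(diff(f_maf) > 0))
  expect_true(all(diff(f_se) > 0))
})

test_that("confounder exclusions remove listed SNPs and log absentees", {
  rec <- make_records(4, snp_id = c("rs6062496", "rs4276914", "rs10", "rs11"))
  excl <- data.frame(snp_id = c("rs6062496", "rs4276914", "rs999"),
                     reason = c("second phenotype: obesity",
                                "second phenotype: smoking",
                                "second phenotype: hypertension"))
  out <- apply_exclusions(rec, excl)
  expect_setequal(out$kept$snp_id, c("rs10", "rs11"))
  expect_equal(out$removed$reason[out$removed$snp_id == "rs999"],
               "second phenotype: hypertension (not found)")
  # empty list is the identity
  id <- apply_exclusions(rec, NULL)
  expect_equal(id$kept, rec)
  expect_equal(nrow(id$removed), 0)
})

test_that("selection applies stages in order and drops weak instruments", {
  s <- simulate_pair(sim_config(n_snps = 30, seed = 11))
  inst <- select_instruments(s$exposure)
  expect_equal(nrow(inst$instruments), 30)
  expect_equal(unname(inst$audit), c(30L, 30L, 30L, 30L, 30L))
  expect_true(all(inst$strengths$f_stat >= 10))
  expect_true(inst$set_strength$f_stat > 10)

  # plant one weak instrument: small effect, tiny sample
  weakling <- s$exposure
  weakling$beta[5] <- 0.05
  weakling$eaf[5] <- 0.5
  weakling$n[5] <- 30
  weakling$pvalue[5] <- 1e-9  # still passes the significance filter
  inst <- select_instruments(weakling)
  expect_equal(nrow(inst$instruments), 29)
  expect_equal(inst$weak$snp_id, weakling$snp_id[5])
  # recompute the weak F by hand: R2 = 2*0.5*0.5*0.05^2, F = R2/(1-R2)*(n-2)
  r2 <- 2 * 0.25 * 0.05^2
  expect_equal(inst$weak$f_stat, r2 / (1 - r2) * 28, tolerance = 1e-10)

  # exclusions are applied before strength computation
  excl <- data.frame(snp_id = s$exposure$snp_id[1:3], reason = "confounder")
  inst <- select_instruments(s$exposure,
                             config = selection_config(exclusions = excl))
  expect_equal(nrow(inst$instruments), 27)
  expect_equal(inst$set_strength$k, 27)
  # selection output is always a subset of the input
  expect_true(all(inst$instruments$snp_id %in% s$exposure$snp_id))
})

test_that("LD tables read in long and square form agree", {
  ld_long <- data.frame(snp_a = c("rs1", "rs1", "rs2"),
                        snp_b = c("rs2", "rs3", "rs3"),
                        r2 = c(0.5, 0.1, 0.02))
  p1 <- tempfile(fileext = ".tsv")
  utils::write.table(ld_long, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- matrix(c(1, .5, .1, .5, 1, .02, .1, .02, 1), 3,
              dimnames = list(NULL, c("rs1", "rs2", "rs3")))
  sq <- cbind(data.frame(snp = c("rs1", "rs2", "rs3")), as.data.frame(m))
  p2 <- tempfile(fileext = ".tsv")
  utils::write.table(sq, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  a <- read_ld_table(p1)
  b <- read_ld_table(p2)
  key <- function(d) d[order(d$snp_a, d$snp_b), ]
  expect_equal(key(a)$r2, key(b)$r2)
})
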
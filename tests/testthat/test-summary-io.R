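test_that("well-formed files pass through and invalid rows are rejected with reasons", {
  rec <- make_records(3)
  got <- read_summary_stats(write_fixture(rec))
  expect_equal(nrow(got), 3)
  expect_equal(nrow(rejected_rows(got)), 0)
  expect_equal(got$snp_id, rec$snp_id)
  expect_equal(got$beta, rec$beta)

  bad <- make_records(4)
  bad$se[2] <- 0
  bad$effect_allele[3] <- "AT"  # indel-like, out of scope
  got <- read_summary_stats(write_fixture(bad))
  expect_equal(nrow(got), 2)
  rej <- rejected_rows(got)
  expect_setequal(rej$reason, c("nonpositive se", "non-SNP alleles"))
  expect_equal(rej$row[rej$reason == "nonpositive se"], 2)
})

test_that("lowercase alleles are uppercased with values untouched (hand-parsed oracle)", {
  rec <- make_records(3, effect_allele = c("a", "c", "t"),
                      other_allele = c("g", "t", "g"),
                      beta = c(0.1, -0.2, 0.05))
  path <- write_fixture(rec)
  got <- read_summary_stats(path)
  # independent hand parse of the raw file
  lines <- strsplit(readLines(path), "\t")
  header <- lines[[1]]
  for (i in 1:3) {
    row <- lines[[i + 1]]
    expect_equal(got$effect_allele[i], toupper(row[header == "EA"]))
    expect_equal(got$other_allele[i], toupper(row[header == "OA"]))
    expect_equal(got$beta[i], as.numeric(row[header == "BETA"]))
    expect_equal(got$se[i], as.numeric(row[header == "SE"]))
    expect_equal(got$pvalue[i], as.numeric(row[header == "P"]))
  }
})

test_that("missing required column is a configuration error; column_map renames work", {
  rec <- make_records(2)
  path <- write_fixture(rec, headers = c("rsid", "CHR", "BP", "EA", "OA",
                                         "EAF", "BETA", "SE", "P", "N"))
  expect_error(read_summary_stats(path), "missing required column")
  got <- read_summary_stats(path, column_map = c(snp_id = "rsid"))
  expect_equal(got$snp_id, rec$snp_id)
})

test_that("duplicate snp_id keeps the smallest p-value and logs the discard", {
  rec <- make_records(3, snp_id = c("rs1", "rs1", "rs2"),
                      pvalue = c(1e-8, 1e-12, 1e-9))
  got <- validate_summary_records(rec)
  expect_equal(nrow(got), 2)
  expect_equal(got$pvalue[got$snp_id == "rs1"], 1e-12)
  expect_equal(rejected_rows(got)$reason, "duplicate snp_id (larger p)")
})

test_that("harmonization resolves the allele configuration truth table", {
  ex <- make_records(1, effect_allele = "A", other_allele = "G",
                     eaf = 0.3, beta = 0.10)
  mk_out <- function(ea, oa, beta = -0.05, eaf = 0.7) {
    make_records(1, effect_allele = ea, other_allele = oa, beta = beta,
                 eaf = eaf, se = 0.02)
  }
  # direct match: unchanged
  h <- harmonize(ex, mk_out("A", "G", beta = 0.05, eaf = 0.3))
  expect_equal(h$beta_y, 0.05)
  # swapped alleles: sign flips
  h <- harmonize(ex, mk_out("G", "A", beta = -0.05))
  expect_equal(h$beta_y, 0.05)
  # strand complement, same orientation (A/G on the other strand is T/C)
  h <- harmonize(ex, mk_out("T", "C", beta = 0.05, eaf = 0.3))
  expect_equal(h$beta_y, 0.05)
  # strand complement, swapped: sign flips
  h <- harmonize(ex, mk_out("C", "T", beta = -0.05))
  expect_equal(h$beta_y, 0.05)
  # irreconcilable alleles
  expect_error(harmonize(ex, mk_out("A", "C")),
               "dropped all")
  ex2 <- rbind(ex, make_records(1, snp_id = "rs9", effect_allele = "T",
                                other_allele = "C", eaf = 0.2, beta = 0.2))
  out2 <- rbind(mk_out("A", "C"),
                make_records(1, snp_id = "rs9", effect_allele = "T",
                             other_allele = "C", eaf = 0.2, beta = 0.1,
                             se = 0.02))
  h <- harmonize(ex2, out2)
  expect_equal(h$snp_id, "rs9")
  expect_equal(dropped_snps(h)$reason, "allele-mismatch")
})

test_that("palindromic SNPs follow the frequency rule", {
  pal_ex <- function(eaf) make_records(1, effect_allele = "A",
                                       other_allele = "T", eaf = eaf,
                                       beta = 0.1)
  pal_out <- function(eaf) make_records(1, effect_allele = "A",
                                        other_allele = "T", eaf = eaf,
                                        beta = 0.05, se = 0.02)
  # same frequency side, both minor: kept, orientation unchanged
  h <- harmonize(pal_ex(0.10), pal_out(0.12), palindrome_eaf_limit = 0.42)
  expect_equal(h$beta_y, 0.05)
  # near 0.5: ambiguous
  expect_error(harmonize(pal_ex(0.49), pal_out(0.49),
                         palindrome_eaf_limit = 0.42), "dropped all")
  # opposite frequency sides: ambiguous
  expect_error(harmonize(pal_ex(0.10), pal_out(0.90)), "dropped all")
  # missing frequency: ambiguous
  expect_error(harmonize(pal_ex(NA), pal_out(0.10)), "dropped all")
  # C/G behaves like A/T
  cg_ex <- make_records(1, effect_allele = "C", other_allele = "G",
                        eaf = 0.2, beta = 0.1)
  cg_out <- make_records(1, effect_allele = "C", other_allele = "G",
                         eaf = 0.22, beta = -0.03, se = 0.02)
  expect_equal(harmonize(cg_ex, cg_out)$beta_y, -0.03)
})

test_that("harmonization preserves magnitudes, partitions the intersection, and is idempotent", {
  for (seed in 1:5) {
    s <- simulate_pair(sim_config(n_snps = 40, theta = 0.1,
                                  frac_palindromic = 0.3, frac_flipped = 0.5,
                                  seed = seed))
    h <- harmonize(s$exposure, s$outcome)
    shared <- intersect(s$exposure$snp_id, s$outcome$snp_id)
    # partition: every shared SNP appears exactly once in records or dropped
    expect_setequal(c(h$snp_id, dropped_snps(h)$snp_id), shared)
    expect_equal(nrow(h) + nrow(dropped_snps(h)), length(shared))
    # magnitudes never altered, sign at most flipped
    m <- match(h$snp_id, s$outcome$snp_id)
    expect_equal(abs(h$beta_y), abs(s$outcome$beta[m]))
    # idempotence: re-harmonizing the harmonized orientation changes nothing
    ex2 <- s$exposure[match(h$snp_id, s$exposure$snp_id), ]
    out2 <- ex2
    out2$beta <- h$beta_y
    out2$se <- h$se_y
    h2 <- harmonize(ex2, out2)
    expect_equal(h2$beta_y[match(h$snp_id, h2$snp_id)], h$beta_y)
    expect_equal(nrow(dropped_snps(h2)), 0)
  }
})

test_that("harmonized sets round-trip through their writer", {
  h <- sim_hset(sim_config(n_snps = 10, seed = 3))
  path <- tempfile(fileext = ".tsv")
  write_harmonized_set(h, path)
  back <- utils::read.delim(path)
  expect_equal(back$beta_y, h$beta_y, tolerance = 1e-12)
  expect_true(file.exists(paste0(path, ".dropped")))
})
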
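# Shared fixture builders: everything is generated in code at test time.

# minimal valid summary-record data.frame
make_records <- function(n = 3, snp_id = paste0("rs", seq_len(n)),
                         chrom = "1", pos = seq_len(n) * 1e6,
                         effect_allele = "A", other_allele = "G",
                         eaf = 0.3, beta = 0.1, se = 0.01,
                         pvalue = 1e-10, nn = 10000) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = nn,
             stringsAsFactors = FALSE)
}

# write records to a temporary tsv under the default header names
write_fixture <- function(records, headers = NULL) {
  path <- tempfile(fileext = ".tsv")
  out <- records
  names(out) <- headers %||% unname(cortexmr::default_column_map()[names(records)])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# harmonized set straight from a simulated pair, bypassing allele games
sim_hset <- function(cfg) {
  cfg$frac_flipped <- 0  # outcome betas stay on the exposure orientation
  s <- simulate_pair(cfg)
  harmonized_set(s$exposure$beta, s$exposure$se,
                 s$outcome$beta, s$outcome$se,
                 snp_id = s$exposure$snp_id, eaf_x = s$exposure$eaf)
}

# random harmonized set for estimator-oracle comparisons
random_hset <- function(j = 10, theta = 0.2) {
  bx <- stats::rnorm(j, 0.1, 0.05)
  bx[abs(bx) < 0.01] <- 0.01
  sx <- stats::runif(j, 0.004, 0.02)
  sy <- stats::runif(j, 0.005, 0.03)
  by <- theta * bx + stats::rnorm(j, 0, sy)
  harmonized_set(bx, sx, by, sy)
}
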
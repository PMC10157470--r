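#' Instrument-selection configuration
#'
#' Bundles the screening thresholds used by [select_instruments()]:
#' genome-wide significance for the SNP-exposure association, LD independence
#' (greedy clumping), a confounder exclusion list, and the weak-instrument
#' F-statistic floor.
#'
#' @param p_threshold SNP-exposure significance cutoff (default `5e-8`;
#'   relax to e.g. `5e-6` for sparsely instrumented exposures such as IL-6,
#'   keeping the F floor).
#' @param clump_r2 LD r-squared ceiling between retained instruments
#'   (default 0.001).
#' @param clump_kb Clumping window in kilobases (default 10000).
#' @param f_min Weak-instrument floor: instruments with F below this are
#'   dropped (default 10).
#' @param exclusions `data.frame(snp_id, reason)` of SNPs associated with a
#'   secondary phenotype (confounders), or `NULL`.
#' @return List of class `selection_config`.
#' @export
selection_config <- function(p_threshold = 5e-8, clump_r2 = 0.001,
                             clump_kb = 10000, f_min = 10,
                             exclusions = NULL) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            clump_r2 >= 0, clump_r2 <= 1, clump_kb > 0)
  structure(list(p_threshold = p_threshold, clump_r2 = clump_r2,
                 clump_kb = clump_kb, f_min = f_min,
                 exclusions = exclusions),
            class = "selection_config")
}

#' Filter summary records by association p-value
#'
#' @param records Summary-record `data.frame`.
#' @param p_threshold Keep records with `pvalue < p_threshold`.
#' @return The qualifying records, input order preserved.
#' @export
filter_by_pvalue <- function(records, p_threshold) {
  out <- records[records$pvalue < p_threshold, , drop = FALSE]
  if (nrow(out) == 0L) warnf("no records pass p < %g", p_threshold)
  rownames(out) <- NULL
  out
}

#' Read a pairwise LD table
#'
#' Accepts either the 3-column long format (`snp_a`, `snp_b`, `r2`) or a
#' square matrix file whose first column and header row hold SNP ids.
#' Pairs absent from the table are treated as r-squared 0 by [ld_clump()].
#'
#' @param path Tab-delimited file.
#' @return `data.frame(snp_a, snp_b, r2)`.
#' @export
read_ld_table <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(raw) == 3L && all(c("snp_a", "snp_b", "r2") %in% names(raw))) {
    ld <- raw[, c("snp_a", "snp_b", "r2")]
  } else {
    ids <- as.character(raw[[1L]])
    m <- as.matrix(raw[, -1L, drop = FALSE])
    if (!identical(colnames(m), ids)) {
      stopf("square LD matrix must have identical row and column SNP ids")
    }
    idx <- which(upper.tri(m), arr.ind = TRUE)
    ld <- data.frame(snp_a = ids[idx[, 1L]], snp_b = ids[idx[, 2L]],
                     r2 = as.numeric(m[idx]), stringsAsFactors = FALSE)
  }
  if (any(is.na(ld$r2)) || any(ld$r2 < 0 | ld$r2 > 1)) {
    stopf("LD r2 values must lie in [0, 1]")
  }
  ld
}

# symmetric lookup environment keyed "a|b" with a < b
.ld_lookup <- function(ld) {
  env <- new.env(parent = emptyenv(), size = max(1L, nrow(ld) %||% 1L))
  if (!is.null(ld) && nrow(ld)) {
    if (any(is.na(ld$r2)) || any(ld$r2 < 0 | ld$r2 > 1)) {
      stopf("LD r2 values must lie in [0, 1]")
    }
    key <- ifelse(ld$snp_a < ld$snp_b,
                  paste(ld$snp_a, ld$snp_b, sep = "|"),
                  paste(ld$snp_b, ld$snp_a, sep = "|"))
    for (i in seq_along(key)) assign(key[i], ld$r2[i], envir = env)
  }
  function(a, b) {
    k <- if (a < b) paste(a, b, sep = "|") else paste(b, a, sep = "|")
    get0(k, envir = env, ifnotfound = 0)
  }
}

#' Greedy LD clumping
#'
#' Repeatedly promotes the remaining SNP with the smallest p-value to index
#' SNP (ties broken by lexicographically smaller `snp_id`) and removes all
#' remaining SNPs on the same chromosome within `clump_kb` kilobases whose
#' r-squared with the index is at least `clump_r2`. Pairs absent from `ld`
#' count as r-squared 0; SNPs on different chromosomes are never clumped.
#'
#' @param records Summary-record `data.frame`.
#' @param ld `data.frame(snp_a, snp_b, r2)` (see [read_ld_table()]) or `NULL`
#'   for no measured LD.
#' @param clump_r2,clump_kb Clumping thresholds (defaults 0.001 and 10000 kb).
#' @return Index SNPs sorted by chromosome then position.
#' @export
ld_clump <- function(records, ld = NULL, clump_r2 = 0.001, clump_kb = 10000) {
  if (nrow(records) == 0L) return(records)
  r2_of <- .ld_lookup(ld)
  remaining <- records[order(records$pvalue, records$snp_id), , drop = FALSE]
  kept <- character(0)
  while (nrow(remaining) > 0L) {
    index <- remaining[1L, ]
    kept <- c(kept, index$snp_id)
    same_chr <- remaining$chrom == index$chrom
    near <- same_chr & abs(remaining$pos - index$pos) <= clump_kb * 1000
    linked <- vapply(remaining$snp_id, r2_of, numeric(1), b = index$snp_id) >= clump_r2
    drop <- near & linked
    drop[1L] <- TRUE
    remaining <- remaining[!drop, , drop = FALSE]
  }
  out <- records[records$snp_id %in% kept, , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$snp_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Instrument strength: variance explained and F-statistic
#'
#' Per SNP, the proportion of exposure variance explained is
#' `R2 = 2 * MAF * (1 - MAF) * beta^2` with `MAF = min(eaf, 1 - eaf)`;
#' when the allele frequency is missing the fallback
#' `R2 = beta^2 / (beta^2 + se^2 * n)` is used instead. The instrument
#' F-statistic is `F = (R2 / (1 - R2)) * ((n - k - 1) / k)` where `n` is the
#' exposure GWAS sample size and `k` the number of instruments in the set.
#' F below 10 conventionally flags a weak instrument.
#'
#' @param records Summary-record `data.frame` (one row per instrument).
#' @param k Instrument count entering the F formula (set size; use `k = 1`
#'   for per-SNP strength).
#' @return `data.frame(snp_id, r2, f_stat, formula_used)` with
#'   `formula_used` in `{"maf_formula", "se_formula"}`.
#' @export
#' @examples
#' rec <- data.frame(snp_id = "rs1", eaf = 0.5, beta = 0.1, se = 0.01,
#'                   n = 10000)
#' compute_strength(rec, k = 1)  # R2 = 0.005, F ~ 50.24
compute_strength <- function(records, k) {
  stopifnot(k >= 1)
  if (any(records$n <= k + 1)) {
    stopf("sample size must exceed k + 1 = %d for the F-statistic", k + 1)
  }
  maf <- pmin(records$eaf, 1 - records$eaf)
  use_maf <- !is.na(maf)
  r2 <- ifelse(use_maf,
               2 * maf * (1 - maf) * records$beta^2,
               records$beta^2 / (records$beta^2 + records$se^2 * records$n))
  if (any(r2 >= 1)) stopf("R-squared >= 1; check beta/eaf scales")
  f_stat <- (r2 / (1 - r2)) * ((records$n - k - 1) / k)
  data.frame(snp_id = records$snp_id, r2 = r2, f_stat = f_stat,
             formula_used = ifelse(use_maf, "maf_formula", "se_formula"),
             stringsAsFactors = FALSE)
}

#' Strength of an instrument set
#'
#' Set-level variance explained is the sum of the per-SNP `R2`; the
#' F-statistic uses `k` = the number of instruments in the set and `n` =
#' the mean exposure sample size across them.
#'
#' @param records Summary-record `data.frame` (the instrument set).
#' @return List `r2`, `f_stat`, `k`, `n`.
#' @export
set_strength <- function(records) {
  k <- nrow(records)
  r2 <- sum(compute_strength(records, k = 1)$r2)
  n <- mean(records$n)
  if (r2 >= 1) stopf("set R-squared >= 1; check beta/eaf scales")
  list(r2 = r2, f_stat = (r2 / (1 - r2)) * ((n - k - 1) / k), k = k, n = n)
}

#' Read a confounder exclusion list
#'
#' Two-column tab-delimited file (`snp_id`, `reason`), e.g. SNPs whose
#' secondary phenotype in a genotype-phenotype catalogue (obesity,
#' hyperlipemia, hypertension, neurodegenerative or neuropsychiatric traits,
#' smoking, alcohol) could confound the exposure-outcome path.
#'
#' @param path File path.
#' @return `data.frame(snp_id, reason)`.
#' @export
read_exclusion_list <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("snp_id", "reason") %in% names(df))) {
    stopf("exclusion list needs columns snp_id and reason")
  }
  df[, c("snp_id", "reason")]
}

#' Remove confounder-associated SNPs
#'
#' @param records Summary-record `data.frame`.
#' @param exclusions `data.frame(snp_id, reason)` or `NULL`.
#' @return List with `kept` (records) and `removed`
#'   (`data.frame(snp_id, reason)`; exclusion ids absent from `records` are
#'   logged with reason suffix `"(not found)"`).
#' @export
apply_exclusions <- function(records, exclusions = NULL) {
  if (is.null(exclusions) || nrow(exclusions) == 0L) {
    return(list(kept = records,
                removed = data.frame(snp_id = character(),
                                     reason = character(),
                                     stringsAsFactors = FALSE)))
  }
  exclusions <- exclusions[!duplicated(exclusions$snp_id), , drop = FALSE]
  hit <- exclusions$snp_id %in% records$snp_id
  removed <- data.frame(
    snp_id = exclusions$snp_id,
    reason = ifelse(hit, exclusions$reason,
                    paste(exclusions$reason, "(not found)")),
    stringsAsFactors = FALSE)
  kept <- records[!(records$snp_id %in% exclusions$snp_id), , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, removed = removed)
}

#' Select genetic instruments for one exposure
#'
#' Applies, in order: the significance filter, greedy LD clumping, the
#' confounder exclusion list, and the weak-instrument screen. Strength is
#' assessed per instrument (F with `k = 1`, after the exclusion stage so
#' removed SNPs never enter the screen); instruments with `F < f_min` are
#' dropped. The strength of the whole surviving set (summed R-squared,
#' F at `k` = set size) is reported via [set_strength()]. The audit log
#' records the instrument count after every stage.
#'
#' @param exposure Validated summary-record `data.frame`.
#' @param ld Pairwise LD table (see [ld_clump()]) or `NULL`.
#' @param config A [selection_config()].
#' @return List of class `instrument_set`: `instruments` (records),
#'   `strengths` (per-SNP `data.frame` with `r2`, `f_stat`,
#'   `formula_used`), `removed` (exclusion log), `weak`
#'   (`data.frame(snp_id, f_stat)` of weak-IV drops), `set_strength`
#'   (set-level R-squared and F), `audit` (named counts per stage).
#' @export
select_instruments <- function(exposure, ld = NULL,
                               config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  audit <- c(input = nrow(exposure))
  sig <- filter_by_pvalue(exposure, config$p_threshold)
  audit <- c(audit, significant = nrow(sig))
  clumped <- ld_clump(sig, ld, config$clump_r2, config$clump_kb)
  audit <- c(audit, clumped = nrow(clumped))
  excl <- apply_exclusions(clumped, config$exclusions)
  cand <- excl$kept
  audit <- c(audit, after_exclusion = nrow(cand))
  if (nrow(cand) < 1L) stopf("no instruments survive selection")
  st <- compute_strength(cand, k = 1)
  weak <- st$f_stat < config$f_min
  weak_log <- data.frame(snp_id = st$snp_id[weak], f_stat = st$f_stat[weak],
                         stringsAsFactors = FALSE)
  final <- cand[!weak, , drop = FALSE]
  audit <- c(audit, strong = nrow(final))
  if (nrow(final) < 1L) stopf("all candidate instruments are weak (F < %g)",
                              config$f_min)
  st_final <- compute_strength(final, k = 1)
  rownames(final) <- NULL
  structure(list(instruments = final, strengths = st_final,
                 removed = excl$removed, weak = weak_log,
                 set_strength = set_strength(final), audit = audit),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %d instruments (stage counts: %s)\n",
              nrow(x$instruments),
              paste(names(x$audit), x$audit, sep = "=", collapse = ", ")))
  cat(sprintf("Per-SNP F range: %.1f - %.1f; set R2 = %.3f, set F = %.1f\n",
              min(x$strengths$f_stat), max(x$strengths$f_stat),
              x$set_strength$r2, x$set_strength$f_stat))
  invisible(x)
}
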
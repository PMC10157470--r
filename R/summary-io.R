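#' Default column mapping for GWAS summary-statistic files
#'
#' Maps the internal field names to the header names expected in a
#' tab-delimited summary-statistics file. Override individual entries via the
#' `column_map` argument of [read_summary_stats()] (e.g. from a YAML config).
#'
#' @return Named character vector: internal field -> file column name.
#' @export
#' @examples
#' default_column_map()
default_column_map <- function() {
  c(snp_id = "SNP", chrom = "CHR", pos = "BP",
    effect_allele = "EA", other_allele = "OA", eaf = "EAF",
    beta = "BETA", se = "SE", pvalue = "P", n = "N")
}

.required_fields <- c("snp_id", "chrom", "pos", "effect_allele",
                      "other_allele", "eaf", "beta", "se", "pvalue", "n")

#' Read and validate GWAS summary statistics
#'
#' Reads a tab-delimited file of per-SNP association statistics (one GWAS),
#' normalizes alleles to uppercase, and applies row-level validation:
#' alleles must be single A/C/G/T bases (indels and multi-allelic records are
#' rejected), `se > 0`, `pvalue` in (0, 1], `eaf` in [0, 1] when present,
#' `pos >= 1` and `n` a positive count. Duplicated SNP ids keep the record
#' with the smallest p-value; the discard is logged among the rejected rows.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param column_map Named character vector overriding entries of
#'   [default_column_map()]; `NULL` uses the defaults. The `eaf` column may be
#'   absent from the file (frequencies then treated as missing).
#' @return A `data.frame` of validated records with columns `snp_id, chrom,
#'   pos, effect_allele, other_allele, eaf, beta, se, pvalue, n`, carrying a
#'   `"rejected"` attribute: a `data.frame` (`row`, `snp_id`, `reason`) of
#'   rows that failed validation (see [rejected_rows()]).
#' @export
read_summary_stats <- function(path, column_map = NULL) {
  cmap <- default_column_map()
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), names(cmap))
    if (length(unknown)) stopf("unknown column_map fields: %s",
                               paste(unknown, collapse = ", "))
    cmap[names(column_map)] <- unlist(column_map)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character",
                           stringsAsFactors = FALSE, check.names = FALSE)
  required <- setdiff(.required_fields, "eaf")
  missing_cols <- cmap[required][!(cmap[required] %in% names(raw))]
  if (length(missing_cols)) {
    stopf("missing required column(s) in %s: %s", path,
          paste(missing_cols, collapse = ", "))
  }
  has_eaf <- cmap[["eaf"]] %in% names(raw)
  df <- data.frame(
    snp_id = raw[[cmap[["snp_id"]]]],
    chrom = raw[[cmap[["chrom"]]]],
    pos = suppressWarnings(as.numeric(raw[[cmap[["pos"]]]])),
    effect_allele = toupper(trimws(raw[[cmap[["effect_allele"]]]])),
    other_allele = toupper(trimws(raw[[cmap[["other_allele"]]]])),
    eaf = if (has_eaf) suppressWarnings(as.numeric(raw[[cmap[["eaf"]]]])) else NA_real_,
    beta = suppressWarnings(as.numeric(raw[[cmap[["beta"]]]])),
    se = suppressWarnings(as.numeric(raw[[cmap[["se"]]]])),
    pvalue = suppressWarnings(as.numeric(raw[[cmap[["pvalue"]]]])),
    n = suppressWarnings(as.numeric(raw[[cmap[["n"]]]])),
    stringsAsFactors = FALSE
  )
  validate_summary_records(df)
}

#' Validate summary-statistic records
#'
#' Applies the row-level invariants described in [read_summary_stats()] to an
#' in-memory `data.frame`; used by the reader and by the synthetic-data
#' generator's round-trip checks.
#'
#' @param df `data.frame` with the ten standard columns.
#' @return Validated records with a `"rejected"` attribute.
#' @export
validate_summary_records <- function(df) {
  n_in <- nrow(df)
  reason <- character(n_in)
  flag <- function(bad, why) {
    bad <- which(bad & reason == "")
    reason[bad] <<- why
  }
  numeric_bad <- is.na(df$pos) | is.na(df$beta) | is.na(df$se) |
    is.na(df$pvalue) | is.na(df$n)
  flag(numeric_bad, "unparseable numeric")
  base <- c("A", "C", "G", "T")
  flag(!(df$effect_allele %in% base) | !(df$other_allele %in% base),
       "non-SNP alleles")
  flag(df$effect_allele == df$other_allele, "identical alleles")
  flag(df$se <= 0, "nonpositive se")
  flag(!is.na(df$pvalue) & (df$pvalue <= 0 | df$pvalue > 1), "p-value out of (0,1]")
  flag(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1), "eaf out of [0,1]")
  flag(df$pos < 1, "position < 1")
  flag(df$n < 1, "nonpositive n")
  keep <- reason == ""
  # duplicates among valid rows: smallest p wins, ties by earlier row
  if (any(keep)) {
    idx <- which(keep)
    ord <- idx[order(df$pvalue[idx], idx)]
    dup <- ord[duplicated(df$snp_id[ord])]
    reason[dup] <- "duplicate snp_id (larger p)"
    keep <- reason == ""
  }
  rejected <- data.frame(row = which(!keep),
                         snp_id = df$snp_id[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Rejected rows from a summary-statistics read
#'
#' @param records Value returned by [read_summary_stats()] or
#'   [validate_summary_records()].
#' @return `data.frame` with columns `row`, `snp_id`, `reason`.
#' @export
rejected_rows <- function(records) {
  attr(records, "rejected") %||%
    data.frame(row = integer(), snp_id = character(), reason = character())
}

#' Write summary statistics to a tab-delimited file
#'
#' Inverse of [read_summary_stats()] under the default column names.
#'
#' @param records Summary-record `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(records, path) {
  out <- records[, .required_fields]
  names(out) <- unname(default_column_map()[.required_fields])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Construct a harmonized exposure-outcome set
#'
#' The container every estimator consumes: per-SNP exposure and outcome
#' effects on a common effect-allele orientation. Usually produced by
#' [harmonize()]; this constructor also builds sets directly from vectors
#' (simulation, testing).
#'
#' @param beta_x,se_x SNP-exposure effects and standard errors.
#' @param beta_y,se_y SNP-outcome effects and standard errors.
#' @param snp_id SNP identifiers (defaults to `snp_1 ... snp_J`).
#' @param eaf_x Exposure effect-allele frequencies (optional).
#' @param pair_label Label "exposure x outcome" carried into reports.
#' @param dropped `data.frame(snp_id, reason)` of SNPs excluded upstream.
#' @return Object of class `harmonized_set` (a `data.frame` with columns
#'   `snp_id, beta_x, se_x, beta_y, se_y, eaf_x`).
#' @export
harmonized_set <- function(beta_x, se_x, beta_y, se_y, snp_id = NULL,
                           eaf_x = NA_real_, pair_label = "",
                           dropped = NULL) {
  j <- length(beta_x)
  if (is.null(snp_id)) snp_id <- paste0("snp_", seq_len(j))
  df <- data.frame(snp_id = as.character(snp_id),
                   beta_x = as.numeric(beta_x), se_x = as.numeric(se_x),
                   beta_y = as.numeric(beta_y), se_y = as.numeric(se_y),
                   eaf_x = rep_len(as.numeric(eaf_x), j),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$snp_id)) stopf("duplicate snp_id in harmonized set")
  if (any(df$se_x <= 0) || any(df$se_y <= 0)) stopf("all se_x, se_y must be > 0")
  structure(df,
            pair_label = pair_label,
            dropped = dropped %||% data.frame(snp_id = character(),
                                              reason = character(),
                                              stringsAsFactors = FALSE),
            class = c("harmonized_set", "data.frame"))
}

# subset rows of a harmonized set, preserving label and drop log
hset_subset <- function(x, idx) {
  out <- as.data.frame(x)[idx, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, pair_label = attr(x, "pair_label"),
            dropped = attr(x, "dropped"),
            class = c("harmonized_set", "data.frame"))
}

#' Dropped SNPs from harmonization
#'
#' @param x A `harmonized_set`.
#' @return `data.frame(snp_id, reason)`.
#' @export
dropped_snps <- function(x) attr(x, "dropped")

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set%s: %d SNPs (%d dropped)\n",
              if (nzchar(attr(x, "pair_label"))) paste0(" [", attr(x, "pair_label"), "]") else "",
              nrow(x), nrow(dropped_snps(x))))
  print.data.frame(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat(sprintf("... %d more rows\n", nrow(x) - 10))
  invisible(x)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome records onto the exposure's effect-allele orientation for
#' every SNP shared between the two GWAS. Outcome alleles matching the
#' exposure's directly are kept as-is; matching with effect/other swapped
#' flips the sign of the outcome beta (and reflects its frequency); strand
#' complements are resolved the same way after complementing. Palindromic
#' (A/T or C/G) SNPs, whose strand cannot be read off the allele letters, are
#' kept only when both allele frequencies fall on the same side of 0.5 and
#' both minor-allele frequencies are below `palindrome_eaf_limit`; otherwise
#' they are dropped as `"palindromic-ambiguous"`. Irreconcilable alleles drop
#' as `"allele-mismatch"`. Every shared SNP lands in exactly one of the
#' harmonized records or the dropped table.
#'
#' @param exposure,outcome Validated summary-record `data.frame`s.
#' @param palindrome_eaf_limit Minor-allele-frequency ceiling below which a
#'   frequency-matched palindromic SNP is considered resolvable (default
#'   0.42, standard two-sample MR practice).
#' @param pair_label Optional label for reports.
#' @return A [harmonized_set()].
#' @export
#' @examples
#' ex <- data.frame(snp_id = "rs1", chrom = "1", pos = 100,
#'                  effect_allele = "A", other_allele = "G", eaf = 0.3,
#'                  beta = 0.1, se = 0.01, pvalue = 1e-10, n = 10000)
#' out <- ex; out$effect_allele <- "G"; out$other_allele <- "A"
#' out$beta <- -0.05; out$eaf <- 0.7
#' harmonize(ex, out)  # outcome beta becomes +0.05
harmonize <- function(exposure, outcome, palindrome_eaf_limit = 0.42,
                      pair_label = "") {
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (length(shared) == 0L) {
    stopf("no shared SNPs between exposure and outcome summary statistics")
  }
  ex <- exposure[match(shared, exposure$snp_id), ]
  ou <- outcome[match(shared, outcome$snp_id), ]

  keep <- logical(length(shared))
  flip <- logical(length(shared))
  reason <- character(length(shared))

  pal <- is_palindromic(ex$effect_allele, ex$other_allele)

  # non-palindromic resolution
  direct <- ex$effect_allele == ou$effect_allele & ex$other_allele == ou$other_allele
  swapped <- ex$effect_allele == ou$other_allele & ex$other_allele == ou$effect_allele
  c_ea <- unname(.complement[ou$effect_allele])
  c_oa <- unname(.complement[ou$other_allele])
  comp_direct <- ex$effect_allele == c_ea & ex$other_allele == c_oa
  comp_swapped <- ex$effect_allele == c_oa & ex$other_allele == c_ea

  np <- !pal
  keep[np & (direct | comp_direct)] <- TRUE
  sw <- np & !(direct | comp_direct) & (swapped | comp_swapped)
  keep[sw] <- TRUE
  flip[sw] <- TRUE
  reason[np & !keep] <- "allele-mismatch"

  # palindromic: alleles match both ways; resolve by frequency, else drop
  if (any(pal)) {
    letters_ok <- (direct | swapped | comp_direct | comp_swapped)
    maf_x <- pmin(ex$eaf, 1 - ex$eaf)
    maf_y <- pmin(ou$eaf, 1 - ou$eaf)
    same_side <- (ex$eaf - 0.5) * (ou$eaf - 0.5) > 0
    resolvable <- pal & letters_ok & !is.na(ex$eaf) & !is.na(ou$eaf) &
      same_side & maf_x < palindrome_eaf_limit & maf_y < palindrome_eaf_limit
    keep[resolvable] <- TRUE
    flip[resolvable] <- FALSE  # same frequency side => already aligned
    reason[pal & letters_ok & !resolvable] <- "palindromic-ambiguous"
    reason[pal & !letters_ok] <- "allele-mismatch"
  }

  beta_y <- ifelse(flip, -ou$beta, ou$beta)
  kept_idx <- which(keep)
  dropped <- data.frame(snp_id = shared[!keep], reason = reason[!keep],
                        stringsAsFactors = FALSE)
  if (length(kept_idx) == 0L) {
    stopf("harmonization dropped all %d shared SNPs", length(shared))
  }
  harmonized_set(beta_x = ex$beta[kept_idx], se_x = ex$se[kept_idx],
                 beta_y = beta_y[kept_idx], se_y = ou$se[kept_idx],
                 snp_id = shared[kept_idx], eaf_x = ex$eaf[kept_idx],
                 pair_label = pair_label, dropped = dropped)
}

#' Write a harmonized set and its drop log
#'
#' Emits the harmonized records as a tab-delimited table and, alongside it,
#' a `<path>.dropped` side file with the per-SNP drop reasons.
#'
#' @param x A `harmonized_set`.
#' @param path Output path for the records table.
#' @return `path`, invisibly.
#' @export
write_harmonized_set <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dropped_snps(x), paste0(path, ".dropped"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
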
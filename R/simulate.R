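# Seeded generator of two-sample GWAS summary statistics with known causal
# truth, used to validate every pipeline stage.

#' Simulation configuration for synthetic two-sample GWAS data
#'
#' Defines the generative model behind [simulate_pair()] and
#' [simulate_study()]. Per SNP j: a minor-allele frequency `maf_j` drawn
#' uniformly from `maf_range`; a true exposure effect `b_j` of magnitude
#' `sqrt(h2_per_snp / (2 maf_j (1 - maf_j)))` (so each instrument explains
#' `h2_per_snp` of the unit-variance exposure) with random sign; a direct
#' (pleiotropic) outcome effect `a_j` per regime; a true outcome effect
#' `c_j = theta * b_j + a_j`. Observed effects are
#' `beta_x ~ N(b, se_x)`, `beta_y ~ N(c, se_y)` with the standard
#' summary-statistic approximation `se = 1 / sqrt(2 maf (1 - maf) n)`,
#' independent between the two samples. Outlier SNPs have `c_j` displaced
#' by `outlier_scale` outcome SEs (equivalently, their Wald ratio by
#' `outlier_scale` ratio SEs). A fraction of SNPs is assigned palindromic
#' (A/T or C/G) alleles and a fraction is written allele-swapped in the
#' outcome file, so harmonization is exercised.
#'
#' Defaults mirror the scale of the motivating study: around 50 instruments
#' from an exposure meta-analysis of ~60,000 participants (inflammatory
#' bowel disease scale) against cortical phenotype GWAS of ~51,665
#' (brain-imaging consortium scale), with top-locus instrument strength
#' (per-SNP F about `h2_per_snp * n_exposure` = 240).
#'
#' @param n_snps Instrument count J (default 50).
#' @param theta True causal effect (default 0).
#' @param n_exposure,n_outcome GWAS sample sizes (defaults 60000, 51665).
#' @param maf_range Minor-allele-frequency interval within (0, 0.5].
#' @param h2_per_snp Exposure variance explained per instrument
#'   (default 0.004).
#' @param pleiotropy One of `"none"`, `"balanced"` (direct effects with
#'   mean 0), `"directional"` (mean `pleiotropy_mean`), or
#'   `"inside_violating"` (direct effects proportional to instrument
#'   strength: `a_j = pleiotropy_ratio * b_j + noise`, violating InSIDE).
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of direct effects
#'   (directional / balanced regimes).
#' @param pleiotropy_ratio Direct effect per unit of true exposure effect
#'   (`inside_violating` regime).
#' @param pleiotropy_frac Fraction of SNPs carrying the pleiotropic effect
#'   (default 1; e.g. 0.4 for a 40%-invalid weighted-median stress test).
#' @param n_outliers Number of displaced-outlier SNPs (default 0).
#' @param outlier_scale Displacement in outcome-SE units (default 10).
#' @param frac_palindromic Fraction of SNPs given A/T or C/G alleles
#'   (default 0.1).
#' @param frac_flipped Fraction of SNPs written with swapped alleles (and
#'   negated beta) in the outcome file (default 0.3).
#' @param ld_blocks `NULL`, or `list(n_blocks, block_size, within_r2)` to
#'   group the first `n_blocks * block_size` SNPs into LD blocks (nearby
#'   positions, correlated true effects, an emitted pairwise r2 table).
#' @param b_sign `"random"` (true exposure effects carry random signs) or
#'   `"positive"` (instruments oriented to the exposure-increasing allele,
#'   the convention under which directional pleiotropy biases IVW).
#' @param seed Integer seed; all randomness flows through it.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_snps = 50, theta = 0, n_exposure = 60000,
                       n_outcome = 51665, maf_range = c(0.05, 0.5),
                       h2_per_snp = 0.004,
                       pleiotropy = c("none", "balanced", "directional",
                                      "inside_violating"),
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       pleiotropy_ratio = 0, pleiotropy_frac = 1,
                       n_outliers = 0, outlier_scale = 10,
                       frac_palindromic = 0.1, frac_flipped = 0.3,
                       ld_blocks = NULL, b_sign = c("random", "positive"),
                       seed = NULL) {
  pleiotropy <- match.arg(pleiotropy)
  b_sign <- match.arg(b_sign)
  stopifnot(n_snps >= 1, n_exposure > 2, n_outcome > 2,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            h2_per_snp > 0, pleiotropy_sd >= 0, pleiotropy_frac >= 0,
            pleiotropy_frac <= 1, n_outliers >= 0,
            n_outliers <= n_snps, frac_palindromic >= 0,
            frac_palindromic <= 1, frac_flipped >= 0, frac_flipped <= 1)
  structure(as.list(environment()), class = "sim_config")
}

.draw_pleiotropy <- function(cfg, b) {
  j <- length(b)
  a <- numeric(j)
  n_pleio <- round(cfg$pleiotropy_frac * j)
  idx <- if (n_pleio > 0 && cfg$pleiotropy != "none") {
    sample.int(j, n_pleio)
  } else integer(0)
  if (length(idx)) {
    a[idx] <- switch(cfg$pleiotropy,
      balanced = stats::rnorm(length(idx), 0, cfg$pleiotropy_sd),
      directional = stats::rnorm(length(idx), cfg$pleiotropy_mean,
                                 cfg$pleiotropy_sd),
      inside_violating = cfg$pleiotropy_ratio * b[idx] +
        stats::rnorm(length(idx), 0, cfg$pleiotropy_sd))
  }
  list(a = a, idx = sort(idx))
}

.assign_alleles <- function(j, frac_palindromic) {
  pal_pairs <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  np_pairs <- rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
                    c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
  n_pal <- round(frac_palindromic * j)
  is_pal <- logical(j)
  is_pal[if (n_pal > 0) sample.int(j, n_pal) else integer(0)] <- TRUE
  ea <- oa <- character(j)
  pick_pal <- sample.int(nrow(pal_pairs), sum(is_pal), replace = TRUE)
  ea[is_pal] <- pal_pairs[pick_pal, 1L]; oa[is_pal] <- pal_pairs[pick_pal, 2L]
  pick_np <- sample.int(nrow(np_pairs), sum(!is_pal), replace = TRUE)
  ea[!is_pal] <- np_pairs[pick_np, 1L]; oa[!is_pal] <- np_pairs[pick_np, 2L]
  list(ea = ea, oa = oa, is_pal = is_pal)
}

# positions far apart across chromosomes so nothing clumps by accident;
# LD-block members sit within 50 kb of each other instead
.assign_positions <- function(j, ld_blocks) {
  chrom <- as.character(rep_len(1:22, j))
  pos <- 1e6 + (seq_len(j) - 1L) %/% 22L * 2e7
  if (!is.null(ld_blocks)) {
    k <- ld_blocks$n_blocks * ld_blocks$block_size
    stopifnot(k <= j)
    block <- rep(seq_len(ld_blocks$n_blocks), each = ld_blocks$block_size)
    chrom[seq_len(k)] <- as.character(block)
    pos[seq_len(k)] <- 1e6 +
      (seq_len(k) - (block - 1L) * ld_blocks$block_size) * 10000
  }
  list(chrom = chrom, pos = pos)
}

#' Simulate one exposure-outcome pair of GWAS summary statistics
#'
#' Draws per-SNP summary statistics for one exposure GWAS and one outcome
#' GWAS under the generative model of [sim_config()], returning both record
#' tables and the complete latent truth.
#'
#' @param config A [sim_config()].
#' @return List: `exposure` and `outcome` (summary-record `data.frame`s in
#'   the format of [read_summary_stats()]), `truth` (latent values: `theta`,
#'   `maf`, `b`, `a`, `c`, `se_x`, `se_y`, indices of pleiotropic, outlier,
#'   palindromic and allele-flipped SNPs), and `ld` (pairwise r2 table, or
#'   `NULL` when no LD blocks were requested).
#' @export
simulate_pair <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    j <- cfg$n_snps
    maf <- stats::runif(j, cfg$maf_range[1], cfg$maf_range[2])
    var_g <- 2 * maf * (1 - maf)
    b <- sqrt(cfg$h2_per_snp / var_g) *
      (if (cfg$b_sign == "positive") 1 else sample(c(-1, 1), j, replace = TRUE))
    if (!is.null(cfg$ld_blocks)) {
      # correlated true effects within a block: share the block leader's sign
      k <- cfg$ld_blocks$n_blocks * cfg$ld_blocks$block_size
      block <- rep(seq_len(cfg$ld_blocks$n_blocks),
                   each = cfg$ld_blocks$block_size)
      lead_sign <- sign(b[match(seq_len(cfg$ld_blocks$n_blocks), block)])
      b[seq_len(k)] <- abs(b[seq_len(k)]) * lead_sign[block]
    }
    se_x <- 1 / sqrt(var_g * cfg$n_exposure)
    se_y <- 1 / sqrt(var_g * cfg$n_outcome)
    pl <- .draw_pleiotropy(cfg, b)
    cc <- cfg$theta * b + pl$a
    out_idx <- if (cfg$n_outliers > 0) sort(sample.int(j, cfg$n_outliers))
               else integer(0)
    cc[out_idx] <- cc[out_idx] +
      cfg$outlier_scale * se_y[out_idx] *
      sample(c(-1, 1), length(out_idx), replace = TRUE)
    beta_x <- stats::rnorm(j, b, se_x)
    beta_y <- stats::rnorm(j, cc, se_y)
    al <- .assign_alleles(j, cfg$frac_palindromic)
    loc <- .assign_positions(j, cfg$ld_blocks)
    snp_id <- sprintf("rs%06d", seq_len(j))

    exposure <- data.frame(
      snp_id = snp_id, chrom = loc$chrom, pos = loc$pos,
      effect_allele = al$ea, other_allele = al$oa, eaf = maf,
      beta = beta_x, se = se_x, pvalue = z_pvalue(beta_x / se_x),
      n = cfg$n_exposure, stringsAsFactors = FALSE)

    n_flip <- round(cfg$frac_flipped * j)
    flip_idx <- if (n_flip > 0) sort(sample.int(j, n_flip)) else integer(0)
    flip <- seq_len(j) %in% flip_idx
    outcome <- data.frame(
      snp_id = snp_id, chrom = loc$chrom, pos = loc$pos,
      effect_allele = ifelse(flip, al$oa, al$ea),
      other_allele = ifelse(flip, al$ea, al$oa),
      eaf = ifelse(flip, 1 - maf, maf),
      beta = ifelse(flip, -beta_y, beta_y), se = se_y,
      pvalue = z_pvalue(beta_y / se_y), n = cfg$n_outcome,
      stringsAsFactors = FALSE)

    ld <- NULL
    if (!is.null(cfg$ld_blocks)) {
      k <- cfg$ld_blocks$n_blocks * cfg$ld_blocks$block_size
      block <- rep(seq_len(cfg$ld_blocks$n_blocks),
                   each = cfg$ld_blocks$block_size)
      pair <- which(outer(block, block, `==`) &
                      upper.tri(matrix(0, k, k)), arr.ind = TRUE)
      ld <- data.frame(snp_a = snp_id[pair[, 1L]], snp_b = snp_id[pair[, 2L]],
                       r2 = cfg$ld_blocks$within_r2, stringsAsFactors = FALSE)
    }

    list(exposure = exposure, outcome = outcome,
         truth = list(theta = cfg$theta, maf = maf, b = b, a = pl$a, c = cc,
                      se_x = se_x, se_y = se_y, snp_id = snp_id,
                      pleiotropic_idx = pl$idx, outlier_idx = out_idx,
                      palindromic_idx = which(al$is_pal),
                      flipped_idx = flip_idx),
         ld = ld)
  })
}

#' Simulate a full exposure x outcome study
#'
#' Generates one exposure GWAS per exposure and one outcome GWAS per
#' outcome over the union of all instruments, with a nonzero causal effect
#' only in the planted cells. Each instrument belongs to one exposure; its
#' true effect on outcome o is `theta[exposure, o] * b + a`.
#'
#' @param n_exposures,n_outcomes Grid dimensions; names default to
#'   `exposure_1 ...` and `outcome_1 ...`.
#' @param planted_effects `NULL` (all-null grid) or a
#'   `data.frame(exposure, outcome, theta)` naming the nonzero cells.
#' @param config A [sim_config()]; `n_snps` is the per-exposure instrument
#'   count and `seed` drives the whole study.
#' @param outdir Optional directory: writes `<exposure>.tsv`,
#'   `<outcome>.tsv`, `truth.yaml` and (with LD blocks) `ld.tsv`. Refuses a
#'   non-empty existing directory unless `overwrite = TRUE`.
#' @param overwrite Allow writing into an existing non-empty directory.
#' @return List: `exposures`, `outcomes` (named lists of record
#'   `data.frame`s), `theta` (exposure x outcome matrix of true effects),
#'   `truths` (per-exposure latent truth), `ld`.
#' @export
simulate_study <- function(n_exposures, n_outcomes, planted_effects = NULL,
                           config = sim_config(), outdir = NULL,
                           overwrite = FALSE) {
  ex_names <- paste0("exposure_", seq_len(n_exposures))
  out_names <- paste0("outcome_", seq_len(n_outcomes))
  theta <- matrix(0, n_exposures, n_outcomes,
                  dimnames = list(ex_names, out_names))
  if (!is.null(planted_effects)) {
    bad_e <- setdiff(planted_effects$exposure, ex_names)
    bad_o <- setdiff(planted_effects$outcome, out_names)
    if (length(bad_e) || length(bad_o)) {
      stopf("planted cells outside the grid: %s",
            paste(c(bad_e, bad_o), collapse = ", "))
    }
    theta[cbind(planted_effects$exposure, planted_effects$outcome)] <-
      planted_effects$theta
  }
  with_seed(config$seed, {
    truths <- list()
    exposures <- list()
    outcome_parts <- list()
    for (e in seq_len(n_exposures)) {
      cfg_e <- config
      cfg_e$seed <- NULL  # inside the seeded stream already
      sim <- simulate_pair(cfg_e)  # outcome part discarded; per-outcome below
      # relabel SNPs uniquely per exposure
      ids <- sprintf("rs%d%05d", e, seq_len(config$n_snps))
      sim$exposure$snp_id <- ids
      sim$truth$snp_id <- ids
      exposures[[ex_names[e]]] <- sim$exposure
      truths[[ex_names[e]]] <- sim$truth
      outcome_parts[[e]] <- sim
    }
    outcomes <- list()
    for (o in seq_len(n_outcomes)) {
      parts <- lapply(seq_len(n_exposures), function(e) {
        sim <- outcome_parts[[e]]
        tr <- sim$truth
        cc <- theta[e, o] * tr$b + tr$a
        beta_y <- stats::rnorm(config$n_snps, cc, tr$se_y)
        ex <- sim$exposure
        flip <- seq_len(config$n_snps) %in% tr$flipped_idx
        data.frame(
          snp_id = tr$snp_id, chrom = ex$chrom, pos = ex$pos,
          effect_allele = ifelse(flip, ex$other_allele, ex$effect_allele),
          other_allele = ifelse(flip, ex$effect_allele, ex$other_allele),
          eaf = ifelse(flip, 1 - tr$maf, tr$maf),
          beta = ifelse(flip, -beta_y, beta_y), se = tr$se_y,
          pvalue = z_pvalue(beta_y / tr$se_y), n = config$n_outcome,
          stringsAsFactors = FALSE)
      })
      outcomes[[out_names[o]]] <- do.call(rbind, parts)
    }
    ld <- do.call(rbind, Filter(Negate(is.null),
                                lapply(outcome_parts, `[[`, "ld")))
    result <- list(exposures = exposures, outcomes = outcomes, theta = theta,
                   truths = truths, ld = ld)
    if (!is.null(outdir)) .write_sim_study(result, outdir, overwrite)
    result
  })
}

.write_sim_study <- function(result, outdir, overwrite) {
  if (dir.exists(outdir) && length(list.files(outdir)) && !overwrite) {
    stopf("output directory %s exists and is not empty (use overwrite = TRUE)",
          outdir)
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (e in names(result$exposures)) {
    write_summary_stats(result$exposures[[e]],
                        file.path(outdir, paste0(e, ".tsv")))
  }
  for (o in names(result$outcomes)) {
    write_summary_stats(result$outcomes[[o]],
                        file.path(outdir, paste0(o, ".tsv")))
  }
  manifest <- list(theta = lapply(seq_len(nrow(result$theta)), function(i) {
    as.list(stats::setNames(result$theta[i, ], colnames(result$theta)))
  }))
  names(manifest$theta) <- rownames(result$theta)
  yaml::write_yaml(manifest, file.path(outdir, "truth.yaml"))
  if (!is.null(result$ld)) {
    utils::write.table(result$ld, file.path(outdir, "ld.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}
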
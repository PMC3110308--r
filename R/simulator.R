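#' Generate a synthetic phased haplotype panel
#'
#' Builds a diploid-phased 0/1 haplotype panel with a skewed
#' minor-allele-frequency spectrum and LD that decays with inter-SNP
#' distance, standing in for a population-scale resampled panel.
#' Haplotypes are drawn i.i.d. from a first-order Markov chain across
#' SNPs: the allele at each SNP is drawn conditionally on the previous
#' SNP's allele using the two-locus LD engine, with target adjacent
#' correlation \eqn{r = e^{-d/\lambda}} (distance \eqn{d} bp, decay scale
#' \eqn{\lambda} = \code{ld_scale}) clipped into the feasible range for
#' the two frequencies.  For binary Markov chains correlations multiply
#' along the chain, so LD between any two SNPs decays approximately as
#' \eqn{e^{-D/\lambda}} in their distance \eqn{D}.
#'
#' Minor allele frequencies follow a rare-skewed Beta spectrum organized
#' into haplotype-block-like runs: each SNP either continues the previous
#' SNP's target frequency (probability \eqn{e^{-d/\lambda}}, so block
#' length tracks the LD scale) or draws a fresh frequency and allele
#' orientation.  Frequency-matched runs make near-perfect LD feasible
#' within blocks — as in real panels, where strong LD forces near-equal
#' frequencies — while fresh draws create block boundaries.  The sign of
#' the adjacent target correlation is aimed at whichever direction the
#' two frequencies make more feasible (the sign of r is a coding
#' artifact).  Per-SNP frequencies recorded in the panel are the realized
#' column means.  A chip mask marks the SNPs available to a genome scan:
#' common SNPs (MAF at least \code{chip_maf}) are retained independently
#' with probability \code{chip_prob}, emulating array thinning.
#'
#' @param n_hap Number of haplotypes (even, at least 2).
#' @param n_snp Number of SNPs.
#' @param region_bp Region length in base pairs.
#' @param ld_scale Correlation decay scale in bp; larger means stronger,
#'   longer-range LD.
#' @param maf_shape Beta shape parameters for the MAF spectrum (values
#'   below 1 in the first shape skew toward rare alleles).
#' @param maf_min Lower truncation of the MAF spectrum.
#' @param chip_maf Minimum MAF for chip eligibility.
#' @param chip_prob Retention probability for eligible SNPs.
#' @param seed Integer seed; the panel is reproducible given the seed.
#' @return An object of class \code{"haplotype_panel"}: list with
#'   \code{haplotypes} (n_hap x n_snp integer matrix), \code{positions},
#'   \code{freqs} (realized allele-1 frequencies), \code{chip_mask}.
#' @examples
#' p <- generate_panel(200, 20, region_bp = 1e5, ld_scale = 5e4, seed = 1)
#' p
#' @export
generate_panel <- function(n_hap, n_snp, region_bp = 1e6, ld_scale = 5e4,
                           maf_shape = c(0.35, 1), maf_min = 0.01,
                           chip_maf = 0.05, chip_prob = 0.5, seed = 1L) {
  stopifnot(n_hap >= 2, n_hap %% 2 == 0, n_snp >= 2, region_bp > n_snp,
            ld_scale > 0)
  set.seed(seed)
  positions <- sort(sample.int(region_bp, n_snp))
  draw_f <- function() {
    maf <- maf_min + (0.5 - maf_min) * stats::rbeta(1, maf_shape[1], maf_shape[2])
    if (stats::runif(1) < 0.5) maf else 1 - maf
  }
  f <- numeric(n_snp)
  f[1] <- draw_f()
  for (j in seq_len(n_snp)[-1]) {
    d <- positions[j] - positions[j - 1]
    f[j] <- if (stats::runif(1) < exp(-d / ld_scale)) f[j - 1] else draw_f()
  }
  H <- matrix(0L, n_hap, n_snp)
  H[, 1] <- stats::rbinom(n_hap, 1, f[1])
  for (j in seq_len(n_snp)[-1]) {
    d <- positions[j] - positions[j - 1]
    bounds <- r_bounds(f[j], f[j - 1])
    # the sign of r is a coding artifact; aim the target magnitude at
    # whichever direction the two frequencies make more feasible
    m <- exp(-d / ld_scale)
    r <- if (bounds[["r_max"]] >= -bounds[["r_min"]])
      min(m, 0.999 * bounds[["r_max"]])
    else -min(m, -0.999 * bounds[["r_min"]])
    q <- conditional_probs(two_locus_ld(f[j], f[j - 1], r))
    H[, j] <- stats::rbinom(n_hap, 1, ifelse(H[, j - 1] == 1L,
                                             q[["q1"]], q[["q0"]]))
  }
  freqs <- colMeans(H)
  emp_maf <- pmin(freqs, 1 - freqs)
  chip_mask <- emp_maf >= chip_maf & stats::runif(n_snp) < chip_prob
  if (!any(chip_mask)) chip_mask[which.max(emp_maf)] <- TRUE
  structure(list(haplotypes = H, positions = positions, freqs = freqs,
                 chip_mask = chip_mask),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf(
    "Haplotype panel: %d haplotypes x %d SNPs (%d on chip), region %g bp\n",
    nrow(x$haplotypes), ncol(x$haplotypes), sum(x$chip_mask),
    max(x$positions) - min(x$positions) + 1))
  invisible(x)
}

#' Squared correlation between two panel SNPs
#'
#' Empirical haplotype \eqn{r^2} between two SNP columns of a panel.
#'
#' @param panel A [generate_panel()] or [read_panel()] object.
#' @param i,j SNP indices.
#' @return \eqn{r^2} in [0, 1] (NA if either SNP is monomorphic).
#' @export
panel_r2 <- function(panel, i, j) {
  h <- panel$haplotypes
  suppressWarnings(stats::cor(h[, i], h[, j])^2)
}

#' Sample a case-control study from a haplotype panel
#'
#' Controls are unphenotyped cohort samples: haplotypes drawn uniformly
#' without replacement and combined in pairs.  Case genotypes at the
#' causal SNP are first drawn with probabilities proportional to
#' \deqn{(1-f)^2,\quad 2f(1-f)\,\alpha_1,\quad f^2\,\alpha_2,}
#' where \eqn{\alpha_1, \alpha_2} are the genotype relative risks and
#' \eqn{f} the panel frequency of the risk allele; haplotype pairs
#' consistent with each genotype are then drawn uniformly without
#' replacement.  All draws within one study are without replacement
#' (cases before controls); the panel is restored between studies.
#'
#' @param panel A haplotype panel.
#' @param causal_snp Column index of the causal SNP.
#' @param model A [general_model()] for the disease at the causal SNP.
#' @param n_case,n_ctrl Numbers of diploid cases and controls.
#' @param risk_allele Which panel allele (1 or 0) is the risk allele;
#'   genotypes count copies of this allele.
#' @param exclude Haplotype indices already consumed (e.g. by a scan
#'   stage when sampling its replication stage).
#' @return List with index vectors \code{case_h1}, \code{case_h2},
#'   \code{ctrl_h1}, \code{ctrl_h2}, the vector \code{used} of all
#'   consumed haplotype indices, and \code{case_genotypes}.
#' @export
sample_cases_controls <- function(panel, causal_snp, model, n_case, n_ctrl,
                                  risk_allele = 1L, exclude = integer(0)) {
  h <- panel$haplotypes
  a <- h[, causal_snp]
  if (risk_allele == 0L) a <- 1L - a
  avail <- setdiff(seq_len(nrow(h)), exclude)
  f <- mean(a[avail])
  if (f <= 0 || f >= 1)
    stop(errorCondition("causal SNP is monomorphic among available haplotypes",
                        class = c("distortgwas_sample_error", "error",
                                  "condition")))
  rr <- genotype_relative_risks(model)
  w <- c((1 - f)^2, 2 * f * (1 - f) * rr[["alpha1"]], f^2 * rr[["alpha2"]])
  gc <- sample(0:2, n_case, replace = TRUE, prob = w)
  n_g <- tabulate(gc + 1L, 3L)
  need_risk <- 2L * n_g[3] + n_g[2]
  need_nonrisk <- 2L * n_g[1] + n_g[2]
  pool_risk <- avail[a[avail] == 1L]
  pool_non <- avail[a[avail] == 0L]
  if (length(pool_risk) < need_risk || length(pool_non) < need_nonrisk)
    stop(errorCondition(
      "insufficient haplotypes of the required allele class in the panel",
      class = c("distortgwas_sample_error", "error", "condition")))
  sel_risk <- sample(pool_risk, need_risk)
  sel_non <- sample(pool_non, need_nonrisk)
  case_h1 <- integer(n_case); case_h2 <- integer(n_case)
  i2 <- gc == 2L; i1 <- gc == 1L; i0 <- gc == 0L
  case_h1[i2] <- sel_risk[seq_len(n_g[3])]
  case_h2[i2] <- sel_risk[n_g[3] + seq_len(n_g[3])]
  case_h1[i1] <- sel_risk[2L * n_g[3] + seq_len(n_g[2])]
  case_h2[i1] <- sel_non[seq_len(n_g[2])]
  case_h1[i0] <- sel_non[n_g[2] + seq_len(n_g[1])]
  case_h2[i0] <- sel_non[n_g[2] + n_g[1] + seq_len(n_g[1])]
  used_cases <- c(sel_risk, sel_non)
  remaining <- setdiff(avail, used_cases)
  if (length(remaining) < 2L * n_ctrl)
    stop(errorCondition("insufficient haplotypes left for controls",
                        class = c("distortgwas_sample_error", "error",
                                  "condition")))
  sel_ctrl <- sample(remaining, 2L * n_ctrl)
  list(case_h1 = case_h1, case_h2 = case_h2,
       ctrl_h1 = sel_ctrl[seq_len(n_ctrl)],
       ctrl_h2 = sel_ctrl[n_ctrl + seq_len(n_ctrl)],
       used = c(used_cases, sel_ctrl),
       case_genotypes = gc)
}

# genotype count matrix (n_snp_subset x 3) for given haplotype index pairs,
# oriented so genotypes count panel allele 1
.count_genotypes <- function(panel, h1, h2, snps) {
  g <- panel$haplotypes[h1, snps, drop = FALSE] +
    panel$haplotypes[h2, snps, drop = FALSE]
  cbind(colSums(g == 0L), colSums(g == 1L), colSums(g == 2L))
}

#' Default significance thresholds of the scan pipeline
#'
#' Genome-wide scan threshold 1e-6, replication threshold 0.01, and
#' deviation-test level 0.05.
#'
#' @return Named numeric vector.
#' @export
default_thresholds <- function() {
  c(scan = 1e-6, replication = 0.01, deviation = 0.05)
}

#' Run one simulated association + replication study
#'
#' The full single-study pipeline: sample a scan-stage case-control
#' sample at a designated causal SNP, apply the trend test to every chip
#' SNP, take the hit SNP (smallest p-value; ties broken by lowest index
#' and flagged), and classify the study through the cascade: the hit must
#' reach the scan threshold, then replicate (fresh case-control sample,
#' genotyped at the hit SNP only) at the replication threshold; among
#' replicated associations, the deviation test on the replication counts
#' decides whether departure from multiplicativity was detected.  This
#' models the ascertainment implicit in reported GWAS associations.
#'
#' Replication tables where the general model is unfittable (empty
#' genotype cells) are treated as showing no significant deviation and
#' flagged in the output.
#'
#' @inheritParams sample_cases_controls
#' @param n_case,n_ctrl Per-stage sample sizes (the replication stage
#'   uses the same numbers with fresh haplotypes).
#' @param thresholds Named vector as [default_thresholds()].
#' @param causal_on_chip \code{"panel"} uses the panel's chip mask as is;
#'   \code{"include"}/\code{"exclude"} forces the causal SNP onto/off the
#'   chip.
#' @param seed Integer seed; the outcome is a deterministic function of
#'   (panel, causal SNP, model, design, thresholds, seed).
#' @return One-row data.frame: causal and hit SNP indices, risk allele,
#'   \code{r2} between causal and hit SNPs, the three stage p-values,
#'   replication-sample estimates \code{beta_hat}, \code{gamma_hat},
#'   outcome (\code{"undetected"}, \code{"assoc_only"},
#'   \code{"assoc_plus_deviation"}), and flags \code{tie},
#'   \code{unfittable}.
#' @export
run_study <- function(panel, causal_snp, model, n_case = 2000, n_ctrl = 2000,
                      thresholds = default_thresholds(), risk_allele = 1L,
                      causal_on_chip = c("panel", "include", "exclude"),
                      seed = NULL) {
  causal_on_chip <- match.arg(causal_on_chip)
  if (!is.null(seed)) set.seed(seed)
  chip <- panel$chip_mask
  if (causal_on_chip == "include") chip[causal_snp] <- TRUE
  if (causal_on_chip == "exclude") chip[causal_snp] <- FALSE
  chip_idx <- which(chip)
  if (length(chip_idx) == 0L) stop("no SNPs on the chip")

  scan <- sample_cases_controls(panel, causal_snp, model, n_case, n_ctrl,
                                risk_allele = risk_allele)
  cc <- .count_genotypes(panel, scan$case_h1, scan$case_h2, chip_idx)
  uc <- .count_genotypes(panel, scan$ctrl_h1, scan$ctrl_h2, chip_idx)
  stat <- trend_stat(cc, uc)
  pvals <- stats::pchisq(stat, 1L, lower.tail = FALSE)
  best <- which(pvals == min(pvals))
  tie <- length(best) > 1L
  hit <- chip_idx[best[1L]]
  scan_p <- pvals[best[1L]]
  r2 <- panel_r2(panel, causal_snp, hit)

  res <- data.frame(causal_snp = causal_snp, risk_allele = risk_allele,
                    hit_snp = hit, r2 = r2, scan_p = scan_p,
                    replication_p = NA_real_, deviation_p = NA_real_,
                    beta_hat = NA_real_, gamma_hat = NA_real_,
                    outcome = "undetected", tie = tie, unfittable = FALSE,
                    stringsAsFactors = FALSE)
  if (scan_p >= thresholds[["scan"]]) return(res)

  repl <- sample_cases_controls(panel, causal_snp, model, n_case, n_ctrl,
                                risk_allele = risk_allele, exclude = scan$used)
  rc <- .count_genotypes(panel, repl$case_h1, repl$case_h2, hit)
  ru <- .count_genotypes(panel, repl$ctrl_h1, repl$ctrl_h2, hit)
  res$replication_p <- stats::pchisq(trend_stat(rc, ru), 1L, lower.tail = FALSE)
  if (res$replication_p >= thresholds[["replication"]]) return(res)

  tab <- genotype_counts(as.vector(rc), as.vector(ru))
  dev <- tryCatch({
    fit <- fit_cc_model(tab, "general")
    list(test = deviation_test(tab), fit = fit)
  }, distortgwas_fit_error = function(e) NULL)
  if (is.null(dev)) {
    res$unfittable <- TRUE
    res$outcome <- "assoc_only"
    return(res)
  }
  res$deviation_p <- dev$test$p_value
  res$beta_hat <- dev$fit$coef[["g"]]
  res$gamma_hat <- dev$fit$coef[["h"]]
  res$outcome <- if (res$deviation_p < thresholds[["deviation"]])
    "assoc_plus_deviation" else "assoc_only"
  res
}

#' Run a grid of simulated studies and aggregate the outcomes
#'
#' Runs [run_study()] once per (SNP, risk allele) combination — each
#' allele of each SNP in \code{snp_set} in turn presumed causal — with
#' per-study seeds derived reproducibly from \code{seed}, and aggregates
#' the three-way outcome distribution.
#'
#' @param panel A haplotype panel.
#' @param model A [general_model()] applied at every presumed causal SNP.
#' @param snp_set SNP indices to presume causal (default: all panel
#'   SNPs).
#' @param alleles Risk-allele codings to run per SNP (default both).
#' @param n_case,n_ctrl,thresholds,causal_on_chip Passed to [run_study()].
#' @param seed Master seed for the experiment.
#' @param out_prefix Optional path prefix; if given, per-study, aggregate
#'   and LD-binned tables are written as TSV
#'   (\code{<prefix>_outcomes.tsv}, \code{_aggregate.tsv}, \code{_by_ld.tsv}).
#' @return List of class \code{"gwas_experiment"}: \code{outcomes} (one
#'   row per study), \code{aggregate} (see [aggregate_outcomes()]),
#'   \code{by_ld} (see [outcome_by_ld_bins()]).
#' @export
run_experiment <- function(panel, model, snp_set = NULL, alleles = c(1L, 0L),
                           n_case = 2000, n_ctrl = 2000,
                           thresholds = default_thresholds(),
                           causal_on_chip = "panel", seed = 1L,
                           out_prefix = NULL) {
  if (is.null(snp_set)) snp_set <- seq_len(ncol(panel$haplotypes))
  grid <- expand.grid(snp = snp_set, allele = alleles)
  set.seed(seed)
  study_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    rows[[i]] <- tryCatch(
      run_study(panel, grid$snp[i], model, n_case = n_case, n_ctrl = n_ctrl,
                thresholds = thresholds, risk_allele = grid$allele[i],
                causal_on_chip = causal_on_chip, seed = study_seeds[i]),
      distortgwas_sample_error = function(e) NULL)
    if (is.null(rows[[i]])) {
      rows[[i]] <- data.frame(causal_snp = grid$snp[i],
                              risk_allele = grid$allele[i],
                              hit_snp = NA_integer_, r2 = NA_real_,
                              scan_p = NA_real_, replication_p = NA_real_,
                              deviation_p = NA_real_, beta_hat = NA_real_,
                              gamma_hat = NA_real_, outcome = "failed",
                              tie = FALSE, unfittable = FALSE,
                              stringsAsFactors = FALSE)
    }
  }
  outcomes <- do.call(rbind, rows)
  res <- structure(list(outcomes = outcomes,
                        aggregate = aggregate_outcomes(outcomes),
                        by_ld = outcome_by_ld_bins(outcomes)),
                   class = "gwas_experiment")
  if (!is.null(out_prefix)) {
    write_tsv_atomic(outcomes, paste0(out_prefix, "_outcomes.tsv"))
    write_tsv_atomic(res$aggregate, paste0(out_prefix, "_aggregate.tsv"))
    write_tsv_atomic(res$by_ld, paste0(out_prefix, "_by_ld.tsv"))
  }
  res
}

#' @export
print.gwas_experiment <- function(x, ...) {
  cat(sprintf("GWAS simulation experiment: %d studies\n", nrow(x$outcomes)))
  print(x$aggregate, row.names = FALSE)
  invisible(x)
}

#' Aggregate study outcomes into a power summary row
#'
#' Percentages of the three outcomes across studies (undetected,
#' association only, association plus deviation) and the deviation
#' detection rate among detected associations.  Studies whose sampling
#' failed (e.g. too few haplotypes of a rare allele class) are excluded
#' from the denominator and counted separately.
#'
#' @param outcomes The \code{outcomes} data.frame from [run_experiment()]
#'   or row-bound [run_study()] results.
#' @return A one-row data.frame with columns \code{n}, \code{n_failed},
#'   \code{pct_undetected}, \code{pct_assoc_only},
#'   \code{pct_assoc_deviation}, \code{deviation_rate_among_assoc}.
#' @export
aggregate_outcomes <- function(outcomes) {
  ok <- outcomes[outcomes$outcome != "failed", , drop = FALSE]
  n <- nrow(ok)
  n_dev <- sum(ok$outcome == "assoc_plus_deviation")
  n_assoc <- n_dev + sum(ok$outcome == "assoc_only")
  data.frame(n = n, n_failed = sum(outcomes$outcome == "failed"),
             pct_undetected = 100 * sum(ok$outcome == "undetected") / n,
             pct_assoc_only = 100 * sum(ok$outcome == "assoc_only") / n,
             pct_assoc_deviation = 100 * n_dev / n,
             deviation_rate_among_assoc =
               if (n_assoc > 0) 100 * n_dev / n_assoc else NA_real_)
}

#' Outcome distribution by LD between causal and hit SNPs
#'
#' Splits studies into bins of width \code{width} on the \eqn{r^2}
#' between the causal and hit SNPs (bins labeled by their upper edge)
#' and tabulates outcome counts, proportions, and the deviation rate
#' among detected associations per bin.  Empty bins are reported with
#' zero counts and \code{NA} proportions.
#'
#' @inheritParams aggregate_outcomes
#' @param width Bin width on the \eqn{r^2} scale.
#' @return A data.frame with one row per bin.
#' @export
outcome_by_ld_bins <- function(outcomes, width = 0.1) {
  ok <- outcomes[outcomes$outcome != "failed" & !is.na(outcomes$r2), ,
                 drop = FALSE]
  edges <- seq(0, 1, by = width)
  bin <- cut(ok$r2, edges, include.lowest = TRUE, labels = FALSE)
  rows <- lapply(seq_len(length(edges) - 1L), function(b) {
    sub <- ok[which(bin == b), , drop = FALSE]
    n <- nrow(sub)
    n_un <- sum(sub$outcome == "undetected")
    n_ao <- sum(sub$outcome == "assoc_only")
    n_ad <- sum(sub$outcome == "assoc_plus_deviation")
    data.frame(r2_upper = edges[b + 1L], n = n,
               n_undetected = n_un, n_assoc_only = n_ao,
               n_assoc_deviation = n_ad,
               prop_undetected = if (n > 0) n_un / n else NA_real_,
               prop_assoc_only = if (n > 0) n_ao / n else NA_real_,
               prop_assoc_deviation = if (n > 0) n_ad / n else NA_real_,
               deviation_rate_among_assoc =
                 if (n_ao + n_ad > 0) n_ad / (n_ao + n_ad) else NA_real_)
  })
  do.call(rbind, rows)
}
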
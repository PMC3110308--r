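test_that("panel generation is reproducible and internally consistent", {
  p1 <- generate_panel(400, 40, region_bp = 2e5, seed = 5)
  p2 <- generate_panel(400, 40, region_bp = 2e5, seed = 5)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_identical(p1$chip_mask, p2$chip_mask)
  expect_equal(p1$freqs, colMeans(p1$haplotypes))
  expect_true(any(p1$chip_mask))
  maf <- pmin(p1$freqs, 1 - p1$freqs)
  expect_true(all(maf[p1$chip_mask] >= 0.05))
  expect_error(generate_panel(401, 40), "n_hap")
})

test_that("LD strength tracks the decay scale and falls with distance", {
  # near-zero decay scale: adjacent SNPs essentially independent
  p <- generate_panel(4000, 30, region_bp = 3e5, ld_scale = 1, seed = 9)
  r2_adj <- sapply(2:30, function(j) panel_r2(p, j - 1, j))
  expect_lt(mean(r2_adj, na.rm = TRUE), 0.05)
  # huge decay scale: adjacent SNPs near-copies
  p <- generate_panel(4000, 30, region_bp = 3e5, ld_scale = 1e9, seed = 9)
  r2_adj <- sapply(2:30, function(j) panel_r2(p, j - 1, j))
  expect_gt(mean(r2_adj, na.rm = TRUE), 0.9)
  # mean pairwise r^2 decreases across distance bins
  p <- generate_panel(6000, 150, region_bp = 1e6, ld_scale = 5e4, seed = 13)
  pairs <- t(combn(seq(1, 150, by = 5), 2))
  d <- abs(p$positions[pairs[, 1]] - p$positions[pairs[, 2]])
  r2 <- mapply(function(i, j) panel_r2(p, i, j), pairs[, 1], pairs[, 2])
  bins <- cut(d, c(0, 3e4, 1e5, 1e6))
  means <- tapply(r2, bins, mean, na.rm = TRUE)
  expect_true(all(diff(means) < 0))
})

test_that("case ascertainment follows the genotype-weight law", {
  p <- generate_panel(20000, 10, region_bp = 1e5, ld_scale = 2e4, seed = 17)
  causal <- which.min(abs(p$freqs - 0.3))[1]
  f <- p$freqs[causal]
  # null model: case and control genotype distributions agree
  set.seed(19)
  s <- sample_cases_controls(p, causal, general_model(0, 0), 2000, 2000)
  g_case <- tabulate(p$haplotypes[s$case_h1, causal] +
                     p$haplotypes[s$case_h2, causal] + 1L, 3L)
  g_ctrl <- tabulate(p$haplotypes[s$ctrl_h1, causal] +
                     p$haplotypes[s$ctrl_h2, causal] + 1L, 3L)
  expect_gt(suppressWarnings(chisq.test(rbind(g_case, g_ctrl)))$p.value, 1e-3)
  # recessive model: heterozygote case share matches the 2f(1-f)/Z weight
  rec <- model_from_hom_rr("recessive", 2^2)
  w <- c((1 - f)^2, 2 * f * (1 - f), f^2 * 4)
  set.seed(23)
  het <- replicate(20, {
    s <- sample_cases_controls(p, causal, rec, 1000, 0)
    mean(s$case_genotypes == 1)
  })
  expect_lt(abs(mean(het) - w[2] / sum(w)),
            3 * sd(het) / sqrt(20) + 1e-3)
  # risk allele enrichment in cases for positive effects
  dom <- model_from_hom_rr("dominant", 1.5^2)
  set.seed(29)
  enrich <- replicate(20, {
    s <- sample_cases_controls(p, causal, dom, 1000, 1000)
    mean(p$haplotypes[c(s$case_h1, s$case_h2), causal]) -
      mean(p$haplotypes[c(s$ctrl_h1, s$ctrl_h2), causal])
  })
  expect_gt(mean(enrich), 0)
  # draws are without replacement and respect exclusions
  set.seed(31)
  s1 <- sample_cases_controls(p, causal, dom, 500, 500)
  expect_false(anyDuplicated(s1$used) > 0)
  s2 <- sample_cases_controls(p, causal, dom, 500, 500, exclude = s1$used)
  expect_length(intersect(s1$used, s2$used), 0)
  # insufficient haplotypes raise the classed sampling error
  expect_error(sample_cases_controls(p, causal, dom, 6000, 6000),
               class = "distortgwas_sample_error")
})

test_that("study outcomes are deterministic given the seed", {
  p <- generate_panel(12000, 60, region_bp = 3e5, ld_scale = 5e4, seed = 37)
  m <- model_from_hom_rr("dominant", 1.4^2)
  o1 <- run_study(p, 10, m, n_case = 1000, n_ctrl = 1000, seed = 41)
  o2 <- run_study(p, 10, m, n_case = 1000, n_ctrl = 1000, seed = 41)
  expect_identical(o1, o2)
  e1 <- run_experiment(p, m, snp_set = c(5, 20, 40), n_case = 1000,
                       n_ctrl = 1000, seed = 43)
  e2 <- run_experiment(p, m, snp_set = c(5, 20, 40), n_case = 1000,
                       n_ctrl = 1000, seed = 43)
  expect_identical(e1$outcomes, e2$outcomes)
})

test_that("a strong on-chip causal SNP is detected; a null model is not", {
  p <- generate_panel(30000, 60, region_bp = 3e5, ld_scale = 5e4, seed = 47)
  causal <- which.min(abs(p$freqs - 0.3))[1]
  strong <- model_from_hom_rr("multiplicative", 2^2)
  # analytic power at the causal SNP itself is essentially 1
  nc <- ncp_trend(strong, p$freqs[causal], study_design(4000))
  expect_gt(power_from_ncp(nc, 1e-6), 0.999)
  for (seed in 1:3) {
    o <- run_study(p, causal, strong, causal_on_chip = "include", seed = seed)
    expect_true(o$outcome != "undetected")
    expect_equal(o$r2, 1, tolerance = 1e-9)
  }
  null <- general_model(0, 0)
  outs <- sapply(1:8, function(seed)
    run_study(p, causal, null, seed = seed)$outcome)
  expect_true(all(outs == "undetected"))
})

test_that("experiment aggregation percentages are complete and LD bins consistent", {
  p <- generate_panel(16000, 50, region_bp = 2.5e5, ld_scale = 5e4, seed = 53)
  m <- model_from_hom_rr("dominant", 1.5^2)
  ex <- run_experiment(p, m, snp_set = seq(2, 50, by = 4), n_case = 1000,
                       n_ctrl = 1000, seed = 59)
  agg <- ex$aggregate
  expect_equal(agg$pct_undetected + agg$pct_assoc_only + agg$pct_assoc_deviation,
               100, tolerance = 1e-9)
  expect_equal(agg$n + agg$n_failed, nrow(ex$outcomes))
  bins <- ex$by_ld
  nonempty <- bins[bins$n > 0, ]
  expect_equal(nonempty$prop_undetected + nonempty$prop_assoc_only +
                 nonempty$prop_assoc_deviation, rep(1, nrow(nonempty)))
  empty <- bins[bins$n == 0, ]
  expect_true(all(is.na(empty$prop_undetected)))
  expect_true(all(empty$n_undetected == 0))
  expect_equal(sum(bins$n), sum(!is.na(ex$outcomes$r2) &
                                  ex$outcomes$outcome != "failed"))
})

test_that("deviation detection among detected associations declines with falling LD", {
  # dominant truth: the dominance signal decays as r^4 while the additive
  # signal decays as r^2, so detected associations at low r^2 should show
  # deviation less often (checked with a wide qualitative tolerance)
  p <- generate_panel(40000, 250, seed = 101)
  ex <- run_experiment(p, model_from_hom_rr("dominant", 1.4^2), seed = 203)
  det <- ex$outcomes[ex$outcomes$outcome %in%
                       c("assoc_only", "assoc_plus_deviation") &
                       !is.na(ex$outcomes$r2), ]
  high <- det[det$r2 > 0.7, ]
  low <- det[det$r2 <= 0.7 & det$r2 > 0.1, ]
  expect_gt(nrow(high), 30)
  expect_gt(nrow(low), 10)
  rate <- function(d) mean(d$outcome == "assoc_plus_deviation")
  expect_gt(rate(high), rate(low))
})
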
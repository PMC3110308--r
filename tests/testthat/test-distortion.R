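test_that("marker penetrances flatten at r = 0 and copy the causal model at r = 1", {
  m <- model_from_hom_rr("dominant", 1.4^2)
  # no LD: marker carries no signal, all penetrances equal the mean risk
  pB <- marker_penetrances(m, two_locus_ld(0.3, 0.4, 0))
  mean_risk <- sum(dbinom(0:2, 2, 0.3) * penetrances(m))
  expect_equal(unname(pB), rep(mean_risk, 3), tolerance = 1e-12)
  # perfect LD with equal frequencies: marker = causal
  pB <- marker_penetrances(m, two_locus_ld(0.3, 0.3, 1))
  expect_equal(unname(pB), unname(penetrances(m)), tolerance = 1e-12)
})

test_that("second differences scale exactly by (q1 - q0)^2 and mean risk is conserved", {
  # oracle: mix penetrances through the 9-cell diplotype table directly
  mix_oracle <- function(m, ld) {
    joint <- diplotype_distribution(ld)
    pA <- penetrances(m)
    sapply(1:3, function(g) sum(joint[, g] * pA) / sum(joint[, g]))
  }
  set.seed(23)
  lds <- rand_ld(1000)
  models <- rand_model(1000, beta_max = log(2))
  for (i in seq_len(1000)) {
    ld <- lds[[i]]; m <- models[[i]]
    pA <- penetrances(m)
    pB <- marker_penetrances(m, ld)
    expect_equal(unname(pB), mix_oracle(m, ld), tolerance = 1e-12)
    q <- conditional_probs(ld)
    expect_lt(abs((pB[["p2"]] - 2 * pB[["p1"]] + pB[["p0"]]) -
                    (q[["q1"]] - q[["q0"]])^2 *
                      (pA[["p2"]] - 2 * pA[["p1"]] + pA[["p0"]])),
              1e-12)
    expect_equal(sum(dbinom(0:2, 2, ld$f_B) * pB),
                 sum(dbinom(0:2, 2, ld$f_A) * pA), tolerance = 1e-12)
  }
})

test_that("exact marker model inverts the marker penetrances", {
  set.seed(29)
  lds <- rand_ld(100)
  models <- rand_model(100)
  for (i in seq_len(100)) {
    mm <- marker_model(models[[i]], lds[[i]])
    expect_equal(unname(penetrances(mm)),
                 unname(marker_penetrances(models[[i]], lds[[i]])),
                 tolerance = 1e-12)
  }
  # causal parameters recovered at r = 1, f_A = f_B
  m <- model_from_hom_rr("recessive", 1.5^2)
  mm <- marker_model(m, two_locus_ld(0.25, 0.25, 1))
  expect_equal(c(mm$beta, mm$gamma), c(m$beta, m$gamma), tolerance = 1e-10)
})

test_that("a multiplicative causal model stays nearly multiplicative at markers", {
  m <- model_from_hom_rr("multiplicative", 1.4^2)
  for (r in seq(0.05, 0.95, by = 0.1))
    for (f in seq(0.05, 0.95, by = 0.15)) {
      b <- r_bounds(f, 0.3)
      if (r > b[["r_max"]]) next
      mm <- marker_model(m, two_locus_ld(f, 0.3, r))
      expect_lt(abs(mm$gamma), 1e-2)
    }
})

test_that("dominant marker parameters shrink to zero monotonically as |r| decreases", {
  m <- model_from_hom_rr("dominant", 1.4^2)
  rs <- seq(0.95, 0.05, by = -0.1)
  par <- t(sapply(rs, function(r) {
    mm <- marker_model(m, two_locus_ld(0.3, 0.3, r))
    c(mm$beta, mm$gamma)
  }))
  expect_true(all(diff(par[, 1]) < 0))
  expect_true(all(diff(par[, 2]) < 0))
  expect_true(all(par > 0))
})

test_that("linear/quadratic approximation matches the exact computation for small effects", {
  # r = 0 gives the null
  m <- model_from_hom_rr("dominant", 1.1^2)
  expect_equal(unname(approx_marker_params(m, two_locus_ld(0.3, 0.3, 0))),
               c(0, 0))
  # small dominant effect: gamma within 5% of exact; beta within 5% once
  # the same-order dominance leakage c(1 - q0 - q1) gamma is accounted
  # for (the linear beta law itself is derived for multiplicative truths)
  ld <- two_locus_ld(0.3, 0.3, 0.8)
  ap <- approx_marker_params(m, ld)
  mm <- marker_model(m, ld)
  expect_equal(ap[["gamma"]], mm$gamma, tolerance = 0.05)
  q <- conditional_probs(ld)
  leak <- (q[["q1"]] - q[["q0"]]) * (1 - q[["q0"]] - q[["q1"]]) * m$gamma
  expect_equal(ap[["beta"]] + leak, mm$beta, tolerance = 0.05)
  # for a multiplicative truth the linear law itself is accurate
  mult <- model_from_hom_rr("multiplicative", 1.1^2)
  expect_equal(approx_marker_params(mult, ld)[["beta"]],
               marker_model(mult, ld)$beta, tolerance = 0.05)
  # gamma ratio is the square of the beta ratio (equal frequencies)
  expect_equal(ap[["gamma"]] / m$gamma, (ap[["beta"]] / m$beta)^2,
               tolerance = 1e-12)
  # approximation error vanishes along a shrinking-effect ladder
  rel_err <- sapply(c(1.4^2, 1.2^2, 1.1^2, 1.05^2), function(rr) {
    m <- model_from_hom_rr("dominant", rr)
    ap <- approx_marker_params(m, ld); mm <- marker_model(m, ld)
    abs(ap[["gamma"]] - mm$gamma) / abs(mm$gamma)
  })
  expect_true(all(diff(rel_err) < 0))
  expect_lt(rel_err[4], 0.01)
})

test_that("interaction distortion obeys the determinant law and the (q1-q0)(q1'-q0') decay", {
  # tau = 0 stays exactly 0 under any LD
  m0 <- interaction_model(0.2, -0.1, 0)
  mm0 <- marker_interaction(m0, two_locus_ld(0.2, 0.3, 0.5),
                            two_locus_ld(0.4, 0.4, 0.7))
  expect_equal(mm0$tau, 0, tolerance = 1e-12)
  # no LD at either locus kills the interaction
  mm <- marker_interaction(interaction_model(0.1, 0.1, 0.3),
                           two_locus_ld(0.3, 0.3, 0),
                           two_locus_ld(0.3, 0.3, 0))
  expect_equal(mm$tau, 0, tolerance = 1e-12)
  # small tau: marker tau ~ (q1-q0)(q1'-q0') tau within 5%
  tau <- log(1.1)
  ld1 <- two_locus_ld(0.3, 0.35, 0.7); ld2 <- two_locus_ld(0.4, 0.3, 0.55)
  cc1 <- diff(conditional_probs(ld1)); cc2 <- diff(conditional_probs(ld2))
  mm <- marker_interaction(interaction_model(0.05, 0.05, tau), ld1, ld2)
  expect_equal(mm$tau, unname(cc1 * cc2) * tau, tolerance = 0.05)
  # exact determinant scaling over 1,000 random scenarios
  set.seed(31)
  lds1 <- rand_ld(1000); lds2 <- rand_ld(1000)
  for (i in seq_len(1000)) {
    m <- interaction_model(runif(1, -0.5, 0.5), runif(1, -0.5, 0.5),
                           runif(1, -0.5, 0.5))
    P_A <- interaction_penetrance_matrix(m)
    P_B <- interaction_penetrance_matrix(marker_interaction(m, lds1[[i]], lds2[[i]]))
    c1 <- diff(conditional_probs(lds1[[i]]))
    c2 <- diff(conditional_probs(lds2[[i]]))
    expect_lt(abs(det(P_B) - unname(c1 * c2) * det(P_A)), 1e-12)
  }
})

test_that("effective additive parameter equals beta for multiplicative truths", {
  for (f in seq(0.05, 0.95, by = 0.1)) {
    bp <- effective_additive(model_from_hom_rr("multiplicative", 1.4^2), f)
    expect_equal(bp, log(1.4), tolerance = 1e-8)
  }
  expect_equal(effective_additive(general_model(0, 0), 0.3), 0,
               tolerance = 1e-10)
})

test_that("dominant/recessive effective parameters reach the doubled-effect limits", {
  rec <- model_from_hom_rr("recessive", 1.4^2)   # hom RR 1.96
  # rare risk allele: genotypes 0 and 1 dominate and share one risk
  expect_equal(effective_additive(rec, 1e-3), 0, tolerance = 1e-3)
  # near-fixed risk allele: genotypes 1 and 2 dominate, differing by the
  # full homozygous effect per single allele step: double the matched
  # multiplicative model's log(1.4)
  expect_equal(effective_additive(rec, 1 - 1e-3), log(1.96), tolerance = 1e-2)
  dom <- model_from_hom_rr("dominant", 1.4^2)
  expect_equal(effective_additive(dom, 1 - 1e-3), 0, tolerance = 1e-2)
  expect_equal(effective_additive(dom, 1e-3), log(1.96), tolerance = 1e-2)
  # the limits bracket a monotone trajectory for the recessive model
  grid <- sapply(c(0.05, 0.25, 0.5, 0.75, 0.95),
                 function(f) effective_additive(rec, f))
  expect_true(all(diff(grid) > 0))
})

test_that("model-space trajectories bend toward the multiplicative line", {
  dom <- model_from_hom_rr("dominant", 1.4^2)
  expect_equal(model_space_trajectory(dom, 0.3, 0.3, 0)[, c("beta", "gamma")],
               data.frame(beta = 0, gamma = 0))
  tr <- model_space_trajectory(dom, 0.3, 0.3, seq(0.1, 1, by = 0.1))
  # |gamma/beta| non-increasing as |r| decreases
  ratio <- abs(tr$gamma / tr$beta)
  expect_true(all(diff(ratio) >= -1e-10))
  expect_equal(tr$beta[10], dom$beta, tolerance = 1e-10)
  expect_equal(tr$gamma[10], dom$gamma, tolerance = 1e-10)
  # recessive curves stay below the multiplicative line
  rec <- model_from_hom_rr("recessive", 1.4^2)
  tr <- model_space_trajectory(rec, 0.25, 0.35, seq(0.1, 0.7, by = 0.1))
  expect_true(all(tr$gamma <= 0))
  # distortion toward multiplicativity for matched frequencies, both kinds
  set.seed(37)
  for (i in 1:50) {
    f <- runif(1, 0.1, 0.9); r <- runif(1, 0.05, 0.95)
    m <- if (i %% 2) dom else rec
    mm <- marker_model(m, two_locus_ld(f, f, r))
    expect_lte(abs(mm$gamma) / abs(mm$beta),
               abs(m$gamma) / abs(m$beta) + 1e-10)
  }
})
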
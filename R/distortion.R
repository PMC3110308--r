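#' Penetrances observed at a marker SNP
#'
#' Given a causal-SNP disease model and the LD between the causal SNP A and
#' a marker SNP B, computes the penetrances at the marker by mixing over
#' the conditional genotype law:
#' \deqn{p_B(g) = \sum_{g_A} \Pr(G_A = g_A \mid G_B = g)\, p_A(g_A).}
#' Mixing preserves the population mean risk.  The second difference obeys
#' the exact distortion law
#' \eqn{p_{B2} - 2p_{B1} + p_{B0} = (q_1 - q_0)^2 (p_{A2} - 2p_{A1} + p_{A0})},
#' the source of the quadratic decay of dominance effects with LD.
#'
#' @param causal A [general_model()] at the causal SNP.
#' @param ld A [two_locus_ld()] with \code{f_A} the causal and \code{f_B}
#'   the marker allele frequency.
#' @return Named vector \code{c(p0, p1, p2)} of marker penetrances.
#' @export
marker_penetrances <- function(causal, ld) {
  stopifnot(inherits(causal, "general_model"), inherits(ld, "two_locus_ld"))
  p_A <- penetrances(causal)
  p_B <- as.vector(crossprod(genotype_conditional(ld), p_A))
  names(p_B) <- c("p0", "p1", "p2")
  p_B
}

#' Exact disease model at a marker SNP
#'
#' Inverts the marker penetrances into general-model parameters:
#' \deqn{\mu_B = \log p_{B0}, \quad \beta_B = \tfrac12\log(p_{B2}/p_{B0}),
#'  \quad \gamma_B = \log p_{B1} - \mu_B - \beta_B.}
#' Since the general model is saturated for a single SNP this is exact:
#' the returned model reproduces [marker_penetrances()].  At \eqn{r = 0}
#' the marker model is null; at \eqn{r = \pm 1} with matching frequencies
#' it equals the causal model.
#'
#' @inheritParams marker_penetrances
#' @return A [general_model()] holding \eqn{(\mu_B, \beta_B, \gamma_B)}.
#' @examples
#' causal <- model_from_hom_rr("dominant", 1.4^2)
#' marker_model(causal, two_locus_ld(0.3, 0.3, 0.8))
#' @export
marker_model <- function(causal, ld) {
  p <- marker_penetrances(causal, ld)
  if (any(p <= 0)) stop("marker penetrance is zero; cannot take logs")
  mu_B <- log(p[["p0"]])
  beta_B <- 0.5 * log(p[["p2"]] / p[["p0"]])
  gamma_B <- log(p[["p1"]]) - mu_B - beta_B
  general_model(beta = beta_B, gamma = gamma_B, mu = mu_B)
}

#' Small-effect approximation to the marker-SNP parameters
#'
#' For small effects the additive parameter at the marker decays linearly
#' and the dominance parameter quadratically in the mixing factor
#' \eqn{c = q_1 - q_0} (which equals \eqn{r} when \eqn{f_A = f_B}):
#' \deqn{\beta_B \approx c\,\beta_A, \qquad \gamma_B \approx c^2\gamma_A.}
#'
#' @inheritParams marker_penetrances
#' @return Named vector \code{c(beta, gamma)} of approximate marker
#'   parameters.
#' @seealso [marker_model()] for the exact values.
#' @export
approx_marker_params <- function(causal, ld) {
  q <- conditional_probs(ld)
  cc <- q[["q1"]] - q[["q0"]]
  c(beta = cc * causal$beta, gamma = cc^2 * causal$gamma)
}

#' Interaction model observed at a pair of marker SNPs
#'
#' For two causal SNPs tagged by two markers (LD acting independently at
#' each locus pair, the two loci themselves unlinked), the haplotype-level
#' penetrance matrix at the markers is the two-sided mixture
#' \eqn{P_B = M^\top P_A M'} with
#' \eqn{M[a, b] = \Pr(A = a \mid B = b)} built from \eqn{(q_0, q_1)} at each
#' locus.  The mixture satisfies the exact determinant law
#' \eqn{\det P_B = (q_1 - q_0)(q_1' - q_0')\det P_A}, and for small
#' \eqn{\tau} the marker interaction contrast is approximately
#' \eqn{(q_1-q_0)(q_1'-q_0')\,\tau}: interaction effects decay as the
#' product of the per-locus correlations.
#'
#' Because the 2x2 matrix is saturated by the four interaction-model
#' parameters, the result is returned as an exact [interaction_model()];
#' its \code{tau} is the marker interaction parameter
#' \eqn{\tau_B = \log(p_{B11}p_{B00}/(p_{B10}p_{B01}))}.
#'
#' @param causal An [interaction_model()] at the causal pair.
#' @param ld LD between the first causal SNP and its marker.
#' @param ld2 LD between the second causal SNP and its marker.
#' @return An [interaction_model()] reproducing the marker penetrance
#'   matrix exactly.
#' @export
marker_interaction <- function(causal, ld, ld2) {
  stopifnot(inherits(causal, "interaction_model"),
            inherits(ld, "two_locus_ld"), inherits(ld2, "two_locus_ld"))
  P_A <- interaction_penetrance_matrix(causal)
  P_B <- t(.mixing_matrix(ld)) %*% P_A %*% .mixing_matrix(ld2)
  if (any(P_B <= 0)) stop("marker penetrance is zero; cannot take logs")
  interaction_model(mu = log(P_B[1, 1]),
                    beta1 = log(P_B[2, 1]) - log(P_B[1, 1]),
                    beta2 = log(P_B[1, 2]) - log(P_B[1, 1]),
                    tau = log_cross_ratio(P_B))
}

# M[a, b] = Pr(A = a | B = b); det(M) = q1 - q0
.mixing_matrix <- function(ld) {
  q <- conditional_probs(ld)
  matrix(c(1 - q[["q0"]], q[["q0"]], 1 - q[["q1"]], q[["q1"]]), 2, 2)
}

#' Effective additive parameter beta-prime
#'
#' The large-sample additive coefficient obtained when the multiplicative
#' model is fitted (by logistic regression) to case-control data generated
#' by an arbitrary single-SNP truth.  Computed by fitting to the
#' theoretical genotype frequencies, treated as sample counts: cases carry
#' frequency proportional to \eqn{\Pr(G = g)\,p(g)}, controls the cohort
#' (population) genotype frequencies, weighted \eqn{\phi : 1-\phi}.
#' With cohort controls the logistic fit coincides with the log-risk
#' model, so for a multiplicative truth \eqn{\beta' = \beta} exactly, at
#' every risk allele frequency.
#'
#' @param model A [general_model()] describing the truth at the SNP.
#' @param f Risk allele frequency at the SNP, in (0, 1).
#' @param phi Proportion of cases in the sample (default 0.5, equal
#'   numbers of cases and controls).
#' @return The effective additive parameter \eqn{\beta'} (log scale).
#' @examples
#' effective_additive(model_from_hom_rr("multiplicative", 1.4^2), f = 0.3)
#' log(1.4)
#' @export
effective_additive <- function(model, f, phi = 0.5) {
  fr <- cc_genotype_freqs(model, f, phi)
  fit <- cc_logit_fit(fr$case, fr$control, cbind(1, 0:2), phi)
  unname(fit$coef[2])
}

#' Marker-model trajectory through model space
#'
#' Traces the exact marker-SNP disease model \eqn{(\beta_B, \gamma_B)} as a
#' function of \eqn{r} for fixed allele frequencies — the data behind a
#' model-space plot.  As \eqn{|r|} decreases the points move toward the
#' origin and bend toward the multiplicative (\eqn{\gamma = 0}) line:
#' LD distorts every model toward multiplicativity.
#'
#' @param causal A [general_model()] at the causal SNP.
#' @param f_A,f_B Causal and marker risk allele frequencies.
#' @param r_grid Vector of correlations, each feasible for
#'   \code{(f_A, f_B)}.
#' @param phi Case proportion used for the effective additive parameter.
#' @return A data.frame with columns \code{r}, \code{beta}, \code{gamma},
#'   \code{beta_eff}.
#' @export
model_space_trajectory <- function(causal, f_A, f_B, r_grid, phi = 0.5) {
  rows <- lapply(r_grid, function(r) {
    if (r == 0) {
      data.frame(r = r, beta = 0, gamma = 0, beta_eff = 0)
    } else {
      mm <- marker_model(causal, two_locus_ld(f_A, f_B, r))
      data.frame(r = r, beta = mm$beta, gamma = mm$gamma,
                 beta_eff = effective_additive(mm, f_B, phi))
    }
  })
  do.call(rbind, rows)
}
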
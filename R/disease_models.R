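#' General single-SNP log-risk disease model
#'
#' The disease risk given genotype \eqn{G \in \{0,1,2\}} (count of allele 1)
#' follows the log-risk regression
#' \deqn{\log p(G) = \mu + \beta G + \gamma \, 1\{G = 1\},}
#' where \eqn{\mu} is the baseline log risk, \eqn{\beta} the additive
#' (per-allele, log-scale) parameter, and \eqn{\gamma} the dominance
#' parameter measuring deviation from a multiplicative model at the
#' heterozygote.  Special cases: \eqn{\gamma = 0} multiplicative,
#' \eqn{\gamma = \beta} dominant, \eqn{\gamma = -\beta} recessive.
#'
#' With cohort (population) controls, analysing a case-control sample by
#' logistic regression is equivalent to fitting this log-risk model, and
#' for low prevalence the two links agree closely; the log-risk form is
#' used for all penetrance-level computations.  The baseline \eqn{\mu}
#' is not identifiable from case-control data; it is carried explicitly
#' (default prevalence-scale \code{log(0.01)}) so that penetrances are
#' well defined, and all results of interest are free of it.
#'
#' @param beta Additive parameter (log relative risk per allele).
#' @param gamma Dominance parameter (heterozygote log-risk deviation).
#' @param mu Baseline log risk; default \code{log(0.01)}.
#' @return An object of class \code{"general_model"}.
#' @examples
#' m <- general_model(beta = log(1.4), gamma = log(1.4))  # dominant
#' penetrances(m)
#' genotype_relative_risks(m)
#' @export
general_model <- function(beta, gamma = 0, mu = log(0.01)) {
  stopifnot(is.finite(beta), is.finite(gamma), is.finite(mu))
  m <- structure(list(mu = mu, beta = beta, gamma = gamma),
                 class = "general_model")
  .check_penetrances(penetrances(m))
  m
}

.check_penetrances <- function(p) {
  if (any(p > 1 + 1e-12))
    stop("invalid model: a penetrance exceeds 1; lower mu or the effect sizes")
  invisible(p)
}

#' @export
print.general_model <- function(x, ...) {
  kind <- model_kind(x)
  cat(sprintf("General disease model (%s): mu = %.4g, beta = %.4g, gamma = %.4g\n",
              kind, x$mu, x$beta, x$gamma))
  cat(sprintf("  genotype RRs (vs genotype 0): alpha1 = %.4g, alpha2 = %.4g\n",
              exp(x$beta + x$gamma), exp(2 * x$beta)))
  invisible(x)
}

#' Classify a general model as multiplicative/dominant/recessive/general
#'
#' @param model A [general_model()].
#' @param tol Tolerance for comparing \code{gamma} with \code{0, beta, -beta}.
#' @return A character scalar.
#' @export
model_kind <- function(model, tol = 1e-8) {
  g <- model$gamma; b <- model$beta
  if (abs(g) <= tol) "multiplicative"
  else if (abs(g - b) <= tol) "dominant"
  else if (abs(g + b) <= tol) "recessive"
  else "general"
}

#' Genotype penetrances of a disease model
#'
#' @param model A [general_model()] or [interaction_model()].
#' @param ... Unused.
#' @return For a single-SNP model, the vector
#'   \code{c(p0, p1, p2)} of \eqn{\Pr(Y=1 \mid G=g)}; for an interaction
#'   model, a 2x2 per-haplotype penetrance-factor matrix (see
#'   [interaction_penetrance_matrix()]).
#' @export
penetrances <- function(model, ...) UseMethod("penetrances")

#' @export
penetrances.general_model <- function(model, ...) {
  c(p0 = exp(model$mu),
    p1 = exp(model$mu + model$beta + model$gamma),
    p2 = exp(model$mu + 2 * model$beta))
}

#' @export
penetrances.interaction_model <- function(model, ...)
  interaction_penetrance_matrix(model)

#' Genotype relative risks
#'
#' The relative risks \eqn{\alpha_1 = e^{\beta+\gamma}} and
#' \eqn{\alpha_2 = e^{2\beta}} of genotypes 1 and 2 relative to genotype 0.
#' These are the weights used when ascertaining case genotypes in the
#' simulation engine.
#'
#' @param model A [general_model()].
#' @return Named vector \code{c(alpha1, alpha2)}.
#' @export
genotype_relative_risks <- function(model) {
  c(alpha1 = exp(model$beta + model$gamma), alpha2 = exp(2 * model$beta))
}

#' Genotype odds ratios implied by a log-risk model
#'
#' Odds of disease at each genotype relative to genotype 0.  For small
#' baseline risk these approach the relative risks
#' [genotype_relative_risks()]; the comparison quantifies the agreement
#' between the logistic and log-risk links at low prevalence.
#'
#' @param model A [general_model()].
#' @return Named vector \code{c(or1, or2)}.
#' @export
genotype_odds_ratios <- function(model) {
  p <- penetrances(model)
  odds <- p / (1 - p)
  c(or1 = unname(odds[2] / odds[1]), or2 = unname(odds[3] / odds[1]))
}

#' Construct a model from its homozygous relative risk
#'
#' Standard effect-size scale for simulation scenarios: the homozygous RR
#' compares genotype 2 to genotype 0, so \eqn{\beta = \log(\mathrm{RR_{hom}})/2},
#' with \eqn{\gamma = 0}, \eqn{+\beta} or \eqn{-\beta} for the
#' multiplicative, dominant and recessive kinds.
#'
#' @param kind One of \code{"multiplicative"}, \code{"dominant"},
#'   \code{"recessive"}.
#' @param hom_rr Homozygous relative risk (> 0), e.g. \code{1.4^2}.
#' @param mu Baseline log risk.
#' @return A [general_model()].
#' @examples
#' model_from_hom_rr("dominant", 1.4^2)  # beta = gamma = log(1.4)
#' @export
model_from_hom_rr <- function(kind = c("multiplicative", "dominant", "recessive"),
                              hom_rr, mu = log(0.01)) {
  kind <- match.arg(kind)
  stopifnot(hom_rr > 0)
  beta <- 0.5 * log(hom_rr)
  gamma <- switch(kind, multiplicative = 0, dominant = beta, recessive = -beta)
  general_model(beta = beta, gamma = gamma, mu = mu)
}

#' Two-SNP interaction disease model
#'
#' The simplest statistical interaction between two SNPs: a log-risk model
#' with per-allele additive effects and a single additive interaction
#' parameter \eqn{\tau}.  The model is naturally defined per haplotype:
#' a haplotype carrying alleles \eqn{(a, a')} at the two SNPs contributes
#' a factor \eqn{\exp(\mu + a\beta_1 + a'\beta_2 + a a' \tau)} (with
#' \eqn{\mu} split across an individual's two haplotypes), so that
#' \eqn{\tau = 0} recovers the two-SNP multiplicative model.
#'
#' @param beta1,beta2 Per-allele additive parameters at the two SNPs.
#' @param tau Additive interaction parameter (log scale).
#' @param mu Baseline log risk.
#' @return An object of class \code{"interaction_model"}.
#' @export
interaction_model <- function(beta1, beta2, tau, mu = log(0.01)) {
  stopifnot(is.finite(beta1), is.finite(beta2), is.finite(tau), is.finite(mu))
  m <- structure(list(mu = mu, beta1 = beta1, beta2 = beta2, tau = tau),
                 class = "interaction_model")
  .check_penetrances(interaction_penetrance_matrix(m))
  m
}

#' @export
print.interaction_model <- function(x, ...) {
  cat(sprintf(
    "Two-SNP interaction model: mu = %.4g, beta1 = %.4g, beta2 = %.4g, tau = %.4g\n",
    x$mu, x$beta1, x$beta2, x$tau))
  invisible(x)
}

#' Haplotype-level penetrance matrix of an interaction model
#'
#' Entry \eqn{(a, a')} is \eqn{\exp(\mu + a\beta_1 + a'\beta_2 + aa'\tau)}
#' for allele pair \eqn{(a, a') \in \{0,1\}^2} at the two SNPs.  The
#' log cross-ratio \eqn{\log(p_{11}p_{00}/(p_{10}p_{01}))} of this matrix
#' equals \eqn{\tau}, and its determinant is exactly 0 when \eqn{\tau = 0}.
#'
#' @param model An [interaction_model()].
#' @return A 2x2 matrix with rows indexing the allele at the first SNP
#'   and columns at the second.
#' @export
interaction_penetrance_matrix <- function(model) {
  a <- 0:1
  m <- outer(a, a, function(x, y)
    exp(model$mu + x * model$beta1 + y * model$beta2 + x * y * model$tau))
  dimnames(m) <- list(a = 0:1, a_prime = 0:1)
  m
}

#' Log cross-ratio of a 2x2 penetrance matrix
#'
#' The interaction contrast \eqn{\log(p_{11}p_{00}/(p_{10}p_{01}))};
#' equals \eqn{\tau} for an [interaction_model()] and 0 for any two-SNP
#' multiplicative model.
#'
#' @param p A 2x2 positive matrix.
#' @return Numeric scalar.
#' @export
log_cross_ratio <- function(p) {
  stopifnot(is.matrix(p), all(dim(p) == 2), all(p > 0))
  log(p[2, 2]) + log(p[1, 1]) - log(p[2, 1]) - log(p[1, 2])
}
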
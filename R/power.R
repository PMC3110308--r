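#' Case-control study design
#'
#' @param n_total Total number of individuals genotyped.
#' @param phi Proportion of cases in the sample, in (0, 1); default 0.5.
#' @return An object of class \code{"study_design"} with elements
#'   \code{n_total}, \code{phi}, \code{n_case}, \code{n_control}.
#' @export
study_design <- function(n_total, phi = 0.5) {
  stopifnot(n_total > 0, phi > 0, phi < 1)
  structure(list(n_total = n_total, phi = phi,
                 n_case = round(n_total * phi),
                 n_control = n_total - round(n_total * phi)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Case-control design: N = %d (%d cases, %d controls; phi = %g)\n",
              x$n_total, x$n_case, x$n_control, x$phi))
  invisible(x)
}

#' Theoretical case and control genotype frequencies at a SNP
#'
#' Under HWE with risk allele frequency \code{f} and a single-SNP truth,
#' case genotype frequencies are proportional to
#' \eqn{\Pr(G = g)\,p(g)}; controls are an unphenotyped cohort sample, so
#' their genotype frequencies are the population (HWE) ones.
#'
#' @param model A [general_model()] (or any object for which
#'   [penetrances()] returns three values).
#' @param f Risk allele frequency in (0, 1).
#' @param phi Case proportion (recorded in the result; the frequencies
#'   themselves are per-phenotype distributions).
#' @return List with elements \code{case}, \code{control} (each a
#'   probability vector over genotypes 0:2) and \code{phi}.
#' @export
cc_genotype_freqs <- function(model, f, phi = 0.5) {
  stopifnot(f > 0, f < 1)
  pop <- stats::dbinom(0:2, 2, f)
  p <- penetrances(model)
  list(case = pop * p / sum(pop * p), control = pop, phi = phi)
}

# Weighted logistic fit of a linear logit model to theoretical
# case/control cell frequencies treated as fractional counts.
# X: one row per cell; case_freq/ctrl_freq: per-phenotype cell
# probabilities.  Returns the population-limit coefficients and the
# per-individual expected-information covariance (weights sum to 1).
cc_logit_fit <- function(case_freq, ctrl_freq, X, phi = 0.5) {
  stopifnot(length(case_freq) == nrow(X), length(ctrl_freq) == nrow(X))
  w <- c(phi * case_freq, (1 - phi) * ctrl_freq)
  y <- rep(c(1, 0), each = nrow(X))
  XX <- rbind(X, X)
  keep <- w > 0
  if (qr(XX[keep, , drop = FALSE])$rank < ncol(X))
    stop("degenerate cell frequencies: model not identifiable (separation)")
  fit <- suppressWarnings(stats::glm.fit(
    XX[keep, , drop = FALSE], y[keep], weights = w[keep],
    family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-14, maxit = 200)))
  if (!fit$converged) stop("weighted logistic fit did not converge")
  info <- crossprod(XX[keep, , drop = FALSE] * sqrt(fit$weights))
  list(coef = fit$coefficients, vcov = solve(info))
}

#' Noncentrality parameter of the Cochran-Armitage trend test
#'
#' Computes the analytic noncentrality parameter (NCP) of the 1-df trend
#' test at a SNP, for a case-control sample of \code{design$n_total}
#' individuals with case proportion \eqn{\phi}.  The NCP is
#' \eqn{\eta = N (\beta')^2 / v}, where \eqn{\beta'} is the effective
#' additive parameter at the SNP (the population limit of the
#' multiplicative logistic fit; for a multiplicative truth simply
#' \eqn{\beta}) and \eqn{v} is the per-individual asymptotic variance of
#' its estimator from the expected Fisher information at the theoretical
#' case/control genotype frequencies.  The NCP is proportional to
#' \eqn{N\theta^2} for small effects.
#'
#' To evaluate power at a marker SNP, first map the causal model through
#' [marker_model()] and pass the marker model with the marker frequency:
#' for small effects and \eqn{f_A = f_B}, the marker NCP is \eqn{r^2}
#' times the causal NCP — the classical \eqn{N/r^2} sample-size rule.
#'
#' @param model A [general_model()] describing the truth at the tested
#'   SNP (causal model, or the output of [marker_model()]).
#' @param f Risk allele frequency at the tested SNP.
#' @param design A [study_design()].
#' @return An object of class \code{"ncp_result"}: list with \code{ncp},
#'   \code{df}, \code{theta} (the tested parameter's population limit)
#'   and \code{se} (its asymptotic standard error at this design).
#' @examples
#' d <- study_design(4000)
#' ncp_trend(model_from_hom_rr("multiplicative", 1.4^2), f = 0.3, d)
#' @export
ncp_trend <- function(model, f, design) {
  fr <- cc_genotype_freqs(model, f, design$phi)
  .ncp_from_fit(fr$case, fr$control, cbind(1, 0:2), design$phi,
                k = 2L, n_obs = design$n_total)
}

#' Noncentrality parameter of the deviation (dominance) test
#'
#' The 1-df Wald test of \eqn{\gamma = 0} in the general model, testing
#' for deviation from the multiplicative model.  The NCP is
#' \eqn{N\gamma^2/v_\gamma} with \eqn{v_\gamma} the \eqn{\gamma}
#' component of the inverse expected information of the general-model
#' logistic fit (profiling over \eqn{\mu} and \eqn{\beta}).
#'
#' At a marker SNP (pass [marker_model()] output with the marker
#' frequency), for small effects and \eqn{f_A = f_B}, the NCP scales as
#' \eqn{r^4} — an \eqn{N/r^4} sample-size rule, quartic rather than
#' quadratic decay of power with LD.
#'
#' @inheritParams ncp_trend
#' @return An \code{"ncp_result"} (df = 1, theta = \eqn{\gamma} limit).
#' @export
ncp_deviation <- function(model, f, design) {
  fr <- cc_genotype_freqs(model, f, design$phi)
  X <- cbind(1, 0:2, c(0, 1, 0))
  .ncp_from_fit(fr$case, fr$control, X, design$phi,
                k = 3L, n_obs = design$n_total)
}

#' Noncentrality parameter of the two-SNP interaction test
#'
#' The 1-df Wald test of \eqn{\tau = 0} comparing the interaction model
#' with the two-SNP multiplicative model.  Because the interaction model
#' is defined per haplotype and risk factorizes over an individual's two
#' haplotypes, case ascertainment preserves haplotype independence; the
#' computation therefore works at the haplotype level with \eqn{2N}
#' observations over the four allele-pair classes \eqn{(a, a')}.
#'
#' To evaluate at marker SNPs, pass the marker interaction model from
#' [marker_interaction()] with the marker allele frequencies: for small
#' \eqn{\tau} the NCP scales as \eqn{(r r')^2}, giving the
#' \eqn{N/(r r')^2} sample-size rule.
#'
#' @param model An [interaction_model()] at the tested SNP pair.
#' @param f1,f2 Allele frequencies at the two tested SNPs (assumed
#'   mutually unlinked).
#' @param design A [study_design()].
#' @return An \code{"ncp_result"} (df = 1, theta = \eqn{\tau} limit).
#' @export
ncp_interaction <- function(model, f1, f2, design) {
  stopifnot(inherits(model, "interaction_model"), f1 > 0, f1 < 1, f2 > 0, f2 < 1)
  pop <- as.vector(outer(c(1 - f1, f1), c(1 - f2, f2)))      # cells (a, a')
  pen <- as.vector(interaction_penetrance_matrix(model))     # same order
  case <- pop * pen / sum(pop * pen)
  a <- c(0, 1, 0, 1); ap <- c(0, 0, 1, 1)
  X <- cbind(1, a, ap, a * ap)
  .ncp_from_fit(case, pop, X, design$phi, k = 4L, n_obs = 2 * design$n_total)
}

# shared: fit, extract tested coefficient k, scale information by n_obs
.ncp_from_fit <- function(case_freq, ctrl_freq, X, phi, k, n_obs) {
  fit <- cc_logit_fit(case_freq, ctrl_freq, X, phi)
  theta <- unname(fit$coef[k])
  v <- fit$vcov[k, k] / n_obs
  structure(list(ncp = theta^2 / fit$vcov[k, k] * n_obs, df = 1L,
                 theta = theta, se = sqrt(v)),
            class = "ncp_result")
}

#' @export
print.ncp_result <- function(x, alpha = c(5e-8, 1e-6, 0.05), ...) {
  cat(sprintf("Noncentrality: ncp = %.4g (df = %d), theta = %.4g, se = %.4g\n",
              x$ncp, x$df, x$theta, x$se))
  for (a in alpha)
    cat(sprintf("  power at alpha = %g: %.4g\n", a, power_from_ncp(x, a)))
  invisible(x)
}

#' Power of a chi-square test from its noncentrality parameter
#'
#' \eqn{\Pr(\chi^2_{df}(\eta) > q_{1-\alpha})} with \eqn{q_{1-\alpha}}
#' the upper-\eqn{\alpha} quantile of the central chi-square.
#'
#' @param res An \code{"ncp_result"} or a plain numeric NCP.
#' @param alpha Significance level in (0, 1).
#' @param df Degrees of freedom, used only when \code{res} is numeric.
#' @return Power in [0, 1]; equals \code{alpha} when the NCP is 0.
#' @export
power_from_ncp <- function(res, alpha, df = 1L) {
  stopifnot(all(alpha > 0), all(alpha < 1))
  if (inherits(res, "ncp_result")) {
    ncp <- res$ncp; df <- res$df
  } else ncp <- res
  stats::pchisq(stats::qchisq(alpha, df, lower.tail = FALSE),
                df = df, ncp = ncp, lower.tail = FALSE)
}

#' Equivalent sample size at a marker SNP
#'
#' The sample size required at a marker to match the power of a study of
#' size \code{N_A} typing the causal SNP(s) directly:
#' \eqn{N_A/r^2} for the trend test, \eqn{N_A/r^4} for the deviation
#' test, and \eqn{N_A/(r r')^2} for the interaction test.
#'
#' @param test One of \code{"trend"}, \code{"deviation"},
#'   \code{"interaction"}.
#' @param N_A Sample size at the causal SNP(s).
#' @param r Correlation between the (first) causal SNP and its marker;
#'   must be nonzero.
#' @param r2 For the interaction test, the correlation at the second
#'   locus pair.
#' @return The equivalent marker sample size \eqn{N_B}.
#' @examples
#' equivalent_sample_size("deviation", 2000, r = sqrt(0.5))  # 4x
#' @export
equivalent_sample_size <- function(test = c("trend", "deviation", "interaction"),
                                   N_A, r, r2 = NULL) {
  test <- match.arg(test)
  if (r == 0 || (test == "interaction" && (is.null(r2) || r2 == 0)))
    stop("marker uninformative: r = 0 gives no power at any sample size")
  switch(test,
         trend = N_A / r^2,
         deviation = N_A / r^4,
         interaction = N_A / (r * r2)^2)
}
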
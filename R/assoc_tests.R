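#' Genotype count table for case-control association tests
#'
#' Container for observed genotype counts.  Single-SNP variant: counts
#' over genotypes 0/1/2 for cases and controls.  Two-SNP variant: 3x3
#' matrices over the genotype grid \eqn{(G_A, G_B)} per phenotype.
#'
#' @param cases,controls Nonnegative integer count vectors of length 3,
#'   or 3x3 matrices for the two-SNP variant.
#' @return An object of class \code{"genotype_counts"} with attribute
#'   \code{n_snp} (1 or 2).
#' @examples
#' genotype_counts(c(50, 30, 20), c(20, 30, 50))
#' @export
genotype_counts <- function(cases, controls) {
  two <- is.matrix(cases)
  if (two) {
    stopifnot(is.matrix(controls), all(dim(cases) == 3), all(dim(controls) == 3))
  } else {
    stopifnot(length(cases) == 3, length(controls) == 3)
  }
  stopifnot(all(cases >= 0), all(controls >= 0),
            all(cases == round(cases)), all(controls == round(controls)))
  if (sum(cases) == 0 || sum(controls) == 0)
    stop("each phenotype must have at least one individual")
  structure(list(cases = cases, controls = controls),
            class = "genotype_counts", n_snp = if (two) 2L else 1L)
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("Genotype counts (%d SNP%s):\n", attr(x, "n_snp"),
              if (attr(x, "n_snp") > 1) "s" else ""))
  if (attr(x, "n_snp") == 1L) {
    m <- rbind(cases = x$cases, controls = x$controls)
    colnames(m) <- 0:2
    print(m)
  } else {
    cat("cases:\n"); print(x$cases)
    cat("controls:\n"); print(x$controls)
  }
  invisible(x)
}

.new_test_result <- function(statistic, df, estimate = NA_real_,
                             se = NA_real_, method) {
  statistic <- max(0, statistic)
  structure(list(statistic = statistic, df = df,
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
                 estimate = estimate, se = se, method = method),
            class = "assoc_test")
}

#' @export
print.assoc_test <- function(x, ...) {
  cat(sprintf("%s: chi-square = %.4g (df = %d), p = %.3g\n",
              x$method, x$statistic, x$df, x$p_value))
  if (!is.na(x$estimate))
    cat(sprintf("  estimate = %.4g (se = %.4g)\n", x$estimate, x$se))
  invisible(x)
}

#' Cochran-Armitage trend test
#'
#' The 1-df trend test with genotype scores (0, 1, 2); the score test of
#' \eqn{\beta = 0} under the multiplicative logistic model, and the
#' standard genome-wide scan statistic.  Monomorphic tables (zero score
#' variance) carry no trend information and return statistic 0, p = 1.
#'
#' @param t A single-SNP [genotype_counts()] table.
#' @return An \code{"assoc_test"} result (statistic, df = 1, p-value).
#' @examples
#' trend_test(genotype_counts(c(50, 30, 20), c(20, 30, 50)))
#' @export
trend_test <- function(t) {
  stopifnot(inherits(t, "genotype_counts"), attr(t, "n_snp") == 1L)
  stat <- trend_stat(rbind(t$cases), rbind(t$controls))
  .new_test_result(stat, 1L, method = "Cochran-Armitage trend test")
}

#' Vectorized trend statistics across SNPs
#'
#' Closed-form Cochran-Armitage statistics for many SNPs at once; used by
#' the simulation engine's genome scan.  Rows are SNPs, columns genotype
#' counts 0/1/2.
#'
#' @param case_counts,control_counts Integer matrices (n_snp x 3).
#' @return Numeric vector of chi-square statistics (0 where degenerate).
#' @export
trend_stat <- function(case_counts, control_counts) {
  s <- c(0, 1, 2)
  R <- rowSums(case_counts); S <- rowSums(control_counts)
  N <- R + S
  n <- case_counts + control_counts
  T1 <- as.vector(case_counts %*% s)
  Tn <- as.vector(n %*% s)
  Tn2 <- as.vector(n %*% s^2)
  phat <- R / N
  U <- T1 - phat * Tn
  V <- phat * (1 - phat) * (Tn2 - Tn^2 / N)
  stat <- ifelse(V > 0, U^2 / V, 0)
  pmax(stat, 0)
}

#' Maximum-likelihood fit of a disease model to a count table
#'
#' Fits the case-control logistic likelihood for the chosen model by
#' maximum likelihood (via [stats::glm()] on count-weighted cells).
#' Kinds: \code{"multiplicative"} (logit linear in genotype),
#' \code{"general"} (adds the heterozygote indicator; saturated for a
#' single SNP), \code{"two_snp_mult"} (additive in both genotypes) and
#' \code{"interaction"} (adds the genotype product term).
#'
#' Tables with empty cells can render a parameter unestimable (infinite
#' MLE).  No continuity correction is applied; such fits raise an error
#' with condition class \code{"distortgwas_fit_error"} so that pipeline
#' callers can treat the replicate as unfittable (and, for significance
#' cascades, non-significant).
#'
#' @param t A [genotype_counts()] table (single- or two-SNP to match
#'   \code{kind}).
#' @param kind Model to fit; see Details.
#' @return An object of class \code{"cc_fit"}: coefficients, covariance
#'   matrix, residual and null deviances, and the fit kind.  Methods
#'   \code{coef()} and \code{vcov()} apply.
#' @export
fit_cc_model <- function(t, kind = c("multiplicative", "general",
                                     "two_snp_mult", "interaction")) {
  kind <- match.arg(kind)
  stopifnot(inherits(t, "genotype_counts"))
  single <- kind %in% c("multiplicative", "general")
  stopifnot(attr(t, "n_snp") == if (single) 1L else 2L)
  if (single) {
    g <- rep(0:2, 2)
    d <- data.frame(y = rep(c(1, 0), each = 3), g = g, h = as.numeric(g == 1),
                    w = c(as.vector(t$cases), as.vector(t$controls)))
    form <- if (kind == "multiplicative") y ~ g else y ~ g + h
  } else {
    gA <- rep(rep(0:2, 3), 2); gB <- rep(rep(0:2, each = 3), 2)
    d <- data.frame(y = rep(c(1, 0), each = 9), gA = gA, gB = gB,
                    w = c(as.vector(t$cases), as.vector(t$controls)))
    form <- if (kind == "two_snp_mult") y ~ gA + gB else y ~ gA * gB
  }
  d <- d[d$w > 0, , drop = FALSE]
  fit <- suppressWarnings(stats::glm(form, family = stats::binomial(),
                                     data = d, weights = d$w,
                                     control = stats::glm.control(epsilon = 1e-12,
                                                                  maxit = 100)))
  co <- stats::coef(fit)
  if (!fit$converged || anyNA(co) || any(abs(co) > 30))
    stop(errorCondition(
      paste0("model '", kind, "' is not estimable from this table ",
             "(empty cells / separation); treat the replicate as unfittable"),
      class = c("distortgwas_fit_error", "error", "condition")))
  structure(list(coef = co, vcov = stats::vcov(fit),
                 deviance = fit$deviance, null_deviance = fit$null.deviance,
                 kind = kind), class = "cc_fit")
}

#' @export
coef.cc_fit <- function(object, ...) object$coef

#' @export
vcov.cc_fit <- function(object, ...) object$vcov

#' @export
print.cc_fit <- function(x, ...) {
  cat(sprintf("Case-control ML fit (%s model):\n", x$kind))
  print(cbind(estimate = x$coef, se = sqrt(diag(x$vcov))))
  invisible(x)
}

# Wald chi-square on one coefficient of a cc_fit
.wald <- function(fit, name, method) {
  est <- fit$coef[[name]]
  se <- sqrt(fit$vcov[name, name])
  .new_test_result((est / se)^2, 1L, estimate = est, se = se, method = method)
}

#' Deviation test for departure from a multiplicative model
#'
#' The 1-df Wald test of the dominance parameter \eqn{\gamma = 0},
#' comparing the general and multiplicative models.  A significant result
#' indicates that per-allele risks do not act multiplicatively (e.g.
#' dominant or recessive truths).
#'
#' @param t A single-SNP [genotype_counts()] table.
#' @param type \code{"wald"} (default, matching the power theory) or
#'   \code{"lr"} for the likelihood-ratio variant (internal cross-check).
#' @return An \code{"assoc_test"} with the \eqn{\gamma} estimate and
#'   standard error (Wald form).
#' @export
deviation_test <- function(t, type = c("wald", "lr")) {
  type <- match.arg(type)
  gen <- fit_cc_model(t, "general")
  if (type == "wald") return(.wald(gen, "h", "Deviation (dominance) test"))
  mult <- fit_cc_model(t, "multiplicative")
  .new_test_result(mult$deviance - gen$deviance, 1L,
                   estimate = gen$coef[["h"]],
                   se = sqrt(gen$vcov["h", "h"]),
                   method = "Deviation (dominance) test, LR form")
}

#' General (2 df) association test
#'
#' Likelihood-ratio test comparing the general model with the null model
#' of no association; 2 degrees of freedom.
#'
#' @param t A single-SNP [genotype_counts()] table.
#' @return An \code{"assoc_test"} result.
#' @export
general_test <- function(t) {
  gen <- fit_cc_model(t, "general")
  .new_test_result(gen$null_deviance - gen$deviance, 2L,
                   method = "General (2 df) association test")
}

#' Two-SNP interaction test
#'
#' The 1-df Wald test of the interaction coefficient in the two-SNP
#' logistic model with additive genotype codings and their product,
#' comparing the interaction model to the two-SNP multiplicative model.
#'
#' @param t A two-SNP (3x3) [genotype_counts()] table.
#' @return An \code{"assoc_test"} with the \eqn{\tau} estimate.
#' @export
interaction_test <- function(t) {
  fit <- fit_cc_model(t, "interaction")
  .wald(fit, "gA:gB", "Interaction test")
}
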
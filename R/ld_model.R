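#' Two-locus linkage disequilibrium model
#'
#' Represents the joint population distribution of alleles at two biallelic
#' SNPs, A and B, parameterized by the allele-1 frequencies \code{f_A},
#' \code{f_B} and the population correlation coefficient \code{r} between
#' the allele indicators on a haplotype.  The squared correlation \eqn{r^2}
#' is the usual LD measure; here the signed \code{r} is carried because a
#' correlation in either direction makes the marker a useful surrogate.
#'
#' The three parameters fully and uniquely determine the four haplotype
#' probabilities, provided \code{r} lies within the feasibility bounds
#' implied by the frequencies (see [r_bounds()]).  Alleles are coded 0/1
#' and frequencies always refer to allele 1; negative \code{r} is allowed.
#'
#' @param f_A,f_B Allele-1 frequencies at SNPs A and B, each in (0, 1).
#' @param r Correlation between allele indicators; must lie within
#'   \code{r_bounds(f_A, f_B)}.
#' @return An object of class \code{"two_locus_ld"}: a list with elements
#'   \code{f_A}, \code{f_B}, \code{r}.
#' @examples
#' ld <- two_locus_ld(0.1, 0.2, 0.5)
#' haplotype_distribution(ld)
#' conditional_probs(ld)
#' @seealso [haplotype_distribution()], [conditional_probs()],
#'   [diplotype_distribution()], [r_bounds()], [d_coefficient()]
#' @export
two_locus_ld <- function(f_A, f_B, r) {
  stopifnot(length(f_A) == 1L, length(f_B) == 1L, length(r) == 1L,
            is.finite(f_A), is.finite(f_B), is.finite(r))
  if (f_A <= 0 || f_A >= 1 || f_B <= 0 || f_B >= 1)
    stop("allele frequencies must lie in the open interval (0, 1)")
  b <- r_bounds(f_A, f_B)
  # tiny numerical slack at the endpoints; anything beyond is a user error
  if (r < b[1] - 1e-12 || r > b[2] + 1e-12)
    stop(sprintf(
      "LD infeasible for these frequencies: r = %g outside [%g, %g] for f_A = %g, f_B = %g",
      r, b[1], b[2], f_A, f_B))
  r <- min(max(r, b[1]), b[2])
  structure(list(f_A = f_A, f_B = f_B, r = r), class = "two_locus_ld")
}

#' @export
print.two_locus_ld <- function(x, ...) {
  cat(sprintf("Two-locus LD: f_A = %g, f_B = %g, r = %g (r^2 = %.4g)\n",
              x$f_A, x$f_B, x$r, x$r^2))
  invisible(x)
}

#' Feasible range of the allelic correlation r
#'
#' The correlation between two Bernoulli allele indicators is constrained
#' by their marginal frequencies: the haplotype-11 probability
#' \eqn{p_{11} = f_A f_B + r\sqrt{f_A(1-f_A)f_B(1-f_B)}} must lie between
#' \eqn{\max(0, f_A + f_B - 1)} and \eqn{\min(f_A, f_B)}.  A correlation of
#' +1 is only achievable when \eqn{f_A = f_B}, and strong negative
#' correlation requires both frequencies to be large.
#'
#' @inheritParams two_locus_ld
#' @return Numeric vector \code{c(r_min, r_max)}.
#' @examples
#' r_bounds(0.3, 0.3)  # r_max = 1
#' r_bounds(0.1, 0.2)  # r_max = 2/3
#' @export
r_bounds <- function(f_A, f_B) {
  stopifnot(f_A > 0, f_A < 1, f_B > 0, f_B < 1)
  s <- sqrt(f_A * (1 - f_A) * f_B * (1 - f_B))
  lo <- (max(0, f_A + f_B - 1) - f_A * f_B) / s
  hi <- (min(f_A, f_B) - f_A * f_B) / s
  c(r_min = max(lo, -1), r_max = min(hi, 1))
}

#' Haplotype distribution induced by a two-locus LD model
#'
#' @param ld A [two_locus_ld()] object.
#' @return Named numeric vector \code{c(p11, p10, p01, p00)} of the
#'   probabilities of haplotypes (A,B) = (1,1), (1,0), (0,1), (0,0).
#' @examples
#' haplotype_distribution(two_locus_ld(0.1, 0.2, 0.5))
#' @export
haplotype_distribution <- function(ld) {
  stopifnot(inherits(ld, "two_locus_ld"))
  p11 <- ld$f_A * ld$f_B +
    ld$r * sqrt(ld$f_A * (1 - ld$f_A) * ld$f_B * (1 - ld$f_B))
  p <- c(p11 = p11,
         p10 = ld$f_A - p11,
         p01 = ld$f_B - p11,
         p00 = 1 - ld$f_A - ld$f_B + p11)
  .clamp_probs(p)
}

# floating-point hygiene: clamp roundoff-level violations, refuse real ones
.clamp_probs <- function(p, tol = 1e-12) {
  if (any(p < -tol) || any(p > 1 + tol))
    stop("probabilities outside [0, 1] beyond numerical tolerance")
  pmin(pmax(p, 0), 1)
}

#' Recover r from a haplotype distribution
#'
#' Inverse of [haplotype_distribution()]: computes the allelic correlation
#' from four haplotype probabilities via the covariance identity
#' \eqn{\mathrm{Cov}(A,B) = p_{11} - f_A f_B}.
#'
#' @param p Numeric vector or list with elements \code{p11, p10, p01, p00}.
#' @return The correlation \code{r}.
#' @export
r_from_haplotypes <- function(p) {
  p <- unlist(p)[c("p11", "p10", "p01", "p00")]
  stopifnot(!anyNA(p), abs(sum(p) - 1) < 1e-8)
  f_A <- p[["p11"]] + p[["p10"]]
  f_B <- p[["p11"]] + p[["p01"]]
  (p[["p11"]] - f_A * f_B) / sqrt(f_A * (1 - f_A) * f_B * (1 - f_B))
}

#' Conditional allele probabilities q0 and q1
#'
#' The probabilities of carrying allele 1 at SNP A given the allele at
#' SNP B on the same haplotype:
#' \eqn{q_1 = \Pr(A=1 \mid B=1)}, \eqn{q_0 = \Pr(A=1 \mid B=0)}.
#' They satisfy the total-probability identity
#' \eqn{q_1 f_B + q_0 (1-f_B) = f_A}, and their difference
#' \eqn{q_1 - q_0 = r\sqrt{f_A(1-f_A)/(f_B(1-f_B))}} is the mixing factor
#' that drives all distortion results.
#'
#' @inheritParams haplotype_distribution
#' @return Named numeric vector \code{c(q0, q1)}.
#' @export
conditional_probs <- function(ld) {
  p <- haplotype_distribution(ld)
  c(q0 = p[["p10"]] / (1 - ld$f_B), q1 = p[["p11"]] / ld$f_B)
}

#' Disequilibrium coefficient D
#'
#' \eqn{D = \Pr(11) - f_A f_B = r\sqrt{f_A(1-f_A)f_B(1-f_B)}}, the
#' classical covariance-scale LD measure.
#'
#' @inheritParams haplotype_distribution
#' @return The coefficient D.
#' @export
d_coefficient <- function(ld) {
  unname(haplotype_distribution(ld)[["p11"]] - ld$f_A * ld$f_B)
}

#' Two-SNP genotype (diplotype) distribution under HWE
#'
#' Assuming Hardy-Weinberg equilibrium for haplotypes (an individual's two
#' haplotypes are drawn independently from the haplotype distribution),
#' returns the joint distribution of the genotype pair
#' \eqn{(G_A, G_B) \in \{0,1,2\}^2}.  Ten diplotypes collapse to nine
#' distinguishable genotype pairs; the double-heterozygote cell sums the
#' two phase configurations (11/00 and 10/01).
#'
#' Conditionally on \eqn{G_B}, the causal genotype is
#' Binomial(2, q0), Bernoulli(q0) + Bernoulli(q1), or Binomial(2, q1)
#' for \eqn{G_B} = 0, 1, 2 respectively.
#'
#' @inheritParams haplotype_distribution
#' @return A 3x3 matrix; rows index \eqn{G_A} = 0,1,2, columns \eqn{G_B}.
#' @export
diplotype_distribution <- function(ld) {
  cond <- genotype_conditional(ld)        # rows G_A, cols G_B
  gB <- stats::dbinom(0:2, 2, ld$f_B)
  m <- sweep(cond, 2, gB, "*")
  dimnames(m) <- list(G_A = 0:2, G_B = 0:2)
  m
}

#' Conditional distribution of G_A given G_B
#'
#' @inheritParams haplotype_distribution
#' @return A 3x3 matrix with column g+1 holding \eqn{\Pr(G_A = \cdot \mid G_B = g)}.
#' @keywords internal
#' @export
genotype_conditional <- function(ld) {
  q <- conditional_probs(ld)
  q0 <- q[["q0"]]; q1 <- q[["q1"]]
  # G_B = 1: one haplotype carries B=1, the other B=0
  het <- c((1 - q0) * (1 - q1),
           q0 * (1 - q1) + q1 * (1 - q0),
           q0 * q1)
  m <- cbind(stats::dbinom(0:2, 2, q0), het, stats::dbinom(0:2, 2, q1))
  dimnames(m) <- list(G_A = 0:2, G_B = 0:2)
  m
}
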
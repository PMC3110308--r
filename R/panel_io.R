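#' Write a haplotype panel in IMPUTE-style text format
#'
#' Writes three plain-text files: \code{<prefix>.haps} (one SNP per row,
#' space-separated 0/1 alleles across haplotypes), \code{<prefix>.legend}
#' (header \code{id position a0 a1}, one SNP per row) and
#' \code{<prefix>.chip} (header \code{chip}, one 0/1 per SNP marking chip
#' membership).  All writes are atomic (write to a temporary file in the
#' same directory, then rename).  [read_panel()] round-trips bit-exactly.
#'
#' @param panel A haplotype panel.
#' @param prefix Path prefix for the three files.
#' @return Invisibly, the three file paths.
#' @export
write_panel <- function(panel, prefix) {
  H <- panel$haplotypes
  haps <- vapply(seq_len(ncol(H)), function(j) paste(H[, j], collapse = " "),
                 character(1))
  legend <- c("id position a0 a1",
              sprintf("snp%d %d 0 1", seq_len(ncol(H)), panel$positions))
  chip <- c("chip", as.integer(panel$chip_mask))
  paths <- paste0(prefix, c(".haps", ".legend", ".chip"))
  .write_lines_atomic(haps, paths[1])
  .write_lines_atomic(legend, paths[2])
  .write_lines_atomic(chip, paths[3])
  invisible(paths)
}

#' Read a haplotype panel written by [write_panel()]
#'
#' @param prefix Path prefix of the \code{.haps}/\code{.legend}/\code{.chip}
#'   files.
#' @return A \code{"haplotype_panel"} object; per-SNP frequencies are
#'   recomputed from the alleles.
#' @export
read_panel <- function(prefix) {
  haps <- readLines(paste0(prefix, ".haps"))
  H <- vapply(strsplit(haps, " ", fixed = TRUE),
              function(x) as.integer(x), integer(length(strsplit(haps[1], " ",
                                                                 fixed = TRUE)[[1]])))
  H <- matrix(as.integer(H), ncol = length(haps))  # haplotypes x SNPs
  legend <- utils::read.table(paste0(prefix, ".legend"), header = TRUE)
  chip <- utils::read.table(paste0(prefix, ".chip"), header = TRUE)
  stopifnot(nrow(legend) == ncol(H), nrow(chip) == ncol(H))
  structure(list(haplotypes = H, positions = legend$position,
                 freqs = colMeans(H), chip_mask = chip$chip == 1L),
            class = "haplotype_panel")
}

.write_lines_atomic <- function(lines, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) stop("atomic rename failed for ", path)
  invisible(path)
}

#' Atomic TSV writer
#'
#' Writes a data.frame as tab-separated text with a header row, using a
#' write-then-rename so readers never see a partial file.  Numeric
#' formatting is locale-independent.
#'
#' @param df A data.frame.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_tsv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  old <- Sys.getlocale("LC_NUMERIC")
  on.exit(suppressWarnings(Sys.setlocale("LC_NUMERIC", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_NUMERIC", "C"))
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!file.rename(tmp, path)) stop("atomic rename failed for ", path)
  invisible(path)
}

#' Deterministic fixtures for tests and examples
#'
#' Three fixture kinds:
#' \describe{
#'   \item{\code{two_snp_panel}}{A bespoke two-SNP haplotype panel that
#'     realizes a requested \code{(f_A, f_B, r)} exactly (up to count
#'     rounding): haplotype counts are the rounded haplotype
#'     probabilities times \code{n}, with largest-remainder correction so
#'     they sum to \code{n}.  SNP 1 is the causal SNP (off chip), SNP 2
#'     the marker (on chip).  Params: \code{f_A}, \code{f_B}, \code{r},
#'     \code{n}, optional \code{spacing_bp}.}
#'   \item{\code{toy_counts}}{A genotype count table drawn from the
#'     case/control genotype frequencies of a disease model.  Params:
#'     \code{model} (a [general_model()]; default null), \code{f},
#'     \code{n_case}, \code{n_ctrl}.}
#'   \item{\code{ld_grid}}{The marker-model trajectory
#'     [model_space_trajectory()] over an r grid — the data behind
#'     distortion curves.  Params: \code{model}, \code{f_A}, \code{f_B},
#'     \code{r_grid}.}
#' }
#'
#' @param kind One of \code{"two_snp_panel"}, \code{"toy_counts"},
#'   \code{"ld_grid"}.
#' @param params Named list of kind-specific parameters (see Details).
#' @param seed Seed for the stochastic kinds (\code{toy_counts}).
#' @param dir Optional directory; if given, the fixture is also written
#'   there (panel files, or a TSV) and paths attached as attribute
#'   \code{"paths"}.
#' @return The fixture object (a panel, a [genotype_counts()], or a
#'   data.frame).
#' @export
make_fixture <- function(kind = c("two_snp_panel", "toy_counts", "ld_grid"),
                         params = list(), seed = 1L, dir = NULL) {
  kind <- match.arg(kind)
  obj <- switch(kind,
    two_snp_panel = {
      p <- params
      stopifnot(!is.null(p$f_A), !is.null(p$f_B), !is.null(p$r), !is.null(p$n))
      ld <- two_locus_ld(p$f_A, p$f_B, p$r)
      probs <- haplotype_distribution(ld)
      counts <- .round_to_total(probs * p$n, p$n)
      alle <- rbind(c(1L, 1L), c(1L, 0L), c(0L, 1L), c(0L, 0L))
      H <- alle[rep(1:4, counts), , drop = FALSE]
      spacing <- if (is.null(p$spacing_bp)) 1000L else p$spacing_bp
      structure(list(haplotypes = H, positions = c(1L, 1L + spacing),
                     freqs = colMeans(H), chip_mask = c(FALSE, TRUE)),
                class = "haplotype_panel")
    },
    toy_counts = {
      set.seed(seed)
      p <- params
      model <- if (is.null(p$model)) general_model(0, 0) else p$model
      f <- if (is.null(p$f)) 0.3 else p$f
      n_case <- if (is.null(p$n_case)) 100L else p$n_case
      n_ctrl <- if (is.null(p$n_ctrl)) 100L else p$n_ctrl
      fr <- cc_genotype_freqs(model, f)
      genotype_counts(as.vector(stats::rmultinom(1, n_case, fr$case)),
                      as.vector(stats::rmultinom(1, n_ctrl, fr$control)))
    },
    ld_grid = {
      p <- params
      model <- if (is.null(p$model)) model_from_hom_rr("dominant", 1.4^2)
               else p$model
      model_space_trajectory(model, p$f_A, p$f_B, p$r_grid)
    })
  if (!is.null(dir)) {
    paths <- switch(kind,
      two_snp_panel = write_panel(obj, file.path(dir, "two_snp_panel")),
      toy_counts = write_tsv_atomic(
        data.frame(phenotype = c("case", "control"),
                   rbind(obj$cases, obj$controls)),
        file.path(dir, "toy_counts.tsv")),
      ld_grid = write_tsv_atomic(obj, file.path(dir, "ld_grid.tsv")))
    attr(obj, "paths") <- paths
  }
  obj
}

# round nonnegative reals to integers preserving the total
# (largest-remainder method)
.round_to_total <- function(x, total) {
  base <- floor(x)
  rem <- total - sum(base)
  if (rem > 0) {
    extra <- order(x - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Read a genotype count table from TSV
#'
#' Reads tables in the layout written by [make_fixture()]'s
#' \code{toy_counts}: a \code{phenotype} column (\code{case}/\code{control})
#' followed by one column per genotype.
#'
#' @param path TSV path.
#' @return A [genotype_counts()] object.
#' @export
read_counts_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE)
  stopifnot("phenotype" %in% names(d))
  num <- as.matrix(d[, setdiff(names(d), "phenotype"), drop = FALSE])
  genotype_counts(as.vector(num[d$phenotype == "case", ]),
                  as.vector(num[d$phenotype == "control", ]))
}
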
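#' Default run configuration
#'
#' Defaults shared by the simulation pipeline and the command-line
#' interface: equal case/control sampling (\eqn{\phi = 0.5}), the
#' scan/replication/deviation thresholds 1e-6 / 0.01 / 0.05, per-stage
#' sample sizes of 2,000 cases and 2,000 controls, a multiplicative
#' disease model with homozygous RR \eqn{1.4^2}, and the synthetic-panel
#' parameters.
#'
#' @return A nested named list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    phi = 0.5,
    n_case = 2000L,
    n_ctrl = 2000L,
    thresholds = list(scan = 1e-6, replication = 0.01, deviation = 0.05),
    model = list(kind = "multiplicative", hom_rr = 1.4^2, mu = log(0.01)),
    ld = NULL,  # optional: list(f_A =, f_B =, r =)
    panel = list(n_hap = 40000L, n_snp = 250L, region_bp = 1e6,
                 ld_scale = 5e4, chip_maf = 0.05, chip_prob = 0.5),
    causal_on_chip = "panel"
  )
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration file, fills in [default_config()] values
#' for anything unspecified, rejects unknown keys with a field-level
#' message, and validates parameter ranges — including feasibility of a
#' requested LD value \code{r} for the given allele frequencies, reported
#' with the admissible [r_bounds()] interval.  An empty file yields the
#' full defaults.
#'
#' @param path Path to a YAML file.
#' @return The validated configuration list (class \code{"run_config"}).
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- .merge_config(default_config(), user, "")
  validate_config(cfg)
}

.merge_config <- function(base, user, prefix) {
  unknown <- setdiff(names(user), names(base))
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ",
         paste0(prefix, unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(base[[k]]) && is.list(user[[k]]) && !is.null(names(base[[k]])))
      base[[k]] <- .merge_config(base[[k]], user[[k]], paste0(prefix, k, "."))
    else base[[k]] <- user[[k]]
  }
  base
}

#' Validate a configuration list
#'
#' @param cfg A configuration list shaped like [default_config()].
#' @return \code{cfg}, classed \code{"run_config"}, or an error naming
#'   the offending field.
#' @export
validate_config <- function(cfg) {
  if (cfg$phi <= 0 || cfg$phi >= 1) stop("phi: must be in (0, 1)")
  for (k in c("scan", "replication", "deviation")) {
    v <- cfg$thresholds[[k]]
    if (is.null(v) || v <= 0 || v >= 1)
      stop("thresholds.", k, ": must be in (0, 1)")
  }
  if (!cfg$model$kind %in% c("multiplicative", "dominant", "recessive"))
    stop("model.kind: must be multiplicative, dominant or recessive")
  if (cfg$model$hom_rr <= 0) stop("model.hom_rr: must be positive")
  if (!is.null(cfg$ld)) {
    b <- r_bounds(cfg$ld$f_A, cfg$ld$f_B)
    if (cfg$ld$r < b[1] || cfg$ld$r > b[2])
      stop(sprintf("ld.r: %g infeasible for f_A = %g, f_B = %g; must lie in [%.4g, %.4g]",
                   cfg$ld$r, cfg$ld$f_A, cfg$ld$f_B, b[1], b[2]))
  }
  if (cfg$panel$n_hap < 2 || cfg$panel$n_hap %% 2 != 0)
    stop("panel.n_hap: must be even and >= 2")
  structure(cfg, class = c("run_config", "list"))
}

#' Save a configuration to YAML
#'
#' Writes the configuration so that [load_config()] recovers it
#' (save-then-load is the identity on the configuration values).
#'
#' @param cfg A configuration list.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
save_config <- function(cfg, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  yaml::write_yaml(unclass(cfg), tmp)
  if (!file.rename(tmp, path)) stop("atomic rename failed for ", path)
  invisible(path)
}

#' Build the disease model described by a configuration
#'
#' @param cfg A \code{"run_config"} (or compatible list).
#' @return A [general_model()].
#' @export
config_model <- function(cfg) {
  model_from_hom_rr(cfg$model$kind, cfg$model$hom_rr, cfg$model$mu)
}
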
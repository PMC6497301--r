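#' Default run configuration
#'
#' Central registry of every tunable threshold with its conventional default:
#' flux-activation threshold \code{epsilon} (1e-4 mmol gDW^-1 hr^-1),
#' QP slack threshold (1e-6), C-sweep grid size (500), essentiality
#' growth-drop threshold (1\%), exchange-prediction growth fraction (90\%),
#' drug-response biomass fraction (50\%), FDR level (0.05), z-score
#' discretization thresholds (5 and 0), minimum |Spearman rho| for
#' growth-correlated reactions (0.9), open-exchange magnitude (1000),
#' cell-specific-volume coefficient (4.3 mL gDW^-1), and the RNG seed.
#'
#' @param ... named overrides of the defaults.
#' @return a named list of class \code{run_config}.
#' @export
default_config <- function(...) {
  cfg <- list(
    epsilon = 1e-4,
    slack_threshold = 1e-6,
    n_steps = 500,
    essentiality_threshold = 0.01,
    growth_fraction = 0.9,
    biomass_fraction = 0.5,
    alpha_fdr = 0.05,
    z_hi = 5,
    z_lo = 0,
    rho_min = 0.9,
    open_bound = 1000,
    volume_coefficient = 4.3,
    c_brk_tol = 1e-6,
    c_brk_rel_width = 1e-3,
    changepoint_which = "first",
    seed = 1L,
    solver = "simplex"
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file; keys as in [default_config()].
#' @return a \code{run_config}.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_config, vals)
}

#' Write a run configuration to YAML (lossless round-trip)
#' @param config a \code{run_config}.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
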
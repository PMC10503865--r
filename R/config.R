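#' Pipeline configuration
#'
#' Central list of numeric conventions used across the pipeline. Every value
#' can be overridden per call; the defaults are the modelling conventions of
#' the microbiome community-modelling literature this package follows.
#'
#' @details
#' * `coupling_factor` (400, dimensionless): each microbial reaction flux is
#'   bounded in magnitude by `coupling_factor` times the flux of that species'
#'   biomass reaction, so species that do not grow carry no flux.
#' * `abundance_cutoff` (1e-4, relative abundance): species below this
#'   relative abundance after coverage filtering are dropped before community
#'   assembly.
#' * `growth_lb`, `growth_ub` (0.4, 1.0 per day): bounds on the community
#'   biomass flux; a positive lower bound makes the coupling constraints bind.
#' * `secretion_threshold` (30 mmol/person/day): a microbial metabolite is
#'   called a high secretor when its lumen-to-host flux exceeds this value in
#'   the urine-maximising solution.
#' * `flag_threshold` (0.10): a reaction knockout is flagged when it reduces
#'   the target urine flux by more than this fraction.
#' * `supplement_amount` (300 mmol/person/day): default dietary dose in the
#'   supplementation screen.
#' * `min_growth` (1e-6 per day): feasibility threshold for pan-species
#'   growth checks under a diet.
#' * `pseudocount` (0.5 counts): added to zero counts in log-ratio analysis.
#' * `hc_type` ("HC3"): flavour of heteroscedasticity-robust covariance.
#' * `exhaustive_max` (15): minimal-set search enumerates all subsets up to
#'   this many candidates, and falls back to greedy selection beyond it.
#' * `tol_feas` (1e-6), `tol_det` (1e-9): feasibility and determinism
#'   tolerances for all linear-programming work.
#'
#' @param ... named overrides of the defaults.
#' @return A named list with class `cometab_config`.
#' @export
#' @examples
#' cfg <- cometab_config(coupling_factor = 200)
#' cfg$coupling_factor
cometab_config <- function(...) {
  cfg <- list(
    coupling_factor = 400,
    abundance_cutoff = 1e-4,
    growth_lb = 0.4,
    growth_ub = 1.0,
    secretion_threshold = 30,
    flag_threshold = 0.10,
    supplement_amount = 300,
    min_growth = 1e-6,
    pseudocount = 0.5,
    hc_type = "HC3",
    exhaustive_max = 15,
    tol_feas = 1e-6,
    tol_det = 1e-9,
    default_bound = 1000
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "cometab_config")
}

#' Hash a configuration for provenance
#'
#' Serialises the configuration to a canonical text form and returns its MD5,
#' so every report can record which settings produced it.
#'
#' @param config a `cometab_config` list.
#' @return A length-1 character MD5 hash.
#' @export
config_hash <- function(config) {
  stopifnot(inherits(config, "cometab_config"))
  txt <- paste(names(config), vapply(config, function(x) paste(format(x, digits = 15), collapse = ","),
                                     character(1)),
               sep = "=", collapse = ";")
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(txt, tf)
  unname(tools::md5sum(tf))
}
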
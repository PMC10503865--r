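# Host-microbiome integration.
#
# A community model is attached to the large-intestinal lumen [luLI] of a
# sex-specific multi-organ host: the community's microbial lumen [luM] is
# linked to [luLI] by per-metabolite reversible transports (positive flux =
# microbiome -> host), and the community's own diet interface is removed so
# the microbes feed exclusively from the host lumen. The germ-free host and
# the personalised (host + community) assembly are then interrogated for
# maximum urine secretion of a metabolite, and the gain over germ-free is
# decomposed into direct microbial secretion of the metabolite itself and a
# co-metabolism residual (host conversion of microbially derived precursors).

LUT_PREFIX <- "LUt_"

#' Attach a community to a host model's intestinal lumen
#'
#' For every metabolite of the community lumen that also exists in the host's
#' `[luLI]` compartment, a reversible transport `LUt_<met>` (lumen [luM] ->
#' [luLI], positive = delivery to the host) is added; community metabolites
#' with no `[luLI]` counterpart are skipped with a warning. The community's
#' diet-side exchanges and transports are removed — attached microbes feed
#' only from the host lumen — while its fecal-excretion route and all
#' coupling constraints are preserved.
#'
#' @param host a `host_model`.
#' @param community a `community_model` (may have zero species).
#' @return A combined `stoich_model`.
#' @export
attach_community <- function(host, community) {
  stopifnot(inherits(host, "host_model"), inherits(community, "community_model"))
  comm <- community
  diet_side <- comm$reactions$id[grepl("^(EX_.*\\[d\\]$|DUt_)", comm$reactions$id)]
  if (length(diet_side) > 0) comm <- remove_reactions(comm, diet_side)

  clash <- intersect(host$reactions$id, comm$reactions$id)
  if (length(clash) > 0) {
    stop("reaction id clash between host and community: ",
         paste(utils::head(clash, 5), collapse = ", "), call. = FALSE)
  }

  lumen <- comm$metabolites$id[comm$metabolites$compartment == comm$lumen_tag]
  base <- vapply(lumen, function(x) split_met_id(x)$base, character(1))
  host_lu <- host$metabolites$id[host$metabolites$compartment == host$lumen_tag]
  host_base <- vapply(host_lu, function(x) split_met_id(x)$base, character(1))
  linkable <- base %in% host_base
  if (any(!linkable)) {
    warning("no [", host$lumen_tag, "] counterpart for community metabolite(s): ",
            paste(base[!linkable], collapse = ", "), "; transport skipped",
            call. = FALSE)
  }

  mets <- dplyr::bind_rows(host$metabolites, comm$metabolites) |>
    dplyr::distinct(.data$id, .keep_all = TRUE)
  rxns <- dplyr::bind_rows(host$reactions, comm$reactions)
  st <- dplyr::bind_rows(host$stoichiometry, comm$stoichiometry)
  for (k in which(linkable)) {
    b <- base[k]
    rxns <- dplyr::bind_rows(rxns, tibble::tibble(
      id = paste0(LUT_PREFIX, b), lower_bound = -1000, upper_bound = 1000,
      subsystem = "lumen transport"))
    st <- dplyr::bind_rows(st, tibble::tibble(
      reaction = paste0(LUT_PREFIX, b),
      metabolite = c(lumen[k], met_id(b, host$lumen_tag)),
      coef = c(-1, 1)))
  }
  out <- stoich_model(mets, rxns, st,
                      extra_constraints = comm$extra_constraints,
                      id = paste(host$id, comm$id, sep = "+"))
  out$sex <- host$sex
  out$lumen_tag <- host$lumen_tag
  out$urine_tag <- host$urine_tag
  out
}

#' An empty community (no species)
#'
#' Attaching it to a host reproduces the germ-free optimum; useful as the
#' identity element of [attach_community()].
#'
#' @return A `community_model` with no species, no reactions beyond an empty
#'   shell.
#' @export
empty_community <- function() {
  cm <- stoich_model(
    tibble::tibble(id = character(), compartment = character(), name = character()),
    tibble::tibble(id = character(), lower_bound = numeric(),
                   upper_bound = numeric(), subsystem = character()),
    tibble::tibble(reaction = character(), metabolite = character(),
                   coef = numeric()),
    id = "empty_community")
  cm$species <- tibble::tibble(species = character(), abundance = numeric())
  cm$coupling_factor <- 400
  cm$biomass_reaction_id <- "communityBiomass"
  cm$lumen_tag <- "luM"
  cm$fecal_exchange_prefix <- "EX_"
  class(cm) <- c("community_model", class(cm))
  cm
}

#' Maximum urine secretion flux of a metabolite
#'
#' FBA maximum of the urine exchange `EX_<met>[u]` under the model's current
#' (diet-constrained) bounds.
#'
#' @param model a diet-constrained host or host+community `stoich_model`.
#' @param metabolite base metabolite id (e.g. `"for"`).
#' @return The maximum flux (mmol/person/day).
#' @export
max_urine_secretion <- function(model, metabolite) {
  rid <- paste0("EX_", metabolite, "[u]")
  if (!rid %in% model$reactions$id) {
    stop("no urine exchange ", rid, " in model", call. = FALSE)
  }
  sol <- solve_fba(model, rid, "max")
  if (sol$status != "optimal") {
    stop("urine secretion LP not optimal (status ", sol$status, ")", call. = FALSE)
  }
  sol$objective_value
}

#' Maximum direct microbial secretion of a metabolite into the host lumen
#'
#' The extremal flux of the `[luM] -> [luLI]` transport in the direction
#' microbiome -> host, reported as a non-negative magnitude.
#'
#' @param model a host+community model from [attach_community()], diet
#'   constrained.
#' @param metabolite base metabolite id.
#' @return Non-negative maximum delivery flux (mmol/person/day).
#' @export
max_microbial_secretion <- function(model, metabolite) {
  rid <- paste0(LUT_PREFIX, metabolite)
  if (!rid %in% model$reactions$id) {
    stop("no lumen transport ", rid, " in model (is the community attached?)",
         call. = FALSE)
  }
  sol <- solve_fba(model, rid, "max")
  if (sol$status != "optimal") {
    stop("microbial secretion LP not optimal (status ", sol$status, ")",
         call. = FALSE)
  }
  max(sol$objective_value, 0)
}

#' Decompose urine secretion into microbial secretion and co-metabolism
#'
#' Computes the germ-free maximum urine secretion, the personalised
#' (host + community) maximum, and the maximum direct microbial secretion of
#' the metabolite itself, then reports `delta = personalised - germfree` and
#' `cometabolism_residual = delta - microbial_secretion_max`. A positive
#' residual is the share of the gain that direct secretion cannot explain:
#' host conversion of microbially derived precursors.
#'
#' @param host a `host_model`.
#' @param community a `community_model`.
#' @param diet a `diet_spec` (applied to the host diet compartment `[d]`).
#' @param metabolite base metabolite id.
#' @return A `cometab_report`: list with `metabolite`, `germfree_max`,
#'   `personalised_max`, `microbial_secretion_max`, `delta`,
#'   `cometabolism_residual`.
#' @export
cometabolism_decomposition <- function(host, community, diet, metabolite = "for") {
  gf <- suppressWarnings(apply_diet(host, diet, compartments = "d"))
  germfree_max <- max_urine_secretion(gf, metabolite)
  combined <- attach_community(host, community)
  combined <- suppressWarnings(apply_diet(combined, diet, compartments = "d"))
  personalised_max <- max_urine_secretion(combined, metabolite)
  microbial <- if (nrow(community$species) > 0) {
    max_microbial_secretion(combined, metabolite)
  } else 0
  delta <- personalised_max - germfree_max
  structure(list(metabolite = metabolite,
                 germfree_max = germfree_max,
                 personalised_max = personalised_max,
                 microbial_secretion_max = microbial,
                 delta = delta,
                 cometabolism_residual = delta - microbial),
            class = "cometab_report")
}

#' @export
print.cometab_report <- function(x, ...) {
  cat("<cometab_report> ", x$metabolite, "\n", sep = "")
  cat("  germ-free max:      ", format(x$germfree_max), "\n",
      "  personalised max:   ", format(x$personalised_max), "\n",
      "  microbial secretion:", format(x$microbial_secretion_max), "\n",
      "  delta:              ", format(x$delta), "\n",
      "  co-metabolism:      ", format(x$cometabolism_residual), "\n", sep = "")
  invisible(x)
}

#' Tidy a co-metabolism report
#' @param x a `cometab_report`.
#' @param ... unused.
#' @return One-row tibble of the report fields.
#' @method tidy cometab_report
#' @export
tidy.cometab_report <- function(x, ...) {
  tibble::tibble(metabolite = x$metabolite, germfree_max = x$germfree_max,
                 personalised_max = x$personalised_max,
                 microbial_secretion_max = x$microbial_secretion_max,
                 delta = x$delta,
                 cometabolism_residual = x$cometabolism_residual)
}

#' Microbial metabolites highly secreted in a urine-maximising solution
#'
#' Given the flux solution of maximising a urine exchange on a
#' host+community model, returns the base ids of metabolites whose
#' `[luM] -> [luLI]` transport flux exceeds the threshold.
#'
#' @param solution a `flux_solution` from the combined model.
#' @param threshold flux threshold (mmol/person/day), default 30.
#' @return Character vector of base metabolite ids, ordered by decreasing
#'   flux.
#' @export
high_secretors <- function(solution, threshold = 30) {
  stopifnot(inherits(solution, "flux_solution"))
  if (is.null(solution$fluxes)) return(character(0))
  lut <- solution$fluxes[startsWith(names(solution$fluxes), LUT_PREFIX)]
  lut <- lut[lut > threshold]
  names(lut) <- sub(paste0("^", LUT_PREFIX), "", names(lut))
  names(sort(lut, decreasing = TRUE))
}
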
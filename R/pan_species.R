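# Pan-species models: the union of the strain-level reconstructions of one
# species. The pan model can do anything any of its strains can do: shared
# reactions take the widest bound interval across strains, and the strain
# biomass reactions are merged into one "biomassPan" reaction.

#' Build a pan-species model from strain models
#'
#' Takes the set-union of reactions and metabolites across all strain models
#' of one species. Reactions shared by several strains must have identical
#' stoichiometry (an error names the offending reaction otherwise) and get
#' the widest bound interval found in any strain. Strain biomass reactions —
#' any reaction whose id starts with `"biomass"` — are replaced by a single
#' `biomassPan` reaction whose stoichiometry is the union of all strain
#' biomass terms with, for each term, the mean coefficient across the strains
#' carrying it.
#'
#' @param strain_models list of `stoich_model`s (at least one).
#' @param species_id id for the resulting model.
#' @return A `stoich_model` whose feasible exchange fluxes contain every
#'   strain's (capability monotonicity).
#' @export
build_pan_model <- function(strain_models, species_id) {
  if (length(strain_models) == 0) stop("no strain models given", call. = FALSE)
  is_biomass <- function(ids) grepl("^biomass", ids, ignore.case = TRUE)

  rxn_all <- list(); st_all <- list(); bio_terms <- list()
  for (sm in strain_models) {
    stopifnot(inherits(sm, "stoich_model"))
    bio_ids <- sm$reactions$id[is_biomass(sm$reactions$id)]
    st <- sm$stoichiometry
    bio_terms[[length(bio_terms) + 1L]] <-
      st[st$reaction %in% bio_ids, c("metabolite", "coef")]
    keep <- !is_biomass(sm$reactions$id)
    rxn_all[[length(rxn_all) + 1L]] <- sm$reactions[keep, ]
    st_all[[length(st_all) + 1L]] <- st[!st$reaction %in% bio_ids, ]
  }
  rxns <- dplyr::bind_rows(rxn_all)
  st <- dplyr::bind_rows(st_all) |> dplyr::distinct()

  # shared reaction ids must agree on stoichiometry
  sig <- st |>
    dplyr::arrange(.data$reaction, .data$metabolite) |>
    dplyr::group_by(.data$reaction) |>
    dplyr::summarise(sig = paste(.data$metabolite, .data$coef, collapse = "|"),
                     n_sig = 1L, .groups = "drop")
  multi <- st |>
    dplyr::distinct(.data$reaction, .data$metabolite, .data$coef) |>
    dplyr::count(.data$reaction, .data$metabolite) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi) > 0) {
    stop("conflicting stoichiometry across strains for reaction(s): ",
         paste(unique(multi$reaction), collapse = ", "), call. = FALSE)
  }

  pan_rxns <- rxns |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(lower_bound = min(.data$lower_bound),
                     upper_bound = max(.data$upper_bound),
                     subsystem = dplyr::first(.data$subsystem),
                     .groups = "drop")

  # merged biomass: union of terms, mean coefficient over strains with the term
  bio <- dplyr::bind_rows(bio_terms)
  if (nrow(bio) == 0) stop("no strain biomass reaction found", call. = FALSE)
  bio_pan <- bio |>
    dplyr::group_by(.data$metabolite) |>
    dplyr::summarise(coef = mean(.data$coef), .groups = "drop")
  pan_rxns <- dplyr::bind_rows(
    pan_rxns,
    tibble::tibble(id = "biomassPan", lower_bound = 0, upper_bound = 1000,
                   subsystem = "biomass"))
  st <- dplyr::bind_rows(
    st[, c("reaction", "metabolite", "coef")],
    tibble::tibble(reaction = "biomassPan", metabolite = bio_pan$metabolite,
                   coef = bio_pan$coef))

  met_ids <- unique(st$metabolite)
  mets <- dplyr::bind_rows(lapply(strain_models, function(sm) sm$metabolites)) |>
    dplyr::distinct(.data$id, .keep_all = TRUE) |>
    dplyr::filter(.data$id %in% met_ids)
  stoich_model(mets, pan_rxns, st, id = species_id)
}
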
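# Sample-personalised community models.
#
# Each species' pan model is namespaced ("species__reaction"), its
# extracellular metabolites are rewired to a shared microbial lumen [luM],
# and its exchange and biomass-demand reactions are dropped — metabolites
# flow between species only through the lumen, and species biomass is
# consumed only by the abundance-weighted community biomass reaction. The
# lumen is connected to a diet compartment [d] and a fecal compartment [fe]
# through per-metabolite transports, so the standalone community eats a diet
# and its net secretion is read off the fecal exchanges. Coupling rows tie
# every species reaction's flux magnitude to that species' biomass flux.

NS_SEP <- "__"

#' Namespace / de-namespace species reaction ids
#' @param species species id.
#' @param id reaction id(s).
#' @return Namespaced id(s) `"species__id"`.
#' @export
namespace_id <- function(species, id) paste0(species, NS_SEP, id)

#' @rdname namespace_id
#' @param ns_id namespaced id(s).
#' @return `denamespace_id`: list with `species` and `id` character vectors.
#' @export
denamespace_id <- function(ns_id) {
  parts <- regmatches(ns_id, regexpr(NS_SEP, ns_id), invert = TRUE)
  list(species = vapply(parts, `[`, character(1), 1),
       id = vapply(parts, `[`, character(1), 2))
}

#' Filter an abundance table to model-covered species and renormalise
#'
#' Mirrors the read-processing step of abundance-based community modelling:
#' reads assigned to species without a metabolic reconstruction are
#' discarded (their retained fraction per sample is the coverage), the table
#' is renormalised, species below the relative-abundance cutoff are dropped,
#' and the survivors are renormalised again to sum to one.
#'
#' @param table an `abundance_table` (counts or relative).
#' @param covered_species species ids with a model available.
#' @param cutoff relative-abundance cutoff applied after the first
#'   renormalisation.
#' @return list with `table` (relative `abundance_table` over surviving
#'   species) and `coverage` (tibble sample, coverage).
#' @export
filter_and_renormalize <- function(table, covered_species, cutoff = 1e-4) {
  sp <- abundance_species(table)
  keep <- intersect(sp, covered_species)
  vals <- as.matrix(table[, sp, drop = FALSE])
  tot <- rowSums(vals)
  cov_vals <- rowSums(vals[, keep, drop = FALSE]) / tot
  if (any(cov_vals == 0)) {
    stop("sample(s) with zero covered reads: ",
         paste(table$sample[cov_vals == 0], collapse = ", "), call. = FALSE)
  }
  rel <- vals[, keep, drop = FALSE] / rowSums(vals[, keep, drop = FALSE])
  rel[rel < cutoff] <- 0
  if (any(rowSums(rel) == 0)) {
    stop("sample(s) with no species above cutoff: ",
         paste(table$sample[rowSums(rel) == 0], collapse = ", "), call. = FALSE)
  }
  rel <- rel / rowSums(rel)
  drop_sp <- colSums(rel) == 0
  rel <- rel[, !drop_sp, drop = FALSE]
  out <- dplyr::bind_cols(tibble::tibble(sample = table$sample),
                          tibble::as_tibble(rel))
  list(table = abundance_table(out, mode = "relative"),
       coverage = tibble::tibble(sample = table$sample,
                                 coverage = unname(cov_vals)))
}

#' Assemble a personalised community model
#'
#' @param pan_models named list of pan-species `stoich_model`s (names are
#'   species ids).
#' @param abundances named numeric vector of relative abundances for one
#'   sample (must sum to 1 within 1e-9); every named species needs a model.
#' @param coupling_factor coupling constant c: each species reaction flux v
#'   satisfies `|v| <= c * v_biomass` for that species' biomass flux.
#' @param growth_bounds community biomass flux bounds (per day).
#' @param sample_id id for the community model.
#' @return A `community_model` (inherits `stoich_model`) with fields
#'   `species` (tibble species, abundance), `coupling_factor`,
#'   `biomass_reaction_id` (`"communityBiomass"`), `lumen_tag` (`"luM"`).
#' @export
build_community <- function(pan_models, abundances, coupling_factor = 400,
                            growth_bounds = c(0.4, 1.0),
                            sample_id = "community") {
  abundances <- abundances[abundances > 0]
  if (abs(sum(abundances) - 1) > 1e-9) {
    stop("abundances must sum to 1 (got ", format(sum(abundances)), ")",
         call. = FALSE)
  }
  missing <- setdiff(names(abundances), names(pan_models))
  if (length(missing) > 0) {
    stop("species without a pan model: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  mets <- list(); rxns <- list(); st <- list(); coupling <- list()
  lumen_mets <- character(0)
  bio_terms <- tibble::tibble(metabolite = character(), coef = numeric())

  for (sp in names(abundances)) {
    pm <- pan_models[[sp]]
    ex <- exchange_reactions(pm)
    dm <- pm$reactions$id[grepl("^DM_", pm$reactions$id)]
    drop_ids <- unique(c(ex$reaction, dm))
    keep <- !pm$reactions$id %in% drop_ids

    # extracellular metabolites join the shared lumen, everything else is
    # namespaced per species
    met_map <- vapply(pm$metabolites$id, function(mid) {
      p <- split_met_id(mid)
      if (p$compartment == "e") met_id(p$base, "luM") else namespace_id(sp, mid)
    }, character(1))
    lumen_mets <- union(lumen_mets, unname(met_map[vapply(
      pm$metabolites$id, function(mid) split_met_id(mid)$compartment == "e",
      logical(1))]))

    rt <- pm$reactions[keep, ]
    rt$id <- namespace_id(sp, rt$id)
    rxns[[sp]] <- rt
    stt <- pm$stoichiometry[!pm$stoichiometry$reaction %in% drop_ids, ]
    stt$reaction <- namespace_id(sp, stt$reaction)
    stt$metabolite <- unname(met_map[stt$metabolite])
    st[[sp]] <- stt

    bio_id <- namespace_id(sp, "biomassPan")
    if (!bio_id %in% rt$id) {
      stop("pan model for ", sp, " lacks a biomassPan reaction", call. = FALSE)
    }
    bio_met <- stt$metabolite[stt$reaction == bio_id & stt$coef > 0]
    if (length(bio_met) != 1) {
      stop("biomassPan of ", sp, " must produce exactly one biomass metabolite",
           call. = FALSE)
    }
    bio_terms <- dplyr::bind_rows(
      bio_terms, tibble::tibble(metabolite = bio_met,
                                coef = -unname(abundances[[sp]])))

    for (rid in setdiff(rt$id, bio_id)) {
      coupling[[length(coupling) + 1L]] <- list(
        id = paste0("cpl_ub_", rid),
        coefs = stats::setNames(c(1, -coupling_factor), c(rid, bio_id)),
        sense = "<=", rhs = 0)
      coupling[[length(coupling) + 1L]] <- list(
        id = paste0("cpl_lb_", rid),
        coefs = stats::setNames(c(1, coupling_factor), c(rid, bio_id)),
        sense = ">=", rhs = 0)
    }
  }

  rxn_tbl <- dplyr::bind_rows(rxns)
  st_tbl <- dplyr::bind_rows(st)

  # lumen infrastructure: diet and fecal transports plus outside exchanges
  for (lm in lumen_mets) {
    b <- split_met_id(lm)$base
    st_tbl <- dplyr::bind_rows(st_tbl, tibble::tibble(
      reaction = c(paste0("EX_", b, "[d]"),
                   rep(paste0("DUt_", b), 2),
                   rep(paste0("UFEt_", b), 2),
                   paste0("EX_", b, "[fe]")),
      metabolite = c(met_id(b, "d"),
                     met_id(b, "d"), lm,
                     lm, met_id(b, "fe"),
                     met_id(b, "fe")),
      coef = c(-1, -1, 1, -1, 1, -1)))
    rxn_tbl <- dplyr::bind_rows(rxn_tbl, tibble::tibble(
      id = c(paste0("EX_", b, "[d]"), paste0("DUt_", b),
             paste0("UFEt_", b), paste0("EX_", b, "[fe]")),
      lower_bound = c(-1000, 0, 0, 0),
      upper_bound = c(1000, 1000, 1000, 1000),
      subsystem = "lumen exchange"))
  }

  # abundance-weighted community biomass
  rxn_tbl <- dplyr::bind_rows(rxn_tbl, tibble::tibble(
    id = "communityBiomass", lower_bound = growth_bounds[1],
    upper_bound = growth_bounds[2], subsystem = "community biomass"))
  st_tbl <- dplyr::bind_rows(st_tbl, tibble::tibble(
    reaction = "communityBiomass", metabolite = bio_terms$metabolite,
    coef = bio_terms$coef))

  met_ids <- unique(st_tbl$metabolite)
  met_tbl <- tibble::tibble(
    id = met_ids,
    compartment = unname(vapply(met_ids, function(x) split_met_id(x)$compartment,
                                character(1))),
    name = unname(vapply(met_ids, function(x) split_met_id(x)$base, character(1))))

  cm <- stoich_model(met_tbl, rxn_tbl, st_tbl, extra_constraints = coupling,
                     id = sample_id)
  cm$species <- tibble::tibble(species = names(abundances),
                               abundance = unname(abundances))
  cm$coupling_factor <- coupling_factor
  cm$biomass_reaction_id <- "communityBiomass"
  cm$lumen_tag <- "luM"
  cm$fecal_exchange_prefix <- "EX_"
  class(cm) <- c("community_model", class(cm))
  cm
}

#' Maximum net secretion capacities of a community under a diet
#'
#' Applies the diet to the community's diet compartment and computes, for
#' each metabolite, the FVA maximum of its fecal exchange flux — the
#' community's maximum net secretion capacity in mmol/person/day. Maxima
#' below zero (forced net uptake) are floored at zero and flagged.
#'
#' @param community a `community_model`.
#' @param diet a `diet_spec`.
#' @param metabolites base metabolite ids; default all with a fecal exchange.
#' @return A `secretion_profile` tibble (metabolite, max_secretion, floored).
#' @export
secretion_profile <- function(community, diet, metabolites = NULL) {
  stopifnot(inherits(community, "community_model"))
  md <- suppressWarnings(apply_diet(community, diet, compartments = "d"))
  fe <- md$reactions$id[grepl("^EX_.*\\[fe\\]$", md$reactions$id)]
  fe_base <- sub("^EX_(.*)\\[fe\\]$", "\\1", fe)
  if (is.null(metabolites)) metabolites <- sort(fe_base)
  unknown <- setdiff(metabolites, fe_base)
  if (length(unknown) > 0) {
    stop("no fecal exchange for metabolite(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ids <- paste0("EX_", metabolites, "[fe]")
  fv <- tryCatch(fva(md, ids), error = function(e) {
    stop("community infeasible under this diet (", conditionMessage(e),
         "); run check_growth() on the member pan models", call. = FALSE)
  })
  out <- tibble::tibble(metabolite = metabolites,
                        max_secretion = pmax(fv$max_flux, 0),
                        floored = fv$max_flux < 0)
  class(out) <- c("secretion_profile", class(out))
  out
}
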
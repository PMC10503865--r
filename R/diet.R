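# Diet application: a diet is a metabolite -> flux map in mmol/person/day
# applied as uptake bounds on diet-facing exchange reactions. Uptake is a
# negative exchange flux; metabolites absent from the diet have their uptake
# closed, secretion is never touched.

#' Apply diet constraints to a model
#'
#' Diet-facing exchanges are exchange reactions (touching exactly one
#' metabolite, with coefficient -1 by convention) whose metabolite lives in
#' one of the given compartments. For a metabolite in the diet the exchange
#' lower bound becomes `-scale * flux`; for every other diet-facing exchange
#' the lower bound is raised to 0 (uptake closed). Upper bounds (secretion)
#' are untouched. Diet metabolites with no matching exchange produce a
#' warning, not an error: realistic diet tables contain compounds a toy model
#' does not carry.
#'
#' @param model a `stoich_model`.
#' @param diet a `diet_spec`.
#' @param scale multiplier on diet fluxes (host-level and standalone-community
#'   runs can share one table).
#' @param compartments compartment tags whose exchanges are diet-facing.
#' @return The diet-constrained model. Idempotent for fixed diet and scale.
#' @export
apply_diet <- function(model, diet, scale = 1, compartments = c("e", "d")) {
  stopifnot(inherits(diet, "diet_spec"))
  ex <- exchange_reactions(model)
  comp <- vapply(ex$metabolite, function(x) split_met_id(x)$compartment, character(1))
  base <- vapply(ex$metabolite, function(x) split_met_id(x)$base, character(1))
  facing <- comp %in% compartments
  dmap <- stats::setNames(diet$flux, diet$metabolite)
  hit <- character(0)
  for (k in which(facing)) {
    rid <- ex$reaction[k]
    b <- base[k]
    if (b %in% names(dmap)) {
      model <- set_bounds(model, rid, lb = -scale * dmap[[b]])
      hit <- c(hit, b)
    } else {
      i <- match(rid, model$reactions$id)
      model$reactions$lower_bound[i] <- max(model$reactions$lower_bound[i], 0)
    }
  }
  missing <- setdiff(diet$metabolite, hit)
  if (length(missing) > 0) {
    warning("diet metabolite(s) with no exchange in model '", model$id, "': ",
            paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_stoich_model(model)
}

#' Check pan-species growth under a diet
#'
#' Applies the diet to every pan model and maximises its `biomassPan` flux;
#' models whose maximum growth falls below `min_growth` are flagged.
#'
#' @param pan_models named list of pan-species `stoich_model`s.
#' @param diet a `diet_spec`.
#' @param min_growth feasibility threshold (per day).
#' @param compartments diet-facing compartments (see [apply_diet()]).
#' @return Tibble (species, max_growth, ok).
#' @export
check_growth <- function(pan_models, diet, min_growth = 1e-6,
                         compartments = c("e", "d")) {
  stopifnot(length(pan_models) > 0, !is.null(names(pan_models)))
  rows <- purrr::imap(pan_models, function(m, sp) {
    md <- suppressWarnings(apply_diet(m, diet, compartments = compartments))
    sol <- solve_fba(md, "biomassPan", "max")
    g <- if (sol$status == "optimal") sol$objective_value else 0
    tibble::tibble(species = sp, max_growth = g, ok = g >= min_growth)
  })
  dplyr::bind_rows(rows)
}

#' Supplement a diet with one metabolite
#'
#' Returns a copy of the diet in which the metabolite's flux is the maximum
#' of its existing entry (0 if absent) and `amount` — supplementation never
#' lowers an intake.
#'
#' @param diet a `diet_spec`.
#' @param metabolite base metabolite id.
#' @param amount non-negative flux (mmol/person/day).
#' @return The supplemented `diet_spec`.
#' @export
supplement_diet <- function(diet, metabolite, amount) {
  stopifnot(length(metabolite) == 1, amount >= 0)
  tbl <- tibble::as_tibble(diet)
  if (metabolite %in% tbl$metabolite) {
    i <- match(metabolite, tbl$metabolite)
    tbl$flux[i] <- max(tbl$flux[i], amount)
  } else if (amount > 0) {
    tbl <- dplyr::bind_rows(tbl, tibble::tibble(metabolite = metabolite,
                                                flux = amount))
  }
  diet_spec(tbl)
}
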
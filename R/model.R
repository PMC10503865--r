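#' Stoichiometric model container
#'
#' A `stoich_model` bundles a metabolite table, a reaction table with flux
#' bounds, a long (triplet) stoichiometry table, optional extra linear
#' constraint rows over reaction fluxes, and an optional objective. It is the
#' universal substrate for all flux-balance work in the package: single
#' microbes, pan-species models, communities, hosts and host+community
#' assemblies are all `stoich_model`s (possibly with extra metadata).
#'
#' Metabolite identifiers carry their compartment as a bracketed suffix,
#' e.g. `"for[u]"` is formate in the urine compartment. Exchange reactions are
#' reactions touching exactly one metabolite; by convention a negative
#' exchange flux is uptake and a positive one secretion.
#'
#' @param metabolites tibble with columns `id` (full id incl. compartment
#'   tag), `compartment`, `name`.
#' @param reactions tibble with columns `id`, `lower_bound`, `upper_bound`,
#'   `subsystem`.
#' @param stoichiometry tibble with columns `reaction`, `metabolite`, `coef`
#'   (negative = consumed).
#' @param extra_constraints list of constraint rows, each a list with fields
#'   `id`, `coefs` (named numeric over reaction ids), `sense` (`"<="` or
#'   `">="`), `rhs`.
#' @param objective optional list(`reaction`, `sense`) carried as a default
#'   objective.
#' @param id model identifier.
#' @return A `stoich_model` object.
#' @export
stoich_model <- function(metabolites, reactions, stoichiometry,
                         extra_constraints = list(), objective = NULL,
                         id = "model") {
  metabolites <- tibble::as_tibble(metabolites)
  reactions <- tibble::as_tibble(reactions)
  stoichiometry <- tibble::as_tibble(stoichiometry)
  if (!all(c("id", "compartment") %in% names(metabolites))) {
    stop("metabolites needs columns id, compartment", call. = FALSE)
  }
  if (!"name" %in% names(metabolites)) metabolites$name <- metabolites$id
  if (!all(c("id", "lower_bound", "upper_bound") %in% names(reactions))) {
    stop("reactions needs columns id, lower_bound, upper_bound", call. = FALSE)
  }
  if (!"subsystem" %in% names(reactions)) reactions$subsystem <- ""
  m <- structure(
    list(id = id, metabolites = metabolites, reactions = reactions,
         stoichiometry = stoichiometry, extra_constraints = extra_constraints,
         objective = objective),
    class = "stoich_model"
  )
  validate_stoich_model(m)
}

#' Validate a stoichiometric model
#'
#' Checks the structural invariants: unique ids, every stoichiometry entry
#' resolving to a declared metabolite and reaction, lower bounds not above
#' upper bounds, and extra constraints referencing existing reactions only.
#'
#' @param model a `stoich_model`.
#' @return The model, invisibly usable; errors describe the offending element.
#' @export
validate_stoich_model <- function(model) {
  met_ids <- model$metabolites$id
  rxn_ids <- model$reactions$id
  if (anyDuplicated(met_ids)) {
    stop("duplicate metabolite ids: ",
         paste(unique(met_ids[duplicated(met_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rxn_ids)) {
    stop("duplicate reaction ids: ",
         paste(unique(rxn_ids[duplicated(rxn_ids)]), collapse = ", "),
         call. = FALSE)
  }
  bad_met <- setdiff(model$stoichiometry$metabolite, met_ids)
  if (length(bad_met) > 0) {
    stop("stoichiometry references undeclared metabolite(s): ",
         paste(bad_met, collapse = ", "), call. = FALSE)
  }
  bad_rxn <- setdiff(model$stoichiometry$reaction, rxn_ids)
  if (length(bad_rxn) > 0) {
    stop("stoichiometry references undeclared reaction(s): ",
         paste(bad_rxn, collapse = ", "), call. = FALSE)
  }
  if (any(model$reactions$lower_bound > model$reactions$upper_bound)) {
    bad <- model$reactions$id[model$reactions$lower_bound > model$reactions$upper_bound]
    stop("lower_bound > upper_bound for: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (ct in model$extra_constraints) {
    unknown <- setdiff(names(ct$coefs), rxn_ids)
    if (length(unknown) > 0) {
      stop("constraint ", ct$id, " references unknown reaction(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (!ct$sense %in% c("<=", ">=")) {
      stop("constraint ", ct$id, " has sense ", ct$sense,
           "; must be <= or >=", call. = FALSE)
    }
  }
  model
}

#' Build a model from a compact reaction list
#'
#' Convenience constructor for toy models: reactions are given as a named
#' list of `list(stoich = c("met[tag]" = coef, ...), lb, ub)` entries and the
#' metabolite table is inferred from the stoichiometry keys, with the
#' compartment parsed from the bracketed suffix.
#'
#' @param reactions named list of reaction specs (names become reaction ids).
#' @param id model id.
#' @param objective optional default objective reaction id.
#' @return A `stoich_model`.
#' @export
#' @examples
#' m <- model_from_reactions(list(
#'   EX_a = list(stoich = c("a[e]" = -1), lb = -10, ub = 1000),
#'   t_a  = list(stoich = c("a[e]" = -1, "b[e]" = 1), lb = 0, ub = 1000),
#'   EX_b = list(stoich = c("b[e]" = -1), lb = 0, ub = 1000)
#' ))
model_from_reactions <- function(reactions, id = "model", objective = NULL) {
  stopifnot(is.list(reactions), length(reactions) > 0, !is.null(names(reactions)))
  rows <- purrr::imap(reactions, function(r, nm) {
    tibble::tibble(
      reaction = nm,
      metabolite = names(r$stoich),
      coef = unname(as.numeric(r$stoich))
    )
  })
  stoich <- dplyr::bind_rows(rows)
  rxn_tbl <- tibble::tibble(
    id = names(reactions),
    lower_bound = unname(vapply(reactions, function(r) as.numeric(r$lb %||% -1000), numeric(1))),
    upper_bound = unname(vapply(reactions, function(r) as.numeric(r$ub %||% 1000), numeric(1))),
    subsystem = unname(vapply(reactions, function(r) r$subsystem %||% "", character(1)))
  )
  met_ids <- unique(stoich$metabolite)
  met_tbl <- tibble::tibble(
    id = met_ids,
    compartment = unname(vapply(met_ids, function(x) split_met_id(x)$compartment, character(1))),
    name = unname(vapply(met_ids, function(x) split_met_id(x)$base, character(1)))
  )
  obj <- if (!is.null(objective)) list(reaction = objective, sense = "max") else NULL
  stoich_model(met_tbl, rxn_tbl, stoich, objective = obj, id = id)
}

#' Split a compartment-tagged metabolite id
#'
#' @param x a full metabolite id such as `"for[u]"`.
#' @return list with `base` and `compartment` (empty string when untagged).
#' @export
split_met_id <- function(x) {
  m <- regmatches(x, regexec("^(.*)\\[([^]]+)\\]$", x))[[1]]
  if (length(m) == 3) list(base = m[2], compartment = m[3])
  else list(base = x, compartment = "")
}

#' Compose a compartment-tagged metabolite id
#' @param base base metabolite id, e.g. `"for"`.
#' @param compartment compartment tag, e.g. `"u"`.
#' @return full id `"for[u]"`.
#' @export
met_id <- function(base, compartment) paste0(base, "[", compartment, "]")

#' Dense stoichiometric matrix of a model
#'
#' @param model a `stoich_model`.
#' @return Numeric matrix S with metabolites as rows, reactions as columns.
#' @export
s_matrix <- function(model) {
  S <- matrix(0, nrow(model$metabolites), nrow(model$reactions),
              dimnames = list(model$metabolites$id, model$reactions$id))
  S[cbind(model$stoichiometry$metabolite, model$stoichiometry$reaction)] <-
    model$stoichiometry$coef
  S
}

#' Exchange reactions of a model
#'
#' Exchange reactions touch exactly one metabolite; negative flux is uptake,
#' positive is secretion.
#'
#' @param model a `stoich_model`.
#' @return Tibble (reaction, metabolite, coef) of exchange reactions.
#' @export
exchange_reactions <- function(model) {
  model$stoichiometry |>
    dplyr::add_count(.data$reaction, name = "n_mets") |>
    dplyr::filter(.data$n_mets == 1L) |>
    dplyr::select("reaction", "metabolite", "coef")
}

#' Set flux bounds on reactions
#'
#' @param model a `stoich_model`.
#' @param ids reaction ids.
#' @param lb,ub new bounds (recycled); `NULL` leaves the bound unchanged.
#' @return The modified model.
#' @export
set_bounds <- function(model, ids, lb = NULL, ub = NULL) {
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown reaction id(s): ", paste(ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(lb)) model$reactions$lower_bound[idx] <- rep_len(lb, length(idx))
  if (!is.null(ub)) model$reactions$upper_bound[idx] <- rep_len(ub, length(idx))
  validate_stoich_model(model)
}

#' Add a reaction to a model
#'
#' @param model a `stoich_model`.
#' @param id reaction id (must be new).
#' @param stoich named numeric of metabolite coefficients; metabolites not yet
#'   in the model are added with the compartment parsed from their id.
#' @param lb,ub flux bounds.
#' @param subsystem free-text subsystem label.
#' @return The extended model.
#' @export
add_reaction <- function(model, id, stoich, lb = -1000, ub = 1000,
                         subsystem = "") {
  if (id %in% model$reactions$id) stop("reaction ", id, " already exists", call. = FALSE)
  new_mets <- setdiff(names(stoich), model$metabolites$id)
  if (length(new_mets) > 0) {
    model$metabolites <- dplyr::bind_rows(
      model$metabolites,
      tibble::tibble(
        id = new_mets,
        compartment = vapply(new_mets, function(x) split_met_id(x)$compartment, character(1)),
        name = vapply(new_mets, function(x) split_met_id(x)$base, character(1))
      )
    )
  }
  model$reactions <- dplyr::bind_rows(
    model$reactions,
    tibble::tibble(id = id, lower_bound = lb, upper_bound = ub, subsystem = subsystem)
  )
  model$stoichiometry <- dplyr::bind_rows(
    model$stoichiometry,
    tibble::tibble(reaction = id, metabolite = names(stoich),
                   coef = unname(as.numeric(stoich)))
  )
  validate_stoich_model(model)
}

#' Remove reactions (and orphaned metabolites) from a model
#'
#' Unlike [delete_reactions()], which closes bounds, this drops the columns
#' entirely; extra constraints touching a removed reaction are dropped too.
#'
#' @param model a `stoich_model`.
#' @param ids reaction ids to remove.
#' @param drop_orphans drop metabolites no longer referenced by any reaction.
#' @return The reduced model.
#' @export
remove_reactions <- function(model, ids, drop_orphans = TRUE) {
  unknown <- setdiff(ids, model$reactions$id)
  if (length(unknown) > 0) {
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  model$reactions <- dplyr::filter(model$reactions, !.data$id %in% ids)
  model$stoichiometry <- dplyr::filter(model$stoichiometry, !.data$reaction %in% ids)
  model$extra_constraints <- purrr::keep(
    model$extra_constraints,
    function(ct) !any(names(ct$coefs) %in% ids)
  )
  if (drop_orphans) {
    keep <- model$metabolites$id %in% unique(model$stoichiometry$metabolite)
    model$metabolites <- model$metabolites[keep, ]
  }
  validate_stoich_model(model)
}

#' Append a linear inequality constraint over reaction fluxes
#'
#' @param model a `stoich_model`.
#' @param coefs named numeric over reaction ids.
#' @param sense `"<="` or `">="`.
#' @param rhs right-hand side.
#' @param id constraint id.
#' @return The model with the extra row appended.
#' @export
add_constraint <- function(model, coefs, sense, rhs, id = NULL) {
  if (is.null(id)) id <- paste0("ct_", length(model$extra_constraints) + 1L)
  model$extra_constraints <- c(
    model$extra_constraints,
    list(list(id = id, coefs = coefs, sense = sense, rhs = rhs))
  )
  validate_stoich_model(model)
}

#' @export
print.stoich_model <- function(x, ...) {
  cat("<stoich_model> ", x$id, "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      " | reactions: ", nrow(x$reactions),
      " | extra constraints: ", length(x$extra_constraints), "\n", sep = "")
  comps <- sort(unique(x$metabolites$compartment))
  cat("  compartments: ", paste(comps, collapse = ", "), "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
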
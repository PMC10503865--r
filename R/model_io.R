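# Readers/writers for models, abundance tables, diets and reports.
#
# Two model dialects are supported:
#  * "tabular": a directory of three TSVs (metabolites.tsv, reactions.tsv
#    with the stoichiometry encoded as "met:coef;met:coef", bounds.tsv) —
#    hand-writable and diffable, the native fixture format;
#  * "sbml": SBML Level 3 Version 1 with the FBC flux-bounds package, the
#    community standard for exchanging genome-scale models.

#' Read a stoichiometric model
#'
#' @param path for `format = "tabular"` a directory containing
#'   `metabolites.tsv`, `reactions.tsv`, `bounds.tsv`; for `format = "sbml"`
#'   an SBML file.
#' @param format `"tabular"` or `"sbml"`.
#' @return A validated [stoich_model()].
#' @export
read_model <- function(path, format = c("tabular", "sbml")) {
  format <- match.arg(format)
  if (format == "tabular") read_model_tabular(path) else read_model_sbml(path)
}

#' Write a stoichiometric model
#'
#' @param model a `stoich_model`.
#' @param path target directory (tabular) or file (sbml).
#' @param format `"tabular"` or `"sbml"`.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("tabular", "sbml")) {
  format <- match.arg(format)
  if (format == "tabular") write_model_tabular(model, path)
  else write_model_sbml(model, path)
  invisible(path)
}

read_model_tabular <- function(path) {
  if (!dir.exists(path)) stop("model directory not found: ", path, call. = FALSE)
  fm <- file.path(path, "metabolites.tsv")
  fr <- file.path(path, "reactions.tsv")
  fb <- file.path(path, "bounds.tsv")
  for (f in c(fm, fr)) if (!file.exists(f)) stop("missing model file: ", f, call. = FALSE)
  mets <- readr::read_tsv(fm, col_types = readr::cols(.default = "c"))
  rxns <- readr::read_tsv(fr, col_types = readr::cols(.default = "c"))
  if (!all(c("id", "stoichiometry") %in% names(rxns))) {
    stop("reactions.tsv needs columns id, stoichiometry", call. = FALSE)
  }
  stoich <- purrr::map2(rxns$id, rxns$stoichiometry, function(id, s) {
    if (is.na(s) || s == "") {
      stop("reaction ", id, " has empty stoichiometry", call. = FALSE)
    }
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, ":", fixed = TRUE)
    bad <- lengths(kv) != 2
    if (any(bad)) stop("malformed stoichiometry term '", parts[bad][1],
                       "' in reaction ", id, call. = FALSE)
    tibble::tibble(reaction = id,
                   metabolite = vapply(kv, `[`, character(1), 1),
                   coef = as.numeric(vapply(kv, `[`, character(1), 2)))
  }) |> dplyr::bind_rows()
  bounds <- if (file.exists(fb)) {
    readr::read_tsv(fb, col_types = readr::cols(reaction = "c",
                                                lower_bound = "d",
                                                upper_bound = "d"))
  } else tibble::tibble(reaction = character(), lower_bound = numeric(),
                        upper_bound = numeric())
  rxn_tbl <- tibble::tibble(
    id = rxns$id,
    subsystem = if ("subsystem" %in% names(rxns)) dplyr::coalesce(rxns$subsystem, "") else ""
  ) |>
    dplyr::left_join(bounds, by = c(id = "reaction")) |>
    dplyr::mutate(lower_bound = dplyr::coalesce(.data$lower_bound, -1000),
                  upper_bound = dplyr::coalesce(.data$upper_bound, 1000)) |>
    dplyr::select("id", "lower_bound", "upper_bound", "subsystem")
  met_tbl <- tibble::tibble(
    id = mets$id,
    compartment = if ("compartment" %in% names(mets)) mets$compartment
                  else vapply(mets$id, function(x) split_met_id(x)$compartment, character(1)),
    name = if ("name" %in% names(mets)) dplyr::coalesce(mets$name, mets$id) else mets$id
  )
  stoich_model(met_tbl, rxn_tbl, stoich, id = basename(path))
}

write_model_tabular <- function(model, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(model$metabolites[, c("id", "compartment", "name")],
                   file.path(path, "metabolites.tsv"))
  stoich_str <- model$stoichiometry |>
    dplyr::group_by(.data$reaction) |>
    dplyr::summarise(stoichiometry = paste(.data$metabolite,
                                           format_coef(.data$coef), sep = ":",
                                           collapse = ";"),
                     .groups = "drop")
  rxns <- model$reactions |>
    dplyr::left_join(stoich_str, by = c(id = "reaction"))
  readr::write_tsv(rxns[, c("id", "subsystem", "stoichiometry")],
                   file.path(path, "reactions.tsv"))
  readr::write_tsv(
    tibble::tibble(reaction = model$reactions$id,
                   lower_bound = model$reactions$lower_bound,
                   upper_bound = model$reactions$upper_bound),
    file.path(path, "bounds.tsv"))
  invisible(path)
}

format_coef <- function(x) {
  # full double precision, no scientific-notation surprises in fixtures
  vapply(x, function(v) format(v, digits = 17, scientific = FALSE, trim = TRUE),
         character(1))
}

# ---- SBML L3 FBC ----------------------------------------------------------

sbml_ns <- c(
  s = "http://www.sbml.org/sbml/level3/version1/core",
  fbc = "http://www.sbml.org/sbml/level3/version1/fbc/version2"
)

sanitize_sid <- function(x) gsub("[^A-Za-z0-9_]", "_", x)

write_model_sbml <- function(model, path) {
  comps <- sort(unique(model$metabolites$compartment))
  comps[comps == ""] <- "default"
  bnds <- sort(unique(c(model$reactions$lower_bound, model$reactions$upper_bound)))
  bnd_id <- function(v) paste0("b_", sanitize_sid(format(v, digits = 17, trim = TRUE)))
  met_sid <- function(full) {
    p <- split_met_id(full)
    paste0("M_", sanitize_sid(p$base), "_", sanitize_sid(ifelse(p$compartment == "", "default", p$compartment)))
  }
  rxn_sid <- function(id) paste0("R_", sanitize_sid(id))

  doc <- xml2::xml_new_root(
    "sbml", xmlns = sbml_ns[["s"]], "xmlns:fbc" = sbml_ns[["fbc"]],
    level = "3", version = "1", "fbc:required" = "false")
  mdl <- xml2::xml_add_child(doc, "model", id = sanitize_sid(model$id),
                             "fbc:strict" = "true")
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(lc, "compartment", id = paste0("c_", sanitize_sid(cp)),
                        name = cp, constant = "true")
  }
  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    cp <- ifelse(m$compartment == "", "default", m$compartment)
    xml2::xml_add_child(ls, "species", id = met_sid(m$id), name = m$name,
                        compartment = paste0("c_", sanitize_sid(cp)),
                        hasOnlySubstanceUnits = "false",
                        boundaryCondition = "false", constant = "false")
  }
  lprm <- xml2::xml_add_child(mdl, "listOfParameters")
  for (v in bnds) {
    xml2::xml_add_child(lprm, "parameter", id = bnd_id(v),
                        value = format(v, digits = 17, trim = TRUE),
                        constant = "true")
  }
  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  st <- split(model$stoichiometry, model$stoichiometry$reaction)
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rx <- xml2::xml_add_child(lr, "reaction", id = rxn_sid(r$id), name = r$id,
                              reversible = ifelse(r$lower_bound < 0, "true", "false"),
                              fast = "false",
                              "fbc:lowerFluxBound" = bnd_id(r$lower_bound),
                              "fbc:upperFluxBound" = bnd_id(r$upper_bound))
    rows <- st[[r$id]]
    rea <- rows[rows$coef < 0, ]
    pro <- rows[rows$coef > 0, ]
    if (nrow(rea) > 0) {
      lrea <- xml2::xml_add_child(rx, "listOfReactants")
      for (k in seq_len(nrow(rea))) {
        xml2::xml_add_child(lrea, "speciesReference",
                            species = met_sid(rea$metabolite[k]),
                            stoichiometry = format(-rea$coef[k], digits = 17, trim = TRUE),
                            constant = "true")
      }
    }
    if (nrow(pro) > 0) {
      lpro <- xml2::xml_add_child(rx, "listOfProducts")
      for (k in seq_len(nrow(pro))) {
        xml2::xml_add_child(lpro, "speciesReference",
                            species = met_sid(pro$metabolite[k]),
                            stoichiometry = format(pro$coef[k], digits = 17, trim = TRUE),
                            constant = "true")
      }
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

read_model_sbml <- function(path) {
  if (!file.exists(path)) stop("SBML file not found: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("SBML parse failure in ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
  ns <- c(s = xml2::xml_ns(doc)[["d1"]] %||% sbml_ns[["s"]], fbc = sbml_ns[["fbc"]])
  mdl <- xml2::xml_find_first(doc, ".//s:model", ns)
  comp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfCompartments/s:compartment", ns)
  comp_map <- stats::setNames(
    xml2::xml_attr(comp_nodes, "name"),
    xml2::xml_attr(comp_nodes, "id"))
  comp_map[is.na(comp_map)] <- sub("^c_", "", names(comp_map)[is.na(comp_map)])
  sp_nodes <- xml2::xml_find_all(mdl, ".//s:listOfSpecies/s:species", ns)
  sp_ids <- xml2::xml_attr(sp_nodes, "id")
  sp_comp_ref <- xml2::xml_attr(sp_nodes, "compartment")
  sp_comp <- unname(comp_map[sp_comp_ref])
  sp_base <- mapply(function(sid, cp) {
    b <- sub("^M_", "", sid)
    suffix <- paste0("_", sanitize_sid(ifelse(cp == "", "default", cp)))
    sub(paste0(suffix, "$"), "", b)
  }, sp_ids, sp_comp)
  sp_full <- ifelse(sp_comp %in% c("default", ""), sp_base,
                    met_id(sp_base, sp_comp))
  names(sp_full) <- sp_ids
  met_tbl <- tibble::tibble(
    id = unname(sp_full),
    compartment = ifelse(sp_comp == "default", "", sp_comp),
    name = dplyr::coalesce(xml2::xml_attr(sp_nodes, "name"), unname(sp_full)))

  par_nodes <- xml2::xml_find_all(mdl, ".//s:listOfParameters/s:parameter", ns)
  par_map <- stats::setNames(as.numeric(xml2::xml_attr(par_nodes, "value")),
                             xml2::xml_attr(par_nodes, "id"))
  rxn_nodes <- xml2::xml_find_all(mdl, ".//s:listOfReactions/s:reaction", ns)
  rxn_rows <- list(); st_rows <- list()
  for (rx in rxn_nodes) {
    rid_raw <- xml2::xml_attr(rx, "id")
    rid <- xml2::xml_attr(rx, "name")
    if (is.na(rid) || rid == "") rid <- sub("^R_", "", rid_raw)
    lb_ref <- xml2::xml_attr(rx, "fbc:lowerFluxBound", ns = ns)
    ub_ref <- xml2::xml_attr(rx, "fbc:upperFluxBound", ns = ns)
    lb <- if (!is.na(lb_ref) && lb_ref %in% names(par_map)) par_map[[lb_ref]] else -1000
    ub <- if (!is.na(ub_ref) && ub_ref %in% names(par_map)) par_map[[ub_ref]] else 1000
    rxn_rows[[length(rxn_rows) + 1L]] <- tibble::tibble(
      id = rid, lower_bound = lb, upper_bound = ub, subsystem = "")
    for (side in c("listOfReactants", "listOfProducts")) {
      sgn <- if (side == "listOfReactants") -1 else 1
      refs <- xml2::xml_find_all(rx, paste0("./s:", side, "/s:speciesReference"), ns)
      if (length(refs) == 0) next
      sp_ref <- xml2::xml_attr(refs, "species")
      unknown <- setdiff(sp_ref, names(sp_full))
      if (length(unknown) > 0) {
        stop("reaction ", rid, " references undeclared species: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      st_rows[[length(st_rows) + 1L]] <- tibble::tibble(
        reaction = rid,
        metabolite = unname(sp_full[sp_ref]),
        coef = sgn * as.numeric(xml2::xml_attr(refs, "stoichiometry")))
    }
  }
  stoich_model(met_tbl, dplyr::bind_rows(rxn_rows), dplyr::bind_rows(st_rows),
               id = sub("\\.xml$|\\.sbml$", "", basename(path)))
}

# ---- abundances, diets, reports -------------------------------------------

#' Read a sample-by-species abundance table
#'
#' The table is TSV with a `sample` column and one column per species.
#' Duplicate species columns (e.g. genome-level OTUs collapsing to the same
#' species name) are summed. In `"relative"` mode every sample row must sum
#' to one.
#'
#' @param path TSV path.
#' @param mode `"counts"` (raw, kept as is) or `"relative"`.
#' @return An `abundance_table` tibble (first column `sample`, then species)
#'   with attribute `mode`.
#' @export
read_abundances <- function(path, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  tbl <- readr::read_tsv(path, col_types = readr::cols(sample = "c", .default = "d"),
                         name_repair = "minimal")
  if (!"sample" %in% names(tbl)) stop("abundance table needs a 'sample' column", call. = FALSE)
  abundance_table(tbl, mode = mode)
}

#' Construct/validate an abundance table
#'
#' @param tbl tibble with `sample` column plus one numeric column per species;
#'   duplicate species columns are summed.
#' @param mode `"counts"` or `"relative"`.
#' @return An `abundance_table` tibble.
#' @export
abundance_table <- function(tbl, mode = c("counts", "relative")) {
  mode <- match.arg(mode)
  tbl <- tibble::as_tibble(tbl, .name_repair = "minimal")
  sp_cols <- names(tbl)[names(tbl) != "sample"]
  if (length(sp_cols) == 0) stop("no species in abundance table", call. = FALSE)
  vals <- as.matrix(tbl[, names(tbl) != "sample", drop = FALSE])
  if (any(vals < 0, na.rm = TRUE)) stop("negative abundance values", call. = FALSE)
  if (anyNA(vals)) stop("missing abundance values", call. = FALSE)
  if (anyDuplicated(sp_cols)) {
    merged <- t(rowsum(t(vals), group = colnames(vals)))
    out <- tibble::as_tibble(merged)
    out <- dplyr::bind_cols(tibble::tibble(sample = tbl$sample), out)
  } else {
    out <- dplyr::bind_cols(tibble::tibble(sample = tbl$sample),
                            tibble::as_tibble(vals))
  }
  if (mode == "relative") {
    rs <- rowSums(out[, names(out) != "sample", drop = FALSE])
    if (any(abs(rs - 1) > 1e-9)) {
      bad <- out$sample[abs(rs - 1) > 1e-9]
      stop("relative abundances do not sum to 1 for sample(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(out, mode = mode, class = c("abundance_table", class(out)))
}

#' Species names of an abundance table
#' @param table an `abundance_table`.
#' @return Character vector of species ids.
#' @export
abundance_species <- function(table) setdiff(names(table), "sample")

#' Renormalise an abundance table to relative mode
#'
#' Each sample row is divided by its total. Idempotent on relative tables.
#'
#' @param table an `abundance_table`.
#' @return The table in `"relative"` mode.
#' @export
normalize_abundances <- function(table) {
  sp <- abundance_species(table)
  vals <- as.matrix(table[, sp, drop = FALSE])
  rs <- rowSums(vals)
  if (any(rs <= 0)) {
    stop("sample(s) with zero total abundance: ",
         paste(table$sample[rs <= 0], collapse = ", "), call. = FALSE)
  }
  out <- dplyr::bind_cols(tibble::tibble(sample = table$sample),
                          tibble::as_tibble(vals / rs))
  abundance_table(out, mode = "relative")
}

#' Read a diet specification
#'
#' Two-column TSV `metabolite`, `flux` in mmol/person/day. Fluxes must be
#' non-negative; duplicate metabolite rows are an error (ambiguous intent).
#' An empty file yields an empty diet, under which all uptakes are closed
#' downstream.
#'
#' @param path TSV path.
#' @return A `diet_spec` tibble (metabolite, flux).
#' @export
read_diet <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(metabolite = "c", flux = "d"))
  diet_spec(tbl)
}

#' Construct/validate a diet specification
#'
#' @param tbl tibble with columns `metabolite` (base ids, no compartment
#'   tags) and `flux` (mmol/person/day, non-negative).
#' @return A `diet_spec` tibble.
#' @export
diet_spec <- function(tbl = NULL) {
  if (is.null(tbl)) tbl <- tibble::tibble(metabolite = character(), flux = numeric())
  tbl <- tibble::as_tibble(tbl)
  if (!all(c("metabolite", "flux") %in% names(tbl))) {
    stop("diet needs columns metabolite, flux", call. = FALSE)
  }
  if (any(tbl$flux < 0)) stop("negative diet flux", call. = FALSE)
  if (any(grepl("\\[", tbl$metabolite))) {
    stop("diet metabolite ids must be base ids without compartment tags", call. = FALSE)
  }
  if (anyDuplicated(tbl$metabolite)) {
    dup <- unique(tbl$metabolite[duplicated(tbl$metabolite)])
    stop("duplicate diet entries (ambiguous): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  structure(tbl[, c("metabolite", "flux")],
            class = c("diet_spec", class(tbl)))
}

#' Write a diet specification
#' @param diet a `diet_spec`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_diet <- function(diet, path) {
  readr::write_tsv(tibble::as_tibble(diet), path)
  invisible(path)
}

#' Write a result table or report
#'
#' Tabular objects go to TSV with their column order preserved; list-like
#' report objects (co-metabolism reports, knockout reports) go to JSON.
#'
#' @param obj a tibble/data.frame or a report list.
#' @param path target path (`.tsv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_report <- function(obj, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(obj), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    stopifnot(is.data.frame(obj))
    readr::write_tsv(tibble::as_tibble(obj), path)
  }
  invisible(path)
}
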
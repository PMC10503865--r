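# Formate-focused screening procedures on the (germ-free) host model:
# diet-supplementation screen, single-reaction knockout screen, minimal-set
# search over knockout combinations, and the join against a static table of
# disease associations for the screened reactions.

#' Diet-supplementation screen for a urine metabolite
#'
#' For each candidate metabolite, the diet is supplemented to `amount`
#' (mmol/person/day, max rule) and the maximum urine secretion of the target
#' recomputed on the host; candidates raising the optimum by more than 1e-6
#' are classified as increasing. Infeasible supplemented runs are recorded as
#' failed, not raised.
#'
#' @param host a `host_model` (typically germ-free).
#' @param diet baseline `diet_spec`.
#' @param candidates base metabolite ids to supplement one at a time.
#' @param amount supplementation dose (> 0), default 300.
#' @param target base id of the urine metabolite, default `"for"`.
#' @return Tibble (candidate, baseline, supplemented, increases, status).
#' @export
supplementation_screen <- function(host, diet, candidates, amount = 300,
                                   target = "for") {
  stopifnot(amount > 0)
  gf <- suppressWarnings(apply_diet(host, diet, compartments = "d"))
  baseline <- max_urine_secretion(gf, target)
  rows <- purrr::map(candidates, function(cand) {
    d2 <- supplement_diet(diet, cand, amount)
    res <- tryCatch({
      m2 <- suppressWarnings(apply_diet(host, d2, compartments = "d"))
      list(value = max_urine_secretion(m2, target), status = "ok")
    }, error = function(e) list(value = NA_real_, status = "failed"))
    tibble::tibble(candidate = cand, baseline = baseline,
                   supplemented = res$value,
                   increases = !is.na(res$value) &&
                     res$value > baseline + 1e-6,
                   status = res$status)
  })
  dplyr::bind_rows(rows)
}

#' Single-reaction knockout screen for a urine metabolite
#'
#' Deletes each candidate reaction in turn (bounds closed to zero) and
#' recomputes the maximum urine secretion of the target. The reduction
#' fraction is `(baseline - ko_flux) / baseline`, clamped into [0, 1] at
#' numerical tolerance; reactions whose deletion reduces the target by more
#' than `flag_threshold` are flagged.
#'
#' @param host a `host_model` or combined model with the urine exchange.
#' @param diet a `diet_spec`.
#' @param candidates reaction ids to delete one at a time.
#' @param target base id of the urine metabolite.
#' @param flag_threshold fractional-reduction flag threshold, default 0.10.
#' @return A `knockout_report`: list with `baseline`, `results` tibble
#'   (reaction, ko_flux, reduction_fraction, flagged), `flagged` ids,
#'   `flag_threshold`.
#' @export
knockout_screen <- function(host, diet, candidates, target = "for",
                            flag_threshold = 0.10) {
  unknown <- setdiff(candidates, host$reactions$id)
  if (length(unknown) > 0) {
    stop("candidate reaction(s) not in model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- suppressWarnings(apply_diet(host, diet, compartments = "d"))
  baseline <- max_urine_secretion(m, target)
  if (baseline <= 0) {
    stop("baseline urine secretion of ", target,
         " is zero; a knockout screen is meaningless", call. = FALSE)
  }
  rows <- purrr::map(candidates, function(rid) {
    ko <- delete_reactions(m, rid)
    v <- max_urine_secretion(ko, target)
    red <- min(max((baseline - v) / baseline, 0), 1)
    tibble::tibble(reaction = rid, ko_flux = v, reduction_fraction = red)
  })
  results <- dplyr::bind_rows(rows) |>
    dplyr::mutate(flagged = .data$reduction_fraction > flag_threshold)
  structure(list(baseline = baseline, results = results,
                 flagged = results$reaction[results$flagged],
                 flag_threshold = flag_threshold, target = target),
            class = "knockout_report")
}

#' @export
print.knockout_report <- function(x, ...) {
  cat("<knockout_report> target ", x$target, ", baseline ",
      format(x$baseline), "\n", sep = "")
  cat("  ", nrow(x$results), " candidates, ", length(x$flagged),
      " flagged (> ", 100 * x$flag_threshold, "% reduction)\n", sep = "")
  invisible(x)
}

#' Tidy a knockout report
#' @param x a `knockout_report`.
#' @param ... unused.
#' @return The per-reaction results tibble with the baseline attached.
#' @method tidy knockout_report
#' @export
tidy.knockout_report <- function(x, ...) {
  dplyr::mutate(x$results, baseline = x$baseline, .before = 1)
}

#' One-row summary of a knockout report
#' @param x a `knockout_report`.
#' @param ... unused.
#' @return Tibble with baseline, candidate and flagged counts, threshold.
#' @method glance knockout_report
#' @export
glance.knockout_report <- function(x, ...) {
  tibble::tibble(baseline = x$baseline, n_candidates = nrow(x$results),
                 n_flagged = length(x$flagged),
                 flag_threshold = x$flag_threshold)
}

ms_reduction <- function(m, baseline, target, set) {
  v <- if (length(set) == 0) baseline else {
    max_urine_secretion(delete_reactions(m, set), target)
  }
  min(max((baseline - v) / baseline, 0), 1)
}

#' Minimal reaction set reducing a urine secretion flux
#'
#' Searches for a small set of candidate reactions whose joint deletion
#' reduces the target's maximum urine secretion by at least `goal_reduction`.
#' With `method = "greedy"` (default): forward selection repeatedly adds the
#' candidate with the largest marginal reduction until the goal is met or no
#' candidate improves by more than 1e-6, then a backward pass drops members
#' whose removal keeps the goal satisfied (minimality with respect to the
#' greedy set). With `method = "exhaustive"` (candidate lists up to
#' `exhaustive_max`): all subsets are enumerated in order of increasing size
#' and the first (lexicographically earliest) subset meeting the goal is
#' returned.
#'
#' @param host a `host_model` or combined model.
#' @param diet a `diet_spec`.
#' @param candidates candidate reaction ids.
#' @param target base id of the urine metabolite.
#' @param goal_reduction fractional reduction to reach, in [0, 1].
#' @param method `"greedy"` or `"exhaustive"`.
#' @param exhaustive_max largest candidate count for which exhaustive search
#'   is allowed.
#' @return A `minimal_set_result`: list with `set`, `achieved_reduction`,
#'   `reached` (goal met?), `baseline`, `goal_reduction`, `method`.
#' @export
minimal_set_search <- function(host, diet, candidates, target = "for",
                               goal_reduction = 0.85,
                               method = c("greedy", "exhaustive"),
                               exhaustive_max = 15) {
  method <- match.arg(method)
  unknown <- setdiff(candidates, host$reactions$id)
  if (length(unknown) > 0) {
    stop("candidate reaction(s) not in model: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- suppressWarnings(apply_diet(host, diet, compartments = "d"))
  baseline <- max_urine_secretion(m, target)
  if (baseline <= 0) stop("baseline urine secretion is zero", call. = FALSE)
  if (goal_reduction <= 0) {
    return(structure(list(set = character(0), achieved_reduction = 0,
                          reached = TRUE, baseline = baseline,
                          goal_reduction = goal_reduction, method = method),
                     class = "minimal_set_result"))
  }

  if (method == "exhaustive") {
    if (length(candidates) > exhaustive_max) {
      stop("exhaustive search limited to ", exhaustive_max,
           " candidates; use method = \"greedy\"", call. = FALSE)
    }
    best_set <- candidates
    best_red <- ms_reduction(m, baseline, target, candidates)
    for (k in seq_along(candidates)) {
      for (idx in utils::combn(length(candidates), k, simplify = FALSE)) {
        set <- candidates[idx]
        red <- ms_reduction(m, baseline, target, set)
        if (red >= goal_reduction) {
          return(structure(list(set = set, achieved_reduction = red,
                                reached = TRUE, baseline = baseline,
                                goal_reduction = goal_reduction,
                                method = method),
                           class = "minimal_set_result"))
        }
      }
    }
    return(structure(list(set = best_set, achieved_reduction = best_red,
                          reached = FALSE, baseline = baseline,
                          goal_reduction = goal_reduction, method = method),
                     class = "minimal_set_result"))
  }

  # greedy forward selection
  set <- character(0)
  achieved <- 0
  pool <- candidates
  while (achieved < goal_reduction && length(pool) > 0) {
    reds <- vapply(pool, function(r) ms_reduction(m, baseline, target, c(set, r)),
                   numeric(1))
    best <- which.max(reds)          # ties: first in candidate order
    if (reds[best] <= achieved + 1e-6) break
    set <- c(set, pool[best])
    achieved <- unname(reds[best])
    pool <- pool[-best]
  }
  reached <- achieved >= goal_reduction
  if (reached && length(set) > 1) {
    # backward pass: drop members not needed to hold the goal
    for (r in set) {
      trial <- setdiff(set, r)
      red <- ms_reduction(m, baseline, target, trial)
      if (red >= goal_reduction) {
        set <- trial
        achieved <- red
      }
    }
  }
  structure(list(set = set, achieved_reduction = achieved, reached = reached,
                 baseline = baseline, goal_reduction = goal_reduction,
                 method = "greedy"),
            class = "minimal_set_result")
}

#' @export
print.minimal_set_result <- function(x, ...) {
  cat("<minimal_set_result> ", length(x$set), " reaction(s): ",
      paste(x$set, collapse = ", "), "\n", sep = "")
  cat("  achieved reduction ", format(x$achieved_reduction),
      if (x$reached) " (goal met)" else " (goal NOT met)", "\n", sep = "")
  invisible(x)
}

#' Join knockout results with disease-association annotations
#'
#' Annotations are a static table (reaction, genes, ad_association in
#' {positive, negative, none}, optional evidence); reactions missing from it
#' get `"none"`. Duplicated annotation rows for one reaction are an error —
#' the association direction would be ambiguous.
#'
#' @param report a `knockout_report`.
#' @param annotations tibble with columns `reaction`, `genes`,
#'   `ad_association` (and optionally `evidence`).
#' @return An `ad_annotation` list with `table` (joined tibble) and `summary`
#'   (n_candidates, n_flagged, n_annotated, n_overlap).
#' @export
annotate_with_ad <- function(report, annotations) {
  stopifnot(inherits(report, "knockout_report"))
  annotations <- tibble::as_tibble(annotations)
  if (nrow(annotations) == 0) {
    annotations <- tibble::tibble(reaction = character(), genes = character(),
                                  ad_association = character())
  }
  if (!all(c("reaction", "ad_association") %in% names(annotations))) {
    stop("annotations need columns reaction, ad_association", call. = FALSE)
  }
  if (anyDuplicated(annotations$reaction)) {
    dup <- unique(annotations$reaction[duplicated(annotations$reaction)])
    stop("duplicated annotation rows (ambiguous direction) for: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(annotations$reaction, report$results$reaction)
  if (length(extra) > 0) {
    stop("annotation(s) for reaction(s) outside the screened candidates: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  joined <- report$results |>
    dplyr::left_join(annotations, by = "reaction") |>
    dplyr::mutate(ad_association = dplyr::coalesce(.data$ad_association, "none"))
  summary <- tibble::tibble(
    n_candidates = nrow(joined),
    n_flagged = sum(joined$flagged),
    n_annotated = sum(joined$ad_association != "none"),
    n_overlap = sum(joined$flagged & joined$ad_association != "none"))
  structure(list(table = joined, summary = summary), class = "ad_annotation")
}

#' @export
print.ad_annotation <- function(x, ...) {
  cat("<ad_annotation> ", x$summary$n_annotated, "/", x$summary$n_candidates,
      " annotated, overlap with flagged: ", x$summary$n_overlap, "\n", sep = "")
  invisible(x)
}
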
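# End-to-end orchestration over the synthetic bundle: generate inputs, build
# pan-species and community models, run secretion FVA, host integration and
# the co-metabolism decomposition, the formate screens, and the cohort
# statistics, writing every result as TSV/JSON into an output directory.
# Every stage is an exported function; run_pipeline() chains them. All
# randomness flows from the single `seed`, so two runs with the same seed
# produce byte-identical reports.

#' Generate the full synthetic input bundle
#'
#' @param seed integer seed driving every generator.
#' @param n_species number of toy species.
#' @param n_strains strains per species (pan models are built from these).
#' @param cohort a [cohort_spec()]; its seed and species count are overridden
#'   to match.
#' @return list with `strains` (list of per-species strain lists), `host_f`,
#'   `host_m`, `diet_minimal`, `diet_full`, `cohort` (counts + metadata),
#'   `metabolome`.
#' @export
generate_inputs <- function(seed = 1, n_species = 6, n_strains = 2,
                            cohort = cohort_spec()) {
  microbes <- make_toy_microbes(n_species, seed = seed)
  strains <- lapply(names(microbes), function(sp) {
    make_toy_strains(microbes[[sp]], n_strains, seed = seed + match(sp, names(microbes)))
  })
  names(strains) <- names(microbes)
  cohort$seed <- seed
  cohort$n_species <- n_species
  list(strains = strains,
       host_f = make_toy_host(toy_host_spec(sex = "female")),
       host_m = make_toy_host(toy_host_spec(sex = "male")),
       diet_minimal = make_diet("minimal"),
       diet_full = make_diet("full"),
       cohort = make_cohort(cohort),
       metabolome = make_metabolome(seed = seed))
}

#' Build pan-species models from strain bundles
#'
#' @param strains named list (species -> list of strain models).
#' @return Named list of pan `stoich_model`s.
#' @export
build_pan_models <- function(strains) {
  out <- lapply(names(strains), function(sp) build_pan_model(strains[[sp]], sp))
  names(out) <- names(strains)
  out
}

#' Run the whole synthetic analysis
#'
#' Executes every pipeline stage on the synthetic bundle and writes the
#' reports below into `out_dir`. Problem sizes (species, strains, host-run
#' samples) are kept at toy scale so a full run takes well under a minute.
#'
#' Outputs: `growth_report.tsv`, `coverage.tsv`, `secretion_profiles.tsv`,
#' `cometabolism.tsv`, `high_secretors.tsv`, `knockout_report.tsv` (+
#' `.json`), `minimal_set.json`, `supplementation.tsv`, `ad_annotation.tsv`,
#' `metabolite_screen.tsv`, `fractional_regression.tsv`, `log_ratio.tsv`,
#' `flux_comparison.tsv`, `run_info.tsv` (seed, config hash).
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed.
#' @param config a [cometab_config()].
#' @param n_species,n_strains synthetic bundle size.
#' @param n_host_samples number of cohort samples run through the host
#'   integration (LP-heavy; the cohort statistics always use all samples).
#' @return Invisibly, a list with every in-memory result.
#' @export
run_pipeline <- function(out_dir, seed = 1, config = cometab_config(),
                         n_species = 6, n_strains = 2, n_host_samples = 4) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inp <- generate_inputs(seed = seed, n_species = n_species,
                         n_strains = n_strains)
  pans <- build_pan_models(inp$strains)

  growth <- check_growth(pans, inp$diet_full, min_growth = config$min_growth)
  write_report(growth, file.path(out_dir, "growth_report.tsv"))

  flt <- filter_and_renormalize(inp$cohort$counts, names(pans),
                                cutoff = config$abundance_cutoff)
  write_report(flt$coverage, file.path(out_dir, "coverage.tsv"))

  # host runs take samples from both groups so the flux comparison is defined
  meta <- inp$cohort$metadata
  run_samples <- unlist(lapply(split(meta$sample, meta$group), function(s) {
    s[seq_len(min(ceiling(n_host_samples / 2), length(s)))]
  }), use.names = FALSE)[seq_len(min(n_host_samples, nrow(meta)))]
  gb <- c(config$growth_lb, config$growth_ub)
  sec_rows <- list(); cm_rows <- list(); hs_rows <- list()
  for (s in run_samples) {
    ab <- as.numeric(flt$table[flt$table$sample == s,
                               abundance_species(flt$table)])
    names(ab) <- abundance_species(flt$table)
    comm <- build_community(pans, ab[ab > 0],
                            coupling_factor = config$coupling_factor,
                            growth_bounds = gb, sample_id = s)
    sp <- secretion_profile(comm, inp$diet_full,
                            intersect(c("for", "ser_L", "trp_L", "fald"),
                                      sub("^EX_(.*)\\[fe\\]$", "\\1",
                                          grep("^EX_.*\\[fe\\]$",
                                               comm$reactions$id, value = TRUE))))
    sec_rows[[s]] <- dplyr::mutate(tibble::as_tibble(sp), sample = s,
                                   .before = 1)
    host <- if (meta$sex[meta$sample == s] == "female") inp$host_f else inp$host_m
    rep <- cometabolism_decomposition(host, comm, inp$diet_full, "for")
    cm_rows[[s]] <- dplyr::mutate(tidy.cometab_report(rep), sample = s,
                                  sex = host$sex, .before = 1)
    combined <- suppressWarnings(apply_diet(attach_community(host, comm),
                                            inp$diet_full, compartments = "d"))
    sol <- solve_fba(combined, "EX_for[u]", "max")
    hs <- high_secretors(sol, threshold = config$secretion_threshold)
    hs_rows[[s]] <- tibble::tibble(sample = s,
                                   metabolite = if (length(hs)) hs else NA_character_)
  }
  write_report(dplyr::bind_rows(sec_rows),
               file.path(out_dir, "secretion_profiles.tsv"))
  cometab <- dplyr::bind_rows(cm_rows)
  write_report(cometab, file.path(out_dir, "cometabolism.tsv"))
  write_report(dplyr::bind_rows(hs_rows),
               file.path(out_dir, "high_secretors.tsv"))

  # germ-free formate screens on the female host
  host <- inp$host_f
  candidates <- intersect(
    c("PSP_L", "SFGTH", "TRPO2", "DKMPPD", "PGCD", "PSERT", "SERFORM",
      "GLYCOLYSIS", "FALDH", "FKYNH", "DM_lkynr", "ABSt_chola"),
    host$reactions$id)
  ko <- knockout_screen(host, inp$diet_full, candidates,
                        flag_threshold = config$flag_threshold)
  write_report(tidy.knockout_report(ko),
               file.path(out_dir, "knockout_report.tsv"))
  write_report(list(baseline = ko$baseline, flagged = ko$flagged,
                    flag_threshold = ko$flag_threshold),
               file.path(out_dir, "knockout_report.json"))
  ms <- minimal_set_search(host, inp$diet_full,
                           c("PSP_L", "SFGTH", "TRPO2", "DKMPPD"),
                           goal_reduction = 0.85,
                           exhaustive_max = config$exhaustive_max)
  write_report(list(set = ms$set, achieved_reduction = ms$achieved_reduction,
                    reached = ms$reached, baseline = ms$baseline),
               file.path(out_dir, "minimal_set.json"))
  sup <- supplementation_screen(host, inp$diet_minimal,
                                c("ser_L", "fald", "trp_L", "dkmpp", "chola"),
                                amount = config$supplement_amount)
  write_report(sup, file.path(out_dir, "supplementation.tsv"))
  ann <- annotate_with_ad(ko, synthetic_ad_annotations(candidates))
  write_report(ann$table, file.path(out_dir, "ad_annotation.tsv"))

  # cohort statistics over all samples
  scr <- screen_metabolites(inp$metabolome$concentrations,
                            inp$metabolome$metadata,
                            hc_type = config$hc_type)
  write_report(scr, file.path(out_dir, "metabolite_screen.tsv"))
  fr <- fractional_regression(normalize_abundances(inp$cohort$counts), meta,
                              hc_type = config$hc_type)
  write_report(fr, file.path(out_dir, "fractional_regression.tsv"))
  lr <- log_ratio_test(inp$cohort$counts, meta, c("sp01", "sp02"),
                       c("sp03", "sp04"), pseudocount = config$pseudocount)
  write_report(lr$test, file.path(out_dir, "log_ratio.tsv"))
  fc <- compare_fluxes(
    tibble::tibble(sample = cometab$sample, flux = cometab$personalised_max),
    meta, hc_type = config$hc_type)
  write_report(fc, file.path(out_dir, "flux_comparison.tsv"))

  write_report(tibble::tibble(key = c("seed", "config_hash"),
                              value = c(as.character(seed),
                                        config_hash(config))),
               file.path(out_dir, "run_info.tsv"))
  invisible(list(growth = growth, coverage = flt$coverage,
                 secretion = dplyr::bind_rows(sec_rows), cometabolism = cometab,
                 knockout = ko, minimal_set = ms, supplementation = sup,
                 annotation = ann, metabolite_screen = scr,
                 fractional = fr, log_ratio = lr, flux_comparison = fc))
}

#' Synthetic disease-association annotation table
#'
#' A deterministic stand-in for a curated reaction-to-gene disease
#' association table: the serine-branch reactions are marked positively
#' associated, the tryptophan-branch ones negatively, everything else none.
#'
#' @param candidates reaction ids screened.
#' @return Tibble (reaction, genes, ad_association, evidence).
#' @export
synthetic_ad_annotations <- function(candidates) {
  pos <- intersect(c("PGCD", "PSERT", "PSP_L", "SFGTH"), candidates)
  neg <- intersect(c("TRPO2", "FKYNH"), candidates)
  tibble::tibble(
    reaction = c(pos, neg),
    genes = paste0("GENE_", c(pos, neg)),
    ad_association = c(rep("positive", length(pos)), rep("negative", length(neg))),
    evidence = "synthetic annotation")
}

#' Compare two pipeline output directories for identity
#'
#' @param dir_a,dir_b output directories of [run_pipeline()].
#' @return TRUE when both hold the same files with identical MD5 hashes.
#' @export
pipeline_outputs_identical <- function(dir_a, dir_b) {
  fa <- sort(list.files(dir_a)); fb <- sort(list.files(dir_b))
  if (!identical(fa, fb)) return(FALSE)
  ha <- unname(tools::md5sum(file.path(dir_a, fa)))
  hb <- unname(tools::md5sum(file.path(dir_b, fb)))
  identical(ha, hb)
}
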
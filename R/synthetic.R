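# Synthetic-data generators: every input the pipeline needs, at toy scale.
#
# The generators emulate (i) gut microbes with distinct fermentation traits
# (formate secretors, precursor secretors, substrate requirements),
# (ii) a multi-organ host carrying the four known formate-producing branches
# (serine, formaldehyde, tryptophan, methionine-salvage) ending in the
# capacity-limited reactions PSP_L, SFGTH, TRPO2 and DKMPPD, (iii) diets,
# and (iv) case/control cohorts with planted compositional shifts. Every
# generator is a pure function of its spec and seed.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate toy gut microbe models
#'
#' Each species model has diet exchanges and transporters (glucose,
#' ammonium, optionally fructose), a growth reaction producing a biomass
#' metabolite (plus a demand so the standalone model can grow), and —
#' depending on its traits — a bounded formate-fermentation pathway and
#' bounded precursor-synthesis pathways (L-serine, L-tryptophan,
#' formaldehyde) with export to the extracellular space. Capacities are
#' drawn deterministically from the seed.
#'
#' @param n number of species (>= 1).
#' @param traits optional list (length n) of per-species lists with fields
#'   `formate_secretor` (logical), `precursor_secretor` (character vector of
#'   base metabolite ids among ser_L, trp_L, fald), `substrate_needs`
#'   (character; `"fruc"` marks a fructose-requiring species), and optional
#'   `formate_cap`, `precursor_caps` (named numeric). When `NULL`, traits are
#'   generated from the seed: about half the species secrete formate, a third
#'   secrete each precursor, and (for n >= 5) species 5 requires fructose.
#' @param seed integer seed.
#' @return Named list of `stoich_model`s (`sp01`, `sp02`, ...).
#' @export
make_toy_microbes <- function(n, traits = NULL, seed = 1) {
  stopifnot(n >= 1)
  with_seed(seed, {
    if (is.null(traits)) {
      traits <- lapply(seq_len(n), function(i) {
        list(
          formate_secretor = stats::runif(1) < 0.5,
          precursor_secretor = c("ser_L", "trp_L", "fald")[stats::runif(3) < 1 / 3],
          substrate_needs = if (i == 5) c("glc_D", "nh4", "fruc") else c("glc_D", "nh4")
        )
      })
    }
    stopifnot(length(traits) == n)
    out <- lapply(seq_len(n), function(i) {
      tr <- traits[[i]]
      sp <- sprintf("sp%02d", i)
      for_cap <- tr$formate_cap %||% round(stats::runif(1, 4, 10), 2)
      pre_caps <- tr$precursor_caps %||% stats::setNames(
        round(stats::runif(length(tr$precursor_secretor), 3, 8), 2),
        tr$precursor_secretor)
      make_toy_microbe(sp, tr, for_cap, pre_caps)
    })
    names(out) <- sprintf("sp%02d", seq_len(n))
    out
  })
}

make_toy_microbe <- function(sp, tr, for_cap, pre_caps) {
  rx <- list(
    EX_glc_D = list(stoich = c("glc_D[e]" = -1), lb = -1000, ub = 1000),
    t_glc_D = list(stoich = c("glc_D[e]" = -1, "glc_D[c]" = 1), lb = 0, ub = 1000),
    EX_nh4 = list(stoich = c("nh4[e]" = -1), lb = -1000, ub = 1000),
    t_nh4 = list(stoich = c("nh4[e]" = -1, "nh4[c]" = 1), lb = 0, ub = 1000)
  )
  growth_in <- c("glc_D[c]" = -1, "nh4[c]" = -0.5)
  if ("fruc" %in% (tr$substrate_needs %||% character(0))) {
    rx$EX_fruc <- list(stoich = c("fruc[e]" = -1), lb = -1000, ub = 1000)
    rx$t_fruc <- list(stoich = c("fruc[e]" = -1, "fruc[c]" = 1), lb = 0, ub = 1000)
    growth_in <- c(growth_in, "fruc[c]" = -0.2)
  }
  rx[[paste0("biomass_", sp)]] <- list(
    stoich = c(growth_in, "biomass[c]" = 1), lb = 0, ub = 1000)
  rx$DM_biomass <- list(stoich = c("biomass[c]" = -1), lb = 0, ub = 1000)
  if (isTRUE(tr$formate_secretor)) {
    rx$FORferm <- list(stoich = c("glc_D[c]" = -1, "for[c]" = 2),
                       lb = 0, ub = for_cap)
    rx$t_for <- list(stoich = c("for[c]" = -1, "for[e]" = 1), lb = 0, ub = 1000)
    rx$EX_for <- list(stoich = c("for[e]" = -1), lb = 0, ub = 1000)
  }
  for (p in tr$precursor_secretor %||% character(0)) {
    rx[[paste0("PSYN_", p)]] <- list(
      stoich = c("glc_D[c]" = -1, "nh4[c]" = -0.3,
                 stats::setNames(1, met_id(p, "c"))),
      lb = 0, ub = unname(pre_caps[[p]]))
    rx[[paste0("t_", p)]] <- list(
      stoich = stats::setNames(c(-1, 1), c(met_id(p, "c"), met_id(p, "e"))),
      lb = 0, ub = 1000)
    rx[[paste0("EX_", p)]] <- list(
      stoich = stats::setNames(-1, met_id(p, "e")), lb = 0, ub = 1000)
  }
  model_from_reactions(rx, id = sp)
}

#' Derive strain variants of a species model
#'
#' Strains are downgraded copies of the species model: each strain may lose
#' some optional pathways (precursor synthesis, formate fermentation) and has
#' its remaining internal upper bounds shrunk by a random factor. Biomass
#' stoichiometry is shared across strains, so the pan model (set union,
#' widest bounds) contains every strain's feasible exchange fluxes.
#'
#' @param species_model a `stoich_model` from [make_toy_microbes()].
#' @param n_strains number of strains (>= 1); strain 1 is the full model.
#' @param seed integer seed.
#' @return List of `stoich_model`s with strain-named biomass reactions.
#' @export
make_toy_strains <- function(species_model, n_strains = 2, seed = 1) {
  stopifnot(n_strains >= 1)
  with_seed(seed, {
    bio_old <- species_model$reactions$id[grepl("^biomass", species_model$reactions$id)]
    stopifnot(length(bio_old) == 1)
    optional <- species_model$reactions$id[grepl("^(PSYN_|FORferm)", species_model$reactions$id)]
    lapply(seq_len(n_strains), function(k) {
      m <- species_model
      bio_new <- paste0("biomass_", m$id, "_s", k)
      m$reactions$id[m$reactions$id == bio_old] <- bio_new
      m$stoichiometry$reaction[m$stoichiometry$reaction == bio_old] <- bio_new
      if (k > 1) {
        # strains lose optional pathways and run the rest at reduced capacity
        lose <- optional[stats::runif(length(optional)) < 0.4]
        lose <- unique(unlist(lapply(lose, function(r) {
          if (startsWith(r, "PSYN_")) {
            p <- sub("^PSYN_", "", r)
            c(r, paste0("t_", p), paste0("EX_", p))
          } else if (r == "FORferm") c("FORferm", "t_for", "EX_for") else r
        })))
        if (length(lose) > 0 &&
            length(lose) < sum(grepl("^(PSYN_|FORferm|t_|EX_)", m$reactions$id))) {
          m <- remove_reactions(m, intersect(lose, m$reactions$id))
        }
        internal <- m$reactions$id[grepl("^(PSYN_|FORferm)", m$reactions$id)]
        if (length(internal) > 0) {
          f <- stats::runif(length(internal), 0.5, 1)
          i <- match(internal, m$reactions$id)
          m$reactions$upper_bound[i] <- m$reactions$upper_bound[i] * f
        }
      }
      m$id <- paste0(m$id, "_s", k)
      validate_stoich_model(m)
    })
  })
}

#' Toy host specification
#'
#' @param sex `"female"` or `"male"`.
#' @param organs organ names; branches live in the first organ's cytosol, the
#'   last organ exports to urine.
#' @param branches subset of `"serine"` (3pg -> ser_L -> formate, endpoint
#'   PSP_L), `"formaldehyde"` (fald -> S-formylglutathione -> formate,
#'   endpoint SFGTH), `"tryptophan"` (trp_L -> N-formylkynurenine -> formate,
#'   endpoint TRPO2), `"methionine_salvage"` (dkmpp -> formate, endpoint
#'   DKMPPD).
#' @param capacities named capacities (mmol/person/day) of the branch
#'   endpoint reactions.
#' @param basal capacity of the diet-independent basal formate source.
#' @param nh4_branch include an ammonium-limited formate branch (a non-carbon
#'   dietary candidate that relieves a nitrogen bottleneck).
#' @return A `toy_host_spec` list.
#' @export
toy_host_spec <- function(sex = c("female", "male"),
                          organs = c("liver", "kidney"),
                          branches = c("serine", "formaldehyde", "tryptophan",
                                       "methionine_salvage"),
                          capacities = c(serine = 5, formaldehyde = 3,
                                         tryptophan = 2, methionine_salvage = 1),
                          basal = 1, nh4_branch = FALSE) {
  sex <- match.arg(sex)
  if (length(branches) > 0) branches <- match.arg(branches, several.ok = TRUE)
  stopifnot(all(branches %in% names(capacities)), length(organs) >= 1)
  structure(list(sex = sex, organs = organs, branches = branches,
                 capacities = capacities[branches], basal = basal,
                 nh4_branch = nh4_branch),
            class = "toy_host_spec")
}

#' Build the toy multi-organ host model
#'
#' The host has a diet compartment `[d]`, a large-intestinal lumen `[luLI]`
#' reachable from the diet, organ cytosols, and a urine compartment `[u]`
#' with the exchange `EX_for[u]`. The enabled formate branches sit in the
#' first organ with their endpoint reactions capacity-bounded, plus a basal
#' formate source; under a diet supplying every precursor in excess, the
#' germ-free maximum urine formate flux equals the sum of the enabled branch
#' capacities plus the basal capacity. Microbial metabolites reach the host
#' through absorption transports from `[luLI]`.
#'
#' @param spec a [toy_host_spec()].
#' @return A `host_model` (inherits `stoich_model`) with fields `sex`,
#'   `lumen_tag = "luLI"`, `urine_tag = "u"`, `organ_tags`.
#' @export
make_toy_host <- function(spec = toy_host_spec()) {
  stopifnot(inherits(spec, "toy_host_spec"))
  organ_tags <- paste0("c", toupper(substr(spec$organs, 1, 1)),
                       substr(spec$organs, 2, 2))
  o1 <- organ_tags[1]
  oN <- organ_tags[length(organ_tags)]
  absorbable <- c("glc_D", "fruc", "nh4", "for", "ser_L", "fald", "trp_L",
                  "dkmpp", "chola")
  rx <- list()
  for (b in absorbable) {
    rx[[paste0("EX_", b, "[d]")]] <- list(
      stoich = stats::setNames(-1, met_id(b, "d")), lb = -1000, ub = 1000)
    rx[[paste0("DUt_", b)]] <- list(
      stoich = stats::setNames(c(-1, 1), c(met_id(b, "d"), met_id(b, "luLI"))),
      lb = 0, ub = 1000)
    rx[[paste0("ABSt_", b)]] <- list(
      stoich = stats::setNames(c(-1, 1), c(met_id(b, "luLI"), met_id(b, o1))),
      lb = 0, ub = 1000)
  }
  rx$DM_chola <- list(stoich = stats::setNames(-1, met_id("chola", o1)),
                      lb = 0, ub = 1000)
  cim <- function(b) met_id(b, o1)  # first-organ cytosol metabolite
  if ("serine" %in% spec$branches) {
    rx$GLYCOLYSIS <- list(stoich = stats::setNames(c(-1, 2), cim(c("glc_D", "3pg"))),
                          lb = 0, ub = 1000)
    rx$PGCD <- list(stoich = stats::setNames(c(-1, 1), cim(c("3pg", "3php"))),
                    lb = 0, ub = 1000)
    rx$PSERT <- list(stoich = stats::setNames(c(-1, 1), cim(c("3php", "pser_L"))),
                     lb = 0, ub = 1000)
    rx$PSP_L <- list(stoich = stats::setNames(c(-1, 1), cim(c("pser_L", "ser_L"))),
                     lb = 0, ub = unname(spec$capacities[["serine"]]))
  }
  # serine-to-formate conversion is always present so microbially derived
  # serine can be co-metabolised even when the endogenous branch is off
  rx$SERFORM <- list(stoich = stats::setNames(c(-1, 1), cim(c("ser_L", "for"))),
                     lb = 0, ub = 1000)
  if ("formaldehyde" %in% spec$branches) {
    rx$FALDH <- list(stoich = stats::setNames(c(-1, -1, 1),
                                              cim(c("fald", "gthrd", "Sfglutth"))),
                     lb = 0, ub = 1000)
    rx$SFGTH <- list(stoich = stats::setNames(c(-1, 1, 1),
                                              cim(c("Sfglutth", "gthrd", "for"))),
                     lb = 0, ub = unname(spec$capacities[["formaldehyde"]]))
  }
  if ("tryptophan" %in% spec$branches) {
    rx$TRPO2 <- list(stoich = stats::setNames(c(-1, 1), cim(c("trp_L", "Lfkyn"))),
                     lb = 0, ub = unname(spec$capacities[["tryptophan"]]))
    rx$FKYNH <- list(stoich = stats::setNames(c(-1, 1, 1),
                                              cim(c("Lfkyn", "lkynr", "for"))),
                     lb = 0, ub = 1000)
    rx$DM_lkynr <- list(stoich = stats::setNames(-1, cim("lkynr")),
                        lb = 0, ub = 1000)
  }
  if ("methionine_salvage" %in% spec$branches) {
    rx$DKMPPD <- list(stoich = stats::setNames(c(-1, 1, 1),
                                               cim(c("dkmpp", "for", "5mtr"))),
                      lb = 0, ub = unname(spec$capacities[["methionine_salvage"]]))
    rx$DM_5mtr <- list(stoich = stats::setNames(-1, cim("5mtr")),
                       lb = 0, ub = 1000)
  }
  if (isTRUE(spec$nh4_branch)) {
    rx$AMFORM <- list(stoich = stats::setNames(c(-1, -1, 1, 1),
                                               cim(c("glc_D", "nh4", "for", "gly"))),
                      lb = 0, ub = 1000)
    rx$DM_gly <- list(stoich = stats::setNames(-1, cim("gly")), lb = 0, ub = 1000)
  }
  if (spec$basal > 0) {
    rx$FORbasal <- list(stoich = stats::setNames(1, cim("for")),
                        lb = 0, ub = spec$basal)
  }
  if (o1 != oN) {
    rx$FORtk <- list(stoich = stats::setNames(c(-1, 1),
                                              c(met_id("for", o1), met_id("for", oN))),
                     lb = 0, ub = 1000)
  }
  rx$URIt <- list(stoich = stats::setNames(c(-1, 1),
                                           c(met_id("for", oN), met_id("for", "u"))),
                  lb = 0, ub = 1000)
  rx[["EX_for[u]"]] <- list(stoich = c("for[u]" = -1), lb = 0, ub = 1000)

  hm <- model_from_reactions(rx, id = paste0("toyhost_", spec$sex))
  hm$sex <- spec$sex
  hm$lumen_tag <- "luLI"
  hm$urine_tag <- "u"
  hm$organ_tags <- organ_tags
  hm$branch_capacities <- spec$capacities
  hm$basal <- spec$basal
  class(hm) <- c("host_model", class(hm))
  hm
}

#' Generate a synthetic diet
#'
#' `"minimal"` supplies carbon and nitrogen sources only (glucose, ammonium),
#' `"full"` adds every precursor used by the toy formate branches, fructose,
#' and the bile-acid placeholder entries. All fluxes are mmol/person/day.
#'
#' @param style `"minimal"` or `"full"`.
#' @return A `diet_spec`.
#' @export
make_diet <- function(style = c("full", "minimal")) {
  style <- match.arg(style)
  base <- tibble::tibble(
    metabolite = c("glc_D", "nh4"),
    flux = c(30, 20))
  if (style == "minimal") return(diet_spec(base))
  diet_spec(dplyr::bind_rows(base, tibble::tibble(
    metabolite = c("fald", "trp_L", "dkmpp", "fruc", "chola", "cdca"),
    flux = c(10, 5, 5, 10, 1, 1))))
}

#' Cohort specification for the synthetic case/control generator
#'
#' @param n_cases,n_controls group sizes.
#' @param n_species number of species in the composition.
#' @param planted_up,planted_down lists `list(species =, fold =)`; the
#'   Dirichlet concentration of the named species is multiplied (up) or
#'   divided (down) by `fold` in cases.
#' @param reads_meanlog,reads_sdlog log-normal parameters of the per-sample
#'   read depth.
#' @param apoe4_rate_cases,apoe4_rate_controls APOE4-carrier probabilities.
#' @param theta total Dirichlet concentration (smaller = more overdispersed).
#' @param seed integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_cases = 24, n_controls = 24, n_species = 12,
                        planted_up = list(species = c("sp01", "sp02"), fold = 3),
                        planted_down = list(species = c("sp03", "sp04"), fold = 3),
                        reads_meanlog = log(2.5e6), reads_sdlog = 0.5,
                        apoe4_rate_cases = 0.6, apoe4_rate_controls = 0.2,
                        theta = 50, seed = 1) {
  stopifnot(planted_up$fold > 0, planted_down$fold > 0,
            apoe4_rate_cases >= 0, apoe4_rate_cases <= 1,
            apoe4_rate_controls >= 0, apoe4_rate_controls <= 1)
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 n_species = n_species, planted_up = planted_up,
                 planted_down = planted_down, reads_meanlog = reads_meanlog,
                 reads_sdlog = reads_sdlog,
                 apoe4_rate_cases = apoe4_rate_cases,
                 apoe4_rate_controls = apoe4_rate_controls,
                 theta = theta, seed = seed),
            class = "cohort_spec")
}

#' Generate a synthetic case/control cohort
#'
#' Per-sample species counts are Dirichlet-multinomial: a species proportion
#' vector is drawn from a Dirichlet whose concentration parameters follow a
#' power-law baseline scaled to `theta`, with the planted species'
#' concentrations multiplied/divided by their fold in cases; counts are then
#' multinomial at a log-normal read depth. Metadata carries group, sex,
#' APOE4 carriage, age and BMI.
#'
#' @param spec a [cohort_spec()].
#' @return list with `counts` (an `abundance_table` in counts mode) and
#'   `metadata` (tibble sample, group, sex, apoe4, age, bmi).
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    sp <- sprintf("sp%02d", seq_len(spec$n_species))
    base <- 1 / seq_len(spec$n_species)
    alpha0 <- spec$theta * base / sum(base)
    names(alpha0) <- sp
    n <- spec$n_cases + spec$n_controls
    group <- rep(c("AD", "control"), c(spec$n_cases, spec$n_controls))
    samples <- sprintf("s%03d", seq_len(n))
    counts <- matrix(0L, n, spec$n_species, dimnames = list(NULL, sp))
    for (i in seq_len(n)) {
      a <- alpha0
      if (group[i] == "AD") {
        up <- intersect(spec$planted_up$species, sp)
        dn <- intersect(spec$planted_down$species, sp)
        a[up] <- a[up] * spec$planted_up$fold
        a[dn] <- a[dn] / spec$planted_down$fold
      }
      p <- stats::rgamma(spec$n_species, shape = a, rate = 1)
      p <- p / sum(p)
      depth <- round(stats::rlnorm(1, spec$reads_meanlog, spec$reads_sdlog))
      counts[i, ] <- stats::rmultinom(1, size = depth, prob = p)[, 1]
    }
    meta <- tibble::tibble(
      sample = samples,
      group = group,
      sex = rep_len(c("female", "male"), n),
      apoe4 = stats::rbinom(n, 1, ifelse(group == "AD", spec$apoe4_rate_cases,
                                         spec$apoe4_rate_controls)),
      age = round(stats::rnorm(n, 73, 5), 1),
      bmi = round(stats::rnorm(n, 27, 4), 1))
    tbl <- dplyr::bind_cols(tibble::tibble(sample = samples),
                            tibble::as_tibble(counts))
    list(counts = abundance_table(tbl, mode = "counts"), metadata = meta)
  })
}

#' The hand-solvable host+community co-metabolism fixture
#'
#' A branch-free host whose only endogenous formate source is a basal
#' capacity of 2, together with a single-species community (abundance 1)
#' that can secrete up to 3 formate (fermentation bound 1.5 at 2 formate per
#' glucose) and up to 4 L-serine, which the host converts to formate 1:1.
#' Under the minimal diet the decomposition is therefore exactly: germ-free
#' maximum 2, personalised maximum 9, direct microbial secretion 3,
#' co-metabolism residual 4.
#'
#' @param coupling_factor community coupling constant.
#' @param growth_bounds community biomass bounds.
#' @return list with `host`, `community`, `diet`.
#' @export
make_cometab_fixture <- function(coupling_factor = 400,
                                 growth_bounds = c(0.4, 1.0)) {
  host <- make_toy_host(toy_host_spec(branches = character(0), basal = 2))
  microbe <- make_toy_microbes(
    1,
    traits = list(list(formate_secretor = TRUE,
                       precursor_secretor = "ser_L",
                       substrate_needs = c("glc_D", "nh4"),
                       formate_cap = 1.5,
                       precursor_caps = c(ser_L = 4))),
    seed = 1)
  pan <- list(sp01 = build_pan_model(make_toy_strains(microbe$sp01, 1, seed = 1),
                                     "sp01"))
  community <- build_community(pan, c(sp01 = 1),
                               coupling_factor = coupling_factor,
                               growth_bounds = growth_bounds,
                               sample_id = "fixture")
  list(host = host, community = community, diet = make_diet("minimal"))
}

#' Generate a synthetic urine-metabolome cohort
#'
#' Log-normal creatinine-normalised concentrations for `n_metabolites`
#' metabolites over case/control groups, with a planted shift on the log
#' scale for selected metabolites in cases, missingness injected as zeros at
#' a per-metabolite rate, and age/sex/BMI metadata.
#'
#' @param n_cases,n_controls group sizes.
#' @param n_metabolites number of metabolites.
#' @param shift log-scale shift added in cases (e.g. -0.5 for a decrease).
#' @param shifted_metabolites metabolite indices carrying the shift.
#' @param zero_rate probability of a zero (treated as missing downstream).
#' @param sdlog residual log-scale standard deviation; the default 0.45 is
#'   calibrated so that the default planted shift is detectable after
#'   multiple-testing correction at the default group sizes.
#' @param seed integer seed.
#' @return list with `concentrations` (long tibble sample, metabolite,
#'   concentration) and `metadata` (sample, group, age, sex, bmi).
#' @export
make_metabolome <- function(n_cases = 40, n_controls = 40, n_metabolites = 49,
                            shift = -0.5, shifted_metabolites = 1,
                            zero_rate = 0.2, sdlog = 0.45, seed = 1) {
  with_seed(seed, {
    n <- n_cases + n_controls
    samples <- sprintf("m%03d", seq_len(n))
    group <- rep(c("AD", "control"), c(n_cases, n_controls))
    meta <- tibble::tibble(
      sample = samples, group = group,
      age = round(stats::rnorm(n, 72, 6), 1),
      sex = rep_len(c("female", "male"), n),
      bmi = round(stats::rnorm(n, 26, 4), 1))
    mets <- sprintf("met%02d", seq_len(n_metabolites))
    rows <- lapply(seq_len(n_metabolites), function(j) {
      mu <- stats::runif(1, -1, 1)
      eff <- if (j %in% shifted_metabolites) shift else 0
      conc <- stats::rlnorm(n, mu + eff * (group == "AD") +
                              0.01 * (meta$age - 72), sdlog)
      conc[stats::runif(n) < zero_rate] <- 0
      tibble::tibble(sample = samples, metabolite = mets[j],
                     concentration = conc)
    })
    list(concentrations = dplyr::bind_rows(rows), metadata = meta)
  })
}
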
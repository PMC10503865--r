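counts_table <- function() {
  abundance_table(tibble::tibble(sample = c("s1", "s2"),
                                 spA = c(40, 30), spB = c(30, 30),
                                 spC = c(10, 20), spX = c(20, 20)),
                  mode = "counts")
}

test_that("filter_and_renormalize drops uncovered species and reports coverage", {
  res <- filter_and_renormalize(counts_table(), c("spA", "spB", "spC"),
                                cutoff = 0)
  expect_equal(res$coverage$coverage, c(0.8, 0.8))
  rel <- res$table
  expect_equal(unname(rowSums(rel[, abundance_species(rel)])), c(1, 1))
  expect_equal(rel$spA[1], 0.5)   # 40 / 80
})

test_that("species below the cutoff are dropped and the rest renormalised", {
  tbl <- abundance_table(tibble::tibble(sample = "s1", spA = 99990,
                                        spB = 5, spC = 5),
                         mode = "counts")
  res <- filter_and_renormalize(tbl, c("spA", "spB", "spC"), cutoff = 1e-4)
  expect_setequal(abundance_species(res$table), "spA")
  expect_equal(res$table$spA, 1)
})

test_that("cutoff 0 with full coverage only renormalises", {
  res <- filter_and_renormalize(counts_table(), c("spA", "spB", "spC", "spX"),
                                cutoff = 0)
  expect_equal(res$coverage$coverage, c(1, 1))
  expect_equal(res$table$spA[1], 0.4)
})

test_that("zero covered reads is an error naming the sample", {
  expect_error(filter_and_renormalize(counts_table(), "nope", cutoff = 0),
               "s1")
})

test_that("community biomass is abundance-weighted and namespacing is bijective", {
  pans <- coupling_fixture_pans()
  cm <- build_community(pans, c(spA = 0.6, spB = 0.4))
  bio <- cm$stoichiometry[cm$stoichiometry$reaction == "communityBiomass", ]
  expect_equal(bio$coef[bio$metabolite == "spA__biomass[c]"], -0.6)
  expect_equal(bio$coef[bio$metabolite == "spB__biomass[c]"], -0.4)
  sp_rxns <- grep("__", cm$reactions$id, value = TRUE)
  dn <- denamespace_id(sp_rxns)
  expect_equal(namespace_id(dn$species, dn$id), sp_rxns)
  expect_error(build_community(pans, c(spA = 0.5, ghost = 0.5)),
               "without a pan model")
  expect_error(build_community(pans, c(spA = 0.5, spB = 0.6)), "sum to 1")
})

test_that("zero community growth forces every species flux to zero", {
  pans <- coupling_fixture_pans()
  cm <- build_community(pans, c(spA = 0.6, spB = 0.4))
  cm0 <- set_bounds(cm, "communityBiomass", lb = 0, ub = 0)
  fv <- fva(cm0, grep("__", cm0$reactions$id, value = TRUE))
  expect_lt(max(abs(c(fv$min_flux, fv$max_flux))), 1e-6)
})

test_that("coupling bounds an otherwise unbounded species flux at c * biomass", {
  pans <- coupling_fixture_pans()
  cm <- build_community(pans, c(spA = 0.4, spB = 0.6), coupling_factor = 400,
                        growth_bounds = c(0.4, 1))
  cm <- set_bounds(cm, "communityBiomass", lb = 1, ub = 1)
  cm <- suppressWarnings(apply_diet(cm, make_diet("minimal"), compartments = "d"))
  # spA biomass flux is forced to 0.4; the futile cycle reaction is limited
  # only by the coupling rows at 400 * 0.4 = 160
  fv <- fva(cm, c("spA__cycA", "spA__biomassPan"))
  expect_equal(fv$max_flux[fv$reaction == "spA__biomassPan"], 0.4,
               tolerance = 1e-6)
  expect_equal(fv$max_flux[fv$reaction == "spA__cycA"], 160, tolerance = 1e-6)
  expect_equal(fv$min_flux[fv$reaction == "spA__cycA"], -160, tolerance = 1e-6)
})

secretor_pans <- function(for_cap = 2) {
  mk <- function(sp, secretes) {
    tr <- list(formate_secretor = secretes,
               precursor_secretor = character(0),
               substrate_needs = c("glc_D", "nh4"),
               formate_cap = for_cap)
    make_toy_microbes(1, traits = list(tr), seed = 3)[[1]]
  }
  a <- mk("spS", TRUE); a$id <- "spS"
  b <- mk("spN", FALSE); b$id <- "spN"
  list(spS = build_pan_model(list(a), "spS"),
       spN = build_pan_model(list(b), "spN"))
}

test_that("secretion profile is positive with a secretor, zero without", {
  pans <- secretor_pans()
  cm <- build_community(pans, c(spS = 0.5, spN = 0.5))
  sp <- secretion_profile(cm, make_diet("minimal"), "for")
  expect_gt(sp$max_secretion[sp$metabolite == "for"], 0)

  cm2 <- build_community(pans["spN"], c(spN = 1))
  expect_error(secretion_profile(cm2, make_diet("minimal"), "for"),
               "no fecal exchange")
})

test_that("secretion respects the fermentation yield bound", {
  pans <- secretor_pans(for_cap = 1000)  # capacity unbinding
  cm <- build_community(pans, c(spS = 0.9, spN = 0.1))
  glc <- 5
  d <- diet_spec(tibble::tibble(metabolite = c("glc_D", "nh4"),
                                flux = c(glc, 20)))
  sp <- secretion_profile(cm, d, "for")
  # 2 formate per glucose is the only formate source
  expect_lte(sp$max_secretion, 2 * glc + 1e-6)
})

test_that("raising a secretor's abundance never lowers max formate secretion", {
  pans <- secretor_pans()
  d <- make_diet("minimal")
  vals <- vapply(c(0.2, 0.5, 0.8), function(a) {
    cm <- build_community(pans, c(spS = a, spN = 1 - a))
    secretion_profile(cm, d, "for")$max_secretion
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-6))
})
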
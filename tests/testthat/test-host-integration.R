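test_that("attaching an empty community reproduces the germ-free optimum", {
  host <- make_toy_host(toy_host_spec())
  diet <- make_diet("full")
  gf <- suppressWarnings(apply_diet(host, diet, compartments = "d"))
  v0 <- max_urine_secretion(gf, "for")
  combined <- attach_community(host, empty_community())
  combined <- suppressWarnings(apply_diet(combined, diet, compartments = "d"))
  expect_equal(max_urine_secretion(combined, "for"), v0, tolerance = 1e-9)
})

test_that("germ-free urine maximum follows the diet-limited analytic bound", {
  # single serine branch with huge capacity: diet serine (via supplement)
  # plus the basal source set the optimum
  host <- make_toy_host(toy_host_spec(branches = "serine",
                                      capacities = c(serine = 1000),
                                      basal = 2))
  diet <- diet_spec(tibble::tibble(metabolite = c("ser_L"), flux = 10))
  gf <- suppressWarnings(apply_diet(host, diet, compartments = "d"))
  expect_equal(max_urine_secretion(gf, "for"), 12)

  # no formate precursors and no basal source: conservation forces zero
  host0 <- make_toy_host(toy_host_spec(branches = character(0), basal = 0))
  gf0 <- suppressWarnings(apply_diet(host0, diet_spec(), compartments = "d"))
  expect_equal(max_urine_secretion(gf0, "for"), 0)
})

test_that("doubling every diet flux never lowers the urine maximum", {
  host <- make_toy_host(toy_host_spec())
  d1 <- make_diet("full")
  gf1 <- suppressWarnings(apply_diet(host, d1, compartments = "d"))
  gf2 <- suppressWarnings(apply_diet(host, d1, scale = 2, compartments = "d"))
  expect_gte(max_urine_secretion(gf2, "for"),
             max_urine_secretion(gf1, "for") - 1e-9)
})

test_that("the co-metabolism fixture decomposes exactly as constructed", {
  fx <- make_cometab_fixture()
  rep <- cometabolism_decomposition(fx$host, fx$community, fx$diet, "for")
  expect_equal(rep$germfree_max, 2, tolerance = 1e-6)
  expect_equal(rep$personalised_max, 9, tolerance = 1e-6)
  expect_equal(rep$microbial_secretion_max, 3, tolerance = 1e-6)
  expect_identical(rep$delta, rep$personalised_max - rep$germfree_max)
  expect_identical(rep$cometabolism_residual,
                   rep$delta - rep$microbial_secretion_max)
  expect_equal(rep$delta, 7, tolerance = 1e-6)
  expect_equal(rep$cometabolism_residual, 4, tolerance = 1e-6)
})

test_that("max_microbial_secretion matches the secretor capacity", {
  fx <- make_cometab_fixture()
  combined <- attach_community(fx$host, fx$community)
  combined <- suppressWarnings(apply_diet(combined, fx$diet,
                                          compartments = "d"))
  expect_equal(max_microbial_secretion(combined, "for"), 3, tolerance = 1e-6)
  # never exceeds the community's standalone net secretion capacity
  standalone <- secretion_profile(fx$community, fx$diet, "for")
  expect_lte(max_microbial_secretion(combined, "for"),
             standalone$max_secretion + 1e-6)
  expect_error(max_microbial_secretion(combined, "ghost"), "no lumen transport")
})

test_that("a formate-only secretor leaves no co-metabolism residual", {
  host <- make_toy_host(toy_host_spec(branches = character(0), basal = 2))
  microbe <- make_toy_microbes(1, traits = list(list(
    formate_secretor = TRUE, precursor_secretor = character(0),
    substrate_needs = c("glc_D", "nh4"), formate_cap = 1.5)), seed = 1)
  pan <- list(sp01 = build_pan_model(list(microbe$sp01), "sp01"))
  comm <- build_community(pan, c(sp01 = 1))
  rep <- cometabolism_decomposition(host, comm, make_diet("minimal"), "for")
  expect_equal(rep$cometabolism_residual, 0, tolerance = 1e-6)
  expect_equal(rep$delta, 3, tolerance = 1e-6)
})

test_that("personalised maximum is never below germ-free on fixtures", {
  fx <- make_cometab_fixture()
  rep <- cometabolism_decomposition(fx$host, fx$community, fx$diet, "for")
  expect_gte(rep$personalised_max, rep$germfree_max - 1e-6)
})

test_that("both sexes run through the identical pipeline path", {
  for (sex in c("female", "male")) {
    host <- make_toy_host(toy_host_spec(sex = sex))
    gf <- suppressWarnings(apply_diet(host, make_diet("full"),
                                      compartments = "d"))
    expect_equal(max_urine_secretion(gf, "for"), 12)
    expect_equal(host$sex, sex)
  }
})

test_that("high_secretors applies the flux threshold", {
  fake <- structure(list(
    objective_value = 1,
    fluxes = c(LUt_P = 40, LUt_Q = 10, LUt_for = 35, other = 99),
    status = "optimal", objective = "EX_for[u]", sense = "max"),
    class = "flux_solution")
  expect_equal(high_secretors(fake, 30), c("P", "for"))
  expect_setequal(high_secretors(fake, 0), c("P", "Q", "for"))
  expect_equal(high_secretors(fake, Inf), character(0))
})
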
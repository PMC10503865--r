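host_full <- function() make_toy_host(toy_host_spec())
cands_all <- c("PSP_L", "SFGTH", "TRPO2", "DKMPPD", "PGCD", "PSERT",
               "SERFORM", "GLYCOLYSIS", "FALDH", "FKYNH", "ABSt_chola")

test_that("knockout screen reproduces the analytic branch shares", {
  ko <- knockout_screen(host_full(), make_diet("full"), cands_all)
  expect_equal(ko$baseline, 12)
  res <- ko$results
  red <- function(r) res$reduction_fraction[res$reaction == r]
  expect_equal(red("PSP_L"), 5 / 12, tolerance = 1e-9)
  expect_equal(red("SFGTH"), 3 / 12, tolerance = 1e-9)
  expect_equal(red("TRPO2"), 2 / 12, tolerance = 1e-9)
  expect_equal(red("DKMPPD"), 1 / 12, tolerance = 1e-9)
  expect_equal(red("ABSt_chola"), 0)        # off the formate cone
  expect_false("DKMPPD" %in% ko$flagged)    # 1/12 < 10 %
  expect_true(all(c("PSP_L", "SFGTH", "TRPO2") %in% ko$flagged))
})

test_that("deleting the only route gives reduction 1; a redundant path its share", {
  host <- make_toy_host(toy_host_spec(branches = "serine",
                                      capacities = c(serine = 5), basal = 0))
  ko <- knockout_screen(host, make_diet("full"), "PSP_L")
  expect_equal(ko$results$reduction_fraction, 1)

  # two equal-capacity branches: removing one halves the optimum
  host2 <- make_toy_host(toy_host_spec(
    branches = c("serine", "formaldehyde"),
    capacities = c(serine = 3, formaldehyde = 3), basal = 0))
  ko2 <- knockout_screen(host2, make_diet("full"), c("PSP_L", "SFGTH"))
  expect_equal(ko2$results$reduction_fraction, c(0.5, 0.5), tolerance = 1e-9)
})

test_that("knockout screen refuses a zero baseline and unknown candidates", {
  host0 <- make_toy_host(toy_host_spec(branches = character(0), basal = 0))
  expect_error(knockout_screen(host0, diet_spec(), "SERFORM"), "meaningless")
  expect_error(knockout_screen(host_full(), make_diet("full"), "nope"),
               "not in model")
})

test_that("greedy minimal set finds the four endpoints at goal 0.85", {
  ms <- minimal_set_search(host_full(), make_diet("full"),
                           c("PSP_L", "SFGTH", "TRPO2", "DKMPPD"),
                           goal_reduction = 0.85)
  expect_setequal(ms$set, c("PSP_L", "SFGTH", "TRPO2", "DKMPPD"))
  expect_equal(ms$achieved_reduction, 11 / 12, tolerance = 1e-9)
  expect_true(ms$reached)
})

test_that("exhaustive search agrees with greedy on the endpoint fixture", {
  ms <- minimal_set_search(host_full(), make_diet("full"),
                           c("PSP_L", "SFGTH", "TRPO2", "DKMPPD"),
                           goal_reduction = 0.85, method = "exhaustive")
  expect_setequal(ms$set, c("PSP_L", "SFGTH", "TRPO2", "DKMPPD"))
  expect_true(ms$reached)
})

test_that("independent capacities (5,3,2,1) at goal 0.9 need only three deletions", {
  # goal 0.9 of total 11 (basal 0): {5,3,2} reaches 10/11
  host <- make_toy_host(toy_host_spec(basal = 0))
  cands <- c("PSP_L", "SFGTH", "TRPO2", "DKMPPD")
  g <- minimal_set_search(host, make_diet("full"), cands, goal_reduction = 0.9)
  e <- minimal_set_search(host, make_diet("full"), cands, goal_reduction = 0.9,
                          method = "exhaustive")
  expect_setequal(g$set, c("PSP_L", "SFGTH", "TRPO2"))
  expect_equal(g$achieved_reduction, 10 / 11, tolerance = 1e-9)
  expect_equal(length(e$set), 3)
  expect_equal(e$achieved_reduction, 10 / 11, tolerance = 1e-9)
})

test_that("goal 0 returns the empty set; unreachable goals are flagged", {
  ms0 <- minimal_set_search(host_full(), make_diet("full"), "DKMPPD",
                            goal_reduction = 0)
  expect_equal(ms0$set, character(0))
  msu <- minimal_set_search(host_full(), make_diet("full"), "DKMPPD",
                            goal_reduction = 0.5)
  expect_false(msu$reached)
  expect_equal(msu$achieved_reduction, 1 / 12, tolerance = 1e-9)
})

test_that("a singleton screen equals one greedy step", {
  ko <- knockout_screen(host_full(), make_diet("full"), "SFGTH")
  ms <- minimal_set_search(host_full(), make_diet("full"), "SFGTH",
                           goal_reduction = 0.2)
  expect_equal(ms$set, "SFGTH")
  expect_equal(ms$achieved_reduction, ko$results$reduction_fraction,
               tolerance = 1e-9)
})

test_that("deletion-set monotonicity holds on the branch fixture", {
  host <- host_full(); diet <- make_diet("full")
  m <- suppressWarnings(apply_diet(host, diet, compartments = "d"))
  base <- max_urine_secretion(m, "for")
  sets <- list("PSP_L", c("PSP_L", "SFGTH"), c("PSP_L", "SFGTH", "TRPO2"))
  reds <- vapply(sets, function(s) {
    (base - max_urine_secretion(delete_reactions(m, s), "for")) / base
  }, numeric(1))
  expect_true(all(diff(reds) >= -1e-9))
})

test_that("supplementation screen classifies precursors and inert compounds", {
  host <- make_toy_host(toy_host_spec(nh4_branch = TRUE))
  # nitrogen-poor baseline diet: ammonium relieves a non-carbon bottleneck
  diet <- diet_spec(tibble::tibble(metabolite = c("glc_D", "nh4", "chola"),
                                   flux = c(30, 2, 1)))
  sup <- supplementation_screen(host, diet, c("ser_L", "nh4", "chola"),
                                amount = 300)
  expect_true(sup$increases[sup$candidate == "ser_L"])
  expect_true(sup$increases[sup$candidate == "nh4"])
  expect_false(sup$increases[sup$candidate == "chola"])
  expect_true(all(sup$status == "ok"))
})

test_that("annotation join counts overlaps and rejects duplicates", {
  ko <- knockout_screen(host_full(), make_diet("full"), cands_all)
  ann <- tibble::tibble(
    reaction = c("PSP_L", "DKMPPD"),
    genes = c("PSPH", "ADI1"),
    ad_association = c("positive", "negative"))
  res <- annotate_with_ad(ko, ann)
  expect_equal(res$summary$n_annotated, 2)
  expect_equal(res$summary$n_overlap, 1)   # PSP_L flagged, DKMPPD not
  expect_true(all(res$table$ad_association[
    !res$table$reaction %in% ann$reaction] == "none"))

  empty <- annotate_with_ad(ko, tibble::tibble())
  expect_equal(empty$summary$n_annotated, 0)

  expect_error(annotate_with_ad(ko, ann[c(1, 1), ]), "duplicated")
  expect_error(annotate_with_ad(ko, tibble::tibble(
    reaction = "ghost", genes = "g", ad_association = "positive")),
    "outside the screened")
})
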
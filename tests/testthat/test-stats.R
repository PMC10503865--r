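test_that("prevalence filter excludes metabolites below 50% non-zero", {
  mb <- make_metabolome(n_cases = 20, n_controls = 20, n_metabolites = 2,
                        zero_rate = 0, seed = 2)
  conc <- mb$concentrations
  # force met02 to 40% non-zero
  i2 <- conc$metabolite == "met02"
  idx <- which(i2)
  conc$concentration[idx[seq_len(ceiling(0.6 * length(idx)))]] <- 0
  res <- screen_metabolites(conc, mb$metadata, min_nonzero = 0.5)
  expect_false(res$excluded[res$metabolite == "met01"])
  expect_true(res$excluded[res$metabolite == "met02"])
  expect_true(is.na(res$p_case[res$metabolite == "met02"]))
})

test_that("a planted log shift is recovered with a significant group term", {
  mb <- make_metabolome(seed = 5)   # met01 shifted by -0.5
  res <- screen_metabolites(mb$concentrations, mb$metadata)
  r1 <- res[res$metabolite == "met01", ]
  expect_lt(abs(r1$estimate - (-0.5)), 3 * r1$se)
  expect_lt(r1$p_case, 0.05)
})

test_that("negative concentrations are rejected", {
  mb <- make_metabolome(n_metabolites = 1, seed = 1)
  conc <- mb$concentrations
  conc$concentration[1] <- -1
  expect_error(screen_metabolites(conc, mb$metadata), "negative")
})

test_that("fractional regression flags invalid input and constant species", {
  ch <- make_cohort(cohort_spec(seed = 8))
  expect_error(fractional_regression(ch$counts, ch$metadata), "relative mode")
  rel <- normalize_abundances(ch$counts)
  # a species with identical abundance in every sample: estimate ~ 0, p ~ 1
  rel2 <- rel
  rel2$sp06 <- 0.01
  rel2[, setdiff(abundance_species(rel2), "sp06")] <-
    rel2[, setdiff(abundance_species(rel2), "sp06")] * (0.99 / rowSums(
      rel2[, setdiff(abundance_species(rel2), "sp06")]))
  res <- fractional_regression(abundance_table(rel2, "relative"), ch$metadata)
  r6 <- res[res$species == "sp06", ]
  expect_lt(abs(r6$estimate), 1e-8)
  expect_gt(r6$p, 0.99)
})

test_that("fractional regression recovers a planted abundance shift", {
  ch <- make_cohort(cohort_spec(seed = 9))
  rel <- normalize_abundances(ch$counts)
  res <- fractional_regression(rel, ch$metadata)
  expect_gt(res$estimate[res$species == "sp01"], 0)   # planted up in AD
  expect_lt(res$estimate[res$species == "sp03"], 0)   # planted down in AD
  expect_lt(res$q[res$species == "sp01"], 0.05)
})

test_that("log-ratio test separates planted shifts and is null on equal sets", {
  ch <- make_cohort(cohort_spec(seed = 10))
  lr <- log_ratio_test(ch$counts, ch$metadata, c("sp01", "sp02"),
                       c("sp03", "sp04"))
  expect_lt(lr$test$p, 0.05)
  expect_gt(lr$test$estimate, 0)

  same <- log_ratio_test(ch$counts, ch$metadata, c("sp01", "sp02"),
                         c("sp01", "sp02"))
  expect_equal(stats::sd(same$samples$log_ratio), 0)
  expect_gt(same$test$p, 0.99)

  expect_error(log_ratio_test(ch$counts, ch$metadata, character(0), "sp01"),
               "non-empty")
})

test_that("Welch t-test agrees with a hand-worked example", {
  # two small samples; expected values computed from the Welch formulas
  x <- c(3.1, 2.9, 3.4, 3.0, 3.2)
  y <- c(2.5, 2.7, 2.4, 2.8)
  tt <- stats::t.test(x, y)
  se <- sqrt(stats::var(x) / 5 + stats::var(y) / 4)
  t_manual <- (mean(x) - mean(y)) / se
  df_manual <- se^4 / ((stats::var(x) / 5)^2 / 4 + (stats::var(y) / 4)^2 / 3)
  expect_equal(unname(tt$statistic), t_manual, tolerance = 1e-6)
  expect_equal(unname(tt$parameter), df_manual, tolerance = 1e-6)
})

test_that("compare_fluxes recovers a planted difference and handles rank issues", {
  ch <- make_cohort(cohort_spec(seed = 11))
  set.seed(11)
  fl <- tibble::tibble(sample = ch$metadata$sample,
                       flux = stats::rnorm(48, 20, 1) -
                         2 * (ch$metadata$group == "AD"))
  res <- compare_fluxes(fl, ch$metadata)
  expect_lt(res$conf.low, -2)
  expect_gt(res$conf.high, -2)
  expect_lt(res$p, 0.05)

  meta2 <- ch$metadata
  meta2$apoe4 <- 1
  expect_warning(compare_fluxes(fl, meta2), "constant covariate")

  same <- fl
  same$flux <- 7
  expect_equal(suppressWarnings(compare_fluxes(same, ch$metadata))$estimate, 0,
               tolerance = 1e-9)
})

test_that("BH q-values match the hand computation and are order-invariant", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(3)
  p <- stats::runif(20)
  perm <- sample(20)
  expect_equal(bh_fdr(p)[perm], bh_fdr(p[perm]))
  expect_error(bh_fdr(c(0.5, 1.2)), "outside")
})
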
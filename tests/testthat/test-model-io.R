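models_equal <- function(a, b) {
  sa <- dplyr::arrange(a$stoichiometry, reaction, metabolite)
  sb <- dplyr::arrange(b$stoichiometry, reaction, metabolite)
  ra <- as.data.frame(a$reactions[order(a$reactions$id),
                                  c("id", "lower_bound", "upper_bound")])
  rb <- as.data.frame(b$reactions[order(b$reactions$id),
                                  c("id", "lower_bound", "upper_bound")])
  isTRUE(all.equal(as.data.frame(sa), as.data.frame(sb), tolerance = 1e-12,
                   check.attributes = FALSE)) &&
    isTRUE(all.equal(ra, rb, check.attributes = FALSE)) &&
    setequal(a$metabolites$id, b$metabolites$id)
}

toy4 <- function() {
  model_from_reactions(list(
    EX_glc = list(stoich = c("glc_D[e]" = -1), lb = -10, ub = 1000),
    FERM = list(stoich = c("glc_D[e]" = -1, "for[c]" = 2, "atp[c]" = 0.5),
                lb = 0, ub = 812.75),
    EX_for = list(stoich = c("for[c]" = -1), lb = 0, ub = 1000),
    EX_atp = list(stoich = c("atp[c]" = -1), lb = 0, ub = 1000)), id = "toy")
}

test_that("tabular round-trip preserves ids, bounds and coefficients", {
  m <- toy4()
  d <- withr::local_tempdir()
  write_model(m, d, "tabular")
  expect_true(models_equal(m, read_model(d, "tabular")))
})

test_that("SBML round-trip preserves ids, bounds and coefficients", {
  m <- toy4()
  f <- withr::local_tempfile(fileext = ".xml")
  write_model(m, f, "sbml")
  expect_true(models_equal(m, read_model(f, "sbml")))
})

test_that("written SBML is readable by an external SBML/FBC parser", {
  m <- toy4()
  f <- withr::local_tempfile(fileext = ".xml")
  write_model(m, f, "sbml")
  out <- suppressWarnings(system2(
    "python",
    c("-c", shQuote(sprintf(
      "import cobra; m = cobra.io.read_sbml_model(%s); print(len(m.reactions), len(m.metabolites), int(m.reactions.get_by_id('EX_glc').lower_bound))",
      deparse(f)))),
    stdout = TRUE, stderr = FALSE))
  expect_equal(utils::tail(out, 1), "4 3 -10")
})

test_that("a reaction citing an undeclared metabolite is a validation error", {
  d <- withr::local_tempdir()
  writeLines(c("id\tcompartment\tname", "a[e]\te\ta"),
             file.path(d, "metabolites.tsv"))
  writeLines(c("id\tsubsystem\tstoichiometry", "r1\t\ta[e]:-1;ghost[c]:1"),
             file.path(d, "reactions.tsv"))
  expect_error(read_model(d, "tabular"), "undeclared metabolite")
})

test_that("bounds default to +/-1000 when bounds.tsv is absent", {
  d <- withr::local_tempdir()
  writeLines(c("id\tcompartment\tname", "a[e]\te\ta"),
             file.path(d, "metabolites.tsv"))
  writeLines(c("id\tsubsystem\tstoichiometry", "EX_a\t\ta[e]:-1"),
             file.path(d, "reactions.tsv"))
  m <- read_model(d, "tabular")
  expect_equal(m$reactions$lower_bound, -1000)
  expect_equal(m$reactions$upper_bound, 1000)
})

test_that("abundance reading sums duplicate species and validates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tspA\tspB\tspA", "s1\t10\t5\t2", "s2\t1\t1\t1"), f)
  a <- read_abundances(f, "counts")
  expect_equal(sort(abundance_species(a)), c("spA", "spB"))
  expect_equal(a$spA, c(12, 2))

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tspA\tspB", "s1\t0.5\t0.3"), f2)
  expect_error(read_abundances(f2, "relative"), "sum to 1")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tspA", "s1\t-1"), f3)
  expect_error(read_abundances(f3, "counts"), "negative")

  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample", f4)
  expect_error(read_abundances(f4, "counts"), "no species")
})

test_that("abundance normalisation is idempotent", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tspA\tspB", "s1\t3\t1", "s2\t1\t1"), f)
  a <- read_abundances(f, "counts")
  r1 <- normalize_abundances(a)
  r2 <- normalize_abundances(r1)
  expect_equal(as.data.frame(r1), as.data.frame(r2))
  expect_equal(rowSums(r1[, abundance_species(r1)]), c(1, 1))
})

test_that("diet reading validates fluxes and duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("metabolite\tflux", "glc_D\t30", "chola\t1"), f)
  d <- read_diet(f)
  expect_equal(nrow(d), 2)
  expect_equal(d$flux[d$metabolite == "glc_D"], 30)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("metabolite\tflux", "glc_D\t30", "glc_D\t10"), f2)
  expect_error(read_diet(f2), "duplicate")

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("metabolite\tflux", "glc_D\t-3"), f3)
  expect_error(read_diet(f3), "negative")

  f4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines("metabolite\tflux", f4)
  expect_equal(nrow(read_diet(f4)), 0)
})

test_that("reports round-trip through TSV and JSON", {
  tb <- tibble::tibble(b_first = 1:2, a_second = c("x", "y"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_report(tb, f)
  back <- readr::read_tsv(f, show_col_types = FALSE)
  expect_equal(names(back), names(tb))   # column order is stable

  j <- withr::local_tempfile(fileext = ".json")
  write_report(list(baseline = 12, flagged = c("A", "B")), j)
  parsed <- jsonlite::read_json(j, simplifyVector = TRUE)
  expect_equal(parsed$baseline, 12)
  expect_equal(parsed$flagged, c("A", "B"))
})
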
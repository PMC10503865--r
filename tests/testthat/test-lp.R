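test_that("FBA on a linear chain matches the mass-balance bound", {
  m <- chain_model(ex_a_lb = -10)
  sol <- solve_fba(m, "EX_b", "max")
  expect_equal(sol$status, "optimal")
  expect_equal(sol$objective_value, 10)
  expect_equal(unname(sol$fluxes["EX_a"]), -10)

  closed <- chain_model(ex_a_lb = 0)
  expect_equal(solve_fba(closed, "EX_b", "max")$objective_value, 0)
})

test_that("repeated FBA solves are deterministic to 1e-9", {
  set.seed(11)
  m <- rand_toy_net()
  v1 <- solve_fba(m, m$reactions$id[1], "max")$objective_value
  v2 <- solve_fba(m, m$reactions$id[1], "max")$objective_value
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("infeasible and unbounded problems are reported in status", {
  m <- chain_model(ex_a_lb = 0)
  m <- set_bounds(m, "EX_b", lb = 5)   # demands output with no input
  expect_equal(solve_fba(m, "EX_b", "max")$status, "infeasible")

  unb <- model_from_reactions(list(
    r1 = list(stoich = c("a[c]" = 1), lb = -Inf, ub = Inf),
    r2 = list(stoich = c("a[c]" = -1), lb = -Inf, ub = Inf)))
  expect_equal(solve_fba(unb, "r1", "max")$status, "unbounded")
})

test_that("FBA optima match vertex-enumeration on random toy networks", {
  set.seed(101)
  for (rep in 1:12) {
    m <- rand_toy_net()
    verts <- enumerate_vertices(m)
    j <- sample(nrow(m$reactions), 1)
    for (mx in c(TRUE, FALSE)) {
      oracle <- vertex_optimum(verts, j, mx)
      sol <- solve_fba(m, m$reactions$id[j], if (mx) "max" else "min")
      expect_equal(sol$objective_value, oracle, tolerance = 1e-6)
    }
  }
})

test_that("FVA brackets the chain and honours fixed fluxes", {
  m <- chain_model()
  fv <- fva(m, c("EX_a", "EX_b"))
  expect_equal(fv$min_flux, c(-10, 0))
  expect_equal(fv$max_flux, c(0, 10))

  fixed <- set_bounds(m, "t_ab", lb = 5, ub = 5)
  fv2 <- fva(fixed, "EX_b")
  expect_equal(fv2$min_flux, 5)
  expect_equal(fv2$max_flux, 5)

  expect_true(all(fv$min_flux <= fv$max_flux + 1e-6))
})

test_that("FVA envelopes contain random feasible points", {
  set.seed(202)
  for (rep in 1:5) {
    m <- rand_toy_net()
    verts <- enumerate_vertices(m)
    pts <- sample_feasible_points(verts, 200)
    fv <- fva(m)
    for (j in seq_len(ncol(pts))) {
      expect_true(all(pts[, j] >= fv$min_flux[j] - 1e-6))
      expect_true(all(pts[, j] <= fv$max_flux[j] + 1e-6))
    }
  }
})

test_that("FVA max of the objective equals the FBA optimum", {
  set.seed(33)
  m <- rand_toy_net()
  j <- 1L
  expect_equal(fva(m, m$reactions$id[j])$max_flux,
               solve_fba(m, m$reactions$id[j], "max")$objective_value,
               tolerance = 1e-9)
})

test_that("delete_reactions closes bounds without touching the input model", {
  m <- chain_model()
  ko <- delete_reactions(m, "t_ab")
  expect_equal(solve_fba(ko, "EX_b", "max")$objective_value, 0)
  expect_equal(m$reactions$upper_bound[m$reactions$id == "t_ab"], 1000)
  expect_error(delete_reactions(m, "nope"), "unknown reaction")
})

test_that("deleting one of two redundant parallel paths keeps the optimum", {
  m <- model_from_reactions(list(
    EX_a = list(stoich = c("a[e]" = -1), lb = -10, ub = 1000),
    p1 = list(stoich = c("a[e]" = -1, "b[e]" = 1), lb = 0, ub = 1000),
    p2 = list(stoich = c("a[e]" = -1, "b[e]" = 1), lb = 0, ub = 1000),
    EX_b = list(stoich = c("b[e]" = -1), lb = 0, ub = 1000)))
  base <- solve_fba(m, "EX_b", "max")$objective_value
  expect_equal(solve_fba(delete_reactions(m, "p2"), "EX_b", "max")$objective_value,
               base)
})

test_that("knockout never increases a maximisation optimum (random toys)", {
  set.seed(404)
  for (rep in 1:10) {
    m <- rand_toy_net()
    j <- sample(nrow(m$reactions), 1)
    base <- solve_fba(m, m$reactions$id[j], "max")$objective_value
    kill <- sample(setdiff(m$reactions$id, m$reactions$id[j]),
                   sample(1:2, 1))
    v <- solve_fba(delete_reactions(m, kill), m$reactions$id[j],
                   "max")$objective_value
    expect_lte(v, base + 1e-6)
  }
})

test_that("a redundant constraint row leaves FVA intervals unchanged", {
  m <- chain_model()
  fv0 <- fva(m)
  # EX_b <= 1000 is implied by the bound on EX_b
  m2 <- add_constraint(m, c(EX_b = 1), "<=", 1000)
  fv1 <- fva(m2)
  expect_equal(fv0$min_flux, fv1$min_flux, tolerance = 1e-9)
  expect_equal(fv0$max_flux, fv1$max_flux, tolerance = 1e-9)
})

test_that("optimal solutions satisfy mass balance and constraint rows", {
  m <- add_constraint(chain_model(), c(EX_b = 1), "<=", 4)
  sol <- solve_fba(m, "EX_b", "max")
  expect_equal(sol$objective_value, 4)
  expect_lt(max(abs(s_matrix(m) %*% sol$fluxes)), 1e-6)
  expect_lte(sol$fluxes[["EX_b"]], 4 + 1e-6)
})
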
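# Independent oracles and fixture builders shared across tests.
#
# The LP oracle never calls the package solver: optima are found by
# enumerating the basic solutions (vertices) of the bounded polytope
# {S v = 0, lb <= v <= ub}, and random feasible points are drawn as convex
# combinations of the enumerated vertices.

# small random metabolic-like network with finite bounds (v = 0 always
# feasible, so the polytope is non-empty and bounded)
rand_toy_net <- function(n_met = NULL, n_rxn = NULL) {
  if (is.null(n_met)) n_met <- sample(3:5, 1)
  if (is.null(n_rxn)) n_rxn <- sample(5:9, 1)
  S <- matrix(0, n_met, n_rxn)
  for (j in seq_len(n_rxn)) {
    k <- sample(1:min(3, n_met), 1)
    rows <- sample(n_met, k)
    S[rows, j] <- sample(c(-2, -1, 1, 2), k, replace = TRUE)
  }
  mets <- paste0("m", seq_len(n_met), "[c]")
  rxns <- paste0("r", seq_len(n_rxn))
  st <- do.call(rbind, lapply(seq_len(n_rxn), function(j) {
    nz <- which(S[, j] != 0)
    data.frame(reaction = rxns[j], metabolite = mets[nz], coef = S[nz, j])
  }))
  stoich_model(
    tibble::tibble(id = mets, compartment = "c", name = mets),
    tibble::tibble(id = rxns,
                   lower_bound = round(stats::runif(n_rxn, -10, 0), 1),
                   upper_bound = round(stats::runif(n_rxn, 0, 10), 1),
                   subsystem = ""),
    tibble::as_tibble(st), id = "toy")
}

# all vertices of {S v = 0, lb <= v <= ub}; returns a matrix (vertex x rxn)
enumerate_vertices <- function(model, tol = 1e-7) {
  S <- s_matrix(model)
  lb <- model$reactions$lower_bound
  ub <- model$reactions$upper_bound
  n <- ncol(S)
  qrS <- qr(t(S))
  r <- qrS$rank
  Sr <- S[qrS$pivot[seq_len(r)], , drop = FALSE]
  m <- nrow(Sr)
  verts <- list()
  for (Bset in utils::combn(n, m, simplify = FALSE)) {
    B <- Sr[, Bset, drop = FALSE]
    if (abs(det(B)) < 1e-9) next
    Nset <- setdiff(seq_len(n), Bset)
    for (pat in 0:(2^length(Nset) - 1)) {
      vN <- ifelse(bitwAnd(pat, 2^(seq_along(Nset) - 1)) > 0,
                   ub[Nset], lb[Nset])
      vB <- drop(solve(B, -Sr[, Nset, drop = FALSE] %*% vN))
      if (all(vB >= lb[Bset] - tol) && all(vB <= ub[Bset] + tol)) {
        v <- numeric(n)
        v[Bset] <- vB
        v[Nset] <- vN
        verts[[length(verts) + 1L]] <- v
      }
    }
  }
  out <- do.call(rbind, verts)
  colnames(out) <- model$reactions$id
  out
}

# brute-force optimum of one reaction flux over the vertex set
vertex_optimum <- function(vertices, rxn_idx, maximize = TRUE) {
  vals <- vertices[, rxn_idx]
  if (maximize) max(vals) else min(vals)
}

# random feasible points: convex combinations of vertices (the polytope is
# bounded, so it is the convex hull of its vertices)
sample_feasible_points <- function(vertices, n_points = 1000) {
  k <- nrow(vertices)
  w <- matrix(stats::rexp(n_points * k), n_points, k)
  w <- w / rowSums(w)
  w %*% vertices
}

# linear a -> b -> out chain used across lp tests
chain_model <- function(ex_a_lb = -10) {
  model_from_reactions(list(
    EX_a = list(stoich = c("a[e]" = -1), lb = ex_a_lb, ub = 1000),
    t_ab = list(stoich = c("a[e]" = -1, "b[e]" = 1), lb = 0, ub = 1000),
    EX_b = list(stoich = c("b[e]" = -1), lb = 0, ub = 1000)
  ), id = "chain")
}

# two-species community where species A carries a futile cycle, so that the
# coupling rows are the only thing bounding its internal flux
coupling_fixture_pans <- function() {
  mk <- function(sp, with_cycle) {
    rx <- list(
      EX_glc_D = list(stoich = c("glc_D[e]" = -1), lb = -1000, ub = 1000),
      t_glc_D = list(stoich = c("glc_D[e]" = -1, "glc_D[c]" = 1), lb = 0, ub = 1000),
      biomass_s1 = list(stoich = c("glc_D[c]" = -1, "biomass[c]" = 1),
                        lb = 0, ub = 1000),
      DM_biomass = list(stoich = c("biomass[c]" = -1), lb = 0, ub = 1000))
    if (with_cycle) {
      rx$cycA <- list(stoich = c("x[c]" = -1, "y[c]" = 1), lb = -1000, ub = 1000)
      rx$cycB <- list(stoich = c("y[c]" = -1, "x[c]" = 1), lb = -1000, ub = 1000)
    }
    build_pan_model(list(model_from_reactions(rx, id = sp)), sp)
  }
  list(spA = mk("spA", TRUE), spB = mk("spB", FALSE))
}
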
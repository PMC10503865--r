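# Deterministic LP core: bounded-variable primal simplex with Bland's rule.
#
# The LP solved everywhere in the package is
#     optimise  c'v   s.t.  S v = 0,  extra rows (<=/>=),  lb <= v <= ub
# assembled from a stoich_model. Inequality rows get slack columns, phase I
# uses one artificial per row. Bland's rule (smallest eligible index for both
# entering and leaving variables) makes the solver cycle-free and, with fixed
# input ordering, bit-reproducible run to run.

#' Solve a bounded linear program by primal simplex
#'
#' Low-level deterministic solver used by [solve_fba()] and [fva()]. Solves
#' `min/max obj'x` subject to `A x = b` and `lb <= x <= ub`.
#'
#' @param A constraint matrix (equalities).
#' @param b right-hand side.
#' @param lb,ub variable bounds (may be `-Inf`/`Inf`).
#' @param obj objective coefficients.
#' @param maximize logical.
#' @param tol feasibility tolerance.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`),
#'   `x`, `objective`.
#' @keywords internal
#' @export
simplex_solve <- function(A, b, lb, ub, obj, maximize = TRUE, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(b) == m, length(lb) == n, length(ub) == n, length(obj) == n)
  if (m == 0L) {
    # box-only problem
    cc <- if (maximize) obj else -obj
    x <- ifelse(cc > 0, ub, ifelse(cc < 0, lb, ifelse(is.finite(lb), lb, 0)))
    if (any(!is.finite(x) & cc != 0)) {
      return(list(status = "unbounded", x = NULL, objective = NA_real_))
    }
    x[!is.finite(x)] <- 0
    return(list(status = "optimal", x = x, objective = sum(obj * x)))
  }

  # initial nonbasic placement at a finite bound (0 for free variables)
  x <- numeric(n)
  vstat <- character(n)
  for (j in seq_len(n)) {
    if (is.finite(lb[j])) { x[j] <- lb[j]; vstat[j] <- "L" }
    else if (is.finite(ub[j])) { x[j] <- ub[j]; vstat[j] <- "U" }
    else { x[j] <- 0; vstat[j] <- "F" }
  }
  r <- b - as.vector(A %*% x)
  sg <- ifelse(r >= 0, 1, -1)
  Aext <- cbind(A, diag(sg, m, m))
  lbe <- c(lb, rep(0, m)); ube <- c(ub, rep(Inf, m))
  x <- c(x, abs(r))
  vstat <- c(vstat, rep("B", m))
  basis <- n + seq_len(m)

  run_phase <- function(cost, basis, vstat, x, lbe, ube, max_iter) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > max_iter) return(list(status = "maxiter", basis = basis,
                                     vstat = vstat, x = x))
      if (it %% 50L == 0L) {
        # refresh basic values against accumulated drift
        nb <- setdiff(seq_along(x), basis)
        x[basis] <- solve(Aext[, basis, drop = FALSE],
                          b - as.vector(Aext[, nb, drop = FALSE] %*% x[nb]))
      }
      B <- Aext[, basis, drop = FALSE]
      y <- solve(t(B), cost[basis])
      d <- cost - as.vector(crossprod(Aext, y))
      movable <- vstat != "B" & (ube - lbe) > tol  # fixed variables never enter
      up_ok <- movable & vstat %in% c("L", "F") & d < -tol
      dn_ok <- movable & vstat %in% c("U", "F") & d > tol
      cand <- which(up_ok | dn_ok)
      if (length(cand) == 0L) return(list(status = "optimal", basis = basis,
                                          vstat = vstat, x = x))
      enter <- cand[1L]                   # Bland: smallest eligible index
      s <- if (up_ok[enter]) 1 else -1
      w <- solve(B, Aext[, enter])
      step <- -s * w                       # d x_B per unit increase of t
      own <- ube[enter] - lbe[enter]       # entering var's own travel range
      t_best <- own; leave_pos <- 0L
      for (i in seq_len(m)) {
        if (step[i] > tol) {
          lim <- (ube[basis[i]] - x[basis[i]]) / step[i]
        } else if (step[i] < -tol) {
          lim <- (x[basis[i]] - lbe[basis[i]]) / (-step[i])
        } else next
        if (lim < t_best - tol ||
            (lim < t_best + tol && leave_pos > 0L && basis[i] < basis[leave_pos])) {
          t_best <- lim; leave_pos <- i
        } else if (leave_pos == 0L && lim <= t_best + tol) {
          t_best <- min(t_best, lim); leave_pos <- i
        }
      }
      if (!is.finite(t_best)) {
        return(list(status = "unbounded", basis = basis, vstat = vstat, x = x))
      }
      t_best <- max(t_best, 0)
      x[basis] <- x[basis] + t_best * step
      x[enter] <- x[enter] + s * t_best
      if (leave_pos == 0L) {
        # entering variable hits its own opposite bound: flip, no basis change
        vstat[enter] <- if (s > 0) "U" else "L"
        next
      }
      lv <- basis[leave_pos]
      if (step[leave_pos] > tol) { x[lv] <- ube[lv]; vstat[lv] <- "U" }
      else { x[lv] <- lbe[lv]; vstat[lv] <- "L" }
      basis[leave_pos] <- enter
      vstat[enter] <- "B"
    }
  }

  max_iter <- 20000L + 100L * (m + n)

  # phase I: minimise sum of artificials
  c1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(c1, basis, vstat, x, lbe, ube, max_iter)
  if (ph1$status == "maxiter") stop("simplex iteration limit in phase I", call. = FALSE)
  art_sum <- sum(ph1$x[n + seq_len(m)])
  if (art_sum > 1e-7 * max(1, max(abs(b)))) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  ube[n + seq_len(m)] <- 0
  x <- ph1$x; x[n + seq_len(m)][ph1$vstat[n + seq_len(m)] != "B"] <- 0

  # phase II: the real objective (internally minimisation)
  c2 <- c(if (maximize) -obj else obj, rep(0, m))
  ph2 <- run_phase(c2, ph1$basis, ph1$vstat, x, lbe, ube, max_iter)
  if (ph2$status == "maxiter") stop("simplex iteration limit in phase II", call. = FALSE)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL, objective = NA_real_))
  }
  xs <- ph2$x[seq_len(n)]
  list(status = "optimal", x = xs, objective = sum(obj * xs))
}

# Assemble the equality-form LP of a model: slack columns for extra rows.
# Returns A, b, lb, ub, and the column index of each reaction.
assemble_lp <- function(model) {
  S <- s_matrix(model)
  n <- ncol(S)
  k <- length(model$extra_constraints)
  rxn_ids <- model$reactions$id
  if (k == 0L) {
    return(list(A = S, b = rep(0, nrow(S)),
                lb = model$reactions$lower_bound,
                ub = model$reactions$upper_bound,
                n_rxn = n, rxn_ids = rxn_ids))
  }
  G <- matrix(0, k, n, dimnames = list(NULL, rxn_ids))
  h <- numeric(k)
  for (i in seq_len(k)) {
    ct <- model$extra_constraints[[i]]
    coefs <- ct$coefs
    if (ct$sense == ">=") { coefs <- -coefs; rhs <- -ct$rhs } else rhs <- ct$rhs
    G[i, names(coefs)] <- G[i, names(coefs)] + unname(coefs)
    h[i] <- rhs
  }
  A <- rbind(cbind(S, matrix(0, nrow(S), k)),
             cbind(G, diag(1, k)))
  list(A = A, b = c(rep(0, nrow(S)), h),
       lb = c(model$reactions$lower_bound, rep(0, k)),
       ub = c(model$reactions$upper_bound, rep(Inf, k)),
       n_rxn = n, rxn_ids = rxn_ids)
}

#' Flux balance analysis
#'
#' Maximises or minimises one reaction flux subject to steady-state mass
#' balance `S v = 0`, the model's flux bounds, and any extra constraint rows
#' (e.g. community coupling constraints). Infeasibility and unboundedness are
#' reported in the `status` field, never as silent zeros.
#'
#' @param model a `stoich_model`.
#' @param objective reaction id to optimise; defaults to the model's stored
#'   objective.
#' @param sense `"max"` or `"min"`.
#' @return A `flux_solution`: list with `objective_value`, `fluxes` (named
#'   numeric over reactions), `status`, `objective`, `sense`.
#' @export
#' @examples
#' m <- model_from_reactions(list(
#'   EX_a = list(stoich = c("a[e]" = -1), lb = -10, ub = 1000),
#'   t_ab = list(stoich = c("a[e]" = -1, "b[e]" = 1), lb = 0, ub = 1000),
#'   EX_b = list(stoich = c("b[e]" = -1), lb = 0, ub = 1000)
#' ))
#' solve_fba(m, "EX_b", "max")$objective_value  # 10
solve_fba <- function(model, objective = NULL, sense = c("max", "min")) {
  sense <- match.arg(sense)
  if (is.null(objective)) {
    if (is.null(model$objective)) stop("no objective given or stored", call. = FALSE)
    objective <- model$objective$reaction
  }
  if (!objective %in% model$reactions$id) {
    stop("objective reaction not in model: ", objective, call. = FALSE)
  }
  lp <- assemble_lp(model)
  obj <- numeric(ncol(lp$A))
  obj[match(objective, lp$rxn_ids)] <- 1
  sol <- simplex_solve(lp$A, lp$b, lp$lb, lp$ub, obj,
                       maximize = (sense == "max"))
  if (sol$status != "optimal") {
    return(structure(list(objective_value = NA_real_, fluxes = NULL,
                          status = sol$status, objective = objective,
                          sense = sense),
                     class = "flux_solution"))
  }
  v <- sol$x[seq_len(lp$n_rxn)]
  names(v) <- lp$rxn_ids
  resid <- max(abs(s_matrix(model) %*% v))
  if (resid > 1e-6) {
    warning("mass-balance residual ", format(resid), " exceeds 1e-6")
  }
  structure(list(objective_value = sol$objective, fluxes = v,
                 status = "optimal", objective = objective, sense = sense),
            class = "flux_solution")
}

#' @export
print.flux_solution <- function(x, ...) {
  cat("<flux_solution> ", x$sense, " ", x$objective, ": ",
      format(x$objective_value), " [", x$status, "]\n", sep = "")
  invisible(x)
}

#' Tidy a flux solution into a tibble
#' @param x a `flux_solution`.
#' @param ... unused.
#' @return Tibble (reaction, flux).
#' @method tidy flux_solution
#' @export
tidy.flux_solution <- function(x, ...) {
  if (is.null(x$fluxes)) return(tibble::tibble(reaction = character(), flux = numeric()))
  tibble::tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}

#' One-row summary of a flux solution
#' @param x a `flux_solution`.
#' @param ... unused.
#' @return Tibble with objective, sense, value, status.
#' @method glance flux_solution
#' @export
glance.flux_solution <- function(x, ...) {
  tibble::tibble(objective = x$objective, sense = x$sense,
                 objective_value = x$objective_value, status = x$status)
}

#' Flux variability analysis
#'
#' For each requested reaction, the minimum and maximum flux over the feasible
#' region `S v = 0`, bounds, extra constraints. The model is checked for
#' feasibility once before any per-reaction solve.
#'
#' @param model a `stoich_model`.
#' @param reaction_ids reactions to scan; defaults to all.
#' @return An `fva_result` tibble (reaction, min_flux, max_flux).
#' @export
fva <- function(model, reaction_ids = NULL) {
  if (is.null(reaction_ids)) reaction_ids <- model$reactions$id
  unknown <- setdiff(reaction_ids, model$reactions$id)
  if (length(unknown) > 0) {
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  lp <- assemble_lp(model)
  zero <- numeric(ncol(lp$A))
  feas <- simplex_solve(lp$A, lp$b, lp$lb, lp$ub, zero, maximize = TRUE)
  if (feas$status == "infeasible") {
    stop("model is infeasible under current constraints", call. = FALSE)
  }
  res <- purrr::map(reaction_ids, function(id) {
    obj <- numeric(ncol(lp$A))
    obj[match(id, lp$rxn_ids)] <- 1
    lo <- simplex_solve(lp$A, lp$b, lp$lb, lp$ub, obj, maximize = FALSE)
    hi <- simplex_solve(lp$A, lp$b, lp$lb, lp$ub, obj, maximize = TRUE)
    tibble::tibble(
      reaction = id,
      min_flux = if (lo$status == "optimal") lo$objective else -Inf,
      max_flux = if (hi$status == "optimal") hi$objective else Inf
    )
  })
  out <- dplyr::bind_rows(res)
  class(out) <- c("fva_result", class(out))
  out
}

#' Close reactions by knockout
#'
#' Returns a copy of the model in which the named reactions have both flux
#' bounds set to zero; the input model is unmodified.
#'
#' @param model a `stoich_model`.
#' @param reaction_ids reactions to knock out.
#' @return The knockout model.
#' @export
delete_reactions <- function(model, reaction_ids) {
  unknown <- setdiff(reaction_ids, model$reactions$id)
  if (length(unknown) > 0) {
    stop("unknown reaction id(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  set_bounds(model, reaction_ids, lb = 0, ub = 0)
}
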
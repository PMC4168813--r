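## Flux balance analysis and flux variability analysis over the model's
## polytope {v : S v = 0, lb <= v <= ub}, with optional extra linear
## constraints (used e.g. to pin the RMF at a fraction of its optimum).

## Convert a list of constraints (each: list(coef = named numeric over
## reaction ids, dir = "<="|">="|"=", rhs = scalar)) to full-width rows.
constraint_rows <- function(model, constraints) {
  n <- n_reactions(model)
  A_le <- NULL; b_le <- numeric(0)
  A_eq <- NULL; b_eq <- numeric(0)
  for (cn in constraints) {
    row <- numeric(n)
    idx <- match_rxn(model, names(cn$coef))
    row[idx] <- as.numeric(cn$coef)
    if (cn$dir == "<=") {
      A_le <- rbind(A_le, row); b_le <- c(b_le, cn$rhs)
    } else if (cn$dir == ">=") {
      A_le <- rbind(A_le, -row); b_le <- c(b_le, -cn$rhs)
    } else if (cn$dir == "=") {
      A_eq <- rbind(A_eq, row); b_eq <- c(b_eq, cn$rhs)
    } else stop("unknown constraint direction: ", cn$dir)
  }
  list(A_le = A_le, b_le = b_le, A_eq = A_eq, b_eq = b_eq)
}

model_lp_parts <- function(model, constraints = NULL) {
  ex <- constraint_rows(model, constraints %||% list())
  list(
    A_eq = rbind(model$S, ex$A_eq),
    b_eq = c(rep(0, length(model$metabolites)), ex$b_eq),
    A_le = ex$A_le, b_le = ex$b_le,
    lb = model$reactions$lb, ub = model$reactions$ub
  )
}

as_objective <- function(model, objective) {
  n <- n_reactions(model)
  if (is.null(objective)) {
    obj <- model$objective
    if (all(obj == 0)) stop("model has no objective; supply one")
    return(as.numeric(obj))
  }
  if (is.character(objective)) {
    objective <- stats::setNames(rep(1, length(objective)), objective)
  }
  if (!is.null(names(objective))) {
    out <- numeric(n)
    out[match_rxn(model, names(objective))] <- as.numeric(objective)
    return(out)
  }
  stopifnot(length(objective) == n)
  as.numeric(objective)
}

#' Flux balance analysis
#'
#' Maximises `objective . v` subject to steady-state mass balance
#' `S v = 0` and the model's flux bounds.
#'
#' @param model a `metabolic_model`.
#' @param objective objective: a reaction id, a named coefficient vector, a
#'   full-length coefficient vector, or `NULL` to use the model's stored
#'   objective.
#' @param constraints optional extra linear constraints, a list of
#'   `list(coef = c(rxn = coefficient, ...), dir = "<="|">="|"=", rhs = x)`.
#' @param maximize maximise (default) or minimise.
#'
#' @return A `flux_distribution`: list with `flux` (named numeric over
#'   reactions) and `objective_value`.
#' @export
#' @examples
#' m <- chain_model()
#' fba(m, "r3")$objective_value  # 10, limited by the bounds
fba <- function(model, objective = NULL, constraints = NULL, maximize = TRUE) {
  obj <- as_objective(model, objective)
  p <- model_lp_parts(model, constraints)
  res <- solve_lp(obj, A_eq = p$A_eq, b_eq = p$b_eq, A_le = p$A_le,
                  b_le = p$b_le, lb = p$lb, ub = p$ub, maximize = maximize)
  if (res$status == "infeasible") stop("FBA infeasible: the flux polytope is empty")
  if (res$status == "unbounded") stop("FBA unbounded: objective has no finite optimum")
  flux_distribution(stats::setNames(res$x, reaction_ids(model)), res$objective)
}

flux_distribution <- function(flux, objective_value) {
  structure(list(flux = flux, objective_value = objective_value),
            class = "flux_distribution")
}

#' @export
print.flux_distribution <- function(x, ...) {
  cat("<flux_distribution> objective =", format(x$objective_value),
      "|", sum(abs(x$flux) > 1e-6), "of", length(x$flux), "reactions active\n")
  invisible(x)
}

#' Flux variability analysis
#'
#' For each requested reaction, the minimum and maximum flux attainable over
#' the (optionally further constrained) flux polytope: two LPs per reaction.
#'
#' @inheritParams fba
#' @param reactions reaction ids to analyse (default: all).
#' @return A tibble with columns `reaction_id`, `min_flux`, `max_flux`.
#' @export
fva <- function(model, reactions = NULL, constraints = NULL) {
  ids <- reactions %||% reaction_ids(model)
  idx <- match_rxn(model, ids)
  p <- model_lp_parts(model, constraints)
  n <- n_reactions(model)
  lo <- hi <- numeric(length(idx))
  for (k in seq_along(idx)) {
    obj <- numeric(n); obj[idx[k]] <- 1
    r1 <- solve_lp(obj, p$A_eq, p$b_eq, p$A_le, p$b_le, p$lb, p$ub, maximize = FALSE)
    if (r1$status == "infeasible") stop("FVA infeasible: the flux polytope is empty")
    r2 <- solve_lp(obj, p$A_eq, p$b_eq, p$A_le, p$b_le, p$lb, p$ub, maximize = TRUE)
    lo[k] <- r1$objective; hi[k] <- r2$objective
  }
  tibble::tibble(reaction_id = ids, min_flux = lo, max_flux = hi)
}

#' Find blocked reactions by exhaustive FVA
#'
#' A reaction is blocked when it cannot carry non-zero flux at steady state;
#' operationally, when its FVA interval is `{0}` within tolerance. This is
#' the reference detector against which the faster heuristic checkers are
#' validated.
#'
#' @param model a `metabolic_model`.
#' @param tol classification tolerance (default 1e-6).
#' @return character vector of blocked reaction ids (possibly empty).
#' @export
#' @examples
#' find_blocked_fva(chain_model())          # none
find_blocked_fva <- function(model, tol = 1e-6) {
  if (n_reactions(model) == 0) return(character(0))
  fv <- fva(model)
  fv$reaction_id[pmax(abs(fv$min_flux), abs(fv$max_flux)) <= tol]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
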
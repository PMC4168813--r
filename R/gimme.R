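## GIMME-like family: extraction maximising similarity to data subject to a
## Required Metabolic Functionality (RMF).
##
## Two-step scheme: (1) FBA finds the RMF optimum; (2) a second program
## minimises the inconsistency score IS = sum_i p_i |v_i| — penalties times
## flux magnitudes — subject to the RMF being held at a fraction k of its
## optimum. |v| is realised by splitting reversible reactions, which keeps
## GIMME an LP; GIM3E adds key-metabolite sink activation and per-reversible
## direction binaries, making it a MILP.

rmf_opt_value <- function(model, rmf) {
  sol <- fba(model, rmf)
  if (sol$objective_value <= 0) {
    stop("RMF cannot be achieved: its FBA optimum is ", sol$objective_value)
  }
  sol$objective_value
}

split_objective <- function(split, rmf_coef) {
  ## map original-reaction coefficients onto the split model's columns
  sm <- split$model; mp <- split$mapping
  out <- stats::setNames(numeric(n_reactions(sm)), reaction_ids(sm))
  out[mp$forward] <- rmf_coef[mp$id]
  has_rev <- !is.na(mp$reverse)
  out[mp$reverse[has_rev]] <- -rmf_coef[mp$id[has_rev]]
  out
}

#' GIMME: extraction under a required metabolic functionality
#'
#' Step 1 maximises the RMF by FBA; step 2 minimises the inconsistency
#' score `IS = sum p_i * |v_i|` over the flux polytope intersected with
#' `RMF >= k * RMF_opt`. Retained reactions are those with expression at or
#' above the threshold (zero penalty with data present) plus those carrying
#' flux above `epsilon` in the optimal distribution.
#'
#' @param model a `metabolic_model`.
#' @param penalty penalty table from [gimme_penalty()] (columns
#'   `reaction_id`, `data`, `penalty`).
#' @param rmf the required metabolic functionality: a reaction id or named
#'   coefficient vector (as [fba()]'s `objective`).
#' @param k fraction of the RMF optimum to guarantee, in `[0, 1]`
#'   (default 0.9).
#' @param epsilon activation flux for membership (default 1e-4).
#' @return a `gimme_result` (an `extraction_result`) with elements `R_P`,
#'   `flux`, `IS` (the inconsistency score), `RMF_opt` and `k`.
#' @export
#' @examples
#' m <- parallel_model()
#' d <- c(r1 = 10, r2 = 10, r3 = 1, r4 = 10)
#' res <- gimme(m, gimme_penalty(d, threshold = 5), rmf = "r4", k = 0.9)
#' res$IS            # 0: the expressed path covers the RMF
#' res$R_P           # r3 is neither expressed nor used
gimme <- function(model, penalty, rmf, k = 0.9, epsilon = 1e-4) {
  stopifnot(k >= 0, k <= 1)
  p <- as_rxn_vector(model, penalty[, c("reaction_id", "penalty")], default = 0)
  d <- as_rxn_vector(model, penalty[, c("reaction_id", "data")])
  rmf_coef <- stats::setNames(as_objective(model, rmf), reaction_ids(model))
  rmf_opt <- rmf_opt_value(model, rmf)

  split <- split_reversible(model)
  sm <- split$model
  obj <- stats::setNames(numeric(n_reactions(sm)), reaction_ids(sm))
  obj[split$mapping$forward] <- p[split$mapping$id]
  has_rev <- !is.na(split$mapping$reverse)
  obj[split$mapping$reverse[has_rev]] <- p[split$mapping$id[has_rev]]

  rmf_split <- split_objective(split, rmf_coef)
  parts <- model_lp_parts(sm, list(list(
    coef = rmf_split[rmf_split != 0], dir = ">=", rhs = k * rmf_opt
  )))
  sol <- solve_lp(as.numeric(obj), parts$A_eq, parts$b_eq, parts$A_le,
                  parts$b_le, parts$lb, parts$ub, maximize = FALSE)
  if (sol$status != "optimal") {
    stop("internal error: GIMME step-2 LP returned ", sol$status)
  }
  vsplit <- stats::setNames(sol$x, reaction_ids(sm))
  v <- merge_split_flux(vsplit, split$mapping)
  IS <- sum(p * abs(v))
  R_P <- union(names(d)[!is.na(d) & p == 0], names(v)[abs(v) > epsilon])
  R_P <- intersect(reaction_ids(model), R_P)
  new_extraction_result(
    "gimme", model, R_P, flux = v, objective = IS,
    extra = list(IS = IS, RMF_opt = rmf_opt, k = k, epsilon = epsilon,
                 penalty = p, data = d)
  )
}

#' GIM3E: GIMME with metabolite evidence and directed reversibles
#'
#' Minimises `sum p_i |v_i|` (penalties from [gim3e_penalty()]: distance to
#' the sample's maximum intensity, GPR-mapped) subject to the RMF constraint,
#' a minimum flux `epsilon` through the sink of every key metabolite
#' (evidence the metabolite is synthesised), and one binary per reversible
#' reaction forcing a single operating direction. Sinks missing from the
#' model are added automatically.
#'
#' @inheritParams gimme
#' @param penalty penalty table from [gim3e_penalty()] (columns
#'   `reaction_id`, `penalty`).
#' @param key_metabolites metabolite ids with evidence of synthesis.
#' @param epsilon minimum activation flux for key-metabolite sinks and for
#'   membership (default 1e-4).
#' @param widen_fva also retain every reaction able to carry flux above
#'   `epsilon/2` somewhere in the penalty-optimal face (FVA under an
#'   objective-value constraint), not just the incumbent's support.
#' @return a `gim3e_result` (an `extraction_result`) with `R_P`, `flux`,
#'   `IS`, `RMF_opt`, `k`, and `key_met_sinks` (sink reaction ids).
#' @export
gim3e <- function(model, penalty, rmf, key_metabolites = character(0),
                  k = 0.9, epsilon = 1e-4, widen_fva = FALSE) {
  stopifnot(k >= 0, k <= 1)
  added <- add_metabolite_sinks(model, key_metabolites)
  mod <- added$model
  sinks <- added$sinks
  ## sink activation as hard lower bounds
  sidx <- match_rxn(mod, sinks)
  mod$reactions$lb[sidx] <- pmax(mod$reactions$lb[sidx], epsilon)
  ## name the offending metabolite if some sink cannot reach epsilon
  chk <- solve_lp(numeric(n_reactions(mod)), A_eq = mod$S,
                  b_eq = rep(0, length(mod$metabolites)),
                  lb = mod$reactions$lb, ub = mod$reactions$ub)
  if (chk$status != "optimal") {
    for (i in seq_along(sinks)) {
      m1 <- mod
      m1$reactions$lb[sidx] <- 0          # relax all sinks ...
      m1$reactions$lb[sidx[i]] <- epsilon # ... except this one
      one <- solve_lp(numeric(n_reactions(m1)), A_eq = m1$S,
                      b_eq = rep(0, length(m1$metabolites)),
                      lb = m1$reactions$lb, ub = m1$reactions$ub)
      if (one$status != "optimal") {
        stop("key metabolite '", key_metabolites[i],
             "' cannot sustain sink flux >= ", epsilon)
      }
    }
    stop("key metabolite sinks jointly infeasible at epsilon = ", epsilon)
  }

  p <- as_rxn_vector(mod, penalty[, c("reaction_id", "penalty")], default = 0)
  rmf_coef <- stats::setNames(as_objective(mod, rmf), reaction_ids(mod))
  rmf_opt <- rmf_opt_value(mod, rmf)

  split <- split_reversible(mod)
  sm <- split$model
  mp <- split$mapping
  ids_s <- reaction_ids(sm)
  n_s <- n_reactions(sm)

  obj <- stats::setNames(numeric(n_s), ids_s)
  obj[mp$forward] <- p[mp$id]
  has_rev <- !is.na(mp$reverse)
  obj[mp$reverse[has_rev]] <- p[mp$id[has_rev]]

  rev_rows <- which(has_rev)
  n_bin <- length(rev_rows)
  nv <- n_s + n_bin  # flux variables then direction binaries

  parts <- model_lp_parts(sm, list(list(
    coef = split_objective(split, rmf_coef)[split_objective(split, rmf_coef) != 0],
    dir = ">=", rhs = k * rmf_opt
  )))
  A_eq <- cbind(parts$A_eq, matrix(0, nrow(parts$A_eq), n_bin))
  A_le <- if (is.null(parts$A_le)) NULL else
    cbind(parts$A_le, matrix(0, nrow(parts$A_le), n_bin))
  b_le <- parts$b_le
  ## direction coupling: v_for <= ub_for * y ; v_rev <= ub_rev * (1 - y)
  for (b in seq_len(n_bin)) {
    j_for <- match(mp$forward[rev_rows[b]], ids_s)
    j_rev <- match(mp$reverse[rev_rows[b]], ids_s)
    row1 <- numeric(nv); row1[j_for] <- 1; row1[n_s + b] <- -sm$reactions$ub[j_for]
    row2 <- numeric(nv); row2[j_rev] <- 1; row2[n_s + b] <- sm$reactions$ub[j_rev]
    A_le <- rbind(A_le, row1, row2)
    b_le <- c(b_le, 0, sm$reactions$ub[j_rev])
  }
  lb <- c(parts$lb, rep(0, n_bin))
  ub <- c(parts$ub, rep(1, n_bin))
  sol <- solve_milp(c(as.numeric(obj), numeric(n_bin)), A_eq, parts$b_eq,
                    A_le, b_le, lb, ub, bin_idx = n_s + seq_len(n_bin),
                    maximize = FALSE)
  if (sol$status != "optimal") {
    stop("GIM3E MILP returned ", sol$status)
  }
  vsplit <- stats::setNames(sol$x[seq_len(n_s)], ids_s)
  v <- merge_split_flux(vsplit, mp)
  IS <- sum(p * abs(v))
  R_P <- union(names(v)[abs(v) > epsilon / 2], sinks)
  if (widen_fva) {
    ## any reaction able to carry flux on the penalty-optimal face
    pen_row <- list(coef = obj[obj != 0], dir = "<=", rhs = IS + 1e-6)
    rmf_row <- list(coef = split_objective(split, rmf_coef)[split_objective(split, rmf_coef) != 0],
                    dir = ">=", rhs = k * rmf_opt)
    fv <- fva(sm, constraints = list(pen_row, rmf_row))
    able <- fv$reaction_id[pmax(abs(fv$min_flux), abs(fv$max_flux)) > epsilon / 2]
    R_P <- union(R_P, mp$id[mp$forward %in% able | (!is.na(mp$reverse) & mp$reverse %in% able)])
  }
  R_P <- intersect(reaction_ids(mod), R_P)
  new_extraction_result(
    "gim3e", mod, R_P, flux = v, objective = IS,
    extra = list(IS = IS, RMF_opt = rmf_opt, k = k, epsilon = epsilon,
                 penalty = p, key_met_sinks = sinks)
  )
}
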
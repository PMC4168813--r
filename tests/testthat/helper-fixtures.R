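# Shared fixtures and independent oracles for the test suite.

# seeded random toy network: mixed chain/parallel/dead-end/reversible
random_toy <- function(seed, max_linear = 5) {
  set.seed(seed)
  make_toy_model(
    n_linear = sample(2:max_linear, 1),
    n_parallel = sample(0:3, 1),
    n_deadends = sample(0:3, 1),
    reversible_fraction = runif(1),
    seed = seed
  )
}

# independent blocked-reaction oracle: two direct LPs per reaction, built
# straight on solve_lp (bypasses fva()/find_blocked_fva())
oracle_blocked <- function(model, tol = 1e-6) {
  n <- n_reactions(model)
  ids <- reaction_ids(model)
  blocked <- character(0)
  for (j in seq_len(n)) {
    obj <- numeric(n); obj[j] <- 1
    hi <- solve_lp(obj, A_eq = model$S, b_eq = rep(0, nrow(model$S)),
                   lb = model$reactions$lb, ub = model$reactions$ub,
                   maximize = TRUE)
    lo <- solve_lp(obj, A_eq = model$S, b_eq = rep(0, nrow(model$S)),
                   lb = model$reactions$lb, ub = model$reactions$ub,
                   maximize = FALSE)
    if (max(abs(hi$objective), abs(lo$objective)) <= tol) {
      blocked <- c(blocked, ids[j])
    }
  }
  blocked
}

# dead-end variant of the chain: r4 produces an unconsumed metabolite
chain_with_deadend <- function() {
  metabolic_model(tibble::tibble(
    id = c("r1", "r2", "r3", "r4"),
    stoich = list(c(A = 1), c(A = -1, B = 1), c(B = -1), c(A = -1, C = 1)),
    lb = 0, ub = 10,
    gpr = paste0("g_r", 1:4)
  ))
}

# exhaustive direction-fixing oracle for the GIM3E MILP: fix every reversible
# to one sense (flip reverse-fixed columns so |v| = v), solve the penalised
# LP with the full model's RMF bound, return the best objective
gim3e_direction_oracle <- function(m, pen, rmf_id, k, rmf_opt) {
  rev_ids <- reversible_set(m)
  p <- stats::setNames(pen$penalty, pen$reaction_id)
  best <- Inf
  n_rev <- length(rev_ids)
  for (mask in 0:(2^n_rev - 1)) {
    m2 <- m
    for (b in seq_len(n_rev)) {
      rid <- rev_ids[b]
      if (bitwAnd(mask, bitwShiftL(1L, b - 1L)) > 0) {
        m2 <- flip_reaction(m2, rid)
      }
      m2$reactions$lb[match(rid, reaction_ids(m2))] <- 0
    }
    n <- n_reactions(m2)
    rmf_row <- numeric(n); rmf_row[match(rmf_id, reaction_ids(m2))] <- -1
    sol <- solve_lp(unname(p[reaction_ids(m2)]),
                    A_eq = m2$S, b_eq = rep(0, nrow(m2$S)),
                    A_le = matrix(rmf_row, 1), b_le = -k * rmf_opt,
                    lb = m2$reactions$lb, ub = m2$reactions$ub,
                    maximize = FALSE)
    if (sol$status == "optimal") best <- min(best, sol$objective)
  }
  best
}
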
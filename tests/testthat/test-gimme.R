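# GIMME-like family: RMF-constrained inconsistency minimisation.

test_that("gimme routes flux through the expressed path", {
  m <- parallel_model()
  d <- c(r1 = 10, r2 = 10, r3 = 1, r4 = 10)
  res <- gimme(m, gimme_penalty(d, threshold = 5), rmf = "r4", k = 0.9)
  expect_gte(unname(res$flux["r2"]), 9 - 1e-6)
  expect_equal(unname(res$flux["r3"]), 0, tolerance = 1e-9)
  expect_equal(res$IS, 0)
  expect_false("r3" %in% res$R_P)
  expect_setequal(res$R_P, c("r1", "r2", "r4"))
})

test_that("gimme degenerates correctly at zero penalty and k = 0", {
  m <- parallel_model()
  # all expression above threshold: zero inconsistency at any step-1 optimum
  d_hi <- c(r1 = 9, r2 = 9, r3 = 9, r4 = 9)
  res <- gimme(m, gimme_penalty(d_hi, 5), rmf = "r4", k = 0.9)
  expect_equal(res$IS, 0)
  rmf_flux <- sum(res$flux["r4"])
  expect_gte(rmf_flux, 0.9 * res$RMF_opt - 1e-6)
  # k = 0: the zero flux vector is admissible, IS drops to 0
  d_lo <- c(r1 = 1, r2 = 1, r3 = 1, r4 = 1)
  res0 <- gimme(m, gimme_penalty(d_lo, 5), rmf = "r4", k = 0)
  expect_equal(res0$IS, 0, tolerance = 1e-9)
  expect_equal(max(abs(res0$flux)), 0, tolerance = 1e-9)
})

test_that("gimme satisfies the RMF constraint for every k, incl. reversibles", {
  for (seed in 101:104) {
    toy <- random_toy(seed)
    m <- toy$model
    ev <- make_evidence(m, toy$truth, noise_sd = 1.5, seed = seed)
    pen <- gimme_penalty(map_expression(m, ev$gene_values), threshold = 5)
    for (k in c(0, 0.5, 0.9, 1)) {
      res <- gimme(m, pen, rmf = "EX_out", k = k)
      rmf_val <- unname(res$flux["EX_out"])
      expect_gte(rmf_val, k * res$RMF_opt - 1e-6)
      expect_lt(max(abs(m$S %*% res$flux)), 1e-6)
    }
  }
})

test_that("inconsistency score is non-increasing in the threshold's complement", {
  # IS is non-increasing as c decreases (fewer penalised reactions)
  toy <- random_toy(105)
  m <- toy$model
  ev <- make_evidence(m, toy$truth, noise_sd = 2, seed = 105)
  d <- map_expression(m, ev$gene_values)
  is_vals <- vapply(c(9, 6, 3, 1), function(c0) {
    gimme(m, gimme_penalty(d, c0), rmf = "EX_out", k = 0.9)$IS
  }, numeric(1))
  expect_true(all(diff(is_vals) <= 1e-9))
})

test_that("gimme errors when the RMF cannot be achieved", {
  md <- chain_with_deadend()
  expect_error(gimme(md, gimme_penalty(c(r1 = 1), 5), rmf = "r4"),
               "RMF cannot be achieved")
})

test_that("gim3e forces key-metabolite sink flux in every solution", {
  m <- chain_model()
  pen <- gim3e_penalty(m, c(g_r1 = 4, g_r2 = 7, g_r3 = 9), I_max = 10)
  res <- gim3e(m, pen, rmf = "r3", key_metabolites = "B", k = 0.9,
               epsilon = 1e-4)
  sink <- res$key_met_sinks
  expect_gte(unname(res$flux[sink]), 1e-4 - 1e-12)
  expect_true(all(sink %in% res$R_P))
  # a metabolite that is only ever consumed cannot sustain sink flux
  md <- metabolic_model(tibble::tibble(
    id = c("r1", "r2", "r3", "rz"),
    stoich = list(c(A = 1), c(A = -1, B = 1), c(B = -1), c(Z = -1, B = 1)),
    lb = 0, ub = 10, gpr = paste0("g_", c("r1", "r2", "r3", "rz"))
  ))
  pend <- gim3e_penalty(md, c(g_r1 = 5), I_max = 10)
  expect_error(gim3e(md, pend, rmf = "r3", key_metabolites = "Z"),
               "Z")
})

test_that("gim3e without key metabolites or reversibles reduces to gimme", {
  m <- parallel_model()
  vals <- c(g_r1 = 9, g_r2 = 9, g_r3 = 2, g_r4 = 9)
  pen3 <- gim3e_penalty(m, vals, I_max = 10)
  res3 <- gim3e(m, pen3, rmf = "r4", k = 0.9)
  # same program solved as a plain LP through gimme with the GIM3E penalty
  pen_lp <- tibble::tibble(reaction_id = pen3$reaction_id,
                           data = NA_real_, penalty = pen3$penalty)
  res_lp <- gimme(m, pen_lp, rmf = "r4", k = 0.9)
  expect_equal(res3$IS, res_lp$IS, tolerance = 1e-6)
})

test_that("gim3e direction binaries match exhaustive direction enumeration", {
  for (seed in 111:114) {
    toy <- make_toy_model(n_linear = 3, n_parallel = 1, n_deadends = 0,
                          reversible_fraction = 0.75, seed = seed)
    m <- toy$model
    rev_ids <- reversible_set(m)
    ev <- make_evidence(m, toy$truth, noise_sd = 2, seed = seed)
    pen <- gim3e_penalty(m, ev$gene_values)
    res <- gim3e(m, pen, rmf = "EX_out", k = 0.9)
    # oracle: exhaust all direction fixings of the reversibles with a direct
    # LP per fixing (helper gim3e_direction_oracle), take the best
    best <- gim3e_direction_oracle(m, pen, "EX_out", 0.9, res$RMF_opt)
    expect_equal(res$IS, best, tolerance = 1e-6)
  }
})
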
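# Synthetic generators and oracles.

test_that("make_toy_model builds the requested topology deterministically", {
  toy <- make_toy_model(n_linear = 3, n_deadends = 1, seed = 1)
  # 4 internal (3 chain + 1 dead-end) + 2 exchange reactions
  expect_equal(n_reactions(toy$model), 6)
  expect_equal(toy$truth$blocked_set, "d1")
  expect_setequal(find_blocked_fva(toy$model), toy$truth$blocked_set)
  # determinism under the seed
  toy2 <- make_toy_model(n_linear = 3, n_deadends = 1, seed = 1)
  expect_equal(toy$model, toy2$model)
  toy3 <- make_toy_model(4, 2, 1, 0.6, seed = 9)
  toy4 <- make_toy_model(4, 2, 1, 0.6, seed = 9)
  expect_equal(toy3$model, toy4$model)
  # full reversibility on the internal backbone
  tr <- make_toy_model(3, 1, 0, reversible_fraction = 1, seed = 2)
  expect_setequal(reversible_set(tr$model), c("r1", "r2", "r3", "p1"))
  # degenerate spec: minimal one-reaction exchange model
  t0 <- make_toy_model(0)
  expect_equal(n_reactions(t0$model), 1)
  expect_equal(t0$truth$blocked_set, reaction_ids(t0$model))
})

test_that("ground truth is flux-consistent and blocked set exact", {
  for (seed in 301:310) {
    toy <- random_toy(seed)
    expect_setequal(find_blocked_fva(toy$model), toy$truth$blocked_set)
    sub <- extract_submodel(toy$model, toy$truth$active_set)
    expect_length(find_blocked_fva(sub), 0)
  }
})

test_that("make_evidence separates active and inactive genes", {
  toy <- make_toy_model(3, 0, 2, seed = 4)
  ev <- make_evidence(toy$model, toy$truth, noise_sd = 0, seed = 4)
  g <- stats::setNames(ev$gene_values$value, ev$gene_values$gene)
  expect_equal(unname(g[paste0("g_", toy$truth$blocked_set)]), c(2, 2))
  expect_true(all(g[paste0("g_", toy$truth$active_set)] == 8))
  # zero noise: discretisation by the midpoint recovers the truth exactly
  d <- map_expression(toy$model, ev$gene_values)
  sets <- discretize(d, c_low = ev$threshold, c_high = ev$threshold)
  expect_setequal(sets$R_H, toy$truth$active_set)
  expect_setequal(sets$R_L, toy$truth$blocked_set)
  # same seed, same draw; noise must be non-negative
  ev2 <- make_evidence(toy$model, toy$truth, noise_sd = 0, seed = 4)
  expect_identical(ev, ev2)
  expect_error(make_evidence(toy$model, toy$truth, noise_sd = -1), "non-negative")
  # with noise over replicates, active reactions score higher (rank-sum)
  big <- make_toy_model(6, 2, 4, seed = 4)
  evn <- make_evidence(big$model, big$truth, noise_sd = 3, seed = 4,
                       n_samples = 20)
  sc <- mcadre_scores(big$model, evn$profiles)
  act <- sc$expression_score[sc$reaction_id %in% big$truth$active_set &
                               sc$reaction_id %in% big$truth$core_suggestion]
  ina <- sc$expression_score[sc$reaction_id %in% big$truth$blocked_set]
  expect_lt(stats::wilcox.test(act, ina, alternative = "greater",
                               exact = FALSE)$p.value, 0.05)
})

test_that("composite GPR mode scores complexes by their limiting gene", {
  toy <- make_toy_model(3, 1, 0, seed = 6, composite_gpr = TRUE)
  gprs <- toy$model$reactions$gpr
  expect_true(any(grepl("and", gprs)))
  comp <- which(grepl(" and ", gprs))[1]
  expect_false(is.na(comp))
  genes <- gpr_genes(parse_gpr(gprs[comp]))
  vals <- stats::setNames(seq(3, by = 2, length.out = length(genes)), genes)
  # expected value by the AND=min / OR=max convention on the two known forms
  expected <- if (grepl("or", gprs[comp])) {
    max(min(vals[1], vals[2]), vals[3])
  } else {
    min(vals[1], vals[2])
  }
  m1 <- extract_submodel(toy$model, toy$model$reactions$id[comp])
  expect_equal(map_expression(m1, vals)$value[1], unname(expected))
})

test_that("brute_force_consistent_subsets enumerates minima exactly", {
  m <- parallel_model()
  res <- brute_force_consistent_subsets(m, must_keep = "r4")
  mins <- lapply(res$minimal, sort)
  expect_equal(length(mins), 2)
  expect_setequal(vapply(mins, paste, "", collapse = "+"),
                  c("r1+r2+r4", "r1+r3+r4"))
  # empty must_keep includes the empty model
  res0 <- brute_force_consistent_subsets(chain_model())
  expect_true(any(vapply(res0$subsets, length, 1L) == 0))
  # keeping a dead-end yields no consistent superset
  resd <- brute_force_consistent_subsets(chain_with_deadend(), "r4")
  expect_length(resd$minimal, 0)
  big <- make_toy_model(9, 3, 3, seed = 1)
  expect_error(brute_force_consistent_subsets(big$model), "too large")
})

test_that("brute_force_imat degenerates and caps correctly", {
  m <- parallel_model()
  expect_equal(brute_force_imat(m, character(0), character(0)), 0L)
  expect_equal(brute_force_imat(m, "r2", character(0)), 1L)
  expect_error(brute_force_imat(m, rep(reaction_ids(m), 3), character(0)),
               "disjoint|too many")
})
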
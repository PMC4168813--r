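# MBA-like family: consistency checkers, pruning, sparse-mode expansion.

test_that("all three consistency checkers agree with the FVA reference", {
  expect_equal(check_model_consistency_mba(chain_with_deadend()), "r4")
  expect_equal(check_model_consistency_mba(chain_model()), character(0))
  for (seed in 201:215) {
    toy <- random_toy(seed)
    ref <- sort(find_blocked_fva(toy$model))
    expect_equal(sort(check_model_consistency_mba(toy$model, seed = seed)), ref)
    expect_equal(sort(check_model_consistency_fastcore(toy$model)), ref)
    expect_equal(ref, sort(toy$truth$blocked_set))
  }
})

test_that("mba_single follows the commit test on the parallel-path fixture", {
  m <- parallel_model()
  for (perm in list(c("r1", "r3"), c("r3", "r1"))) {
    rp <- mba_single(m, C_H = "r4", C_M = "r2", permutation = perm, k = 0.5)
    expect_setequal(rp, c("r1", "r2", "r4"))
  }
  # empty non-core: everything stays
  rp_all <- mba_single(m, C_H = c("r1", "r4"), C_M = c("r2", "r3"))
  expect_setequal(rp_all, reaction_ids(m))
  # blocked high-likelihood core refuses to start
  expect_error(mba_single(chain_with_deadend(), C_H = "r4"), "blocked")
  # result is consistent and contains C_H
  for (seed in 221:224) {
    toy <- random_toy(seed)
    ch <- intersect(toy$truth$core_suggestion, toy$truth$active_set)[1]
    rp <- mba_single(toy$model, C_H = ch, k = 0.5)
    expect_true(ch %in% rp)
    expect_length(find_blocked_fva(extract_submodel(toy$model, rp)), 0)
  }
})

test_that("permutation order can change the single-pass result", {
  # symmetric two-path fixture: whichever path is attacked first dies
  m <- parallel_model()
  rp1 <- mba_single(m, C_H = "r4", permutation = c("r2", "r3", "r1"), k = 0.5)
  rp2 <- mba_single(m, C_H = "r4", permutation = c("r3", "r2", "r1"), k = 0.5)
  expect_false(setequal(rp1, rp2))
  expect_setequal(union(rp1, rp2), reaction_ids(m))
})

test_that("mba population run is seeded, frequency-ranked and consistent", {
  m <- parallel_model()
  res <- mba(m, C_H = "r4", n_iter = 50, seed = 3, k = 0.5)
  # each symmetric path occurs in about half the population
  occ <- stats::setNames(res$ranking$occurrence, res$ranking$reaction_id)
  ci <- stats::qbinom(c(0.0005, 0.9995), 50, 0.5) / 50
  expect_gte(occ["r2"] + occ["r3"], 1)  # exactly one path survives each pass
  expect_gte(min(occ["r2"], occ["r3"]), ci[1])
  expect_lte(max(occ["r2"], occ["r3"]), ci[2])
  expect_length(find_blocked_fva(extract_submodel(m, res$R_P)), 0)
  expect_true("r4" %in% res$R_P)
  # same seed reproduces everything; n_iter = 1 equals the seeded single pass
  res2 <- mba(m, C_H = "r4", n_iter = 50, seed = 3, k = 0.5)
  expect_identical(res$ranking, res2$ranking)
  expect_identical(res$R_P, res2$R_P)
})

test_that("mcadre_scores computes frequency, neighbourhood mean and pass-through", {
  m <- chain_model()
  prof <- rbind(c(g_r1 = 1, g_r2 = 1, g_r3 = 0),
                c(g_r1 = 1, g_r2 = 0, g_r3 = 0),
                c(g_r1 = 1, g_r2 = 1, g_r3 = 0),
                c(g_r1 = 1, g_r2 = 1, g_r3 = 1))
  sc <- mcadre_scores(m, prof, confidence = c(r1 = 3, r2 = 0, r3 = 1))
  expect_equal(sc$expression_score, c(1, 0.75, 0.25))
  # chain adjacency: r1-r2 share A; r2-r3 share B
  expect_equal(sc$connectivity_score, c(0.75, (1 + 0.25) / 2, 0.75))
  expect_equal(sc$confidence_score, c(3, 0, 1))
  expect_error(mcadre_scores(m, prof * 2.5), "binarized")
  # isolated reaction gets connectivity 0 by convention
  mi <- metabolic_model(tibble::tibble(
    id = c("a", "b"), stoich = list(c(X = 1), c(Y = 1)),
    lb = 0, ub = 10, gpr = c("gA", "gB")
  ))
  sci <- mcadre_scores(mi, rbind(c(gA = 1, gB = 0)))
  expect_equal(sci$connectivity_score, c(0, 0))
})

test_that("mcadre prunes by rank, protects key metabolites, relaxes on negatives", {
  m <- parallel_model()
  sc <- tibble::tibble(
    reaction_id = c("r1", "r2", "r3", "r4"),
    expression_score = c(1, 1, 0.2, 1),
    connectivity_score = c(0.5, 0.5, 0.5, 0.5),
    confidence_score = 0
  )
  res <- mcadre(m, sc, core_threshold = 0.5)
  expect_setequal(res$R_P, c("r1", "r2", "r4"))
  # a removal that would silence a key metabolite is refused regardless of rank
  m2 <- chain_model()
  sc2 <- tibble::tibble(reaction_id = c("r1", "r2", "r3"),
                        expression_score = c(1, 0.1, 1),
                        connectivity_score = 0, confidence_score = 0)
  res2 <- mcadre(m2, sc2, core_threshold = 0.5, key_metabolites = "B")
  expect_true("r2" %in% res2$R_P)  # only producer of B
  # negative-evidence branch arithmetic: core damage 1 vs k * non-core damage
  expect_length(find_blocked_fva(extract_submodel(m2, res2$R_P)), 0)
})

test_that("mcadre negative-evidence branch trades core damage by the ratio k", {
  # y-shaped network: removing the negative-evidence uptake blocks one core
  # reaction (c1) and two non-core reactions (n1, n2)
  m <- metabolic_model(tibble::tibble(
    id = c("up", "c1", "n1", "n2", "ex1", "ex2"),
    stoich = list(c(A = 1), c(A = -1, B = 1), c(B = -1, C = 1), c(B = -1, D = 1),
                  c(C = -1), c(D = -1)),
    lb = 0, ub = 10,
    gpr = c("g_up", "g_c1", "g_n1", "g_n2", NA, NA)
  ))
  sc <- tibble::tibble(
    reaction_id = c("up", "c1", "n1", "n2", "ex1", "ex2"),
    expression_score = c(0, 1, 0.3, 0.3, 0.4, 0.4),
    connectivity_score = 0, confidence_score = 0
  )
  # up carries negative evidence (score 0 with a GPR); its removal blocks
  # c1 (core) and n1, n2, ex1, ex2 (non-core): |e_C| = 1, |e_Nc| = 4
  res_small_k <- mcadre(m, sc, core_threshold = 0.9, k = 0.2)
  expect_true("up" %in% res_small_k$R_P)   # 1 < 0.2*4 fails: retained
  res_big_k <- mcadre(m, sc, core_threshold = 0.9, k = 0.5)
  expect_false("up" %in% res_big_k$R_P)    # 1 < 0.5*4 passes: removed
  expect_false("c1" %in% res_big_k$R_P)    # blocked core removed along
  expect_length(find_blocked_fva(extract_submodel(m, res_big_k$R_P)), 0)
})

test_that("find_sparse_mode activates the target with an L1-minimal support", {
  m <- parallel_model()
  expect_setequal(find_sparse_mode(m, "r2", c("r1", "r3", "r4")),
                  c("r1", "r2", "r4"))
  expect_equal(find_sparse_mode(m, character(0), "r1"), character(0))
  # blocked target cannot be activated
  md <- chain_with_deadend()
  expect_equal(find_sparse_mode(md, "r4", c("r1", "r2", "r3")), character(0))
})

test_that("fastcore returns a minimal consistent superset of the core", {
  m <- parallel_model()
  res <- fastcore(m, C = "r4")
  expect_length(res$R_P, 3)
  expect_true("r4" %in% res$R_P)
  expect_length(find_blocked_fva(extract_submodel(m, res$R_P)), 0)
  # whole consistent model as core: nothing to prune
  res_all <- fastcore(m, C = reaction_ids(m))
  expect_setequal(res_all$R_P, reaction_ids(m))
  # blocked core reaction refused
  expect_error(fastcore(chain_with_deadend(), C = "r4"), "blocked")
  # near-minimality against the enumeration oracle on random fixtures
  for (seed in 231:236) {
    toy <- random_toy(seed, max_linear = 3)
    core <- intersect(toy$truth$core_suggestion, toy$truth$active_set)
    core <- core[seq_len(min(2, length(core)))]
    res <- fastcore(toy$model, core)
    expect_true(all(core %in% res$R_P))
    expect_length(find_blocked_fva(extract_submodel(toy$model, res$R_P)), 0)
    minimal <- brute_force_consistent_subsets(toy$model, core,
                                              minimum_only = TRUE)$minimal
    expect_lte(length(res$R_P), length(minimal[[1]]) + 1)
  }
})

test_that("fastcore handles reversible cores via sense flipping", {
  # reversible bridge that must run in reverse to connect the core
  m <- metabolic_model(tibble::tibble(
    id = c("up", "rv", "out"),
    stoich = list(c(B = 1), c(A = -1, B = 1), c(A = -1)),
    lb = c(0, -10, 0), ub = c(10, 0.0, 10)
  ))
  # rv has bounds [-10, 0]: only its reverse sense (B -> A) can run
  res <- fastcore(m, C = "rv")
  expect_true("rv" %in% res$R_P)
  m2 <- metabolic_model(tibble::tibble(
    id = c("up", "rv", "out"),
    stoich = list(c(B = 1), c(A = -1, B = 1), c(A = -1)),
    lb = c(0, -10, 0), ub = c(10, 10, 10)
  ))
  res2 <- fastcore(m2, C = "rv")
  expect_true("rv" %in% res2$R_P)
  expect_length(find_blocked_fva(extract_submodel(m2, res2$R_P)), 0)
})
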
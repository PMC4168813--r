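# iMAT-like family: match maximisation, tri-state classification, INIT/tINIT.

test_that("imat matches the enumeration oracle on hand fixtures", {
  m <- parallel_model()
  res <- imat(m, R_H = "r2", R_L = "r3", epsilon = 1e-4)
  expect_equal(res$objective, 2)
  expect_equal(res$objective, brute_force_imat(m, "r2", "r3"))
  expect_setequal(res$R_P, c("r1", "r2", "r4"))
  # no labels: zero matches, zero flux admissible
  res0 <- imat(m, character(0), character(0))
  expect_equal(res0$objective, 0)
  # a structurally blocked reaction in R_H can never be matched
  md <- chain_with_deadend()
  resb <- imat(md, R_H = c("r2", "r4"), R_L = character(0))
  expect_equal(resb$objective, 1)
  expect_false("r4" %in% resb$R_P)
})

test_that("imat objective is bounded by the label count and capped by concordance", {
  for (seed in 121:128) {
    toy <- random_toy(seed, max_linear = 4)
    m <- toy$model
    ev <- make_evidence(m, toy$truth, noise_sd = 2, seed = seed)
    d <- map_expression(m, ev$gene_values)
    sets <- tryCatch(discretize(d, 0.25, 0.75), error = function(e) NULL)
    if (is.null(sets) || length(c(sets$R_H, sets$R_L)) > 8) next
    res <- imat(m, sets$R_H, sets$R_L)
    expect_lte(res$objective, length(sets$R_H) + length(sets$R_L))
    expect_equal(res$objective, brute_force_imat(m, sets$R_H, sets$R_L))
  }
})

test_that("imat_classify reproduces the forced-activity comparison", {
  m <- parallel_model()
  cls <- imat_classify(m, R_H = "r2", R_L = "r3")
  lab <- stats::setNames(cls$label, cls$reaction_id)
  expect_equal(unname(lab["r2"]), "active")
  # r3 can stay silent in every optimum: never active
  expect_true(lab["r3"] %in% c("inactive", "undetermined"))
  # forcing r1 (the sole uptake) inactive silences r2 and loses its match
  expect_equal(unname(lab["r1"]), "active")
  # a reaction in R_H that is the only path to its match is active
  mc <- chain_model()
  cls2 <- imat_classify(mc, R_H = "r2", R_L = character(0))
  expect_equal(cls2$label[cls2$reaction_id == "r2"], "active")
  # structurally blocked reactions are never classified active
  md <- chain_with_deadend()
  cls3 <- imat_classify(md, R_H = "r4", R_L = character(0))
  expect_false(cls3$label[cls3$reaction_id == "r4"] == "active")
})

test_that("init selects positively weighted flux-carrying subnetworks", {
  m <- parallel_model()
  w <- c(r1 = 0.1, r2 = 1, r3 = -1, r4 = 0.1)
  res <- init(m, w)
  expect_setequal(res$R_P, c("r1", "r2", "r4"))
  expect_equal(res$objective, 1.2, tolerance = 1e-6)
  # enumeration oracle: best feasible subset by total weight
  best <- -Inf
  ids <- reaction_ids(m)
  for (mask in 0:(2^4 - 1)) {
    keep <- ids[bitwAnd(mask, bitwShiftL(1L, 0:3)) > 0]
    drop <- setdiff(ids, keep)
    lo <- m$reactions$lb; hi <- m$reactions$ub
    lo[match(keep, ids)] <- pmax(lo[match(keep, ids)], 1e-4)
    lo[match(drop, ids)] <- 0; hi[match(drop, ids)] <- 0
    s <- solve_lp(numeric(4), A_eq = m$S, b_eq = c(0, 0), lb = lo, ub = hi)
    if (s$status == "optimal") best <- max(best, sum(w[keep]))
  }
  expect_equal(res$objective, best, tolerance = 1e-6)
  # all-negative weights: empty model wins, with a warning
  expect_warning(res_neg <- init(m, c(r1 = -1, r2 = -1, r3 = -1, r4 = -1)),
                 "empty")
  expect_length(res_neg$R_P, 0)
})

test_that("init net production honours the key-metabolite lower bound", {
  m <- parallel_model()
  w <- c(r1 = 0.1, r2 = 1, r3 = -1, r4 = 0.1)
  res <- init(m, w, key_metabolites = "B", delta = 0.1)
  expect_gte(unname(res$net_production["B"]), 0.1 - 1e-9)
  # mass balance with production: S v = b
  b <- as.numeric(m$S %*% res$flux)
  expect_equal(b[match("B", m$metabolites)], unname(res$net_production["B"]),
               tolerance = 1e-6)
  # unreachable production bound errors by metabolite name
  m2 <- m; m2$reactions$ub[] <- c(10, 10, 10, 10)
  expect_error(init(m2, w, key_metabolites = "Zz", delta = 0.1), "unknown")
})

test_that("tinit enforces tasks and reduces to init without them", {
  m <- chain_model()
  w <- c(r1 = 0.2, r2 = 0.2, r3 = 0.2)
  tasks <- tibble::tibble(task_id = "produce_B", reaction_id = "r2",
                          coefficient = 1, bound = 1)
  res <- tinit(m, w, tasks = tasks)
  expect_true(all(c("r1", "r2") %in% res$R_P))
  expect_gte(unname(res$tasks_ok["produce_B"]), 1 - 1e-6)
  # empty task set in steady-state mode equals init with b = 0
  mp <- parallel_model()
  wp <- c(r1 = 0.1, r2 = 1, r3 = -1, r4 = 0.1)
  r1 <- tinit(mp, wp, tasks = NULL, steady_state = TRUE)
  r2 <- init(mp, wp)
  expect_identical(sort(r1$R_P), sort(r2$R_P))
  expect_equal(r1$objective, r2$objective)
  # unknown task reactions fail the pre-check
  expect_error(tinit(m, w, tasks = tibble::tibble(
    task_id = "t", reaction_id = "nope", coefficient = 1
  )), "absent")
  # task infeasible in the generic model is reported before solving
  expect_error(tinit(m, w, tasks = tibble::tibble(
    task_id = "too_much", reaction_id = "r2", coefficient = 1, bound = 99
  )), "infeasible.*too_much")
})
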
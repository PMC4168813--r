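# GPR parsing, evidence mapping, penalties, discretisation.

test_that("parse_gpr reproduces boolean structure and rejects malformed rules", {
  t1 <- parse_gpr("g1 and (g2 or g3)")
  expect_equal(t1$op, "and")
  expect_equal(t1$args[[1]]$gene, "g1")
  expect_equal(t1$args[[2]]$op, "or")
  expect_equal(gpr_genes(t1), c("g1", "g2", "g3"))
  leaf <- parse_gpr("g1")
  expect_equal(leaf$type, "gene")
  expect_null(parse_gpr(""))
  expect_null(parse_gpr(NA))
  expect_error(parse_gpr("g1 and or g2"), "dangling operator")
  expect_error(parse_gpr("(g1 and g2"), "expected '\\)'")
  expect_error(parse_gpr("g1 g2"), "trailing input")
  # round trip through the canonical form
  for (rule in c("g1", "g1 and g2 and g3", "g1 or (g2 and g3)",
                 "(g1 or g2) and (g3 or g4)")) {
    expect_equal(deparse_gpr(parse_gpr(deparse_gpr(parse_gpr(rule)))),
                 deparse_gpr(parse_gpr(rule)))
  }
})

test_that("map_expression follows AND=min / OR=max and marks missing data", {
  mk <- function(gpr) metabolic_model(tibble::tibble(
    id = "rx", stoich = list(c(A = 1)), lb = 0, ub = 10, gpr = gpr
  ))
  vals <- c(gA = 2, gB = 5, gC = 4)
  expect_equal(map_expression(mk("gA and gB"), vals)$value, 2)
  expect_equal(map_expression(mk("gA or gB"), vals)$value, 5)
  expect_equal(map_expression(mk("(gA and gB) or gC"), vals)$value, 4)
  expect_true(is.na(map_expression(mk(NA), vals)$value))
  # missing gene: ignored by default, strict errors
  expect_equal(map_expression(mk("gA and gZ"), vals)$value, 2)
  expect_error(map_expression(mk("gA and gZ"), vals, missing_gene = "strict"),
               "absent")
})

test_that("gimme_penalty is the non-negative sub-threshold gap", {
  p <- gimme_penalty(c(r1 = 2, r2 = 6, r3 = 4), threshold = 5)
  expect_equal(p$penalty, c(3, 0, 1))
  expect_equal(gimme_penalty(c(r1 = 7, r2 = 9), 5)$penalty, c(0, 0))
  d <- c(r1 = 2, r2 = 6, r3 = 4)
  expect_equal(gimme_penalty(d, min(d))$penalty, c(0, 0, 0))
  # antitone in d, vanishing at and above c
  set.seed(5)
  d2 <- sort(stats::runif(20, 0, 10))
  pen <- gimme_penalty(stats::setNames(d2, paste0("r", 1:20)), 5)$penalty
  expect_true(all(diff(pen) <= 1e-12))
  expect_true(all(pen[d2 >= 5] == 0))
})

test_that("gim3e_penalty maps gene distances with the dual convention", {
  mk <- function(gpr) metabolic_model(tibble::tibble(
    id = "rx", stoich = list(c(A = 1)), lb = 0, ub = 10, gpr = gpr
  ))
  vals <- c(gA = 4, gB = 7)
  expect_equal(gim3e_penalty(mk("gA or gB"), vals, I_max = 10)$penalty, 3)
  expect_equal(gim3e_penalty(mk("gA and gB"), vals, I_max = 10)$penalty, 6)
  # gene at I_max has zero penalty
  expect_equal(gim3e_penalty(mk("gB"), c(gA = 4, gB = 10))$penalty, 0)
  # duality with map_expression for single-gene rules
  for (g in c(1, 4.5, 9)) {
    m1 <- mk("gA")
    v <- c(gA = g, gB = 9)
    expect_equal(gim3e_penalty(m1, v, I_max = 9)$penalty,
                 9 - map_expression(m1, v)$value)
  }
  # penalties bounded by I_max - min(I)
  m2 <- mk("(gA and gB) or gC")
  v2 <- c(gA = 2, gB = 8, gC = 5)
  pen <- gim3e_penalty(m2, v2)$penalty
  expect_gte(pen, 0)
  expect_lte(pen, max(v2) - min(v2))
  expect_error(gim3e_penalty(m2, v2, I_max = 1), "smaller")
})

test_that("discretize yields disjoint sets, stable under monotone transforms", {
  d <- c(r1 = 1, r2 = 2, r3 = 3, r4 = 4)
  sets <- discretize(d, 0.25, 0.75)
  expect_equal(sets$R_L, "r1")
  expect_equal(sets$R_H, "r4")
  # high_q = 1 keeps only the argmax set
  expect_equal(discretize(d, 0.25, 1)$R_H, "r4")
  # absolute threshold mode, ties go high
  ab <- discretize(c(r1 = 2, r2 = 6, r3 = 4), c_low = 5, c_high = 5)
  expect_equal(ab$R_H, "r2")
  expect_setequal(ab$R_L, c("r1", "r3"))
  tie <- discretize(c(r1 = 5, r2 = 5), c_low = 5, c_high = 5)
  expect_setequal(tie$R_H, c("r1", "r2"))
  expect_equal(tie$R_L, character(0))
  # constant data refuses quantile mode
  expect_error(discretize(c(r1 = 3, r2 = 3, r3 = 3), 0.25, 0.75), "absolute")
  # monotone-transform stability in quantile mode
  set.seed(9)
  dd <- stats::setNames(stats::runif(15, 0, 10), paste0("r", 1:15))
  s1 <- discretize(dd, 0.2, 0.8)
  s2 <- discretize(exp(dd / 3), 0.2, 0.8)
  expect_setequal(s1$R_H, s2$R_H)
  expect_setequal(s1$R_L, s2$R_L)
  expect_length(intersect(s1$R_H, s1$R_L), 0)
})
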
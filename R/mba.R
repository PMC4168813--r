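## MBA-like family: consistency-driven pruning.
##
## All three methods share one objective: a final model with no blocked
## reaction that contains (MBA/FastCORE) or favours (mCADRE) a core of
## reactions with positive evidence. MBA prunes non-core reactions in random
## order over many repetitions; mCADRE prunes in evidence-rank order with a
## negative-evidence relaxation of core protection; FastCORE grows the model
## around the core with sparse flux modes (two LPs per iteration).

#' Fast consistency check by iterated flux maximisation
#'
#' The MBA consistency checker: repeatedly maximise the total flux over the
#' still-unresolved reactions (on the split-irreversible form, so reverse
#' senses count), mark every reaction reaching `|v| >= epsilon` as
#' unblocked, additionally minimise over unresolved reversibles, and when an
#' iteration resolves nothing, fall back to FVA of one randomly chosen
#' unresolved reaction. Returns the same blocked set as [find_blocked_fva()]
#' (their equivalence is a tested property).
#'
#' @param model a `metabolic_model`.
#' @param epsilon activation flux (default 1e-4).
#' @param seed seed for the random FVA fallback choice (default 1).
#' @return character vector of blocked reaction ids.
#' @export
check_model_consistency_mba <- function(model, epsilon = 1e-4, seed = 1) {
  if (n_reactions(model) == 0) return(character(0))
  rng <- local_rng(seed)
  split <- split_reversible(model)
  sm <- split$model
  mp <- split$mapping
  p <- model_lp_parts(sm)
  ids <- reaction_ids(model)
  sids <- reaction_ids(sm)
  unresolved <- ids
  blocked <- character(0)

  resolve_from <- function(vsplit, unresolved) {
    v <- merge_split_flux(vsplit, mp)
    ## a reaction is active if either sense carries epsilon (net flux can
    ## cancel on the split form, so look at the split columns directly)
    act_for <- vsplit[mp$forward] >= epsilon
    act_rev <- ifelse(is.na(mp$reverse), FALSE, vsplit[mp$reverse] >= epsilon)
    active <- mp$id[act_for | act_rev | abs(v) >= epsilon]
    intersect(unresolved, active)
  }

  while (length(unresolved) > 0) {
    ## LP1: maximise total flux over unresolved columns (both senses)
    cols <- c(mp$forward[mp$id %in% unresolved],
              stats::na.omit(mp$reverse[mp$id %in% unresolved]))
    obj <- stats::setNames(numeric(length(sids)), sids)
    obj[cols] <- 1
    s1 <- solve_lp(as.numeric(obj), p$A_eq, p$b_eq, p$A_le, p$b_le, p$lb, p$ub)
    progressed <- character(0)
    if (s1$status == "optimal") {
      progressed <- resolve_from(stats::setNames(s1$x, sids), unresolved)
    }
    unresolved <- setdiff(unresolved, progressed)
    ## second program: minimise over unresolved reversibles'
    ## net flux, catching reactions that only operate in reverse
    rev_un <- intersect(unresolved, reversible_set(model))
    if (length(rev_un) > 0) {
      obj2 <- stats::setNames(numeric(length(sids)), sids)
      obj2[mp$forward[mp$id %in% rev_un]] <- 1
      obj2[stats::na.omit(mp$reverse[mp$id %in% rev_un])] <- -1
      s2 <- solve_lp(as.numeric(obj2), p$A_eq, p$b_eq, p$A_le, p$b_le,
                     p$lb, p$ub, maximize = FALSE)
      if (s2$status == "optimal") {
        more <- resolve_from(stats::setNames(s2$x, sids), unresolved)
        progressed <- c(progressed, more)
        unresolved <- setdiff(unresolved, more)
      }
    }
    if (length(progressed) == 0 && length(unresolved) > 0) {
      pick <- rng$sample_chr(unresolved, 1)
      fv <- fva(model, pick)
      if (max(abs(fv$min_flux), abs(fv$max_flux)) < epsilon) {
        blocked <- c(blocked, pick)
      }
      unresolved <- setdiff(unresolved, pick)
    }
  }
  intersect(ids, blocked)
}

#' FastCORE-sweep consistency checker
#'
#' Classifies each reaction by attempting to activate it with one sparse
#' mode ([find_sparse_mode()]), trying the reverse sense for reversibles;
#' reactions activated as a side effect of another reaction's mode are
#' resolved without further LPs.
#'
#' @inheritParams check_model_consistency_mba
#' @return character vector of blocked reaction ids.
#' @export
check_model_consistency_fastcore <- function(model, epsilon = 1e-4) {
  ids <- reaction_ids(model)
  unresolved <- ids
  blocked <- character(0)
  rev_ids <- reversible_set(model)
  for (i in ids) {
    if (!(i %in% unresolved)) next
    supp <- find_sparse_mode(model, J = i, P = setdiff(ids, i), epsilon = epsilon)
    if (!(i %in% supp) && i %in% rev_ids) {
      m2 <- flip_reaction(model, i)
      supp2 <- find_sparse_mode(m2, J = i, P = setdiff(ids, i), epsilon = epsilon)
      supp <- union(supp, supp2)
    }
    if (i %in% supp) {
      unresolved <- setdiff(unresolved, supp)
    } else {
      blocked <- c(blocked, i)
      unresolved <- setdiff(unresolved, i)
    }
  }
  intersect(ids, blocked)
}

#' One MBA pruning pass over a fixed elimination order
#'
#' Scans the non-core reactions in the given order; each is tentatively
#' removed and the blocked reactions of the candidate submodel are split
#' into high-core (`e_H`), moderate-core (`e_M`) and non-core (`e_Nc`)
#' casualties. The removal — of the reaction together with `e_M` and `e_Nc`
#' — commits only when no high-core reaction blocks and the moderate-core
#' damage is acceptable (`e_M` empty, or `|e_M| < k |e_Nc|`); otherwise the
#' reaction is restored. The result is consistent and contains `C_H`.
#'
#' @param model a `metabolic_model`.
#' @param C_H,C_M high- and moderate-likelihood core reaction ids
#'   (disjoint).
#' @param permutation elimination order: a permutation of the non-core set
#'   (default: model order).
#' @param k moderate-core damage ratio in the commit test (default 0.5).
#' @param epsilon activation flux for the consistency checker.
#' @return character vector `R_P`, the retained reactions.
#' @export
mba_single <- function(model, C_H, C_M = character(0), permutation = NULL,
                       k = 0.5, epsilon = 1e-4) {
  C_H <- unique(as.character(C_H)); C_M <- unique(as.character(C_M))
  stopifnot(length(intersect(C_H, C_M)) == 0)
  match_rxn(model, c(C_H, C_M))
  ids <- reaction_ids(model)
  ## pre-reduce to the consistent part of the generic model
  blocked0 <- find_blocked_fva(model)
  if (length(intersect(blocked0, C_H)) > 0) {
    stop("high-likelihood core is blocked in generic model: ",
         paste(intersect(blocked0, C_H), collapse = ", "))
  }
  R_P <- setdiff(ids, blocked0)
  C_M <- setdiff(C_M, blocked0)
  N_C <- setdiff(R_P, union(C_H, C_M))
  permutation <- permutation %||% N_C
  stopifnot(setequal(permutation, N_C))

  for (r in permutation) {
    if (!(r %in% R_P)) next  # already removed as collateral
    cand <- setdiff(R_P, r)
    blocked <- find_blocked_fva(extract_submodel(model, cand))
    e_H <- intersect(blocked, C_H)
    e_M <- intersect(blocked, C_M)
    e_Nc <- setdiff(blocked, union(C_H, C_M))
    if (length(e_H) == 0 &&
        (length(e_M) == 0 || length(e_M) < k * length(e_Nc))) {
      R_P <- setdiff(cand, union(e_M, e_Nc))
    }
  }
  R_P
}

#' MBA: model-building algorithm with a randomised pruning population
#'
#' Runs [mba_single()] over `n_iter` seeded random elimination orders,
#' ranks every reaction outside the high-likelihood core by its occurrence
#' frequency in the resulting population, and rebuilds the final model by
#' adding ranked reactions to `C_H` (frequency descending, reaction id as
#' deterministic tie-break) until the model is flux-consistent.
#'
#' @inheritParams mba_single
#' @param n_iter population size (the published protocol uses 1000; small
#'   toy networks need far fewer).
#' @param seed integer seed; results are reproducible given it.
#' @return an `mba_result` (an `extraction_result`) with `R_P`,
#'   `ranking` (tibble `reaction_id`, `occurrence`) and `n_iter`.
#' @export
mba <- function(model, C_H, C_M = character(0), k = 0.5, n_iter = 1000,
                seed = 1, epsilon = 1e-4) {
  stopifnot(n_iter >= 1)
  rng <- local_rng(seed)
  ids <- reaction_ids(model)
  blocked0 <- find_blocked_fva(model)
  if (length(intersect(blocked0, C_H)) > 0) {
    stop("high-likelihood core is blocked in generic model: ",
         paste(intersect(blocked0, C_H), collapse = ", "))
  }
  N_C <- setdiff(setdiff(ids, blocked0), union(C_H, C_M))
  counts <- stats::setNames(numeric(length(ids)), ids)
  for (it in seq_len(n_iter)) {
    perm <- rng$perm(N_C)
    rp <- mba_single(model, C_H, C_M, permutation = perm, k = k,
                     epsilon = epsilon)
    counts[rp] <- counts[rp] + 1
  }
  occ <- counts / n_iter
  non_ch <- setdiff(ids, C_H)
  ranking <- tibble::tibble(reaction_id = non_ch,
                            occurrence = as.numeric(occ[non_ch]))
  ranking <- ranking[order(-ranking$occurrence, ranking$reaction_id), ]

  ## rebuild: add ranked reactions to C_H until consistent
  R_P <- C_H
  queue <- ranking$reaction_id[ranking$occurrence > 0]
  repeat {
    blocked <- find_blocked_fva(extract_submodel(model, R_P))
    if (length(blocked) == 0) break
    if (length(queue) == 0) {
      if (length(intersect(blocked, C_H)) > 0) {
        stop("could not reach a consistent model containing C_H")
      }
      R_P <- setdiff(R_P, blocked)  # drop blocked non-core remnants
      break
    }
    R_P <- c(R_P, queue[1])
    queue <- queue[-1]
  }
  new_extraction_result(
    "mba", model, R_P, objective = length(R_P),
    extra = list(ranking = ranking, n_iter = n_iter, seed = seed,
                 C_H = C_H, C_M = C_M, k = k,
                 occurrence = occ)
  )
}

#' mCADRE evidence scores
#'
#' Expression score: the frequency of the expressed state across binarized
#' transcript profiles, GPR-mapped per sample (AND = min, OR = max over the
#' 0/1 gene calls). Connectivity score: the mean expression score of the
#' reactions sharing at least one metabolite (adjacency through S); 0 for
#' an isolated reaction. Confidence score: passed through (0 = no
#' evidence). Reactions without a GPR get expression score 0.
#'
#' @param model a `metabolic_model`.
#' @param binarized_profiles samples x genes matrix of 0/1 expression calls
#'   (column names are gene ids), e.g. `profiles` from [make_evidence()].
#' @param confidence optional per-reaction confidence levels (named vector
#'   or tibble `reaction_id`, `confidence`); default 0.
#' @return a tibble with columns `reaction_id`, `expression_score`,
#'   `connectivity_score`, `confidence_score`.
#' @export
mcadre_scores <- function(model, binarized_profiles, confidence = NULL) {
  prof <- as.matrix(binarized_profiles)
  if (nrow(prof) < 1) stop("at least one profile is required")
  if (!all(prof %in% c(0, 1))) {
    stop("profiles must be binarized to 0/1 before scoring")
  }
  ids <- reaction_ids(model)
  expr <- vapply(seq_along(ids), function(j) {
    rule <- parse_gpr(model$reactions$gpr[j])
    if (is.null(rule)) return(0)
    states <- vapply(seq_len(nrow(prof)), function(s) {
      v <- gpr_eval(rule, prof[s, ], min, max, "ignore")
      if (is.na(v)) 0 else v
    }, numeric(1))
    mean(states)
  }, numeric(1))
  adj <- crossprod(model$S != 0)  # reactions sharing metabolites
  conn <- vapply(seq_along(ids), function(j) {
    nb <- which(adj[, j] > 0)
    nb <- setdiff(nb, j)
    if (length(nb) == 0) 0 else mean(expr[nb])
  }, numeric(1))
  conf <- as_rxn_vector(model, confidence %||% stats::setNames(numeric(0), character(0)),
                        default = 0)
  tibble::tibble(reaction_id = ids, expression_score = expr,
                 connectivity_score = conn,
                 confidence_score = as.numeric(conf[ids]))
}

## can every key metabolite sustain production >= epsilon in this submodel?
key_mets_producible <- function(model, keep, key_metabolites, epsilon) {
  if (length(key_metabolites) == 0) return(TRUE)
  sub <- extract_submodel(model, keep)
  for (m in intersect(key_metabolites, sub$metabolites)) {
    added <- add_metabolite_sinks(sub, m)
    opt <- fba(added$model, added$sinks[1], maximize = TRUE)
    if (opt$objective_value < epsilon) return(FALSE)
  }
  ## a key metabolite no longer present in the submodel cannot be produced
  if (length(setdiff(key_metabolites, sub$metabolites)) > 0) return(FALSE)
  TRUE
}

#' mCADRE: score-ranked pruning with core relaxation
#'
#' The core is `{i : expression_score >= core_threshold}`; reactions with
#' expression evidence present but a score of exactly zero carry negative
#' evidence. Non-core reactions are removed in ascending
#' (expression, connectivity, confidence, id) order. A removal commits only
#' if every key metabolite remains producible; a removal that blocks core
#' reactions commits only for negative-evidence reactions with acceptable
#' damage (`e_C` empty or `|e_C| < k |e_Nc|`), in which case the blocked
#' core reactions are removed along with it.
#'
#' @param model a `metabolic_model`.
#' @param scores tibble from [mcadre_scores()].
#' @param core_threshold expression-score threshold defining the core
#'   (default 0.5).
#' @param key_metabolites metabolite ids whose production must be preserved.
#' @param k core-damage ratio for negative-evidence removals (default 0.33).
#' @param epsilon activation flux (default 1e-4).
#' @return an `mcadre_result` (an `extraction_result`) with `R_P`, `core`,
#'   `negative`, and the score table.
#' @export
mcadre <- function(model, scores, core_threshold = 0.5,
                   key_metabolites = character(0), k = 0.33, epsilon = 1e-4) {
  ids <- reaction_ids(model)
  stopifnot(all(scores$reaction_id %in% ids))
  es <- as_rxn_vector(model, scores[, c("reaction_id", "expression_score")], default = 0)
  cs <- as_rxn_vector(model, scores[, c("reaction_id", "connectivity_score")], default = 0)
  fs <- as_rxn_vector(model, scores[, c("reaction_id", "confidence_score")], default = 0)
  has_gpr <- !is.na(model$reactions$gpr) & nzchar(model$reactions$gpr)
  names(has_gpr) <- ids
  core <- ids[es >= core_threshold]
  negative <- ids[es == 0 & has_gpr]

  if (!key_mets_producible(model, ids, key_metabolites, epsilon)) {
    stop("key metabolite unproducible in the generic model")
  }

  ## pre-reduce to the consistent part (blocked core dropped: mCADRE relaxes
  ## whole-core inclusion)
  blocked0 <- find_blocked_fva(model)
  R_P <- setdiff(ids, blocked0)
  non_core <- setdiff(R_P, core)
  ord <- non_core[order(es[non_core], cs[non_core], fs[non_core], non_core)]

  for (r in ord) {
    if (!(r %in% R_P)) next
    cand <- setdiff(R_P, r)
    if (!key_mets_producible(model, cand, key_metabolites, epsilon)) next
    blocked <- find_blocked_fva(extract_submodel(model, cand))
    e_C <- intersect(blocked, core)
    e_Nc <- setdiff(blocked, core)
    if (!(r %in% negative)) {
      if (length(e_C) == 0) {
        R_P <- setdiff(cand, e_Nc)
      }
    } else {
      if (length(e_C) == 0 || length(e_C) < k * length(e_Nc)) {
        R_P <- setdiff(cand, union(e_C, e_Nc))
      }
    }
  }
  new_extraction_result(
    "mcadre", model, R_P, objective = length(R_P),
    extra = list(core = core, negative = negative, k = k,
                 core_threshold = core_threshold,
                 key_metabolites = key_metabolites,
                 expression_score = es, connectivity_score = cs,
                 confidence_score = fs)
  )
}

#' Find a sparse flux mode activating a reaction set
#'
#' The FastCORE primitive. LP1 maximises the number of reactions in `J`
#' pushed to flux `>= epsilon` (via auxiliary variables `z_i \in [0,
#' epsilon]`, `v_i >= z_i`); `K` collects those activated. LP2 then
#' minimises the L1-norm of the flux through the penalised set `P` subject
#' to all of `K` staying at `v >= epsilon`. Returns the support of the LP2
#' solution above the support tolerance.
#'
#' @param model a `metabolic_model`.
#' @param J reaction ids to activate (forward sense); disjoint from `P`.
#' @param P penalised reaction ids.
#' @param epsilon activation flux (default 1e-4).
#' @param support_tol absolute flux threshold for membership in the support
#'   (default `1e-2 * epsilon`).
#' @return character vector: the support set (empty when nothing in `J` can
#'   be activated).
#' @export
find_sparse_mode <- function(model, J, P, epsilon = 1e-4,
                             support_tol = 1e-2 * epsilon) {
  J <- unique(as.character(J)); P <- unique(as.character(P))
  stopifnot(length(intersect(J, P)) == 0)
  if (length(J) == 0) return(character(0))
  match_rxn(model, c(J, P))
  p <- model_lp_parts(model)
  n <- n_reactions(model)
  ids <- reaction_ids(model)
  jidx <- match(J, ids)

  ## LP1: variables [v, z_J]; max sum z, z in [0, eps], v_i >= z_i
  nz <- length(jidx)
  nv <- n + nz
  A_eq <- cbind(p$A_eq, matrix(0, nrow(p$A_eq), nz))
  A_le <- NULL; b_le <- numeric(0)
  for (t in seq_len(nz)) {
    row <- numeric(nv); row[n + t] <- 1; row[jidx[t]] <- -1  # z - v <= 0
    A_le <- rbind(A_le, row); b_le <- c(b_le, 0)
  }
  obj <- c(numeric(n), rep(1, nz))
  s1 <- solve_lp(obj, A_eq, p$b_eq, A_le, b_le,
                 lb = c(p$lb, rep(0, nz)), ub = c(p$ub, rep(epsilon, nz)))
  if (s1$status != "optimal") stop("sparse-mode LP1 ", s1$status)
  v1 <- s1$x[seq_len(n)]
  K <- ids[jidx][v1[jidx] >= epsilon - 1e-9]
  if (length(K) == 0) return(character(0))

  ## LP2: variables [v, z_P]; min sum z_P with -z <= v <= z on P, v_K >= eps
  pidx <- match(P, ids)
  np <- length(pidx)
  nv2 <- n + np
  A_eq2 <- cbind(p$A_eq, matrix(0, nrow(p$A_eq), np))
  A_le2 <- NULL; b_le2 <- numeric(0)
  for (t in seq_len(np)) {
    r1 <- numeric(nv2); r1[pidx[t]] <- 1; r1[n + t] <- -1   # v - z <= 0
    r2 <- numeric(nv2); r2[pidx[t]] <- -1; r2[n + t] <- -1  # -v - z <= 0
    A_le2 <- rbind(A_le2, r1, r2); b_le2 <- c(b_le2, 0, 0)
  }
  lb2 <- c(p$lb, rep(0, np)); ub2 <- c(p$ub, rep(1000, np))
  lb2[match(K, ids)] <- pmax(lb2[match(K, ids)], epsilon)
  obj2 <- c(numeric(n), rep(1, np))
  s2 <- solve_lp(obj2, A_eq2, p$b_eq, A_le2, b_le2, lb2, ub2, maximize = FALSE)
  if (s2$status != "optimal") stop("sparse-mode LP2 ", s2$status)
  v2 <- stats::setNames(s2$x[seq_len(n)], ids)
  names(v2)[abs(v2) > support_tol]
}

#' FastCORE: sparse-mode expansion around a consistent core
#'
#' Grows the extracted model by alternating sparse modes: activate
#' still-uncovered core reactions (irreversible core first), penalise
#' non-core flux, and flip the sense of reversible core reactions that
#' resist activation. Terminates with a flux-consistent model containing
#' the whole core. The core must be consistent in the generic model
#' (checked; error listing blocked core reactions otherwise), and the model
#' is first reduced to its consistent part.
#'
#' @param model a `metabolic_model`.
#' @param C core reaction ids.
#' @param epsilon activation flux (default 1e-4).
#' @return a `fastcore_result` (an `extraction_result`) with `R_P` and the
#'   core.
#' @export
#' @examples
#' res <- fastcore(parallel_model(), C = "r4")
#' sort(res$R_P)  # r4 plus exactly one A -> B path and the uptake
fastcore <- function(model, C, epsilon = 1e-4) {
  C <- unique(as.character(C))
  match_rxn(model, C)
  blocked0 <- find_blocked_fva(model)
  bad <- intersect(C, blocked0)
  if (length(bad) > 0) {
    stop("core contains blocked reaction(s): ", paste(bad, collapse = ", "))
  }
  ids0 <- setdiff(reaction_ids(model), blocked0)
  work <- extract_submodel(model, ids0)
  ## normalise reverse-only reactions (ub <= 0) to run forward, so the
  ## irreversible part of the model is uniformly non-negative
  rev_only <- work$reactions$id[work$reactions$ub <= 0]
  if (length(rev_only) > 0) work <- flip_reaction(work, rev_only)
  rev_ids <- reversible_set(work)

  N <- setdiff(ids0, C)
  irr_core <- setdiff(C, rev_ids)
  A <- character(0)
  if (length(irr_core) > 0) {
    A <- find_sparse_mode(work, irr_core, setdiff(N, A), epsilon)
  }
  J <- setdiff(C, A)
  flipped <- FALSE
  singleton <- FALSE
  guard <- 0L
  while (length(J) > 0) {
    guard <- guard + 1L
    if (guard > 10L * length(ids0) + 50L) {
      stop("FastCORE failed to converge (internal)")
    }
    P <- setdiff(N, A)
    Jcur <- if (singleton) J[1] else J
    supp <- find_sparse_mode(work, Jcur, P, epsilon)
    A <- union(A, supp)
    if (length(intersect(Jcur, A)) > 0) {
      J <- setdiff(J, A)
      flipped <- FALSE; singleton <- FALSE
    } else {
      JiRev <- intersect(Jcur, reversible_set(work))
      if (flipped || length(JiRev) == 0) {
        if (singleton) stop("core reaction cannot be activated: ", J[1])
        flipped <- FALSE; singleton <- TRUE
      } else {
        work <- flip_reaction(work, JiRev)
        flipped <- TRUE
      }
    }
  }
  new_extraction_result(
    "fastcore", model, A, objective = length(A),
    extra = list(C = C, epsilon = epsilon)
  )
}
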
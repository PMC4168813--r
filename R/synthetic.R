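## Synthetic toy models, evidence profiles and brute-force oracles.
##
## The generators build small networks with a known ground truth — which
## reactions can carry steady-state flux, which are structurally blocked —
## so every extraction method can be tested end-to-end without any external
## model or data set. The oracles are exact (exhaustive enumeration) and
## deliberately independent of the algorithms they check.

#' Canonical linear chain fixture
#'
#' `r1: -> A`, `r2: A -> B`, `r3: B ->`, all bounds `[0, 10]`, one synthetic
#' gene per reaction.
#' @param bound upper flux bound (default 10).
#' @return a `metabolic_model`.
#' @export
chain_model <- function(bound = 10) {
  metabolic_model(tibble::tibble(
    id = c("r1", "r2", "r3"),
    stoich = list(c(A = 1), c(A = -1, B = 1), c(B = -1)),
    lb = 0, ub = bound,
    gpr = c("g_r1", "g_r2", "g_r3")
  ))
}

#' Canonical parallel-path fixture
#'
#' `r1: -> A`; `r2, r3: A -> B` (parallel alternatives); `r4: B ->`,
#' all bounds `[0, 10]`.
#' @inheritParams chain_model
#' @return a `metabolic_model`.
#' @export
parallel_model <- function(bound = 10) {
  metabolic_model(tibble::tibble(
    id = c("r1", "r2", "r3", "r4"),
    stoich = list(c(A = 1), c(A = -1, B = 1), c(A = -1, B = 1), c(B = -1)),
    lb = 0, ub = bound,
    gpr = c("g_r1", "g_r2", "g_r3", "g_r4")
  ))
}

#' Generate a toy metabolic model with known ground truth
#'
#' Builds an uptake -> linear chain -> export backbone, optionally adds
#' parallel alternative routes across chain edges, dead-end branches (the
#' exact blocked set), and makes a seeded fraction of the backbone
#' reversible. Every reaction carries a synthetic single-gene GPR
#' (`g_<reaction>`), or seeded composite AND/OR rules when
#' `composite_gpr = TRUE`.
#'
#' @param n_linear chain length (internal chain reactions). `0` degenerates
#'   to a minimal one-reaction exchange model.
#' @param n_parallel number of extra parallel-path reactions.
#' @param n_deadends number of dead-end branch reactions.
#' @param reversible_fraction fraction of chain/parallel reactions made
#'   reversible.
#' @param seed integer seed; the construction is deterministic given it.
#' @param bound flux bound magnitude (default 10).
#' @param composite_gpr give a seeded subset of reactions two-gene
#'   complex/isoenzyme rules instead of single genes.
#' @return list with `model` (a `metabolic_model`) and `truth`, a list with
#'   `active_set`, `blocked_set`, `core_suggestion` (internal unblocked
#'   reactions).
#' @export
#' @examples
#' toy <- make_toy_model(n_linear = 3, n_deadends = 1, seed = 1)
#' toy$truth$blocked_set
make_toy_model <- function(n_linear = 3, n_parallel = 0, n_deadends = 0,
                           reversible_fraction = 0, seed = 1, bound = 10,
                           composite_gpr = FALSE) {
  stopifnot(n_linear >= 0, n_parallel >= 0, n_deadends >= 0,
            reversible_fraction >= 0, reversible_fraction <= 1)
  if (n_linear == 0) {
    model <- metabolic_model(tibble::tibble(
      id = "EX_M1", stoich = list(c(M1 = -1)), lb = -bound, ub = bound,
      gpr = "g_EX_M1"
    ))
    return(list(model = model,
                truth = list(active_set = character(0),
                             blocked_set = "EX_M1",
                             core_suggestion = character(0))))
  }
  rng <- local_rng(seed)
  mets <- paste0("M", seq_len(n_linear + 1))
  rows <- list(
    tibble::tibble(id = "EX_up", stoich = list(stats::setNames(1, mets[1])),
                   lb = 0, ub = bound, gpr = NA_character_)
  )
  chain_ids <- paste0("r", seq_len(n_linear))
  for (i in seq_len(n_linear)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = chain_ids[i],
      stoich = list(stats::setNames(c(-1, 1), mets[c(i, i + 1)])),
      lb = 0, ub = bound, gpr = NA_character_
    )
  }
  par_ids <- character(0)
  if (n_parallel > 0) {
    edges <- rng$sample_int(n_linear, n_parallel, replace = TRUE)
    par_ids <- paste0("p", seq_len(n_parallel))
    for (j in seq_len(n_parallel)) {
      i <- edges[j]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = par_ids[j],
        stoich = list(stats::setNames(c(-1, 1), mets[c(i, i + 1)])),
        lb = 0, ub = bound, gpr = NA_character_
      )
    }
  }
  dead_ids <- character(0)
  if (n_deadends > 0) {
    src <- rng$sample_int(n_linear, n_deadends, replace = TRUE)
    dead_ids <- paste0("d", seq_len(n_deadends))
    for (j in seq_len(n_deadends)) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = dead_ids[j],
        stoich = list(stats::setNames(c(-1, 1), c(mets[src[j]], paste0("D", j)))),
        lb = 0, ub = bound, gpr = NA_character_
      )
    }
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    id = "EX_out", stoich = list(stats::setNames(-1, mets[n_linear + 1])),
    lb = 0, ub = bound, gpr = NA_character_
  )
  tbl <- dplyr::bind_rows(rows)

  internal <- c(chain_ids, par_ids)
  n_rev <- round(reversible_fraction * length(internal))
  if (n_rev > 0) {
    rev_ids <- rng$sample_chr(internal, n_rev)
    tbl$lb[tbl$id %in% rev_ids] <- -bound
  }

  ## GPRs: one synthetic gene per reaction, or seeded composite rules
  tbl$gpr <- paste0("g_", tbl$id)
  if (composite_gpr) {
    pick <- rng$sample_chr(tbl$id, max(1, round(nrow(tbl) / 2)))
    for (id in pick) {
      kind <- rng$sample_int(2, 1)
      tbl$gpr[tbl$id == id] <- if (kind == 1) {
        paste0("gA_", id, " and gB_", id)
      } else {
        paste0("(gA_", id, " and gB_", id, ") or gC_", id)
      }
    }
  }

  model <- metabolic_model(tbl)
  active <- setdiff(tbl$id, dead_ids)
  list(model = model,
       truth = list(active_set = active,
                    blocked_set = dead_ids,
                    core_suggestion = internal))
}

## Small self-contained RNG wrapper so generators are deterministic under a
## seed without touching the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    set.seed(seed)
    st <- get(".Random.seed", .GlobalEnv)
    if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old, .GlobalEnv)
    st
  }
  with_state <- function(f) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    assign(".Random.seed", env$state, .GlobalEnv)
    on.exit({
      env$state <- get(".Random.seed", .GlobalEnv)
      if (is.null(old)) rm(".Random.seed", envir = .GlobalEnv)
      else assign(".Random.seed", old, .GlobalEnv)
    })
    f()
  }
  list(
    sample_int = function(n, size, replace = FALSE)
      with_state(function() sample.int(n, size, replace = replace)),
    sample_chr = function(x, size, replace = FALSE)
      with_state(function() if (length(x) == 1 && !replace && size == 1) x
                 else sample(x, size, replace = replace)),
    rnorm = function(n, mean, sd) with_state(function() stats::rnorm(n, mean, sd)),
    runif = function(n, min = 0, max = 1) with_state(function() stats::runif(n, min, max)),
    perm = function(x) with_state(function() if (length(x) <= 1) x else sample(x))
  )
}

#' Generate synthetic gene evidence for a toy model
#'
#' Genes of truly active reactions draw log-scale intensities from
#' `Normal(active_mean, noise_sd)`, genes of blocked reactions from
#' `Normal(inactive_mean, noise_sd)`, truncated at 0. Binary profiles (one
#' row per sample) threshold each sample's intensities at the midpoint of
#' the two means. With `noise_sd = 0` the separation is perfect.
#'
#' @param model a `metabolic_model` (GPRs define the gene universe).
#' @param truth ground-truth list from [make_toy_model()].
#' @param noise_sd non-negative noise standard deviation.
#' @param seed integer seed.
#' @param n_samples number of replicate samples (default 1).
#' @param active_mean,inactive_mean intensity means (defaults 8 and 2).
#' @return list with `gene_values` (tibble `gene`, `value`: first sample),
#'   `profiles` (samples x genes binary matrix), and `threshold` (the
#'   midpoint used for binarization).
#' @export
make_evidence <- function(model, truth, noise_sd = 0, seed = 1, n_samples = 1,
                          active_mean = 8, inactive_mean = 2) {
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  rng <- local_rng(seed)
  genes <- unique(unlist(lapply(model$reactions$gpr, function(g)
    gpr_genes(parse_gpr(g))), use.names = FALSE))
  if (length(genes) == 0) stop("model has no GPR rules")
  gene_active <- vapply(genes, function(g) {
    rxns <- model$reactions$id[vapply(model$reactions$gpr, function(r)
      g %in% gpr_genes(parse_gpr(r)), logical(1))]
    any(rxns %in% truth$active_set)
  }, logical(1))
  mu <- ifelse(gene_active, active_mean, inactive_mean)
  mid <- (active_mean + inactive_mean) / 2
  mat <- matrix(0, n_samples, length(genes), dimnames = list(NULL, genes))
  for (s in seq_len(n_samples)) {
    mat[s, ] <- pmax(rng$rnorm(length(genes), mu, noise_sd), 0)
  }
  list(
    gene_values = tibble::tibble(gene = genes, value = mat[1, ]),
    profiles = (mat > mid) * 1L,
    threshold = mid
  )
}

#' Enumerate all flux-consistent reaction subsets (oracle)
#'
#' Exhaustively enumerates subsets of the model's reactions containing
#' `must_keep` and tests each induced submodel for flux consistency with
#' [find_blocked_fva()]. Exponential in the number of free reactions;
#' refuses models beyond the size cap.
#'
#' @param model a `metabolic_model` (at most 14 reactions).
#' @param must_keep reaction ids every subset must contain.
#' @param minimum_only stop at the smallest cardinality that admits a
#'   consistent subset and return only those (much faster).
#' @return list with `subsets` (list of character vectors; all consistent
#'   subsets, or only the minima) and `minimal` (the minimum-cardinality
#'   consistent subsets; empty list if none exists).
#' @export
brute_force_consistent_subsets <- function(model, must_keep = character(0),
                                           minimum_only = FALSE) {
  ids <- reaction_ids(model)
  if (length(ids) > 14) stop("model too large for exhaustive enumeration (> 14 reactions)")
  must_keep <- unique(as.character(must_keep))
  match_rxn(model, must_keep)
  free <- setdiff(ids, must_keep)
  consistent <- function(keep) {
    if (length(keep) == 0) return(TRUE)
    sub <- extract_submodel(model, keep)
    length(find_blocked_fva(sub)) == 0
  }
  subsets <- list()
  minimal <- list()
  for (k in 0:length(free)) {
    found_k <- list()
    combs <- if (k == 0) list(character(0)) else
      apply(utils::combn(free, k), 2, identity, simplify = FALSE)
    for (cm in combs) {
      keep <- c(must_keep, cm)
      if (consistent(keep)) found_k[[length(found_k) + 1L]] <- keep
    }
    if (length(found_k) > 0 && length(minimal) == 0) minimal <- found_k
    subsets <- c(subsets, found_k)
    if (minimum_only && length(minimal) > 0) return(list(subsets = minimal, minimal = minimal))
  }
  list(subsets = subsets, minimal = minimal)
}

#' Brute-force iMAT optimum (oracle)
#'
#' Enumerates every subset of the labelled reactions as the "matched" set:
#' matched high reactions must carry `|v| >= epsilon` (both senses tried for
#' reversibles), matched low reactions must carry zero flux, unmatched
#' reactions are unconstrained. Each candidate is checked by one (or a few)
#' feasibility LPs; the maximum number of matches is returned.
#'
#' @param model a `metabolic_model`.
#' @param R_H,R_L high/low expression reaction sets (disjoint, at most 10
#'   labelled reactions in total).
#' @param epsilon activation flux (default 1e-4).
#' @return the optimal match count (integer).
#' @export
brute_force_imat <- function(model, R_H, R_L, epsilon = 1e-4) {
  lab <- c(R_H, R_L)
  stopifnot(length(intersect(R_H, R_L)) == 0)
  if (length(lab) > 10) stop("too many labelled reactions for enumeration (> 10)")
  match_rxn(model, lab)
  p <- model_lp_parts(model)
  n <- n_reactions(model)
  ids <- reaction_ids(model)
  rev_ids <- reversible_set(model)

  feasible_with <- function(lo, hi) {
    r <- solve_lp(numeric(n), p$A_eq, p$b_eq, p$A_le, p$b_le, lo, hi)
    r$status == "optimal"
  }
  pattern_feasible <- function(matched) {
    lo <- p$lb; hi <- p$ub
    for (i in intersect(matched, R_L)) {
      j <- match(i, ids); lo[j] <- 0; hi[j] <- 0
    }
    mh <- intersect(matched, R_H)
    senses <- expand_senses(mh, rev_ids)
    for (s in senses) {
      lo2 <- lo; hi2 <- hi
      ok <- TRUE
      for (i in mh) {
        j <- match(i, ids)
        if (s[[i]] > 0) {
          lo2[j] <- max(lo2[j], epsilon)
        } else {
          hi2[j] <- min(hi2[j], -epsilon)
        }
        if (lo2[j] > hi2[j]) { ok <- FALSE; break }
      }
      if (ok && feasible_with(lo2, hi2)) return(TRUE)
    }
    FALSE
  }

  best <- 0L
  for (k in length(lab):0) {
    if (k <= best) break
    combs <- if (k == 0) list(character(0)) else
      apply(utils::combn(lab, k), 2, identity, simplify = FALSE)
    for (cm in combs) {
      if (pattern_feasible(cm)) { best <- k; break }
    }
    if (best == k) break
  }
  as.integer(best)
}

## all sense assignments (+1 forward / -1 reverse) for matched-high
## reactions; irreversibles are forward-only
expand_senses <- function(mh, rev_ids) {
  if (length(mh) == 0) return(list(stats::setNames(list(), character(0))))
  choices <- lapply(mh, function(i) if (i %in% rev_ids) c(1, -1) else 1)
  names(choices) <- mh
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(r) as.list(grid[r, , drop = FALSE]))
}
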
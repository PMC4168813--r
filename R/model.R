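## Metabolic model container.
##
## A `metabolic_model` is a light S3 object (in the spirit of `phylo` or
## `igraph`): an ordered reaction table, an ordered metabolite vector and a
## dense stoichiometric matrix S (metabolites x reactions). Reaction-level
## data (bounds, GPR strings, objective coefficients) live in a tibble so the
## object plays well with dplyr-style manipulation via `reactions()`.

#' Construct a metabolic model
#'
#' @param reactions a data frame with columns `id` (unique reaction ids),
#'   `stoich` (list column of named numeric vectors: metabolite -> coefficient,
#'   negative for substrates), and optionally `lb`, `ub` (flux bounds, default
#'   -1000/1000 following GEM convention) and `gpr` (gene-protein-reaction
#'   rule string, `NA` for none).
#' @param objective optional named numeric vector of objective coefficients
#'   (names are reaction ids), or a single reaction id (coefficient 1).
#'
#' @return An object of class `metabolic_model` with elements `reactions`
#'   (tibble `id`, `lb`, `ub`, `gpr`), `metabolites` (character), `S`
#'   (metabolites x reactions matrix) and `objective` (numeric over reactions).
#' @export
#' @examples
#' m <- metabolic_model(tibble::tibble(
#'   id = c("r1", "r2", "r3"),
#'   stoich = list(c(A = 1), c(A = -1, B = 1), c(B = -1)),
#'   lb = 0, ub = 10
#' ))
#' m
metabolic_model <- function(reactions, objective = NULL) {
  reactions <- tibble::as_tibble(reactions)
  stopifnot(all(c("id", "stoich") %in% names(reactions)))
  if (anyDuplicated(reactions$id)) {
    stop("duplicate reaction ids: ",
         paste(unique(reactions$id[duplicated(reactions$id)]), collapse = ", "))
  }
  if (!"lb" %in% names(reactions)) reactions$lb <- -1000
  if (!"ub" %in% names(reactions)) reactions$ub <- 1000
  if (!"gpr" %in% names(reactions)) reactions$gpr <- NA_character_
  reactions$lb[is.na(reactions$lb)] <- -1000
  reactions$ub[is.na(reactions$ub)] <- 1000
  if (any(reactions$lb > reactions$ub)) {
    stop("reaction bounds violated (lb > ub) for: ",
         paste(reactions$id[reactions$lb > reactions$ub], collapse = ", "))
  }

  mets <- unique(unlist(lapply(reactions$stoich, names), use.names = FALSE))
  if (anyDuplicated(mets)) stop("duplicate metabolite ids")
  S <- matrix(0, length(mets), nrow(reactions),
              dimnames = list(mets, reactions$id))
  for (j in seq_len(nrow(reactions))) {
    st <- reactions$stoich[[j]]
    if (length(st) > 0) S[names(st), j] <- as.numeric(st)
  }

  obj <- stats::setNames(numeric(nrow(reactions)), reactions$id)
  if (!is.null(objective)) {
    if (is.character(objective)) objective <- stats::setNames(rep(1, length(objective)), objective)
    unknown <- setdiff(names(objective), reactions$id)
    if (length(unknown) > 0) stop("objective names unknown ids: ", paste(unknown, collapse = ", "))
    obj[names(objective)] <- as.numeric(objective)
  }

  structure(
    list(
      reactions = reactions[, c("id", "lb", "ub", "gpr")],
      metabolites = mets,
      S = S,
      objective = obj
    ),
    class = "metabolic_model"
  )
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", n_reactions(x), " reactions, ",
      length(x$metabolites), " metabolites, ",
      length(reversible_set(x)), " reversible\n", sep = "")
  invisible(x)
}

#' Number of reactions in a model
#' @param model a `metabolic_model`.
#' @return integer count.
#' @export
n_reactions <- function(model) nrow(model$reactions)

#' Reaction table of a model
#' @param model a `metabolic_model`.
#' @return tibble with columns `id`, `lb`, `ub`, `gpr`.
#' @export
reactions <- function(model) model$reactions

#' Reaction ids of a model
#' @param model a `metabolic_model`.
#' @return character vector in model order.
#' @export
reaction_ids <- function(model) model$reactions$id

#' Reversible reactions of a model
#'
#' A reaction is reversible when its bounds straddle zero (`lb < 0 < ub`).
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
reversible_set <- function(model) {
  model$reactions$id[model$reactions$lb < 0 & model$reactions$ub > 0]
}

#' Exchange and sink reactions of a model
#'
#' Identified structurally: a reaction whose column of S has exactly one
#' non-zero entry moves mass across the system boundary; no annotation is
#' required.
#' @param model a `metabolic_model`.
#' @return character vector of reaction ids.
#' @export
exchange_set <- function(model) {
  nz <- colSums(model$S != 0)
  model$reactions$id[nz <= 1]
}

#' Validate model invariants
#'
#' Checks `lb <= ub`, unique identifiers, and that every non-exchange
#' reaction column of S is non-zero.
#' @param model a `metabolic_model`.
#' @return `TRUE` invisibly; errors otherwise.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  if (anyDuplicated(model$reactions$id)) stop("duplicate reaction ids")
  if (anyDuplicated(model$metabolites)) stop("duplicate metabolite ids")
  if (any(model$reactions$lb > model$reactions$ub)) stop("lb > ub")
  if (!identical(colnames(model$S), model$reactions$id)) stop("S column order mismatch")
  if (!identical(rownames(model$S), model$metabolites)) stop("S row order mismatch")
  invisible(TRUE)
}

match_rxn <- function(model, ids, what = "reaction") {
  idx <- match(ids, model$reactions$id)
  if (anyNA(idx)) {
    stop("unknown ", what, " id(s): ", paste(ids[is.na(idx)], collapse = ", "))
  }
  idx
}

#' Flip the sense of a reaction
#'
#' Negates column i of S and swaps/negates its bounds, so the feasible set
#' maps by `v_i -> -v_i`. Flipping twice restores the original model. Used by
#' FastCORE to probe the reverse sense of reversible reactions.
#'
#' @param model a `metabolic_model`.
#' @param ids reaction id(s) to flip.
#' @return the modified `metabolic_model`.
#' @export
flip_reaction <- function(model, ids) {
  idx <- match_rxn(model, ids)
  model$S[, idx] <- -model$S[, idx, drop = FALSE]
  lb <- model$reactions$lb[idx]; ub <- model$reactions$ub[idx]
  model$reactions$lb[idx] <- -ub
  model$reactions$ub[idx] <- -lb
  model$objective[idx] <- -model$objective[idx]
  model
}

#' Split reversible reactions into forward and reverse parts
#'
#' Each reversible reaction i (lb < 0 < ub) is replaced by two irreversible
#' reactions: `i` (forward, bounds `[0, ub]`, column S_i) and `i__rev`
#' (reverse, bounds `[0, -lb]`, column -S_i). Any flux `v_i` of the original
#' model corresponds to `v_for - v_rev`, and feasible flux sets correspond
#' bijectively (up to the futile overlap `min(v_for, v_rev)` which does not
#' change the net flux).
#'
#' @param model a `metabolic_model`.
#' @return a list with `model` (the irreversible form) and `mapping`, a tibble
#'   with columns `id` (original), `forward`, `reverse` (`NA` when the
#'   reaction was not split).
#' @export
split_reversible <- function(model) {
  rev_ids <- reversible_set(model)
  mapping <- tibble::tibble(
    id = model$reactions$id,
    forward = model$reactions$id,
    reverse = ifelse(model$reactions$id %in% rev_ids,
                     paste0(model$reactions$id, "__rev"), NA_character_)
  )
  if (length(rev_ids) == 0) {
    return(list(model = model, mapping = mapping))
  }
  rx <- model$reactions
  new_rows <- list()
  stoich_of <- function(j) {
    col <- model$S[, j]
    col[col != 0]
  }
  rows <- vector("list", nrow(rx))
  extra <- vector("list", 0)
  for (j in seq_len(nrow(rx))) {
    st <- stoich_of(j)
    if (rx$id[j] %in% rev_ids) {
      rows[[j]] <- tibble::tibble(id = rx$id[j], stoich = list(st),
                                  lb = 0, ub = rx$ub[j], gpr = rx$gpr[j])
      extra[[length(extra) + 1L]] <- tibble::tibble(
        id = paste0(rx$id[j], "__rev"), stoich = list(-st),
        lb = 0, ub = -rx$lb[j], gpr = rx$gpr[j]
      )
    } else {
      rows[[j]] <- tibble::tibble(id = rx$id[j], stoich = list(st),
                                  lb = rx$lb[j], ub = rx$ub[j], gpr = rx$gpr[j])
    }
  }
  tbl <- dplyr::bind_rows(c(rows, extra))
  out <- metabolic_model(tbl)
  ## carry the objective over: forward keeps c_i, reverse gets -c_i
  out$objective[model$reactions$id] <- model$objective
  ridx <- match(paste0(rev_ids, "__rev"), out$reactions$id)
  out$objective[ridx] <- -model$objective[match(rev_ids, model$reactions$id)]
  list(model = out, mapping = mapping)
}

#' Merge a split flux vector back to the original reactions
#'
#' @param flux named numeric vector over the split model's reactions.
#' @param mapping the mapping tibble from [split_reversible()].
#' @return named numeric vector over the original reactions
#'   (`v = v_for - v_rev`).
#' @export
merge_split_flux <- function(flux, mapping) {
  out <- flux[mapping$forward]
  has_rev <- !is.na(mapping$reverse)
  out[has_rev] <- out[has_rev] - flux[mapping$reverse[has_rev]]
  stats::setNames(as.numeric(out), mapping$id)
}

#' Extract a submodel keeping a subset of reactions
#'
#' Metabolites orphaned by the removal are dropped; bounds, GPR strings and
#' objective coefficients of the kept reactions are preserved. `keep` may be
#' empty (empty model, no error).
#'
#' @param model a `metabolic_model`.
#' @param keep character vector of reaction ids to keep (subset of the
#'   model's reactions).
#' @return a `metabolic_model`.
#' @export
extract_submodel <- function(model, keep) {
  keep <- unique(as.character(keep))
  idx <- match_rxn(model, keep)
  idx <- sort(idx)  # preserve model order
  rx <- model$reactions[idx, , drop = FALSE]
  st <- lapply(idx, function(j) {
    col <- model$S[, j]
    col[col != 0]
  })
  rx$stoich <- st
  out <- metabolic_model(rx)
  out$objective[] <- model$objective[idx]
  out
}

#' Add sink reactions for key metabolites
#'
#' For each named metabolite without an existing sink (an exchange consuming
#' exactly that metabolite), appends an irreversible sink `m ->` with bounds
#' `[0, sink_ub]`. Idempotent: metabolites that already have a sink get no
#' duplicate.
#'
#' @param model a `metabolic_model`.
#' @param key_metabolites character vector of metabolite ids with positive
#'   evidence (must exist in the model).
#' @param sink_ub upper bound of added sinks (default 1000).
#' @return list with `model` (possibly extended) and `sinks`, the character
#'   set of sink reaction ids for the key metabolites (existing or added).
#' @export
add_metabolite_sinks <- function(model, key_metabolites, sink_ub = 1000) {
  key_metabolites <- unique(as.character(key_metabolites))
  unknown <- setdiff(key_metabolites, model$metabolites)
  if (length(unknown) > 0) {
    stop("unknown metabolite id(s): ", paste(unknown, collapse = ", "))
  }
  sinks <- character(0)
  add <- list()
  for (m in key_metabolites) {
    ## an existing sink: exchange reaction consuming m (coef < 0, sole entry)
    cand <- which(colSums(model$S != 0) == 1 & model$S[m, ] < 0 &
                    model$reactions$ub > 0)
    if (length(cand) > 0) {
      sinks <- c(sinks, model$reactions$id[cand[1]])
    } else {
      sid <- paste0("SK_", m)
      if (sid %in% model$reactions$id) sid <- paste0(sid, "_ctx")
      add[[length(add) + 1L]] <- tibble::tibble(
        id = sid, stoich = list(stats::setNames(-1, m)),
        lb = 0, ub = sink_ub, gpr = NA_character_
      )
      sinks <- c(sinks, sid)
    }
  }
  if (length(add) > 0) {
    rx <- model$reactions
    rx$stoich <- lapply(seq_len(nrow(rx)), function(j) {
      col <- model$S[, j]; col[col != 0]
    })
    obj <- model$objective
    model <- metabolic_model(dplyr::bind_rows(c(list(rx), add)))
    model$objective[names(obj)] <- obj
  }
  list(model = model, sinks = sinks)
}
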
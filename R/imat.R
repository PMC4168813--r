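## iMAT-like family: similarity maximisation without an RMF.
##
## iMAT maximises the number of matches between reaction activity states
## (|v| >= epsilon active, v = 0 inactive) and data states (highly / lowly
## expressed). INIT weights per-reaction inclusion binaries with signed
## evidence scores and can force net production of metabolites with
## experimental support; tINIT adds metabolic-task constraints and
## direction binaries. All are MILPs over the model's polytope with big-M
## activation couplings (M = the reaction's own bound magnitude).

## Build activation binaries for reactions: for each reaction id in `who`,
## adds y+ (forward active: v >= eps) and, when the reaction can run in
## reverse, y- (reverse active: v <= -eps). Returns constraint rows in an
## environment-free list. Variables are appended after the n flux columns.
activation_structure <- function(model, who, epsilon) {
  ids <- reaction_ids(model)
  out <- list()
  for (i in who) {
    j <- match(i, ids)
    lbj <- model$reactions$lb[j]; ubj <- model$reactions$ub[j]
    out[[i]] <- list(
      rxn = i, j = j,
      plus = ubj >= epsilon,   # forward activation attainable
      minus = lbj <= -epsilon  # reverse activation attainable
    )
  }
  out
}

#' iMAT: match maximisation between flux states and expression states
#'
#' MILP maximising the number of matched reactions: a reaction in `R_H`
#' matches when it carries `|v| >= epsilon` (either sense for reversibles),
#' a reaction in `R_L` matches when it carries zero flux. Returns the
#' optimal match count, the incumbent flux distribution and the retained
#' set `R_P` (reactions with `|v| > epsilon/2` at the incumbent).
#'
#' @param model a `metabolic_model`.
#' @param R_H,R_L disjoint sets of highly / lowly expressed reaction ids
#'   (as from [discretize()]).
#' @param epsilon activation flux (default 1e-4).
#' @return an `imat_result` (an `extraction_result`) with `objective` (the
#'   match count), `flux`, `R_P`, and `matched` (ids matched at the
#'   incumbent).
#' @export
#' @examples
#' m <- parallel_model()
#' res <- imat(m, R_H = "r2", R_L = "r3")
#' res$objective  # 2: r2 active and r3 silent simultaneously
imat <- function(model, R_H, R_L = character(0), epsilon = 1e-4) {
  R_H <- unique(as.character(R_H)); R_L <- unique(as.character(R_L))
  if (length(intersect(R_H, R_L)) > 0) stop("R_H and R_L must be disjoint")
  match_rxn(model, c(R_H, R_L))
  built <- build_imat_milp(model, R_H, R_L, epsilon)
  sol <- solve_milp(built$obj, built$A_eq, built$b_eq, built$A_le, built$b_le,
                    built$lb, built$ub, bin_idx = built$bin_idx, maximize = TRUE)
  if (sol$status != "optimal") stop("iMAT MILP returned ", sol$status)
  n <- n_reactions(model)
  v <- stats::setNames(sol$x[seq_len(n)], reaction_ids(model))
  matched <- imat_matched(v, R_H, R_L, epsilon)
  R_P <- names(v)[abs(v) > epsilon / 2]
  new_extraction_result(
    "imat", model, R_P, flux = v, objective = round(sol$objective),
    extra = list(R_H = R_H, R_L = R_L, epsilon = epsilon, matched = matched)
  )
}

imat_matched <- function(v, R_H, R_L, epsilon) {
  c(R_H[abs(v[R_H]) >= epsilon - 1e-9], R_L[abs(v[R_L]) <= 1e-9])
}

## Constraint builder shared by imat() and imat_classify().
build_imat_milp <- function(model, R_H, R_L, epsilon) {
  p <- model_lp_parts(model)
  n <- n_reactions(model)
  ids <- reaction_ids(model)
  act <- activation_structure(model, R_H, epsilon)

  nbin <- 0L
  cols <- list()  # per binary: list(kind, rxn, j, sense)
  for (i in R_H) {
    a <- act[[i]]
    if (a$plus) { nbin <- nbin + 1L; cols[[nbin]] <- list(kind = "H", j = a$j, sense = 1, rxn = i) }
    if (a$minus) { nbin <- nbin + 1L; cols[[nbin]] <- list(kind = "H", j = a$j, sense = -1, rxn = i) }
  }
  for (i in R_L) {
    nbin <- nbin + 1L
    cols[[nbin]] <- list(kind = "L", j = match(i, ids), sense = 0, rxn = i)
  }
  nv <- n + nbin
  pad <- function(A) if (is.null(A)) NULL else cbind(A, matrix(0, nrow(A), nbin))
  A_le <- pad(p$A_le); b_le <- p$b_le
  A_eq <- pad(p$A_eq); b_eq <- p$b_eq

  obj <- numeric(nv)
  lbv <- c(p$lb, rep(0, nbin)); ubv <- c(p$ub, rep(1, nbin))
  ## one y+/y- pair per R_H reaction must not double-count
  pair <- split(seq_len(nbin), vapply(cols, function(cl) cl$rxn, ""))
  for (rxn in names(pair)) {
    idxs <- pair[[rxn]]
    if (length(idxs) > 1) {
      row <- numeric(nv); row[n + idxs] <- 1
      A_le <- rbind(A_le, row); b_le <- c(b_le, 1)
    }
  }
  for (b in seq_len(nbin)) {
    cl <- cols[[b]]
    j <- cl$j
    lbj <- model$reactions$lb[j]; ubj <- model$reactions$ub[j]
    if (cl$kind == "H" && cl$sense == 1) {
      ## v_j >= lb + (eps - lb) y  <=>  -v_j + (eps - lb) y <= -lb
      row <- numeric(nv); row[j] <- -1; row[n + b] <- epsilon - lbj
      A_le <- rbind(A_le, row); b_le <- c(b_le, -lbj)
      obj[n + b] <- 1
    } else if (cl$kind == "H" && cl$sense == -1) {
      ## v_j <= ub + (-eps - ub) y
      row <- numeric(nv); row[j] <- 1; row[n + b] <- epsilon + ubj
      A_le <- rbind(A_le, row); b_le <- c(b_le, ubj)
      obj[n + b] <- 1
    } else {
      ## low: y = 1 forces v_j = 0 (big-M with the reaction's own bounds)
      row1 <- numeric(nv); row1[j] <- 1; row1[n + b] <- ubj
      row2 <- numeric(nv); row2[j] <- -1; row2[n + b] <- -lbj
      A_le <- rbind(A_le, row1, row2); b_le <- c(b_le, ubj, -lbj)
      obj[n + b] <- 1
    }
  }
  list(obj = obj, A_eq = A_eq, b_eq = b_eq, A_le = A_le, b_le = b_le,
       lb = lbv, ub = ubv, bin_idx = n + seq_len(nbin), n = n)
}

#' iMAT tri-state reaction classification
#'
#' The adapted flux variability analysis of iMAT: for each reaction, the
#' optimal match count is recomputed with the reaction forced active
#' (`|v| >= epsilon`; both senses tried for reversibles) and forced inactive
#' (`v = 0`). A reaction whose forced-active similarity is strictly higher
#' is `active`, strictly lower `inactive`, equal `undetermined`. An
#' infeasible forcing loses to the other branch.
#'
#' @inheritParams imat
#' @param reactions reaction ids to classify (default: all).
#' @return tibble with columns `reaction_id`, `s_active`, `s_inactive`,
#'   `label`.
#' @export
imat_classify <- function(model, R_H, R_L = character(0), epsilon = 1e-4,
                          reactions = NULL) {
  ids <- reactions %||% reaction_ids(model)
  match_rxn(model, ids)
  built <- build_imat_milp(model, R_H, R_L, epsilon)
  n <- built$n
  solve_with_bounds <- function(lb_j, ub_j, j) {
    lb <- built$lb; ub <- built$ub
    lb[j] <- lb_j; ub[j] <- ub_j
    if (lb[j] > ub[j]) return(-Inf)
    sol <- solve_milp(built$obj, built$A_eq, built$b_eq, built$A_le,
                      built$b_le, lb, ub, bin_idx = built$bin_idx,
                      maximize = TRUE)
    if (sol$status != "optimal") return(-Inf)
    round(sol$objective)
  }
  res <- lapply(ids, function(i) {
    j <- match(i, reaction_ids(model))
    lbj <- model$reactions$lb[j]; ubj <- model$reactions$ub[j]
    s_act <- -Inf
    if (ubj >= epsilon) s_act <- max(s_act, solve_with_bounds(max(lbj, epsilon), ubj, j))
    if (lbj <= -epsilon) s_act <- max(s_act, solve_with_bounds(lbj, min(ubj, -epsilon), j))
    s_in <- solve_with_bounds(0, 0, j)
    label <- if (s_act > s_in) "active" else if (s_act < s_in) "inactive" else "undetermined"
    tibble::tibble(reaction_id = i, s_active = s_act, s_inactive = s_in, label = label)
  })
  dplyr::bind_rows(res)
}

#' INIT: weighted reaction inclusion with net metabolite production
#'
#' MILP maximising `sum w_i y_i` where the binary `y_i = 1` exactly when
#' reaction i is active (`|v_i| >= epsilon`; `y_i = 0` forces `v_i = 0`).
#' Mass balance is `S v = b` with `b_m >= delta` for metabolites with
#' experimental support (`key_metabolites`) and `b_m = 0` otherwise — or
#' `b_m >= 0` for all metabolites when `allow_net_production = TRUE`.
#'
#' @param model a `metabolic_model`.
#' @param weights signed per-reaction weights: tibble
#'   (`reaction_id`, `weight`) or named vector; missing reactions get 0.
#' @param key_metabolites metabolite ids with evidence of presence.
#' @param delta lower bound on net production of key metabolites
#'   (default 0.1).
#' @param epsilon activation flux (default 1e-4).
#' @param allow_net_production allow `b_m >= 0` for every metabolite.
#' @return an `init_result` (an `extraction_result`) with `R_P`
#'   (`{i : y_i = 1}`), `flux`, `objective` (the weighted sum) and
#'   `net_production` (named vector over metabolites).
#' @export
init <- function(model, weights, key_metabolites = character(0), delta = 0.1,
                 epsilon = 1e-4, allow_net_production = FALSE) {
  init_like(model, weights, key_metabolites, delta, epsilon,
            allow_net_production, tasks = NULL, steady_state = FALSE,
            method = "init")
}

#' tINIT: INIT with mandatory metabolic tasks
#'
#' As [init()], plus a set of metabolic tasks the extracted model must
#' perform: each task is a linear combination of reaction fluxes required to
#' reach at least its lower bound. Tasks are first checked for feasibility
#' in the generic model (error listing the failures otherwise). In
#' steady-state mode net production is disabled (`b = 0` everywhere), the
#' alternative being INIT-style net production of the key metabolites.
#'
#' @inheritParams init
#' @param tasks a data frame with columns `task_id`, `reaction_id`,
#'   `coefficient` (one row per term) and optionally `bound` (per-task lower
#'   bound; default `delta`).
#' @param steady_state keep `b = 0` for all metabolites instead of net
#'   production (default `TRUE` when no key metabolites are given).
#' @return a `tinit_result` (an `extraction_result`); `tasks_ok` lists the
#'   per-task flux values achieved at the incumbent.
#' @export
tinit <- function(model, weights, tasks = NULL, key_metabolites = character(0),
                  delta = 0.1, epsilon = 1e-4,
                  allow_net_production = FALSE,
                  steady_state = length(key_metabolites) == 0) {
  init_like(model, weights, key_metabolites = if (steady_state) character(0) else key_metabolites,
            delta, epsilon,
            allow_net_production = if (steady_state) FALSE else allow_net_production,
            tasks = tasks, steady_state = steady_state, method = "tinit")
}

init_like <- function(model, weights, key_metabolites, delta, epsilon,
                      allow_net_production, tasks, steady_state, method) {
  stopifnot(delta > 0, epsilon > 0)
  w <- as_rxn_vector(model, weights, default = 0)
  if (all(w <= 0) && length(key_metabolites) == 0 && is.null(tasks)) {
    warning("no positive weights, key metabolites or tasks: R_P may be empty")
  }
  unknown <- setdiff(key_metabolites, model$metabolites)
  if (length(unknown) > 0) stop("unknown metabolite id(s): ", paste(unknown, collapse = ", "))

  task_list <- list()
  if (!is.null(tasks) && nrow(tasks) > 0) {
    tasks <- tibble::as_tibble(tasks)
    stopifnot(all(c("task_id", "reaction_id", "coefficient") %in% names(tasks)))
    bad <- setdiff(unique(tasks$reaction_id), reaction_ids(model))
    if (length(bad) > 0) {
      stop("task reactions absent from model: ", paste(bad, collapse = ", "))
    }
    for (tid in unique(tasks$task_id)) {
      tt <- tasks[tasks$task_id == tid, ]
      coef <- stats::setNames(as.numeric(tt$coefficient), tt$reaction_id)
      bound <- if ("bound" %in% names(tt)) tt$bound[1] else delta
      task_list[[tid]] <- list(coef = coef, bound = bound)
    }
    ## pre-check: every task individually feasible in the generic model
    failed <- character(0)
    for (tid in names(task_list)) {
      tk <- task_list[[tid]]
      opt <- fba(model, tk$coef, maximize = TRUE)
      if (opt$objective_value < tk$bound - 1e-9) failed <- c(failed, tid)
    }
    if (length(failed) > 0) {
      stop("task(s) infeasible in the generic model: ", paste(failed, collapse = ", "))
    }
  }

  p <- model_lp_parts(model)
  n <- n_reactions(model)
  ids <- reaction_ids(model)
  mets <- model$metabolites

  ## binary layout: per reaction, y+ (and y- when reverse-capable)
  cols <- list(); nbin <- 0L
  for (j in seq_len(n)) {
    lbj <- model$reactions$lb[j]; ubj <- model$reactions$ub[j]
    if (ubj >= epsilon) { nbin <- nbin + 1L; cols[[nbin]] <- list(j = j, sense = 1) }
    if (lbj <= -epsilon) { nbin <- nbin + 1L; cols[[nbin]] <- list(j = j, sense = -1) }
  }
  ## net-production slack variables
  prod_mets <- if (allow_net_production) mets else intersect(mets, key_metabolites)
  if (steady_state) prod_mets <- character(0)
  npd <- length(prod_mets)
  nv <- n + nbin + npd

  pad <- function(A, k) if (is.null(A)) NULL else cbind(A, matrix(0, nrow(A), k))
  A_eq <- pad(p$A_eq, nbin + npd); b_eq <- p$b_eq
  ## S v - b = 0: subtract production slack in the metabolite rows
  for (k in seq_along(prod_mets)) {
    mrow <- match(prod_mets[k], mets)
    A_eq[mrow, n + nbin + k] <- -1
  }
  A_le <- pad(p$A_le, nbin + npd); b_le <- p$b_le

  obj <- numeric(nv)
  ## activation couplings and exclusion (y = 0 forces v = 0)
  ysum_rows <- split(seq_len(nbin), vapply(cols, function(cl) cl$j, 1))
  for (jchr in names(ysum_rows)) {
    j <- as.integer(jchr)
    idxs <- ysum_rows[[jchr]]
    lbj <- model$reactions$lb[j]; ubj <- model$reactions$ub[j]
    if (length(idxs) > 1) {
      row <- numeric(nv); row[n + idxs] <- 1
      A_le <- rbind(A_le, row); b_le <- c(b_le, 1)
    }
    ## v <= ub * sum(y) ; v >= lb * sum(y)
    row1 <- numeric(nv); row1[j] <- 1; row1[n + idxs] <- -ubj
    row2 <- numeric(nv); row2[j] <- -1; row2[n + idxs] <- lbj
    A_le <- rbind(A_le, row1, row2); b_le <- c(b_le, 0, 0)
    for (b in idxs) {
      cl <- cols[[b]]
      if (cl$sense == 1) {
        row <- numeric(nv); row[j] <- -1; row[n + b] <- epsilon - lbj
        A_le <- rbind(A_le, row); b_le <- c(b_le, -lbj)
      } else {
        row <- numeric(nv); row[j] <- 1; row[n + b] <- epsilon + ubj
        A_le <- rbind(A_le, row); b_le <- c(b_le, ubj)
      }
      obj[n + b] <- w[j]
    }
  }
  ## reactions that can never reach epsilon in either sense: weight omitted
  ## (their y does not exist; v stays free within bounds)
  covered <- unique(vapply(cols, function(cl) cl$j, 1))
  uncovered <- setdiff(seq_len(n), covered)
  for (j in uncovered) {
    ## tiny-bound reaction: cannot be "included"; force zero for coherence
    row1 <- numeric(nv); row1[j] <- 1
    row2 <- numeric(nv); row2[j] <- -1
    A_le <- rbind(A_le, row1, row2); b_le <- c(b_le, 0, 0)
  }
  ## task rows: sum coef * v >= bound
  for (tk in task_list) {
    row <- numeric(nv)
    row[match(names(tk$coef), ids)] <- -as.numeric(tk$coef)
    A_le <- rbind(A_le, row); b_le <- c(b_le, -tk$bound)
  }

  lb <- c(p$lb, rep(0, nbin), rep(0, npd))
  ub <- c(p$ub, rep(1, nbin), rep(1000, npd))
  if (length(prod_mets) > 0) {
    kidx <- which(prod_mets %in% key_metabolites)
    lb[n + nbin + kidx] <- delta
  }
  sol <- solve_milp(obj, A_eq, b_eq, A_le, b_le, lb, ub,
                    bin_idx = n + seq_len(nbin), maximize = TRUE)
  if (sol$status != "optimal") {
    if (length(key_metabolites) > 0) {
      for (m in key_metabolites) {
        ## feasibility of each key metabolite's production alone
        p2 <- model_lp_parts(model)
        ob <- as.numeric(model$S[m, ])
        r <- solve_lp(ob, p2$A_eq[-match(m, mets), , drop = FALSE],
                      p2$b_eq[-match(m, mets)], p2$A_le, p2$b_le, p2$lb, p2$ub)
        if (r$status != "optimal" || r$objective < delta - 1e-9) {
          stop("net production of key metabolite '", m,
               "' infeasible at delta = ", delta)
        }
      }
    }
    stop("INIT MILP returned ", sol$status)
  }
  v <- stats::setNames(sol$x[seq_len(n)], ids)
  yv <- sol$x[n + seq_len(nbin)]
  y_by_rxn <- stats::setNames(numeric(n), ids)
  for (b in seq_len(nbin)) {
    y_by_rxn[cols[[b]]$j] <- y_by_rxn[cols[[b]]$j] + yv[b]
  }
  R_P <- ids[y_by_rxn > 0.5]
  bprod <- stats::setNames(numeric(length(mets)), mets)
  if (npd > 0) bprod[prod_mets] <- sol$x[n + nbin + seq_len(npd)]
  task_flux <- vapply(task_list, function(tk) sum(tk$coef * v[names(tk$coef)]), numeric(1))
  new_extraction_result(
    method, model, R_P, flux = v, objective = sol$objective,
    extra = list(weight = w, epsilon = epsilon, delta = delta,
                 key_metabolites = key_metabolites,
                 net_production = bprod,
                 tasks_ok = task_flux)
  )
}
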
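## Linear and mixed-integer programming backend.
##
## Every extraction method in the package is an LP or a MILP over the same
## flux polytope {v : S v = 0, v_min <= v <= v_max}, so the solver sits behind
## one small interface (solve_lp, solve_milp) that the rest of the package
## calls; swapping in another backend means reimplementing these two functions.
## The default backend is a dense two-phase primal simplex with Bland's rule
## (finite termination, no cycling) and a deterministic depth-first
## branch-and-bound for binaries. Problem sizes in this package are tiny
## (tens of variables), where a dense tableau is both robust and fast.

#' Solve a linear program
#'
#' Maximise (or minimise) `obj %*% x` subject to `A_eq x = b_eq`,
#' `A_le x <= b_le` and box bounds `lb <= x <= ub`. All bounds must be finite;
#' genome-scale models conventionally use +/-1000 as "unbounded".
#'
#' @param obj numeric objective coefficient vector.
#' @param A_eq,b_eq equality constraints (matrix and rhs), or `NULL`.
#' @param A_le,b_le inequality (`<=`) constraints, or `NULL`. Encode `>=` rows
#'   by negation.
#' @param lb,ub finite lower/upper variable bounds (recycled to length).
#' @param maximize logical; maximise when `TRUE` (default).
#' @param tol numerical tolerance for pivoting and feasibility (default 1e-9).
#'
#' @return A list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `x` (solution vector, `NULL` unless optimal) and
#'   `objective` (scalar, `NA` unless optimal).
#' @export
solve_lp <- function(obj, A_eq = NULL, b_eq = NULL, A_le = NULL, b_le = NULL,
                     lb, ub, maximize = TRUE, tol = 1e-9) {
  n <- length(obj)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  stopifnot(all(is.finite(lb)), all(is.finite(ub)))
  if (any(ub < lb - tol)) {
    return(list(status = "infeasible", x = NULL, objective = NA_real_))
  }
  ub <- pmax(ub, lb)

  if (!is.null(A_eq)) {
    A_eq <- matrix(as.numeric(A_eq), ncol = n)
  } else {
    A_eq <- matrix(0, 0, n); b_eq <- numeric(0)
  }
  if (!is.null(A_le)) {
    A_le <- matrix(as.numeric(A_le), ncol = n)
  } else {
    A_le <- matrix(0, 0, n); b_le <- numeric(0)
  }

  ## shift variables: y = x - lb, 0 <= y <= ub - lb
  rng <- ub - lb
  b_eq2 <- as.numeric(b_eq - A_eq %*% lb)
  b_le2 <- as.numeric(b_le - A_le %*% lb)

  ## upper bounds as inequality rows (only for variables with rng < Inf; all
  ## finite here, but skip fixed variables handled by rng = 0 rows too --
  ## keep them, simplex treats them as degenerate rows)
  ub_rows <- which(rng > 0 | rng == 0)
  A_ub <- matrix(0, length(ub_rows), n)
  A_ub[cbind(seq_along(ub_rows), ub_rows)] <- 1
  b_ub <- rng[ub_rows]

  cmin <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  res <- simplex_two_phase(
    A_le = rbind(A_le, A_ub), b_le = c(b_le2, b_ub),
    A_eq = A_eq, b_eq = b_eq2, cc = cmin, tol = tol
  )
  if (res$status != "optimal") {
    return(list(status = res$status, x = NULL, objective = NA_real_))
  }
  x <- res$x[seq_len(n)] + lb
  list(status = "optimal", x = x,
       objective = sum(as.numeric(obj) * x))
}

## Two-phase tableau simplex for
##   min c'y  s.t.  A_le y <= b_le, A_eq y = b_eq, y >= 0
## Bland's rule throughout.
simplex_two_phase <- function(A_le, b_le, A_eq, b_eq, cc, tol = 1e-9) {
  n <- length(cc)
  m_le <- nrow(A_le); m_eq <- nrow(A_eq)
  A <- rbind(A_le, A_eq)
  b <- c(b_le, b_eq)
  m <- m_le + m_eq
  is_le <- c(rep(TRUE, m_le), rep(FALSE, m_eq))

  ## normalise to b >= 0
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  ## slack sign: +1 for <= rows not flipped, -1 (surplus) for flipped <= rows
  slack_sign <- ifelse(is_le, ifelse(neg, -1, 1), 0)

  n_slack <- m_le
  slack_cols <- matrix(0, m, n_slack)
  slack_cols[cbind(which(is_le), seq_len(n_slack))] <- slack_sign[is_le]

  ## artificials: needed for eq rows and flipped <= rows (surplus slack)
  need_art <- !is_le | (is_le & neg)
  n_art <- sum(need_art)
  art_cols <- matrix(0, m, n_art)
  art_cols[cbind(which(need_art), seq_len(n_art))] <- 1

  Afull <- cbind(A, slack_cols, art_cols)
  ntot <- ncol(Afull)
  art_idx <- if (n_art > 0) (n + n_slack + 1):ntot else integer(0)

  ## initial basis: slack for clean <= rows, artificial otherwise
  basis <- integer(m)
  slack_of_row <- integer(m); slack_of_row[is_le] <- n + seq_len(n_slack)
  ai <- n + n_slack
  for (i in seq_len(m)) {
    if (is_le[i] && !neg[i]) {
      basis[i] <- slack_of_row[i]
    } else {
      ai <- ai + 1
      basis[i] <- ai
    }
  }

  Tb <- cbind(Afull, b)

  pivot <- function(Tb, pr, pc) {
    piv <- Tb[pr, pc]
    Tb[pr, ] <- Tb[pr, ] / piv
    other <- setdiff(seq_len(nrow(Tb)), pr)
    Tb[other, ] <- Tb[other, ] - outer(Tb[other, pc], Tb[pr, ])
    Tb
  }

  run_simplex <- function(Tb, basis, cost, allowed, tol) {
    ## cost: length ntot vector to minimise; allowed: columns eligible to enter
    repeat {
      cb <- cost[basis]
      ## reduced costs: c_j - cb' B^-1 A_j ; with tableau rows already B^-1 A
      red <- cost[seq_len(ntot)] - as.numeric(crossprod(cb, Tb[, seq_len(ntot), drop = FALSE]))
      cand <- which(allowed & red < -tol)
      if (length(cand) == 0) {
        return(list(Tb = Tb, basis = basis, status = "optimal"))
      }
      pc <- cand[1]  # Bland: smallest index
      col <- Tb[, pc]
      pos <- which(col > tol)
      if (length(pos) == 0) {
        return(list(Tb = Tb, basis = basis, status = "unbounded"))
      }
      ratios <- Tb[pos, ntot + 1] / col[pos]
      rmin <- min(ratios)
      tie <- pos[ratios <= rmin + tol]
      pr <- tie[which.min(basis[tie])]  # Bland on leaving variable
      Tb <- pivot(Tb, pr, pc)
      basis[pr] <- pc
    }
  }

  allowed <- rep(TRUE, ntot)

  if (n_art > 0) {
    cost1 <- numeric(ntot); cost1[art_idx] <- 1
    r1 <- run_simplex(Tb, basis, cost1, allowed, tol)
    if (r1$status != "optimal") stop("internal: phase-1 simplex unbounded")
    Tb <- r1$Tb; basis <- r1$basis
    phase1_val <- sum(Tb[which(basis %in% art_idx), ntot + 1])
    if (phase1_val > 1e-7) {
      return(list(status = "infeasible", x = NULL))
    }
    ## drive remaining artificials out of the basis where possible
    for (i in which(basis %in% art_idx)) {
      row <- Tb[i, seq_len(n + n_slack)]
      pc <- which(abs(row) > tol)
      pc <- pc[!(pc %in% art_idx)]
      if (length(pc) > 0) {
        Tb <- pivot(Tb, i, pc[1])
        basis[i] <- pc[1]
      }
      ## else: redundant row, artificial stays basic at zero (harmless)
    }
    allowed[art_idx] <- FALSE
  }

  cost2 <- numeric(ntot); cost2[seq_len(n)] <- cc
  r2 <- run_simplex(Tb, basis, cost2, allowed, tol)
  if (r2$status == "unbounded") {
    return(list(status = "unbounded", x = NULL))
  }
  Tb <- r2$Tb; basis <- r2$basis
  x <- numeric(ntot)
  x[basis] <- Tb[seq_len(m), ntot + 1]
  list(status = "optimal", x = x[seq_len(n)])
}

#' Solve a mixed-integer linear program with binary variables
#'
#' Same constraint interface as [solve_lp()], plus `bin_idx`: indices of
#' variables restricted to \{0, 1\}. Solved by deterministic depth-first
#' branch-and-bound on the LP relaxation; with a fixed model and fixed inputs
#' the solution is reproducible.
#'
#' @inheritParams solve_lp
#' @param bin_idx integer indices of binary variables.
#' @param int_tol integrality tolerance (default 1e-6).
#'
#' @return As [solve_lp()]; additionally `nodes`, the number of
#'   branch-and-bound nodes processed.
#' @export
solve_milp <- function(obj, A_eq = NULL, b_eq = NULL, A_le = NULL, b_le = NULL,
                       lb, ub, bin_idx = integer(0), maximize = TRUE,
                       tol = 1e-9, int_tol = 1e-6) {
  n <- length(obj)
  lb <- rep_len(as.numeric(lb), n)
  ub <- rep_len(as.numeric(ub), n)
  bin_idx <- as.integer(bin_idx)
  lb[bin_idx] <- pmax(lb[bin_idx], 0)
  ub[bin_idx] <- pmin(ub[bin_idx], 1)

  sgn <- if (maximize) 1 else -1
  best <- list(x = NULL, objective = -Inf, status = "infeasible")
  nodes <- 0L

  ## explicit stack of (lb, ub) boxes, depth-first
  stack <- list(list(lb = lb, ub = ub))
  while (length(stack) > 0) {
    node <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    nodes <- nodes + 1L
    rel <- solve_lp(obj, A_eq, b_eq, A_le, b_le, node$lb, node$ub,
                    maximize = maximize, tol = tol)
    if (rel$status == "unbounded") {
      return(list(status = "unbounded", x = NULL, objective = NA_real_,
                  nodes = nodes))
    }
    if (rel$status != "optimal") next
    if (is.finite(best$objective) &&
        sgn * rel$objective <= sgn * best$objective + 1e-9) next
    xb <- rel$x[bin_idx]
    frac <- abs(xb - round(xb))
    if (length(frac) == 0 || max(frac) <= int_tol) {
      cand_obj <- rel$objective
      if (!is.finite(best$objective) || sgn * cand_obj > sgn * best$objective + 1e-9) {
        x <- rel$x
        x[bin_idx] <- round(xb)
        best <- list(x = x, objective = cand_obj, status = "optimal")
      }
      next
    }
    j <- bin_idx[which.max(frac)]
    v <- rel$x[j]
    lo <- node; lo$ub[j] <- 0
    hi <- node; hi$lb[j] <- 1
    ## explore the nearer rounding first (pushed last)
    if (v >= 0.5) {
      stack[[length(stack) + 1L]] <- lo
      stack[[length(stack) + 1L]] <- hi
    } else {
      stack[[length(stack) + 1L]] <- hi
      stack[[length(stack) + 1L]] <- lo
    }
  }
  if (best$status != "optimal") {
    return(list(status = "infeasible", x = NULL, objective = NA_real_,
                nodes = nodes))
  }
  c(best, list(nodes = nodes))
}
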
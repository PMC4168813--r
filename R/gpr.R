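## Gene-protein-reaction (GPR) rules.
##
## A GPR rule is a boolean expression over gene identifiers: AND encodes an
## enzyme complex (limited by its scarcest subunit), OR encodes isoenzymes
## (any one suffices). Expression values map through rules with AND = min,
## OR = max — the standard convention. Penalties map with the dual
## convention (AND = max, OR = min): a complex is as penalised as its worst
## subunit, isoenzymes as the best alternative.

gpr_tokenize <- function(text) {
  pat <- "\\(|\\)|[A-Za-z0-9_.:\\-]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) return(tibble::tibble(tok = character(0), pos = integer(0)))
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  ## anything between tokens other than whitespace is an error
  stripped <- gsub(pat, "", text)
  if (grepl("[^[:space:]]", stripped)) {
    bad <- regmatches(stripped, regexpr("[^[:space:]]", stripped))
    stop("GPR parse error: unexpected character '", bad, "'")
  }
  tibble::tibble(tok = toks, pos = as.integer(m))
}

#' Parse a gene-protein-reaction rule
#'
#' Grammar: identifiers, parentheses, and the operators `and` / `or`
#' (case-insensitive), with the usual precedence (`and` binds tighter).
#'
#' @param rule_text the rule string; empty or all-whitespace means "no rule"
#'   and returns `NULL`.
#' @return a `gpr_rule` parse tree (nested lists with `type` `"gene"` or
#'   `"op"`), or `NULL` for an absent rule.
#' @export
#' @examples
#' parse_gpr("g1 and (g2 or g3)")
parse_gpr <- function(rule_text) {
  if (is.null(rule_text) || is.na(rule_text) || !nzchar(trimws(rule_text))) {
    return(NULL)
  }
  toks <- gpr_tokenize(rule_text)
  i <- 1L
  n <- nrow(toks)
  peek <- function() if (i <= n) toks$tok[i] else NA_character_
  advance <- function() {
    t <- toks$tok[i]; i <<- i + 1L; t
  }
  err <- function(msg) {
    at <- if (i <= n) paste0("near position ", toks$pos[i]) else "at end of rule"
    stop("GPR parse error ", at, ": ", msg)
  }
  is_op <- function(t, op) !is.na(t) && tolower(t) == op

  parse_expr <- function() {
    args <- list(parse_term())
    while (is_op(peek(), "or")) {
      advance()
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1) args[[1]] else list(type = "op", op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (is_op(peek(), "and")) {
      advance()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1) args[[1]] else list(type = "op", op = "and", args = args)
  }
  parse_factor <- function() {
    t <- peek()
    if (is.na(t)) err("unexpected end of rule")
    if (t == "(") {
      advance()
      e <- parse_expr()
      if (!identical(peek(), ")")) err("expected ')'")
      advance()
      return(e)
    }
    if (t == ")") err("unexpected ')'")
    if (tolower(t) %in% c("and", "or")) err(paste0("dangling operator '", t, "'"))
    advance()
    list(type = "gene", gene = t)
  }

  tree <- parse_expr()
  if (i <= n) err(paste0("trailing input '", toks$tok[i], "'"))
  structure(tree, class = "gpr_rule")
}

#' Render a GPR parse tree back to its rule string
#' @param rule a `gpr_rule` tree (or `NULL`).
#' @return canonical rule string (`NA` for `NULL`).
#' @export
deparse_gpr <- function(rule) {
  if (is.null(rule)) return(NA_character_)
  rec <- function(node, parent_op = NULL) {
    if (node$type == "gene") return(node$gene)
    inner <- vapply(node$args, rec, "", parent_op = node$op)
    s <- paste(inner, collapse = paste0(" ", node$op, " "))
    if (!is.null(parent_op) && parent_op != node$op) paste0("(", s, ")") else s
  }
  rec(unclass(rule))
}

#' Genes referenced by a GPR rule
#' @param rule a `gpr_rule` tree (or `NULL`).
#' @return character vector of gene ids.
#' @export
gpr_genes <- function(rule) {
  if (is.null(rule)) return(character(0))
  out <- character(0)
  rec <- function(node) {
    if (node$type == "gene") out <<- c(out, node$gene)
    else lapply(node$args, rec)
  }
  rec(unclass(rule))
  unique(out)
}

## Evaluate a rule over gene values with given AND/OR combiners.
## Missing genes: "ignore" treats them as the combiner's neutral element
## (the subexpression is dropped); "strict" errors. All-missing -> NA.
gpr_eval <- function(rule, values, and_fn, or_fn,
                     missing_gene = c("ignore", "strict")) {
  missing_gene <- match.arg(missing_gene)
  rec <- function(node) {
    if (node$type == "gene") {
      v <- values[node$gene]
      if (is.null(v) || length(v) == 0 || is.na(v)) {
        if (missing_gene == "strict") {
          stop("gene '", node$gene, "' absent from the evidence data")
        }
        return(NA_real_)
      }
      return(as.numeric(v))
    }
    vals <- vapply(node$args, rec, numeric(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) return(NA_real_)
    if (node$op == "and") and_fn(vals) else or_fn(vals)
  }
  rec(unclass(rule))
}

as_gene_values <- function(gene_values) {
  if (is.data.frame(gene_values)) {
    stopifnot(ncol(gene_values) >= 2)
    stats::setNames(as.numeric(gene_values[[2]]), as.character(gene_values[[1]]))
  } else {
    stopifnot(!is.null(names(gene_values)))
    gene_values
  }
}

#' Map gene-level evidence to reaction-level data values
#'
#' Evaluates each reaction's GPR over the gene values with AND = min
#' (complexes limited by the scarcest subunit) and OR = max (isoenzymes).
#' Reactions without a GPR — or whose genes are all absent from the data —
#' get `NA`, never a fabricated value.
#'
#' @param model a `metabolic_model`.
#' @param gene_values named numeric vector, or a two-column data frame
#'   (gene id, value).
#' @param missing_gene `"ignore"` (default: absent genes drop out of the
#'   rule) or `"strict"` (error on any absent gene).
#' @return tibble with columns `reaction_id`, `value`.
#' @export
map_expression <- function(model, gene_values,
                           missing_gene = c("ignore", "strict")) {
  missing_gene <- match.arg(missing_gene)
  values <- as_gene_values(gene_values)
  if (length(values) == 0) stop("gene_values is empty")
  vals <- vapply(seq_len(n_reactions(model)), function(j) {
    rule <- parse_gpr(model$reactions$gpr[j])
    if (is.null(rule)) return(NA_real_)
    gpr_eval(rule, values, min, max, missing_gene)
  }, numeric(1))
  tibble::tibble(reaction_id = reaction_ids(model), value = vals)
}

as_rxn_vector <- function(model, x, col = 2, default = NA_real_) {
  ids <- reaction_ids(model)
  out <- stats::setNames(rep(default, length(ids)), ids)
  if (is.data.frame(x)) {
    v <- stats::setNames(as.numeric(x[[col]]), as.character(x[[1]]))
  } else {
    stopifnot(!is.null(names(x)))
    v <- x
  }
  keep <- intersect(names(v), ids)
  out[keep] <- as.numeric(v[keep])
  out
}

#' GIMME reaction penalties
#'
#' `p_i = c - d_i` for reactions whose data value lies below the threshold
#' `c`, zero otherwise. Reactions without data get zero penalty.
#'
#' @param reaction_data tibble (`reaction_id`, `value`) as from
#'   [map_expression()], or a named numeric vector.
#' @param threshold the expression cut-off `c`, in data units.
#' @return tibble with columns `reaction_id`, `data`, `penalty`.
#' @export
gimme_penalty <- function(reaction_data, threshold) {
  if (is.data.frame(reaction_data)) {
    ids <- as.character(reaction_data[[1]])
    d <- as.numeric(reaction_data[[2]])
  } else {
    ids <- names(reaction_data); d <- as.numeric(reaction_data)
  }
  p <- pmax(threshold - d, 0)
  p[is.na(p)] <- 0
  tibble::tibble(reaction_id = ids, data = d, penalty = p)
}

#' GIM3E reaction penalties
#'
#' Per-gene penalties `q_g = I_max - I_g` (distance to the sample's maximum
#' intensity) are mapped to reactions through the GPR with the
#' order-reversed convention (AND = max, OR = min), so every reaction with a
#' GPR receives a penalty — in contrast to GIMME where only sub-threshold
#' reactions do. Reactions without a GPR (or with no gene covered) get zero.
#'
#' @inheritParams map_expression
#' @param I_max maximum intensity of the sample; defaults to
#'   `max(gene_values)` but can be supplied when the sample is wider than
#'   the genes passed here.
#' @return tibble with columns `reaction_id`, `penalty`.
#' @export
gim3e_penalty <- function(model, gene_values, I_max = NULL,
                          missing_gene = c("ignore", "strict")) {
  missing_gene <- match.arg(missing_gene)
  values <- as_gene_values(gene_values)
  if (length(values) == 0) stop("gene_values is empty")
  I_max <- I_max %||% max(values)
  q <- I_max - values
  if (any(q < 0)) stop("I_max is smaller than some gene intensity")
  pen <- vapply(seq_len(n_reactions(model)), function(j) {
    rule <- parse_gpr(model$reactions$gpr[j])
    if (is.null(rule)) return(0)
    v <- gpr_eval(rule, q, max, min, missing_gene)
    if (is.na(v)) 0 else v
  }, numeric(1))
  tibble::tibble(reaction_id = reaction_ids(model), penalty = pen)
}

#' Discretise reaction data into high and low expression sets
#'
#' Quantile mode (default): `R_H` are reactions at or above the `high_q`
#' empirical quantile of the data, `R_L` at or below the `low_q` quantile
#' (linear-interpolation quantiles). Absolute mode: supply `c_low`/`c_high`
#' in data units instead. On ties at a shared threshold the high set wins,
#' keeping the sets disjoint. Reactions with `NA` data are in neither set.
#'
#' @param reaction_data tibble (`reaction_id`, `value`) or named vector.
#' @param low_q,high_q quantiles in `[0, 1]`, `low_q < high_q`.
#' @param c_low,c_high absolute thresholds; when given, quantiles are ignored.
#' @return list with character vectors `R_H` and `R_L`.
#' @export
discretize <- function(reaction_data, low_q = 0.25, high_q = 0.75,
                       c_low = NULL, c_high = NULL) {
  if (is.data.frame(reaction_data)) {
    ids <- as.character(reaction_data[[1]])
    d <- as.numeric(reaction_data[[2]])
  } else {
    ids <- names(reaction_data); d <- as.numeric(reaction_data)
  }
  ok <- !is.na(d)
  if (is.null(c_low) && is.null(c_high)) {
    stopifnot(low_q >= 0, high_q <= 1, low_q < high_q)
    c_low <- stats::quantile(d[ok], low_q, names = FALSE, type = 7)
    c_high <- stats::quantile(d[ok], high_q, names = FALSE, type = 7)
    if (c_high <= c_low) {
      stop("quantile thresholds coincide (data too tied or constant); ",
           "use explicit absolute thresholds c_low/c_high")
    }
  } else {
    c_low <- c_low %||% c_high
    c_high <- c_high %||% c_low
  }
  R_H <- ids[ok & d >= c_high]
  R_L <- setdiff(ids[ok & d <= c_low], R_H)
  list(R_H = R_H, R_L = R_L)
}
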
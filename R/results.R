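## Extraction results.
##
## Every extraction method returns an `extraction_result`: which reactions
## of the generic model are retained (R_P), the incumbent flux distribution
## where the method predicts one, the method's objective value, and a
## per-reaction table. `tidy()` gives the per-reaction tibble, `glance()` a
## one-row summary, `autoplot()` a membership/flux overview.

new_extraction_result <- function(method, model, R_P, flux = NULL,
                                  objective = NA_real_, extra = list()) {
  ids <- reaction_ids(model)
  tbl <- tibble::tibble(
    reaction_id = ids,
    in_model = as.integer(ids %in% R_P),
    flux = if (is.null(flux)) NA_real_ else as.numeric(flux[ids])
  )
  structure(
    c(list(method = method, R_P = R_P, flux = flux, objective = objective,
           reactions = tbl, n_reactions = length(ids)),
      extra),
    class = c(paste0(method, "_result"), "extraction_result")
  )
}

#' @export
print.extraction_result <- function(x, ...) {
  cat("<", x$method, " extraction> retained ", length(x$R_P), " of ",
      x$n_reactions, " reactions",
      if (!is.na(x$objective)) paste0("; objective = ", format(x$objective)),
      "\n", sep = "")
  invisible(x)
}

#' Tidy an extraction result into a per-reaction tibble
#'
#' @param x an `extraction_result`.
#' @param ... unused.
#' @return tibble with one row per reaction of the generic model:
#'   `reaction_id`, `in_model` (0/1), `flux` (`NA` for methods that return no
#'   flux distribution), plus method-specific columns (penalty, weight,
#'   scores, labels) when available.
#' @method tidy extraction_result
#' @export
tidy.extraction_result <- function(x, ...) {
  tbl <- x$reactions
  for (col in c("penalty", "weight", "label", "expression_score",
                "connectivity_score", "confidence_score", "occurrence")) {
    if (!is.null(x[[col]])) tbl[[col]] <- as.numeric(x[[col]][tbl$reaction_id])
  }
  if (!is.null(x$labels)) {
    tbl$label <- as.character(x$labels[tbl$reaction_id])
  }
  tbl
}

#' One-row summary of an extraction result
#'
#' @inheritParams tidy.extraction_result
#' @return one-row tibble: `method`, `n_reactions`, `n_retained`,
#'   `objective`, and `inconsistency_score` where defined.
#' @method glance extraction_result
#' @export
glance.extraction_result <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    n_reactions = x$n_reactions,
    n_retained = length(x$R_P),
    objective = x$objective,
    inconsistency_score = if (!is.null(x$IS)) x$IS else NA_real_
  )
}

#' Plot an extraction result
#'
#' Bar panel of retained/removed membership per reaction, with flux overlaid
#' when the method predicts one.
#'
#' @param object an `extraction_result`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot extraction_result
#' @export
autoplot.extraction_result <- function(object, ...) {
  tbl <- tidy(object)
  tbl$membership <- ifelse(tbl$in_model == 1, "retained", "removed")
  p <- ggplot2::ggplot(tbl, ggplot2::aes(
    x = factor(.data$reaction_id, levels = .data$reaction_id),
    fill = .data$membership
  )) +
    ggplot2::labs(x = NULL, fill = NULL,
                  title = paste(object$method, "extraction")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
  if (all(is.na(tbl$flux))) {
    p + ggplot2::geom_bar(ggplot2::aes(y = 1), stat = "identity") +
      ggplot2::labs(y = NULL) +
      ggplot2::theme(axis.text.y = ggplot2::element_blank())
  } else {
    p + ggplot2::geom_col(ggplot2::aes(y = .data$flux)) +
      ggplot2::labs(y = "flux")
  }
}

#' Tidy a flux distribution
#' @param x a `flux_distribution` from [fba()].
#' @param ... unused.
#' @return tibble with `reaction_id`, `flux`.
#' @method tidy flux_distribution
#' @export
tidy.flux_distribution <- function(x, ...) {
  tibble::tibble(reaction_id = names(x$flux), flux = as.numeric(x$flux))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
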
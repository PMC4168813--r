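## Model and evidence input/output.
##
## Two model formats: a compact JSON dialect (documented below) and SBML
## Level 3 with the flux-bounds/objective (fbc v2) package, written and read
## with xml2. Evidence, core sets and task definitions travel as plain TSV.
##
## JSON dialect:
##   {
##     "metabolites": ["A", "B"],
##     "reactions": [
##       {"id": "r1", "stoich": {"A": 1}, "lb": 0, "ub": 10,
##        "gpr": "g1 and (g2 or g3)"}
##     ],
##     "objective": {"r3": 1}        // optional
##   }
## Bounds default to -1000/1000 when absent; "gpr" may be omitted or null.

#' Read a metabolic model from file
#'
#' @param path file path.
#' @param format `"json"`, `"sbml"`, or `"auto"` (default: by extension,
#'   `.xml`/`.sbml` is SBML, anything else JSON).
#' @return a `metabolic_model`.
#' @export
read_model <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (format == "json") read_model_json(path) else read_model_sbml(path)
}

#' Write a metabolic model to file
#'
#' @param model a `metabolic_model`.
#' @param path destination path.
#' @param format as in [read_model()].
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  if (format == "json") write_model_json(model, path) else write_model_sbml(model, path)
  invisible(path)
}

read_model_json <- function(path) {
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("cannot parse JSON model '", path,
                                           "': ", conditionMessage(e)))
  if (is.null(doc$reactions)) stop("JSON model lacks a 'reactions' element")
  rows <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("JSON reaction without an 'id'")
    st <- unlist(r$stoich %||% list())
    tibble::tibble(
      id = as.character(r$id),
      stoich = list(if (length(st) == 0) stats::setNames(numeric(0), character(0)) else st),
      lb = as.numeric(r$lb %||% -1000),
      ub = as.numeric(r$ub %||% 1000),
      gpr = as.character(r$gpr %||% NA_character_)
    )
  })
  tbl <- dplyr::bind_rows(rows)
  if (anyDuplicated(tbl$id)) {
    stop("duplicate reaction id(s) in '", path, "': ",
         paste(unique(tbl$id[duplicated(tbl$id)]), collapse = ", "))
  }
  obj <- doc$objective
  model <- metabolic_model(tbl, objective = if (length(obj) > 0) unlist(obj))
  ## keep declared metabolite order when given and complete
  declared <- unlist(doc$metabolites)
  if (length(declared) > 0 && setequal(declared, model$metabolites)) {
    model$S <- model$S[declared, , drop = FALSE]
    model$metabolites <- declared
  }
  model
}

write_model_json <- function(model, path) {
  rx <- lapply(seq_len(n_reactions(model)), function(j) {
    col <- model$S[, j]
    st <- as.list(col[col != 0])
    out <- list(id = model$reactions$id[j], stoich = st,
                lb = model$reactions$lb[j], ub = model$reactions$ub[j])
    if (!is.na(model$reactions$gpr[j])) out$gpr <- model$reactions$gpr[j]
    out
  })
  doc <- list(metabolites = as.list(model$metabolites), reactions = rx)
  if (any(model$objective != 0)) {
    nz <- model$objective[model$objective != 0]
    doc$objective <- as.list(nz)
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

SBML_NS <- "http://www.sbml.org/sbml/level3/version1/core"
FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

write_model_sbml <- function(model, path) {
  bounds <- sort(unique(c(model$reactions$lb, model$reactions$ub)))
  bid <- function(v) paste0("bnd_", match(v, bounds))
  genes <- unique(unlist(lapply(model$reactions$gpr, function(g)
    gpr_genes(parse_gpr(g))), use.names = FALSE))

  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  buf <- character(0)
  w <- function(...) buf <<- c(buf, paste0(...))
  w('<?xml version="1.0" encoding="UTF-8"?>')
  w('<sbml xmlns="', SBML_NS, '" xmlns:fbc="', FBC_NS,
    '" level="3" version="1" fbc:required="false">')
  w('  <model id="model" fbc:strict="true">')
  w('    <listOfCompartments><compartment id="c" constant="true"/></listOfCompartments>')
  if (length(model$metabolites) > 0) {
    w('    <listOfSpecies>')
    for (m in model$metabolites) {
      w('      <species id="', esc(m), '" compartment="c" hasOnlySubstanceUnits="false"',
        ' boundaryCondition="false" constant="false"/>')
    }
    w('    </listOfSpecies>')
  }
  w('    <listOfParameters>')
  for (i in seq_along(bounds)) {
    w('      <parameter id="bnd_', i, '" value="', format(bounds[i], digits = 17),
      '" constant="true"/>')
  }
  w('    </listOfParameters>')
  w('    <listOfReactions>')
  gpr_xml <- function(node, indent) {
    pre <- strrep(" ", indent)
    if (node$type == "gene") {
      return(paste0(pre, '<fbc:geneProductRef fbc:geneProduct="', esc(node$gene), '"/>'))
    }
    tag <- paste0("fbc:", node$op)
    inner <- vapply(node$args, gpr_xml, "", indent = indent + 2)
    paste0(pre, "<", tag, ">\n", paste(inner, collapse = "\n"), "\n", pre, "</", tag, ">")
  }
  for (j in seq_len(n_reactions(model))) {
    id <- model$reactions$id[j]
    lbj <- model$reactions$lb[j]; ubj <- model$reactions$ub[j]
    w('      <reaction id="', esc(id), '" reversible="', tolower(lbj < 0),
      '" fast="false" fbc:lowerFluxBound="', bid(lbj),
      '" fbc:upperFluxBound="', bid(ubj), '">')
    col <- model$S[, j]
    subs <- which(col < 0); prods <- which(col > 0)
    if (length(subs) > 0) {
      w('        <listOfReactants>')
      for (i in subs) w('          <speciesReference species="', esc(model$metabolites[i]),
                        '" stoichiometry="', format(-col[i], digits = 17),
                        '" constant="true"/>')
      w('        </listOfReactants>')
    }
    if (length(prods) > 0) {
      w('        <listOfProducts>')
      for (i in prods) w('          <speciesReference species="', esc(model$metabolites[i]),
                         '" stoichiometry="', format(col[i], digits = 17),
                         '" constant="true"/>')
      w('        </listOfProducts>')
    }
    rule <- parse_gpr(model$reactions$gpr[j])
    if (!is.null(rule)) {
      w('        <fbc:geneProductAssociation>')
      w(gpr_xml(unclass(rule), 10))
      w('        </fbc:geneProductAssociation>')
    }
    w('      </reaction>')
  }
  w('    </listOfReactions>')
  if (any(model$objective != 0)) {
    w('    <fbc:listOfObjectives fbc:activeObjective="obj">')
    w('      <fbc:objective fbc:id="obj" fbc:type="maximize">')
    w('        <fbc:listOfFluxObjectives>')
    nz <- which(model$objective != 0)
    for (j in nz) {
      w('          <fbc:fluxObjective fbc:reaction="', esc(model$reactions$id[j]),
        '" fbc:coefficient="', format(model$objective[j], digits = 17), '"/>')
    }
    w('        </fbc:listOfFluxObjectives>')
    w('      </fbc:objective>')
    w('    </fbc:listOfObjectives>')
  }
  if (length(genes) > 0) {
    w('    <fbc:listOfGeneProducts>')
    for (g in genes) {
      w('      <fbc:geneProduct fbc:id="', esc(g), '" fbc:label="', esc(g), '"/>')
    }
    w('    </fbc:listOfGeneProducts>')
  }
  w('  </model>')
  w('</sbml>')
  writeLines(buf, path)
}

read_model_sbml <- function(path) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("cannot parse SBML '", path, "': ",
                                           conditionMessage(e)))
  ns <- c(s = SBML_NS, fbc = FBC_NS)
  params <- xml2::xml_find_all(doc, ".//s:listOfParameters/s:parameter", ns)
  pvals <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                           xml2::xml_attr(params, "id"))
  species <- xml2::xml_attr(xml2::xml_find_all(doc, ".//s:listOfSpecies/s:species", ns), "id")

  gpa_to_string <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      return(xml2::xml_attr(node, "geneProduct"))
    }
    kids <- xml2::xml_children(node)
    inner <- vapply(kids, gpa_to_string, "")
    op <- nm  # "and" / "or"
    paste0("(", paste(inner, collapse = paste0(" ", op, " ")), ")")
  }

  rxn_nodes <- xml2::xml_find_all(doc, ".//s:listOfReactions/s:reaction", ns)
  if (length(rxn_nodes) == 0) stop("SBML model '", path, "' has no reactions")
  rows <- lapply(rxn_nodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    if (is.na(id)) stop("SBML reaction without an id in '", path, "'")
    lb_ref <- xml2::xml_attr(rn, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rn, "upperFluxBound")
    lb <- if (is.na(lb_ref)) -1000 else unname(pvals[lb_ref])
    ub <- if (is.na(ub_ref)) 1000 else unname(pvals[ub_ref])
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rn, "./s:listOfReactants/s:speciesReference", ns)) {
      st[xml2::xml_attr(sr, "species")] <- -as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    for (sr in xml2::xml_find_all(rn, "./s:listOfProducts/s:speciesReference", ns)) {
      sp <- xml2::xml_attr(sr, "species")
      st[sp] <- (if (sp %in% names(st)) st[sp] else 0) +
        as.numeric(xml2::xml_attr(sr, "stoichiometry"))
    }
    gpa <- xml2::xml_find_first(rn, "./fbc:geneProductAssociation", ns)
    gpr <- NA_character_
    if (!inherits(gpa, "xml_missing")) {
      root <- xml2::xml_children(gpa)[[1]]
      gpr <- deparse_gpr(parse_gpr(gpa_to_string(root)))
    }
    tibble::tibble(id = id, stoich = list(st), lb = lb, ub = ub, gpr = gpr)
  })
  tbl <- dplyr::bind_rows(rows)
  if (anyDuplicated(tbl$id)) {
    stop("duplicate reaction id(s) in '", path, "': ",
         paste(unique(tbl$id[duplicated(tbl$id)]), collapse = ", "))
  }
  fo <- xml2::xml_find_all(doc, ".//fbc:listOfFluxObjectives/fbc:fluxObjective", ns)
  objective <- NULL
  if (length(fo) > 0) {
    objective <- stats::setNames(as.numeric(xml2::xml_attr(fo, "coefficient")),
                                 xml2::xml_attr(fo, "reaction"))
  }
  model <- metabolic_model(tbl, objective = objective)
  if (length(species) > 0 && setequal(species, model$metabolites)) {
    model$S <- model$S[species, , drop = FALSE]
    model$metabolites <- species
  }
  model
}

#' Read a gene or reaction evidence table (TSV)
#'
#' Two tab-separated columns: identifier and numeric value; a header line is
#' detected (non-numeric second field) and skipped.
#'
#' @param path TSV file path.
#' @return tibble with columns `id`, `value`.
#' @export
read_evidence <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1)
  f2 <- strsplit(first, "\t")[[1]]
  header <- length(f2) >= 2 && is.na(suppressWarnings(as.numeric(f2[2])))
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  tibble::tibble(id = as.character(df[[1]]), value = as.numeric(df[[2]]))
}

#' Read a core-reaction set (one reaction id per line)
#' @param path text file path.
#' @return character vector of reaction ids.
#' @export
read_core_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Read metabolic task definitions (TSV)
#'
#' Columns `task_id`, `reaction_id`, `coefficient` (one row per term),
#' optional `bound`; header optional.
#'
#' @param path TSV file path.
#' @return tibble suitable for [tinit()]'s `tasks` argument.
#' @export
read_tasks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- strsplit(readLines(path, n = 1), "\t")[[1]]
  header <- length(first) >= 3 && is.na(suppressWarnings(as.numeric(first[3])))
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  names(df)[1:3] <- c("task_id", "reaction_id", "coefficient")
  tibble::as_tibble(df)
}

#' Write a flux vector as TSV (reaction_id, flux)
#' @param flux named numeric vector or `flux_distribution`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_flux_tsv <- function(flux, path) {
  if (inherits(flux, "flux_distribution")) flux <- flux$flux
  utils::write.table(
    data.frame(reaction_id = names(flux), flux = as.numeric(flux)),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
}
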
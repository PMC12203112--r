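#' Read one community member's metabolic model from SBML
#'
#' Parses an SBML Level 3 file with fbc-style flux bounds and gene-product
#' associations into a `member_model`. Only the constraint-based subset is
#' read: compartments, species, reactions with stoichiometry and bounds, and
#' GPR rules. Bounds are resolved from `fbc:lowerFluxBound`/`fbc:upperFluxBound`
#' parameter references when present, otherwise from the `reversible` flag
#' with `default_bound` as magnitude. GPR associations are taken from the fbc
#' `geneProductAssociation` tree (gene products are reported by their
#' `fbc:label` when set, else their id); unparseable associations are dropped
#' with a warning and the reaction is treated as having no GPR.
#'
#' @param path Path to an SBML file.
#' @param member_id Identifier for this member; defaults to the file name
#'   without extension.
#' @param biomass_pattern Case-insensitive regular expression identifying the
#'   biomass reaction. Exactly one reaction must match.
#' @param default_bound Bound magnitude (mmol/gDW/h) used when a reaction
#'   carries no explicit flux-bound parameters.
#' @return A `member_model`: list with `member_id`, `mets` (tibble: `id`,
#'   `compartment`), `rxns` (tibble: `id`, `lb`, `ub`, `gpr`), sparse
#'   stoichiometric matrix `S` (metabolites x reactions), named list `gpr` of
#'   parsed [parse_gpr()] trees, and `biomass_reaction_id`.
#' @export
read_member_sbml <- function(path, member_id = NULL,
                             biomass_pattern = "biomass",
                             default_bound = 1000) {
  if (!file.exists(path)) stop("SBML file not found: ", path, call. = FALSE)
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("not readable as XML/SBML: ", path,
                                           " (", conditionMessage(e), ")", call. = FALSE))
  model <- xp1(doc, "model")
  if (is.null(member_id) || is.na(member_id)) {
    member_id <- sub("\\.(xml|sbml)$", "", basename(path), ignore.case = TRUE)
  }

  sp_nodes <- xp(doc, "species")
  if (length(sp_nodes) == 0L) stop("no species in SBML file: ", path, call. = FALSE)
  mets <- tibble::tibble(
    id = vapply(sp_nodes, attr_any, character(1), "id"),
    compartment = vapply(sp_nodes, attr_any, character(1), "compartment")
  )
  boundary <- vapply(sp_nodes, attr_any, character(1), "boundaryCondition")
  mets <- mets[is.na(boundary) | boundary != "true", , drop = FALSE]

  params <- xp(doc, "parameter")
  pval <- stats::setNames(
    suppressWarnings(as.numeric(vapply(params, attr_any, character(1), "value"))),
    vapply(params, attr_any, character(1), "id")
  )

  gp_nodes <- xp(doc, "geneProduct")
  gp_label <- stats::setNames(
    vapply(gp_nodes, function(n) {
      lab <- attr_any(n, "label")
      if (is.na(lab) || !nzchar(lab)) attr_any(n, "id") else lab
    }, character(1)),
    vapply(gp_nodes, attr_any, character(1), "id")
  )

  rxn_nodes <- xp(doc, "reaction")
  if (length(rxn_nodes) == 0L) stop("no reactions in SBML file: ", path, call. = FALSE)

  ids <- character(0); lbs <- ubs <- numeric(0)
  gprs <- list(); gpr_str <- character(0)
  stoich <- list()
  failures <- character(0)
  for (rn in rxn_nodes) {
    rid <- attr_any(rn, "id")
    rev <- identical(attr_any(rn, "reversible"), "true")
    lb <- resolve_bound(attr_any(rn, "lowerFluxBound"), pval,
                        if (rev) -default_bound else 0)
    ub <- resolve_bound(attr_any(rn, "upperFluxBound"), pval, default_bound)
    if (lb > ub) stop("reaction ", rid, " has lower bound > upper bound in ", path, call. = FALSE)
    sr <- function(xpath_tag, sign) {
      nodes <- xp(rn, "speciesReference", within = xpath_tag)
      if (length(nodes) == 0L) return(numeric(0))
      v <- suppressWarnings(as.numeric(vapply(nodes, attr_any, character(1), "stoichiometry")))
      v[is.na(v)] <- 1
      stats::setNames(sign * v, vapply(nodes, attr_any, character(1), "species"))
    }
    coef <- c(sr("listOfReactants", -1), sr("listOfProducts", 1))
    coef <- tapply(coef, names(coef), sum)  # collapse duplicated species refs
    gt <- NULL
    ga <- xp(rn, "geneProductAssociation")
    if (length(ga) > 0L) {
      gt <- tryCatch(parse_gpa_node(xml2::xml_children(ga[[1]])[[1]], gp_label),
                     error = function(e) {
                       failures <<- c(failures, rid)
                       NULL
                     })
    }
    ids <- c(ids, rid); lbs <- c(lbs, lb); ubs <- c(ubs, ub)
    stoich[[rid]] <- coef
    gpr_str <- c(gpr_str, if (is.null(gt)) NA_character_ else deparse_gpr(gt))
    if (!is.null(gt)) gprs[[rid]] <- gt
  }
  if (length(failures)) {
    warning("unparseable GPR association(s) treated as absent for reaction(s): ",
            paste(failures, collapse = ", "))
  }

  S <- Matrix::sparseMatrix(
    i = match(unlist(lapply(stoich, names), use.names = FALSE), mets$id),
    j = rep(seq_along(ids), lengths(stoich)),
    x = unlist(stoich, use.names = FALSE),
    dims = c(nrow(mets), length(ids)),
    dimnames = list(mets$id, ids)
  )
  if (anyNA(S@i)) stop("reaction references undeclared species in ", path, call. = FALSE)

  bm <- grep(biomass_pattern, ids, ignore.case = TRUE, value = TRUE)
  if (length(bm) == 0L) {
    stop("no biomass reaction matching pattern '", biomass_pattern, "' in ", path, call. = FALSE)
  }
  if (length(bm) > 1L) {
    stop("multiple reactions match biomass pattern '", biomass_pattern, "' in ", path,
         ": ", paste(bm, collapse = ", "), " - disambiguate the pattern", call. = FALSE)
  }

  structure(list(
    member_id = member_id,
    mets = mets,
    rxns = tibble::tibble(id = ids, lb = lbs, ub = ubs, gpr = gpr_str),
    S = S,
    gpr = gprs,
    biomass_reaction_id = bm,
    gpr_failures = failures
  ), class = "member_model")
}

# --- XML helpers: namespace-agnostic lookups -------------------------------

xp <- function(node, tag, within = NULL) {
  pre <- if (is.null(within)) ".//" else paste0(".//*[local-name()='", within, "']/")
  xml2::xml_find_all(node, paste0(pre, "*[local-name()='", tag, "']"))
}

xp1 <- function(node, tag) {
  res <- xp(node, tag)
  if (length(res) == 0L) stop("SBML element <", tag, "> not found", call. = FALSE)
  res[[1]]
}

# attribute by local name, ignoring any namespace prefix
attr_any <- function(node, name) {
  at <- xml2::xml_attrs(node)
  hit <- grep(paste0("(^|:)", name, "$"), names(at))
  if (length(hit) == 0L) NA_character_ else unname(at[hit[1]])
}

resolve_bound <- function(ref, pval, fallback) {
  if (is.na(ref)) return(fallback)
  v <- unname(pval[ref])
  if (length(v) == 0L || is.na(v)) fallback else v
}

parse_gpa_node <- function(node, gp_label) {
  nm <- xml2::xml_name(node)
  label_of <- function(id) {
    v <- unname(gp_label[id])
    if (length(v) == 0L || is.na(v)) id else v
  }
  if (nm == "geneProductRef") {
    gid <- attr_any(node, "geneProduct")
    if (is.na(gid)) stop("geneProductRef without geneProduct attribute")
    return(gpr_gene(label_of(gid)))
  }
  if (nm %in% c("and", "or")) {
    kids <- lapply(xml2::xml_children(node), parse_gpa_node, gp_label = gp_label)
    if (length(kids) < 2L) stop("fbc:", nm, " node with fewer than two children")
    return(gpr_node(nm, kids))
  }
  stop("unsupported geneProductAssociation node <", nm, ">")
}

# --- Writer ----------------------------------------------------------------

#' Write a member model to SBML
#'
#' Emits SBML Level 3 Version 1 with the fbc version 2 package: flux bounds as
#' shared parameters and GPR rules as `geneProductAssociation` trees. The
#' output round-trips through [read_member_sbml()].
#'
#' @param model A `member_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_member_sbml <- function(model, path) {
  stopifnot(inherits(model, "member_model"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  genes <- sort(unique(unlist(lapply(model$gpr, gpr_genes))))
  gene_id <- stats::setNames(paste0("G_", gsub("[^A-Za-z0-9_]", "_", genes)), genes)

  bounds <- sort(unique(c(model$rxns$lb, model$rxns$ub)))
  bkey <- function(v) format(v, digits = 15, trim = TRUE, scientific = FALSE)
  bid <- stats::setNames(paste0("fb_", seq_along(bounds)), bkey(bounds))
  bref <- function(v) unname(bid[bkey(v)])

  gpa_xml <- function(node) {
    if (node$type == "gene") {
      return(sprintf('<fbc:geneProductRef fbc:geneProduct="%s"/>', gene_id[node$gene]))
    }
    inner <- paste(vapply(node$children, gpa_xml, character(1)), collapse = "")
    sprintf("<fbc:%s>%s</fbc:%s>", node$type, inner, node$type)
  }

  comps <- unique(model$mets$compartment)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" ',
           'level="3" version="1" fbc:required="false">'),
    sprintf('<model id="%s" fbc:strict="true">', esc(model$member_id)),
    "<listOfCompartments>",
    sprintf('<compartment id="%s" constant="true"/>', esc(comps)),
    "</listOfCompartments>",
    "<listOfSpecies>",
    sprintf('<species id="%s" compartment="%s" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>',
            esc(model$mets$id), esc(model$mets$compartment)),
    "</listOfSpecies>",
    "<listOfParameters>",
    sprintf('<parameter id="%s" value="%s" constant="true"/>', unname(bid), names(bid)),
    "</listOfParameters>"
  )
  if (length(genes)) {
    lines <- c(lines, "<fbc:listOfGeneProducts>",
               sprintf('<fbc:geneProduct fbc:id="%s" fbc:label="%s"/>',
                       unname(gene_id), esc(genes)),
               "</fbc:listOfGeneProducts>")
  }
  lines <- c(lines, "<listOfReactions>")
  for (k in seq_len(nrow(model$rxns))) {
    r <- model$rxns[k, ]
    coef <- model$S[, r$id]
    nz <- which(coef != 0)
    sub <- nz[coef[nz] < 0]; prod <- nz[coef[nz] > 0]
    lines <- c(lines, sprintf(
      '<reaction id="%s" reversible="%s" fast="false" fbc:lowerFluxBound="%s" fbc:upperFluxBound="%s">',
      esc(r$id), if (r$lb < 0) "true" else "false", bref(r$lb), bref(r$ub)))
    if (length(sub)) {
      lines <- c(lines, "<listOfReactants>",
                 sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         esc(rownames(model$S)[sub]), format(-coef[sub], digits = 15)),
                 "</listOfReactants>")
    }
    if (length(prod)) {
      lines <- c(lines, "<listOfProducts>",
                 sprintf('<speciesReference species="%s" stoichiometry="%s" constant="true"/>',
                         esc(rownames(model$S)[prod]), format(coef[prod], digits = 15)),
                 "</listOfProducts>")
    }
    if (!is.null(model$gpr[[r$id]])) {
      lines <- c(lines, "<fbc:geneProductAssociation>",
                 gpa_xml(model$gpr[[r$id]]),
                 "</fbc:geneProductAssociation>")
    }
    lines <- c(lines, "</reaction>")
  }
  lines <- c(lines, "</listOfReactions>", "</model>", "</sbml>")
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.member_model <- function(x, ...) {
  cat("<member_model> ", x$member_id, ": ", nrow(x$mets), " metabolites, ",
      nrow(x$rxns), " reactions (", length(x$gpr), " with GPR), biomass = ",
      x$biomass_reaction_id, "\n", sep = "")
  invisible(x)
}
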
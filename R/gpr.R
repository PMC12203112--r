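#' Gene-protein-reaction (GPR) rules
#'
#' A GPR rule is a boolean expression over gene identifiers that states which
#' gene products can catalyse a reaction. `parse_gpr()` turns the conventional
#' string form (`"(g1 and g2) or g3"`) into a tree; [evaluate_gpr()] scores the
#' tree against per-gene expression, mapping AND to the minimum (an enzyme
#' complex is limited by its scarcest subunit) and OR to the sum (isoenzymes
#' contribute additively).
#'
#' Accepted operator spellings are `and`/`or` (case-insensitive), `&`/`|` and
#' `&&`/`||`. Parentheses group as usual; `and` binds tighter than `or`.
#'
#' @param x GPR rule as a character string.
#' @return An object of class `gpr`: a nested list with elements `type`
#'   (`"gene"`, `"and"` or `"or"`), and either `gene` (for leaves) or
#'   `children` (a list of `gpr` nodes, at least two).
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  toks <- gpr_tokenize(x)
  if (length(toks) == 0L) stop("empty GPR string", call. = FALSE)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st)
  if (st$pos <= length(st$toks)) {
    stop("trailing input in GPR string near '", st$toks[st$pos], "'", call. = FALSE)
  }
  tree
}

gpr_tokenize <- function(x) {
  x <- gsub("([()])", " \\1 ", x)
  toks <- strsplit(trimws(x), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[st$pos] else NA_character_

gpr_is_op <- function(tok, which) {
  !is.na(tok) && tolower(tok) %in% switch(which, and = c("and", "&", "&&"), or = c("or", "|", "||"))
}

gpr_parse_or <- function(st) {
  kids <- list(gpr_parse_and(st))
  while (gpr_is_op(gpr_peek(st), "or")) {
    st$pos <- st$pos + 1L
    kids <- c(kids, list(gpr_parse_and(st)))
  }
  if (length(kids) == 1L) kids[[1]] else gpr_node("or", kids)
}

gpr_parse_and <- function(st) {
  kids <- list(gpr_parse_atom(st))
  while (gpr_is_op(gpr_peek(st), "and")) {
    st$pos <- st$pos + 1L
    kids <- c(kids, list(gpr_parse_atom(st)))
  }
  if (length(kids) == 1L) kids[[1]] else gpr_node("and", kids)
}

gpr_parse_atom <- function(st) {
  tok <- gpr_peek(st)
  if (is.na(tok)) stop("unexpected end of GPR string", call. = FALSE)
  st$pos <- st$pos + 1L
  if (tok == "(") {
    inner <- gpr_parse_or(st)
    if (!identical(gpr_peek(st), ")")) stop("unbalanced parentheses in GPR string", call. = FALSE)
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tok == ")" || gpr_is_op(tok, "and") || gpr_is_op(tok, "or")) {
    stop("malformed GPR string near '", tok, "'", call. = FALSE)
  }
  gpr_gene(tok)
}

gpr_gene <- function(gene) structure(list(type = "gene", gene = gene), class = "gpr")

gpr_node <- function(type, children) {
  # collapse nested nodes of the same type so parsing is associativity-stable
  flat <- list()
  for (ch in children) {
    if (identical(ch$type, type)) flat <- c(flat, ch$children) else flat <- c(flat, list(ch))
  }
  structure(list(type = type, children = flat), class = "gpr")
}

#' @export
format.gpr <- function(x, ...) deparse_gpr(x)

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", deparse_gpr(x), "\n", sep = "")
  invisible(x)
}

#' Render a GPR tree back to its string form
#'
#' @param tree A `gpr` tree from [parse_gpr()].
#' @return A character string; re-parsing it yields the same tree.
#' @export
deparse_gpr <- function(tree) {
  stopifnot(inherits(tree, "gpr"))
  rec <- function(node, parent_or = FALSE) {
    switch(node$type,
      gene = node$gene,
      and = {
        parts <- vapply(node$children, function(ch) {
          s <- rec(ch)
          if (ch$type == "or") paste0("(", s, ")") else s
        }, character(1))
        paste(parts, collapse = " and ")
      },
      or = paste(vapply(node$children, rec, character(1)), collapse = " or ")
    )
  }
  rec(tree)
}

#' Genes referenced by a GPR tree
#'
#' @param tree A `gpr` tree.
#' @return Character vector of unique gene identifiers.
#' @export
gpr_genes <- function(tree) {
  stopifnot(inherits(tree, "gpr"))
  if (tree$type == "gene") return(tree$gene)
  unique(unlist(lapply(tree$children, gpr_genes)))
}

#' Score a GPR rule against gene expression
#'
#' Computes the reaction-level correction factor f(g) from per-gene expression
#' theta: a leaf evaluates to theta(gene), an AND node to the minimum of its
#' children and an OR node to the sum of its children. Genes absent from
#' `theta` count as 0 — metatranscriptomes are sparse, and the relaxation
#' variables of the community LP exist to rescue reactions silenced this way.
#'
#' @param tree A `gpr` tree from [parse_gpr()].
#' @param theta Named numeric vector of nonnegative expression values (TPM),
#'   names are gene identifiers.
#' @return A single nonnegative number.
#' @examples
#' evaluate_gpr(parse_gpr("(g1 and g2) or g3"), c(g1 = 4, g2 = 6, g3 = 2))
#' @export
evaluate_gpr <- function(tree, theta) {
  stopifnot(inherits(tree, "gpr"))
  if (length(theta) && (is.null(names(theta)) || anyNA(names(theta)))) {
    stop("`theta` must be a named numeric vector", call. = FALSE)
  }
  rec <- function(node) {
    switch(node$type,
      gene = {
        v <- unname(theta[node$gene])
        if (length(v) == 0L || is.na(v)) 0 else v
      },
      and = min(vapply(node$children, rec, numeric(1))),
      or = sum(vapply(node$children, rec, numeric(1)))
    )
  }
  rec(tree)
}
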
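#' Parse a gene-protein-reaction rule
#'
#' Rules use gene identifiers, parentheses and the connectives `and` / `or`
#' (case-insensitive). `and` denotes an enzyme complex (all subunits
#' required), `or` isozymes (any suffices); `and` binds tighter than `or`.
#' Nested same-kind nodes are flattened so every AND/OR node has at least
#' two children and re-serialisation is canonical.
#'
#' @param rule Rule string; empty/whitespace or `NULL` yields `NULL`,
#'   meaning the reaction is not gene-gated.
#' @return A GPR tree (class `gpr`): either
#'   `list(kind = "gene", gene = <id>)` or
#'   `list(kind = "and"|"or", children = <list of trees>)`; or `NULL`.
#' @export
#' @examples
#' parse_gpr("(g1 or g2) and g3")
parse_gpr <- function(rule) {
  if (is.null(rule)) return(NULL)
  stopifnot(is.character(rule), length(rule) == 1L)
  if (!nzchar(trimws(rule))) return(NULL)

  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L

  peek <- function() if (st$i <= nrow(st$toks)) st$toks$type[st$i] else "eof"
  take <- function() { t <- st$toks[st$i, ]; st$i <- st$i + 1L; t }
  fail <- function(msg) {
    pos <- if (st$i <= nrow(st$toks)) st$toks$pos[st$i] else nchar(rule) + 1L
    stop(sprintf("GPR parse error at position %d: %s in rule '%s'",
                 pos, msg, rule), call. = FALSE)
  }

  parse_or <- function() {
    kids <- list(parse_and())
    while (peek() == "or") { take(); kids <- c(kids, list(parse_and())) }
    gpr_node("or", kids)
  }
  parse_and <- function() {
    kids <- list(parse_atom())
    while (peek() == "and") { take(); kids <- c(kids, list(parse_atom())) }
    gpr_node("and", kids)
  }
  parse_atom <- function() {
    tp <- peek()
    if (tp == "gene") {
      structure(list(kind = "gene", gene = take()$text), class = "gpr")
    } else if (tp == "lpar") {
      take()
      inner <- parse_or()
      if (peek() != "rpar") fail("expected ')'")
      take()
      inner
    } else fail(sprintf("expected gene or '(', found %s", tp))
  }

  tree <- parse_or()
  if (peek() != "eof") fail("trailing input")
  tree
}

gpr_tokenize <- function(rule) {
  pat <- "\\(|\\)|[^\\s()]+"
  m <- gregexpr(pat, rule, perl = TRUE)[[1]]
  texts <- regmatches(rule, gregexpr(pat, rule, perl = TRUE))[[1]]
  type <- vapply(texts, function(t) {
    switch(tolower(t), "(" = "lpar", ")" = "rpar",
           "and" = "and", "or" = "or", "&" = "and", "|" = "or", "gene")
  }, character(1), USE.NAMES = FALSE)
  data.frame(text = texts, type = type, pos = as.integer(m),
             stringsAsFactors = FALSE)
}

gpr_node <- function(kind, children) {
  if (length(children) == 1L) return(children[[1]])
  # flatten nested same-kind nodes for canonical form
  flat <- list()
  for (ch in children) {
    if (!is.null(ch$kind) && ch$kind == kind && !is.null(ch$children))
      flat <- c(flat, ch$children)
    else flat <- c(flat, list(ch))
  }
  structure(list(kind = kind, children = flat), class = "gpr")
}

#' Serialise a GPR tree back to rule text
#' @param gpr A GPR tree or `NULL`.
#' @return Rule string (`""` for `NULL`).
#' @export
deparse_gpr <- function(gpr) {
  if (is.null(gpr)) return("")
  if (gpr$kind == "gene") return(gpr$gene)
  sep <- if (gpr$kind == "and") " and " else " or "
  parts <- vapply(gpr$children, function(ch) {
    s <- deparse_gpr(ch)
    # parenthesise an OR child under AND to preserve precedence
    if (gpr$kind == "and" && !is.null(ch$kind) && ch$kind == "or")
      s <- paste0("(", s, ")")
    s
  }, character(1))
  paste(parts, collapse = sep)
}

#' Genes referenced by a GPR tree
#' @param gpr A GPR tree or `NULL`.
#' @return Character vector of gene identifiers (unique, unsorted).
#' @export
gpr_genes <- function(gpr) {
  if (is.null(gpr)) return(character())
  if (gpr$kind == "gene") return(gpr$gene)
  unique(unlist(lapply(gpr$children, gpr_genes)))
}

#' Evaluate a GPR tree over continuous gene activities
#'
#' Continuous Boolean semantics: a GENE leaf takes its activity in
#' `[0, 1]`, AND takes the minimum of its children (complex limited by its
#' scarcest subunit) and OR the maximum (best isozyme). Genes absent from
#' `gene_values` default to 1 (fully available).
#'
#' @param gpr GPR tree or `NULL` (evaluates to 1: not gene-gated).
#' @param gene_values Named numeric vector of activities in `[0, 1]`.
#' @return Scalar in `[0, 1]`.
#' @export
evaluate_gpr <- function(gpr, gene_values = numeric()) {
  if (is.null(gpr)) return(1)
  if (gpr$kind == "gene") {
    v <- gene_values[gpr$gene]
    return(if (!length(v) || is.na(v)) 1 else unname(v))
  }
  vals <- vapply(gpr$children, evaluate_gpr, numeric(1),
                 gene_values = gene_values)
  if (gpr$kind == "and") min(vals) else max(vals)
}
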
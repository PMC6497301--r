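#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers linking genes to a
#' reaction's availability, e.g. \code{"(g1 and g2) or g3"} for an isozyme of
#' a two-subunit complex.  The grammar accepts case-insensitive \code{and} /
#' \code{or}, parentheses and bare identifiers; \code{not} is not part of the
#' grammar.  An empty rule means the reaction has no gene requirement and is
#' always available.
#'
#' @param rule character scalar, the rule text (may be \code{""}).
#' @return an object of class \code{gpr}: a nested expression tree, or
#'   \code{NULL} for the empty rule.
#' @examples
#' tree <- parse_gpr("(g1 and g2) or g3")
#' eval_gpr(tree, knocked_out = "g1")   # TRUE, g3 rescues
#' eval_gpr(tree, knocked_out = c("g1", "g3"))
#' @export
parse_gpr <- function(rule) {
  stopifnot(is.character(rule), length(rule) == 1L)
  if (is.na(rule) || !nzchar(trimws(rule)))
    return(structure(list(op = "true", args = list()), class = "gpr"))
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  tree <- gpr_parse_or(st, rule)
  if (st$pos <= length(st$toks$type))
    stop(sprintf("GPR parse error at position %d in %s: unexpected '%s'",
                 st$toks$at[st$pos], sQuote(rule), st$toks$text[st$pos]))
  structure(tree, class = "gpr")
}

gpr_tokenize <- function(rule) {
  text <- character(0); type <- character(0); at <- integer(0)
  i <- 1L; nc <- nchar(rule)
  while (i <= nc) {
    ch <- substr(rule, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      text <- c(text, ch); type <- c(type, ch); at <- c(at, i)
      i <- i + 1L; next
    }
    m <- regmatches(substr(rule, i, nc),
                    regexpr("^[^()[:space:]]+", substr(rule, i, nc)))
    word <- m[[1]]
    lw <- tolower(word)
    type <- c(type, if (lw %in% c("and", "or")) lw else "id")
    text <- c(text, word); at <- c(at, i)
    i <- i + nchar(word)
  }
  list(text = text, type = type, at = at)
}

gpr_peek <- function(st) {
  if (st$pos > length(st$toks$type)) "eof" else st$toks$type[st$pos]
}

gpr_parse_or <- function(st, rule) {
  args <- list(gpr_parse_and(st, rule))
  while (gpr_peek(st) == "or") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_and(st, rule)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gpr_parse_and <- function(st, rule) {
  args <- list(gpr_parse_primary(st, rule))
  while (gpr_peek(st) == "and") {
    st$pos <- st$pos + 1L
    args <- c(args, list(gpr_parse_primary(st, rule)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gpr_parse_primary <- function(st, rule) {
  tp <- gpr_peek(st)
  if (tp == "eof")
    stop(sprintf("GPR parse error at position %d in %s: unexpected end of rule",
                 nchar(rule) + 1L, sQuote(rule)))
  if (tp == "(") {
    st$pos <- st$pos + 1L
    inner <- gpr_parse_or(st, rule)
    if (gpr_peek(st) != ")")
      stop(sprintf("GPR parse error at position %d in %s: expected ')'",
                   if (st$pos > length(st$toks$at)) nchar(rule) + 1L
                   else st$toks$at[st$pos], sQuote(rule)))
    st$pos <- st$pos + 1L
    return(inner)
  }
  if (tp == "id") {
    id <- st$toks$text[st$pos]
    st$pos <- st$pos + 1L
    return(list(op = "gene", gene = id, args = list()))
  }
  stop(sprintf("GPR parse error at position %d in %s: unexpected '%s'",
               st$toks$at[st$pos], sQuote(rule), st$toks$text[st$pos]))
}

#' Evaluate a GPR expression tree
#'
#' Returns \code{FALSE} exactly when the rule cannot be satisfied with the
#' given genes absent.  Supply either the set of present genes or the set of
#' knocked-out genes (any gene not listed as knocked out counts as present).
#'
#' @param tree a \code{gpr} tree from [parse_gpr()].
#' @param present character vector of present genes, or \code{NULL} to treat
#'   all genes except \code{knocked_out} as present.
#' @param knocked_out character vector of absent genes (used when
#'   \code{present} is \code{NULL}).
#' @return logical scalar.
#' @export
eval_gpr <- function(tree, present = NULL, knocked_out = character(0)) {
  rec <- function(node) {
    switch(node$op,
      "true" = TRUE,
      "gene" = if (is.null(present)) !(node$gene %in% knocked_out)
               else node$gene %in% present,
      "and"  = all(vapply(node$args, rec, logical(1))),
      "or"   = any(vapply(node$args, rec, logical(1))),
      stop("invalid GPR node"))
  }
  rec(unclass(tree))
}

#' Genes referenced by a GPR tree
#' @param tree a \code{gpr} tree from [parse_gpr()].
#' @return character vector of unique gene identifiers (empty for the empty
#'   rule).
#' @export
gpr_genes <- function(tree) {
  rec <- function(node) {
    if (node$op == "gene") return(node$gene)
    if (node$op == "true") return(character(0))
    unlist(lapply(node$args, rec))
  }
  unique(rec(unclass(tree)))
}

# render a tree back to rule text (used by the SBML writer)
gpr_deparse <- function(tree) {
  rec <- function(node) {
    switch(node$op,
      "true" = "",
      "gene" = node$gene,
      "and"  = paste0("(", paste(vapply(node$args, rec, character(1)),
                                 collapse = " and "), ")"),
      "or"   = paste0("(", paste(vapply(node$args, rec, character(1)),
                                 collapse = " or "), ")"))
  }
  rec(unclass(tree))
}
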
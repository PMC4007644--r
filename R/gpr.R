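# Gene-protein-reaction (GPR) boolean expressions.
#
# A GPR is a finite boolean tree over gene identifiers: leaves are genes,
# internal nodes are AND (all subunits of a complex required) or OR
# (isozymes, any one suffices).  The empty GPR means "no gene association":
# the reaction is always catalysable and unaffected by gene deletions.

#' Construct GPR expressions
#'
#' `gpr_gene()` builds a leaf, `gpr_and()`/`gpr_or()` combine sub-expressions,
#' and `gpr_empty()` denotes a reaction with no gene association.
#'
#' @param gene Single gene identifier (character).
#' @param ... GPR expressions to combine.
#' @return An object of class `gpr`.
#' @examples
#' gpr_or(gpr_and(gpr_gene("g1"), gpr_gene("g2")), gpr_gene("g3"))
#' @export
gpr_gene <- function(gene) {
  stopifnot(is.character(gene), length(gene) == 1L, nzchar(gene))
  structure(list(op = "gene", gene = gene), class = "gpr")
}

#' @rdname gpr_gene
#' @export
gpr_and <- function(...) {
  args <- gpr_args(list(...))
  if (length(args) == 1L) return(args[[1L]])
  structure(list(op = "and", args = args), class = "gpr")
}

#' @rdname gpr_gene
#' @export
gpr_or <- function(...) {
  args <- gpr_args(list(...))
  if (length(args) == 1L) return(args[[1L]])
  structure(list(op = "or", args = args), class = "gpr")
}

#' @rdname gpr_gene
#' @export
gpr_empty <- function() {
  structure(list(op = "empty"), class = "gpr")
}

gpr_args <- function(args) {
  stopifnot(length(args) >= 1L)
  lapply(args, function(a) {
    if (!inherits(a, "gpr")) stop("arguments must be gpr expressions")
    if (a$op == "empty") stop("empty GPR cannot be combined with and/or")
    a
  })
}

#' @export
print.gpr <- function(x, ...) {
  cat("<gpr> ", deparse_gpr(x), "\n", sep = "")
  invisible(x)
}

is_gpr_empty <- function(gpr) {
  is.null(gpr) || (inherits(gpr, "gpr") && gpr$op == "empty")
}

#' Evaluate a GPR under a set of gene deletions
#'
#' Returns `TRUE` if the reaction remains catalysable when `deleted_genes`
#' are knocked out.  The empty GPR always evaluates `TRUE`.
#'
#' @param gpr A `gpr` expression.
#' @param deleted_genes Character vector of deleted gene ids.
#' @return Logical scalar: is the reaction still active?
#' @examples
#' evaluate_gpr(gpr_or(gpr_gene("g1"), gpr_gene("g2")), "g1")  # TRUE
#' evaluate_gpr(gpr_and(gpr_gene("g1"), gpr_gene("g2")), "g1") # FALSE
#' @export
evaluate_gpr <- function(gpr, deleted_genes = character()) {
  if (is_gpr_empty(gpr)) return(TRUE)
  switch(gpr$op,
    gene = !(gpr$gene %in% deleted_genes),
    and  = all(vapply(gpr$args, evaluate_gpr, logical(1), deleted_genes)),
    or   = any(vapply(gpr$args, evaluate_gpr, logical(1), deleted_genes)),
    stop("malformed gpr node: ", gpr$op)
  )
}

#' Genes referenced by a GPR
#'
#' @param gpr A `gpr` expression.
#' @return Character vector of distinct gene ids (empty for the empty GPR).
#' @export
gpr_genes <- function(gpr) {
  if (is_gpr_empty(gpr)) return(character())
  switch(gpr$op,
    gene = gpr$gene,
    unique(unlist(lapply(gpr$args, gpr_genes)))
  )
}

#' Remove genes from a GPR
#'
#' Substitutes `FALSE` for the given genes and simplifies.  Returns `NULL`
#' when the expression becomes unsatisfiable (the reaction can no longer be
#' catalysed by the remaining genes); the empty GPR is returned unchanged.
#'
#' @param gpr A `gpr` expression.
#' @param genes Character vector of gene ids to treat as permanently absent.
#' @return A simplified `gpr`, or `NULL` if unsatisfiable.
#' @export
gpr_prune <- function(gpr, genes) {
  if (is_gpr_empty(gpr)) return(gpr_empty())
  switch(gpr$op,
    gene = if (gpr$gene %in% genes) NULL else gpr,
    and = {
      kept <- lapply(gpr$args, gpr_prune, genes)
      if (any(vapply(kept, is.null, logical(1)))) return(NULL)
      if (length(kept) == 1L) kept[[1L]] else structure(list(op = "and", args = kept), class = "gpr")
    },
    or = {
      kept <- Filter(Negate(is.null), lapply(gpr$args, gpr_prune, genes))
      if (length(kept) == 0L) return(NULL)
      if (length(kept) == 1L) kept[[1L]] else structure(list(op = "or", args = kept), class = "gpr")
    }
  )
}

#' Translate GPR genes through a mapping
#'
#' Each leaf gene is replaced by the OR of its mapped target genes (e.g.
#' co-orthologs in another strain).  A leaf with no targets becomes
#' unsatisfiable; an unsatisfiable tree yields `NULL`.
#'
#' @param gpr A `gpr` expression.
#' @param mapping Named list: source gene id -> character vector of target
#'   gene ids (possibly empty).  Genes absent from the mapping count as
#'   having no targets.
#' @return A translated `gpr`, or `NULL` if unsatisfiable.
#' @export
gpr_translate <- function(gpr, mapping) {
  if (is_gpr_empty(gpr)) return(gpr_empty())
  switch(gpr$op,
    gene = {
      targets <- mapping[[gpr$gene]]
      if (is.null(targets) || length(targets) == 0L) return(NULL)
      do.call(gpr_or, lapply(targets, gpr_gene))
    },
    and = {
      kept <- lapply(gpr$args, gpr_translate, mapping)
      if (any(vapply(kept, is.null, logical(1)))) return(NULL)
      if (length(kept) == 1L) kept[[1L]] else structure(list(op = "and", args = kept), class = "gpr")
    },
    or = {
      kept <- Filter(Negate(is.null), lapply(gpr$args, gpr_translate, mapping))
      if (length(kept) == 0L) return(NULL)
      if (length(kept) == 1L) kept[[1L]] else structure(list(op = "or", args = kept), class = "gpr")
    }
  )
}

#' Parse a GPR string
#'
#' Accepts the conventional boolean syntax used in SBML notes and model
#' tables: gene identifiers combined with `and`/`or` (case-insensitive; `&`
#' and `|` also accepted) and parentheses.  `or` binds less tightly than
#' `and`.  An empty or blank string yields the empty GPR.
#'
#' @param text GPR string, e.g. `"(g1 and g2) or g3"`.
#' @return A `gpr` expression.
#' @export
parse_gpr <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- gsub("&&|&", " and ", text)
  text <- gsub("\\|\\||\\|", " or ", text)
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()[:space:]]+", text))[[1]]
  if (length(toks) == 0L) return(gpr_empty())
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- toks[pos]; pos <<- pos + 1L; t }
  parse_or <- function() {
    args <- list(parse_and())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1L]] else do.call(gpr_or, args)
  }
  parse_and <- function() {
    args <- list(parse_atom())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take()
      args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1L) args[[1L]] else do.call(gpr_and, args)
  }
  parse_atom <- function() {
    t <- peek()
    if (is.na(t)) stop("unexpected end of GPR string: ", text)
    if (t == "(") {
      take()
      e <- parse_or()
      if (is.na(peek()) || take() != ")") stop("unbalanced parentheses in GPR: ", text)
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or")) stop("unexpected token '", t, "' in GPR: ", text)
    gpr_gene(take())
  }
  out <- parse_or()
  if (!is.na(peek())) stop("trailing tokens in GPR: ", text)
  out
}

#' Render a GPR as a string
#'
#' Inverse of [parse_gpr()] up to parenthesisation; the empty GPR renders as
#' `""`.
#'
#' @param gpr A `gpr` expression.
#' @return A character scalar.
#' @export
deparse_gpr <- function(gpr) {
  if (is_gpr_empty(gpr)) return("")
  rec <- function(g, parent) {
    switch(g$op,
      gene = g$gene,
      and = {
        s <- paste(vapply(g$args, rec, character(1), "and"), collapse = " and ")
        if (parent == "or") s else if (parent == "top") s else paste0("(", s, ")")
      },
      or = {
        s <- paste(vapply(g$args, rec, character(1), "or"), collapse = " or ")
        if (parent == "top") s else paste0("(", s, ")")
      }
    )
  }
  rec(gpr, "top")
}
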
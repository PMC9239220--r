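#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers with the
#' case-insensitive keywords `and` / `or` and parentheses; `and` binds
#' tighter than `or` (complex subunits group before isozyme
#' alternatives). The empty string denotes a reaction with no gene
#' association.
#'
#' @param text Character scalar with the rule, e.g. `"g1 or g2 and g3"`.
#' @return A GPR expression tree: `NULL` for the empty rule, a character
#'   scalar for a single gene, or a list with elements `op` (`"and"` or
#'   `"or"`) and `args` (list of subtrees).
#' @examples
#' parseGpr("HXK1 or HXK2")
#' parseGpr("(PDA1 and PDB1) or LAT1")
#' @seealso [evaluateGpr()], [renderGpr()], [gprGenes()]
#' @export
parseGpr <- function(text) {
  if (length(text) != 1L || is.na(text))
    stop("GPR rule must be a single character string")
  toks <- .gprTokenize(text)
  if (nrow(toks) == 0L) return(NULL)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- .gprParseOr(st)
  if (st$pos <= nrow(st$toks))
    stop(sprintf("GPR parse error at position %d: unexpected '%s'",
                 st$toks$start[st$pos], st$toks$text[st$pos]))
  expr
}

.gprTokenize <- function(text) {
  out <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      out[[length(out) + 1L]] <- data.frame(type = ch, text = ch, start = i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(text, i, n),
                    regexpr("^[^()\\s]+", substr(text, i, n), perl = TRUE))
    word <- m[1]
    type <- if (tolower(word) == "and") "and"
            else if (tolower(word) == "or") "or"
            else "gene"
    out[[length(out) + 1L]] <- data.frame(type = type, text = word, start = i)
    i <- i + nchar(word)
  }
  if (length(out) == 0L)
    data.frame(type = character(), text = character(), start = integer())
  else do.call(rbind, out)
}

.gprPeek <- function(st) {
  if (st$pos > nrow(st$toks)) NULL else st$toks[st$pos, ]
}

.gprParseOr <- function(st) {
  args <- list(.gprParseAnd(st))
  repeat {
    tk <- .gprPeek(st)
    if (is.null(tk) || tk$type != "or") break
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- .gprParseAnd(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
}

.gprParseAnd <- function(st) {
  args <- list(.gprParseAtom(st))
  repeat {
    tk <- .gprPeek(st)
    if (is.null(tk) || tk$type != "and") break
    st$pos <- st$pos + 1L
    args[[length(args) + 1L]] <- .gprParseAtom(st)
  }
  if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
}

.gprParseAtom <- function(st) {
  tk <- .gprPeek(st)
  if (is.null(tk))
    stop("GPR parse error: dangling operator at end of rule")
  if (tk$type == "gene") {
    st$pos <- st$pos + 1L
    return(tk$text)
  }
  if (tk$type == "(") {
    open_at <- tk$start
    st$pos <- st$pos + 1L
    inner <- .gprParseOr(st)
    tk2 <- .gprPeek(st)
    if (is.null(tk2) || tk2$type != ")")
      stop(sprintf("GPR parse error: unbalanced '(' opened at position %d",
                   open_at))
    st$pos <- st$pos + 1L
    return(inner)
  }
  stop(sprintf("GPR parse error at position %d: unexpected '%s'",
               tk$start, tk$text))
}

#' Evaluate a GPR rule against gene-level values
#'
#' Implements the standard omics-to-reaction mapping: AND nodes take the
#' minimum of their children (a complex is as available as its scarcest
#' subunit) and OR nodes take the maximum (isozymes are interchangeable).
#' Genes without a measured value are skipped at their parent node; a
#' rule in which no leaf is measured, or the empty rule, evaluates to
#' `NA` (the unmapped marker). Missing data is a defined state, never an
#' error.
#'
#' @param gpr A parsed GPR expression (see [parseGpr()]).
#' @param geneValues Named numeric vector of gene-level values; genes may
#'   be absent or `NA`.
#' @return Numeric scalar, or `NA_real_` when the rule is unmapped.
#' @examples
#' evaluateGpr(parseGpr("g1 and g2"), c(g1 = 2, g2 = 6))  # 2
#' evaluateGpr(parseGpr("g1 or g2"),  c(g1 = 2, g2 = 6))  # 6
#' @export
evaluateGpr <- function(gpr, geneValues) {
  if (is.null(gpr)) return(NA_real_)
  if (is.character(gpr)) {
    v <- geneValues[gpr]
    return(if (length(v) == 0L || is.na(v)) NA_real_ else unname(v))
  }
  vals <- vapply(gpr$args, evaluateGpr, numeric(1), geneValues = geneValues)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  if (gpr$op == "and") min(vals) else max(vals)
}

#' Render a GPR expression back to rule text
#'
#' Inverse of [parseGpr()] up to whitespace and redundant parentheses:
#' `parseGpr(renderGpr(parseGpr(x)))` equals `parseGpr(x)`.
#'
#' @param gpr A parsed GPR expression.
#' @return Character scalar (empty string for the empty rule).
#' @export
renderGpr <- function(gpr) {
  if (is.null(gpr)) return("")
  if (is.character(gpr)) return(gpr)
  sep <- paste0(" ", gpr$op, " ")
  parts <- vapply(gpr$args, function(a) {
    s <- renderGpr(a)
    # parenthesize OR children under AND to preserve precedence
    if (gpr$op == "and" && is.list(a) && a$op == "or") paste0("(", s, ")")
    else s
  }, character(1))
  paste(parts, collapse = sep)
}

#' Genes referenced by a GPR expression
#'
#' @param gpr A parsed GPR expression.
#' @return Sorted character vector of unique gene ids (empty for the
#'   empty rule).
#' @export
gprGenes <- function(gpr) {
  if (is.null(gpr)) return(character())
  if (is.character(gpr)) return(gpr)
  sort(unique(unlist(lapply(gpr$args, gprGenes))))
}
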
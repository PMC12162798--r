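## .bnet parsing and serialization.
##
## Format: one "target, expression" line per variable; "#" starts a comment;
## an optional "targets, factors" header is ignored; expressions use variable
## names, !, &, | and parentheses, plus the constants 0 and 1. "&" binds
## tighter than "|", "!" tighter than both.

MAX_IN_DEGREE <- 20L

#' Parse a Boolean network from .bnet text
#'
#' @param text Either a single string containing the whole document, a
#'   character vector of lines, or a file path (when `is_file = TRUE`).
#' @param is_file Treat `text` as a path to read.
#' @return A normalized `boolean_network` (non-essential inputs pruned).
#' @examples
#' parse_bnet("A, B\nB, A")
#' @export
parse_bnet <- function(text, is_file = FALSE) {
  if (is_file) text <- readLines(text, warn = FALSE)
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  lines <- sub("#.*$", "", text)
  targets <- character(0)
  exprs <- character(0)
  linenos <- integer(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    comma <- regexpr(",", ln, fixed = TRUE)
    if (comma < 0L) stop("line ", i, ": expected 'target, expression'")
    tgt <- trimws(substr(ln, 1L, comma - 1L))
    rhs <- trimws(substr(ln, comma + 1L, nchar(ln)))
    if (tolower(tgt) == "targets" && tolower(rhs) == "factors") next
    if (!grepl("^[A-Za-z_][A-Za-z0-9_]*$", tgt)) {
      stop("line ", i, ": invalid target name '", tgt, "'")
    }
    if (tgt %in% targets) stop("line ", i, ": duplicate target '", tgt, "'")
    if (rhs == "") stop("line ", i, ": empty expression")
    targets <- c(targets, tgt)
    exprs <- c(exprs, rhs)
    linenos <- c(linenos, i)
  }
  if (length(targets) == 0L) stop("no update rules found")
  functions <- vector("list", length(targets))
  names(functions) <- targets
  for (j in seq_along(targets)) {
    ast <- tryCatch(parse_bool_expression(exprs[j]),
                    error = function(e) {
                      stop("line ", linenos[j], ": ", conditionMessage(e),
                           call. = FALSE)
                    })
    vars <- bool_expr_vars(ast)
    bad <- setdiff(vars, targets)
    if (length(bad) > 0L) {
      stop("line ", linenos[j], ": undefined variable(s) ",
           paste(bad, collapse = ", "), " in expression for ", targets[j])
    }
    if (length(vars) > MAX_IN_DEGREE) {
      stop("line ", linenos[j], ": expression for ", targets[j], " has ",
           length(vars), " inputs (limit ", MAX_IN_DEGREE, ")")
    }
    functions[[j]] <- list(inputs = vars, tt = bool_expr_tt(ast, vars))
  }
  boolean_network(targets, functions, normalize = TRUE)
}

#' Serialize a Boolean network to .bnet text
#'
#' Variables are emitted in declaration order; each update function is written
#' as the full disjunctive normal form of its truth table (constants as `0` or
#' `1`), so `parse_bnet(write_bnet(net))` is the identity on normalized
#' networks.
#'
#' @param net A `boolean_network`.
#' @param file Optional path to write to.
#' @return The document as a single string (invisibly when `file` is given).
#' @export
write_bnet <- function(net, file = NULL) {
  lines <- c("targets, factors",
             vapply(net$variables, function(v) {
               fn <- net$functions[[v]]
               paste0(v, ", ", function_to_expression(fn$inputs, fn$tt))
             }, character(1)))
  doc <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(sub("\n$", "", doc), file)
    return(invisible(doc))
  }
  doc
}

## full-DNF rendering of a truth table
function_to_expression <- function(inputs, tt) {
  k <- length(inputs)
  if (k == 0L) return(as.character(tt[1L]))
  on <- which(tt == 1L) - 1L
  if (length(on) == 0L) return("0")
  if (length(on) == 2L^k) return("1")
  terms <- vapply(on, function(m) {
    lits <- vapply(seq_len(k), function(j) {
      if (bitwAnd(bitwShiftR(m, j - 1L), 1L) == 1L) inputs[j]
      else paste0("!", inputs[j])
    }, character(1))
    paste(lits, collapse = " & ")
  }, character(1))
  paste(terms, collapse = " | ")
}

## ---- recursive-descent expression parser -----------------------------------

## Tokens: NAME, 0, 1, !, &, |, (, ). AST: list(op = "var"/"const"/"not"/
## "and"/"or", ...)

tokenize_bool <- function(expr) {
  pat <- "[A-Za-z_][A-Za-z0-9_]*|[01]|[!&|()]|\\s+"
  pos <- 1L
  n <- nchar(expr)
  tokens <- character(0)
  while (pos <= n) {
    m <- regexpr(pat, substr(expr, pos, n))
    if (m != 1L) {
      stop("malformed expression: unexpected character '",
           substr(expr, pos, pos), "'")
    }
    len <- attr(m, "match.length")
    tok <- substr(expr, pos, pos + len - 1L)
    if (!grepl("^\\s+$", tok)) tokens <- c(tokens, tok)
    pos <- pos + len
  }
  tokens
}

parse_bool_expression <- function(expr) {
  tokens <- tokenize_bool(expr)
  env <- new.env()
  env$tokens <- tokens
  env$pos <- 1L
  peek <- function() if (env$pos <= length(env$tokens)) env$tokens[env$pos] else NA_character_
  advance <- function() {
    t <- peek()
    env$pos <- env$pos + 1L
    t
  }
  parse_or <- function() {
    node <- parse_and()
    while (!is.na(peek()) && peek() == "|") {
      advance()
      node <- list(op = "or", lhs = node, rhs = parse_and())
    }
    node
  }
  parse_and <- function() {
    node <- parse_atom()
    while (!is.na(peek()) && peek() == "&") {
      advance()
      node <- list(op = "and", lhs = node, rhs = parse_atom())
    }
    node
  }
  parse_atom <- function() {
    t <- advance()
    if (is.na(t)) stop("malformed expression: unexpected end of input")
    if (t == "!") return(list(op = "not", arg = parse_atom()))
    if (t == "(") {
      node <- parse_or()
      if (is.na(peek()) || advance() != ")") {
        stop("malformed expression: missing ')'")
      }
      return(node)
    }
    if (t %in% c("0", "1")) return(list(op = "const", value = as.integer(t)))
    if (grepl("^[A-Za-z_][A-Za-z0-9_]*$", t)) return(list(op = "var", name = t))
    stop("malformed expression: unexpected token '", t, "'")
  }
  node <- parse_or()
  if (!is.na(peek())) stop("malformed expression: trailing token '", peek(), "'")
  node
}

bool_expr_vars <- function(ast) {
  switch(ast$op,
         var = ast$name,
         const = character(0),
         not = bool_expr_vars(ast$arg),
         unique(c(bool_expr_vars(ast$lhs), bool_expr_vars(ast$rhs))))
}

## evaluate the AST over all assignments of `vars` (first variable = LSB)
bool_expr_tt <- function(ast, vars) {
  k <- length(vars)
  idx <- 0:(max(2L^k, 1L) - 1L)
  ev <- function(node) {
    switch(node$op,
           var = bitwAnd(bitwShiftR(idx, match(node$name, vars) - 1L), 1L),
           const = rep(node$value, length(idx)),
           not = 1L - ev(node$arg),
           and = ev(node$lhs) * ev(node$rhs),
           or = pmax(ev(node$lhs), ev(node$rhs)))
  }
  as.integer(ev(ast))
}

#' Build a standalone Boolean function from an expression string
#'
#' Inputs are taken in order of first appearance in the expression; no
#' essentiality pruning is applied, so the function is over exactly the
#' variables written (useful for canalization measures of a given rule).
#'
#' @param expr Expression string, e.g. `"A | B & C"`.
#' @return A list with elements `inputs` and `tt`.
#' @export
boolean_function <- function(expr) {
  ast <- parse_bool_expression(expr)
  vars <- bool_expr_vars(ast)
  if (length(vars) > MAX_IN_DEGREE) stop("too many inputs")
  list(inputs = vars, tt = bool_expr_tt(ast, vars))
}
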
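# Trait formula engine: arithmetic expressions over canonical band/trait
# variables, evaluated element-wise with missing-value guards (division by
# zero, negative sqrt and any missing input all yield missing).

.FORMULA_FUNCTIONS <- c("sqrt")

.tokenize_formula <- function(expression) {
  src <- expression
  tokens <- list()
  pos <- 1L
  n <- nchar(src)
  push <- function(type, text, at)
    tokens[[length(tokens) + 1L]] <<- list(type = type, text = text, at = at)
  while (pos <= n) {
    ch <- substr(src, pos, pos)
    if (grepl("^\\s$", ch)) { pos <- pos + 1L; next }
    if (grepl("^[0-9.]$", ch)) {
      m <- regmatches(substr(src, pos, n),
                      regexpr("^[0-9]*\\.?[0-9]+([eE][+-]?[0-9]+)?", substr(src, pos, n)))
      if (!length(m) || !nzchar(m))
        stop("syntax error at position ", pos, ": bad number in '",
             expression, "'")
      push("num", m, pos)
      pos <- pos + nchar(m)
      next
    }
    if (grepl("^[A-Za-z_]$", ch)) {
      m <- regmatches(substr(src, pos, n),
                      regexpr("^[A-Za-z_][A-Za-z0-9_]*", substr(src, pos, n)))
      push("name", m, pos)
      pos <- pos + nchar(m)
      next
    }
    if (substr(src, pos, pos + 1L) == "**") {  # alias for ^
      push("op", "^", pos)
      pos <- pos + 2L
      next
    }
    if (ch %in% c("+", "-", "*", "/", "^", "(", ")", ",")) {
      push(if (ch %in% c("(", ")", ",")) ch else "op", ch, pos)
      pos <- pos + 1L
      next
    }
    stop("syntax error at position ", pos, ": unexpected character '",
         ch, "' in '", expression, "'")
  }
  tokens
}

.parse_tokens <- function(tokens, expression) {
  idx <- 1L
  peek <- function() if (idx <= length(tokens)) tokens[[idx]] else NULL
  advance <- function() { tok <- tokens[[idx]]; idx <<- idx + 1L; tok }
  expect <- function(text) {
    tok <- peek()
    if (is.null(tok) || tok$text != text)
      stop("syntax error at ",
           if (is.null(tok)) paste0("end of '", expression, "'")
           else paste0("position ", tok$at, " in '", expression, "'"),
           ": expected '", text, "'")
    advance()
  }

  parse_expr <- function() {
    node <- parse_term()
    repeat {
      tok <- peek()
      if (is.null(tok) || tok$type != "op" || !tok$text %in% c("+", "-"))
        return(node)
      advance()
      node <- list(type = "binop", op = tok$text, lhs = node,
                   rhs = parse_term())
    }
  }
  parse_term <- function() {
    node <- parse_unary()
    repeat {
      tok <- peek()
      if (is.null(tok) || tok$type != "op" || !tok$text %in% c("*", "/"))
        return(node)
      advance()
      node <- list(type = "binop", op = tok$text, lhs = node,
                   rhs = parse_unary())
    }
  }
  parse_unary <- function() {
    tok <- peek()
    if (!is.null(tok) && tok$type == "op" && tok$text == "-") {
      advance()
      return(list(type = "unary", op = "-", arg = parse_unary()))
    }
    parse_power()
  }
  parse_power <- function() {
    base <- parse_primary()
    tok <- peek()
    if (!is.null(tok) && tok$type == "op" && tok$text == "^") {
      advance()
      # right-associative; exponent may carry a unary minus
      return(list(type = "binop", op = "^", lhs = base, rhs = parse_unary()))
    }
    base
  }
  parse_primary <- function() {
    tok <- peek()
    if (is.null(tok))
      stop("syntax error at end of '", expression, "': expected operand")
    if (tok$type == "num") {
      advance()
      return(list(type = "num", value = as.numeric(tok$text)))
    }
    if (tok$type == "name") {
      advance()
      nxt <- peek()
      if (!is.null(nxt) && nxt$text == "(") {
        if (!tok$text %in% .FORMULA_FUNCTIONS)
          stop("unknown function '", tok$text, "' at position ", tok$at,
               " in '", expression, "'")
        expect("(")
        arg <- parse_expr()
        expect(")")
        return(list(type = "call", fn = tok$text, arg = arg))
      }
      return(list(type = "var", name = tok$text))
    }
    if (tok$text == "(") {
      advance()
      node <- parse_expr()
      expect(")")
      return(node)
    }
    stop("syntax error at position ", tok$at, " in '", expression,
         "': unexpected '", tok$text, "'")
  }

  node <- parse_expr()
  tok <- peek()
  if (!is.null(tok))
    stop("syntax error at position ", tok$at, " in '", expression,
         "': unexpected trailing '", tok$text, "'")
  node
}

.tree_variables <- function(node) {
  switch(node$type,
    num = character(),
    var = node$name,
    unary = .tree_variables(node$arg),
    call = .tree_variables(node$arg),
    binop = union(.tree_variables(node$lhs), .tree_variables(node$rhs)))
}

#' Parse a trait formula
#'
#' Grammar: numeric literals; variables; unary minus; binary `+ - * / ^`
#' with conventional precedence (`^` highest, right-associative; `**` is an
#' alias); parentheses; `sqrt(x)`. Whitespace is ignored. Variables are not
#' resolved at parse time — unknown names surface when evaluating.
#'
#' @param name trait label for the formula.
#' @param expression formula text, e.g. `"(nir-r)/(nir+r)"`.
#' @return object of class `feature_formula` with fields `name`,
#'   `expression`, `tree` and `variables`.
#' @examples
#' f <- parse_formula("NDVI", "(nir-r)/(nir+r)")
#' f$variables
#' @export
parse_formula <- function(name, expression) {
  if (!nzchar(trimws(expression))) stop("empty formula expression")
  tree <- .parse_tokens(.tokenize_formula(expression), expression)
  structure(list(name = name, expression = expression, tree = tree,
                 variables = sort(.tree_variables(tree))),
            class = "feature_formula")
}

#' @export
print.feature_formula <- function(x, ...) {
  cat(sprintf("<feature_formula> %s = %s\n", x$name, format_formula(x)))
  invisible(x)
}

.PRECEDENCE <- c(`+` = 1L, `-` = 1L, `*` = 2L, `/` = 2L, `^` = 4L)

.format_tree <- function(node) {
  fmt <- function(n, parent_prec, right_side) {
    switch(n$type,
      num = format(n$value, digits = 15),
      var = n$name,
      call = paste0(n$fn, "(", fmt(n$arg, 0L, FALSE), ")"),
      unary = {
        s <- paste0("-", fmt(n$arg, 3L, TRUE))
        if (parent_prec > 1L) paste0("(", s, ")") else s
      },
      binop = {
        prec <- .PRECEDENCE[[n$op]]
        assoc_right <- n$op == "^"
        lhs <- fmt(n$lhs, if (assoc_right) prec + 1L else prec, FALSE)
        rhs <- fmt(n$rhs, if (assoc_right) prec else prec + 1L, TRUE)
        s <- paste0(lhs, n$op, rhs)
        need <- prec < parent_prec ||
          (prec == parent_prec && right_side && !assoc_right)
        if (need) paste0("(", s, ")") else s
      })
  }
  fmt(node, 0L, FALSE)
}

#' Serialize a parsed formula back to text
#'
#' The printed form re-parses to a tree equal to the original.
#'
#' @param formula a [parse_formula()] result.
#' @return character expression.
#' @export
format_formula <- function(formula) .format_tree(formula$tree)

.eval_tree <- function(node, bindings) {
  switch(node$type,
    num = node$value,
    var = {
      if (is.null(bindings[[node$name]]))
        stop("unbound variable '", node$name, "'")
      bindings[[node$name]]
    },
    unary = -.eval_tree(node$arg, bindings),
    call = {
      v <- .eval_tree(node$arg, bindings)
      out <- suppressWarnings(sqrt(v))
      out[!is.na(v) & v < 0] <- NA_real_
      out
    },
    binop = {
      a <- .eval_tree(node$lhs, bindings)
      b <- .eval_tree(node$rhs, bindings)
      out <- switch(node$op,
        `+` = a + b, `-` = a - b, `*` = a * b,
        `/` = {
          r <- a / b
          r[!is.na(b) & b == 0] <- NA_real_
          r
        },
        `^` = suppressWarnings(a ^ b))
      out[is.nan(out)] <- NA_real_
      out
    })
}

#' Evaluate a formula over bound variables
#'
#' Element-wise evaluation over scalars, vectors or equal-shaped grids.
#' Any element where a divisor is 0, a sqrt argument is negative, or an
#' input is missing evaluates to `NA`.
#'
#' @param formula a [parse_formula()] result.
#' @param bindings named list mapping every variable in
#'   `formula$variables` to a numeric scalar/vector/matrix.
#' @return numeric of the common shape of the bindings.
#' @examples
#' ndvi <- parse_formula("NDVI", "(nir-r)/(nir+r)")
#' evaluate_formula(ndvi, list(nir = 0.5, r = 0.1))  # 0.6666667
#' @export
evaluate_formula <- function(formula, bindings) {
  missing_vars <- setdiff(formula$variables, names(bindings))
  if (length(missing_vars))
    stop("unbound variable '", missing_vars[1], "' in formula '",
         formula$name, "'")
  shapes <- lapply(bindings[formula$variables], dim)
  shapes <- shapes[!vapply(shapes, is.null, logical(1))]
  if (length(shapes) > 1) {
    first <- shapes[[1]]
    for (s in shapes[-1])
      if (!identical(s, first)) stop("bound grids must share a shape")
  }
  .eval_tree(formula$tree, bindings)
}
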
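# Shared tokenizer and recursive-descent parsers for the mnet rule language
# and ARCTL formula strings.

TOKEN_PATTERNS <- list(
  c("WS", "[ \t\r\n]+"),
  c("COMMENT", "#[^\n]*"),
  c("NAME", "[A-Za-z_][A-Za-z0-9_]*"),
  c("INT", "[0-9]+"),
  c("OP", ":=|>=|<=|=|!|[&|(){},;:\\[\\]]"))

tokenize <- function(text) {
  toks <- list(); pos <- 1L; n <- nchar(text)
  while (pos <= n) {
    matched <- FALSE
    for (tp in TOKEN_PATTERNS) {
      m <- regexpr(paste0("^(", tp[2], ")"), substr(text, pos, n),
                   perl = TRUE)
      if (m == 1L) {
        len <- attr(m, "match.length")
        val <- substr(text, pos, pos + len - 1L)
        if (!(tp[1] %in% c("WS", "COMMENT")))
          toks[[length(toks) + 1L]] <- list(type = tp[1], value = val,
                                            pos = pos)
        pos <- pos + len
        matched <- TRUE
        break
      }
    }
    if (!matched)
      stop_parse(sprintf("syntax error at position %d: unexpected character '%s'",
                         pos, substr(text, pos, pos)))
  }
  toks[[length(toks) + 1L]] <- list(type = "EOF", value = "", pos = n + 1L)
  toks
}

# Minimal token stream cursor shared by the parsers.
new_stream <- function(toks) {
  env <- new.env(parent = emptyenv())
  env$toks <- toks; env$i <- 1L
  env
}
peek <- function(st) st$toks[[st$i]]
advance <- function(st) {
  t <- st$toks[[st$i]]
  st$i <- st$i + 1L
  t
}
expect <- function(st, value, what = value) {
  t <- advance(st)
  if (!identical(t$value, value))
    stop_parse(sprintf("syntax error at position %d: expected '%s', got '%s'",
                       t$pos, what, t$value))
  t
}
at <- function(st, value) identical(peek(st)$value, value)

# ---- boolean conditions over component comparisons (mnet rules) -----------
# AST node types: const (value), cmp (name, op, level), not, and, or.

parse_cond <- function(st) {
  parse_cond_or(st)
}
parse_cond_or <- function(st) {
  x <- parse_cond_and(st)
  while (at(st, "|")) { advance(st); x <- list(type = "or", a = x,
                                               b = parse_cond_and(st)) }
  x
}
parse_cond_and <- function(st) {
  x <- parse_cond_unary(st)
  while (at(st, "&")) { advance(st); x <- list(type = "and", a = x,
                                               b = parse_cond_unary(st)) }
  x
}
parse_cond_unary <- function(st) {
  t <- peek(st)
  if (at(st, "!")) { advance(st); return(list(type = "not",
                                              a = parse_cond_unary(st))) }
  if (at(st, "(")) {
    advance(st); x <- parse_cond_or(st); expect(st, ")"); return(x)
  }
  if (t$type == "NAME") {
    advance(st)
    if (identical(t$value, "true")) return(list(type = "const", value = TRUE))
    if (identical(t$value, "false")) return(list(type = "const", value = FALSE))
    if (peek(st)$value %in% c("=", ">=", "<=")) {
      op <- advance(st)$value
      lv <- advance(st)
      if (lv$type != "INT")
        stop_parse(sprintf("syntax error at position %d: expected a level",
                           lv$pos))
      return(list(type = "cmp", name = t$value, op = op,
                  level = as.integer(lv$value)))
    }
    return(list(type = "cmp", name = t$value, op = ">=", level = 1L))
  }
  stop_parse(sprintf("syntax error at position %d: unexpected '%s'",
                     t$pos, t$value))
}

cond_names <- function(cond) switch(cond$type,
  const = character(0),
  cmp = cond$name,
  not = cond_names(cond$a),
  union(cond_names(cond$a), cond_names(cond$b)))

eval_cond <- function(cond, levels) switch(cond$type,
  const = rep(cond$value, if (is.matrix(levels)) nrow(levels) else 1L),
  cmp = {
    x <- if (is.matrix(levels)) levels[, cond$name] else levels[[cond$name]]
    cmp_levels(x, cond$op, cond$level)
  },
  not = !eval_cond(cond$a, levels),
  and = eval_cond(cond$a, levels) & eval_cond(cond$b, levels),
  or = eval_cond(cond$a, levels) | eval_cond(cond$b, levels))

cond_text <- function(cond) switch(cond$type,
  const = if (cond$value) "true" else "false",
  cmp = paste0(cond$name, cond$op, cond$level),
  not = paste0("!", cond_text_paren(cond$a)),
  and = paste0(cond_text_paren(cond$a), " & ", cond_text_paren(cond$b)),
  or = paste0(cond_text(cond$a), " | ", cond_text(cond$b)))
cond_text_paren <- function(cond) {
  if (cond$type %in% c("or", "and")) paste0("(", cond_text(cond), ")")
  else cond_text(cond)
}

# ---- ARCTL formula strings ------------------------------------------------

ARCTL_OPS <- c("EAX", "AAX", "EAF", "AAF", "EAG", "AAG")
ARCTL_U_OPS <- c("EAU", "AAU")

#' Parse an ARCTL formula string
#'
#' Grammar: `[INIT <state-pred> ;] <formula>`.  State atoms are component
#' comparisons (`NAME = INT`, `NAME >= INT`, `NAME <= INT`), pattern names,
#' `true` / `false`; connectives `& | ! ( )`; temporal operators
#' `EAX|AAX|EAF|AAF|EAG|AAG (alpha)(phi)` and `EAU|AAU (alpha)[phi U psi]`.
#' An input restriction `alpha` is `{I=1,J=0}` (a conjunction of input
#' assignments), an environment name, `true`, or a boolean combination with
#' `! & | ( )`.
#'
#' When `model` is given, atoms and restrictions are checked at parse time:
#' unknown patterns, environments or components, restrictions citing a
#' non-input, and out-of-range levels are rejected.
#'
#' @param text the formula string.
#' @param model optional [logical_model()] for type checking.
#' @param patterns,environments named lists used to resolve names.
#' @return A list with `init` (an [arctl] formula or `NULL`) and `formula`.
#' @examples
#' parse_formula("INIT PA; EAF({I=0})(PB & AAG({I=0})(PB))",
#'               toggle_model(),
#'               patterns = list(PA = c(A = 1L, B = 0L),
#'                               PB = c(A = 0L, B = 1L)))
#' @export
parse_formula <- function(text, model = NULL, patterns = list(),
                          environments = list()) {
  st <- new_stream(tokenize(text))
  ctx <- list(model = model, patterns = patterns,
              environments = environments)
  init <- NULL
  if (peek(st)$value == "INIT") {
    advance(st)
    init <- parse_f(st, ctx)
    expect(st, ";")
  }
  f <- parse_f(st, ctx)
  t <- peek(st)
  if (t$type != "EOF")
    stop_parse(sprintf("syntax error at position %d: trailing input '%s'",
                       t$pos, t$value))
  list(init = init, formula = f)
}

check_state_atom <- function(name, level, ctx, pos) {
  m <- ctx$model
  if (is.null(m)) return(invisible())
  if (!(name %in% internal_names(m)))
    stop_parse(sprintf("unknown component or non-internal atom '%s' at position %d",
                       name, pos))
  if (!is.null(level) &&
      (level < 0L || level > component_card(m, name) - 1L))
    stop_parse(sprintf("level out of range: %s=%d at position %d",
                       name, level, pos))
}
check_input_atom <- function(name, level, ctx, pos) {
  m <- ctx$model
  if (is.null(m)) return(invisible())
  if (!(name %in% input_names(m)))
    stop_parse(sprintf("input restriction cites a non-input '%s' at position %d",
                       name, pos))
  if (!is.null(level) &&
      (level < 0L || level > component_card(m, name) - 1L))
    stop_parse(sprintf("level out of range: %s=%d at position %d",
                       name, level, pos))
}

parse_f <- function(st, ctx) {
  x <- parse_f_and(st, ctx)
  while (at(st, "|")) { advance(st); x <- f_or(x, parse_f_and(st, ctx)) }
  x
}
parse_f_and <- function(st, ctx) {
  x <- parse_f_unary(st, ctx)
  while (at(st, "&")) { advance(st); x <- f_and(x, parse_f_unary(st, ctx)) }
  x
}
parse_f_unary <- function(st, ctx) {
  t <- peek(st)
  if (at(st, "!")) { advance(st); return(f_not(parse_f_unary(st, ctx))) }
  if (at(st, "(")) {
    advance(st); x <- parse_f(st, ctx); expect(st, ")"); return(x)
  }
  if (t$type != "NAME")
    stop_parse(sprintf("syntax error at position %d: unexpected '%s'",
                       t$pos, t$value))
  advance(st)
  nm <- t$value
  if (nm == "true") return(f_true())
  if (nm == "false") return(f_false())
  if (nm %in% ARCTL_OPS) {
    expect(st, "(")
    alpha <- parse_alpha(st, ctx)
    expect(st, ")"); expect(st, "(")
    phi <- parse_f(st, ctx)
    expect(st, ")")
    return(f_node(nm, alpha = alpha, phi = phi))
  }
  if (nm %in% ARCTL_U_OPS) {
    expect(st, "(")
    alpha <- parse_alpha(st, ctx)
    expect(st, ")"); expect(st, "[")
    phi <- parse_f(st, ctx)
    u <- advance(st)
    if (!identical(u$value, "U"))
      stop_parse(sprintf("syntax error at position %d: expected 'U'", u$pos))
    psi <- parse_f(st, ctx)
    expect(st, "]")
    return(f_node(nm, alpha = alpha, phi = phi, psi = psi))
  }
  if (peek(st)$value %in% c("=", ">=", "<=")) {
    op <- advance(st)$value
    lv <- advance(st)
    if (lv$type != "INT")
      stop_parse(sprintf("syntax error at position %d: expected a level",
                         lv$pos))
    level <- as.integer(lv$value)
    check_state_atom(nm, level, ctx, t$pos)
    return(f_atom(nm, op, level))
  }
  if (nm %in% names(ctx$patterns)) return(f_pattern(nm))
  stop_parse(sprintf("unknown pattern '%s' at position %d", nm, t$pos))
}

parse_alpha <- function(st, ctx) {
  x <- parse_alpha_and(st, ctx)
  while (at(st, "|")) { advance(st)
    x <- alpha_or(x, parse_alpha_and(st, ctx)) }
  x
}
parse_alpha_and <- function(st, ctx) {
  x <- parse_alpha_unary(st, ctx)
  while (at(st, "&")) { advance(st)
    x <- alpha_and(x, parse_alpha_unary(st, ctx)) }
  x
}
parse_alpha_unary <- function(st, ctx) {
  t <- peek(st)
  if (at(st, "!")) { advance(st)
    return(alpha_not(parse_alpha_unary(st, ctx))) }
  if (at(st, "(")) {
    advance(st); x <- parse_alpha(st, ctx); expect(st, ")"); return(x)
  }
  if (at(st, "{")) {
    advance(st)
    a <- NULL
    repeat {
      n <- advance(st)
      if (n$type != "NAME")
        stop_parse(sprintf("syntax error at position %d: expected an input name",
                           n$pos))
      op <- "="
      level <- 1L
      if (peek(st)$value %in% c("=", ">=", "<=")) {
        op <- advance(st)$value
        lv <- advance(st)
        if (lv$type != "INT")
          stop_parse(sprintf("syntax error at position %d: expected a level",
                             lv$pos))
        level <- as.integer(lv$value)
      }
      check_input_atom(n$value, level, ctx, n$pos)
      atom <- alpha_atom(n$value, op, level)
      a <- if (is.null(a)) atom else alpha_and(a, atom)
      if (at(st, ",")) { advance(st); next }
      expect(st, "}")
      break
    }
    return(a)
  }
  if (t$type == "NAME") {
    advance(st)
    if (t$value == "true") return(alpha_true())
    if (t$value %in% names(ctx$environments)) return(alpha_env(t$value))
    stop_parse(sprintf("unknown environment '%s' at position %d",
                       t$value, t$pos))
  }
  stop_parse(sprintf("syntax error at position %d: unexpected '%s'",
                     t$pos, t$value))
}
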
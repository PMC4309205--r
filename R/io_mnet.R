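#' Read and write models in the mnet plain-text format
#'
#' The mnet dialect is a human-writable multivalued rule format: one
#' declaration line per component (`input NAME : MAX` for environment inputs,
#' `NAME : MAX` otherwise) followed by one rule per non-input component,
#' `NAME := { <condition> : <level> ; ... ; default : <level> }`.
#' Conditions are boolean combinations (`& | ! ( )`) of regulator
#' comparisons (`REG=2`, `REG>=1`, `REG<=0`; a bare regulator name means
#' `>= 1`); the first matching clause wins.  Lines starting with `#` are
#' annotations and are ignored on read.
#'
#' Interactions are derived from rule support on read: a regulator is kept
#' iff the rule depends on it, with the threshold at the smallest effective
#' level and the sign derived from the direction of the effect.
#'
#' @param path file path.
#' @return `read_mnet()` returns a validated [logical_model()]; reading
#'   aborts with the list of violations when the model is not well formed.
#' @export
read_mnet <- function(path) {
  text <- paste(readLines(path, warn = FALSE), collapse = "\n")
  st <- new_stream(tokenize(text))
  comps <- list(); rule_specs <- list()
  repeat {
    t <- peek(st)
    if (t$type == "EOF") break
    if (t$type != "NAME")
      stop_parse(sprintf("%s: syntax error at position %d: expected a declaration or rule, got '%s'",
                         path, t$pos, t$value))
    is_input <- FALSE
    if (t$value == "input" && st$toks[[st$i + 1L]]$type == "NAME") {
      advance(st); is_input <- TRUE
      t <- peek(st)
    }
    name <- advance(st)$value
    nxt <- advance(st)
    if (nxt$value == ":") {
      lv <- advance(st)
      if (lv$type != "INT")
        stop_parse(sprintf("%s: syntax error at position %d: expected max level",
                           path, lv$pos))
      comps[[length(comps) + 1L]] <-
        data.frame(name = name, max_level = as.integer(lv$value),
                   is_input = is_input, stringsAsFactors = FALSE)
    } else if (nxt$value == ":=") {
      expect(st, "{")
      clauses <- list()
      repeat {
        if (peek(st)$value == "default" &&
            st$toks[[st$i + 1L]]$value == ":") {
          advance(st); advance(st)
          lv <- advance(st)
          if (lv$type != "INT")
            stop_parse(sprintf("%s: syntax error at position %d: expected default level",
                               path, lv$pos))
          clauses[[length(clauses) + 1L]] <-
            list(cond = list(type = "const", value = TRUE),
                 level = as.integer(lv$value))
        } else {
          cond <- parse_cond(st)
          expect(st, ":")
          lv <- advance(st)
          if (lv$type != "INT")
            stop_parse(sprintf("%s: syntax error at position %d: expected clause level",
                               path, lv$pos))
          clauses[[length(clauses) + 1L]] <-
            list(cond = cond, level = as.integer(lv$value))
        }
        if (at(st, ";")) { advance(st); next }
        expect(st, "}")
        break
      }
      rule_specs[[name]] <- clauses
    } else {
      stop_parse(sprintf("%s: syntax error at position %d: expected ':' or ':=' after '%s'",
                         path, nxt$pos, name))
    }
  }
  comps <- do.call(rbind, comps)
  if (is.null(comps)) stop_parse(paste0(path, ": no components declared"))
  model_from_clauses(comps, rule_specs, context = path)
}

# Compile first-match clause specifications into truth-table rules and
# assemble a validated model.
model_from_clauses <- function(comps, rule_specs, context = "model") {
  card <- stats::setNames(comps$max_level + 1L, comps$name)
  errors <- character(0)
  rules <- list()
  for (nm in names(rule_specs)) {
    clauses <- rule_specs[[nm]]
    if (!(nm %in% comps$name)) {
      errors <- c(errors, paste0("rule for undeclared component: ", nm))
      next
    }
    regs <- unique(unlist(lapply(clauses, function(cl)
      cond_names(cl$cond))))
    unknown <- setdiff(regs, comps$name)
    if (length(unknown)) {
      errors <- c(errors, paste0("rule uses non-regulator: ", nm, " <- ",
                                 unknown))
      next
    }
    regs <- regs[order(match(regs, comps$name))]
    for (cl in clauses) {
      for (cn in intersect(cond_names(cl$cond), comps$name)) {
        lvls <- cond_levels(cl$cond, cn)
        if (any(lvls > card[cn] - 1L) || any(lvls < 0L))
          errors <- c(errors, sprintf("level out of range in rule %s: %s",
                                      nm, cn))
      }
      if (cl$level < 0L || cl$level > card[nm] - 1L)
        errors <- c(errors, sprintf("result level exceeds max level of %s: %d",
                                    nm, cl$level))
    }
    g <- level_grid(card[regs], regs)
    out <- rep(NA_integer_, nrow(g))
    for (cl in clauses) {
      hit <- eval_cond(cl$cond, g) & is.na(out)
      out[hit] <- cl$level
    }
    if (anyNA(out))
      errors <- c(errors, paste0("rule does not cover all regulator combinations (add a default clause): ",
                                 nm))
    rules[[nm]] <- if (!anyNA(out)) logical_rule(nm, regs, card[regs], out)
  }
  for (nm in comps$name[!comps$is_input])
    if (!(nm %in% names(rule_specs)))
      errors <- c(errors, paste0("missing rule for component: ", nm))
  for (nm in comps$name[comps$is_input])
    if (nm %in% names(rule_specs))
      errors <- c(errors, paste0("input component has a rule: ", nm))
  if (length(errors))
    stop_parse(paste0(context, ": invalid model:\n  ",
                      paste(errors, collapse = "\n  ")))
  m <- logical_model(comps, rules)
  v <- validate_model(m, non_functional = "ignore")
  if (length(v$errors))
    stop_parse(paste0(context, ": invalid model:\n  ",
                      paste(v$errors, collapse = "\n  ")))
  m
}

# Levels compared against component `name` inside a condition AST.
cond_levels <- function(cond, name) switch(cond$type,
  const = integer(0),
  cmp = if (cond$name == name) cond$level else integer(0),
  not = cond_levels(cond$a, name),
  c(cond_levels(cond$a, name), cond_levels(cond$b, name)))

#' @rdname read_mnet
#' @param model a [logical_model()].
#' @param annotations optional character vector of extra annotation lines
#'   (written as `#` comments).
#' @return `write_mnet()` invisibly returns the written lines.  The writer
#'   emits a canonical form (one clause per non-default output level, the
#'   most frequent level as default), so writing, re-reading and writing
#'   again is a fixpoint.
#' @export
write_mnet <- function(model, path, annotations = NULL) {
  lines <- c("# logimc mnet model", annotations)
  red <- attr(model, "reduced_from")
  if (!is.null(red))
    lines <- c(lines,
               sprintf("# reduced: removed=%s source_fnv=%s",
                       paste(red$removed, collapse = ","), red$source_hash))
  for (i in seq_len(nrow(model$components))) {
    lines <- c(lines, sprintf("%s%s : %d",
                              if (model$components$is_input[i]) "input " else "",
                              model$components$name[i],
                              model$components$max_level[i]))
  }
  for (nm in intersect(model$components$name, names(model$rules))) {
    r <- model$rules[[nm]]
    lines <- c(lines, sprintf("%s := %s", nm, rule_clause_text(r)))
  }
  writeLines(lines, path)
  invisible(lines)
}

# Canonical first-match clause text for a truth-table rule.
rule_clause_text <- function(r) {
  if (length(r$regulators) == 0L)
    return(sprintf("{ default : %d }", r$outputs))
  tab <- tabulate(r$outputs + 1L, nbins = max(r$outputs) + 1L)
  default <- which.max(tab) - 1L
  g <- level_grid(r$card, r$regulators)
  clauses <- character(0)
  for (lev in sort(unique(r$outputs))) {
    if (lev == default) next
    rows <- which(r$outputs == lev)
    conj <- vapply(rows, function(i)
      paste0(r$regulators, "=", g[i, ], collapse = " & "), character(1))
    conj <- if (length(r$regulators) > 1L && length(conj) > 1L)
      paste0("(", conj, ")") else conj
    clauses <- c(clauses, sprintf("%s : %d",
                                  paste(conj, collapse = " | "), lev))
  }
  clauses <- c(clauses, sprintf("default : %d", default))
  paste0("{ ", paste(clauses, collapse = " ; "), " }")
}

#' Read or write a model, dispatching on format
#'
#' @param path file path.
#' @param format `"mnet"` or `"sbml_qual"`; `NULL` guesses from the
#'   extension (`.mnet` vs `.sbml`/`.xml`).
#' @return `read_model()` returns a validated [logical_model()].
#' @export
read_model <- function(path, format = NULL) {
  format <- format %||% guess_format(path)
  switch(format,
         mnet = read_mnet(path),
         sbml_qual = read_sbml_qual(path),
         stop("read_model: unsupported format: ", format))
}

#' @rdname read_model
#' @param model a [logical_model()].
#' @export
write_model <- function(model, path, format = NULL) {
  format <- format %||% guess_format(path)
  switch(format,
         mnet = write_mnet(model, path),
         sbml_qual = write_sbml_qual(model, path),
         stop("write_model: unsupported format: ", format))
}

guess_format <- function(path) {
  if (grepl("\\.(sbml|xml)$", path, ignore.case = TRUE)) "sbml_qual"
  else "mnet"
}
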
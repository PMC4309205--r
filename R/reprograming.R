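#' Build a reprograming graph
#'
#' Synthesizes the graph of verified reprograming events between phenotype
#' patterns: there is an arc from pattern `c1` to pattern `c2` labeled with
#' environment `e` whenever the property `INIT c1; EAF(e)(c2 & AAG(e)(c2))`
#' holds, i.e. from every `c1`-state some path under inputs compatible with
#' `e` reaches a `c2`-state that is then maintained in `c2` under `e`.
#' Every ordered pair of patterns (including `c1 = c2`, which yields
#' stability self-arcs) is tested against every environment.
#'
#' @param lts a [build_lts()] result.
#' @param patterns named list of phenotype patterns (partial internal
#'   assignments).
#' @param environments named list of environments (partial input
#'   assignments); an environment fixes only its listed inputs, unlisted
#'   inputs vary freely.
#' @param include_self keep self-arcs (default `TRUE`).
#' @return An object of class `reprograming_graph`: list with `nodes`
#'   (pattern names), `arcs` (data.frame `from`, `env`, `to`, sorted), and
#'   `empty_patterns` (patterns matching no state, kept as isolated nodes).
#' @examples
#' build_reprograming_graph(build_lts(toggle_model()),
#'   patterns = list(PA = c(A = 1L, B = 0L), PB = c(A = 0L, B = 1L)),
#'   environments = list(e0 = c(I = 0L), e1 = c(I = 1L)))
#' @export
build_reprograming_graph <- function(lts, patterns, environments,
                                     include_self = TRUE) {
  stopifnot(length(patterns) > 0L)
  empty <- names(patterns)[vapply(patterns, function(p)
    !any(pattern_states(lts, p)), logical(1))]
  if (length(empty))
    warning("pattern(s) matching no state kept as isolated node(s): ",
            paste(empty, collapse = ", "))
  live <- setdiff(names(patterns), empty)
  arcs <- list()
  for (c1 in live) for (c2 in live) {
    if (!include_self && c1 == c2) next
    for (e in names(environments)) {
      f <- EAF(alpha_env(e),
               f_and(f_pattern(c2), AAG(alpha_env(e), f_pattern(c2))))
      v <- check_property(lts, c1, f, patterns, environments)
      if (v$true)
        arcs[[length(arcs) + 1L]] <-
          data.frame(from = c1, env = e, to = c2, stringsAsFactors = FALSE)
    }
  }
  arcs <- do.call(rbind, arcs) %||%
    data.frame(from = character(0), env = character(0), to = character(0))
  arcs <- arcs[order(match(arcs$from, names(patterns)),
                     match(arcs$to, names(patterns)),
                     match(arcs$env, names(environments))), , drop = FALSE]
  rownames(arcs) <- NULL
  structure(list(nodes = names(patterns), arcs = arcs,
                 empty_patterns = empty),
            class = "reprograming_graph")
}

#' @export
print.reprograming_graph <- function(x, ...) {
  cat(sprintf("reprograming graph: %d node(s), %d arc(s)\n",
              length(x$nodes), nrow(x$arcs)))
  if (nrow(x$arcs))
    for (i in seq_len(nrow(x$arcs)))
      cat(sprintf("  %s -[%s]-> %s\n",
                  x$arcs$from[i], x$arcs$env[i], x$arcs$to[i]))
  invisible(x)
}

#' Export a reprograming graph
#'
#' DOT export aggregates the satisfying environments of each (from, to)
#' pair into one labeled arc; JSON export provides both the aggregated and
#' the flat arc list.
#'
#' @param graph a [build_reprograming_graph()] result.
#' @param file output path, or `""` to return the text.
#' @param format `"dot"` or `"json"`.
#' @param hide_self drop self-arcs from the export.
#' @return Invisibly, the exported text.
#' @export
export_reprograming <- function(graph, file = "",
                                format = c("dot", "json"),
                                hide_self = FALSE) {
  format <- match.arg(format)
  arcs <- graph$arcs
  if (hide_self) arcs <- arcs[arcs$from != arcs$to, , drop = FALSE]
  agg <- if (nrow(arcs)) {
    stats::aggregate(env ~ from + to, data = arcs,
                     FUN = function(e) paste(e, collapse = ","))
  } else data.frame(from = character(0), to = character(0),
                    env = character(0))
  if (format == "dot") {
    lines <- c("digraph reprograming {",
               sprintf("  \"%s\";", graph$nodes),
               sprintf("  \"%s\" -> \"%s\" [label=\"%s\"];",
                       agg$from, agg$to, agg$env),
               "}")
    txt <- paste(lines, collapse = "\n")
  } else {
    txt <- jsonlite::toJSON(list(nodes = graph$nodes, arcs = arcs,
                                 aggregated = agg),
                            auto_unbox = TRUE, pretty = TRUE)
  }
  if (nzchar(file)) writeLines(txt, file)
  invisible(txt)
}

#' Multi-phase reprograming strategies
#'
#' A strategy is an ordered sequence of phases, each pairing an environment
#' constraint with a target predicate (`TRUE` for "any state").  It is
#' compiled into the nested ARCTL formula
#' `EAF(e_1)(t_1 & EAF(e_2)(t_2 & ...))`, with the final phase requiring
#' stable maintenance: `EAF(e_n)(t_n & AAG(e_n)(t_n))`.
#'
#' @param lts a [build_lts()] result.
#' @param init initial-state predicate (see [check_property()]).
#' @param strategy list of phases; each phase is a list with `env` (an
#'   environment name or named input assignment) and `target` (a pattern
#'   name, a named internal assignment, or `TRUE`).
#' @param patterns,environments see [sat_set()].
#' @return An object of class `strategy_verdict`: list with `true`, the
#'   compiled `formula`, and the full [check_property()] verdict.
#' @examples
#' lts <- build_lts(toggle_model())
#' check_strategy(lts, c(A = 1L, B = 0L),
#'   list(list(env = c(I = 0L), target = TRUE),
#'        list(env = c(I = 0L), target = c(A = 0L, B = 1L))))
#' @export
check_strategy <- function(lts, init, strategy, patterns = list(),
                           environments = list()) {
  stopifnot(length(strategy) >= 1L)
  as_alpha <- function(e) {
    if (inherits(e, "arctl_alpha")) e
    else if (is.character(e) && is.null(names(e))) alpha_env(e)
    else alpha_assign(e)
  }
  as_target <- function(t) {
    if (isTRUE(t)) f_true()
    else if (inherits(t, "arctl_formula")) t
    else if (is.character(t) && is.null(names(t))) f_pattern(t)
    else {
      f <- f_true()
      for (nm in names(t)) {
        atom <- f_atom(nm, "=", t[[nm]])
        f <- if (f$type == "true") atom else f_and(f, atom)
      }
      f
    }
  }
  n <- length(strategy)
  last <- strategy[[n]]
  tgt <- as_target(last$target)
  if (tgt$type == "true")
    stop("check_strategy: the final phase needs a concrete target pattern")
  formula <- EAF(as_alpha(last$env), f_and(tgt, AAG(as_alpha(last$env), tgt)))
  for (k in rev(seq_len(n - 1L))) {
    ph <- strategy[[k]]
    body <- as_target(ph$target)
    inner <- if (body$type == "true") formula else f_and(body, formula)
    formula <- EAF(as_alpha(ph$env), inner)
  }
  v <- check_property(lts, init, formula, patterns, environments)
  structure(list(true = v$true, formula = formula, verdict = v),
            class = "strategy_verdict")
}

#' @export
print.strategy_verdict <- function(x, ...) {
  cat(sprintf("strategy %s\n", if (x$true) "TRUE" else "FALSE"))
  invisible(x)
}

#' Exhaustive search for reprograming environments
#'
#' Enumerates all assignments of the candidate inputs over one or two phases
#' and returns the strategies that drive every `c1`-state to a stably
#' maintained `c2`-state.  A free-restriction existence pre-check
#' (`EAF(true)(c2)` from `c1`, or with `alpha` restricted to the complement
#' of named environments via `negate_envs`) short-circuits to an empty
#' result when no input sequence at all can achieve the reprograming.
#'
#' @param lts a [build_lts()] result.
#' @param c1,c2 pattern names (in `patterns`) for the source and target.
#' @param candidate_inputs character vector of input names to enumerate;
#'   inputs not listed vary freely.
#' @param max_phases 1 or 2.
#' @param patterns,environments see [sat_set()].
#' @param negate_envs optional character vector of environment names; the
#'   pre-check then uses the restriction "any input combination except
#'   these" instead of the unrestricted one.
#' @param guard maximal number of strategy evaluations (default 4096).
#' @return A list of satisfying strategies (each a list of phases as in
#'   [check_strategy()]); empty when none succeeds.
#' @export
search_environments <- function(lts, c1, c2, candidate_inputs,
                                max_phases = 1L, patterns = list(),
                                environments = list(),
                                negate_envs = NULL, guard = 4096L) {
  stopifnot(max_phases %in% c(1L, 2L))
  bad <- setdiff(candidate_inputs, lts$inputs)
  if (length(bad))
    stop("search_environments: not input components: ",
         paste(bad, collapse = ", "))
  card <- lts$card_in[candidate_inputs]
  n_assign <- prod(card)
  n_total <- n_assign^max_phases
  if (n_total > guard)
    stop_guard(sprintf("search_environments: %g candidate strategies exceed the guard of %d",
                       n_total, guard))

  pre_alpha <- if (is.null(negate_envs)) alpha_true() else {
    a <- NULL
    for (e in negate_envs)
      a <- if (is.null(a)) alpha_env(e) else alpha_or(a, alpha_env(e))
    alpha_not(a)
  }
  pre <- check_property(lts, c1, EAF(pre_alpha, f_pattern(c2)),
                        patterns, environments)
  if (!pre$true) return(list())

  grid <- level_grid(card, candidate_inputs)
  assigns <- lapply(seq_len(nrow(grid)), function(i)
    stats::setNames(grid[i, ], candidate_inputs))
  found <- list()
  if (max_phases == 1L) {
    for (a in assigns) {
      st <- list(list(env = a, target = c2))
      if (check_strategy(lts, c1, st, patterns, environments)$true)
        found[[length(found) + 1L]] <- st
    }
  } else {
    for (a1 in assigns) for (a2 in assigns) {
      st <- list(list(env = a1, target = TRUE),
                 list(env = a2, target = c2))
      if (check_strategy(lts, c1, st, patterns, environments)$true)
        found[[length(found) + 1L]] <- st
    }
  }
  found
}
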
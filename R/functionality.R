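#' Interaction functionality analysis
#'
#' An interaction (source, target, theta) is functional when crossing its
#' threshold changes the target's rule output in at least one combination of
#' the other regulators: the rule is compared with the source at `theta`
#' versus `theta - 1`.  The sign is derived from the direction of the
#' observed changes: `"activation"` if the target value only increases,
#' `"inhibition"` if it only decreases, `"dual"` if both occur, `"none"` if
#' the interaction is not functional.
#'
#' @param model a [logical_model()].
#' @param source,target component names of the interaction.
#' @param threshold interaction threshold; defaults to the declared one.
#' @return An object of class `functionality_report`: a list with fields
#'   `source`, `target`, `threshold`, `functional`, `derived_sign`, and
#'   `context`, the data.frame of other-regulator combinations witnessing
#'   the effect.
#' @examples
#' interaction_functionality(toggle_model(), "B", "A")
#' @export
interaction_functionality <- function(model, source, target,
                                      threshold = NULL) {
  ia <- model$interactions
  hit <- ia$source == source & ia$target == target
  if (is.null(threshold)) {
    if (!any(hit))
      stop("interaction_functionality: unknown interaction ",
           source, " -> ", target)
    threshold <- ia$threshold[hit][1]
  }
  if (!(target %in% names(model$rules)))
    stop("interaction_functionality: target has no rule: ", target)
  rule <- model$rules[[target]]
  card <- component_card(model)
  if (threshold < 1L || threshold > card[source] - 1L)
    stop("interaction_functionality: threshold out of range")

  others <- setdiff(rule$regulators, source)
  ctx_grid <- level_grid(card[others], others)
  if (!(source %in% rule$regulators)) {
    diffs <- rep(0L, nrow(ctx_grid))
  } else {
    hi <- lo <- matrix(0L, nrow = nrow(ctx_grid),
                       ncol = length(rule$regulators),
                       dimnames = list(NULL, rule$regulators))
    if (length(others)) { hi[, others] <- ctx_grid; lo[, others] <- ctx_grid }
    hi[, source] <- as.integer(threshold)
    lo[, source] <- as.integer(threshold) - 1L
    diffs <- eval_rule(rule, hi) - eval_rule(rule, lo)
  }
  witness <- diffs != 0L
  context <- as.data.frame(ctx_grid[witness, , drop = FALSE])
  rownames(context) <- NULL
  sign <- if (!any(witness)) "none"
          else if (all(diffs[witness] > 0L)) "activation"
          else if (all(diffs[witness] < 0L)) "inhibition"
          else "dual"
  structure(list(source = source, target = target,
                 threshold = as.integer(threshold),
                 functional = any(witness), derived_sign = sign,
                 context = context),
            class = "functionality_report")
}

#' @export
print.functionality_report <- function(x, ...) {
  cat(sprintf("%s -> %s (theta=%d): %s (%s), %d witnessing context(s)\n",
              x$source, x$target, x$threshold,
              if (x$functional) "functional" else "not functional",
              x$derived_sign, nrow(x$context)))
  invisible(x)
}

#' Functionality reports for all declared interactions
#'
#' @param model a [logical_model()].
#' @return A data.frame with one row per declared interaction: source,
#'   target, threshold, functional flag, derived sign, and the number of
#'   witnessing contexts.
#' @export
functionality_table <- function(model) {
  ia <- model$interactions
  rows <- lapply(seq_len(nrow(ia)), function(i) {
    fr <- interaction_functionality(model, ia$source[i], ia$target[i],
                                    ia$threshold[i])
    data.frame(source = fr$source, target = fr$target,
               threshold = fr$threshold, functional = fr$functional,
               derived_sign = fr$derived_sign, n_contexts = nrow(fr$context),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(source = character(0), target = character(0),
               threshold = integer(0), functional = logical(0),
               derived_sign = character(0), n_contexts = integer(0))
  rownames(out) <- NULL
  out
}

#' Enumerate elementary regulatory circuits
#'
#' Elementary cycles (feedback loops) of the interaction graph, each returned
#' as the ordered vector of component names along the cycle.  Uses a
#' DFS-based enumeration anchored at the smallest component index of each
#' cycle, so every elementary cycle is reported exactly once, in a
#' deterministic order.
#'
#' @param model a [logical_model()].
#' @param max_length optional cap on the circuit length.
#' @return A list of character vectors.
#' @export
find_circuits <- function(model, max_length = NULL) {
  nodes <- component_names(model)
  idx <- stats::setNames(seq_along(nodes), nodes)
  succ <- split(idx[model$interactions$target],
                factor(model$interactions$source, levels = nodes))
  max_length <- max_length %||% length(nodes)
  out <- list()
  path <- integer(0)
  visit <- function(v, start) {
    path[[length(path) + 1L]] <<- v
    for (w in succ[[nodes[v]]] %||% integer(0)) {
      if (w == start) {
        out[[length(out) + 1L]] <<- nodes[path]
      } else if (w > start && !(w %in% path) &&
                 length(path) < max_length) {
        visit(w, start)
      }
    }
    path <<- path[-length(path)]
  }
  for (s in seq_along(nodes)) visit(s, s)
  out
}

#' Circuit functionality context
#'
#' Determines the sign of a regulatory circuit (positive circuits have an
#' even number of inhibitions, and underlie multistability; negative
#' circuits, an odd number, underlie sustained oscillations) and its
#' functionality context: the combinations of regulators external to the
#' circuit under which every circuit interaction is functional.  An empty
#' context means the circuit is never functional.
#'
#' @param model a [logical_model()].
#' @param circuit character vector of distinct component names, in cycle
#'   order: `c("A", "B")` denotes the cycle A -> B -> A.
#' @return An object of class `circuit_functionality`: a list with `circuit`,
#'   `sign` (`"positive"` or `"negative"`, `NA` if not derivable),
#'   `functional` flag, and `context`, a data.frame of external-regulator
#'   combinations (zero columns when the circuit has no external regulator:
#'   one row then means "always functional").
#' @examples
#' circuit_functionality(toggle_model(), c("A", "B"))
#' @export
circuit_functionality <- function(model, circuit) {
  circuit <- as.character(circuit)
  if (anyDuplicated(circuit))
    stop("circuit_functionality: not an elementary cycle (repeated node)")
  n <- length(circuit)
  ia <- model$interactions
  edges <- lapply(seq_len(n), function(k) {
    u <- circuit[k]; v <- circuit[if (k == n) 1L else k + 1L]
    if (!any(ia$source == u & ia$target == v))
      stop("circuit_functionality: edges do not form an elementary cycle: ",
           "missing interaction ", u, " -> ", v)
    c(u, v)
  })

  reports <- lapply(edges, function(e)
    interaction_functionality(model, e[1], e[2]))

  signs <- vapply(reports, `[[`, character(1), "derived_sign")
  sign <- if (any(signs == "dual")) NA_character_
          else if (any(signs == "none")) NA_character_
          else if (sum(signs == "inhibition") %% 2L == 0L) "positive"
          else "negative"

  card <- component_card(model)
  ext <- character(0)
  for (r in reports)
    ext <- union(ext, setdiff(names(r$context), circuit))
  ext <- ext[order(match(ext, component_names(model)))]
  ctx <- as.data.frame(level_grid(card[ext], ext))

  keep <- rep(TRUE, nrow(ctx))
  for (r in reports) {
    if (!r$functional) { keep[] <- FALSE; break }
    ext_e <- intersect(names(r$context), ext)
    if (length(ext_e) == 0L) next  # edge functional irrespective of ext
    have <- unique(do.call(paste, c(r$context[ext_e], sep = "\r")))
    keep <- keep & do.call(paste, c(ctx[ext_e], sep = "\r")) %in% have
  }
  context <- ctx[keep, , drop = FALSE]
  rownames(context) <- NULL
  structure(list(circuit = circuit, sign = sign,
                 functional = nrow(context) > 0L, context = context),
            class = "circuit_functionality")
}

#' @export
print.circuit_functionality <- function(x, ...) {
  cat(sprintf("circuit %s: sign %s, %s (%d context(s) over %d external regulator(s))\n",
              paste(c(x$circuit, x$circuit[1]), collapse = " -> "),
              x$sign %||% "NA",
              if (x$functional) "functional" else "not functional",
              nrow(x$context), ncol(x$context)))
  invisible(x)
}
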
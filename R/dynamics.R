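#' State successors under a fixed input valuation
#'
#' Computes the successors of a state under unitary updating: every internal
#' component whose rule calls for a different level moves by exactly one
#' level toward the called value.  Under the asynchronous scheme each such
#' component yields its own successor; under the synchronous scheme all of
#' them move simultaneously in a single successor.  A fixed point has no
#' successor.
#'
#' @param model a [logical_model()].
#' @param state named integer vector of internal component levels (entries
#'   for input components are ignored).
#' @param inputs named integer vector of input levels (required when the
#'   model has inputs, unless they are part of `state`).
#' @param scheme `"asynchronous"` (default) or `"synchronous"`.
#' @return Integer matrix with one row per successor state (zero rows for a
#'   fixed point), columns = internal components.
#' @examples
#' successors(toggle_model(), c(A = 1L, B = 0L), inputs = c(I = 0L))
#' @export
successors <- function(model, state, inputs = NULL,
                       scheme = c("asynchronous", "synchronous")) {
  scheme <- match.arg(scheme)
  internal <- internal_names(model)
  card <- component_card(model)
  full <- c(state, inputs)
  miss <- setdiff(component_names(model), names(full))
  if (length(miss))
    stop("successors: missing levels for: ", paste(miss, collapse = ", "))
  full <- full[component_names(model)]
  if (any(full < 0L) || any(full > card[names(full)] - 1L))
    stop("successors: level out of range")
  s <- full[internal]
  targets <- vapply(internal, function(nm)
    eval_rule(model$rules[[nm]], full), integer(1))
  delta <- sign(targets - s)
  moving <- which(delta != 0L)
  if (length(moving) == 0L)
    return(matrix(integer(0), nrow = 0L, ncol = length(internal),
                  dimnames = list(NULL, internal)))
  if (scheme == "synchronous") {
    out <- matrix(s + ifelse(seq_along(s) %in% moving, delta, 0L),
                  nrow = 1L, dimnames = list(NULL, internal))
    storage.mode(out) <- "integer"
    return(out)
  }
  out <- matrix(rep(s, length(moving)), nrow = length(moving), byrow = TRUE,
                dimnames = list(NULL, internal))
  for (k in seq_along(moving))
    out[k, moving[k]] <- out[k, moving[k]] + delta[moving[k]]
  storage.mode(out) <- "integer"
  out
}

#' Build a state transition graph
#'
#' Expands the reachable state transition graph (STG) from a set of initial
#' internal states under a fixed input valuation: the graph contains the
#' initial states together with their direct and indirect successors.
#' Construction aborts when more than `state_cap` states are visited; the
#' symbolic routes ([stable_states()], [build_lts()]) are the supported path
#' for large models.
#'
#' @param model a [logical_model()].
#' @param initial matrix/data.frame of initial internal states (one row per
#'   state, named columns), a single named vector, or `NULL` for the full
#'   internal state space.
#' @param inputs named integer vector fixing every input component.
#' @param scheme updating scheme, see [successors()].
#' @param state_cap maximal number of states explored (default `2^22`).
#' @return An object of class `stg`: list with `states` (integer matrix, one
#'   row per state in discovery order), `edges` (data.frame `from`, `to` of
#'   row indices), `inputs`, and `scheme`.
#' @export
build_stg <- function(model, initial = NULL, inputs = NULL,
                      scheme = c("asynchronous", "synchronous"),
                      state_cap = 2^22) {
  scheme <- match.arg(scheme)
  internal <- internal_names(model)
  card <- component_card(model, internal)
  ins <- input_names(model)
  inputs <- inputs[ins]
  if (length(ins) && (length(inputs) != length(ins) || anyNA(inputs)))
    stop("build_stg: every input must be fixed (missing: ",
         paste(setdiff(ins, names(inputs)), collapse = ", "), ")")
  n_space <- prod(card)
  if (is.null(initial)) {
    if (n_space > state_cap)
      stop_guard(sprintf(
        "state space too large: %g states exceed the cap of %g",
        n_space, state_cap))
    initial <- level_grid(card, internal)
  } else {
    if (is.null(dim(initial)))
      initial <- matrix(initial, nrow = 1L,
                        dimnames = list(NULL, names(initial)))
    initial <- as.matrix(as.data.frame(initial))[, internal, drop = FALSE]
    storage.mode(initial) <- "integer"
  }

  id_of <- integer(n_space)  # full-space index -> local id (0 = unseen)
  states <- list()
  n_states <- 0L
  edges_from <- integer(0); edges_to <- integer(0)
  add_state <- function(s) {
    key <- mr_index(s, card)
    if (id_of[key] == 0L) {
      n_states <<- n_states + 1L
      if (n_states > state_cap)
        stop_guard(sprintf("state space too large: cap of %g exceeded",
                           state_cap))
      id_of[key] <<- n_states
      states[[n_states]] <<- s
    }
    id_of[key]
  }
  for (i in seq_len(nrow(initial))) add_state(initial[i, ])
  head <- 1L
  while (head <= n_states) {  # new states append to the end of `states`
    id <- head; head <- head + 1L
    s <- stats::setNames(states[[id]], internal)
    succ <- successors(model, s, inputs, scheme)
    for (k in seq_len(nrow(succ))) {
      sid <- add_state(succ[k, ])
      edges_from <- c(edges_from, id)
      edges_to <- c(edges_to, sid)
    }
  }
  st <- do.call(rbind, states[seq_len(n_states)])
  colnames(st) <- internal
  structure(list(states = st,
                 edges = data.frame(from = edges_from, to = edges_to),
                 inputs = inputs, scheme = scheme),
            class = "stg")
}

#' @export
print.stg <- function(x, ...) {
  cat(sprintf("stg (%s): %d states, %d transitions", x$scheme,
              nrow(x$states), nrow(x$edges)))
  if (length(x$inputs))
    cat("; inputs ", paste0(names(x$inputs), "=", x$inputs, collapse = ","))
  cat("\n")
  invisible(x)
}

stg_igraph <- function(stg) {
  igraph::graph_from_data_frame(
    stg$edges, directed = TRUE,
    vertices = data.frame(name = seq_len(nrow(stg$states))))
}

#' Condensation of a state transition graph
#'
#' Partitions the STG states into maximal strongly connected components
#' (SCCs) and builds the acyclic SCC graph, a compressed view of the
#' dynamics in which attractors appear as terminal nodes.  SCCs are numbered
#' in reverse topological order (terminal components first).
#'
#' @param stg an [build_stg()] result.
#' @return An object of class `stg_condensation`: list with `membership`
#'   (SCC id per state), `scc` (list of state-index vectors), `edges`
#'   (data.frame of SCC ids), and `terminal` (logical per SCC).
#' @export
condensation <- function(stg) {
  n <- nrow(stg$states)
  g <- stg_igraph(stg)
  comp <- igraph::components(g, mode = "strong")
  memb <- comp$membership
  cedges <- unique(data.frame(from = memb[stg$edges$from],
                              to = memb[stg$edges$to]))
  cedges <- cedges[cedges$from != cedges$to, , drop = FALSE]
  cg <- igraph::graph_from_data_frame(
    cedges, directed = TRUE,
    vertices = data.frame(name = seq_len(comp$no)))
  topo <- as.integer(igraph::topo_sort(cg, mode = "out"))
  rank <- match(seq_len(comp$no), rev(topo))  # reverse topological ids
  memb <- rank[memb]
  cedges$from <- rank[cedges$from]; cedges$to <- rank[cedges$to]
  rownames(cedges) <- NULL
  scc <- unname(split(seq_len(n), factor(memb, levels = seq_len(comp$no))))
  terminal <- !(seq_len(comp$no) %in% cedges$from)
  structure(list(membership = memb, scc = scc, edges = cedges,
                 terminal = terminal),
            class = "stg_condensation")
}

#' @export
print.stg_condensation <- function(x, ...) {
  cat(sprintf("condensation: %d SCCs (%d terminal), %d edges\n",
              length(x$scc), sum(x$terminal), nrow(x$edges)))
  invisible(x)
}

#' Attractors of a state transition graph
#'
#' The attractors are exactly the terminal SCCs of the STG: a single state
#' with no outgoing transition is a stable state; a larger terminal SCC is a
#' cyclic attractor.
#'
#' @param stg an [build_stg()] result.
#' @return A list of objects of class `attractor`, each with `states`
#'   (integer matrix) and `kind` (`"stable_state"` or `"cyclic"`), in
#'   reverse topological order of the condensation.
#' @examples
#' attractors(build_stg(toggle_model(), inputs = c(I = 1L)))
#' @export
attractors <- function(stg) {
  cond <- condensation(stg)
  term <- which(cond$terminal)
  out <- lapply(term, function(k) {
    ix <- cond$scc[[k]]
    st <- stg$states[ix, , drop = FALSE]
    structure(list(states = st,
                   kind = if (length(ix) == 1L) "stable_state" else "cyclic"),
              class = "attractor")
  })
  names(out) <- NULL
  out
}

#' @export
print.attractor <- function(x, ...) {
  cat(sprintf("attractor (%s, %d state(s)):\n", x$kind, nrow(x$states)))
  for (i in seq_len(min(nrow(x$states), 8L)))
    cat(" ", paste0(colnames(x$states), "=", x$states[i, ], collapse = " "),
        "\n")
  if (nrow(x$states) > 8L) cat("  ...\n")
  invisible(x)
}

state_label <- function(states)
  apply(states, 1L, paste, collapse = "")

#' Export a state transition graph or its condensation to DOT
#'
#' Stable states are double-circled; states inside terminal SCCs (and
#' terminal SCC nodes in the condensation view) are shaded.
#'
#' @param stg an [build_stg()] result.
#' @param file path of the DOT file to write, or `""` for a character vector.
#' @param what `"stg"` (default) or `"condensation"`.
#' @return Invisibly, the DOT lines.
#' @export
export_stg_dot <- function(stg, file = "", what = c("stg", "condensation")) {
  what <- match.arg(what)
  cond <- condensation(stg)
  lines <- c("digraph stg {",
             sprintf("  // components: %s",
                     paste(colnames(stg$states), collapse = ",")))
  if (what == "stg") {
    lab <- state_label(stg$states)
    outdeg <- tabulate(stg$edges$from, nbins = nrow(stg$states))
    for (i in seq_len(nrow(stg$states))) {
      attrs <- sprintf("label=\"%s\"", lab[i])
      if (outdeg[i] == 0L) attrs <- paste0(attrs, ", peripheries=2")
      if (cond$terminal[cond$membership[i]])
        attrs <- paste0(attrs, ", style=filled, fillcolor=gray85")
      lines <- c(lines, sprintf("  s%d [%s];", i, attrs))
    }
    for (k in seq_len(nrow(stg$edges)))
      lines <- c(lines, sprintf("  s%d -> s%d;",
                                stg$edges$from[k], stg$edges$to[k]))
  } else {
    for (k in seq_along(cond$scc)) {
      attrs <- sprintf("label=\"%d states\"", length(cond$scc[[k]]))
      if (cond$terminal[k])
        attrs <- paste0(attrs, ", style=filled, fillcolor=gray85")
      lines <- c(lines, sprintf("  c%d [%s];", k, attrs))
    }
    for (k in seq_len(nrow(cond$edges)))
      lines <- c(lines, sprintf("  c%d -> c%d;",
                                cond$edges$from[k], cond$edges$to[k]))
  }
  lines <- c(lines, "}")
  if (nzchar(file)) writeLines(lines, file)
  invisible(lines)
}
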
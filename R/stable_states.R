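#' Enumerate context-dependent stable states
#'
#' Computes all stable states of a model across all input combinations
#' without building a state transition graph.  Stability is required of the
#' internal components only (inputs are free parameters): a full state is
#' stable iff every internal rule returns its component's current level.
#' The enumeration works on the conjunction of per-component stability
#' relations: for each internal component the satisfying assignments of
#' `K_i = s_i` over its regulators form a relation, and the relations are
#' joined component by component (a relational form of the decision-diagram
#' conjunction), pruning inconsistent partial assignments early instead of
#' sweeping the full state space.
#'
#' Identical internal states occurring under several input combinations are
#' grouped into one stable pattern carrying its input-context constraint;
#' [expand_contexts()] expands to one row per input valuation, which is the
#' unit in which context-dependent stable states are counted.
#'
#' @param model a valid [logical_model()].
#' @return An object of class `stable_patterns`: list with `internal`
#'   (data.frame, one row per distinct stable internal state, sorted
#'   lexicographically), `contexts` (list of data.frames over the inputs
#'   constrained by the stability conditions), `free_inputs` (inputs no rule
#'   depends on), and `card`.
#' @examples
#' stable_states(toggle_model())
#' @export
stable_states <- function(model) {
  card <- component_card(model)
  internal <- internal_names(model)
  ord <- component_names(model)

  rel <- as.data.frame(level_grid(integer(0)))  # single empty assignment
  for (nm in internal) {
    r <- model$rules[[nm]]
    vars <- union(r$regulators, nm)
    vars <- vars[order(match(vars, ord))]
    g <- as.data.frame(level_grid(card[vars], vars))
    ok <- eval_rule(r, as.matrix(g)) == g[[nm]]
    ri <- g[ok, , drop = FALSE]
    if (ncol(rel) == 0L) {
      rel <- ri
    } else {
      shared <- intersect(names(rel), names(ri))
      rel <- if (length(shared)) merge(rel, ri, by = shared)
             else merge(rel, ri, by = NULL)  # disjoint vars: cross join
    }
    if (nrow(rel) == 0L) break
  }

  constrained_inputs <- setdiff(names(rel), internal)
  constrained_inputs <- constrained_inputs[order(match(constrained_inputs, ord))]
  free_inputs <- setdiff(input_names(model), constrained_inputs)

  if (nrow(rel) == 0L) {
    internal_df <- as.data.frame(matrix(integer(0), 0L, length(internal),
                                        dimnames = list(NULL, internal)))
    return(structure(list(internal = internal_df, contexts = list(),
                          free_inputs = free_inputs, card = card),
                     class = "stable_patterns"))
  }

  int_df <- rel[internal]
  key <- do.call(paste, c(int_df, sep = "\r"))
  ukey <- !duplicated(key)
  internal_df <- int_df[ukey, , drop = FALSE]
  o <- do.call(order, as.list(internal_df))
  internal_df <- internal_df[o, , drop = FALSE]
  rownames(internal_df) <- NULL
  okey <- key[ukey][o]

  contexts <- lapply(okey, function(k) {
    cx <- rel[key == k, constrained_inputs, drop = FALSE]
    if (ncol(cx)) {
      cx <- unique(cx)
      cx <- cx[do.call(order, as.list(cx)), , drop = FALSE]
    } else {
      cx <- cx[seq_len(min(1L, nrow(cx))), , drop = FALSE]  # one empty row
    }
    rownames(cx) <- NULL
    cx
  })

  structure(list(internal = internal_df, contexts = contexts,
                 free_inputs = free_inputs, card = card),
            class = "stable_patterns")
}

#' Number of context-dependent stable states
#'
#' @param x a [stable_states()] result.
#' @param expanded when `TRUE` (default) each (internal state, input
#'   valuation) pair counts once; when `FALSE`, distinct internal states are
#'   counted.
#' @return Integer count.
#' @export
n_stable <- function(x, expanded = TRUE) {
  if (!expanded) return(nrow(x$internal))
  free_n <- prod(x$card[x$free_inputs])
  as.integer(sum(vapply(x$contexts, nrow, integer(1)) * free_n))
}

#' Expand stable patterns to one row per input valuation
#'
#' @param x a [stable_states()] result.
#' @return data.frame with internal components followed by input components,
#'   one row per context-dependent stable state.
#' @export
expand_contexts <- function(x) {
  free_grid <- as.data.frame(level_grid(x$card[x$free_inputs],
                                        x$free_inputs))
  rows <- lapply(seq_len(nrow(x$internal)), function(i) {
    cx <- x$contexts[[i]]
    # cross product robust to zero-column factors (0-col data.frames keep
    # their row count under subsetting, unlike merge())
    cx_full <- cbind(
      cx[rep(seq_len(nrow(cx)), times = nrow(free_grid)), , drop = FALSE],
      free_grid[rep(seq_len(nrow(free_grid)), each = nrow(cx)), ,
                drop = FALSE])
    rownames(cx_full) <- NULL
    cbind(x$internal[rep(i, nrow(cx_full)), , drop = FALSE], cx_full,
          row.names = NULL)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    return(as.data.frame(matrix(integer(0), 0L,
      ncol(x$internal) + length(x$free_inputs),
      dimnames = list(NULL, c(names(x$internal), x$free_inputs)))))
  }
  rownames(out) <- NULL
  out
}

context_expr <- function(cx, free_inputs) {
  parts <- if (ncol(cx) == 0L) rep("", nrow(cx))
           else do.call(paste, c(Map(function(nm, v) paste0(nm, "=", v),
                                     names(cx), cx), list(sep = ",")))
  free <- if (length(free_inputs)) paste0(free_inputs, "=*", collapse = ",")
          else ""
  rows <- vapply(parts, function(p)
    paste(Filter(nzchar, c(p, free)), collapse = ","), character(1))
  expr <- paste(unique(rows), collapse = " | ")
  if (!nzchar(expr)) "true" else expr
}

#' @export
print.stable_patterns <- function(x, ...) {
  cat(sprintf("stable patterns: %d internal state(s), %d context-dependent stable state(s)\n",
              nrow(x$internal), n_stable(x)))
  df <- as.data.frame(x)
  print(utils::head(df, 20L), row.names = FALSE)
  if (nrow(df) > 20L) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.stable_patterns <- function(x, ...,
                                          stringsAsFactors = FALSE) {
  ctx <- vapply(x$contexts, context_expr, character(1),
                free_inputs = x$free_inputs)
  if (length(ctx) == 0L) ctx <- character(0)
  cbind(x$internal,
        data.frame(input_context = ctx,
                   n_contexts = as.integer(vapply(x$contexts, nrow,
                       integer(1)) * prod(x$card[x$free_inputs])),
                   stringsAsFactors = FALSE))
}

#' Export stable patterns as TSV
#'
#' One row per stable pattern (or per input valuation with
#' `expand = TRUE`), columns = components plus the input-context expression.
#'
#' @param x a [stable_states()] result.
#' @param file output path or `""` for stdout.
#' @param expand expand contexts to one row per input valuation.
#' @export
export_stable_tsv <- function(x, file = "", expand = FALSE) {
  df <- if (expand) expand_contexts(x) else as.data.frame(x)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}

#' Classify stable patterns against phenotype patterns
#'
#' Annotates each stable pattern with every phenotype pattern it satisfies
#' (a phenotype pattern is a partial assignment of required levels; a stable
#' pattern satisfies it when all constrained components match) and with its
#' set of active master regulators (level >= 1).  Stable patterns expressing
#' two or more master regulators are flagged as hybrid; patterns matching no
#' phenotype are annotated `"unclassified"`.
#'
#' @param x a [stable_states()] result.
#' @param patterns named list of phenotype patterns (named integer vectors
#'   of required levels over internal components).
#' @param masters character vector of master-regulator component names.
#' @return data.frame with one row per stable pattern: the internal levels,
#'   `phenotypes` (comma-separated names or `"unclassified"`),
#'   `active_masters`, `n_masters`, and `hybrid`.
#' @export
classify_stable <- function(x, patterns, masters = character(0)) {
  internal <- names(x$internal)
  for (pn in names(patterns)) {
    p <- patterns[[pn]]
    bad <- setdiff(names(p), internal)
    if (length(bad))
      stop("classify_stable: pattern ", pn,
           " constrains non-internal component(s): ",
           paste(bad, collapse = ", "))
    out_of_range <- names(p)[p < 0L | p > x$card[names(p)] - 1L]
    if (length(out_of_range))
      stop("classify_stable: pattern ", pn, " level out of range for: ",
           paste(out_of_range, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(x$internal)), function(i) {
    lev <- unlist(x$internal[i, , drop = FALSE])
    hit <- names(patterns)[vapply(patterns, function(p)
      all(lev[names(p)] == p), logical(1))]
    act <- intersect(masters, internal)
    act <- act[lev[act] >= 1L]
    data.frame(x$internal[i, , drop = FALSE],
               phenotypes = if (length(hit)) paste(hit, collapse = ",")
                            else "unclassified",
               active_masters = paste(act, collapse = ","),
               n_masters = length(act),
               hybrid = length(act) >= 2L,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, rows) %||%
    cbind(x$internal, data.frame(phenotypes = character(0),
                                 active_masters = character(0),
                                 n_masters = integer(0),
                                 hybrid = logical(0)))
  rownames(out) <- NULL
  out
}
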
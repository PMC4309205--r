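#' Build the input-labeled transition system
#'
#' Encodes the asynchronous dynamics of a model as a single transition
#' system over the internal components only: instead of fixing the inputs
#' and obtaining one disconnected STG per input combination, each
#' asynchronous transition is labeled with the set of input valuations that
#' enable it.  An edge enabled by several valuations carries their
#' disjunction.  This is the structure over which ARCTL formulas are
#' evaluated ([sat_set()], [check_property()]).
#'
#' @param model a valid [logical_model()].
#' @param state_cap maximal number of internal states (default `2^22`).
#' @return An object of class `lts`: list with `states` (integer matrix over
#'   internal components), `edges` (data.frame `from`, `to`), `labels`
#'   (logical matrix, edges x input valuations), `valuations` (integer
#'   matrix of input levels, one row per valuation), `internal`, `inputs`,
#'   and the corresponding cardinalities.
#' @examples
#' build_lts(toggle_model())
#' @export
build_lts <- function(model, state_cap = 2^22) {
  internal <- internal_names(model)
  card_int <- component_card(model, internal)
  n <- prod(card_int)
  if (n > state_cap)
    stop_guard(sprintf("state space too large: %g internal states exceed the cap of %g",
                       n, state_cap))
  inputs <- input_names(model)
  card_in <- component_card(model, inputs)
  states <- level_grid(card_int, internal)
  vals <- level_grid(card_in, inputs)
  n_val <- nrow(vals)
  w <- mr_weights(card_int)

  from_l <- list(); to_l <- list(); val_l <- list()
  for (j in seq_len(n_val)) {
    full <- states
    if (length(inputs))
      full <- cbind(states,
                    matrix(rep(vals[j, ], each = n), nrow = n,
                           dimnames = list(NULL, inputs)))
    for (k in seq_along(internal)) {
      tgt <- eval_rule(model$rules[[internal[k]]], full)
      delta <- sign(tgt - states[, k])
      mv <- which(delta != 0L)
      if (length(mv) == 0L) next
      from_l[[length(from_l) + 1L]] <- mv
      to_l[[length(to_l) + 1L]] <- mv + delta[mv] * w[k]
      val_l[[length(val_l) + 1L]] <- rep(j, length(mv))
    }
  }
  from <- unlist(from_l) %||% integer(0)
  to <- as.integer(unlist(to_l) %||% integer(0))
  val <- unlist(val_l) %||% integer(0)

  o <- order(from, to)
  from <- from[o]; to <- to[o]; val <- val[o]
  key <- paste(from, to)
  first <- !duplicated(key)
  eid <- cumsum(first)[match(key, key)]  # id of each triple's edge
  n_edges <- sum(first)
  labels <- matrix(FALSE, nrow = n_edges, ncol = n_val)
  if (length(from)) labels[cbind(eid, val)] <- TRUE
  structure(list(states = states,
                 edges = data.frame(from = from[first], to = to[first]),
                 labels = labels, valuations = vals,
                 internal = internal, card_int = card_int,
                 inputs = inputs, card_in = card_in),
            class = "lts")
}

#' @export
print.lts <- function(x, ...) {
  cat(sprintf("lts: %d internal states, %d labeled edges, %d input valuation(s) over {%s}\n",
              nrow(x$states), nrow(x$edges), nrow(x$valuations),
              paste(x$inputs, collapse = ",")))
  invisible(x)
}

# States satisfying a partial assignment over internal components.
pattern_states <- function(lts, pattern) {
  bad <- setdiff(names(pattern), lts$internal)
  if (length(bad))
    stop("pattern constrains non-internal component(s): ",
         paste(bad, collapse = ", "))
  out_of_range <- names(pattern)[pattern < 0L |
    pattern > lts$card_int[names(pattern)] - 1L]
  if (length(out_of_range))
    stop("pattern level out of range for: ",
         paste(out_of_range, collapse = ", "))
  ok <- rep(TRUE, nrow(lts$states))
  for (nm in names(pattern))
    ok <- ok & lts$states[, nm] == pattern[[nm]]
  ok
}
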
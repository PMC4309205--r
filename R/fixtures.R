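#' Toy model fixtures
#'
#' Hand-built models with fully known behavior, used throughout the
#' documentation and the test suite.
#'
#' * `toggle_model()`: a minimal mutual-inhibition (positive circuit) system
#'   with one Boolean input: components `I` (input), `A`, `B`;
#'   `K_A = 1` iff `I = 1` and `B = 0`; `K_B = 1` iff `A = 0`.  It has three
#'   context-dependent stable states: `(A=0,B=1)` under both input values and
#'   `(A=1,B=0)` under `I = 1` only.
#' * `negative_circuit_model()`: Boolean `A`, `B` with `K_A = [B = 0]`,
#'   `K_B = [A = 1]` — a negative circuit with no stable state and a single
#'   cyclic attractor through all four states (asynchronously).
#' * `step_model()`: ternary component `M` (max 2) driven by a Boolean input
#'   `J`: `K_M = 2` if `J = 1`, else `0`; under unitary updating `M` moves one
#'   level at a time.
#' * `self_activator_model()`: one Boolean component `C` with
#'   `K_C = [C = 1]`, the smallest positive circuit.
#' * `constant_model()`: one Boolean component `C` with `K_C = 0`.
#'
#' @return A [logical_model()].
#' @name fixtures
NULL

#' @rdname fixtures
#' @export
toggle_model <- function() {
  comps <- data.frame(name = c("I", "A", "B"), max_level = 1L,
                      is_input = c(TRUE, FALSE, FALSE))
  rules <- list(
    A = logical_rule("A", c("I", "B"), c(2L, 2L),
                     function(s) as.integer(s["I"] == 1L && s["B"] == 0L)),
    B = logical_rule("B", "A", 2L, function(s) as.integer(s["A"] == 0L)))
  logical_model(comps, rules)
}

#' @rdname fixtures
#' @export
negative_circuit_model <- function() {
  comps <- data.frame(name = c("A", "B"), max_level = 1L, is_input = FALSE)
  rules <- list(
    A = logical_rule("A", "B", 2L, function(s) as.integer(s["B"] == 0L)),
    B = logical_rule("B", "A", 2L, function(s) as.integer(s["A"] == 1L)))
  logical_model(comps, rules)
}

#' @rdname fixtures
#' @export
step_model <- function() {
  comps <- data.frame(name = c("J", "M"), max_level = c(1L, 2L),
                      is_input = c(TRUE, FALSE))
  rules <- list(
    M = logical_rule("M", "J", 2L, function(s) if (s["J"] == 1L) 2L else 0L))
  logical_model(comps, rules)
}

#' @rdname fixtures
#' @export
self_activator_model <- function() {
  comps <- data.frame(name = "C", max_level = 1L, is_input = FALSE)
  rules <- list(C = logical_rule("C", "C", 2L,
                                 function(s) as.integer(s["C"] == 1L)))
  logical_model(comps, rules)
}

#' @rdname fixtures
#' @export
constant_model <- function() {
  comps <- data.frame(name = "C", max_level = 1L, is_input = FALSE)
  rules <- list(C = logical_rule("C", outputs = 0L))
  logical_model(comps, rules)
}

#' Synthetic T-helper demonstration network
#'
#' A small hand-built signaling/transcription network illustrating Th1/Th2
#' lineage commitment: antigen presentation (`APC`) activates a T-cell
#' receptor proxy (`TCR`); the polarizing cytokine inputs `IL12_e` and
#' `IL4_e` signal through `STAT4` and `STAT6` to the mutually inhibitory
#' master regulators `TBET` and `GATA3`, which drive the autocrine cytokines
#' `IFNG` (via `STAT1`) and `IL4`.  This fixture is **synthetic and
#' didactic**: it mirrors the classic mutual-inhibition motif of Th
#' differentiation but is not a published curated model.
#'
#' @return A [logical_model()] with 11 components (3 inputs).
#' @export
th_demo_model <- function() {
  b <- function(x) as.integer(x)
  comps <- data.frame(
    name = c("APC", "IL12_e", "IL4_e",
             "TCR", "STAT1", "STAT4", "STAT6",
             "TBET", "GATA3", "IFNG", "IL4"),
    max_level = 1L,
    is_input = c(TRUE, TRUE, TRUE, rep(FALSE, 8L)))
  card2 <- function(n) rep(2L, n)
  rules <- list(
    TCR = logical_rule("TCR", "APC", 2L, function(s) b(s["APC"] == 1L)),
    STAT1 = logical_rule("STAT1", "IFNG", 2L,
                         function(s) b(s["IFNG"] == 1L)),
    STAT4 = logical_rule("STAT4", c("IL12_e", "GATA3"), card2(2),
                         function(s) b(s["IL12_e"] == 1L && s["GATA3"] == 0L)),
    STAT6 = logical_rule("STAT6", c("IL4_e", "IL4"), card2(2),
                         function(s) b(s["IL4_e"] == 1L || s["IL4"] == 1L)),
    TBET = logical_rule("TBET", c("TCR", "STAT1", "STAT4", "GATA3", "TBET"),
                        card2(5), function(s)
      b(s["TCR"] == 1L && s["GATA3"] == 0L &&
          (s["STAT1"] == 1L || s["STAT4"] == 1L || s["TBET"] == 1L))),
    GATA3 = logical_rule("GATA3", c("TCR", "STAT6", "TBET"), card2(3),
                         function(s)
      b(s["TCR"] == 1L && s["STAT6"] == 1L && s["TBET"] == 0L)),
    IFNG = logical_rule("IFNG", "TBET", 2L, function(s) b(s["TBET"] == 1L)),
    IL4 = logical_rule("IL4", c("GATA3", "STAT1"), card2(2),
                       function(s) b(s["GATA3"] == 1L && s["STAT1"] == 0L)))
  logical_model(comps, rules)
}

#' Seeded random logical models
#'
#' Generates a reproducible random model for property testing: every
#' component draws a random regulator set (1 to 3 regulators among all
#' components) and a uniformly random rule table over it.  Declared signs
#' are derived from the generated rules; rules are pruned to their support,
#' so a drawn regulator without effect disappears.  The state space is
#' guarded to at most 12 binary-equivalent variables (4096 full states) so
#' that brute-force oracles stay applicable.
#'
#' @param n_components number of internal components.
#' @param n_inputs number of input components.
#' @param max_levels maximal level per component: a single integer applied to
#'   all, or a vector recycled over internal then input components.
#' @param seed integer seed; identical seeds yield identical models.
#' @return A [logical_model()].
#' @examples
#' random_model(3, 1, 1, seed = 42)
#' @export
random_model <- function(n_components, n_inputs = 0L, max_levels = 1L,
                         seed = 1L) {
  n_total <- n_components + n_inputs
  maxes <- rep_len(as.integer(max_levels), n_total)
  if (sum(log2(maxes + 1L)) > 12 + 1e-9)
    stop_guard("random_model: more than 12 binary-equivalent variables")
  internal <- if (n_components) paste0("X", seq_len(n_components)) else character(0)
  inputs <- if (n_inputs) paste0("U", seq_len(n_inputs)) else character(0)
  comps <- data.frame(name = c(internal, inputs),
                      max_level = maxes,
                      is_input = c(rep(FALSE, n_components),
                                   rep(TRUE, n_inputs)))
  card <- stats::setNames(maxes + 1L, comps$name)
  with_seed(seed, {
    rules <- lapply(internal, function(nm) {
      k <- sample.int(min(3L, n_total), 1L)
      regs <- sample(comps$name, k)
      regs <- regs[order(match(regs, comps$name))]
      n_rows <- prod(card[regs])
      logical_rule(nm, regs, card[regs],
                   sample.int(card[nm], n_rows, replace = TRUE) - 1L)
    })
    names(rules) <- internal
    logical_model(comps, rules)
  })
}
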
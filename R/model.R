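#' Logical regulatory models
#'
#' A `logical_model` represents a multivalued logical regulatory graph in the
#' Thomas formalism: a set of components, each with a discrete activity level
#' in `0:max_level`; thresholded, signed interactions between components; and
#' one logical rule per non-input component giving the level toward which that
#' component is driven in any state.  Input components carry no rule: their
#' value is environment-controlled and, in the labeled-transition encoding
#' used by [build_lts()], becomes a transition label rather than a state
#' variable.
#'
#' @param components data.frame with columns `name` (unique identifiers,
#'   `[A-Za-z0-9_]`), `max_level` (positive integer, 1 for Boolean), and
#'   `is_input` (logical).  Declaration order fixes all enumeration orders.
#' @param rules named list with one [logical_rule()] per non-input component.
#' @param interactions optional data.frame with columns `source`, `target`,
#'   `threshold`, `sign` (`"activation"`, `"inhibition"`, `"dual"` or
#'   `"unknown"`).  When omitted, interactions are derived from rule support
#'   (a regulator is kept iff the rule depends on it; the threshold is the
#'   smallest level at which crossing it changes the rule output) and rules
#'   are pruned to their support.
#'
#' @return An object of class `logical_model`.
#' @seealso [logical_rule()], [validate_model()], [toggle_model()]
#' @export
logical_model <- function(components, rules, interactions = NULL) {
  components <- as.data.frame(components, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "max_level", "is_input") %in% names(components)))
  components$name <- as.character(components$name)
  components$max_level <- as.integer(components$max_level)
  components$is_input <- as.logical(components$is_input)
  rownames(components) <- NULL

  rules <- rules[intersect(components$name, names(rules))]
  ord <- components$name
  rules <- lapply(rules, function(r) {
    ix <- order(match(r$regulators, ord))
    reorder_rule(r, r$regulators[ix])
  })

  m <- structure(list(components = components,
                      interactions = NULL,
                      rules = rules),
                 class = "logical_model")
  if (is.null(interactions)) {
    m$rules <- lapply(m$rules, prune_rule)
    m$interactions <- derive_interactions(m)
  } else {
    interactions <- as.data.frame(interactions, stringsAsFactors = FALSE)
    if (nrow(interactions) == 0L)
      interactions <- empty_interactions()
    if (is.null(interactions$sign)) interactions$sign <- "unknown"
    interactions$threshold <- as.integer(interactions$threshold)
    rownames(interactions) <- NULL
    m$interactions <- interactions[c("source", "target", "threshold", "sign")]
  }
  m
}

empty_interactions <- function() {
  data.frame(source = character(0), target = character(0),
             threshold = integer(0), sign = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a logical rule
#'
#' A rule is a total mapping from regulator-level combinations to a target
#' level, stored as a truth table over the regulators' mixed-radix grid
#' (first regulator varying fastest).  This representation supports
#' evaluation at a state, enumeration of its entries, partial evaluation,
#' and substitution of a regulator by another rule.
#'
#' @param target name of the regulated component.
#' @param regulators character vector of regulator names (may be empty for a
#'   constant rule).
#' @param card integer vector of regulator cardinalities (`max_level + 1`),
#'   parallel to `regulators`.
#' @param outputs integer vector of length `prod(card)` listing the target
#'   level for every regulator combination, or a function taking a named
#'   integer vector of regulator levels and returning a level.
#' @return An object of class `logical_rule`.
#' @export
logical_rule <- function(target, regulators = character(0),
                         card = integer(0), outputs) {
  regulators <- as.character(regulators)
  card <- as.integer(card)
  stopifnot(length(card) == length(regulators))
  n <- prod(card)
  if (is.function(outputs)) {
    g <- level_grid(card, regulators)
    outputs <- vapply(seq_len(nrow(g)), function(i) {
      as.integer(outputs(g[i, , drop = TRUE]))
    }, integer(1))
  }
  outputs <- as.integer(outputs)
  stopifnot(length(outputs) == n)
  structure(list(target = target, regulators = regulators,
                 card = card, outputs = outputs),
            class = "logical_rule")
}

# Reorder a rule's regulators (same set, new order).
reorder_rule <- function(rule, new_order) {
  if (identical(rule$regulators, new_order)) return(rule)
  stopifnot(setequal(rule$regulators, new_order))
  card_new <- rule$card[match(new_order, rule$regulators)]
  g <- level_grid(card_new, new_order)
  idx <- mr_index(g[, rule$regulators, drop = FALSE], rule$card)
  logical_rule(rule$target, new_order, card_new, rule$outputs[idx])
}

#' Evaluate a logical rule at a state
#'
#' @param rule a [logical_rule()].
#' @param state named integer vector (or one-row matrix / state matrix with
#'   named columns) covering at least the rule's regulators.
#' @return The target level(s) called for by the rule.
#' @export
eval_rule <- function(rule, state) {
  if (length(rule$regulators) == 0L) {
    n <- if (is.matrix(state)) nrow(state) else 1L
    return(rep(rule$outputs, n))
  }
  if (is.matrix(state)) {
    idx <- mr_index(state[, rule$regulators, drop = FALSE], rule$card)
  } else {
    idx <- mr_index(unname(state[rule$regulators]), rule$card)
  }
  rule$outputs[idx]
}

# Partial evaluation: fix some regulators to given levels.
rule_fix <- function(rule, assignment) {
  fix <- intersect(names(assignment), rule$regulators)
  if (length(fix) == 0L) return(rule)
  keep <- setdiff(rule$regulators, fix)
  card_keep <- rule$card[match(keep, rule$regulators)]
  g <- level_grid(card_keep, keep)
  full <- matrix(0L, nrow = nrow(g), ncol = length(rule$regulators),
                 dimnames = list(NULL, rule$regulators))
  if (length(keep)) full[, keep] <- g
  for (f in fix) full[, f] <- as.integer(assignment[[f]])
  logical_rule(rule$target, keep, card_keep, eval_rule(rule, full))
}

# Clamp a regulator's perceived level to at most `max_allowed` within a rule
# (used for interaction suppression: the source is seen as never crossing the
# suppressed threshold).
rule_clamp <- function(rule, reg, max_allowed) {
  if (!(reg %in% rule$regulators)) return(rule)
  g <- level_grid(rule$card, rule$regulators)
  g[, reg] <- pmin(g[, reg], as.integer(max_allowed))
  prune_rule(logical_rule(rule$target, rule$regulators, rule$card,
                          eval_rule(rule, g)))
}

# Substitute regulator `r_name` inside `rule` by `sub_rule` (the rule of the
# removed component).  `comp_order` fixes the regulator order of the result.
rule_substitute <- function(rule, r_name, sub_rule, comp_order) {
  stopifnot(r_name %in% rule$regulators,
            !(r_name %in% sub_rule$regulators))
  regs <- union(setdiff(rule$regulators, r_name), sub_rule$regulators)
  regs <- regs[order(match(regs, comp_order))]
  card <- integer(length(regs))
  for (k in seq_along(regs)) {
    card[k] <- if (regs[k] %in% rule$regulators)
      rule$card[match(regs[k], rule$regulators)]
    else sub_rule$card[match(regs[k], sub_rule$regulators)]
  }
  g <- level_grid(card, regs)
  vr <- eval_rule(sub_rule, g)
  full <- cbind(g, matrix(vr, ncol = 1L, dimnames = list(NULL, r_name)))
  logical_rule(rule$target, regs, card, eval_rule(rule, full))
}

# Thresholds of regulator `reg` at which the rule output changes in at least
# one context.  Returns a data.frame(theta, increases, decreases).
rule_thresholds <- function(rule, reg) {
  k <- match(reg, rule$regulators)
  if (is.na(k)) return(data.frame(theta = integer(0),
                                  increases = logical(0),
                                  decreases = logical(0)))
  card <- rule$card
  others <- setdiff(seq_along(rule$regulators), k)
  g_o <- level_grid(card[others], rule$regulators[others])
  res <- vector("list", card[k] - 1L)
  for (theta in seq_len(card[k] - 1L)) {
    full_hi <- full_lo <- matrix(0L, nrow = nrow(g_o),
                                 ncol = length(rule$regulators),
                                 dimnames = list(NULL, rule$regulators))
    if (length(others)) {
      full_hi[, rule$regulators[others]] <- g_o
      full_lo[, rule$regulators[others]] <- g_o
    }
    full_hi[, reg] <- theta
    full_lo[, reg] <- theta - 1L
    d <- eval_rule(rule, full_hi) - eval_rule(rule, full_lo)
    res[[theta]] <- data.frame(theta = theta,
                               increases = any(d > 0),
                               decreases = any(d < 0))
  }
  out <- do.call(rbind, res) %||% data.frame(theta = integer(0),
                                             increases = logical(0),
                                             decreases = logical(0))
  out[out$increases | out$decreases, , drop = FALSE]
}

# Drop regulators the rule does not depend on.
prune_rule <- function(rule) {
  dead <- vapply(rule$regulators,
                 function(g) nrow(rule_thresholds(rule, g)) == 0L,
                 logical(1))
  if (!any(dead)) return(rule)
  r <- rule
  for (g in rule$regulators[dead])
    r <- rule_fix(r, stats::setNames(0L, g))
  r
}

# Derive the interaction table from rule support: one interaction per
# (source, target) pair, threshold = smallest level whose crossing has an
# effect, sign aggregated over all effective thresholds.
derive_interactions <- function(model) {
  rows <- list()
  for (r in model$rules) {
    for (g in r$regulators) {
      th <- rule_thresholds(r, g)
      if (nrow(th) == 0L) next
      inc <- any(th$increases); dec <- any(th$decreases)
      sign <- if (inc && dec) "dual" else if (inc) "activation" else "inhibition"
      rows[[length(rows) + 1L]] <-
        data.frame(source = g, target = r$target,
                   threshold = min(th$theta), sign = sign,
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty_interactions())
  out <- do.call(rbind, rows)
  ord <- model$components$name
  out <- out[order(match(out$target, ord), match(out$source, ord)), ]
  rownames(out) <- NULL
  out
}

# ---- accessors ------------------------------------------------------------

component_names <- function(model) model$components$name
input_names <- function(model) model$components$name[model$components$is_input]
internal_names <- function(model) model$components$name[!model$components$is_input]

#' Component cardinalities (max_level + 1)
#' @param model a [logical_model()].
#' @param which optional character vector of component names.
#' @return Named integer vector of cardinalities.
#' @export
component_card <- function(model, which = NULL) {
  card <- stats::setNames(model$components$max_level + 1L,
                          model$components$name)
  if (is.null(which)) card else card[which]
}

#' @export
print.logical_model <- function(x, ...) {
  n_in <- sum(x$components$is_input)
  cat(sprintf("logical_model: %d components (%d inputs), %d interactions\n",
              nrow(x$components), n_in, nrow(x$interactions)))
  mv <- x$components$name[x$components$max_level > 1L]
  if (length(mv))
    cat("  multivalued:", paste0(mv, " (max ",
        x$components$max_level[x$components$max_level > 1L], ")",
        collapse = ", "), "\n")
  invisible(x)
}

# ---- validation -----------------------------------------------------------

#' Validate a logical model
#'
#' Checks structural coherence of a model: thresholds within the source's
#' range, uniqueness of component names and of (source, target) interaction
#' pairs, rules present exactly for non-input components, rule outputs within
#' the target's range, and agreement between declared interactions and rule
#' support.  Declared interactions with no effect on their target's rule are
#' reported as non-functional (warning by default, see `non_functional`).
#'
#' @param model a [logical_model()].
#' @param non_functional how to report declared interactions that never
#'   affect their target: `"warning"` (default) or `"ignore"`.
#' @return A list with character vectors `errors` and `warnings`; a valid
#'   model yields an empty error set.
#' @export
validate_model <- function(model, non_functional = c("warning", "ignore")) {
  non_functional <- match.arg(non_functional)
  errors <- character(0); warnings <- character(0)
  comp <- model$components
  card <- component_card(model)

  dup <- comp$name[duplicated(comp$name)]
  if (length(dup))
    errors <- c(errors, paste0("duplicate component name: ", unique(dup)))
  if (any(comp$max_level < 1L))
    errors <- c(errors, paste0("max_level < 1 for component: ",
                               comp$name[comp$max_level < 1L]))
  bad_name <- comp$name[!grepl("^[A-Za-z_][A-Za-z0-9_]*$", comp$name)]
  if (length(bad_name))
    errors <- c(errors, paste0("invalid component name: ", bad_name))

  ia <- model$interactions
  for (i in seq_len(nrow(ia))) {
    if (!(ia$source[i] %in% comp$name)) {
      errors <- c(errors, paste0("interaction source unknown: ", ia$source[i]))
      next
    }
    if (!(ia$target[i] %in% comp$name)) {
      errors <- c(errors, paste0("interaction target unknown: ", ia$target[i]))
      next
    }
    if (ia$threshold[i] < 1L || ia$threshold[i] > card[ia$source[i]] - 1L)
      errors <- c(errors,
                  sprintf("threshold exceeds source max: %s -> %s (theta=%d, max=%d)",
                          ia$source[i], ia$target[i], ia$threshold[i],
                          card[ia$source[i]] - 1L))
  }
  key <- paste(ia$source, ia$target)
  if (anyDuplicated(key))
    errors <- c(errors, paste0("multiple interactions for pair: ",
                               unique(key[duplicated(key)])))

  for (nm in comp$name) {
    is_in <- comp$is_input[comp$name == nm][1]
    has_rule <- nm %in% names(model$rules)
    if (is_in && has_rule)
      errors <- c(errors, paste0("input component has a rule: ", nm))
    if (is_in && any(ia$target == nm))
      errors <- c(errors, paste0("input component has regulators: ", nm))
    if (!is_in && !has_rule)
      errors <- c(errors, paste0("missing rule for component: ", nm))
  }

  for (r in model$rules) {
    tgt <- r$target
    if (!(tgt %in% comp$name)) {
      errors <- c(errors, paste0("rule for unknown component: ", tgt))
      next
    }
    unknown <- setdiff(r$regulators, comp$name)
    if (length(unknown))
      errors <- c(errors, paste0("rule uses non-regulator: ", tgt,
                                 " <- ", unknown))
    declared <- ia$source[ia$target == tgt]
    undecl <- setdiff(intersect(r$regulators, comp$name), declared)
    if (length(undecl))
      errors <- c(errors, paste0("rule uses non-regulator: ", tgt,
                                 " <- ", undecl))
    ok_card <- intersect(r$regulators, comp$name)
    mism <- ok_card[r$card[match(ok_card, r$regulators)] != card[ok_card]]
    if (length(mism))
      errors <- c(errors, paste0("rule cardinality mismatch: ", tgt,
                                 " <- ", mism))
    if (any(r$outputs < 0L) || any(r$outputs > card[tgt] - 1L))
      errors <- c(errors, paste0("rule output out of range for: ", tgt))
  }

  if (non_functional == "warning" && length(errors) == 0L) {
    for (i in seq_len(nrow(ia))) {
      r <- model$rules[[ia$target[i]]]
      if (is.null(r)) next
      th <- rule_thresholds(r, ia$source[i])
      if (!(ia$threshold[i] %in% th$theta))
        warnings <- c(warnings,
                      sprintf("non-functional interaction: %s -> %s (theta=%d)",
                              ia$source[i], ia$target[i], ia$threshold[i]))
    }
  }

  structure(list(errors = errors, warnings = warnings),
            class = "model_validation")
}

#' @export
print.model_validation <- function(x, ...) {
  cat(sprintf("model validation: %d error(s), %d warning(s)\n",
              length(x$errors), length(x$warnings)))
  for (e in x$errors) cat("  error:", e, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Fix input components to constant levels
#'
#' Partially evaluates every rule at the given input levels and removes the
#' fixed inputs from the model (their regulatory effect is folded into the
#' remaining rules).  Useful to study a model under one environmental
#' condition with tools that expect constant inputs.
#'
#' By default the remaining regulatory structure is kept as declared, so
#' interactions rendered inert by the restriction stay in the graph and can
#' be analyzed (e.g. a circuit losing its functionality context under the
#' restriction).  With `prune = TRUE`, rules are additionally pruned to
#' their support and interactions re-derived, dropping dead regulators.
#'
#' @param model a [logical_model()].
#' @param assignment named integer vector of input levels.
#' @param prune drop regulators that lost their effect (default `FALSE`).
#' @return A [logical_model()] without the fixed inputs.
#' @export
fix_inputs <- function(model, assignment, prune = FALSE) {
  nm <- names(assignment)
  if (!all(nm %in% input_names(model)))
    stop("fix_inputs: not input components: ",
         paste(setdiff(nm, input_names(model)), collapse = ", "))
  card <- component_card(model)
  bad <- nm[assignment < 0L | assignment > card[nm] - 1L]
  if (length(bad)) stop("fix_inputs: level out of range for: ",
                        paste(bad, collapse = ", "))
  comp <- model$components[!(model$components$name %in% nm), , drop = FALSE]
  rules <- lapply(model$rules, rule_fix, assignment = assignment)
  if (prune) return(logical_model(comp, lapply(rules, prune_rule)))
  ia <- model$interactions
  ia <- ia[!(ia$source %in% nm) & !(ia$target %in% nm), , drop = FALSE]
  logical_model(comp, rules, interactions = ia)
}
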
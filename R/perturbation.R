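#' Model perturbations
#'
#' Perturbations model genetic or signaling interventions as modifications of
#' logical rules: a knock-out forces a component to 0, an ectopic expression
#' (knock-in) forces it to a fixed level, a range restriction caps the level
#' its rule can call for, and an edge suppression makes a target blind to one
#' of its regulators crossing the interaction threshold.  Perturbations on
#' several components combine independently.
#'
#' @param target name of the perturbed component (non-input; use
#'   [fix_inputs()] to fix environmental inputs).
#' @param level forced level ([ectopic()]) or maximal allowed level
#'   ([range_restriction()]).
#' @param source,threshold for [edge_suppression()]: the suppressed
#'   interaction's source and (optionally) threshold; defaults to the declared
#'   threshold of the unique (source, target) interaction.
#' @return An object of class `perturbation`.
#' @name perturbations
NULL

new_perturbation <- function(kind, target, level = NULL, source = NULL,
                             threshold = NULL) {
  structure(list(kind = kind, target = target, level = level,
                 source = source, threshold = threshold),
            class = "perturbation")
}

#' @rdname perturbations
#' @export
knock_out <- function(target) new_perturbation("knock_out", target)

#' @rdname perturbations
#' @export
ectopic <- function(target, level = 1L)
  new_perturbation("ectopic", target, level = as.integer(level))

#' @rdname perturbations
#' @export
range_restriction <- function(target, level)
  new_perturbation("range_restriction", target, level = as.integer(level))

#' @rdname perturbations
#' @export
edge_suppression <- function(source, target, threshold = NULL)
  new_perturbation("edge_suppression", target, source = source,
                   threshold = if (!is.null(threshold)) as.integer(threshold))

#' Apply perturbations to a model
#'
#' Returns a new model with the perturbations' rule modifications applied;
#' the original model is unchanged.  At most one perturbation per component
#' is allowed.  Interactions are re-derived from the modified rules' support,
#' so interactions severed by a perturbation disappear from the graph.
#'
#' @param model a [logical_model()].
#' @param perturbations a single `perturbation` or a list of them.
#' @return A perturbed [logical_model()].
#' @examples
#' m <- toggle_model()
#' stable_states(apply_perturbation(m, knock_out("B")))
#' @export
apply_perturbation <- function(model, perturbations) {
  if (inherits(perturbations, "perturbation"))
    perturbations <- list(perturbations)
  targets <- vapply(perturbations, `[[`, character(1), "target")
  unknown <- setdiff(targets, component_names(model))
  if (length(unknown))
    stop("apply_perturbation: unknown target: ",
         paste(unknown, collapse = ", "))
  if (anyDuplicated(targets))
    stop("apply_perturbation: conflicting perturbations on: ",
         paste(unique(targets[duplicated(targets)]), collapse = ", "))
  if (any(targets %in% input_names(model)))
    stop("apply_perturbation: targets are input components ",
         "(use fix_inputs): ",
         paste(intersect(targets, input_names(model)), collapse = ", "))

  card <- component_card(model)
  rules <- model$rules
  for (p in perturbations) {
    r <- rules[[p$target]]
    rules[[p$target]] <- switch(p$kind,
      knock_out = logical_rule(p$target, outputs = 0L),
      ectopic = {
        if (p$level < 0L || p$level > card[p$target] - 1L)
          stop("apply_perturbation: ectopic level out of range for ", p$target)
        logical_rule(p$target, outputs = p$level)
      },
      range_restriction = {
        if (p$level < 0L || p$level > card[p$target] - 1L)
          stop("apply_perturbation: restriction level out of range for ",
               p$target)
        prune_rule(logical_rule(r$target, r$regulators, r$card,
                                pmin(r$outputs, p$level)))
      },
      edge_suppression = {
        ia <- model$interactions
        hit <- ia$source == p$source & ia$target == p$target
        if (!any(hit))
          stop("apply_perturbation: no interaction ", p$source, " -> ",
               p$target)
        theta <- p$threshold %||% ia$threshold[hit][1]
        rule_clamp(r, p$source, theta - 1L)
      },
      stop("apply_perturbation: unknown kind ", p$kind))
  }
  logical_model(model$components, rules)
}
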
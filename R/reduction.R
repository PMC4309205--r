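#' Reduce a logical model by eliminating components
#'
#' Removes the listed components one by one, rewriting the rules of each
#' removed component's targets by substituting the removed component's rule
#' for its occurrences.  This preserves the stable states: the stable states
#' of the reduced model are in one-to-one projection correspondence with
#' those of the original.  Self-regulated components cannot be removed (the
#' substitution would be circular), including components that become
#' self-regulated through earlier removals in the list.  Input components
#' can be removed only when no rule depends on them (to fold a fixed input
#' into the rules, use [fix_inputs()]).
#'
#' Interactions of the reduced model are re-derived from the rewritten
#' rules' support, so vestigial edges vanish.  The result carries a
#' `reduced_from` attribute (removed components and a content hash of the
#' source model) that the model writers emit as provenance annotation.
#'
#' Reduction can split or isolate oscillatory behavior: cyclic attractors of
#' the original model are not guaranteed to map onto cyclic attractors of
#' the reduced one (stable states are).
#'
#' @param model a [logical_model()].
#' @param remove character vector of component names, processed in order.
#' @return The reduced [logical_model()].
#' @examples
#' reduce_model(toggle_model(), "B")
#' @export
reduce_model <- function(model, remove) {
  remove <- as.character(remove)
  unknown <- setdiff(remove, component_names(model))
  if (length(unknown))
    stop("reduce_model: unknown component: ", paste(unknown, collapse = ", "))
  src_hash <- model_hash(model)

  comp <- model$components
  rules <- model$rules
  for (r in remove) {
    users <- names(rules)[vapply(rules, function(ru)
      r %in% ru$regulators, logical(1))]
    if (comp$is_input[comp$name == r]) {
      if (length(users))
        stop("reduce_model: input ", r,
             " is still used by: ", paste(users, collapse = ", "),
             " (fix it with fix_inputs to fold it in)")
    } else {
      sub <- rules[[r]]
      if (r %in% sub$regulators)
        stop("reduce_model: component is self-regulated: ", r)
      for (t in setdiff(users, r)) {
        rules[[t]] <- prune_rule(
          rule_substitute(rules[[t]], r, sub, comp$name))
      }
    }
    comp <- comp[comp$name != r, , drop = FALSE]
    rules[[r]] <- NULL
  }
  out <- logical_model(comp, rules)
  attr(out, "reduced_from") <- list(removed = remove, source_hash = src_hash)
  out
}

# 32-bit FNV-1a content hash of a model's canonical text (used only for
# provenance annotations).
model_hash <- function(model) {
  txt <- paste(utils::capture.output({
    print(model$components)
    print(model$interactions)
    for (r in model$rules)
      cat(r$target, r$regulators, r$card, r$outputs, "\n")
  }), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
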
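#' ARCTL formulas
#'
#' Action-Restricted CTL extends CTL path quantifiers with an input
#' restriction `alpha`: quantified paths range only over transitions whose
#' input label satisfies `alpha`.  State formulas are built from atoms over
#' internal components (`f_atom("A", "=", 1)`), named phenotype patterns
#' (`f_pattern("Th1")`), the constants `f_true()` / `f_false()`, boolean
#' connectives, and the temporal operators [EAF()], [AAF()], [EAG()],
#' [AAG()], [EAX()], [AAX()], [EAU()], [AAU()].  Input restrictions are
#' built from [alpha_true()], [alpha_atom()], [alpha_assign()], named
#' environments ([alpha_env()]), and boolean connectives; named environments
#' expand to the conjunction of their input assignments, and `alpha_not()`
#' expresses queries over all input combinations except the named ones.
#'
#' The semantics used by [sat_set()] restricts the edge set to transitions
#' whose label contains at least one `alpha`-satisfying valuation; inputs
#' may change between consecutive transitions of a path as long as each
#' transition's label satisfies `alpha`.  At states with no outgoing
#' `alpha`-edge ("alpha-deadlocks"), universally quantified next is
#' vacuously true and existential next is false; maximal finite alpha-paths
#' are admitted by the G-operators, so a stable state satisfies
#' `AAG(alpha)(phi)` whenever it satisfies `phi`.
#'
#' @name arctl
NULL

f_node <- function(type, ...) structure(list(type = type, ...),
                                        class = "arctl_formula")
a_node <- function(type, ...) structure(list(type = type, ...),
                                        class = "arctl_alpha")

#' @rdname arctl
#' @export
f_true <- function() f_node("true")
#' @rdname arctl
#' @export
f_false <- function() f_node("false")
#' @param component internal component name.
#' @param op comparison operator: `"="`, `">="`, or `"<="`.
#' @param level integer level.
#' @rdname arctl
#' @export
f_atom <- function(component, op = "=", level = 1L) {
  stopifnot(op %in% c("=", ">=", "<="))
  f_node("atom", component = component, op = op, level = as.integer(level))
}
#' @param name pattern or environment name, resolved at evaluation time.
#' @rdname arctl
#' @export
f_pattern <- function(name) f_node("pattern", name = name)
#' @param phi,psi state subformulas.
#' @rdname arctl
#' @export
f_not <- function(phi) f_node("not", phi = phi)
#' @rdname arctl
#' @export
f_and <- function(phi, psi) f_node("and", phi = phi, psi = psi)
#' @rdname arctl
#' @export
f_or <- function(phi, psi) f_node("or", phi = phi, psi = psi)

#' @param alpha an input restriction.
#' @rdname arctl
#' @export
EAX <- function(alpha, phi) f_node("EAX", alpha = alpha, phi = phi)
#' @rdname arctl
#' @export
AAX <- function(alpha, phi) f_node("AAX", alpha = alpha, phi = phi)
#' @rdname arctl
#' @export
EAF <- function(alpha, phi) f_node("EAF", alpha = alpha, phi = phi)
#' @rdname arctl
#' @export
AAF <- function(alpha, phi) f_node("AAF", alpha = alpha, phi = phi)
#' @rdname arctl
#' @export
EAG <- function(alpha, phi) f_node("EAG", alpha = alpha, phi = phi)
#' @rdname arctl
#' @export
AAG <- function(alpha, phi) f_node("AAG", alpha = alpha, phi = phi)
#' @rdname arctl
#' @export
EAU <- function(alpha, phi, psi) f_node("EAU", alpha = alpha, phi = phi,
                                        psi = psi)
#' @rdname arctl
#' @export
AAU <- function(alpha, phi, psi) f_node("AAU", alpha = alpha, phi = phi,
                                        psi = psi)

#' @rdname arctl
#' @export
alpha_true <- function() a_node("true")
#' @param input input component name.
#' @rdname arctl
#' @export
alpha_atom <- function(input, op = "=", level = 1L) {
  stopifnot(op %in% c("=", ">=", "<="))
  a_node("atom", input = input, op = op, level = as.integer(level))
}
#' @param assignment named integer vector of input levels; the restriction
#'   is their conjunction.
#' @rdname arctl
#' @export
alpha_assign <- function(assignment) {
  a <- alpha_true()
  for (nm in names(assignment))
    a <- if (a$type == "true") alpha_atom(nm, "=", assignment[[nm]])
         else alpha_and(a, alpha_atom(nm, "=", assignment[[nm]]))
  a
}
#' @rdname arctl
#' @export
alpha_env <- function(name) a_node("env", name = name)
#' @param a,b input restrictions.
#' @rdname arctl
#' @export
alpha_not <- function(a) a_node("not", a = a)
#' @rdname arctl
#' @export
alpha_and <- function(a, b) a_node("and", a = a, b = b)
#' @rdname arctl
#' @export
alpha_or <- function(a, b) a_node("or", a = a, b = b)

cmp_levels <- function(x, op, level) {
  switch(op, "=" = x == level, ">=" = x >= level, "<=" = x <= level)
}

# Evaluate an input restriction to a logical vector over the LTS valuations.
eval_alpha <- function(alpha, lts, environments = list()) {
  n_val <- nrow(lts$valuations)
  rec <- function(a) switch(a$type,
    true = rep(TRUE, n_val),
    atom = {
      if (!(a$input %in% lts$inputs))
        stop("input restriction mentions a non-input: ", a$input)
      if (a$level < 0L || a$level > lts$card_in[a$input] - 1L)
        stop("level out of range in input restriction: ",
             a$input, "=", a$level)
      cmp_levels(lts$valuations[, a$input], a$op, a$level)
    },
    env = {
      e <- environments[[a$name]]
      if (is.null(e)) stop("unknown environment: ", a$name)
      rec(alpha_assign(e))
    },
    not = !rec(a$a),
    and = rec(a$a) & rec(a$b),
    or = rec(a$a) | rec(a$b),
    stop("unknown alpha node: ", a$type))
  rec(alpha)
}

#' Satisfaction set of an ARCTL formula
#'
#' Computes the exact set of LTS states satisfying a formula by set-based
#' fixpoint iteration on the alpha-restricted edge set.  `EAF(alpha)(phi)`
#' is the least fixpoint of `phi | EAX(alpha)(Z)` (zero-length paths count,
#' so `phi` states always satisfy it); `AAG(alpha)(phi)` is the complement
#' of `EAF(alpha)(!phi)`; `EAG(alpha)(phi)` is the greatest fixpoint of
#' `phi & (EAX(alpha)(Z) | alpha-deadlock)`; `AAF(alpha)(phi)` the least
#' fixpoint of `phi | (AAX(alpha)(Z) & non-deadlocked)`; the until operators
#' are analogous.
#'
#' @param lts a [build_lts()] result.
#' @param formula an [arctl] formula.
#' @param patterns named list of phenotype patterns (partial internal
#'   assignments) referenced by `f_pattern()` leaves.
#' @param environments named list of environments (partial input
#'   assignments) referenced by `alpha_env()` leaves.
#' @return Logical vector over the LTS states.
#' @examples
#' lts <- build_lts(toggle_model())
#' sat_set(lts, EAF(alpha_assign(c(I = 0L)), f_atom("B", "=", 1L)))
#' @export
sat_set <- function(lts, formula, patterns = list(), environments = list()) {
  n <- nrow(lts$states)
  edge_from <- lts$edges$from
  edge_to <- lts$edges$to

  restricted <- function(alpha) {
    av <- eval_alpha(alpha, lts, environments)
    act <- if (any(av)) rowSums(lts$labels[, av, drop = FALSE]) > 0L
           else rep(FALSE, nrow(lts$labels))
    list(from = edge_from[act], to = edge_to[act],
         deadlock = {
           dl <- rep(TRUE, n); dl[edge_from[act]] <- FALSE; dl
         })
  }
  ex <- function(E, Z) {
    pre <- rep(FALSE, n)
    pre[E$from[Z[E$to]]] <- TRUE
    pre
  }
  ax <- function(E, Z) {  # vacuously true at deadlocks
    bad <- rep(FALSE, n)
    bad[E$from[!Z[E$to]]] <- TRUE
    !bad
  }
  lfp <- function(step, init) {
    Z <- init
    repeat {
      Z2 <- step(Z)
      if (identical(Z2, Z)) return(Z)
      Z <- Z2
    }
  }

  rec <- function(f) switch(f$type,
    true = rep(TRUE, n),
    false = rep(FALSE, n),
    atom = {
      if (!(f$component %in% lts$internal))
        stop("unknown atom: state formula mentions ", f$component,
             " which is not an internal component")
      if (f$level < 0L || f$level > lts$card_int[f$component] - 1L)
        stop("level out of range in state atom: ", f$component, "=", f$level)
      cmp_levels(lts$states[, f$component], f$op, f$level)
    },
    pattern = {
      p <- patterns[[f$name]]
      if (is.null(p)) stop("unknown pattern: ", f$name)
      pattern_states(lts, p)
    },
    not = !rec(f$phi),
    and = rec(f$phi) & rec(f$psi),
    or = rec(f$phi) | rec(f$psi),
    EAX = { E <- restricted(f$alpha); ex(E, rec(f$phi)) },
    AAX = { E <- restricted(f$alpha); ax(E, rec(f$phi)) },
    EAF = {
      E <- restricted(f$alpha); phi <- rec(f$phi)
      lfp(function(Z) Z | ex(E, Z), phi)
    },
    AAF = {
      E <- restricted(f$alpha); phi <- rec(f$phi)
      lfp(function(Z) Z | (ax(E, Z) & !E$deadlock), phi)
    },
    EAG = {
      E <- restricted(f$alpha); phi <- rec(f$phi)
      Z <- phi
      repeat {
        Z2 <- phi & (ex(E, Z) | E$deadlock)
        if (identical(Z2, Z)) break
        Z <- Z2
      }
      Z
    },
    AAG = {
      E <- restricted(f$alpha); nphi <- !rec(f$phi)
      !lfp(function(Z) Z | ex(E, Z), nphi)
    },
    EAU = {
      E <- restricted(f$alpha); phi <- rec(f$phi); psi <- rec(f$psi)
      lfp(function(Z) Z | (phi & ex(E, Z)), psi)
    },
    AAU = {
      E <- restricted(f$alpha); phi <- rec(f$phi); psi <- rec(f$psi)
      lfp(function(Z) Z | (phi & ax(E, Z) & !E$deadlock), psi)
    },
    stop("unknown formula node: ", f$type))
  rec(formula)
}

#' Check an ARCTL property from a set of initial states
#'
#' A property is true iff it is verified by the whole set of initial states:
#' every state satisfying the initial-state predicate must belong to the
#' formula's satisfaction set.  The initial states outside the satisfaction
#' set form the counterexample.
#'
#' @param lts a [build_lts()] result.
#' @param init the initial-state predicate: a pattern name, a named partial
#'   internal assignment, or an [arctl] state formula.
#' @param formula the [arctl] formula to verify.
#' @param patterns,environments see [sat_set()].
#' @return An object of class `arctl_verdict`: list with `true`, `n_init`,
#'   `witness` (initial states inside the satisfaction set, as a state
#'   matrix) and `counterexample` (those outside).
#' @examples
#' lts <- build_lts(toggle_model())
#' e0 <- alpha_assign(c(I = 0L))
#' check_property(lts, c(A = 1L, B = 0L),
#'                EAF(e0, f_and(f_atom("B"), AAG(e0, f_atom("B")))))
#' @export
check_property <- function(lts, init, formula, patterns = list(),
                           environments = list()) {
  init_set <-
    if (inherits(init, "arctl_formula"))
      sat_set(lts, init, patterns, environments)
    else if (is.character(init) && length(init) == 1L && is.null(names(init))) {
      p <- patterns[[init]]
      if (is.null(p)) stop("unknown pattern: ", init)
      pattern_states(lts, p)
    } else pattern_states(lts, init)
  if (!any(init_set))
    stop(structure(class = c("logimc_vacuous_property", "error", "condition"),
                   list(message = "vacuous property: no state satisfies the initial predicate",
                        call = sys.call())))
  sat <- sat_set(lts, formula, patterns, environments)
  ok <- init_set & sat
  ce <- init_set & !sat
  structure(list(true = !any(ce), n_init = sum(init_set),
                 witness = lts$states[ok, , drop = FALSE],
                 counterexample = lts$states[ce, , drop = FALSE]),
            class = "arctl_verdict")
}

#' @export
print.arctl_verdict <- function(x, ...) {
  cat(sprintf("property %s (%d initial state(s)%s)\n",
              if (x$true) "TRUE" else "FALSE", x$n_init,
              if (x$true) "" else sprintf(", %d counterexample state(s)",
                                          nrow(x$counterexample))))
  invisible(x)
}
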
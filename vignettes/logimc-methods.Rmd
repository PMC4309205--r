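---
title: "Methods: logical models, stable states, and action-restricted model checking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: logical models, stable states, and action-restricted model checking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(logimc)
```

## The modeling formalism

`logimc` implements multivalued logical regulatory graphs in the Thomas
tradition. A model consists of components $s_1,\dots,s_n$, each with a
discrete level in $S_i=\{0,\dots,\max_i\}$ ($\max_i = 1$ for Boolean
components), interactions $(s_i,s_j,\theta)$ that are *effective* when
$s_i\ge\theta$ (with $\theta\le\max_i$), and one logical rule
$\mathcal{K}_i:\mathbb{S}\to S_i$ per non-input component giving the level
toward which $s_i$ is driven in each state. The state space is
$\mathbb{S}=\prod_i S_i$.

Two representation decisions shape everything downstream:

* **Rules are truth tables over their regulators.** Each rule stores its
  regulator list (in component-declaration order) and an output vector over
  the mixed-radix grid of regulator levels, first regulator varying
  fastest. This makes evaluation an index lookup and makes the two
  operations the package leans on — partial evaluation and substitution of
  a regulator by another rule — exact and total. Human-facing formats
  (mnet clauses, SBML-qual function terms) are compiled to this form on
  read and re-derived canonically on write.
* **Interactions track rule support.** When a model arrives without an
  explicit interaction list (mnet, the fixtures, reduced models), a
  regulator is declared iff the rule depends on it, the threshold is the
  smallest level whose crossing changes the output in some context, and
  the sign is the direction of those changes (`activation`, `inhibition`,
  or `dual` when both occur). Vestigial edges therefore vanish from
  derived graphs; declared-but-inert edges in explicit lists are kept and
  flagged by `validate_model()` as non-functional warnings (a documented
  interaction may be worth keeping even when the current rules ignore it,
  so this is configurable, default `"warning"`).

Input components carry no rule: a free input is the *absence* of a
constraint, not a self-loop. Perturbations therefore target non-input
components only; fixing an environmental input is a separate operation
(`fix_inputs()`), which partially evaluates every rule. By default
`fix_inputs()` keeps the declared regulatory structure — so a circuit
whose functionality context dies under the restriction can still be
queried — and prunes only on request.

## Updating semantics and dynamics

Updating is fully asynchronous and *unitary*: every internal component
with $\mathcal{K}_i(s)\ne s_i$ may move, alone, by exactly one level
toward its target. The unit step is a deliberate choice for multivalued
components — rules only state target values, and allowing jumps of two or
more levels would create transitions through levels the component never
actually crosses. A synchronous scheme (all called components move one
unit simultaneously, a single successor) is provided for comparison.

Stable states have out-degree zero in the STG; no self-loops are added.
The totalization that temporal-logic semantics usually requires is handled
inside the model checker (below), not by mutating the graph.

`build_stg()` expands only the reachable graph from the initial set and
aborts beyond a configurable cap (default $2^{22}$ states): the symbolic
routes — stable-state enumeration and the labeled transition system — are
the supported path for large models. SCC condensation uses igraph's
linear-time strong components; SCCs are renumbered in reverse topological
order so terminal components (the attractors) come first and output is
deterministic.

## Stable-state enumeration without the STG

A full state is stable iff $\mathcal{K}_i(s)=s_i$ for every internal $i$;
inputs are free parameters. `stable_states()` evaluates the conjunction of
these per-component stability conditions relationally: component $i$
contributes the relation over $\text{regs}(i)\cup\{i\}$ of assignments
satisfying $\mathcal{K}_i = s_i$, and the relations are natural-joined in
declaration order, pruning inconsistent partial assignments long before a
full state is formed. This is the relational counterpart of the
decision-diagram conjunction used by symbolic tools; its cost is bounded
by the largest intermediate relation, not by $|\mathbb{S}|$ (join order is
the declared component order; no reordering heuristic is attempted at the
problem sizes this package targets).

Identical internal states arising under several input combinations are
grouped into one *stable pattern* with its input-context constraint;
`expand_contexts()` produces one row per input valuation — the unit in
which context-dependent stable states are counted. Patterns are sorted
lexicographically by internal levels for reproducible output.
`classify_stable()` annotates each pattern with the phenotype patterns it
satisfies (partial-assignment subsumption), its active master regulators
(level $\ge 1$ — masters in typical differentiation models are Boolean,
so "expressed at all" is the biologically meaningful predicate), and a
hybrid flag for patterns expressing two or more masters.

## Reduction

`reduce_model()` removes components one at a time by substituting the
removed component's rule into each of its targets' rules, then re-deriving
regulators from the rewritten rules' support. Self-regulated components
cannot be removed — substitution would be circular — and a component that
*becomes* self-regulated through earlier removals in the list aborts the
run with a message naming it (the removal order is the user's; the result
is order-independent whenever every prefix is legal). Inputs can be
removed only when unused; a fixed input is folded in with `fix_inputs()`.

This construction preserves the stable states exactly: the stable states
of the reduced model are the projections of the original's, one-to-one.
It does *not* preserve oscillatory behavior in general — reduction can
split or isolate cycles — and the package makes no attempt to detect
affected cyclic attractors beyond this caveat. Removing pure output
components additionally preserves attractor reachability, which the test
suite spot-checks by STG comparison.

Reduced models carry provenance (removed components, an FNV-1a content
hash of the source) that the writers emit as annotation comments.

## The labeled transition system and ARCTL

For reachability across environments the package follows the
input-as-label encoding: instead of one disconnected STG per input
combination, `build_lts()` builds a single transition system over the
internal components only, labeling each asynchronous transition with the
set of input valuations that enable it (stored as a logical matrix edges
× valuations; an edge enabled by several valuations carries their
disjunction).

ARCTL formulas restrict path quantifiers by an input constraint $\alpha$:
the $\alpha$-edge set $E_\alpha$ contains the edges whose label includes
at least one $\alpha$-satisfying valuation. Inputs may change between
consecutive transitions of one path as long as each edge's label
satisfies $\alpha$ — this is precisely what makes "is there any (possibly
varying) input sequence that reprograms $c_1$ into $c_2$" expressible,
e.g. with a negated-environment restriction covering all input
combinations except the named prototypic ones.

`sat_set()` evaluates formulas by set-based fixpoint iteration on
$E_\alpha$:

* $EAF(\alpha)(\varphi)$ = least fixpoint of
  $Z \mapsto \varphi \cup EAX(\alpha)(Z)$ — zero-length paths count, so
  $\varphi \subseteq EAF(\alpha)(\varphi)$;
* $AAG(\alpha)(\varphi) = \neg EAF(\alpha)(\neg\varphi)$;
* $EAG(\alpha)(\varphi)$ = greatest fixpoint of
  $Z \mapsto \varphi \cap (EAX(\alpha)(Z) \cup \text{deadlock}_\alpha)$;
* $AAF(\alpha)(\varphi)$ = least fixpoint of
  $Z \mapsto \varphi \cup (AAX(\alpha)(Z)\cap$ non-deadlocked$)$;
* the until operators analogously.

**Deadlock handling is a semantic decision, not an accident.** At states
with no outgoing $\alpha$-edge, universally quantified *next* is
vacuously true and existential *next* is false, and maximal finite
$\alpha$-paths are admitted by the G-operators. The motivation is the
reprograming property itself: attractor states have no outgoing edges
under the environment that maintains them, and $AAG(e)(c_2)$ must hold
*at* a stable $c_2$-state for the property to be satisfiable at all.
Reference checkers usually totalize the transition relation instead;
both treatments agree on every property class exercised here, but exact
operator-level agreement on pathological formulas at deadlocked states is
not asserted anywhere.

`check_property()` applies the whole-initial-set convention: a property
is true iff *every* state satisfying the initial predicate is in the
satisfaction set; the initial states outside it are returned as the
counterexample (an empty initial set is reported as a vacuous property,
distinct from false). Satisfaction sets are plain logical vectors over
the internal state space; the representation sits behind `sat_set()`'s
interface, so a decision-diagram backend could replace it without
touching callers, at sizes where the explicit vectors stop being a
sensible choice.

## Reprograming graphs and strategies

`build_reprograming_graph()` instantiates
`INIT c1; EAF(e)(c2 & AAG(e)(c2))` for every ordered pattern pair and
every environment. Self-arcs ($c_1=c_2$) are computed and kept — the
absence of a self-arc is informative (a pattern not maintained under its
own polarizing condition) — and can be hidden at export. Environments fix
only their listed inputs; unlisted inputs vary freely within a phase.

Multi-phase strategies compile to nested reachability:
phase $k$ contributes $EAF(e_k)(t_k \wedge \langle\text{next}\rangle)$,
and the final phase requires stable maintenance,
$EAF(e_n)(t_n \wedge AAG(e_n)(t_n))$. Phase switches are modeled purely
by changing $\alpha$ between nested operators — no explicit switching
state or time is introduced, which matches the experimental reading of
"apply condition 1, wait, then apply condition 2".
`search_environments()` enumerates candidate-input assignments over one
or two phases (guarded), after a free-restriction existence pre-check
(`EAF` with unrestricted or negated-environment $\alpha$) that
short-circuits impossible searches.

## Formats and the command line

The `mnet` dialect is a human-writable rule format (`input I : 1`,
`A := { I=1 & B=0 : 1 ; default : 0 }`, first matching clause wins);
SBML-qual (Level 3 `qual` package) is the interchange format, so models
curated in other tools can be exported and loaded. Only the deterministic
first-match interpretation of multiple function terms is supported, and
component names are restricted to `[A-Za-z0-9_]` (Greek or decorated
names are expected to be transliterated, e.g. `RORGT`, `NFKB`). The
`logimc` script exposes the pipeline with stable exit codes (0 success /
property true, 1 property false, 2 usage or parse error, 3 resource
guard).

## The random-model generator and what the tests show

`random_model()` generates property-testing models: each internal
component draws 1–3 regulators uniformly among all components and a
uniformly random rule table over them (declared signs then derived from
the table; drawn regulators without effect are pruned). A guard keeps
models at or below 12 binary-equivalent variables (≤ 4096 full states) so
brute-force oracles remain exact companions. The oracle batteries draw
2–4 internal components and 0–2 inputs with occasional ternary levels,
giving internal state spaces of at most a few dozen states — sizes chosen
so that the $O(n^3)$ matrix-closure oracles and the exhaustive sweeps
stay trivially cheap while still covering multivalued unit-stepping,
free and constrained inputs, and disconnected dependency structures.

These random tables emulate the *combinatorics* of regulatory logic, not
its biology: real curated networks have canalizing, sparse, sign-coherent
rules, scale-free-ish wiring, and far larger state spaces. Passing the
batteries therefore certifies the algorithms (enumeration, reduction,
fixpoint semantics) — it does not certify that any particular biological
model is right, and the bundled `th_demo_model()` is exactly what its
documentation says: a synthetic didactic network wired like the classic
Th1/Th2 mutual-inhibition motif, not a curated published model.

The independent oracles are deliberately different algorithms, not
re-runs: stable states by full-grid sweep, attractors by
mutual-reachability (Warshall closure) rather than Tarjan/BFS, ARCTL by
matrix reachability with explicit lasso detection rather than fixpoint
iteration.

## Numerical and degenerate-input choices

* All enumeration orders (components, contexts, states, input
  valuations) follow component declaration order; ties never depend on
  hash order, so every output is reproducible byte-for-byte.
* A model with zero inputs has exactly one (empty) input valuation; LTS
  labels are then all-true and ARCTL collapses to CTL.
* The projection of a state set onto zero components is one empty state —
  relevant when a reduction removes every component of a subproblem.
* Writers emit a canonical clause form (one clause per non-default output
  level, most frequent level as default), making write–read–write a
  fixpoint; model equality after round-trips is semantic (truth-table)
  equality, not byte equality of inputs.
* Guards (`state_cap`, the search guard, the generator's 12-variable
  bound) raise a dedicated condition class that the CLI maps to exit
  code 3.

## Known limitations

* Cyclic attractors are found only via explicit STG construction
  (terminal SCCs); no SAT/symbolic detection of asynchronous complex
  attractors is attempted.
* Hierarchical transition graphs, priority classes, timed updating, and
  stochastic (Markovian) semantics are out of scope.
* Circuit functionality intersects per-edge contexts projected onto
  circuit-external regulators; for deeply intertwined circuits this is a
  useful approximation of the full contextual analysis, and dual-signed
  edges leave the circuit sign undefined.
* `search_environments()` enumerates at most two phases exhaustively;
  optimal or minimal strategy synthesis is not attempted.
* The explicit set backend targets models up to a few million internal
  states; beyond that, only stable-state enumeration applies.
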
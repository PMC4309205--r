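# logimc

Multivalued logical models, attractors, and action-restricted model
checking for regulatory and signaling networks.

## The problem

Signaling/transcriptional networks that control cell differentiation are
commonly modeled as *logical regulatory graphs* in the multivalued Thomas
formalism: each component *s<sub>i</sub>* carries a discrete level in
{0, …, max<sub>i</sub>}, interactions (*s<sub>i</sub>*, *s<sub>j</sub>*, θ)
become effective when *s<sub>i</sub>* ≥ θ, and a logical rule
𝒦<sub>i</sub>(s) gives the level toward which each component is driven in
state **s**. Under fully asynchronous, unitary updating the model induces a
state transition graph (STG) whose terminal strongly connected components
are the attractors — stable states read as differentiated expression
patterns, terminal cycles as oscillatory behavior. Input components stand
for environmental cues (cytokines, antigen presentation, …); every input
combination confines the dynamics to its own region of state space.
*Cell plasticity* is then the question of which environmental conditions
switch the system from one attractor (phenotype pattern) to another.

`logimc` provides the full pipeline for this kind of analysis:

- **model_core** — model definition/validation, perturbations (knock-out,
  ectopic expression, range restriction, interaction suppression),
  interaction functionality and sign derivation, regulatory-circuit
  functionality contexts;
- **dynamics** — asynchronous/synchronous STGs, SCC condensation,
  attractor identification (`attractors()`), DOT export;
- **stable_states** — enumeration of all context-dependent stable states
  across all input combinations without building the STG, plus phenotype
  classification (master regulators, hybrid patterns);
- **reduction** — elimination of non-self-regulated components by rule
  substitution, preserving the stable states exactly;
- **arctl** — an input-labeled transition system (inputs become transition
  labels, not state variables) and a set-based fixpoint model checker for
  ARCTL, the action-restricted extension of CTL: `EAF(α)(φ)` asks for a
  path to φ whose every transition is enabled by an input valuation
  satisfying α, `AAG(α)(φ)` for invariance along all α-paths, and so on;
- **reprograming** — synthesis of *reprograming graphs*: an arc
  c₁ —e→ c₂ is drawn whenever `INIT c1; EAF(e)(c2 & AAG(e)(c2))` holds,
  i.e. environment *e* can drive every c₁-state to a stably maintained
  c₂-state; plus multi-phase strategies and exhaustive environment search;
- **io_cli** — SBML-qual and a plain-text multivalued rule format
  (`mnet`), JSON side files for patterns/environments/strategies, an ARCTL
  formula parser, and a `logimc` command-line tool.

## A worked example

The bundled `toggle.mnet` fixture is a minimal mutual-inhibition switch —
two Boolean master-regulator proxies `A` and `B` (`K_A = I & !B`,
`K_B = !A`) behind one environmental input `I`:

```r
library(logimc)
m <- read_model(system.file("extdata", "toggle.mnet", package = "logimc"))
stable_states(m)
#> stable patterns: 2 internal state(s), 3 context-dependent stable state(s)
#>  A B input_context n_contexts
#>  0 1     I=0 | I=1          2
#>  1 0           I=1          1
```

Three context-dependent stable states: the `B`-dominant state is stable
under both input values, the `A`-dominant state only while the input is
present. The reprograming graph over the two phenotype patterns
(`PA = {A=1,B=0}`, `PB = {A=0,B=1}`) and the two environments
(`e0 = {I=0}`, `e1 = {I=1}`):

```r
lts  <- build_lts(m)
pats <- read_patterns(system.file("extdata", "toggle_patterns.json",
                                  package = "logimc"))
envs <- read_environments(system.file("extdata", "toggle_environments.json",
                                      package = "logimc"))
build_reprograming_graph(lts, pats, envs)
#> reprograming graph: 2 node(s), 4 arc(s)
#>   PA -[e1]-> PA
#>   PA -[e0]-> PB
#>   PB -[e0]-> PB
#>   PB -[e1]-> PB
```

Withdrawing the input (`e0`) reprograms `PA` into `PB`; `PB` is stable
under every condition, so no environment converts it back — exactly what
the single positive circuit of the model predicts. Individual properties
can be written as ARCTL strings:

```r
f <- parse_formula("EAF(e0)(PB & AAG(e0)(PB))", m, pats, envs)
check_property(lts, "PA", f$formula, pats, envs)
#> property TRUE (1 initial state(s))
```

The same pipeline runs from a shell via the installed script:

```sh
logimc stable-states toggle.mnet --expand-contexts
logimc reprogram toggle.mnet --patterns p.json --envs e.json -o graph.dot
```

A larger didactic fixture, `th_demo_synthetic.mnet`, wires the classic
Th1/Th2 mutual-inhibition motif (APC/IL12/IL4 inputs, STAT factors, TBET
and GATA3 with autocrine IFNγ/IL4 feedback). It is synthetic — built for
documentation and tests, not a curated published model — but reproduces
the expected biology: polarizing environments commit the naive state to
the matching lineage and committed states resist the opposing cytokine.

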
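---
title: "Extracting context-specific metabolic models: methods and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting context-specific metabolic models: methods and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctxcut)
```

## The problem

A genome-scale metabolic model (GEM) is a stoichiometric matrix $S$
(metabolites $\times$ reactions) with flux bounds $v_{\min} \le v \le
v_{\max}$ analysed at steady state, $Sv = 0$. Constraint-based analysis
treats the set of feasible flux vectors as a polytope and asks what the
network *can* do; flux balance analysis (FBA) picks the flux vector
maximising a linear objective over it. In any specific context — a tissue,
a cell type, a condition — only part of the network is active, and
high-throughput evidence (transcripts, proteins, metabolites) tells us,
noisily and incompletely, which part. Context-specific extraction methods
turn a GEM plus such evidence into a subnetwork, and `ctxcut` implements
the three families these methods fall into, on one shared abstraction, so
they can be compared and swapped.

Two concepts recur throughout:

* **Blocked reaction** — a reaction that cannot carry non-zero flux at
  steady state. `find_blocked_fva()` detects them by flux variability
  analysis (FVA: per reaction, minimise and maximise $v_i$ — two LPs each)
  and is the reference implementation; `check_model_consistency_mba()`
  (iterated total-flux maximisation with a seeded FVA fallback) and
  `check_model_consistency_fastcore()` (sparse-mode sweep) are the fast
  checkers, and their agreement with the reference is a tested property.
* **GPR rule** — the boolean gene–protein–reaction association. Expression
  maps through it with AND = min (a complex is limited by its scarcest
  subunit) and OR = max (isoenzymes are alternatives). Penalties map with
  the dual convention (AND = max, OR = min), which preserves order duality:
  for single-gene rules the GIM3E penalty is exactly $I_{\max}$ minus the
  mapped expression.

## The three families

### GIMME-like: similarity subject to functionality

`gimme()` solves two programs. FBA first finds the optimum
$\mathrm{RMF}_{opt}$ of a *required metabolic functionality* — a flux
objective the context is known to sustain (growth, ATP production, an
export). A second LP then minimises the *inconsistency score*

$$\mathrm{IS} = \sum_i p_i\,|v_i|, \qquad
  p_i = \max(c - d_i,\, 0),$$

over the polytope intersected with $\mathrm{RMF} \ge k \cdot
\mathrm{RMF}_{opt}$: flux through reactions expressed below the threshold
$c$ is penalised in proportion to the shortfall. $|v_i|$ is realised by
splitting each reversible reaction into two non-negative senses, so GIMME
stays an LP. The extracted model keeps reactions expressed at or above $c$
plus those carrying flux above $\varepsilon$ at the optimum (the method's
original description ends at the flux distribution; which reactions to
*keep* is a policy, and this is ours).

`gim3e()` differs in three ways: every reaction with a GPR gets a penalty
(the gene-level distance $I_{\max} - I_g$ mapped through the rule), each
metabolite with evidence of synthesis must carry at least $\varepsilon$
flux through its sink (sinks are added when missing), and each reversible
reaction is forced to a single direction by a binary variable — a MILP.
An optional flag widens the retained set to every reaction able to carry
flux on the penalty-optimal face (FVA under an objective-value
constraint) rather than only the incumbent's support; the incumbent
support is the default.

### iMAT-like: similarity without a functionality

`imat()` discretises reaction data into highly and lowly expressed sets
(`discretize()`, quantile or absolute thresholds) and maximises the number
of *matches*: a high reaction matches when $|v_i| \ge \varepsilon$ (either
sense), a low reaction when $v_i = 0$. Activation is coupled to binaries
with per-reaction big-M constants equal to the reaction's own bound
magnitude. Because many flux states can tie, `imat_classify()` re-solves
the MILP per reaction with the reaction forced active and forced inactive;
whichever forcing scores strictly higher labels the reaction `active` or
`inactive`, ties are `undetermined` — exactly the tri-state the method
family defines.

`init()` drops the discretisation and weights each reaction's inclusion
binary with a signed evidence score (`init_weights()` supplies the default
log-ratio to threshold; arbitrary weights pass through), maximising
$\sum_i w_i y_i$ where $y_i = 1 \iff |v_i| \ge \varepsilon$ and $y_i = 0$
forces $v_i = 0$. Metabolites with experimental support get mandatory net
production: $Sv = b$ with $b_m \ge \delta$ for supported metabolites and
$b_m = 0$ otherwise (a relaxed mode allows $b \ge 0$ everywhere; both
scopes are defensible readings and both are exposed). `tinit()` adds
metabolic tasks — linear combinations of fluxes that must reach a lower
bound inside the retained network — each pre-checked for feasibility in
the generic model, plus a steady-state mode ($b = 0$). Direction binaries
and task constraints are solved jointly in one MILP; solving them jointly
rather than fixing directions first is an interpretation we make
explicitly.

### MBA-like: consistency around a core

These methods return a model only, no flux prediction. The contract is:
no blocked reaction in the extracted model, and core reactions (positive
evidence) retained.

`mba_single()` scans the non-core in a given order, tentatively removes
each reaction, and measures the damage: blocked reactions split into
high-core ($e_H$), moderate-core ($e_M$) and non-core ($e_{Nc}$)
casualties. The removal commits — together with $e_M \cup e_{Nc}$ — only
when $e_H$ is empty and the moderate damage is acceptable: $e_M$ empty, or
$|e_M| < k\,|e_{Nc}|$. (The strict inequality alone would block even
harmless removals with no casualties at all; requiring it only when $e_M$
is non-empty is the reading consistent with the method's purpose of
removing reactions "unnecessary to ensure consistency".) Because the
outcome depends on the scan order, `mba()` repeats the pass over many
seeded random permutations — the published protocol uses 1000; our toy
fixtures need an order of magnitude fewer — ranks reactions by occurrence
in the population, and rebuilds the final model by adding ranked reactions
to the high core until it is consistent.

`mcadre()` replaces the manual core with an automated one: the expression
score is the *frequency* of the expressed state across binarized profiles
(GPR-mapped per sample), the core is everything scoring at or above a
threshold, and reactions whose transcripts are never expressed carry
negative evidence. Non-core reactions are removed in ascending
(expression, connectivity, confidence) order — connectivity being the mean
expression score of reactions sharing a metabolite, zero for isolated
reactions, and reaction id the final deterministic tie-break. Every
removal must leave each key metabolite producible (at least $\varepsilon$
through a temporary sink — we test producibility directly rather than only
checking whether a producing reaction became blocked, which would miss the
sole-producer case); a removal that blocks core reactions commits only for
negative-evidence reactions with acceptable damage, in which case the
blocked core goes too. This core relaxation is the method's signature.
Reactions without any GPR score zero but are never treated as negative
evidence (absence of evidence, not evidence of absence).

`fastcore()` works in the opposite direction: it grows the model around
the core with sparse flux modes. `find_sparse_mode()` is two LPs — LP1
pushes as many core reactions as possible to flux $\ge \varepsilon$ (via
auxiliary $z_i \in [0, \varepsilon]$, $v_i \ge z_i$), LP2 minimises the
genuine L1-norm of flux through the penalised non-core (auxiliary
$z \ge |v|$) while keeping the activated core active. The loop alternates
activation and penalisation, flipping the sign of reversible core columns
that resist forward activation, until the whole core is covered.
Reverse-only reactions (upper bound $\le 0$) are normalised to run forward
first. The result provably contains the core and is flux-consistent;
minimality is a tendency, not a guarantee — our tests bound the gap to the
enumerated minimum at one reaction on small fixtures.

## Parameters that matter

| parameter | meaning | default | rationale |
|---|---|---|---|
| $k$ (GIMME family) | RMF fraction to guarantee, in $[0,1]$ | 0.9 | conventional "near-optimal functionality"; always user-set |
| $c$ | expression threshold, data units | user | context- and platform-specific; no sensible universal default |
| $\varepsilon$ | activation flux, flux units | $10^{-4}$ | small against bounds of order 10–1000, large against solver noise |
| $\delta$ (INIT/tINIT) | net-production lower bound | 0.1 | qualitative "is produced"; only its sign matters at toy scale |
| $k$ (MBA) | moderate-core damage ratio | 0.5 | midpoint of the published usage range |
| $k$ (mCADRE) | core damage ratio for negative evidence | 0.33 | the method's customary third |
| `core_threshold` (mCADRE) | expression-score cut for the core | 0.5 | "expressed in at least half the profiles" |
| `n_iter` (MBA) | population size | 1000 | the published protocol's count; toy networks converge far earlier |
| blocked tolerance | FVA interval width treated as zero | $10^{-6}$ | two orders below $\varepsilon$, so activation and blocking cannot flap |
| solver tolerance | pivot/feasibility | $10^{-9}$ | one order below the blocked tolerance |

The sources this framework descends from never state numeric values for
$\varepsilon$ or the tolerances; the ladder above ($10^{-9}$ solver,
$10^{-6}$ blocked, $10^{-4}$ activation) is our choice, made once so that
each layer's noise is negligible at the next, and every value is an
exposed argument.

## Numerical and design choices

* **Solver.** All programs are LPs or MILPs over the same polytope, so the
  backend is one small interface: `solve_lp()` (dense two-phase primal
  simplex, Bland's rule — finite termination on the degenerate problems
  that upper-bound rows create) and `solve_milp()` (deterministic
  depth-first branch-and-bound on binary variables, nearer rounding
  explored first). Determinism matters: identical inputs and seeds must
  reproduce identical extractions, and do — it is a tested property. The
  tests cross-check the simplex against an independent implementation and
  the MILP against exhaustive pattern enumeration. Problem sizes in this
  package's regime (tens of variables) sit comfortably in dense-tableau
  territory; plugging in an industrial solver means reimplementing two
  functions.
* **Bounds are finite.** Missing file bounds default to $\pm 1000$, the
  GEM convention, and FVA reports at most the bound, never infinities, so
  intervals stay comparable.
* **Sign conventions.** The GIMME objective is implemented as the
  non-negative penalty $(c - d_i)\,|v_i|$ summed over sub-threshold
  reactions, so minimisation penalises — not rewards — flux through
  unexpressed reactions; the printed form of the objective in the
  literature has the opposite sign on the summand, which would do the
  reverse. Similarly the FastCORE pruning LP is implemented as a genuine
  L1 minimisation.
* **Exchanges are structural.** A reaction whose column of $S$ has a
  single non-zero entry crosses the system boundary; no annotation is
  trusted or required.
* **Missing genes** in a GPR are ignored (the subexpression drops out via
  the combiner's neutral element) because partial omics coverage is the
  norm; a strict mode errors instead. Reactions with *no* data keep an
  `NA` marker and zero penalty — never a fabricated value.
* **Ties.** `discretize()` keeps the high and low sets disjoint by letting
  the high set win shared thresholds, and refuses quantile mode on data so
  tied that the two quantiles coincide (use absolute thresholds there).
  mCADRE's removal order ends with the reaction id, for reproducibility.

## What the synthetic generator does and does not emulate

`make_toy_model()` builds uptake → chain → export backbones with parallel
routes (alternative pathways), dead-end branches (the exact blocked set:
ground truth by construction), a seeded fraction of reversible internal
reactions, and one synthetic gene per reaction (or seeded two-gene
complex/isoenzyme rules). `make_evidence()` draws gene intensities from
$\mathcal{N}(8, \sigma)$ for active and $\mathcal{N}(2, \sigma)$ for
inactive genes on a log-like scale, truncated at zero, with binary
profiles thresholded at the midpoint (5); at $\sigma = 0$ the separation
is perfect. These values define the test regime, not biology.

What this captures: the logical structure every extraction method actually
exercises — blocked subnetworks, alternative routes that force choices,
evidence that favours one route, cores that must be connected. What it
does not: genome-scale size (hundreds to thousands of reactions),
compartments, cofactor coupling, realistic degree distributions, biomass
stoichiometry, platform-specific noise. Passing tests therefore certify
algorithmic correctness — objectives reached, constraints honoured,
oracles matched — not predictive performance on real tissues.

The brute-force oracles (`brute_force_consistent_subsets()`,
`brute_force_imat()`, the direction-enumeration check for GIM3E) are exact
and exponential; size caps (14 reactions, 10 labelled reactions, 8
reversibles) keep the full suite and the acceptance script within a few
minutes on one CPU, which is also why the acceptance battery uses 100
random models for checker agreement and single-digit fixture counts for
the extraction loops.

## Known limitations

* **Thermodynamically infeasible loops are not excluded** (loopless
  constraints are out of scope). Consequence: on networks where reversible
  parallel routes form a two-reaction cycle, an L1-minimal mode can
  "activate" a core reaction by cycling flux internally without touching
  the exchanges, so FastCORE may return a smaller, loop-carried model.
  Exact ground-truth recovery is therefore stated — and tested — on
  irreversible chain/parallel fixtures.
* **iMAT's low-expression match requires $v_i = 0$ exactly** (not merely
  $|v_i| < \varepsilon$); the enumeration oracle uses the same convention,
  so the equivalence tests pin the implemented semantics, which is the
  honest claim available when the source material's constraint table is
  not reproducible.
* **INIT's retained set is certified by its incumbent** $(v, y)$: the
  binaries guarantee the incumbent pattern is simultaneously feasible, but
  no claim is made that every subset of the retained set is.
* The SBML writer/reader covers Level 3 core plus the flux-bounds/
  objective/gene-association package as this package produces it; it is an
  exchange format here, not a general SBML validator.
* `gimme()`'s retained set (`above threshold ∪ flux-carrying`) is a
  documented policy where the method family defines only the flux
  distribution.

## A minimal session

```{r example}
toy <- make_toy_model(n_linear = 3, n_parallel = 1, n_deadends = 1, seed = 4)
ev <- make_evidence(toy$model, toy$truth, noise_sd = 0, seed = 4)
d <- map_expression(toy$model, ev$gene_values)

res <- gimme(toy$model, gimme_penalty(d, threshold = 5),
             rmf = "EX_out", k = 0.9)
glance(res)
tidy(res)

# the same context by consistency pruning, no RMF needed
sort(fastcore(toy$model, C = c("r1", "r2", "r3", "p1"))$R_P)

# and the advisor's view of that situation
advise(need_flux = FALSE, core_available = TRUE)
```
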
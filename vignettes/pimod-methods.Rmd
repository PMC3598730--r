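---
title: "Process-Interaction Models: one basis, two formalisms"
author: "pimod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Process-Interaction Models: one basis, two formalisms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pimod)
```

## The modeling problem

Early signaling events are dominated by large multi-domain proteins: a
receptor carries a ligand binding site, a dimerization site and several
phosphorylation sites, and each site can change state independently.  A
complete state-based description of such a system explodes combinatorially
(a protein with $n$ independently phosphorylatable and bindable sites has up
to $3^n$ states).  Two established answers exist at different levels of
detail: *rule-based models* (BioNetGen language, BNGL), which describe
classes of reactions by patterns under the "don't care, don't write"
principle, and *logical models*, which capture the causal structure with
three-valued node states $\{0, 1, *\}$ and gate functions.

A Process-Interaction-Model (PIM) is a single structure from which both can
be generated consistently.  It is a directed graph whose nodes are
*processes* — binding, (post-translational) modification, homodimerization,
degradation — each annotated with the molecules and sites it affects (its
*reaction center*).  An edge $i \to j$ (an *influence*) states that process
$j$ occurs with different kinetics depending on whether process $i$ has
occurred.  Influences are plain (uni- or bidirectional) or *all-or-none*
(AON): the target can occur only after the source has, the typical case
being binding at a site that must first be phosphorylated.

Every node owns a *parameter table* with one row per admissible *reaction
context*, i.e. per combination of occurrence values of its preceding
processes.  A row holds a forward rate constant $k_{fw} > 0$, for reversible
processes a backward rate constant $k_{bw} > 0$, and implicitly the
equilibrium constant $k_{eq} = k_{fw} / k_{bw}$.

## From a PIM to a rule-based model

Each process node aggregates all reaction rules that share its reaction
center; its contexts enumerate exactly those rules.  `exportBngl()` emits
one rule per admissible context, with the context written identically on
both rule sides and only the center sites changing:

```{r small-bngl}
small <- buildSmallExample()
bngl <- exportBngl(small)
bngl[grep("begin reaction rules", bngl):grep("end reaction rules", bngl)]
```

Admissibility removes two kinds of context: assignments where an AON
predecessor has not occurred, and assignments where two predecessors that
compete for a common binding site have both occurred.  Competition is
detected only when the shared site lies on a reaction-center molecule of the
target: there it is a single pattern instance that can hold one bond.  A
site shared on a non-center molecule — one ligand species binding two
receptor domains — is no conflict, because each occurrence attaches its own
copy of the ligand; the generated patterns make this explicit.

Homodimerization needs duplicated context columns (the two monomers need
not be in the same state).  Contexts are unordered monomer pairs, and rules
whose monomers are in identical states carry $0.5\,k_{fw}$, the usual
symmetry correction.  Degradation is irreversible by definition and emits
deletion rules (`A(...) -> 0`), restricted to single molecules.

Seed species are the uncomplexed molecules with all sites unmodified at
concentration 1 (a placeholder to be adjusted before simulation).
Parameters are named `kf_n<node>_c<contextbits>` so every rate constant is
traceable to its table row.

`dropMolecule()` produces scenario variants: it removes the molecule's
processes, cascades through AON prerequisites that can no longer be met,
and collapses downstream tables by fixing the removed predecessors to 0.

## Discretization: parameter tables as truth tables

Two thresholds $t_1 < t_2$ turn each table row into a three-valued output:
$y = 1$ if $k_{eq} \ge t_2$ (the context makes the process occur), $y = 0$
if $k_{eq} \le t_1$, otherwise $y = *$ (unknown).  Irreversible processes
use $k_{fw}$ in place of $k_{eq}$.  Comparisons are inclusive and exact; no
epsilon is applied, since thresholds and rates are user-chosen numbers.
Thresholds are global with optional per-process overrides
(`thresholds(pim)$overrides`), the hook `sweepThresholds()` reuses.

Three conventions complete the truth table: AON-violating contexts are
explicit $0$ rows; mutual-exclusion contexts (impossible kinetically but
meaningful logically, where both competing bindings are represented by
independent nodes) take a per-row logical override, defaulting to $*$; and
homodimerization tables keep only the equal-monomer rows, since the logical
view assumes all copies of a species share one state.

## The site-specific logical model

The logical model is built in two steps.  First the *interaction graph*:
one L-node per referenced (molecule, site), one *basal activity* L-node per
molecule — the model inputs, encoding presence/absence — and one L-node per
degradation process.  Every P-node is associated with exactly one L-node
(the *corresponds-to* relation): a modification or homodimerization process
with its unique site; a binding gated by an AON from a modification of one
of its own sites with the *partner* site (the modified site already belongs
to the modification process); an ungated binding with one of its two sites.
Edges are: activating from each basal node to its molecule's sites;
activating along the free-partner correspondence (the partner site merely
passes the basal value on); one unsigned edge per PIM influence, between
the corresponding L-nodes and with the same orientation; and a
delay-flagged inhibiting edge from each degradation node onto its
molecule's basal node.

Second, gates: each L-node with a corresponding P-node interprets that
node's truth table as a logical function of its unsigned inputs, minimized
into disjunctive normal form by the Quine–McCluskey algorithm (prime
implicants, essential primes, then a greedy cover with deterministic
tie-breaks — fewest literals, then term order), AND-conjoined with all
activating inputs.  L-nodes without a P-node get the plain AND of their
activating inputs; nodes without inputs are the model inputs.  Negative
literals arise naturally when a table row demands a predecessor's absence.

Design choices worth making explicit:

* **Orientation tie-break.**  For a binding without prior modification one
  of the two sites must be chosen to represent the process.  The package
  claims the site of the second-listed molecule by default
  (`orientation = "second"`); the choice is arbitrary and verified not to
  affect steady states away from the pair.  When exactly one of the two
  sites is itself a modification site, that site already carries
  modification state, so the plain site is claimed regardless of
  orientation and the pass-through activating edge comes from the partner's
  basal node rather than from the modifiable site (whose activity would
  wrongly read as "modified").
* **Auxiliary nodes.**  When one molecule binds, through a single physical
  site, two different partners (e.g. one adaptor binding two receptors),
  two binding P-nodes would claim the same L-node.  An auxiliary L-node
  (`site#processId`) is inserted for the later process so the
  correspondence stays one-to-one; the lowest-id process keeps the plain
  site name.
* **Unknown outputs (ITT gates).**  Tables containing $*$ cannot be
  minimized as boolean functions.  The default `"conservative"` policy
  excludes unknown rows from both the on- and off-set and runs the
  minimization with them as don't-cares, flagging the gate `itt = TRUE`;
  policies `"as0"`/`"as1"` force them instead.  The conservative default
  keeps the gate's behaviour on defined rows exact and auditable.
* **Multiple gate routes** into one node are OR-combined; after auxiliary
  insertion this is a defensive default rather than a common case.

## Three-valued analysis

`steadyState()` iterates all gates synchronously under Kleene logic from
the all-unknown state with the scenario's inputs fixed.  Since Kleene
AND/OR/NOT are monotone in the information order ($* \sqsubseteq 0, 1$),
values only ever become defined, the iteration reaches the least fixed
point in at most one pass per node, and nodes on unresolved feedback loops
stay $*$ — which is exactly the desired reading, e.g. for the
high-threshold variant below where ligand binding and dimerization require
each other.  Delay-flagged degradation edges are excluded, so the result is
the pre-degradation response; the affected edges are recorded on the gates.

`equivalenceClasses()` enumerates all $2^k$ completions of $k$ undefined
inputs ($k \le 16$), computes each steady state, and groups nodes by their
value vector; constant nodes are input-independent and reported separately.
`minimalInterventionSets()` searches knockout sets (nodes fixed to 0, up to
`kmax` $\le 4$, exhaustively) that prevent a target's activation — its
steady value must be defined and different from the prevented value, so an
unresolved $*$ does not count as blocked — and keeps only subset-minimal
sets.  Candidates default to all site, auxiliary and basal nodes except the
scenario's stimulus inputs; the target itself is a legitimate candidate
(blocking a binding site directly is an intervention at the site level).

## The shipped models

`buildSmallExample()` is a four-process teaching system (ligand A, effector
B, receptor R with one binding and two phosphorylation sites) whose node-2
kinetics make an OR-shaped gate at the default thresholds
$t_1 = 0.01, t_2 = 0.1$.

`buildEgfInsulin()` is an 18-process model of early insulin/EGF receptor
crosstalk: two mutually influencing insulin binding domains feeding two
receptor phosphorylations, AON-gated recruitment of Shc and IRS, Shc
phosphorylation on either receptor recruiting Grb2 and then Sos, IRS
phosphorylation recruiting PI3K, and an EGF arm with ligand binding,
receptor homodimerization, two phosphorylations and recruitment of Shc and
Grb2.  Shc and Grb2 each use one physical binding site for both receptors,
which exercises both the mutual-exclusion rows and the auxiliary-node
insertion.

The graph structure is what the crosstalk literature describes; the kinetic
values, however, are **synthetic**: they are drawn once from the grid
$\{0.001, 0.01, 0.1, 0.25, 1\}$ so that the derived logical models show the
intended qualitative regimes, and they are not calibrated to measured
rates.  Concretely, at the default thresholds the model $M$ has
ligand-dependent receptor phosphorylation and binding-dependent Shc/IRS
phosphorylation; lowering both thresholds to $(0.001, 0.01)$ ($M_{down}$)
loses the binding dependence of the Shc/IRS phosphorylations (they reduce
to basal activity); raising them to $(0.1, 0.25)$ ($M_{up}$) adds the
mutual inhibition of the two insulin binding sites and makes EGF binding
and dimerization require each other, deadlocking that arm.  The gate
dependencies nest, $M_{down} \subseteq M \subseteq M_{up}$.

What passing analyses on these fixtures shows, therefore, is that the
*derivations* are correct — rule counts equal to the combinatorial context
counts (8 and 36 rules), three equivalence classes under undefined
insulin/EGF inputs (an insulin arm, an EGF arm, and the shared
Shc–Grb2–Sos tail), and the nine documented knockout sets preventing
Grb2–Shc binding under insulin stimulation.  It does not validate the
synthetic rate values against biology.

`randomPim()` drives the property tests: structurally valid random PIMs
(influences restricted to pairs whose context is expressible in a rule
pattern; AON only from a modification onto a binding at the modified site;
at least one decided context per node so gates are always synthesizable).
It emulates graph/table structure, not realistic kinetics, and random
models contain no long signaling cascades, so cascade behaviour is covered
by the two fixtures instead.

## Numerical and scale choices

All problem sizes here are small by construction: the largest table has
$2^4$ rows, gate minimization is exercised up to 10 inputs (exhaustively
checked against the defining table), equivalence-class enumeration is
capped at 16 undefined inputs and intervention search at $k_{max} = 4$.
The default test suite uses 200–300 random models per property; the
acceptance script re-checks the rule-count/round-trip/validity properties
on 200 seeded models and runs in well under a minute.  Determinism is a
design goal throughout: ascending-id predecessor order, binary-counting
context order, canonical YAML serialization (byte-identical round trips),
and deterministic QMC tie-breaks.

## Known limitations

* Influences whose context cannot be written into a rule pattern (source
  process on a molecule unconnected to the target's reaction center) are
  rejected rather than approximated.
* Compartments are not modeled; a compartment change can be encoded as an
  ordinary modification process if needed.  Synthesis processes are out of
  scope (their logical models would add nothing, as basal activities are
  inputs), as are ODE generation and simulation — the BNGL export is meant
  to be consumed by external rule-based tooling.
* The timed semantics of degradation feedback is not implemented; delay
  edges are carried as metadata and excluded from steady states.
* `minimalInterventionSets()` is a brute-force search; it is exact but not
  meant for large models or deep intervention sets.
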
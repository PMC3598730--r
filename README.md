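# pimod — Process-Interaction Models for signaling systems

Signal transduction is carried by multi-domain proteins whose sites bind
and get modified independently, so state-based models explode
combinatorially. Two formalisms tame this at different levels of detail:
**rule-based models** (BNGL patterns, "don't care, don't write") for
quantitative work, and **three-valued logical models** for causal analysis.
Keeping two hand-written models of one system consistent is error-prone.

`pimod` implements the **Process-Interaction-Model (PIM)**: a directed
graph whose nodes are processes (binding, modification, homodimerization,
degradation) and whose edges say that a process's kinetics depend on
whether another process has occurred. Each node carries a parameter table
with one row per reaction context, holding `k_fw`, `k_bw` and thereby
`k_eq = k_fw / k_bw`. From this single structure the package generates:

* a complete **BNGL model** — one reaction rule per admissible context
  (all-or-none prerequisites and competing-site exclusions pruned),
  parameters transferred row by row;
* a **site-specific logical model** — per-site and per-molecule L-nodes,
  edges mirroring the influences, and DNF gate functions obtained by
  discretizing each table with thresholds `t1 < t2`
  (`y = 1` iff `k_eq >= t2`, `y = 0` iff `k_eq <= t1`, else unknown `*`)
  and minimizing with the Quine–McCluskey algorithm;
* **analyses** of the logical model: Kleene three-valued steady states,
  species equivalence classes over undefined inputs, and minimal
  intervention sets (knockout combinations blocking a target).

The package is intended for modelers of early signaling events who want
one auditable model basis, plus reproducible conversions for BioNetGen-
style simulation and CellNetAnalyzer-style structural analysis.

## Worked example

```r
library(pimod)

pim <- buildSmallExample()      # ligand A, effector B, receptor R(b1, p1, p2)
validatePim(pim)
#> PIM validation: OK (0 errors, 0 warnings)

bngl <- exportBngl(pim)
bnglRuleCount(bngl)
#> [1] 8
```

The 8 rules split 1/4/2/1 over the four processes: process 2 (phosphorylation
of `R.p1`) depends on two other processes, so all four context combinations
become rules, e.g.

```
R(b1,p1~U,p2~U) <-> R(b1,p1~M,p2~U) kf_n2_c00, kb_n2_c00
R(b1!2,p1~U,p2~M).A(b1!2) <-> R(b1!2,p1~M,p2~M).A(b1!2) kf_n2_c11, kb_n2_c11
```

while the all-or-none gated binding of B to phosphorylated `p1` yields the
single rule `B(b1) + R(p1~M) <-> B(b1!1).R(p1~M!1)`.

The logical side of the same model:

```r
model <- deriveLogicalModel(pim)           # thresholds t1 = 0.01, t2 = 0.1
gateFunctions(model)[["R.p1"]]$terms
#> [[1]]
#> [1] "R.p2"
#>
#> [[2]]
#> [1] "R.b1"
steadyState(model, makeScenario(model, off = "A"))[c("R.b1", "R.p1", "B.b1")]
#>  R.b1  R.p1  B.b1
#>   "0"   "1"   "1"
```

`R.p1` is an OR gate (binding of A *or* prior `p2` modification suffices at
these thresholds), so removing molecule A still activates the pathway.

The 18-process EGF–insulin crosstalk model (synthetic kinetics, see
`?buildEgfInsulin` and the vignette) exercises everything at once:

```r
egf <- buildEgfInsulin()
bnglRuleCount(exportBngl(egf))
#> [1] 36
m <- deriveLogicalModel(egf)
ec <- equivalenceClasses(m, makeScenario(m, undefined = c("ins", "egf")),
                         undefined = c("ins", "egf"))
length(ec$classes)
#> [1] 3
mis <- minimalInterventionSets(m, makeScenario(m, on = "ins", off = "egf"),
                               target = "grb2.b_shc", kmax = 2)
length(mis)
#> [1] 9
mis[[9]]
#> [1] "ir.b_ins"  "ir.b_ins2"
```

The three classes are the insulin-specific arm, the EGF-specific arm and
the shared Shc–Grb2–Sos tail; the nine intervention sets range from
removing whole proteins (basal knockouts) to blocking single binding or
phosphorylation sites, with the two insulin binding domains only effective
as a pair.

A command-line front end wraps these functions
(`inst/scripts/pim-tools.R`): `validate`, `export-bngl`, `truth-tables`,
`export-logic`, `analyze-classes`, `analyze-mis`, `sweep-thresholds`.

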
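Package: pimod
Title: Process-Interaction Models for Rule-Based and Site-Specific Logical
    Modeling of Signal Transduction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Defines the Process-Interaction-Model (PIM): a directed graph of
    signaling processes (binding, modification, homodimerization,
    degradation) with per-node kinetic parameter tables. From a single PIM
    the package generates a complete rule-based model in BioNetGen language
    (BNGL) and, after threshold discretization of the kinetics, a
    site-specific three-valued logical model with gate functions synthesized
    by the Quine-McCluskey algorithm. Logical analysis utilities compute
    three-valued steady states, species equivalence classes and minimal
    intervention sets. Ships a four-process teaching example and an
    18-process EGF-insulin crosstalk model (synthetic kinetic values), plus
    a random-PIM generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'pim-core.R'
    'pim-io.R'
    'fixtures.R'
    'random-pim.R'
    'discretize.R'
    'rulegen.R'
    'qmc.R'
    'logicgen.R'
    'logic-analysis.R'
    'sweep.R'
    'zzz.R'
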
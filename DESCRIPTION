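Package: caulocycle
Title: Hybrid ODE/Event Model of the Caulobacter crescentus Cell Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic hybrid simulator of the Caulobacter crescentus
    cell cycle coupling chromosome replication and methylation, the five
    master regulators (DnaA, GcrA, CtrA, CcrM, SciP) with explicit mRNAs,
    and hierarchical ClpXP-dependent proteolysis of CtrA through three
    adaptor-primed protease complexes.  Continuous dynamics are Hill-type
    mass-action ODEs integrated with event location for the discrete
    replication/division milestones (initiation, fork passage of the ccrM
    and ctrA loci, termination, Z-ring constriction).  Includes limit-cycle
    period detection, a quasi-steady-state variant for the third protease
    complex, a panel of knockout and proteolysis mutants, synthetic
    observation-set generation, and two-objective (trajectory misfit vs.
    cycle-period error) parameter estimation by an elitist nondominated
    sorting genetic algorithm with Pareto archiving and perturbation
    sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
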
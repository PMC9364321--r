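Package: dockbench
Title: Deterministic Docking Pipeline with Benchmark Suites for
    Docking-Score Machine Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A deterministic ligand and receptor preparation pipeline for
    AutoDock-family docking with a pluggable scoring backend, together with
    dataset tooling (fingerprints, Jaccard-distance DBSCAN clustering,
    generic Bemis-Murcko scaffolds, cluster-respecting train/test splits,
    druglikeness profiling) and three benchmark suites for evaluating
    machine-learning models on docking scores: regression metrics,
    enrichment-factor virtual screening, and QED-penalized de novo design
    under a fixed evaluation budget.  Baseline optimizers are included: a
    Tanimoto-kernel Gaussian process with a Bayesian-optimization loop (UCB
    and expected improvement), a graph genetic algorithm, a SELFIES genetic
    algorithm, fingerprint similarity search, and a random baseline.
    Ligand chemistry (parsing, protonation at physiological pH, 3D
    embedding, MMFF94 refinement, Gasteiger charges, PDBQT emission) is
    delegated to Open Babel through ChemmineR/ChemmineOB.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    ChemmineOB,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
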
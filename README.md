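# dockbench

Deterministic ligand/receptor preparation for AutoDock-family docking, plus
the benchmark suites used to evaluate machine-learning models on docking
scores — regression, enrichment-factor virtual screening, and QED-penalized
*de novo* molecular design under a fixed evaluation budget — with classical
baseline optimizers.

Docking scores are heuristic estimates of protein–ligand binding free
energy; lower (more negative) is better, and in practice they fall between
−13 and −4. A reproducible pipeline from SMILES string to scored pose is
the prerequisite for using them as machine-learning targets, and a set of
shared benchmark definitions is what makes model comparisons meaningful.
This package provides both, for:

* **method developers** benchmarking regressors, rankers, or molecule
  optimizers against docking-score objectives;
* **computational chemists** who need a scripted, deterministic
  prep-and-dock path with explicit rejection accounting.

## What is inside

| Area | Functions (selection) |
|---|---|
| Ligand prep | `validate_ligand`, `adjust_protonation`, `embed_conformer`, `prepare_ligand`, `ligand_to_pdbqt` |
| Target prep | `derive_search_box`, `prepare_target`, `null_adapter`, `obabel_adapter` |
| Docking | `dock`, `best_score`, `mock_backend`, `vina_backend`, `docking_params` |
| Chemical space | `fingerprint`, `jaccard_distance`, `dbscan_jaccard`, `generic_murcko_scaffold`, `cluster_split`, `property_profile`, `qed_score` |
| Benchmarks | `regression_metrics`, `score_threshold`, `enrichment_factor`, `run_screen`, `qed_penalty`, `objective_spec`, `objective_value`, `new_ledger`, `evaluate_with_budget`, `trajectory` |
| Optimizers | `graph_ga_generation`, `selfies_ga_generation`, `gp_fit`, `gp_predict`, `bo_select_batch`, `fss_rank`, `random_baseline`, `run_optimizer` |
| Fixtures | `generate_library`, `generate_mock_targets`, `make_mini_target_fixture` |

The search box attached to every target follows the pad-and-clamp rule:
per axis, side = max(span + 2 × 12.5 Å, 30 Å), centered on the reference
ligand. The three *de novo* objectives (minimized, with
penalty = 10 × (1 − QED)):

* **F2** — `s(F2, m) + penalty`
* **Promiscuous PPAR** — `max over t in {PPARA, PPARD, PPARG} of s(t, m) + penalty`
* **Selective JAK2** — `s(JAK2, m) − min(s(LCK, m), −8.1) + penalty`

Every optimizer operates under an evaluation ledger: 5000 unique molecules
by default, cache hits free, failures charged.

A deterministic mock scoring backend (descriptor-based, squashed into the
empirical score range, with controllable inter-target correlation) makes
the whole package runnable with no docking binary and no downloads; the
AutoDock Vina adapter drives a real `vina` executable when one is
available.

## Worked example

```r
library(dockbench)

# a synthetic druglike library and a correlated two-kinase mock target set
lib <- generate_library(library_spec(2000, seed = 1))
sm  <- generate_mock_targets(
  list(mock_target_spec("JAK2"),
       mock_target_spec("LCK", correlation_to = "JAK2", rho = 0.8)),
  lib, seed = 1)
round(cor(sm$scores[, "JAK2"], sm$scores[, "LCK"]), 3)
#> [1] 0.799
range(round(sm$scores, 2))
#> [1] -12.84  -4.16

# prepare a ligand end to end
p <- prepare_ligand("CC(=O)Oc1ccccc1C(=O)O")
p
#> <prepared_ligand> CC(=O)Oc1ccccc1C(=O)[O-]  (13 atoms, net charge -1, seed 0)
sum(p$partial_charges)
#> [1] -1

# dock it against the miniature fixture target (mock backend)
tgt <- make_mini_target_fixture()
best_score(dock(tgt, "CC(=O)Oc1ccccc1C(=O)O"))
#> [1] -11.73726

# de novo design on the mock F2 objective with a small budget
sm2  <- generate_mock_targets(list(mock_target_spec("F2")), lib[1:200], seed = 1)
spec <- objective_spec("F2")
q    <- qed_cached(lib[1:200])
init <- data.frame(
  smiles = lib[1:200],
  value  = vapply(seq_len(200), function(i)
    objective_value(spec, c(F2 = sm2$scores[i, "F2"]), q[[i]]), numeric(1)))
res <- run_optimizer("graph_ga", spec, mock_score_function(sm2$weights),
                     init, budget = 200, seed = 1,
                     ga = ga_config(population_size = 50, seed = 1))
res$best$value   # best (lowest) objective found within the budget
#> [1] -8.96479
```

The prepared aspirin record shows the pipeline working: the carboxylic
acid is deprotonated at pH 7.4 (net charge −1), and the Gasteiger partial
charges sum to that net charge. The JAK2/LCK correlation realized over the
2000-molecule library (0.799) sits within sampling error of the requested
0.8. The genetic algorithm improves the objective beyond the best initial
library value (-8.68) within its 200-evaluation budget.

A command-line umbrella over the same functions ships in
`inst/cli/dockbench.R` (`prep`, `prep-target`, `dock`, `cluster`,
`scaffolds`, `split`, `profile`, `screen`, `denovo`, `fixtures make`).

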
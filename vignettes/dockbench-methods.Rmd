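---
title: "dockbench: models, pipelines and benchmark design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dockbench: models, pipelines and benchmark design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`dockbench` packages a deterministic molecular-docking preparation pipeline
together with the dataset tooling and the three benchmark suites used to
evaluate machine-learning models on docking scores: regression, virtual
screening by enrichment factor, and QED-penalized *de novo* design under a
fixed evaluation budget, with classical baselines (Tanimoto-kernel GP
Bayesian optimization, graph and SELFIES genetic algorithms, fingerprint
similarity search, random sampling).

Everything runs download-free: a synthetic-library generator, a miniature
protein fixture and a deterministic mock scoring backend stand in for a real
docking binary wherever one is not available, behind the same interfaces.

# Ligand preparation

A ligand enters as a SMILES string and leaves as a charged, 3D-embedded
PDBQT record. The stages, and the choices behind them:

1. **Validation.** Molecules that do not parse, consist of more than one
   fragment, or carry radical electrons are rejected — as a returned value
   with a reason code, never an exception, so library-scale preparation can
   account for rejections exactly.
2. **Protonation at pH 7.4.** The default engine is Open Babel's pH
   transform model, which rewrites ionizable groups to their majority
   microstate (carboxylates deprotonate, aliphatic amines protonate, and so
   on) and is idempotent. Automated protonation is imperfect in general, so
   the engine is a plain `SMILES -> SMILES` function argument: a bespoke
   rule table can be swapped in without touching the pipeline. We chose the
   Open Babel model over a hand-maintained rule table because it is the
   engine the original preparation protocol used, it reproduces the
   textbook behavior of the common ionizable groups, and a separate table
   would only duplicate it with more surface for error.
3. **3D embedding.** One conformer per molecule, built with Open Babel's
   rule-based builder (`gen3d` at the "fast" setting) and refined with
   MMFF94 (up to 1000 iterations, convergence criterion 1e-4). We verified
   that the rotor-search-based builder settings are *not* reproducible
   across process invocations, while the rule-based builder is; since
   downstream scores must be bit-reproducible, the rule-based builder is
   the default and the only mode used. Defined stereocenters survive the
   embedding; undefined ones receive a fixed assignment that is identical
   across runs, which is the property the reproducibility contract
   requires. A seed is threaded through the API for forward compatibility
   but the default path consumes no randomness.
4. **Charges and serialization.** Gasteiger partial charges are assigned at
   PDBQT emission. Open Babel's Gasteiger routine does not seed formal
   charges, so an ionic ligand's raw charges sum to roughly zero; the
   pipeline redistributes the residual uniformly over the atoms (rounding
   residual on the largest-magnitude atom) so that the serialized record
   conserves the net formal charge exactly. The suite checks per-molecule
   charge conservation (sum of partials equals the net formal charge
   within 0.01 e) and torsion-tree consistency (declared torsions match
   the rotatable-bond count).

# Target preparation and the search box

The package computes the docking search box natively: per axis, the box
side is the reference ligand's coordinate span plus 12.5 Å padding on both
sides, raised to a 30 Å minimum; the center is the span midpoint. All atoms
present in the reference coordinate file are used (the convention when the
reference's hydrogen content is unknown). The box rule is exercised by a
property suite: translation equivariance, monotonicity under added atoms,
and the 30 Å floor.

Receptor standardization (adding polar hydrogens, PDBQT conversion) wraps
external tools behind an adapter function; a null adapter passes
pre-prepared PDBQT through for tests and fixtures, and an Open Babel
adapter handles PDB input. Element symbols are normalized before
conversion, because metal records with nonstandard case are otherwise
dropped by AutoDock-family tools. Binding sites chosen by visual
inspection are supported by passing an explicit box instead of reference
coordinates.

# Docking backends

`dock()` routes a validated ligand to a backend and returns up to
`num_modes` poses ordered by score; only the minimum (best) score feeds the
benchmarks. Defaults mirror the AutoDock Vina defaults: exhaustiveness 8,
nine modes, energy range 3. The Vina adapter shells out with an explicit
`--seed` and parses the result table, treating the binary's version as
configuration recorded in the result; its command construction and parsing
are unit-tested against a synthetic transcript so the adapter logic is
covered even where no binary exists.

The mock backend makes every benchmark runnable without Vina. It scores a
molecule as

\[ s = -8.5 - 4.5\,\tanh(z/2), \qquad z = \frac{w^\top \phi(m) - c}{\sigma} \]

where \(\phi(m)\) is a 12-dimensional descriptor vector (scaled molecular
weight, a lipophilicity proxy, ring count, H-bond donors/acceptors,
rotatable bonds, and six Morgan-fingerprint block densities) and \(w\) a
per-target weight vector. The map is bounded into \((-13, -4)\), the range
docking scores occupy empirically, so thresholds and objectives operate on
realistic magnitudes. Because \(\tanh\) is near-linear in its core and the
weighted sum is standardized over the library, two targets' scores
correlate according to the angle between their weight vectors *in the
library's descriptor covariance metric*; `generate_mock_targets()` uses
this to plant a requested inter-target correlation (e.g. the 0.8 observed
between kinase score columns) within about ±0.05 at library sizes of 2000.

A docking failure inside an optimization loop yields objective value
`+Inf` and still consumes budget — the conservative accounting that
prevents an optimizer from exploiting failures as free evaluations.

# Fingerprints, clustering, scaffolds, splits

Two binary fingerprints are implemented on the package's own molecular
graph (both computed after canonicalization, hence invariant to input atom
order): hashed linear paths of up to six bonds in 2048 bits, and a
Morgan-style radius-2 circular fingerprint folded to 1024 bits. They were
written in-package because no installed R package provides these exact
definitions; both are pinned by invariance and identity tests.

Clustering is DBSCAN under Jaccard distance with eps 0.25; the minimum
neighbor count is not fixed by the protocol, so the common default of 5 is
used, exposed in configuration. The implementation is validated against a
brute-force density-reachability oracle on instances up to n = 50. Note
one standard DBSCAN caveat: border points within eps of cores from two
different clusters are assigned to whichever cluster claims them first;
the oracle comparison therefore checks the core partition exactly and
border membership up to that ambiguity.

Generic Bemis–Murcko scaffolds iteratively prune terminal atoms until only
ring systems and linkers remain, then substitute every atom by carbon. The
stated rule fixes atom substitution only; we additionally reduce all bonds
to single order, otherwise "same scaffold" is ill-defined for
aromatic/saturated analog pairs — with the consequence that a benzene and a
cyclohexane core share a key, which is the behavior the decomposition is
meant to deliver. A second consequence of strict terminal pruning is that
exocyclic double-bonded atoms (e.g. a carbonyl oxygen on a linker) are
pruned; reference implementations that keep them will differ on such
molecules, and the tests freeze this package's convention.

Cluster splits shuffle cluster ids with a seeded RNG and assign whole
clusters greedily to the test side until the requested fraction is
reached; noise points travel as singletons. A split never divides a
cluster, is deterministic per seed, and is reported (not silently
accepted) when the achieved fraction misses the request by more than five
percentage points or the input is a single cluster.

# Druglikeness

QED is computed from eight descriptors (MW, logP, HBA, HBD, TPSA,
rotatable bonds, aromatic rings, structural alerts) through the published
asymmetric-double-sigmoid desirability functions and mean weights
(Bickerton et al. 2012), as the weighted geometric mean of normalized
desirabilities — a scalar in (0, 1]. Descriptor inputs come from Open
Babel, and the structural-alert term uses a curated fifteen-pattern SMARTS
subset of common reactive/unstable motifs rather than the full published
alert list; QED values therefore track reference implementations closely
on typical druglike molecules but can differ where alert coverage differs
(molecules carrying e.g. ester-adjacent motifs absent from the subset).
Within this package QED only ever enters objectives through the linear
penalty `weight * (1 - QED)` with weight 10 — zero for a perfectly
druglike molecule, 10 at QED = 0 — so benchmark semantics are insensitive
to small descriptor-level differences.

# Benchmarks

**Regression** reports `R^2 = 1 - SSres/SStot`, MSE and MAE; zero-variance
targets make `R^2` undefined and are reported as such. The benchmark
panels (PARP1, F2, KIT, ESR2, PGR for regression; PARP1, KIT, PGR for
screening) ship as named configuration.

**Virtual screening** ranks a library with a user-supplied model, docks
the top-k (default 5000), labels actives below a threshold, and reports
the enrichment factor — active rate in the selection over the library base
rate (1e-3 by construction in the reference setup, making 1000 the
ceiling). The activity threshold is the lowest 0.1-percentile of the
reference library's scores, implemented as the order statistic at rank
`ceil(p/100 * n)` of the ascending scores (a lower-tail convention,
recorded in output); the published per-target constants (KIT −10.7, PARP1
−12.1, PGR −10.1) are served from configuration because recomputing them
requires the full reference library. Ties at the top-k boundary break by
canonical-SMILES order for determinism. Molecules rejected by preparation
are excluded from the selection count; other backend failures count as
inactive selections.

**De novo design** minimizes one of three objectives, each carrying the
QED penalty:

* F2: `s(F2) + 10(1 - QED)`;
* Promiscuous PPAR: `max(s(PPARA), s(PPARD), s(PPARG)) + 10(1 - QED)` —
  the worst of the three scores is optimized, so all three must bind;
* Selective JAK2: `s(JAK2) - min(s(LCK), -8.1) + 10(1 - QED)` — the LCK
  score is anchored at its library median −8.1, so weakening LCK binding
  beyond the anchor brings no further gain (the anchor creates the flat
  region the tests assert).

Evaluations run through a ledger with a budget of 5000 unique molecules:
cache hits are free, failures cost budget, and the call exceeding the
budget raises a typed condition. Trajectories report the running k-th best
value (k = 1 and 25 by convention).

# Baseline optimizers

The **graph GA** selects parents fitness-proportionally on rank-transformed
objective values, recombines them by cutting one acyclic single bond in
each parent and joining complementary fragments, mutates children with
probability 0.01 (atom insertion/deletion/element swap), and keeps the
best 250 of parents plus 25 children (elitism). Crossover failures are
retried and fall back to cloning. Every emitted molecule is revalidated
through the chemistry layer, so invalid children cannot enter the
population.

The **SELFIES GA** applies exactly one token edit (insert, delete,
substitute) per child on a SELFIES-style string representation implemented
in the package: a valence-constrained derivation in which *any* token
sequence decodes to a valid molecule. The dialect covers the neutral
organic subset with nested branches and kekulized rings — the chemistry the
generator and GAs emit; molecules outside it (charged, exotic valence) are
skipped as parents. Robustness is tested with a thousand random edits and
with arbitrary garbage token streams.

The **Tanimoto GP** uses `k(a,b) = amplitude * T(a,b) + noise * 1[a = b]`
with a constant mean; hyperparameters maximize the log marginal likelihood
(L-BFGS-B on log-scale parameters) and are fixed after the initial fit.
Posterior correctness is pinned to a dense-linear-algebra oracle at 1e-8,
and parameter recovery is tested on GP-simulated data. The BO loop models
the *negated* objective so "maximize μ + 10σ" applies literally while
objectives are minimized; EI is computed in closed form against the best
observed value. Batches of five are proposed by maximizing the acquisition
with the graph GA over molecule space (offspring 1000, 25 generations by
default), without between-pick acquisition updates; an explicit
candidate-pool mode replaces the inner GA by exhaustive enumeration when a
finite pool is the search space. The training subset is the 2000 best plus
3000 random points, disjoint by construction.

GA populations initialize from the best dataset molecules by default
(`init_population = "random"` is available), the reading of "the dataset
can seed the initial population" that gives every optimizer the same
starting information as the GP.

# Synthetic data and what it does not show

The library generator decorates a fixed pool of druglike ring scaffolds
with small substituents (Poisson-distributed count, mean 2), yielding
libraries that are overwhelmingly Lipinski-compliant, with planted
radical/multi-fragment defects available for rejection accounting. It
emulates the size, druglikeness profile and scaffold redundancy of a
curated screening library; it does **not** emulate real binding-pocket
structure–activity relationships — mock scores are smooth functions of
whole-molecule descriptors, with none of the activity cliffs of real
docking landscapes. Tests passing on these fixtures certify the machinery
(accounting, invariants, orderings), not predictive performance on real
docking scores; the reference dataset-scale quantities (R² tables, EF
tables, cluster counts, real inter-target correlations) are out of
desk-reproducible scope by design.

# Problem sizes used by the test suite

The suite runs on one CPU with fixture-scale problems, chosen once:
libraries of 40–600 molecules for unit tests, 2000 for the correlation
check; DBSCAN oracle instances up to n = 50; GP oracle instances up to
n = 50 and recovery at n = 200; the optimizer-ordering comparison runs the
full budget of 1000 evaluations per optimizer over ten seeds with a
600-molecule dataset, the random baseline drawing from a 1500-molecule
library, the GA at population 100, and GP-BO proposing batches of 100 with
an inner acquisition GA of 40 offspring for 4 generations — scaled-down
counterparts of the default configurations, which remain the defaults. The
random baseline's library is deliberately much larger than its budget
covers relative to the optimizers' open search space, mirroring the
negligible coverage a random sample achieves over a commercial library.

# Known limitations

* Protonation parity with other pKa engines is not promised; the engine is
  swappable.
* The embedding builder trades conformer quality for determinism; no
  conformer ensembles, no tautomer enumeration.
* The SELFIES dialect excludes charged and hypervalent species (they are
  valid pipeline inputs, just not GA-editable).
* The generic-scaffold convention (bond-order reduction, strict terminal
  pruning) is one of several in circulation; keys from different toolkits
  are not interchangeable.
* DBSCAN border-point assignment is order-dependent, as in every standard
  implementation.
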
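---
title: "Predicting FMO sites of metabolism: models, features and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting FMO sites of metabolism: models, features and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Flavin-containing monooxygenases (FMOs) are Phase I metabolic enzymes that
oxidize soft nucleophiles — above all nitrogen and sulfur — by nucleophilic
addition, in contrast with the radical chemistry of cytochrome P450.  For a
drug candidate, knowing *which atom* the enzyme will oxidize (the site of
metabolism, SOM) guides structural optimization.  Because N- and S-oxidation
dominate FMO metabolism, every heavy N or S atom of a molecule is treated as
a *potential* SOM, and the task is a binary, atom-level classification:
SOM versus non-SOM.

`fmosom` implements that classifier and everything around it: feature
construction, dataset assembly, training, and a complete evaluation
protocol.

## The model

Each candidate atom is described by 5 quantum-mechanics (QM) features plus
numerically encoded circular-fingerprint attributes, and classified with a
radial-basis-function SVM.

### Condensed Fukui features

The electronic reactivity of atom $A$ is captured by condensed Fukui
indices, finite differences of the Mulliken population
$P_A(s) = Z_A - q_A(s)$ across three electron states of the whole molecule
(neutral $N$, anion $N{+}1$, cation $N{-}1$):

$$f_A^+ = P_A(N{+}1) - P_A(N), \qquad
  f_A^- = P_A(N) - P_A(N{-}1), \qquad
  f_A^0 = \tfrac12\left[P_A(N{+}1) - P_A(N{-}1)\right].$$

$f_A^-$ measures nucleophilicity, which is exactly the property FMO
chemistry selects for; $f_A^+$ is electrophilicity and $f_A^0$ radical
susceptibility.  Since $Z_A$ cancels in every difference, the package
computes the indices directly from the three charges.  The 5-feature QM
block is $(q_A(N),\, f_A^+,\, f_A^-,\, f_A^0,\, \mathrm{SA}_A)$ where
$\mathrm{SA}_A$ is a per-atom surface area from a continuum-solvation
calculation.

The package deliberately does **not** run electronic-structure
calculations.  Those live upstream (typically a DFT geometry optimization
followed by single points at $N\pm1$ electrons); `fmosom` ingests their
per-atom output either through a documented CSV exchange format
(`parse_population_table()`) or by scraping Mulliken-charge blocks from log
text (`parse_mulliken_log()`, last block wins, matching the convention that
post-optimization values are printed last).  Spin multiplicities of the
ionic states are stored as opaque metadata: whichever single block per
state the user supplies is used.

### Circular fingerprint attributes

Local electronics are not enough: the enzyme also senses the substructure
around the atom.  Each candidate gets a Molprint2D-style fingerprint over
the 53 Tripos SYBYL atom types: the center's type, then the frequency of
each neighbor type at one and at two bond lengths.  Its text form is
`<center>; <layer>-<freq>-<type>; ...;` and its numeric form is a
$53\times3 = 159$-slot vector (one-hot center block, then the two layer
blocks by type index).  Hydrogens are never counted — their columns would
be identically zero — and layers count atoms at their *shortest* bond
distance (BFS semantics; ring closures count once).  The phrase "within
two bonds" admits a cumulative reading in which layer 2 re-counts the
direct neighbors; we default to exact-distance counting, the standard
Molprint2D behavior, and expose `layer_mode = "cumulative"` for the other
reading since the published worked example cannot disambiguate the two.

Columns that are zero across a dataset (types absent from the chemistry at
hand) are pruned.  Pruning is **fit on the training partition only** and
frozen into an `attribute_schema` that is replayed — never re-fit — on test
data.  A single published attribute count does not say which partition it
was fit on; train-only fitting is the leak-safe reading, and on a
training set drawn from the same chemistry the retained column set is the
same in practice.

The 53-entry type table ships as a plain CSV (`inst/extdata/sybyl_types.csv`)
because only its first entries (C.3, C.2, C.ar, C.1) and last entries
(Mo, Mn, Co.oh) are fixed by the convention the encoding follows; the rest
of the ordering is a documented choice and can be overridden per dataset.
Typing itself is delegated to Open Babel (SMILES/SDF input is converted to
MOL2, which carries SYBYL types); MOL2 input keeps its native types.  Open
Babel's aromaticity model therefore decides C.ar/N.ar assignments — a
different typing dialect (e.g. N.pl3 versus N.am at anilines/amides) would
shift fingerprint columns, which is why the type table and the typed MOL2
are both inspectable outputs.

### Classifier and protocol

The SVM uses an RBF kernel with the preset `C = 15`,
`gamma = "1/n"` (resolved to one over the number of training instances),
class weight 1, per-feature min-max normalization to $[0,1]$ fitted on the
training data, and Platt probability estimates.  The non-SOM set is class I
(the positive class for SE/SP) by convention; every report also prints the
flipped orientation so the two readings cannot be confused.

Evaluation: sensitivity, specificity, accuracy and Matthews correlation
from the confusion counts; ROC by threshold sweep with simultaneous steps
at tied scores and trapezoidal AUC (verified in the tests against the
Mann–Whitney rank statistic).  Validation: stratified seeded 10-fold
cross-validation with pooled out-of-fold predictions, deterministic
jackknife (leave-one-out), and grid search over $C$ and $\gamma$ scored by
CV AUC with ties broken toward smaller $C$, then smaller $\gamma$.  The
default grid is the standard log-2 lattice ($C \in 2^{-5..15}$,
$\gamma \in 2^{-15..3}$, step $2^2$).  Normalization and schema pruning are
re-fit inside every fold, so no held-out information leaks into the fit.
For a training-set performance table both readings are available and should
be labeled: `cross_validate()` gives the pooled 10-fold estimate,
`evaluate()` on the training data gives resubstitution.

All randomness — fold assignment, probability calibration, fixture
generation, seeded splits — flows from explicit integer seeds, and repeated
runs with the same seed are bit-identical.

## The synthetic fixture study

Real inputs require a quantum-chemistry engine, so the package carries a
generator (`fixture_spec()`, `gen_molecules()`, `gen_populations()`) that
emulates exactly what the pipeline consumes:

* **Molecules**: random connected heavy-atom trees over C/N/O/S with
  valence-legal single bonds, 8–16 atoms, 25% heteroatoms, at least one
  N/S candidate each, typed through the same Open Babel path as real
  input.  Trees keep the generator trivially valence-correct; rings and
  aromatic systems are exercised by a pinned library of real drug SMILES
  (benzydamine, voriconazole, K11777, alvameline, tozasertib).
* **Labels**: each candidate is SOM with probability 0.35, matching the
  SOM prevalence of the published atom tables.
* **Populations**: baseline charges are element-typical constants plus
  Gaussian noise (no further physical realism is attempted).  The raw
  $f^-$ draws receive an additive effect $\delta$ at SOM atoms
  ($\sigma = 0.02$ noise), then each Fukui vector is shifted uniformly so
  it sums to exactly 1 per compound — the $N \leftrightarrow N\pm1$
  transitions move exactly one electron — which preserves all between-atom
  differences.  Consistency invariants therefore hold by construction, and
  the planted SOM/non-SOM separation is $\delta$ up to noise.
* **Logs**: `gen_log_fixture()` renders the three Mulliken blocks in
  standard log layout at full precision, so the parser inverts it exactly.

`run_fixture_study()` chains the whole pipeline: assemble, split **by
compound** (no molecule straddles partitions), prune on the training half,
grid search (a compact $3\times3$ grid — $C \in \{1, 8, 64\}$,
$\gamma \in \{1/n, 0.05, 0.5\}$ — is the default here because the planted
signal does not need the full lattice), train, evaluate held out.  At the
study conditions ($\delta = 0.3$, $\sigma = 0.02$, 60 compounds) the
held-out AUC is at ceiling, and with $\delta = 0$ it stays in a narrow band
around 0.5; for the null runs the preset configuration is used without grid
search, since tuning on pure noise only adds variance and runtime.  The
null band is checked over 20 seeds.

What passing these tests shows — and does not show.  They demonstrate that
the pipeline is plumbed correctly end to end: a nucleophilicity signal of
realistic size planted in $f^-$ survives featurization, compound-level
splitting, normalization, tuning and calibration, and nothing else
generates spurious signal.  They do **not** certify accuracy on real
drugs: real Fukui distributions are not Gaussian, real fingerprints
correlate with labels (here they are pure nuisance), and real candidate
marking involved judgment this package replaces with the explicit
"all N and S" rule plus an exclusion list (shipped empty), so candidate
counts can exceed hand-marked ones.

## Numerical and edge-case policy

* Metrics with a zero denominator return `NA` rather than a silent 0.
* Constant feature columns normalize to 0; test values may leave $[0,1]$.
* Dense descending ranking: tied $f^-$ values share the better rank.
* Missing surface areas: the column is dropped dataset-wide by default
  (`surface_area_policy = "zero"` imputes instead); the choice is recorded
  in the dataset's schema attributes.
* An atom whose environment Open Babel cannot type falls back to a generic
  per-element code with a warning.
* Candidate exclusion rules are expressed as SYBYL type codes (e.g.
  `"N.am"`); this is deterministic and auditable, whereas SMARTS-level
  rules would add a matcher dependency without a written rule to encode.

## Known limitations

* Everything upstream of the charge tables (functional, basis set,
  solvation, conformer choice) is out of scope and simply trusted.
* Typing follows Open Babel's dialect; other toolkits disagree on a few
  percent of nitrogen types, which shifts fingerprint columns.
* Layers beyond two bonds are accepted by the config surface but untested.
* The baseline Naive Bayes / Random Forest comparisons are deliberately
  thin wrappers a user can run with library defaults (`e1071::naiveBayes`,
  `randomForest`); they are not part of this package's surface.
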
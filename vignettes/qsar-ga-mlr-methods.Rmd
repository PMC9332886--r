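---
title: "Methods: pharmacophore-pair descriptors, GA-MLR selection, and the validation battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pharmacophore-pair descriptors, GA-MLR selection, and the validation battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`qsarga` builds multilinear QSAR models for small-molecule bioactivity
(its reference use case is a set of 84 LSD1/KDM1A inhibitors with EC50
values spanning 0.38–89,500 nM) from two ingredients: a pool of
distance-constrained pharmacophore-pair descriptors computed on typed
molecular graphs, and a genetic-algorithm search for the descriptor
subset whose ordinary-least-squares model maximizes leave-one-out
predictivity. This vignette explains the model, every consequential
design choice, and what the synthetic tests do and do not demonstrate.

## The molecular graph and atom typing

Structures enter as SMILES (or SDF) and are interpreted by Open Babel:
explicit hydrogens, aromaticity perception, SYBYL-style hybridisation,
and Gasteiger–Marsili partial charges. On top of that the package
computes all-pairs shortest-path bond counts (the topological distances
all `...B` descriptors use) and assigns the pharmacophore classes of the
descriptor grammar with a configurable rule table
(`default_atom_typing()`):

* **donor** — N or O bearing at least one hydrogen;
* **amide N** — N single-bonded to a carbonyl carbon;
* **lipophilic** — carbon with no N/O neighbour, any halogen, or sulfur;
* **sp2 O** — oxygen with a double bond; **non-ring O** — oxygen outside
  any ring; **ring C / ring S** — by ring membership; **sp3/sp2 C** — by
  hybridisation.

These rules are the simplest set consistent with the grammar's worked
descriptor meanings; whether sulfur and halogens belong in the
lipophilic class is genuinely ambiguous in the field, so the table is an
argument, not a constant. Two numerical notes:

* Charges are read at the 4-decimal precision of the underlying MOL2
  block and re-centred so the molecular sum equals the net formal charge
  exactly (each atom moves by less than 1e-4 electrons). Charge sums in
  descriptors therefore behave as exact zero-sum quantities on neutral
  molecules.
* 3D coordinates, needed only by the `com_*` geometric counts, come from
  Open Babel's 3D builder with force-field cleanup. That builder is not
  seedable, so embedded coordinates carry small run-to-run jitter.
  Geometric descriptors are integer counts within multi-Angstrom radii
  and are insensitive to this in practice, but when exact geometric
  reproducibility matters, supply coordinates via SDF — file coordinates
  always take precedence over embedding.

## The descriptor grammar

Four families cover the descriptors the models use:

| form | meaning | example |
|---|---|---|
| `f<A><B><n>B` | ordered count of class-B atoms exactly n bonds from a class-A atom | `fNringC6B` |
| `<cls>_<A>_<n>Bc` | sum of partial charges of class-`cls` atoms within 1..n bonds of any class-A centre | `lipo_ringS_8Bc` |
| `com_<B>_<r>A` | count of class-B atoms within r Å of the centre of mass | `com_sp2O_4A` |
| `avg_molweight` | molecular weight / atom count (explicit-H graph) | |

Counting is over **ordered (centre, target) pairs**: a target atom seen
by two centres counts twice. This reproduces "frequency of occurrence"
semantics; the alternative (distinct targets) is a one-line change in
`count_exact_pairs()`. "Within n bonds" means distances 1..n and counts
each qualifying atom once even when several centres reach it. `com_` is
interpreted as the mass-weighted centre of mass; `avg_molweight` as
molecular weight over the explicit-hydrogen atom count. Unknown
descriptor names fail loudly — nothing silently evaluates to 0.
`descriptor_pool()` expands the grammar over an atom-class and distance
grid into a pool of ≈1,700 columns, the scale at which objective
filtering operates in practice.

## Data curation and splitting

EC50 values are converted to molar and transformed to pEC50 =
−log10(EC50 [M]). Curation flags, in order of precedence: unparsable
SMILES, multi-component structures (salts/mixtures, detected by a
disconnected canonical structure), imprecise activities (qualifier other
than `=`), and duplicates (same canonical structure key as an earlier
kept record; first occurrence kept, in input order). Duplicate keys
ignore stereochemistry by default — curation granularity is a judgement
call, so the key is an argument. The train/prediction split is simple
random sampling under a recorded seed with training size
`floor(fraction × n)`; 80% of 84 compounds gives the 67/17 partition.
The split membership is always written to the run directory because an
unrecorded split is the single largest obstacle to reproducing any QSAR
model.

## Objective feature selection

Three deterministic passes: constant columns; near-constant columns
(most frequent value covering > 95% of rows — a common QSAR convention,
configurable); then greedy correlation pruning at |r| > 0.90, scanning
columns in input order and keeping the earlier column of an offending
pair. Keep-the-earlier is arbitrary but auditable: every removal is
logged with its reason and, for correlation removals, the retained
partner.

## GA-MLR subset selection

Chromosomes are sorted index sets of fixed size k; fitness is Q²_LOO of
the OLS model on the training set, computed through the hat-matrix
deletion identity (no refits), with rank-deficient candidates assigned
−∞. Selection is binary tournament, crossover one-point on the sorted
lists with duplicate repair by resampling, mutation per-gene replacement,
and a small elite is carried unchanged, making best fitness monotone
over generations. The defaults (population 50, 100 generations,
crossover 0.9, mutation 0.1, elitism 2) were chosen for reproducibility
on the study-scale problems the package targets, and every run logs its
full trajectory. After the GA, the best subset is polished by
best-improvement swap sweeps until no single-descriptor exchange raises
fitness; on every instance small enough to enumerate (C(p,k) ≤ 1000)
this matches exhaustive search across seeds in the test suite.

Model size is chosen by the breaking-point rule: run the GA for
k = 1..k_max and take the smallest k at which the gain
Q²_LOO(k+1) − Q²_LOO(k) falls below ε = 0.02. Reading a knee off a plot
is inherently subjective; ε makes the rule explicit and configurable,
and the k-versus-R²/Q² curve is emitted as plot data.

## The validation battery

For a fitted model the package reports: training fit (R², R²_adj, F, s,
RMSE_tr = √(RSS/n), MAE, CCC); leave-one-out Q², PRESS, RMSE_cv and
CCC_cv from deletion residuals; leave-many-out Q² as the mean over
seeded random deletion groups of 1 − PRESS_g/TSS_g (TSS_g about the
retained-set mean); external Q²_F1/Q²_F2/Q²_F3, R²_ext, CCC_ex, Roy's
r²m in both regression directions (average and absolute difference) and
the Golbraikh–Tropsha checks (Q²_LOO > 0.5, R²_ext > 0.6,
(r²−r²₀)/r² < 0.1 in at least one direction, through-origin slope in
[0.85, 1.15]); Y-randomization (response permuted, model refit on the
same descriptors, R² and Q² recorded — 2000 iterations by default); and
the QUIK rule.

QUIK compares the Todeschini multivariate correlation index K of the
descriptor block against the block augmented with the response,
requiring K_xxy − K_xx ≥ 0.05. K is defined on eigenvalues of a
**correlation** matrix; a constant intercept column has no defined
correlation with anything, so the occasionally-mooted "intercept
included" variant is degenerate and only the correlation-based form is
implemented.

The applicability domain is the Williams construction: leverages
h_i = x_i(XᵀX)⁻¹x_iᵀ with intercept, warning threshold h* = 3(p+1)/n,
and standardized residuals e_i/s with a ±3 cutoff (2.5 is also used in
the literature; the cutoff is an argument). Labels: `X_outlier` for
h > h*, `Y_outlier` for |std. residual| > 3 (both margins exceeded
reports `XY_outlier`), and `model_outlier` — the "visible only after the
model exists" category — for compounds inside both margins whose
leave-one-out deletion residual still exceeds 3 × RMSE_cv. The
model-outlier rule is an interpretation; it is documented here precisely
because no standard operationalization exists.

## The synthetic-data generator

`make_planted()` emulates the statistical regime of the reference study:
84 compounds (67 train / 17 prediction), a descriptor pool of ~200
columns after objective filtering, a 5-descriptor linear signal, and
noise solved so the **population** R² equals 0.83. Descriptor columns
are standard normal; planted coefficients have random signs and
magnitudes drawn from ±25% around a common scale, so that each planted
descriptor is individually identifiable at n = 67 — with strongly graded
magnitudes the weakest descriptor drops below the selection noise floor
and no subset-search method (nor the leave-one-out criterion itself) can
be expected to find it. An optional decoy mode correlates a chosen
number of decoy columns at ~0.6 with planted ones to mimic the
collinearity of real descriptor pools. The realized training R²
fluctuates around the 0.83 target with a spread of roughly ±0.07 across
seeds, which the tests treat as the sampling distribution it is.

What passing the synthetic suite shows: the selection machinery finds a
true sparse linear signal of realistic strength at the study's sample
size in ≥95% of seeded replicates, validation statistics obey their
defining inequalities (PRESS ≥ RSS, R² > Q²_LOO ≥ Q²_LMO), scrambled
responses yield mean R² < 0.2, and planted coefficients are covered by
±2 standard errors at close to nominal rates. What it does not show:
anything about real descriptor distributions (counts are discrete,
skewed and collinear in ways Gaussian columns are not), assay noise
structure, or activity cliffs. The toy-molecule suite covers the
chemistry side — every atom class and descriptor family is checked
against brute-force enumeration on real (small) structures — but no
synthetic check substitutes for external validation on new chemistry.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the study regime at its
natural size (n = 84, p = 200, k = 5; 100 replicates for recovery and
coverage; 1000 LMO groups and 2000 randomizations for the representative
run) — a few minutes on one CPU, dominated by the GA. Tolerances: exact
linear-algebra identities are asserted at 1e-10; LOO via the hat matrix
equals brute-force refits at that tolerance; leverage-1 rows (exact
interpolation of a deleted point) raise an error rather than returning
an unstable number; ties in the GA are broken by the first maximum, and
all stochastic components (split, GA, LMO, Y-randomization, generator)
take explicit seeds, which the pipeline records in its run directory.

## Known limitations

Tautomer/protonation enumeration, stereochemistry-aware descriptors and
conformer ensembles are out of scope. The charge model is the Gasteiger
scheme as implemented by Open Babel; published charge-sum descriptor
values computed with other tools will differ in the third decimal.
Geometric (`com_*`) descriptors inherit the embedding caveat above.
The GA matches exhaustive search on small instances, but for p in the
hundreds global optimality is not guaranteed on any given seed — which
is also why the model-quality statistics, not subset identity, are the
meaningful point of comparison with other implementations.
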
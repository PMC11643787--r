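---
title: "Consensus QSAR with atom-neighbourhood descriptors: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus QSAR with atom-neighbourhood descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scrqsar)
```

## The modelling problem

`scrqsar` models the inhibitory potency of small organic molecules
against an enzyme target — the motivating case is 15-lipoxygenase
(15-LOX), a non-heme iron oxidoreductase whose inhibition is relevant to
inflammatory and proliferative disease — as a quantitative
structure-activity relationship (QSAR).  The response is
pIC50 = −log10(IC50 in mol/L).  The pipeline covers the whole study
design: parsing structures, computing descriptors, splitting an activity
set into training and test subsets, fitting pools of partial regression
models, averaging them into consensus models with an applicability
domain, and judging the result with a full external-validation suite.

## Descriptors

Three descriptor families feed every model.

**MNA (Multilevel Neighborhoods of Atoms).**  Each atom carries a mark:
its element symbol, prefixed with `-` when the atom lies on no ring
(benzene carbon `C`, ethanol oxygen `-O`).  The level-k descriptor of an
atom is its mark followed by the parenthesised, lexicographically sorted
level-(k−1) descriptors of its neighbours; level 0 is the mark itself.
Hydrogens are made explicit first, so a methane carbon at level 1 reads
`-C(-H-H-H-H)`.  A molecule is the multiset of all its atoms' strings at
all levels up to `mna_level` (default 2 — deep enough to separate common
functional environments, shallow enough that strings recur across a
100-compound set).  Regression uses the counts over the training
vocabulary, filtered to strings occurring in at least `min_support = 3`
training molecules; rarer strings cannot support a stable coefficient
but still participate in the applicability-domain similarity.

**QNA (Quantitative Neighborhoods of Atoms).**  Each heavy atom k
carries B_k = IP_k − EA_k and A_k = (IP_k + EA_k)/2 from tabulated
atomic ionization potentials and electron affinities (eV, Mulliken
scale).  With C the heavy-atom adjacency matrix and D_B = diag(B),

  M = D_B^(−1/2) · exp(−C/2) · D_B^(−1/2),
  P_i = Σ_k M_ik,  Q_i = Σ_k M_ik · A_k,

so each atom's (P, Q) pair blends the electronegativity landscape of the
whole molecule, damped through the connectivity by the matrix
exponential.  Because molecules differ in size, the (P, Q) point cloud
is turned into a fixed-length vector: P and Q are affinely mapped onto
[−1, 1] using the training ranges (out-of-range values at prediction
time are clipped and counted against the applicability domain), and all
products T_a(p)·T_b(q) of Chebyshev polynomials up to `qna_degree = 2`
are averaged over atoms, giving 9 features.  The Chebyshev basis is a
bounded, orthogonal polynomial family on exactly the interval the
scaling produces; degree 2 keeps the feature count far below the
training-set sizes in play.

**Whole-molecule descriptors.**  Topological length (graph diameter in
bonds), topological volume (additive sphere volume from covalent radii,
Å³) and lipophilicity (element-level additive logP contributions).
These three are candidates in *every* model.  The property tables ship
as a CSV (`inst/extdata/element_properties.csv`) so they can be swapped.

Hydrogens are included in MNA (the recursion is defined over all atoms)
but excluded from QNA and the whole-molecule descriptors, where their
near-uniform contributions would only add noise.

## Self-consistent regression and its radial-basis extension

A partial model is fitted by **self-consistent regression (SCR)**:
ridge-regularised least squares on standardised candidate columns with
iterative elimination of insignificant variables.  The ridge value is
chosen by leave-one-out PRESS over a log grid (10^−6 … 10^2), under a
degrees-of-freedom guard: values whose effective model degrees of
freedom exceed 90% of the sample are skipped, because a
near-interpolating fit makes the closed-form leave-one-out residuals
arbitrarily optimistic.  The error variance comes from the PRESS rather
than the training residuals, for the same reason.  Elimination then
removes the variable with the smallest |coefficient|/SE below the
significance threshold (|t| ≥ 2 by default) and refits — choosing the
ridge anew each round — until every retained variable is significant;
variables below half the threshold are removed together, which gives the
same fixed point as strict one-at-a-time removal in all but pathological
tie cases at a fraction of the cost.  If everything is eliminated the
model degrades to a flagged intercept.

**RBF-SCR** reuses the SCR-selected variables and fits a Gaussian
radial-basis interpolant in that subspace: centres at the training
points, kernel width the median pairwise distance (mean distance as a
flagged fallback when the median vanishes), and a kernel ridge chosen by
leave-one-out PRESS (a user-supplied value, e.g. a negligible 10^−12,
turns it into an exact interpolator of the training responses).

## Consensus models

A consensus model averages `n_partials` partial models — 20 for a
single-family (QNA or MNA) pool, 320 for a mixed pool alternating QNA-
and MNA-based partials (160 + 160); with the combined selection method
the pool also alternates SCR and RBF-SCR.  Partials differ by a seeded
random 80% subsample of compounds (without replacement — resampling
with replacement would let duplicated rows leak into the leave-one-out
ridge selection) and a seeded random 50–90% subset of the family's
columns, capped below the subsample size so each fit stays well-posed;
the three whole-molecule descriptors are always candidates.  Count
columns with fewer than three non-zero entries inside a subsample are
excluded from that partial only.  All randomness flows from one integer
seed, with per-partial draws taken sequentially, so a consensus model is
a pure function of (data, configuration, seed).

Summary statistics are arithmetic means over partials: training R² (on
the full training set), the Fisher criterion F and residual SD, the
number of selected variables V, and Q²_LMO from 20 rounds of random 20%
holdouts.  For the per-partial Q²_LMO the holdout refits re-estimate the
regression stage (ridge or RBF weights) with the partial's selected
variables and regularisation held fixed; re-running variable selection
20 times for each of up to 320 partials would dominate the runtime while
measuring the same stability signal.  The standalone
`lmo_cross_validation()` refits its fitter from scratch each round.
Stability is A = R̄² − Q̄²_LMO, classed high below 0.1, acceptable to
0.2, low to 0.3 and unstable beyond — a consensus whose partials predict
held-out compounds much worse than their training data is memorising.

The **applicability domain** combines a structural and a range
criterion: Tanimoto similarity of the MNA descriptor *set* to the
nearest training compound of at least 0.3, and all three whole-molecule
descriptors inside the training min–max expanded by 10%.  Out-of-domain
compounds (including any whose descriptors cannot be computed, e.g. an
element missing from the property table) get no numeric prediction
unless the caller forces extrapolation, and remain flagged then.

## Validation

`external_metrics()` computes, for one observed/predicted pairing: r²;
the through-origin determination coefficients r0² (observed against
predicted) and r0'² (the reverse); rm² = r²(1 − √|r² − r0²|) and its
reverse, with their mean and absolute difference (the absolute value
keeps the root real when the through-origin fit outperforms the free
one); the concordance correlation coefficient with population (1/n)
moments; QF1² (errors normalised by deviation from the *training* mean)
and QF2² (by the test mean — the two coincide exactly when the means
do); and RMSE, MAE, the population SD of absolute errors, and
B = MAE + 3·SD.  The population form of that SD is the one consistent
with the B values the suite reproduces.  Every statistic is checked to
1e-10 against an independently coded oracle.

Reports are produced for 100% of the data and for the best 95% —
`trim_worst()` removes round(0.05·n), at least one, pairs with the
largest absolute errors (ties broken by observation order), which
quantifies how much a handful of outliers drives the error statistics.
Ability classification bands MAE at 0.10/0.15 and B at 0.20/0.25 of the
training activity range Δ (upper bounds inclusive), combines them with
the r²-family thresholds (r² > 0.8, CCC > 0.8, Q² > 0.7 for high), and
reports the worst triggered band.  `systematic_error_check()` flags a
mean signed error above half the MAE or more than 80% of residuals
sharing a sign.  External compounds are judged against the ±2·RMSEP
window (boundary inclusive), using the smallest stored RMSEP.

## The assay side

Percent inhibition is (Dc − Dt)/Dc × 100 from control and test optical
densities.  IC50 comes from linear interpolation between the bracketing
pair around the first upward 50% crossing of the
concentration–inhibition curve; a point exactly at 50% short-circuits to
its concentration, and with multiple crossings (noisy data) the pair
closest to 50% is used with a warning.  Replicate rows are averaged per
concentration before interpolation; their SDs are carried in reports but
do not enter the interpolation.  Sigmoidal (4PL/Hill) fitting is
deliberately out of scope: the supported protocol interpolates the
means.  The bundled curve fixture reproduces the measured inhibition
table for eight 2H-(benzo)pyran-2-one derivatives; interpolating its
printed means reproduces the published IC50 of compounds 3 and 7 exactly
and the others within 0.7 µmol/L — those IC50s were evidently
interpolated from unrounded replicate means, so the printed means cannot
reproduce them to the last digit.

## The synthetic-data generator

Real compound sets of this kind — a hundred literature inhibitors
spanning a dozen scaffold families — are not redistributable, so the
generator emulates one: 100 molecules of 10–28 heavy atoms over a
C/N/O alphabet, grown as random trees with up to two ring closures
(ring probability 0.8), each molecule drawing its own element
composition (Dirichlet around the alphabet) and chain-versus-branched
growth style.  That per-molecule diversity keeps size, shape and
composition only loosely coupled, which is what makes planted linear
models on the descriptors identifiable at n = 100.  Activities are a
planted linear combination of named descriptors plus Gaussian noise
(SD 0.3 by default — the order of inter-laboratory spread in literature
IC50 data), affinely rescaled so the set mean (5.308) and range (3.873)
are exact; the rescaled planted coefficients are recorded for recovery
tests.  The default planted model takes the three whole-molecule
descriptors plus up to two frequent MNA counts screened for low
collinearity (R² < 0.6 against the descriptors already planted), with
balanced contributions.

What passing tests on this generator do **not** show: real medicinal
chemistry has correlated scaffold series, activity cliffs,
heteroscedastic assay noise and descriptor distributions far from these
random graphs.  The generator validates the *machinery* — splitting,
selection, averaging, validation arithmetic — not the chemistry.  Note
also that whole-molecule volume and lipophilicity are exact linear
combinations of level-0 MNA counts, so coefficient-level recovery is
only meaningful when the planted variables are not duplicated in the
candidate pool (the recovery tests therefore use the QNA family or an
explicit candidate matrix).

## Numerical and design choices

* Aromatic bonds are stored as order 1.5 and rounded valence keeps a
  benzene carbon at 4 without kekulisation; stereochemistry is ignored
  (the descriptors are 2D).
* Multi-fragment inputs (salts) are reduced to the largest connected
  component with a warning.
* Formal charges are kept on atoms but excluded from MNA marks by
  default (configurable), as the mark is defined by element and
  cyclicity.
* Ranked splitting sorts ascending by pIC50 (stable on ties) and
  transfers ranked positions 6, 12, … to the test set; modelling
  requires a training range Δ > 3 (strict).
* Canonical MNA ordering uses C-locale string sorting, so vocabularies
  are platform-stable.
* Reported pIC50 values and thresholds are rounded to 3 decimals, IC50
  to 1 decimal, and rounding happens last.
* The grid rehearsal sizes — 100 compounds, 18 models, pools of 20/320
  partials, 20×20% cross-validation — run end to end in a few minutes
  on one core; the test suite exercises the full grid at exactly these
  sizes.

## Known limitations

The QNA functional form and the SCR internals follow the method family's
published descriptions but are this package's own formulation; fitted
coefficients are not interchangeable with any proprietary
implementation.  The applicability-domain rule (Tanimoto 0.3 + 10%
range expansion) is a pragmatic default, not a calibrated boundary.
Element coverage is the property table's 12 main-group elements;
organometallics are out of scope.
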
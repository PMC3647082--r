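---
title: "Co-migration profiling: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-migration profiling: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comigr)
```

## The measurement this package models

BN-PAGE coupled directly with LC-MS/MS replaces the classical
two-dimensional BN/SDS workflow: a native gel lane is cut into ~60
horizontal slices at regular intervals, each slice is in-gel digested with
trypsin and its peptides identified by LC-MS/MS. Every protein then has a
migration profile — a vector of per-slice abundance estimates — and
subunits of one complex share profile peaks because they entered the gel
bound together. The analysis chain is:

1. **Digestion** (`cleave_tryptic`, `count_observable_peptides`): in-silico
   trypsin digest of each protein, and the count of distinct tryptic
   peptides whose m/z falls in the instrument scan range at an allowed
   charge. This count is the emPAI denominator.
2. **Quantification** (`quantify_slices`): per slice, the number of
   distinct identified peptide sequences per protein, converted to
   emPAI `= 10^(N_obs/N_obsable) − 1`, with `compute_mol_percent` for
   sample composition.
3. **Profiling** (`build_profiles`, `detect_peaks`, `fit_calibration`):
   dense profile matrix, peak calling, and native-mass estimation from a
   log-linear marker fit.
4. **Co-migration** (`group_comigrating`, `find_slice_partners`,
   `profile_similarity`): candidate complexes from overlapping peak apexes;
   partner lookup and Pearson profile similarity for ranked candidates.
5. **Export** (`build_entry`, `export_dataset`): one database-style JSON
   record per protein.

## emPAI conventions

Three conventions are deliberate and exposed as parameters:

* **Denominator missed cleavages** (`missed_cleavages_observable`, default
  0). The original emPAI formulation counts fully cleaved observable
  peptides; search engines typically accept up to two missed cleavages for
  identifications (`max_missed_observed`, default 2). Both limits are
  independent parameters because the ratio `N_obs/N_obsable` can then
  legitimately exceed 1 — an identified protein saturating its observable
  peptides plus missed-cleavage variants gets emPAI above 9, which is
  expected behaviour, not an error.
* **The denominator is a protein property.** Per-slice emPAI divides
  per-slice observed counts by the whole-protein observable count; slices
  do not change a protein's tryptic repertoire.
* **mol% scope.** Composition summaries normalize the per-protein emPAI
  *totals* (summed over slices) across the dataset; a per-slice variant is
  a one-line `compute_mol_percent` call on a profile column.

Fixed physical constants (monoisotopic residue masses, water 18.010565 Da,
proton 1.007276 Da, carbamidomethyl +57.021464 Da, the Kyte–Doolittle
hydropathy table) live in a single source file and are applied nowhere
else. Peptides containing nonstandard residue letters (B, J, O, U, X, Z)
are kept in sequences but excluded from observability counting: inventing
masses for ambiguity codes would silently bias denominators.

## Peak detection

Profiles are short, nonnegative, zero-inflated vectors, so peak calling is
a direct combinatorial definition rather than smoothing-based: an apex is a
slice whose value beats the nearest *differing* neighbours on both sides,
with runs of equal values merged into one plateau whose apex is the topmost
slice (ties break toward the larger complex, deterministically), and
profile ends eligible as apexes. Two thresholds gate apexes:
`rel_height` (default 0.1 of the profile maximum) and `min_value` (default
0.01 emPAI, roughly the signal of a single stray peptide of a
high-denominator protein). The defaults suppress one-peptide trailing noise
while retaining genuine minor oligomer peaks such as a free subcomplex next
to its holoenzyme. Peak support extends to the half-height crossing or the
nearest local minimum, whichever comes first, and neighbouring supports are
trimmed at the inter-apex valley (valley slices go with the upper peak), so
reported intervals are always disjoint.

Mass calibration is log-linear in slice index. Slices are cut at regular
intervals, so slice number is an affine proxy for migration distance, and
native-gel migration distance is approximately linear in log molecular
mass over a gradient gel's resolving range. Estimates outside the marker
range are flagged `extrapolated` rather than suppressed.

## Co-migration groups

Two partner notions coexist, and both are exposed because they answer
different questions. *Same-slice detection* (`find_slice_partners`) is the
permissive, browse-style lookup: everything identified in the slice of
interest. *Apex grouping* (`group_comigrating`) is the stricter
candidate-complex call: proteins whose peak apexes lie within `tolerance`
slices (default 0, i.e. the same slice) of a common anchor, with
singletons dropped.

One design choice goes beyond deduplication: by default only *maximal*
member sets are reported (`maximal_only = TRUE`). With any nonzero apex
scatter, anchors at neighbouring occupied slices otherwise emit nested
subsets of the same complex — one true complex would surface as a family of
fragments, making precision against a known truth undefined. A group wholly
contained in another carries no additional co-migration evidence, so it is
dropped; `maximal_only = FALSE` restores the raw behaviour.

## The synthetic-data model

The generator emulates exactly the structure the analysis assumes, and no
more. A complex contributes abundance
`a(s) = abundance · exp(−(s − apex)² / (2 · width²))` in slice `s`; each
observable peptide (identification convention, ≤ 2 missed cleavages) of
each member is reported independently with probability

```
p = (1 − exp(−k · q · a(s))) · (1 − penalty · h(peptide)),  clamped to [0, 1]
```

where `q` is the member's stoichiometry, `k` the detection saturation
constant, and `h` the peptide's Kyte–Doolittle hydropathy rescaled to
[0, 1]. The saturating form makes expected observed counts grow with
log-abundance, which is what makes emPAI a sensible transform; a linear
clamp was rejected because it destroys rank correlation at high abundance.
The hydrophobicity term reproduces the depressed emPAI of very hydrophobic
membrane subunits relative to their soluble partners in the same complex.
Background identifications are Poisson per slice, drawn uniformly from the
proteome's true tryptic peptides. All randomness flows from one seed
through deterministic substreams, so tables are bit-reproducible.

Defaults: `detection_rate_k = 5` (near-saturated detection of a
unit-abundance complex at its apex), `background_rate = 0.2` spurious rows
per slice (sparse contamination, as in a clean native prep),
`hydrophobicity_penalty = 0.3` (a strongly hydrophobic peptide loses about
a third of its detection probability — enough to depress, not erase,
membrane-protein signal). Proteome generation uses a typical globular
residue composition with Lys+Arg ≈ 11%, so tryptic peptide lengths are
realistic.

What the generator does **not** emulate: chimeric spectra, retention-time
effects, protein-inference ambiguity from shared peptides, cross-lane
variation, and partial complex dissociation smearing down the lane.
Pipeline tests passing on synthetic data therefore demonstrate correctness
of the computation under the stated model, not robustness to every
pathology of real complexome data.

## The recovery benchmark

The standing end-to-end check simulates five complexes of 3–6 members from
a 25-protein proteome (200–350 residues) on a 60-slice lane, apexes at
slices 8/18/30/42/53, width 1.2 slices, apex abundance 0.35, `k = 6`, no
background, twenty replicate seeds. Width and abundance are placed so that
per-peptide detection is sharply peaked but *not* saturated across several
slices — the regime where apex position is informative, matching how
discrete BN bands behave; fully saturated profiles would plateau and make
apex calls arbitrary for any method. The pipeline (quantify → profiles →
peaks → groups at tolerance 1) must recover the ground-truth member sets
with precision = recall = 1 in every replicate, and does. The same
benchmark yields the rank correlation between true slice abundance and
computed emPAI, evaluated over each complex's detectable window (slices
with at least 1% of apex abundance; outside it the true Gaussian is
analytically positive while emPAI is exactly zero, so including the whole
lane would only measure tie handling).

These problem sizes — 20 × (25 proteins × 60 slices), 200 random proteins
against the digestion oracle, 1,000 random profiles against the
local-maxima scan — keep the full suite around a minute while exercising
every code path.

## Numerical and degenerate-input policy

* emPAI with `n_observable = 0` and positive observations is an error (it
  flags a protein whose reported peptides cannot be tryptic in-range
  products), while 0/0 is defined as 0.
* mol% of an all-zero vector is an error, not NaN.
* Constant profiles have undefined Pearson similarity: scalar
  `profile_similarity` errors, matrix `similarity_matrix` returns NA with a
  warning.
* Percentages are reported half-up (`41%` from 40.85) alongside full
  precision; JSON exports carry full precision only.
* Validation never silently drops rows: strict mode errors, permissive mode
  warns and returns rejected row numbers.

## Limitations

Peptides shared between proteins are counted for whichever accession the
input table asserts — protein grouping/parsimony is upstream's job.
Overlapping peaks are not deconvolved; a shoulder inside another peak's
half-height support is merged. Co-migration is necessary, not sufficient,
evidence of interaction: two unrelated complexes of similar native mass
co-migrate indistinguishably, so groups are candidates for orthogonal
validation, not asserted interactions.
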
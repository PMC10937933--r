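---
title: "Structural determinants of protein-RNA photo-crosslinking: methods"
author: "xlink3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural determinants of protein-RNA photo-crosslinking: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xlink3d)
```

## The problem

UV irradiation of cells covalently conjugates amino acids and nucleotides
that are in direct contact, and essentially all modern protein-RNA
interaction mapping (CLIP and its variants, RNA-interactome capture,
RBS-ID) rests on this chemistry. Yet crosslinking is far from uniform over
an interaction interface: within one bound motif, typically one or two
nucleotides and one or two amino acids carry almost all of the
crosslinking signal. `xlink3d` asks which *structural* properties of a
contact make it photo-reactive. It extracts interface geometry from 3D
complex structures, labels residues as crosslinked or not from assay
evidence, trains imbalance-aware classifiers on the resulting tables, and
ranks the structural features that drive the classification.

## Interface annotation

All geometry operates on heavy atoms only; deposited structures rarely
carry hydrogens, so hydrogen bonds are called on donor-acceptor heavy-atom
distance alone.

* **Contacts.** A nucleotide and an amino acid are in direct contact when
  their minimum heavy-atom distance is at most 4.5 Å (inclusive). This
  single threshold defines the "contacting" population from which
  classification sets are drawn.
* **Hydrogen bonds.** Donor/acceptor-capable N and O atoms (pinned
  capability tables per residue) within 3.5 Å. Each bond is typed by the
  RNA moiety (base / sugar / phosphate, from pinned atom lists: phosphate
  is P, OP1, OP2, O5', O3'; sugar is C1'-C5', O4', O2') and the protein
  moiety (sidechain / backbone).
* **Planar stacking.** Planes are fitted by total least squares to base
  rings, Phe/Tyr six-rings, the Trp indole, the His ring, the Arg
  guanidinium group (NE, CZ, NH1, NH2), and the peptide-bond plane
  (CA\(_i\), C\(_i\), O\(_i\), N\(_{i+1}\), CA\(_{i+1}\)) of consecutive
  residues. Two planes stack when the acute interplane angle is ≤ 30°, the
  vertical separation (projection of the centroid-centroid vector onto the
  averaged normal) lies in [2.0, 4.5] Å and the lateral offset is ≤ 3.0 Å.
  The defaults reproduce textbook π-stack geometry (~3.4 Å parallel
  separation) and are configurable in `contactConfig()`.
* **Pseudo base pairing.** A planar amino-acid group (guanidinium, amide,
  carboxyl, His or aromatic ring) coplanar with a base (angle ≤ 30°,
  vertical separation ≤ 1.5 Å — larger separations are stacking, not
  pairing) and linked to it by at least two hydrogen bonds.
* **Sugar pucker.** The five endocyclic ribose torsions ν0–ν4 give the
  pseudorotation phase via
  tan P = ((ν4+ν1) − (ν3+ν0)) / (2 ν2 (sin 36° + sin 72°)), with P
  shifted by 180° when ν2 < 0, and amplitude τ\(_m\) = ν2 / cos P. P is
  binned into ten 36°-wide named classes (C3'-endo at the bin containing
  0°–36°, around the wheel to C2'-exo) and the N/S family
  (N iff P ∈ [270°, 360°) ∪ [0°, 90°)).
* **Base orientation.** Glycosidic torsion χ (O4'-C1'-N9-C4 for purines,
  O4'-C1'-N1-C2 for pyrimidines); anti iff |χ| ≥ 90°.
* **Pairing context.** Base pairs are called from ≥ 2 base-base hydrogen
  bonds plus ring coplanarity; a nested-pair analysis assigns
  helix-internal/helix-end to paired nucleotides and hairpin-loop,
  internal-loop, bulge, junction, terminal-ss or isolated-ss to unpaired
  ones, and 5'/3' neighbor base-stacking flags come from the stacking
  detector restricted to base-base partners.

Typed interactions occasionally sit slightly above the generic 4.5 Å
contact cutoff; such residue pairs are retained in the contact table
(flagged `typedOnly`) so the residues still count as contacting.

## Feature schemas

Per nucleotide, 246 features in 15 groups: eight typed-contact classes
(stacking; pseudo pairing; hydrogen bonds by base/sugar/phosphate ×
sidechain/backbone) each tallied per amino acid (20 columns) and per
amino-acid category (6 columns: polar, positive, negative, hydrophobic,
aromatic, aliphatic — overlapping by design, e.g. His is polar, positive
and aromatic), plus sugar-pucker one-hots (10 classes + 2 families), base
orientation (2), secondary element (8), pairing status (2), neighbor
stacking flags (2), per-class totals (8) and an interface summary (4).
Category aggregates are sums over their member amino-acid columns and
per-class totals are sums over the 20 amino-acid columns, so the schema
carries internal conservation identities that the tests assert.

Per amino acid, 36 features: hydrogen bonds by base (A, C, G, U) × RNA
moiety × protein moiety (24), stacking and pseudo-pair counts per base
(4 + 4) and four summary features. Peptide-bond stacks credit both
residues of the dipeptide.

The published schema sizes (246 in 15 groups; 36) are the fixed contract;
the exact column-level layout is this package's pinned reconstruction
(schema tag `v1`) built only from the feature kinds named above.
Identity blocks are optional append-ons: base one-hot plus overlapping
left/right dinucleotide one-hots (4 + 16 + 16) for nucleotides;
amino-acid one-hot plus preceding/following dipeptide one-hots (expanded
only over observed pairs, to avoid 400-wide constant-zero blocks) for
amino acids.

## Crosslink labels

CLIP evidence arrives as instance tables: each transcriptome instance of
an RNA ligand with its 0-based crosslink offsets. The per-position
crosslinking frequency divides the number of instances crosslinked at the
position by the number of instances carrying at least one crosslink call
(instances without evidence do not dilute the frequency; an all-instances
denominator is available behind a flag). A position is crosslinked iff
(n ≥ 20 and f ≥ 0.3) or (n ≥ 10 and f ≥ 0.5); the rule is monotone in
both count and frequency. Positions without any protein contact are
excluded from classification sets.

Protein crosslink sites arrive in full-protein numbering and are mapped
onto (often truncated, renumbered) structure chains by global alignment
(match +1, mismatch −1, gap −2); a mapping is accepted only when the
aligned letter matches and local identity around the site (gap-free
columns in a ±10 window) is at least 90%. When several structures cover
one domain, the representative maximizes (crosslink count, non-zero
features, lexicographically smallest accession) — deterministic under
candidate permutation.

## Classification and ranking

The primary classifier is a random forest (per-task defaults: nucleotides
mtry 17 / 100 trees, amino acids mtry 6 / 1000 trees, ribosome-scale
mtry 6 / 100 trees), evaluated by stratified 10-fold cross-validation
with held-out predictions pooled into one ROC AUC. Class imbalance
(roughly 0.2 positive rate for nucleotides, 0.08 for amino acids) is
corrected by SMOTE — each synthetic minority row is x + u(x′ − x) with
u ~ U(0,1) and x′ one of the k = 5 nearest minority neighbors — applied
*inside each training fold only*: oversampling before the split leaks
interpolated copies of test rows into training and biases the AUC upward
(the leaky variant is available behind a flag for comparison). The 95%
confidence interval comes from bootstrap refits scored on their
out-of-bag rows (percentile 2.5/97.5); 2000 bootstrap models is the full
protocol, scaled down in the test suite. Logistic regression, an RBF SVM,
gradient-boosted trees and a seed-averaged single-hidden-layer neural
network run under the identical folds as comparators.

Features are ranked three ways:

* **Mean Gini decrease** from a forest trained on the full table. Ranking
  is done *without* SMOTE by default: interpolated minority rows measurably
  destabilize impurity rankings (in our simulations the worst informative
  feature drifts from rank 5 to rank 12 once synthetic rows are added),
  while the label signal itself is unchanged.
* **Permutation robustness.** Labels are permuted N times (N = 2000 in
  the full protocol), the forest retrained each time with the same
  parameters, and features re-ranked (rank 1 = most important, ties by
  average rank). With r\(_s\) the true-model rank and r\(_{is}\) the rank
  in permutation i, R\(_s\) = −log10((Σ\(_i\) I(r\(_{is}\) < r\(_s\)) + 1)
  / (N + 1)). The +1 pseudocount departs from the bare fraction only at
  Σ = 0, where −log10(0) is undefined; it caps R\(_s\) at log10(N+1)
  ≈ 3.30 for N = 2000. R\(_s\) deliberately punishes features whose high
  rank survives label destruction — e.g. high-variance columns that
  impurity importance favors regardless of signal.
* **Direction sign** from an elastic-net-penalized logistic regression on
  standardized features (defaults α = 0.56, λ = 0.14, the nucleotide-task
  CV optimum; α = 0, λ = 7.37 for the amino-acid task; a CV tuner over an
  α grid is available). Zero coefficients leave the direction
  undetermined rather than forcing a sign.

## Synthetic fixtures

The generator builds everything the tests and the acceptance script need
without downloads:

* **Geometry fixtures.** Idealized planar rings (1.39 Å aromatic bonds,
  1.23 Å C=O, 1.33 Å guanidinium C-N) posed at requested interplane
  angle / vertical separation / lateral offset; hydrogen-bond poses at
  requested donor-acceptor distance; an Arg-G pseudo pair solved so both
  edge hydrogen bonds hit their target length; a Watson-Crick G-C hairpin
  (4-bp stem at 3.6 Å rise — far enough that cross-level atoms stay
  beyond hydrogen-bond range — plus a 4-nt loop); riboses whose
  out-of-plane displacements are solved numerically so the recovered
  pseudorotation phase lands within 1° of target across the full wheel;
  and nucleotides with the base spun about the glycosidic bond to an
  exact χ. Every fixture writes to PDB/mmCIF and survives
  read → annotate → featurize, closing the loop between generator and
  analyzer.
* **Labeled tables.** Count features are Poisson(0.3); five informative
  features are Poisson(1.0) (the higher rate gives them dynamic range to
  carry signal) with logistic effect β = 1.2 each; labels are Bernoulli
  with the intercept calibrated against the realized signal distribution
  so the expected positive rate equals the study imbalance (43:171 —
  the naive logit intercept overshoots once βx has variance). These
  defaults emulate the size and imbalance of the nucleotide task; they
  do not emulate feature correlation structure, group structure across
  complexes, or annotation noise of real interfaces, so passing tests
  demonstrate method correctness, not expected field performance.

## Numerical choices

Plane normals follow a pinned sign convention (positive z, then x, then
y) so orientation is deterministic; collinear atom sets raise a
degenerate-plane error and the moiety is skipped with a warning. The
acute interplane angle min(θ, 180° − θ) is used throughout. Contact and
gate comparisons carry a 1e-9 absolute slack so exact boundary fixtures
(4.5 Å contacts, 30° angles) classify inclusively and reproducibly.
Altloc duplicates resolve to the highest-occupancy copy (ties toward
altloc "A", then file order); only the first model of multi-model files
is used. Author residue numbering (chain, residue number, insertion
code) is the coordinate system for all site mapping. The two-sided
Fisher p is the sum of all hypergeometric table probabilities no more
probable than the observed one, with a 1e-7 relative tolerance on the
probability comparison; the binomial rate comparison tests group a's
events against group b's rate as the null. All randomness flows from one
master seed via named substreams; forests run single-threaded so reruns
are byte-identical, and the pipeline writes a config hash into every
output file.

The test suite and acceptance script scale the expensive protocols down
to keep runs short: N = 200 permutations (the N = 2000 arithmetic is
asserted in closed form), 10 seeded recovery replicates at n = 214 rows
× 246 features, bootstrap B = 200 for the reported interval, and the
exhaustive Fisher enumeration check runs vectorized over all margins up
to 30.

## Known limitations

The interface annotators reimplement a pinned subset of what dedicated
structure-annotation suites compute; exact thresholds of those tools are
not published, so edge-case disagreement (e.g. lateral-offset
definitions, guanidinium plane membership) is possible. Base-pair
calling requires ≥ 2 base-base hydrogen bonds and does not classify pair
geometries; water-mediated bridges, backbone suites and assembly
symmetry are out of scope. Rows from one complex are correlated;
row-level stratified 10-fold CV is the default protocol, with
leave-complex-out grouping available where metadata permit. Modified
residues map to parents through a small alias table; unmapped residues
are excluded from feature tables with a warning.
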
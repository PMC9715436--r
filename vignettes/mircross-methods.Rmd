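---
title: "Cross-kingdom miRNA target prediction and panel analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-kingdom miRNA target prediction and panel analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircross)
```

## Scope and pipeline

`mircross` models the computational arm of a cross-kingdom regulation
study: a pool of mature plant miRNAs is screened against an animal gene
panel, candidate duplexes are scored by an ensemble of predictors, the
ensemble scores feed a calibrated SVM with a strict 0.60 probability
cutoff, predictions are intersected across species, and the predicted
targets are related to the genes a qPCR expression panel reports as
modulated. Every stage consumes inputs the synthetic-data module can
generate with recorded ground truth, which is how the package is tested.

## Duplex predictors

The multi-algorithm prediction stacks used in this field combine the
outputs of many external tools. This package deliberately abstracts that
stack behind a predictor contract: a predictor is anything that, for one
miRNA–transcript pair, emits either an interaction energy (kcal/mol, ≤ 0)
or a probability in [0, 1]. Three built-in surrogates make the contract
concrete and keep the downstream mathematics fully testable without
third-party binaries; an external-process plugin (one
`predictor_id<TAB>kind<TAB>value` row on stdout) lets real tools be wired
in. A failing plugin is recorded as a missing output and flags the
candidate incomplete rather than aborting the scan.

**Seed complementarity** slides the miRNA antiparallel along the site and
scores positions 2–8 (1-based from the 5' end), the seed region that
dominates target recognition: Watson–Crick pairs count 1, G:U wobbles count
`wobble_weight` (default 0.5), normalized by the seed length and maximized
over offsets.

**Duplex free energy** is the minimum over all intermolecular antiparallel
alignments allowing bulges and internal loops, computed by an O(n·m)
dynamic program with two matrices: the best duplex ending at a given pair,
and a running affine-loop minimum. Energetics come from a fixed, versioned
nearest-neighbour table (`builtin-v1`): stacking energies for all WC and
G:U pair steps (−1.1 to −2.7 kcal/mol, stronger for G:C-rich steps), an
affine loop penalty of 3.0 + 0.5 per unpaired base, and a +4.1 kcal/mol
initiation penalty. The table has plausible Turner-style magnitudes but is
not a thermodynamic reference; what matters for this package is bit-exact
reproducibility, which is why the table ships as a hashed data file and why
an independent brute-force enumerator (`duplex_free_energy_exhaustive`)
validates the dynamic program exactly on short sequences. "No stable
duplex" is encoded as energy 0, not +∞, so the energy score below stays
finite and such a predictor contributes a neutral 0.5 term.

**Scanning** evaluates fixed-length windows (default 28 nt, step 7, plus a
window flush with the transcript end); ties are broken by the smallest
start coordinate so results are reproducible. A transcript shorter than the
window is scanned as one whole-transcript window with a warning. The
seed-anchored variant runs the dynamic program only on the best seed site
plus a 4-nt flank. Coordinates are 0-based half-open on the sense strand
throughout; transcripts are never reverse-complement scanned, because
miRNA targeting acts on the mature mRNA sense strand. The transcript
region scanned (3'UTR, CDS or full mRNA) is carried as metadata with a
3'UTR default — plant-style targeting can also hit coding regions, so the
region choice is left to the user rather than hard-coded.

## Ensemble scores

Energies aggregate through a Fermi–Dirac form,
`ES = Σ_i 1/(1 + exp(E_i/(R·T)))`, and probabilities by plain summation,
`PS = Σ_i SCORE_i`. The sums run over predictors (N = number of
algorithms), not over candidate sites: each predictor already reports its
best site, and summing over predictors is the reading under which ES and PS
are bounded by the predictor count. `RT` is taken as R·T with
R = 1.987×10⁻³ kcal·mol⁻¹·K⁻¹ and T = 310.15 K (≈ 0.6163 kcal/mol,
physiological temperature); both are configurable through
`thermo_constants()`. Only this dimensionless Fermi–Dirac reading of the
energy aggregate is bounded and monotone, which is why it is the one
implemented.

One numerical property is worth knowing: at physiological RT the logistic
term is extremely sharp around E = 0, so any pair with a stably negative
duplex energy contributes a term numerically close to 1 and ES behaves
largely as a "how many predictors found a stable duplex" count. In double
precision the term saturates to exactly 1 for energies below about
−22 kcal/mol; the package's tests therefore check strict monotonicity and
the `ES < n` bound only in the resolvable range, and treat the saturated
regime as the limit behaviour it is. Discrimination between strongly and
weakly bound pairs is carried mostly by PS and by the optional raw
per-predictor features (`include_raw = TRUE`), which are an opt-in
extension — the default feature vector is exactly (ES, PS).

## Classifier

The classifier is an RBF-kernel SVM with fixed hyperparameters (cost 1,
kernel width 1/n_features) rather than tuned ones: no hyperparameters are
published for this pipeline, and fixed defaults keep runs reproducible.
Features are standardized with training-fold statistics only; class
imbalance is handled by inverse-frequency class weights, not resampling,
again for determinism. Probability calibration is a Platt sigmoid fitted by
logistic regression on a stratified held-out fold (20% per class,
seed-pinned): calibrating on held-out decision values avoids the
overconfidence of calibrating on training scores, and implementing the
sigmoid directly (rather than using the SVM library's internal CV
calibration, whose fold shuffling is not controlled by R's RNG) makes
retraining with the same seed byte-identical. The decision rule is strict:
a pair is a predicted target when its calibrated probability exceeds the
cutoff (default 0.60), so a probability of exactly 0.60 is not a target,
and raising the cutoff can only shrink the predicted set. Models serialize
to a single-file bundle that reproduces probabilities exactly on reload.

Training data: no validated plant-miRNA/animal-mRNA interaction set ships
with the package; the synthetic generators are the canonical source, and
labeled TSVs from user-supplied validated sets are accepted in the same
format. Published per-pair probabilities for the 19-gene cross-species
table are bundled as an *input* fixture (the table's parenthesized numbers
are treated as class probabilities; where a source instead reports binding
scores, the `extras` channel of the feature vector accommodates that
reading without changing the machinery).

## Expression panel

ΔCt is the group-mean target Ct minus the group housekeeping mean
(arithmetic mean of per-sample housekeeper Ct values, i.e. a geometric mean
on the expression scale, the standard choice when multiple housekeepers are
combined); ΔΔCt contrasts two groups and fold change is 2^−ΔΔCt. The
significance rule is threshold-only and strict — up when FC > 1.50, down
when FC < 0.5 — with boundary values classified unchanged; no p-value is
attached, because the panel criterion being modelled is itself
threshold-only. Percentages are reported to one decimal with half-up
rounding, matching how such panels are conventionally summarized. Samples
without a housekeeping well are excluded with a warning; targets present in
only one group are skipped with a warning.

The sample-size operation searches for the smallest integer n ≥ 2 whose
exact two-sided two-sample t-test power — noncentral t with df = 2n−2 and
noncentrality d·√(n/2) — reaches the target; at the design point d = 4.0,
α = 0.05, power 0.8 it returns n = 3 per group. The two-sample equal-n,
equal-SD form is assumed, matching a two-arm animal design.

## Concordance

"Modulated" means fold-change class ≠ unchanged under the panel
thresholds. Overlap between modulated and predicted genes is reported as
raw counts plus a one-sided upper-tail hypergeometric p-value; the p-value
is an added diagnostic (clearly labelled as such) and never alters the
counts. An exhaustive subset-enumeration oracle validates the tail
probability for all panel configurations up to size 12. Direction
consistency is the fraction of modulated predicted targets that are
downregulated, the direction miRNA targeting predicts.

## Synthetic data: what it emulates, and what it does not

The generator defaults encode the study conditions this package targets: a
pool of 17 mature miRNAs of 21 nt, an 84-gene panel, transcripts of
300–800 nt (typical 3'UTR lengths), two diet groups with 3 replicates, a
balanced labeled set of 400 positives and 400 negatives, and planted sites
that are exact reverse complements (`site_quality = 1`). Site degradation
mutates a random subset of positions to bases that can pair neither WC nor
G:U, non-seed positions first, so quality maps monotonically to binding
strength. Negatives are sampled uniformly from non-planted pairs with no
hard-negative mining — the simplest null; harder negatives are available by
planting low-quality sites. Labeled-set features are always computed by the
real predictor ensemble, never simulated. Ct tables give every sample a
housekeeper well at Normal(20, σ) and build each target well from that
sample's housekeeper value plus a fixed per-gene offset, minus the planted
log2 fold change in non-reference groups, plus independent Normal(0, σ)
well noise — i.e. a shared per-sample loading shift plus well noise, the
error structure ΔCt normalization is designed to remove. Per-gene planted
log2 fold changes are drawn uniformly from [−2, 2] with σ = 0.1 cycles by
default, a realistic qPCR precision.

Each generator draws from its own RNG stream derived from the master seed
by a fixed label, so adding a generator never perturbs the others, and
every generator is byte-reproducible per seed.

What passing on this synthetic data does **not** show: real 3'UTRs are not
uniform random sequence (composition bias, repeats, structure), real
binding sites are not un-structured exact complements, transcript
accessibility is ignored, and real validated interaction sets are smaller
and noisier than the planted ones. Synthetic recovery therefore validates
the machinery — scores, calibration, thresholds, bookkeeping — not the
biological error rate of any predictor stack.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at deliberate desk scale:
exhaustive duplex enumeration on 200 random pairs of length ≤ 8, ES
agreement with an independent logistic evaluation on 1,000 random energy
lists at 1×10⁻¹⁰ relative tolerance, classifier recovery on 800-pair
labeled sets over five seeds (held-out AUC ≥ 0.95, accuracy ≥ 0.9), ΔΔCt
recovery of planted effects within ±0.15 log2 units for ≥ 95% of genes at
σ = 0.1 with six replicates over ten seeds, and hypergeometric enumeration
over all panels of size ≤ 12. These sizes were chosen so the full suite
completes in about a minute while still exercising every contract.

Other numerical decisions: ties in scanning always resolve to the smallest
start; percentages round half-up; the duplex DP returns min(0, optimum) so
energies are never positive; degenerate inputs (empty score lists, single
windows, missing housekeepers, fold-change values on a threshold) each have
a defined behaviour exercised by tests rather than being left unspecified.

## Known limitations

The built-in predictors are surrogates: they are honest, reproducible
implementations of seed matching and duplex energetics, but they are not
re-implementations of any published external tool, and the bundled energy
table is versioned for reproducibility, not thermodynamic accuracy.
Reported per-pair probabilities from external prediction stacks cannot be
regenerated by this package — they depend on unpublished training sets and
third-party predictor versions — which is precisely why the bundled
cross-species table is treated as input data, and why the classifier's
accuracy claims are made only on synthetic ground truth. GEO series
ingestion is out of scope; expression inputs are Ct tables or fold-change
records.
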
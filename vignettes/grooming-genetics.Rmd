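---
title: "From grooming frames to genes: methods behind groomscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From grooming frames to genes: methods behind groomscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(groomscan)
```

`groomscan` covers the analysis chain of a mouse grooming strain survey:
frame-level classifier probabilities are cleaned into ethograms, ethograms
into bout phenotypes, phenotypes into strain patterns and mapped loci, and
mapped genes into cross-species trait modules. This vignette explains the
models, the tunable parameters, the simulators used for validation, and the
design decisions taken where more than one reasonable choice existed.

## 1. From probabilities to ethograms

A video classifier scores each frame with a grooming probability. Ensembles
help: independently trained models and symmetry-transformed inputs give a
set of streams that `merge_predictions()` combines per frame by arithmetic
mean (default and best-performing), maximum, or median vote. With an even
number of streams the vote uses the *lower* median — deterministic and
conservative toward not-grooming.

`smooth_predictions()` applies a centered rolling mean over 46 frames
(about 1.5 s at 30 fps), the window at which frame-flicker in grooming
predictions is suppressed without erasing real short bouts. At the sequence
ends the window shrinks to the frames that exist; we deliberately do not
pad, because padded values would fabricate evidence and change the output
length contract. `binarize()` calls a frame grooming when its probability
is `>=` the threshold (default 0.5; the operating point is a user choice on
the ROC curve, not a fixed constant of the method).

A mouse resting in a hunched posture looks, frame by frame, much like a
grooming mouse. Motion separates them: during grooming the ellipse-fit
shape ratio W/L (minor over major axis) fluctuates with standard deviation
above about 2.5×10⁻⁴, while at rest it stays below 2×10⁻⁵. `resting_mask()`
computes the rolling standard deviation of W/L over a centered 31-frame
window and flags frames strictly below 5×10⁻⁵ — the midpoint on a log scale
between those two regimes — and `apply_resting_mask()` forces flagged
frames to not-grooming. The comparison is strict `<`, mirroring the rule's
phrasing, and the mask is invariant to rescaling W and L by a common
factor, so camera zoom does not matter. The mask is applied to the
frame-level ethogram *before* bout segmentation; the alternative order
(mask after segmentation) would let a resting period bridge two bouts into
one, which is exactly the artifact the heuristic exists to prevent.

## 2. Annotator agreement

`classify_disagreements()` reduces annotator comparison to maximal runs of
differing frames and classifies each run by its agreed flanks: not-grooming
on both sides means one annotator called a bout the other missed
(*missed bout*); grooming on both sides means one recorded a break the
other bridged (*skipped break*); opposite flanks mean both saw a transition
but placed it differently (*misalignment*). Two conventions make the
taxonomy total: sequence boundaries count as agreed not-grooming (assays
begin and end outside grooming), and a run with opposite flanks is
misalignment regardless of its length. The taxonomy is symmetric in the two
annotators by construction.

## 3. Bouts and the phenotype panel

A grooming *bout* is continuous grooming exceeding 3 s, within which brief
pauses are tolerated: `segment_bouts()` merges two grooming runs when the
gap is shorter than 10 s *and* the cumulative centroid path length across
the gap is at most twice the average body length (mean major axis over the
whole video). Path length, not net displacement, is used — a mouse that
wanders and returns has locomoted. Merging happens first; the merged
segment qualifies when its *groomed* seconds (pauses excluded) strictly
exceed 3 s. This order reconciles "pauses are allowed" with "un-joined
segments under 3 s are not bouts": a 2 s + 2 s pair separated by a
motion-free 1 s pause is one valid 4 s bout. Whether the 3 s rule should
instead apply to the merged span is genuinely underdetermined; groomed time
is used because the phenotype definitions divide total groomed duration by
bout count, and a span-based rule would let two short segments qualify on
pause time alone.

Binning credits a bout's entire groomed time, and its count of one, to the
bin containing its start frame — bins hold whole bouts, so a bin can exceed
its own width when a long bout starts inside it. The panel summarizes
totals, counts and mean bout lengths at 5/20/55 min; OLS slopes of
1-min-binned groomed seconds and bout counts against bin index (units s/min
and bouts/min) describe temporal patterning; and the 5-min peak statistics
(GrPeakMidBin = midpoint minute of the argmax bin, earliest bin on ties;
GrPeakVal = groomed seconds there; GrPeakSlope = GrPeakVal/GrPeakMidBin)
summarize when and how strongly grooming peaks. Horizons longer than the
recording are `NA` rather than silently truncated.

## 4. Strain patterns

Animals are filtered within strain by the Q1 − 1.5·IQR / Q3 + 1.5·IQR rule
on total grooming time, with type-7 (linear interpolation) quartiles —
stated explicitly because quartile conventions differ across software.
Groups under 4 animals pass through unfiltered. Strain-level pattern types
come from k-means (k = 3 by default, chosen by inspection in the source
study; 50 restarts, seeded) on z-scored features combining grooming
quantity with the relative 5-min profile; z-scoring makes the partition
invariant to the units of any one feature. Labels are re-ordered by
descending cluster-mean total grooming so "cluster 1" is stable across
runs. `GrPeakLength` — how long a strain stays near its peak — is
operationalized as the number of consecutive 5-min bins, in the run
containing the peak, at ≥ 90% of the peak bin's mean; the 90% fraction is a
package choice (no formula was given for the concept) and is configurable.

## 5. Covariate selection

`stepwise_select()` wraps `stats::step` in two passes: main environmental
effects first, then interactions of sex with the selected terms. AIC is the
default criterion (BIC available); both forward and backward searches run
and the report says whether they agree, since agreement is itself evidence
the selection is not an artifact of search order. Continuous covariates are
standardized so criterion changes are comparable across terms;
rank-deficient candidates are detected via the aliased coefficients of the
full fit, warned about, and dropped rather than silently breaking the
search.

## 6. The mixed model

Per phenotype and chromosome the model is `y = Wα + xβ + u + ε`,
`u ~ N(0, σg²K)`, `ε ~ N(0, σe²I)`. `K` is the centered genomic
relationship matrix `XcXc'/m` (columns centered by twice the allele
frequency), computed from all chromosomes *except* the one being tested —
leave-one-chromosome-out — so the tested SNPs do not shrink their own
signal (proximal contamination). The variance ratio `λ = σg²/σe²` is
profiled out by REML: one eigendecomposition `K = USU'` rotates the model
to independent observations with variances `λsᵢ + 1`, and the restricted
log-likelihood is maximized over `log λ ∈ [−10, 10]` by bounded scalar
search (tolerance 10⁻⁶). λ is estimated once per chromosome under the null
and then held fixed for the per-SNP generalized least squares scan — the
standard approximation that makes a genome scan one matrix product instead
of m optimizations. The Wald p-value is `P(χ²₁ ≥ (β̂/se)²)` with the
residual variance estimated per SNP, which makes the identity-kinship case
agree with ordinary least squares to floating precision (a property the
test suite checks against an independently coded OLS oracle). SNPs constant
after filtering return `p = 1` rather than erroring, so batch scans never
die mid-genome. Missing dosages are mean-imputed per SNP after the MAF ≥
10% / missingness ≤ 5% filter (both bounds inclusive).

Chip heritability uses the all-SNP kinship, no SNP term:
`PVE = σg²κ/(σg²κ + σe²)` where `κ = mean(diag K)` converts the variance
component to an average per-individual genetic variance. Its standard
error comes from the observed curvature of the profiled restricted
likelihood at the optimum, via the delta method on `log λ`
(`dPVE/dlogλ = PVE(1 − PVE)`); when the likelihood is flat near a boundary
a broader finite-difference step bounds the curvature and the result is
flagged as non-converged. The exact information matrix used by other
implementations is not published, so curvature-based is our documented
choice.

The genome-wide threshold is empirical: shuffle one approximately normal
phenotype, rescan the genome, record the minimum p, and take the 5%
order-statistic of that distribution (the ⌈αB⌉-th smallest of B
permutation minima). This respects LD — duplicating every SNP changes
nothing — and for M independent SNPs converges to the closed form
`1 − 0.95^(1/M)`.

## 7. QTL and pleiotropy

LD decay is summarized by Pearson r² of all intra-chromosome SNP pairs
within 2.5 Mb, binned at 5 kb with a loess overlay. Significant SNPs are
clumped greedily: the smallest p-value genome-wide seeds a locus and
absorbs unassigned significant SNPs within 10 Mb (upstream and downstream
of the peak) whose dosage r² with the peak exceeds 0.2, repeating until the
significant set is partitioned. The r² rule is strict `>` (the source
material uses both ≥ and > in different places; strict is chosen and
configurable), and p-value ties break by (chromosome, position) so results
never depend on input order. Coordinates are 1-based inclusive internally;
BED export converts to 0-based half-open.

Peaks pooled across phenotypes form a peak-SNP × phenotype matrix of
−log₁₀ p (zero where absent) that k-means (k = 7 default, seeded) clusters
into pleiotropy groups; each cluster's scans combine by per-SNP minimum p
over the phenotypes owning its peaks. Gene-level pleiotropy counts the
distinct phenotypes whose QTL spans overlap a gene interval by at least one
base (via `GenomicRanges`); the default selection keeps genes with ≥ 6
phenotypes.

## 8. Bipartite PheWAS modules

Gene–trait associations at p ≤ 10⁻³ become edges weighted −log₁₀ p in a
bipartite network. Module detection maximizes Barber's weighted bipartite
modularity — only gene–trait pairs enter the null term — by asynchronous
label propagation (each node adopts the neighboring label with the best
modularity gain, ties to the smallest label) followed by a greedy
label-merge phase; zero-gain merges are allowed only between labels that
share edges, which makes a connected pair collapse to one module while
leaving disconnected equal blocks apart (two such blocks have exactly
Q = 0.5, a closed-form case in the tests). Twenty seeded restarts keep the
best Q; results are deterministic given the seed.

Modules are ranked two ways, both reported: by each module's additive
contribution to Q (contributions sum to Q exactly), and by the median over
the module's traits of −log₁₀ of the Simes-combined p-value of that trait
with the module's genes (`min_i m·p₍ᵢ₎/i`). Whether a "module modularity
score" should be the contribution or a recomputed Q on the induced
subnetwork is not settled usage; the contribution is the primary number
because the contributions are additive and comparable across modules.
Simes combination is restricted to the module's own genes (rather than all
genes in the study) so the ranking reflects the module, not the background;
this scope is configurable through the association table passed in.

## 9. What the simulators emulate — and what they do not

* `simulate_ethogram()` draws bout initiations from an inhomogeneous
  Poisson process (thinning) whose rate profile encodes three archetypes —
  inverted-U, early plateau, monotone increase — with lognormal bout
  durations (default median 15 s, log-sd 0.6), occasional sub-10 s pauses,
  logistic-channel prediction streams with stream-specific bias, and a
  track whose W/L noise is 2.5×10⁻⁴ during grooming and 10⁻⁵ otherwise with
  near-zero centroid motion during grooming and pauses. It does *not*
  emulate grooming syntax (paw lick vs face wash), wall-rearing confusions,
  tracker dropouts, or arena geometry; passing tests show the pipeline's
  rules are implemented correctly, not that any classifier reaches a given
  accuracy on real video.
* `simulate_annotators()` applies boundary jitter (normal, rounded, clamped
  between neighboring-boundary midpoints so segments keep their order),
  short-bout deletion, and pause fill-in independently per annotator. With
  a single mode enabled, every disagreement interval falls in the matching
  taxonomy category — the property the agreement tests exploit.
* `simulate_population()` builds strain genomes from a few founder
  haplotypes per block (default 4 founders, 10-SNP blocks at 50 kb
  spacing), giving realistic block LD and kinship; replicates of a strain
  share its genotype, as in an inbred survey. Phenotypes add a polygenic
  term drawn from the realized kinship, scaled so the polygenic share of
  variance equals the target h², plus optional planted SNP effects and a
  sex effect. It is not a coalescent simulation: allele-frequency spectra,
  recombination hotspots and mutation processes are not modeled.
* `simulate_phewas()` plants gene/trait modules whose within-module
  p-values are Beta(a, 1) (a = 0.1 by default; at the 10⁻³ edge cutoff a
  Beta(a, 1) gives edge probability (10⁻³)ᵃ, so a can be chosen to hit any
  target density).

All generators are deterministic under their seed and return their ground
truth alongside the data.

## 10. Problem sizes and numerical choices in the test suite

The validation suite runs entirely on simulated data at sizes chosen to
make the statistical checks sharp but quick: bout segmentation is checked
against a brute-force segmenter on 10,000 random ethogram–track pairs;
mixed-model Wald tests against the OLS oracle on 50 random instances;
heritability recovery on populations of 500 individuals × 2,000 SNPs at
h² ∈ {0, 0.25, 0.5, 0.75} with 20 replicates each (requiring |PVE − h²| ≤
2·PVESE in ≥ 90%); the permutation threshold on 100 independent SNPs with
2,000 permutations against `1 − 0.95^(1/100) ≈ 5.13×10⁻⁴`, and its
calibration on 1,000 fresh null scans; and module recovery on planted
8-module networks (within-module edge probability 0.8, background 0.02)
over 20 seeds. Numerical tolerances: REML search tolerance 10⁻⁶ on log λ,
eigenvalues clamped at zero with a 10⁻⁶-relative PSD check, OLS equivalence
at 10⁻⁶ relative, p-values floored at the smallest positive double so the
(0, 1] contract holds.

## 11. Known limitations

* The classifier itself — network training and inference on video — is out
  of scope; the package starts from prediction streams or annotations.
* The per-SNP scan fixes λ at its null estimate (the usual approximation);
  for extremely strong single-SNP effects an exact per-SNP REML would give
  slightly different standard errors.
* The permutation threshold permutes one designated phenotype, so it is a
  genome-wide, not study-wide, correction.
* Binary and count phenotypes, multiple variance components, and
  imputation beyond per-SNP means are not supported.
* k (pattern types, peak clusters) is a user choice; the package supplies
  determinism and restarts, not model selection for k.
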
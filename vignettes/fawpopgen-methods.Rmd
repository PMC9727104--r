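---
title: "Models and design choices behind fawpopgen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind fawpopgen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(fawpopgen)
```

This vignette documents the statistical models the package implements,
the knobs that matter, what the synthetic cohort does and does not
emulate, and the numerical decisions a maintainer would want written
down.

## The synthetic cohort

All inference stages are exercised on a simulated cohort whose sampling
design copies the fall-armyworm study it supports: 12 geographic
populations, 99 native and 78 invasive diploids (177 total), three
nuclear groups ("Rice", "Corn.Mex", "Corn") and an invasive gene pool
derived from the Corn group.

**Model.** Genotypes follow a hierarchical Balding–Nichols scheme. Each
site draws an ancestral frequency `p_anc` from a Beta(0.5, 0.5) clipped
to [0.02, 0.98] (a U-shaped spectrum that keeps both common and rare
variants without generating unusable monomorphic draws). Each nuclear
group g then draws

> p_g ~ Beta(p_anc (1−F_g)/F_g, (1−p_anc)(1−F_g)/F_g),

which has mean `p_anc` and variance `F_g p_anc (1−p_anc)`; the invasive
pool drifts a second time from Corn with coefficient `F_extra`.
Genotypes are Binomial(2, p) draws. The closed-form control this gives
over expected differentiation is the reason for choosing it over a
coalescent simulator: recovery of the drift coefficients by the
Weir–Cockerham estimator is a direct acceptance check. For two groups
that each drifted with coefficient F from a common ancestor, the
estimator converges on ≈ F (the between-group variance contributed by
two independent branches is 2F, of which the estimator's
among-population component captures half after centring on the pooled
mean); with drift on only one branch it converges on ≈ F/2.

**Default parameters and why.**

* `group_f = (Rice 0.15, Corn.Mex 0.15, Corn 0.05)`: strong, clearly
  separable outlying groups and a broader Corn group, matching the
  qualitative PCA geometry of the study (Rice and Corn.Mex at the ends
  of component 1, Corn between them).
* `invasive_f_extra = 0.08`: with one drifted branch this puts expected
  F_ST between invasive and native Corn samples near 0.04, the scale
  the study reports for that contrast.
* `n_sites = 20000` over five 1-Mb scaffolds (4 SNVs/kb) and sweep
  `alpha = 1e-5`/bp: desk-scale stand-ins for a dataset whose real
  counterpart has ~70 SNVs/kb. The pair was chosen, before the test
  suite was frozen, so that a hard sweep is unambiguous at the
  conventional outlier threshold Λ > 100 (peak Λ ≈ 200–250 against a
  neutral-scaffold maximum < 10) while a full scan stays under a minute.
  With `alpha = 1e-5` the strongly distorted footprint spans roughly
  ±100 kb around the sweep center.
* Mitochondrial marker: 1536 bp (the full-length COX1 barcode), 30
  clade-diagnostic substitutions (~2% divergence, the observed scale
  between the two FAW mitochondrial strains), within-clade mutation rate
  0.002/bp. The outgroup is simulated from the clade ancestor — half of
  the diagnostic sites in each state — so that it attaches on the branch
  between the clades and rooting recovers both strains as monophyletic.
* TPI marker: 10 diagnostic SNVs nearly fixed between strains (residual
  frequency 0.03) plus 40 shared background SNVs. Hemizygosity of the Z
  chromosome is not modelled; the locus is treated as autosomal-diploid.
* Population-to-group assignments, host plants and the fraction of sfC
  mitochondria per population are fixed in `default_populations()`:
  Rice-group populations carry the sfR mitochondrion, Mexico is pure
  sfC, and the remaining corn-feeding populations are 50–80% sfC. That
  crossing of mitochondrial strain over nuclear group is what produces
  the deliberate TPI/COX1 marker discordance and gives the
  between-strain D_XY contrast something to detect: the invasive pool
  contains both mitochondrial clades inside one nuclear gene pool.

**What the generator does not emulate.** No linkage disequilibrium
except the sweep itself; no missing data by default; no sequencing or
genotyping error (INFO annotations are drawn inside the retention
thresholds, filter behaviour is tested with dedicated fixtures); no
within-group population substructure; REF is always the ancestral
allele, so unfolded spectra are exact by construction. Passing tests
therefore demonstrate correctness of the estimators under a
well-specified model, not robustness to the pathologies of real
resequencing data. In particular the sweep generator implements the same
star-like escape model the scan assumes, so detection-power results are
well-specified-model results.

## Variant filtering

Sites are removed when QD < 2.0, FS > 60.0, MQ < 40.0,
MQRankSum < −12.5 or ReadPosRankSum < −8.0. A site lacking an
annotation passes that filter — callers omit rank-sum annotations at
sites without heterozygotes, and dropping such sites would silently bias
toward heterozygous sites; `drop_missing_info = TRUE` inverts the
policy. Multi-allelic records are parsed losslessly and excluded only at
`select_biallelic_complete()`, together with any site missing a genotype
in any sample. Coordinates are 1-based as in VCF; all window arithmetic
is half-open `[start, end)` aligned at coordinate 1 and never spans
scaffolds.

## Distances and trees

The Kimura 2-parameter distance uses the closed form
−½ ln[(1 − 2P − Q)√(1 − 2Q)] with pairwise deletion of non-ACGT
positions and a uniform rate across the alignment. Saturation
(1 − 2P − Q ≤ 0 or 1 − 2Q ≤ 0) raises a dedicated condition class
rather than returning NaN, so callers can distinguish "undefined" from
"zero information".

The individual-level nuclear distance is the Euclidean distance of
per-individual allele frequencies f = dosage/2 with transversion sites
weighted double. The weight enters multiplicatively on the squared
per-site difference (`weight_on = "squared_difference"`); the
alternative reading — doubling the unsquared difference, i.e. a factor
four on the squared term — is available as
`weight_on = "difference"`. Using dosage instead of f only rescales all
distances and cannot change any topology. The distance is Euclidean by
construction, hence a metric, which is also why the bootstrap resamples
*sites*: resampling distance-matrix entries would not preserve metric
validity.

Trees are built with the BIONJ agglomeration (variance-weighted branch
estimation); negative branch estimates are clamped to zero. Bootstrap
replicates resample columns with replacement and are summarised by a
majority-rule extended consensus: splits above 50% enter first (they
are mutually compatible), remaining splits are added greedily in order
of decreasing frequency while compatible, with ties broken by
frequency, then split size, then the lexicographic split key — fully
deterministic. Each internal node is labelled with the percentage of
replicates containing its bipartition. Monophyly of a label set on an
unrooted tree means the set is one side of some edge; its support is
that edge's label (0 when the tree carries none; singletons and the
full set are trivially monophyletic at 100). Trees are unrooted
internally; Newick output roots on an outgroup only when one is given.

A note on degenerate inputs: when many leaves are at zero distance
(e.g. flat concordant signal), their resolution is an arbitrary
zero-length refinement and the extended consensus will carry
low-support splits among them. Support values are therefore only
meaningful for edges with actual signal; the test suite asserts 100%
supports on data whose signal resolves every internal edge.

## Strain typing

TPI: PCA on the marker genotypes, 2-means on component 1, clusters
named by anchor samples of known strain. A cluster containing anchors
of both strains leaves its samples unassigned with a warning. COX1:
K2P + BIO-NJ rooted on the outgroup; the clade of strain S is the
largest clade containing every S anchor and no anchor of the other
strain (walking rootward from the anchor MRCA), which tolerates
non-anchor samples branching basally inside the strain clade. Samples
in both clades (unresolved trees) or neither are unassigned; an
alignment with zero within-sample divergence short-circuits to
all-unassigned. The study rooted its barcode tree on a congeneric
outgroup and used previously typed Mississippi/Puerto Rico individuals
as anchors; the simulator mirrors that by anchoring Mississippi, Puerto
Rico and Florida samples with their generating labels. The barcode tree
is built by distance (K2P + BIO-NJ) rather than maximum likelihood;
only clade membership is consumed downstream, for which the two
approaches agree on clean barcode data.

## Differentiation statistics

Weir–Cockerham components are computed per site from diploid genotype
counts (sample sizes, allele frequencies and observed heterozygosity
per group), the genome-wide value as the weighted mean
Σa ⁄ Σ(a+b+c) over sites with a defined non-zero denominator. Sites
with undefined components (monomorphic, singleton groups) are flagged,
not dropped silently. The permutation test shuffles group labels
preserving sizes and reports both the study's convention
p = #{null > obs}/R — which can be exactly 0 — and the conservative
(1 + #{null ≥ obs})/(1 + R). D_XY is reported per SNV (no per-bp
normalisation and no accessible-site mask exists for the synthetic
cohort), so absolute levels are comparable only within a run; the
strain contrast summarises windows by class medians and the proportion
of windows where the invasive value is lower, ties counting one half.
The genome-wide permutation statistic is the genome-wide weighted mean
(not a window average).

## The sweep scan

The background model assigns every segregating site the genome-wide
spectrum probability φ̂(k) (estimated from the scanned samples, add-one
smoothing on empty classes so L₀ is finite). The sweep model at escape
probability P_e = 1 − e^(−αd): the number of escaping lineages is
Binomial(n, P_e); the escapees' derived count is a hypergeometric draw
from the pre-sweep sample configuration (itself drawn from φ̂); all
non-escapees inherit one beneficial haplotype, derived with the
pre-sweep sample frequency. This distribution sums to one for every
(α, d) and reduces *exactly* to the background at P_e = 1, so appending
α = ∞ to the maximisation grid guarantees Λ ≥ 0. The α grid defaults
to 16 log-spaced values over 1e-8–1e-2 per bp; distance is physical
(bp), recombination-rate scaling being absorbed into α. The scan is a
re-implementation of the SFS-based composite-likelihood method class,
not a bit-compatible clone of any particular scanner.

Numerics: per-site sweep log-probabilities are tabulated over a
64-point log grid of x = αd on [1e-4, 50] and linearly interpolated in
ln x; x ≥ 50 means P_e = 1 to double precision and contributes exactly
zero to Λ (the endpoint stores the background itself, keeping the
Λ ≥ 0 guarantee exact); x below 1e-4 is clamped (a site exactly on a
grid position would otherwise have −∞ log-likelihood under any finite
α). Probabilities are floored at 1e-300 before logging.

Thresholding uses the conventional Λ > 100, an explicitly arbitrary
and scale-dependent choice; the summary reports the full count, the
percentage (3 decimals) and the median Λ so users can judge thresholds
per dataset. Neighbouring flagged grids (index gap ≤ `max_gap_grids`,
default 0 = strictly adjacent) merge into loci spanning first to last
grid position. A locus is invasive-specific iff no native-scan grid
inside its span exceeds the same threshold; both scans must share grid
coordinates. One behavioural note: a single sweep can fragment into a
main locus plus small satellites separated by one sub-threshold grid,
and a satellite's narrow span may contain no native outlier even when
the main locus does. Judgements about a particular sweep should
therefore be made on the locus containing its peak, or with a positive
`max_gap_grids`.

## Pipeline and reproducibility

`run_pipeline()` executes simulate/load → filter → strain typing →
PCA/groups → F_ST/D_XY → bootstrap phylogeny → sweep scans → report,
writing every intermediate in plain-text formats (VCF, TSV, Newick,
JSON). All randomness is derived deterministically from one master
seed, so identical configurations reproduce identical numeric content;
the numbered `analysis/` drivers are the same stages as standalone
scripts. The "native Corn" comparison set is defined algorithmically as
the native members of the k-means cluster holding the majority of
invasive samples (the study identified its groups by inspection of the
same components).

Problem sizes used by the tests and the acceptance script — 20,000
SNVs, 200 bootstrap replicates (down from the 1,000 default), 100
permutations, 1,000 grids per scaffold, 500 repeated calibration tests
at 20 samples × 60 sites — were chosen as the smallest sizes at which
each check is decisive (bootstrap supports near 100%, calibration
within its exact binomial interval, sweep localisation within one grid
spacing).

## Known limitations

* Power statements transfer to real data only qualitatively: the
  generator and the scan share the same sweep model, and real SNV
  densities are an order of magnitude higher than the desk-scale
  default.
* The TPI caller assumes the two strains separate on the first marker
  component; markers with three or more clusters would need k > 2.
* D_XY per SNV is not comparable across datasets with different
  filtering.
* The consensus builder targets cohort-scale label sets (hundreds of
  tips), not thousands; its split bookkeeping is quadratic in the worst
  case.
* `wc_fst` treats groups as fixed; no block jackknife or confidence
  intervals are provided.
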
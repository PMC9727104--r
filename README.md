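# fawpopgen

Inference toolkit for the population genomics of the fall armyworm
(*Spodoptera frugiperda*, FAW) invasion. FAW is a major corn pest native
to the Americas that spread through Africa, Asia and Oceania after 2016.
Whole-genome resequencing of native and invasive individuals can answer
three questions that morphology cannot: which host-plant strain (sfC,
the corn strain, or sfR, the rice strain) the invaders belong to; whether
the invasive populations descend from a single ancestry or from repeated
introductions; and whether invasive genomes carry population-specific
signatures of adaptive evolution.

The package implements the full inference chain for these questions and a
hierarchical Balding–Nichols genotype simulator that reproduces the study
design (177 individuals from 12 geographic populations: 99 native, 78
invasive), so every stage is testable end to end without any sequencing
data.

## Methods at the core

* **Strain typing.** TPI-locus genotypes are classified by PCA + 2-means
  with anchor samples naming the clusters; mitochondrial strains come
  from the COX1 barcode tree (Kimura 2-parameter distances,
  d = −½ ln[(1 − 2P − Q)√(1 − 2Q)], BIO-NJ, rooted on an outgroup) with
  anchored clades.
* **Population structure.** Variance-standardised genotype PCA (each
  variant centred by 2p̂ and scaled by √(2p̂(1−p̂))), ten components,
  k-means grouping on the two leading components.
* **Differentiation.** Weir & Cockerham (1984) variance components a, b,
  c per site; genome-wide weighted F_ST = Σa ⁄ Σ(a+b+c), in 100-kb
  windows and genome-wide; significance by label permutation (R = 100),
  p = #{F_ST(null) > F_ST(obs)}/R. Windowed absolute divergence
  D_XY = p_A(1−p_B) + p_B(1−p_A) per SNV contrasts the two mitochondrial
  strains within invasive versus native samples.
* **Individual-level phylogeny.** Transversion-weighted Euclidean
  genotype distance D(i,j) = √(Σ_s w_s (f_is − f_js)²), w_s = 2 at
  transversions; BIO-NJ per site-bootstrap replicate; majority-rule
  extended consensus with bipartition supports; monophyly of the invasive
  label set read off the consensus.
* **Selective sweeps.** SFS-based composite-likelihood ratio
  Λ = 2(max_α ln L₁ − ln L₀) on 1,000 grids per scaffold under the
  star-like sweep model (each lineage escapes at distance d with
  probability 1 − e^(−αd); non-escapees collapse onto the beneficial
  haplotype). Grids with Λ > 100 merge into candidate loci; a matched
  scan of native Corn-group samples removes sweeps that are not
  invasive-specific.

## Worked example

The numbered drivers under `analysis/` run the whole chain on the
default synthetic cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_filter_variants.R
# ... through analysis/08_report.R
```

Selected output from a full run:

```
cohort: 177 samples (99 native, 78 invasive) in 12 populations
accuracy vs truth: TPI 100.0%, COX1 100.0%
marker agreement: 74.6% - the corn-feeding sfR-mitochondria samples drive the discordance
invasive samples in cluster 2: 78 of 78 -> the invasive gene pool sits inside one nuclear group
  genome-wide weighted F_ST = 0.0511, permutation p = 0 (conservative 0.0099, R = 100)
between-strain D_XY per SNV: invasive median 0.2232 vs native 0.2544; invasive lower in 100% of windows
invasive monophyly: TRUE with 100.0% bootstrap support (200 replicates)
COX1 sfC/sfR split: monophyletic = TRUE, support 99.0%
invasive scan: 5000 grids, median CLR 0.0332; 22 grids above 100 (0.440%)
  scaffold_3:486487-505506  max CLR 247.3  invasive_specific TRUE
```

Reading: both markers recover the generating strains perfectly, yet they
agree for only ~75% of samples — corn-feeding individuals can carry the
sfR mitochondrion, which is exactly why the TPI marker, not COX1, tracks
the host-plant strain. All 78 invasive samples fall inside the Corn
nuclear cluster, are mildly but significantly differentiated from its
native members (F_ST ≈ 0.05, no permutation reaches the observed value),
and form a 100%-supported clade — a single invasive ancestry. The lower
between-strain D_XY inside the invasive pool reflects the admixture of
the two mitochondrial lineages after introduction. The sweep scan
recovers the one injected sweep at scaffold_3:500000 within one grid
spacing and the native-comparison filter confirms it as
invasive-specific.

The same machinery accepts real data at any entry point: a VCF with
QD/FS/MQ/MQRankSum/ReadPosRankSum INFO fields, marker FASTA/VCF files
and a sample manifest (see `pipeline_config()` / `run_pipeline()`).

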
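---
title: "Linking chromatin accessibility to expression through TADs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking chromatin accessibility to expression through TADs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadlink)
```

## The problem this package addresses

Oncogene-induced transformation rewires transcription. Two genome-wide
readouts capture this rewiring from different angles: RNA expression (which
genes go up or down) and chromatin accessibility (which regulatory elements
open or close). Connecting the two is hard because most accessibility
changes happen far from promoters, and naive nearest-gene assignment is
often wrong. `tadlink` implements an integrative pipeline that uses
topologically associating domains (TADs) — genomic intervals with high
internal 3D contact frequency that are largely invariant across cell
types — as the spatial framework for connecting differentially accessible
regions (DARs) to differentially expressed genes, and then asks which
transcription-factor motifs and binding sites redistribute between the
parental and the transformed state.

The pipeline's stages, in dependency order:

1. **Differential expression thresholding.** A DE table (gene, log2FC, FDR)
   is an input; genes with `fdr < 0.05` and `|log2fc| > 0.5` (both strict)
   are `up`/`down`, the rest `stable`. The alternative published-style
   cutoff (>1.3-fold at p < 0.05) can be configured via `de_thresholds()`;
   the FDR-based rule is the operational default because it is the one the
   methods of such studies actually execute.
2. **Peak calling.** A transparent fixed-window local-Poisson scan
   (`call_peaks()`): reads adjusted to the transposase insertion center
   (+4/−5 bp), extended ±75 bp, counted in 150-bp windows advanced in
   75-bp steps; a window is significant when its Poisson upper-tail
   probability against `max(genome-wide rate, 25-kb local rate)` falls
   below 1e-4; significant windows within 100 bp merge into peaks; the
   summit is the leftmost maximal-count 150-bp window.
3. **Comparative DAR calling** (`call_dars()`): the same scan with one
   condition's counts against the other condition's (depth-scaled) rate as
   the expectation — including the background's count in the window itself,
   so regions equally open in both states are not called. A condition's solo
   peak overlapping (≥1 bp) a significant comparative region is a gained
   (transformed-specific) or lost (parental-specific) DAR; everything else
   is shared.
4. **Annotation** (`annotate_location()`): strand-aware promoter windows
   (1000 bp upstream to 500 bp downstream of the TSS), ±100-kb mid-range
   windows, priority promoter > midrange > far, each peak counted once.
5. **TAD linking** (`merge_tad_sets()`, `assign_smallest_tad()`,
   `declare_direction()`): TAD calls from several cell lines are pooled
   without flattening (so nested domains survive), each gene body gets the
   smallest overlapping TAD, and a TAD is `up`/`down`/`mixed`/`none`
   according to the DE genes it contains.
6. **Segregation permutation test** (`segregation_permutation()`): the
   observed statistic is the Mb overlap between the genomic footprint of up
   TADs and of down TADs. Direction labels are shuffled over the fixed DE
   gene set; the empirical lower-tail p uses the add-one rule. A small p
   means up- and down-domains segregate in the genome more than chance
   predicts.
7. **Motif analysis** (`build_logodds()`, `calibrate_threshold()`,
   `scan_pwm()`, `motif_enrichment()`): JASPAR-style count matrices become
   log-odds PWMs (pseudocount 0.25, uniform background); the score
   threshold is calibrated by exact dynamic programming to a target
   background hit rate of 1e-4 per position per strand; the 150-bp summit
   windows of gained DARs are scored against the lost DARs as background
   and vice versa, with a one-sided hypergeometric p on window-level
   presence/absence and BH adjustment across the panel.
8. **ChIP overlap** (`partition_peaks()`, `dar_chip_overlap()`): binding
   sites shared between conditions versus condition-specific by ≥1-bp
   overlap (presence/absence, not a count model); per TAD-direction
   stratum, the percentage of gained versus lost DARs carrying a binding
   site, compared with the two-proportion test.
9. **Treatment response** (`build_groups()`, `compare_response()`): genes
   down-regulated after transformation whose TAD harbors a lost DAR with a
   p53-motif summit form the focal group; their |log2FC| after an MDM2
   inhibitor (Nutlin-3a style p53 activation) is compared to all expressed
   genes by Mann-Whitney.

## Statistical kernel

- *Two-proportion test*: chi-square with continuity correction, the classic
  `prop.test` behaviour; equal observed proportions return statistic 0 and
  p 1 (also in the all-success case where `prop.test` itself yields NaN).
  Fisher's exact test is available via `method = "fisher"`.
- *Enrichment*: one-sided hypergeometric, `P(X >= k_fg)`.
- *Mann-Whitney*: exact distribution (via the Wilcoxon U CDF) when the
  combined sample size is at most 12 with no ties; otherwise the normal
  approximation with tie and continuity correction. `U + U' = n1 n2`.
- *Empirical p*: `(1 + exceedances) / (n_perm + 1)`, never zero.

## The synthetic-data generator

Real deposited sequencing data cannot ship with a package, so every stage
is validated against `simulate_dataset()`, which plants a known truth and
emulates the statistical structure the analysis assumes:

- a genome of `n_chrom = 2` chromosomes x 10 Mb, partitioned into TADs of
  0.3-1.5 Mb; additional cell-line variants split ~30% of domains, so
  smallest-TAD assignment is exercised by genuinely nested calls;
- 1-4 genes per TAD; 20% of genes differentially expressed. DE is assigned
  domain-wise: gene-rich TADs are chosen as DE domains with alternating
  directions, and each DE gene adopts its domain's direction with
  probability `segregation_pi` (default 0.95). This per-gene formulation is
  deliberate: at `pi = 0.5` directions are i.i.d. coin flips, which is
  exactly the exchangeable null the label-permutation test assumes, so the
  null variant calibrates the test rather than a different data-generating
  process. Single-gene DE remainders are avoided once two DE domains exist,
  because singleton domains blunt the combinatorial resolution of the
  permutation null;
- 150 DARs per direction, 300 bp wide, placed inside a TAD of the matching
  direction with probability 0.9; 200 shared accessible regions anywhere;
- reads: per-bp Poisson background of 0.02 reads/bp/condition (split over
  two replicates), 8-fold total enrichment inside a region for its owning
  condition. Enriched reads follow a Gaussian profile around the region
  center rather than a uniform one, so each planted region has a
  well-defined summit — which the motif-planting scheme presupposes, and
  which matches the unimodal pileups of real accessibility peaks;
- motifs: two synthetic consensus PFMs; the gained-direction motif is
  planted in gained-DAR centers with probability 0.4 and in lost-DAR
  centers with 0.05, mirrored for the lost-direction (p53-like) motif;
- ChIP peaks co-located with gained DARs with probability 0.7 and with
  lost DARs with 0.1 (plus background peaks), with the mirrored
  parental-condition set for partition tests;
- the treatment table adds +0.5 to the |log2FC| of the planted
  down-with-p53-motif group over a baseline sd of 0.2.

Values not fixed by the study design (background rate, DAR width and count,
placement bias, ChIP probabilities, treatment effect) were chosen once to
give realistic per-peak read counts (~50 reads per planted region) and
group sizes, and are all exposed in `sim_params()`.

Everything is reproducible bit-exactly from the single seed; `tracks =
FALSE` skips read-track generation for studies that only need the planted
structure (e.g. null calibration of the statistical tests, which does not
depend on the read-level caller).

What the generator does **not** emulate: GC composition structure (the
background is i.i.d. uniform ACGT, which keeps threshold calibration
exact), mappability artifacts, fragment-length distributions, duplicate
reads, copy-number variation, and correlated biological replicates beyond
shared truth with independent Poisson noise. Passing recovery tests
therefore demonstrates the correctness of the pipeline's logic under its
own model assumptions, not robustness to the full messiness of real
libraries.

## Numerical and design choices

- **Coordinates** are 0-based half-open everywhere internally (BED
  convention); abutting intervals do not overlap; chromosome names match by
  exact string equality.
- **Interval algebra** (overlap pairs, footprints, unions) is delegated to
  IRanges; brute-force oracles in the test suite keep that delegation
  honest.
- **Tn5 adjustment** is +4 (plus strand) / −5 (minus strand, from the read
  end); both offsets are arguments.
- **Summit ties** break leftmost, making summit extraction deterministic
  and testable against exhaustive argmax.
- **Comparative calling** adds the background's own window count to the
  expectation; solo calling must not (a window would explain itself away),
  which is why the two modes share one scanner with a flag.
- **The permutation null** shuffles direction labels over DE genes while
  keeping gene positions and gene-to-TAD memberships fixed: the occupancy
  structure (how many DE genes share a domain) is the confounder of
  interest and is preserved. Mixed TADs enter **both** footprints for the
  overlap statistic (they are the overlap) but are excluded from up/down
  strata in density and DAR-linkage analyses. A single-direction DE set
  makes the test degenerate; it returns p = 1 with `flagged = TRUE` rather
  than failing.
- **DAR recovery Jaccard** is region-level by default (≥1-bp matching):
  with windows advancing in 75-bp steps the caller cannot localise a
  300-bp region's boundaries to better than a window, so base-pair Jaccard
  conflates boundary resolution with detection; `mode = "bp"` is available.
- **PWM threshold discretisation** is 0.01 bits; the returned threshold
  sits half a step below the smallest admissible discretised score so that
  continuous-score comparison reproduces the DP's tail set.
- **k-means** rows are scaled to unit total (shape, not depth), initialised
  by a seeded farthest-point heuristic, and clusters are relabelled by
  decreasing mean raw signal, so the ordering is reproducible under a
  fixed seed; `k` defaults to 2 and binning is 50 bp over ±2 kb.
- **Multiple testing**: motif-panel p-values are BH-adjusted in the report;
  raw p-values are kept alongside.
- **Per-stage seeds** derive deterministically from the single
  configuration seed, so adding a stage never perturbs another stage's
  stream.

## Problem sizes used in the validation suite

The test suite runs the full pipeline on the default two-chromosome, 10-Mb
study conditions for the planted-recovery study (50 seeds, 1000
permutations each), the null-calibration study on 200 track-free null
datasets with 200 permutations each, and unit tests on 0.3-5-Mb single
chromosomes. These sizes keep each planted region's evidence (dozens of
reads) comparable to a real peak while the whole suite completes in
minutes.

A resolution caveat follows from these sizes. With ~55 genes and 20% DE,
only ~8-12 genes carry direction labels, concentrated in two or three
domains. The permutation null over their labels then has a *combinatorial
floor*: the smallest attainable p is the probability that a random
relabelling is fully direction-homogeneous, of order
(#homogeneous patterns) / C(m, m_up), which for 8 genes in two 4-gene
domains is 2/70 ≈ 0.03. Fully planted segregation therefore often cannot
reach p ≤ 0.01 at this scale — not a defect of the test but a property of
its resolution. For the same reason the null distribution of p at this
scale is discrete (a handful of overlap values), so only superuniformity
(type-I control) is a meaningful calibration check there; the
KS-uniformity check in the calibration study uses an 8-chromosome null
universe (~250 genes, ~50 DE), where the statistic is rich enough for a
continuous-uniformity comparison. Users analysing real data, with
thousands of DE genes, are on the right side of both caveats.

## Known limitations

- The peak caller is a deliberate simplification of fragment-model callers:
  no duplicate marking, blacklist filtering, or model-based shift
  estimation; it is not bit-compatible with MACS output.
- Differential ChIP binding is presence/absence overlap, not a count-based
  model; strongly rebalanced binding at a shared site is invisible to it.
- Known-motif enrichment only; no de novo discovery, no GC-matched
  backgrounds (the opposing DAR set *is* the background, by design).
- Gene-to-TAD assignment uses the gene body; genes spanning TAD boundaries
  get the smallest overlapping domain, which may not be the domain of
  their promoter.
- 4C profiles are reported as windowed tracks; no domain-boundary calls are
  made from them.
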
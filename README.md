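# tadlink

Linking differential chromatin accessibility to differential gene
expression through the 3D genome, for regulatory genomicists studying how
an oncogene-transformed cell state rewires its enhancer landscape.

Most accessibility changes after cell transformation happen far from
promoters, so assigning a differentially accessible region (DAR) to its
target gene by linear proximity is unreliable. `tadlink` instead uses
topologically associating domains (TADs) — largely cell-type-invariant
intervals of high internal 3D contact — as the assignment framework, and
builds the full analysis chain around that idea:

- a simplified **local-Poisson peak caller** for accessibility read tracks:
  a 150-bp window is significant when its read count *k* satisfies
  `P(Pois(λ) ≥ k) < 1e-4` with `λ = max(λ_genome, λ_25kb-local)`, and
  **comparative DAR calling** re-runs the scan with the *other* condition's
  depth-scaled rate as λ ("one sample as the background of the other"),
  classifying peaks as gained / lost / shared;
- **smallest-TAD gene assignment** over TAD sets merged from several cell
  lines, and per-TAD direction calls (up / down / mixed) from the DE genes
  inside;
- a **permutation test for domain segregation**: observed Mb overlap of the
  up-TAD and down-TAD genomic footprints versus the null of shuffled
  direction labels over the DE genes, `p = (1 + #{null ≤ obs})/(n_perm+1)`;
- **PWM motif scanning** of 150-bp peak summits with an exactly calibrated
  score threshold (dynamic programming over the discretised score
  distribution), and **swapped-background enrichment** — gained-DAR summits
  scored against lost-DAR summits and vice versa, one-sided hypergeometric;
- **ChIP peak partitioning** (shared vs condition-specific by ≥1-bp
  overlap) and DAR-ChIP overlap statistics stratified by TAD direction;
- **p53-responsiveness stratification**: down-regulated genes whose TAD
  harbors a lost DAR with a p53-motif summit, compared on post-treatment
  |log2FC| by Mann-Whitney;
- a **synthetic-data generator** that plants all of the above structure
  (DARs, TAD-wise DE segregation, motifs, ChIP co-location, response
  shifts) with machine-readable ground truth, so the whole pipeline is
  testable without any downloads.

## Worked example

Simulate the default study conditions (2 x 10 Mb genome, 150 planted DARs
per direction, direction homogeneity 0.95) and run the full pipeline:

```r
library(tadlink)
params <- sim_params(seed = 42)
report <- run_pipeline(pipeline_config(simulate = params, seed = 42, n_perm = 1000))
print(report)
#> tadlink report
#>   DE genes: 6 up, 4 down, 38 stable
#>   peaks: parental 360, transformed 361
#>   DARs: 159 gained, 158 lost, 404 shared
#>   segregation: observed 0.000 Mb, p = 0.02498
#>   motif enrichment (top):
#>     P53LIKE_synthetic in lost DARs: 38.6% vs 6.3%, p = 9.98e-13
#>   planted-DAR Jaccard: 0.940
```

Reading the output: the caller recovers the ~150+150 planted DARs (plus the
200 shared regions with a handful of noise peaks); the observed up/down
domain overlap of 0 Mb is lower than ~97.5% of permuted relabellings — the
permutation p has limited resolution here because only ten genes are
differentially expressed (see the methods vignette); the lost-direction
(p53-like) motif is present in 39% of lost-DAR summits versus 6% of gained
ones (planted: 40% vs 5%); and the region-level Jaccard against the
planted truth is 0.94.
Individual stages are ordinary functions (`call_peaks()`, `call_dars()`,
`assign_smallest_tad()`, `segregation_permutation()`, `motif_enrichment()`,
...) and a thin CLI lives at `inst/cli/tadlink`.

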
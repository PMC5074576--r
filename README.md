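# coupling3c

Pairwise analysis of meiotic non-homologous centromere coupling from
3C-qPCR data in budding yeast.

Early in meiotic prophase, before homologs pair, yeast chromosomes
associate two-by-two at their centromeres in mostly non-homologous
"couples". A chromosome-conformation-capture assay with a Taqman qPCR
readout and an EcoRI + MfeI double digestion (3C2D) can interrogate all
480 side-combinations of the 120 unique non-homologous centromere pairs
of *S. cerevisiae*. This package implements the complete analysis path
for such experiments, for geneticists and genomicists working on meiotic
chromosome organization:

- **Assay design** — in-silico single/double restriction digestion
  (GAATTC / CAATTG motif scans), CEN-fragment definition with flanking-site
  distance statistics, and rule checks for 3C primers and Taqman probes.
- **qPCR processing** — dilution adjustment of crossing points
  (`Cp - log2(dilution)`), per-side-combination averaging, normalization
  against a randomly ligated control library and a loading-control
  dilution series, giving the interaction frequency
  `IF(i,j) = 2^(Cp_control - Cp_sample) / loading`.
- **Matrix analyses** — partner and global couple ranks, binned
  size-similarity scores, difference matrices between genotypes or
  time points, ancestral (post-whole-genome-duplication) partner checks,
  k-means size groups, log2-scale heatmaps.
- **Permutation tests** — the size-preference overlap statistic
  `T = sum_i |top-k partners by IF  ∩  top-k most size-similar|`
  with a matrix-randomization null (the 120 unique values are permuted and
  mirrored; `p = #(T* >= T_obs) / iterations`), plus sensitivity, subset,
  size-dissimilarity avoidance, arm-homology, telomere-cluster and
  cross-strain top-5 overlap variants.
- **Cytology statistics** — Fisher's exact comparison of pooled
  chromosome-spread coupling counts and fold contrasts.
- **Synthetic data** — a generator that simulates coupling as weighted
  perfect matchings per cell and emits every input table the pipeline
  consumes; used throughout the test suite and for power/calibration
  studies.

## Worked example

Simulate a coupling-proficient haploid library with a planted chromosome
size preference (pairing weight `exp(-|dL|/tau)`, `tau` = 100 kb, 5000
cells, 0.3-cycle qPCR noise), process it end-to-end, and test the size
preference:

```r
library(coupling3c)
set.seed(42)
model  <- coupling_model("size_similarity", tau = 1e5)
params <- sim_params(n_cells = 5000, ploidy = "haploid")
m <- simulate_matrix(model, params)            # counts -> Cp -> normalized IF
res <- null_distribution(m, partner_preference(chrom_sizes()), seed = 1)
print(res)
#> Matrix-randomization permutation test: size_similarity
#>   k_if = 3; k_size = 3; mode = size_similarity; lowest = FALSE; method = values
#>   T = 42, null 9.58 +/- 3.07 (100000 iterations)
#>   p = 0 (conservative 9.9999e-06)
#>   seed = 1
```

Of the 48 possible row-wise overlaps between "3 strongest partners" and
"3 closest in size", 42 are realized, against a null expectation of
`16 * 9/15 = 9.6`; none of 100,000 randomized matrices reached the
observed `T`, so the plain-fraction p is 0 and the conservative
`(r+1)/(n+1)` estimate is reported alongside. The binned score shows the
same preference descriptively — couples in the most-similar bin sit well
above the library-average interaction level:

```r
binned_score(m, chrom_sizes())
#>    bin      score
#>    1-3  2.0193744
#>    4-6 -0.1059389
#>    7-9 -0.5391284
#>  10-12 -0.6177387
#>  13-15 -0.7565684

ancestral_check(m)$n_strongest_is_sister
#> 0        # ancestral sisters are never the strongest partner here

enrichment_difference(32.64, 37.21)  # raw-cycle contrast of two libraries
#> log2 enrichment 4.57, fold 23.75 (~24)
```

A shell-free pipeline run over TSV inputs (Cp records, control library,
loading series) is available through `run_pipeline()`, which writes the
matrix TSVs, heatmap, test JSONs and a manifest with input digests and
seeds; `simulate_dataset()` writes a complete synthetic fixture set in
the same dialects.

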
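---
title: "Methods: models, parameters and design choices in coupling3c"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in coupling3c}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the quantities it computes, the assumptions behind them, the tunable
parameters and their defaults, and the choices made where the design was
genuinely open.

## The measurement model

A 3C library converts spatial proximity of two restriction fragments into
the abundance of their ligation product. With a Taqman qPCR readout,
abundance is observed as a crossing point `Cp`: at perfect amplification
efficiency one cycle corresponds to a twofold abundance difference, so
`Cp` lives on a (negated) log2 scale. The package's processing chain is
built entirely on that identity:

1. **Dilution adjustment.** A reaction run on `d`-fold diluted template is
   back-corrected as `Cp - log2(d)` (`adjust_cp()`). The default assumes
   efficiency exactly 2; the language of "one cycle = ~2-fold" underlies
   the whole assay, and a fitted per-library efficiency from the loading
   control can be substituted via the `efficiency` argument when a library
   deviates.
2. **Averaging.** The four ligation geometries of a centromere pair
   (left/right fragment sides on either chromosome) are biologically
   equivalent but use different primer/probe pairs. Adjusted Cp values are
   therefore averaged per side-combination first and the four
   side-combination means are averaged with equal weight
   (`aggregate_combinations()`). Averaging on the Cp scale is a geometric
   mean of abundances, which is the right choice for a log-scale
   measurement.
3. **Normalization.** The randomly ligated, un-crosslinked control
   library contains every ligation product in near-equimolar amounts, so
   its Cp per side-combination is a direct measurement of that primer/probe
   pair's efficiency. The interaction frequency is
   `IF = 2^(Cp_control - Cp_sample) / loading`. The control subtraction is
   applied per side-combination *before* pair averaging (default), so
   systematic efficiency offsets between the four geometries cancel
   exactly; subtracting pair-level means instead is available via
   `order = "pair_mean"` since the original protocol wording does not
   disambiguate the order. The loading factor is a single per-library
   scalar (relative DNA concentration from the SYBR dilution series), not
   a per-combination quantity.
4. **Loading control.** `loading_concentration()` fits Cp against
   log2(relative dilution). At efficiency 2 the slope is -1; the fitted
   efficiency is `2^(-1/slope)`, the standard-curve formula in log2 units
   (a slope of -1.1 cycles per twofold step gives `2^(1/1.1) = 1.88`).
   Concentrations are compared between libraries as
   `2^(Cp_ref - Cp_lib)` at a fixed reference dilution (default 1/50).

**Failed reactions.** The instrument runs 55 cycles; reactions that never
cross threshold are censored, not zero. Two policies are implemented
because the original correction is not specified: `"exclude"` (default)
drops failed reactions and requires at least 2 of 4 side-combinations per
pair, which is unbiased when failures are driven by dilution; `"censor"`
imputes the 55-cycle cap as a lower abundance bound. Neither is asserted
to be the original authors' rule. Pairs below the side-combination
minimum propagate as missing matrix cells; missing cells are **never**
imputed, and every whole-matrix analysis refuses incomplete matrices with
an explicit error.

## Chromosome sizes

Two bundled size tables are provided (`chrom_sizes()`): `"assembly"`
(nominal R64 lengths, where the rDNA array collapses and chromosome 4 is
the longest) and `"physical"` (default), which adds an rDNA-array term to
chromosome 12 so that it ranks longest, as it does in vivo. The rDNA term
defaults to 1.5 Mb (~165 repeats of 9.1 kb, within the commonly cited
100–200 copy range); the exact copy number is strain- and
culture-dependent and is exposed as `rdna_bp`. Size-similarity partner
orderings use |length difference| ascending with ties broken to the
smaller chromosome index (real yeast lengths have no exact ties;
synthetic tables may). The short-arm analysis reuses the same machinery
with the `short_arm_bp` column (centromere midpoint to nearest telomere)
swapped in — no separate code path.

## The permutation tests

The statistic is `T = sum over chromosomes of |top-k_if partners by IF
intersect top-k_size preferred partners|`, with preference orderings by
size similarity, size dissimilarity, arm homology (any user-supplied
pairwise homology matrix), or telomere-cluster membership (where the
preferred set is the same-cluster partners and `k_size` is ignored; no
published formula exists for this variant, so the same overlap form is
used). The avoidance variant intersects the *bottom*-k partners with the
most dissimilar chromosomes.

The null randomizes the matrix by permuting its 120 unique off-diagonal
values uniformly and mirroring to symmetry. This preserves the value
multiset and the symmetry of the data structure and is the most literal
reading of "randomizing the matrix"; permuting chromosome labels instead
is provided as `method = "labels"` for robustness checks (it additionally
preserves row profiles). The p-value is the plain fraction of iterations
with `T* >= T_obs`, with the conservative `(r+1)/(n+1)` estimate reported
alongside so that `p = 0` never appears silently. Default 100,000
iterations; below 1,000 a resolution warning is raised.

Tie-breaks: the observed statistic breaks ties in top-k selection by
chromosome index (deterministic and logged via the result object); inside
null iterations ties are broken by the random placement of the permuted
values, which is itself random and avoids systematic bias. One RNG stream
per test invocation, seeded explicitly and recorded in the result.

Under the null, `E[T] = n_rows * k_if * k_size / (n-1)` by linearity of
expectation over hypergeometric overlaps (9.6 for the 3/3 test over 16
rows; 26.67 for 5/5), which the suite checks to within three Monte-Carlo
standard errors. For the cross-strain overlap test, the null draws
independent uniform k-subsets per chromosome and strain, a sum of
hypergeometric variables with expectation `16 * k^2 / 15` (33.3% of 80
for k = 5).

**Calibration of a discrete test.** `T` is integer-valued, so the
plain-fraction p-value is super-uniform: its distribution has atoms of
up to ~0.15 at the achievable significance levels. A literal KS test of
those p-values against the uniform sits at the rejection boundary by
construction rather than by miscalibration. Calibration is therefore
assessed (in the test suite and the acceptance script) on the randomized
p-value `(#{T* > T} + U * #{T* = T}) / n`, which is exactly uniform for a
correctly calibrated discrete test; the *reported* p-value remains the
plain fraction.

## The synthetic-data generator

The generator is first-class, tested code that defines the study
conditions for all end-to-end validation. Per cell it draws a perfect
matching of the chromosome set: a random unmatched chromosome picks a
partner among the unmatched with probability proportional to the model
weight. Haploid cells form 8 couples from 16 chromosomes; diploid cells
form 16 couples from 32 copies with homolog pairing forbidden (weight 0),
and an unordered chromosome pair is counted at most once per cell because
3C primers cannot distinguish the two copies. Dead ends (the last two
unmatched copies being homologs) restart the cell.

Weights: 1 under the null; `exp(-|dL|/tau)` for size similarity;
`exp(-max(0, |dL| - d0)/tau)` for size avoidance, with `d0` the 0.7
quantile of pairwise size gaps. The avoidance form deliberately deviates
from a naive `exp(+|dL|/tau)`: inflating dissimilar weights would make
dissimilar pairs the *top* interactors, which is the opposite of the
avoidance signature (a deficit of couples between the most dissimilar
chromosomes, with like-sized pairings otherwise unremarkable). The
soft-threshold form produces that deficit without forcing a surplus of
the most similar pairs. `tau` defaults to 100 kb, a value at which the
planted preference is strong enough that the 3/3 size test detects it in
essentially every simulated library at 5000 cells and 0.3-cycle noise —
a calibration chosen for the validation suite, not an inference about
real coupling strength, which no published number quantifies.

The sequential pairing scheme is not exactly the Gibbs distribution over
weighted perfect matchings (early picks constrain later ones); it is
accepted as a generator with this bias documented, and a Metropolis
swap-chain sampler targeting the Gibbs distribution exactly is available
(`sampler = "mcmc"`) as a slower option.

Couple counts become Cp data as `Cp = c0 - log2(count + pseudo)` plus a
per-side-combination efficiency offset `N(0, control_sd)` shared with the
control library, plus `log2(dilution)` and per-reaction noise
`N(0, sigma)`; reactions beyond the 55-cycle cap are emitted as failed.
Defaults: `c0 = 38` (placing typical Cp values in the low 30s),
`sigma = 0.3` cycles, `control_sd = 1.3` cycles (chosen so that roughly
half of control combinations fall within one cycle of the library mean,
matching the observed scatter of real control libraries),
`pseudo = 0.5`, triplicates at 2-, 4- and 8-fold dilution. With
`sigma = control_sd = 0` the full processing chain recovers interaction
frequencies exactly proportional to `count + pseudo` — the round-trip
identity the suite asserts to machine precision.

What the generator does *not* emulate: spatial/polymer structure of the
nucleus, bouquet geometry, time-resolved partner switching, cell-stage
heterogeneity within a culture, or sequence-dependent qPCR artifacts.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated generative model, not biological fidelity of
that model.

## Assay-design module

Restriction sites are motif starts (GAATTC, CAATTG) on the forward
strand — both motifs are palindromic, so one strand suffices; the <= 5 bp
offset to the actual cut position is immaterial at multi-kb distances.
Coordinates are 0-based half-open (BED convention) throughout; the CEN
midpoint is the integer floor of the interval midpoint, consistent with
distances being measured "to the center" of the CEN. N bases never match
a motif; other unexpected characters are converted to N with a warning.
The CEN fragment takes the greatest site strictly below the CEN start and
the least site at or beyond its end; a site inside the CEN interval or a
missing flank is an explicit error.

Primer/probe validation is geometric and compositional only (distance
windows, length, Tm, orientation encoded as side + strand, 5'/3'
composition rules); no secondary-structure prediction. The melting
temperature uses the unified nearest-neighbor parameter set with a
monovalent-salt entropy correction, since the original design protocol
names target Tm windows but no formula; Wallace and GC-fraction formulas
are selectable, and a pre-computed Tm column is always honored.

The flanking-distance summary (sites more than 2 kb from the CEN, out of
32) and the 2-kb fragment-size histogram reproduce the design-stage
statistics of the assay; on the reference genome their exact values are
assembly-version sensitive, so the suite validates them on planted
synthetic genomes where the truth is known by construction.

## Cytology statistics

Spread counts are summarized per strain (mean of per-replicate
percentages, range, pooled proportion) and compared by a two-tailed
Fisher's exact test on pooled counts — pooling matches the single
reported comparison; the two-tailed convention sums all tables with the
same margins whose point probability does not exceed the observed one.
Counts reconstructed from printed percentages are re-verified against
the printed value at its precision and error out on mismatch.

## Problem sizes in the validation suite

The suite runs oracle-equivalence checks on randomized 16x16 instances,
analytic null calibration at 20,000–100,000 iterations, and parameter
recovery over 100 simulated libraries per condition (5000 cells each,
5000-iteration tests), which keeps the full suite and the acceptance
script each around a minute on one CPU while leaving Monte-Carlo standard
errors far below the tested tolerances.

## Known limitations

- Interaction frequencies are relative enrichments; no absolute contact
  probabilities are estimated.
- The permutation tests are marginal per variant; no multiplicity
  correction is applied across variants (matching the original analysis
  practice).
- The sequential matching sampler's deviation from the Gibbs target is
  unquantified (the MCMC option exists for exactness at extra cost).
- Cis (intra-chromosomal) contacts, baseline calling from fluorescence
  curves, and melt-curve analysis are out of scope.
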
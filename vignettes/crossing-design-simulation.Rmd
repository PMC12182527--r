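---
title: "Simulating crossing designs for association mapping in wild relative populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating crossing designs for association mapping in wild relative populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wildmap)
```

## The question the package answers

Wild relatives of crops — here modelled on sea beet, the outcrossing wild
relative of sugar beet — carry allelic variation that elite breeding pools
have lost.  Quantitative traits such as yield cannot be phenotyped on wild
plants directly; some elite genome must first be crossed in.  Every cross,
self, backcross, or doubled-haploid (DH) step, however, risks losing the
very wild alleles one hopes to map.  The package simulates nine crossing
designs (M1–M9) that turn a wild population into a testcross mapping
population and measures, per design, the power to detect wild-origin QTL
(true positive rate, TPR) and the false detection rate (FD).

The designs form a 3 × 3 layout.  Rows: how the entry parent is derived
(directly, M1–M3 with ~50% wild genome in the testcross progeny; from a
wild × elite F1, M4–M6 with ~25%; from a backcross B1, M7–M9 with ~12.5%).
Columns: whether the final step is none, a selfing, or DH production.  Per
wild individual exactly one random offspring is carried through each
intermediate generation, and the resulting pre-testcross genotype is crossed
to a common tester to produce the entry's progeny (594 by default, i.e. six
field plots of 99 beets).

## Genetic model

Genomes are phased, biallelic, and origin-tagged: every allele copy carries
an integer tag naming the founder haplotype it descends from (wild founders
positive, elite/tester negative).  Meiosis follows the Haldane model —
per-chromosome crossover counts Poisson with mean length/100, positions
uniform, no interference, no obligate chiasma — and copies tags along with
alleles, which is how wild-genome fraction and wild-haplotype coverage are
scored exactly.  Downstream genotyping is origin-blind 0/1/2 dosage, as an
SNP array would deliver; identical-by-state alleles from wild and elite
backgrounds are deliberately confounded there, as in reality.

The trait is purely additive, built from three effect sets over the marker
panel (per allele copy, `E` = 100 arbitrary units by default):

* elite infinitesimal background: `E/M` on every elite-origin copy;
* wild QTL: `n` markers polymorphic in the selected wild subset, effects
  `e_i = emax (1/2)^(i-1)` with `emax` = 5% of `E`, attached to one
  randomly chosen wild allele per QTL (the other wild allele scores 0);
* wild genomic background: `E/2 − Σ e_i` spread equally over the non-QTL
  markers on wild-origin copies, so the haploid wild total is exactly
  `E/2` — elite material outperforms wild two to one.

Entry phenotypes are entry-mean progeny genotypic values plus one normal
deviate per entry with variance `v_e = v_g (1 − h²)/h²`, `v_g` being the
realized between-entry genetic variance of the mapping population, so the
broad-sense heritability of entry means equals the set `h²` (grid
0.5–0.9).  No dominance, no epistasis, no negative wild effects.

## The association scan

A marker-based kinship matrix (frequency-weighted allele sharing, self
kinship ≈ 0.5; an IBS variant is available) scales the polygenic covariance
`σ²_G Φ` in the mixed model `y = μ + Xβ + G + e`.  The model is fitted by
maximum likelihood via the eigendecomposition of `Φ` and a bounded 1-D
search on the heritability ratio (tolerance 1e-8, small diagonal jitter if
`Φ` is numerically non-PSD).  Each marker is then scored with the 1-df
score test

```
((g − E[g])' V⁻¹ residualY)² / ((g − E[g])' V⁻¹ (g − E[g]))
```

**A consequential implementation choice.**  Two readings of `residualY`
circulate: the covariate-adjusted phenotypes `y − Xβ̂`, and the
family-adjusted residuals `ê = y − Xβ̂ − Ĝ`.  The fit object exposes both,
but the scan uses `y − Xβ̂`: since `ê = σ²_e V⁻¹(y − Xβ̂)`, the `ê` form
scales the statistic by `σ⁴_e` and collapses to zero whenever the ML fit
pushes the heritability ratio to its upper bound — which it reliably does
when a single QTL drives the genetic variance, as in design M1.  With the
marginal form the statistic is the standard generalized-least-squares score
test and reduces, at `σ²_G = 0`, to the ordinary single-marker regression
score statistic exactly.

Markers carrying simulated QTL effects are excluded from the scan (the
causal site is assumed untyped); detection must come from linked markers.
P-values are Benjamini–Hochberg adjusted, significance requires
`−log10(p) > 3`, and significant markers are clustered into QTL regions: a
region needs at least `region_min_markers` significant markers within a
5-cM window, and clusters split at gaps of 5 cM or more.  A simulated QTL
counts as detected if a region overlaps its ±2.5-cM window; FD is the share
of regions overlapping no QTL window, set to 100% when QTL were simulated
but nothing was called.

Two conventions are exposed because they matter:

* `threshold_on`: `"p_adj"` (default) thresholds the BH-adjusted values;
  `"p"` thresholds the raw scan p-values.  Applying `−log10 > 3` *on top of*
  BH adjustment double-counts the multiplicity correction; on sparse
  desk-scale panels it leaves essentially nothing significant, so the
  desk-scale protocol below uses `"p"`.
* `region_min_markers`: the 5-markers-in-5-cM default presumes the
  study-scale density of ~26 markers/cM (~128 markers per window).  On a
  2,000-marker genome (3.2 markers/cM) the same rule is unreachable; the
  desk protocol scales it with density to 2, still requiring independent
  corroboration by a second linked marker.

## The synthetic founder generator

Real wild-population genotypes are rarely shareable, so the generator
emulates the published summary statistics of three coastal wild beet
populations: 16,076 SNPs on nine equal chromosomes totalling 625 cM (mean
adjacent spacing 0.0389 cM), per-individual heterozygosity in the low
teens, mean minor allele frequency around 10%, an elite line with ≤ 1%
heterozygous markers, and a tester built as the F1 of two elite-pool lines
diverging at 24.44% of markers.

Three design choices deserve explanation:

* **Ancestral haplotype pool.**  Founder strands are drawn from a finite
  pool (default 6 haplotypes) rather than independently per marker.  Young
  alleles in real populations exist on a limited set of ancestral
  backgrounds, which is precisely what lets a typed marker tag an untyped
  causal site.  Independent-per-marker founders (linkage equilibrium) leave
  only drift LD of order `t/2N` ≈ 0.05 after any realistic burn-in — no
  design can detect anything on such data, at any marker density.  The pool
  size is therefore an *effective local haplotype diversity* knob; 6
  reproduces the tagging effectiveness that makes association mapping in
  these populations work.
* **Burn-in.**  Twenty generations of mating recombine the pool, so LD
  decays with map distance (strong below ~1 cM, weak beyond a few cM) and
  relatives share recombination-shaped blocks — which the haploblock subset
  selection needs to be meaningful.
* **Calibration with inbreeding.**  Published heterozygosity (11–17%) is
  roughly half of the Hardy–Weinberg expectation for the published MAF
  (8–13%): the real populations show substantial homozygosity excess
  (F<sub>IS</sub> ≈ 0.3–0.5, fine-scale substructure and partial
  inbreeding).  The generator fixes the Beta L-shape (`a = 0.4`), solves
  the Beta mean so the folded Beta-binomial pool frequency matches
  `maf_mean`, and closes the heterozygosity gap with a partial-selfing
  fraction of the burn-in (`F = s/(2−s)`).  A heterozygosity target *above*
  the Hardy–Weinberg ceiling cannot be produced by a mating system and
  raises an error.

What the generator does **not** emulate: geographic substructure among
populations, ascertainment of array SNPs, genotyping/phasing error, and any
realistic site-frequency-spectrum detail beyond the one-knob Beta law.
Passing tests on synthetic data therefore demonstrate the pipeline's
statistical machinery, not the biology of any particular population.

## Diversity subset selection

From each population, N = 300 individuals (desk runs: fewer) are chosen in
two stages on 5-marker haploblocks: first the 25 individuals with the
highest rarity score (sum over both haplotypes and all blocks of
1/occurrences), then greedy addition of the individual covering the most
block haplotypes not yet represented, counting only haplotypes present at
least twice in the population (singletons are likely genotyping or phasing
artefacts).  Ties break to the lowest individual index, making the
selection deterministic.  Trailing short blocks at chromosome ends are
kept; blocks never span chromosomes.

## The experiment runner and its statistics

`run_experiment()` crosses populations × designs × heritabilities × QTL
numbers × replicates.  Within a replicate, one QTL draw is shared by all
designs, and one standard-normal noise vector is shared (rescaled) across
the h² grid: both are common-random-numbers choices that make the design
and heritability comparisons paired rather than independent, which is the
variance-optimal way to estimate orderings.  Every run derives its RNG seed
deterministically from the master seed and its coordinates, so results are
independent of execution order; failed runs (e.g. a degenerate
zero-variance mapping population) are recorded as TPR 0 / FD 100% with a
`failed` flag, never dropped.

Problem sizes: the package's own test suite and acceptance script run a
desk-scale protocol — 2,000 markers, 200 wild individuals of which 100 are
selected, 100 testcross progeny per entry, one 5% QTL, and TPR averaged
over three independent synthetic populations of 17 replicates each
(population realizations differ enough that a single draw is not
representative; the study design likewise averages over its three wild
populations).  This reproduces the qualitative design ordering (TPR
M1 > M4 > M9, monotone in h²) in a few minutes.  Study-scale runs (16,076
markers, 300 selected wilds, 594 progeny, 1,000 replicates) use the same
code paths unchanged.

## Known limitations

* Absolute TPR/FD levels at desk scale are not comparable to study-scale
  values: power depends strongly on marker density, entry count, and the
  synthetic LD structure.  Only orderings and trends are expected to
  transfer.
* The ML variance fit can sit on the boundary (ratio 0 or 1); with `Φ = I`
  the split σ²_G/σ²_e is unidentifiable and only their sum is meaningful.
* The kinship estimator's exact normalization is a documented choice
  (frequency-weighted, self ≈ 0.5), not a claim of equivalence to any
  specific historical implementation.
* Whether FD should count false *regions* (implemented) or false
  significant markers is a genuine reading ambiguity; region counting
  matches the definition "falsely detected QTL among all detected QTL".
* No sex-specific maps, crossover interference, mutation, dominance,
  epistasis, selection during burn-in, or seed-production constraints.
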
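---
title: "Methods: detecting GC-biased fixation and sweeps with bgcscan"
author: "bgcscan authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting GC-biased fixation and sweeps with bgcscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bgcscan)
```

## The model and its assumptions

Biased gene conversion (BGC) converts weak (A/T) alleles to strong (G/C)
alleles during recombination-associated repair.  At the population level it
behaves like directional selection on G/C alleles without any fitness
effect, so it leaves two complementary signatures:

* **ongoing bias** — among currently segregating sites, weak-to-strong
  (W2S) mutations drift to higher derived allele frequencies than
  strong-to-weak (S2W) mutations;
* **historical bias** — among changes that already fixed, the W2S:S2W
  ratio exceeds that of segregating sites.

`bgcscan` tests the first with a two-sided Mann–Whitney U (MWU) test on
the two per-class derived-allele-frequency samples (each site contributes
k/n), and the second with a McDonald–Kreitman-like (MK) Fisher exact test
on the 2×2 table {fixed, segregating} × {W2S, S2W}.  OTHER-class changes
(weak-to-weak, strong-to-strong) are excluded from both tests but counted
and reported.

Both tests assume sites are exchangeable within a class and independent
enough that a rank test is meaningful.  Linkage violates independence —
neighboring sites share genealogies — which is exactly why the package
carries calibration simulators (below) to verify that the tests' p-values
still behave like p-values under a neutral model with full linkage.

### The MWU offset

The effect size reported with the MWU test is the Hodges–Lehmann shift:
the median of all pairwise differences between W2S and S2W site
frequencies, multiplied by the reference sample size of 22 chromosomes.
It is computed directly from its definition rather than by inverting the
rank test, because the inversion is undefined for degenerate (fully tied)
inputs.  Positive offsets mean W2S mutations segregate at higher
frequency.

The p-value follows the behavior of `stats::wilcox.test`: the exact rank
distribution when the combined sample is below 50 and tie-free, otherwise
midranks with a continuity-corrected normal approximation.  Derived allele
frequencies are heavily tied (all sites share the denominator n), so real
data essentially always take the approximate path; the threshold and an
exact midrank-permutation enumeration (`exact = "enumerate"`) are exposed
for small-sample work and for testing.

### Site and fixed-difference filters

`filter_segregating_sites()` drops sites genotyped in fewer than 8
chromosomes (low-n sites would skew the DAF distribution upward), sites
with more than two alleles among reference/ancestral/sample alleles, and
sites without a determined ancestral allele; a lowercase (uncertain)
ancestral call is retained but flagged.  `clean_fixed_differences()` keeps
candidate human/chimp differences only at callable positions with a
determined, polarizable ancestral allele, and removes positions that
segregate in the sample or appear in an external SNP catalog (a
still-segregating "fixed difference" is a polymorphism, not a
substitution).

### Masking scans

To ask whether a regional signal is driven by a small core element,
`mask_scan()` re-runs a test after deleting all sites (and fixed
differences) under a mask.  A central mask of width w removes everything
within w/2 of the region center — defaults 500 bp to 10 kb — and a sliding
scan uses 5 kb windows centered every 2.5 kb, which yields fifteen windows
in a 40 kb region.  The "5kbHi" summary is the *largest* (least
significant) sliding-window p: the signal survives localized deletion if
even the worst mask leaves it significant.  A mask that empties a required
class propagates as a missing value, never as p = 1, and the 5kbHi maximum
is taken over non-missing windows only.

## Spectrum projection

Spectra sampled at different depths are made comparable by hypergeometric
projection: class i of an n-spectrum contributes to class j of an
m-spectrum with weight C(i,j)·C(n−i,m−j)/C(n,m), the probability that an
m-subsample contains j derived alleles.  Mass landing on the monomorphic
classes (j = 0 or m) is discarded — a site that stops segregating after
subsampling is unobservable — and the normalized projection divides by its
own total, so it sums to exactly 1.  Spectra store real-valued counts so
projected spectra are representable without rounding.

Two aggregation conventions exist and the package uses both deliberately:
`build_spectrum()` renormalizes each site's projected weights over the
segregating outcomes, so every input site contributes total mass 1 (the
natural choice when the quantity of interest is "number of sites");
`estimate_background()` projects the aggregate spectrum and normalizes
once at the end, which makes background estimation commute exactly with
projection — the property the sweep scan relies on when reducing a
background to a smaller common sample size.

## The sweep scan

`clr_scan()` implements a composite-likelihood-ratio test of a completed
hard sweep at each of a grid of positions (default 1,000, inclusive of the
region endpoints).  The sweep model is the star-genealogy approximation:
at a site at distance d from the swept position, each of the n lineages
escapes the sweep independently with probability
p_e = 1 − exp(−α·d), where the intensity α absorbs the ratio of
recombination rate to selection strength; all non-escaped lineages
coalesce through the sweep into a single ancestral lineage.  The e escaped
lineages plus that one ancestor are a hypergeometric subsample of the
background spectrum, the ancestor's allele is copied to the n − e swept
samples, and the resulting class probabilities are renormalized over the
polymorphic outcomes 1..n−1.

This factorizes usefully: the distribution of the observed derived count
given e escapees does not depend on p_e, so the package precomputes an
(n+1)×(n+1) kernel once per background and mixes it with Binomial(n, p_e)
weights per site/grid-point/α.  α is maximized on a log-spaced grid
(default 10⁻⁷–10⁻¹ per bp) refined by bounded scalar optimization; the
α → ∞ limit reproduces the background exactly, so the CLR
2(log CL_sweep − log CL_background) is floored at zero.  Argmax ties break
toward the leftmost grid point.

P-values are the fraction of neutral coalescent replicates — conditioned
on the observed number of segregating sites, the probe-coverage mask, and
the supplied recombination rate — whose maximum CLR reaches the observed
maximum.  Composite likelihood ignores linkage, so null maxima are large
on single-genealogy data; the simulation p-value is calibrated precisely
because the replicates carry the same linkage.  The calibration check in
the test suite exploits exchangeability: the tail rank of each replicate's
maximum among all replicates must be uniform, which one set of replicate
maxima verifies without nesting simulations.

## Neutral calibration machinery

`simulate_neutral_region()` draws a Kingman coalescent genealogy (times in
units of 4N generations, coalescence rate k(k−1)/2) and either places
exactly S mutations on branches with probability proportional to branch
length (fixed-S conditioning, the classic `-s` behavior) or draws a
Poisson number with mean θ·L_tree/2.  Site positions are uniform over the
covered intervals.  Recombination is approximated by independent blocks:
Poisson(ρ/2) uniformly placed breakpoints partition the region and each
block receives an independent genealogy.  This reproduces the first-order
decay of linkage with ρ but not the correlation structure of a true
ancestral recombination graph; the MWU calibration deliberately runs at
ρ = 0 (one genealogy per replicate), which is the conservative,
maximally-linked case, and the sweep-scan null also defaults to ρ = 0.

`simulate_fixed_differences()` evolves alignment columns on a three-taxon
tree (human, chimp, outgroup) under an HKY model with configurable
equilibrium GC content (default 0.41, a genome-wide average) and ts/tv
ratio κ = 2, collecting columns where human ≠ chimp and the outgroup
matches exactly one of them.  Defaults put 0.006 expected substitutions
per site on each terminal branch and 4× that on the outgroup path; all
branch lengths are configurable since none are dictated by the study
conditions.  The equilibrium-GC knob is the model's W2S/S2W asymmetry
control: at eq_gc = 0.5 the two classes are exchangeable.

`calibrate_test()` repeats the study-shaped neutral experiment (MWU: 85
sites at n = 22, Bernoulli-labeled at the study-wide W2S:S2W ratio
2057:2114; MK: 335 simulated fixed differences against 101 labeled
segregating sites whose class probabilities are the pooled
fixed-difference ratios across replicates) and reports the fraction of
p-values below each α together with the W2S-directed subset.  The test
suite checks both tests against the 99% binomial envelope of α at
α = 0.01, 0.05, 0.10 over 2,000 replicates.  Fisher's exact test is
intrinsically slightly conservative on discrete tables, so the MK
fractions tend to sit in the lower half of the envelope — a property of
the exact test, not an implementation artifact.

## The forward BGC simulator

`run_bgc_replicate()` models BGC as genic selection in a forward
Wright–Fisher population: each new mutation at a weak site (W2S) multiplies
its haplotype's fitness by 1 + |e| and each at a strong site (S2W) by
1 − |e|, with e a normal deviate scaled so the mean population-scaled
effect 4N·E|e| equals 4NB (default 1.3, the literature estimate for
humans).  Fitness composes multiplicatively across sites and the two
haplotypes of a diploid, which is genic selection, so the whole dynamics
reduce to fitness-weighted resampling of haplotype classes; with no
within-locus recombination (the model choice implied by treating BGC
through fitness rather than conversion tracts) the population is clonal
and the simulator tracks classes, not individuals — this is what makes
hundreds of replicates affordable, and the inner loop is C++.

The schedule is 40·N generations of burn-in to stationarity, an
instantaneous split (the human/chimp vicariance), and 6.5 units of 4N
generations in each descendant population, then sampling of 50 human and
1 chimp chromosomes.  Segregating sites in the human sample are polarized
by the chimp sample's allele (at a biallelic site it always matches one
human allele).  Sample-level fixed differences — human sample monomorphic
and different from the chimp allele — are polarized by the
population-majority state recorded at the split: with binary site states
the chimp allele *never* matches the human allele at a fixed difference,
so outgroup-style polarization is impossible there, and the recorded split
state is the simulator's ground truth.

**Mutation-rate sizing.**  The per-locus scaled mutation rate θ = 4Nu
defaults to 21.  This is a deliberate design choice: the downstream MWU
and MK experiments only behave like the study-scale experiments when the
sample contains on the order of a hundred segregating sites and a few
hundred fixed differences.  θ = 21 gives E[S] = θ·a₄₉ ≈ 94 segregating
sites in the 50-chromosome sample and roughly 13·θ ≈ 270 fixed differences
over the 13 units of 4N generations separating the two samples, matching
the study-scale per-region averages (about 85–101 segregating sites and
335 fixed differences).  A literal 4Nu = 1.3 (mirroring 4NB:4Nu = 1 with a
per-locus reading) would yield ~6 segregating sites, at which point the
MWU test cannot reach p ≤ 0.05 at all for typical class splits — too
discrete to reproduce either the biased-run significance rates or neutral
calibration.  The `bgc_mut_ratio` argument restores the literal
parametrization for users who want it.

Scaled-down populations (N = 500–1,000) with 4NB, θ, burn-in, and split
time held fixed in scaled units reproduce the same summaries as N = 10,000
within sampling error; the test suite checks this rescaling invariance
directly.  Single-mutant fixation probabilities from the same machinery
match the diffusion prediction (1 − e^{−2s})/(1 − e^{−4Ns}).

## The synthetic-study generator

`generate_study()` emulates the data shapes of a region-targeted
resequencing study: 49 target and 13 control regions of 40 kb, 22
chromosomes, per-region site and fixed-difference counts Poisson around
101 and 335, the segregating W2S:S2W labeling ratio 2057:2114, and
probe-coverage fractions drawn from 0.65–0.98.  Coverage masks are
alternating covered/uncovered runs with exponential lengths (mean covered
run 2 kb) tuned to the target fraction — the study conditions fix only the
fractions, not the geometry.  Optional bias injection provides positive
controls: `inject_w2s_shift()` adds a Poisson(shift·n) increment to W2S
derived counts (stochastically larger by ≈ shift in frequency), and fixed
differences can be class-reweighted by an odds multiplier.

What the generator does *not* emulate: real recombination maps and
hotspots, chromosomal placement and telomere distance, ascertainment
artifacts, sequencing error, or linkage between segregating sites and
fixed differences.  Tests passing on synthetic data therefore demonstrate
the statistical machinery — calibration, power against injected bias,
determinism — not robustness to every failure mode of real resequencing
data.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open (BED); region centers are the floor of
  the midpoint.
* Projection weights are computed with log-binomials (`lchoose`) to avoid
  overflow at large n.
* Tajima's D and Fay & Wu's H are undefined at S = 0 and reported as `NA`,
  never 0; at n = 2 they are identically 0.
* An MWU or MK test with an empty class/stratum returns an "absent" result
  (p = NA with counts), and mask scans propagate absences as missing.
* Significance defaults to p ≤ 0.05 two-sided everywhere; no
  multiple-testing correction is applied by default, with Bonferroni
  columns available in the pipeline reports.
* The forward simulator guards against configurations whose L×N product
  would exhaust memory, floors fitness multipliers at a small positive
  value, and periodically rescales fitnesses to keep them in floating
  range.
* All randomness flows through R's RNG (including the C++ code via R's
  API), so a single `set.seed()` — or the `seed` recorded in every report
  header — makes every output byte-reproducible.

## Problem sizes used by the shipped checks

The test suite runs the calibrations at 2,000 neutral replicates per test,
the forward-BGC experiment at N = 500 with 300 replicates per condition,
fixation trials at N = 100 with 20,000 trials, and the sweep-scan null
calibration at 500 replicates of 85 sites at n = 22 on a 40-point grid.
These sizes were chosen so each check's sampling error is small relative
to the effect it verifies.

## Known limitations

* The independent-blocks recombination approximation is not an ancestral
  recombination graph; quantities sensitive to fine-scale linkage decay
  with ρ should be interpreted qualitatively.
* The sweep model is the star-genealogy approximation of a completed hard
  sweep; soft or partial sweeps are outside its alternative hypothesis.
* The MK-style test inherits Fisher-exact conservatism at loose
  significance thresholds.
* A printed binomial comparison in the source study (p = 0.003 for at
  least 11/49 at rate 51/499) does not match the standard exact upper
  tail (≈0.009); the package implements the standard tail
  (`association_tests()`), and the discrepancy is documented here rather
  than reproduced.
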
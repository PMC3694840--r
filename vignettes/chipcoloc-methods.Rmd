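---
title: "Profile processing and hotspot colocalization: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile processing and hotspot colocalization: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipcoloc)
```

## The analytical problem

In budding-yeast meiosis, programmed DNA double-strand breaks (DSBs) are
catalyzed by Spo11 at hotspots, while part of the break machinery — notably
Rec114 — is anchored at chromosome axis sites that flank the hotspots.
Phospho-site mutants of Rec114 shift occupancy in opposite directions at the
two kinds of site: a non-phosphorylatable allele (here `8A`) raises hotspot
occupancy by roughly 20–30% over wild type (`WT`), a phospho-mimetic allele
(`8D`) strongly reduces it, and the ordering reverses at axis sites
(`8D > WT > 8A`).

Genome-wide evidence for such shifts comes from tiling ChIP (ChIP-chip)
profiles: a ChIP/whole-cell-extract intensity per probe position. The
analytical chain this package implements is

1. kernel-smooth each profile,
2. rescale each profile by a single *decile normalization* factor,
3. form *ratio profiles* between alleles (e.g. `8A/8D`), whose maxima mark
   positions where one allele's occupancy exceeds the other's,
4. call peaks on the ratio profile and rank them by apex height,
5. ask whether the strongest N peaks colocalize with the strongest M DSB
   hotspot blocks, against a Monte-Carlo random-placement null, with
   Fisher's exact test for the matched/unmatched proportions, and
6. classify axis sites by thresholding an `8D/8A` ratio profile.

A small protein utility ([S/T]Q motifs and SQ/TQ cluster domains, the
signature of ATM/ATR-family kinase substrates) rounds out the toolkit.

Because no public accession exists for the original arrays, the package
ships a calibrated synthetic-data generator, so the full stack runs against
data with known ground truth. The generator is first-class, tested code: its
defaults define the conditions under which every quantitative check in the
test suite is performed.

## The synthetic model

**Genome.** The `"sk1-like"` preset uses the standard 16-chromosome
budding-yeast karyotype (12,071,326 bp). A `"toy"` two-chromosome genome
(500 kb) keeps unit tests fast.

**Hotspot blocks.** DSB hotspots are emulated as 3600 disjoint blocks. Block
widths are lognormal with `meanlog = log(180)` and `sdlog = 0.82`; these two
numbers simultaneously reproduce the published summary statistics of the
block map the analysis targets (median 180 bp, mean
`180·exp(0.82²/2) ≈ 252` bp, 0.9 quantile `180·exp(1.2816·0.82) ≈ 515` bp).
Block *heats* (per-block mapped 5′-end counts) are lognormal
(`meanlog = log(50)`, `sdlog = 1.0` — a realistic right-skewed count
distribution; only relative heats matter downstream) and are coupled to
widths through a Gaussian copula with correlation 0.5, so the hottest blocks
are wider than average. Blocks are placed uniformly (chromosome weighted by
length) with rejection sampling enforcing a 500 bp minimum gap.

**Occupancy profiles.** Probes sit every 50 bp. The noise-free mean at
position $x$ is

$$\mu(x) = b + m_h \sum_j h'_j\, g(x; c_j, 400) +
           m_a \sum_k s'_k\, g(x; p_k, 600) +
           \sum_l A_l\, g(x; q_l, \sigma_l),$$

where $b = 1$ is the background, $m_h, m_a$ are the allele's hotspot and
axis multipliers (`8A`: 1.25/0.8, `WT`: 1/1, `8D`: 0.15/1.4), $h', s'$ are
heats and axis strengths divided by their means, and
$g(x; c, s) = e^{-(x-c)^2/2s^2}$ for $|x - c| \le 2.5\,s$ and exactly 0
beyond. The observed intensity is $\mu(x)\,e^{\varepsilon}$ with
$\varepsilon \sim N(0, 0.15^2)$ — multiplicative lognormal noise, because
ChIP/WCE intensities are positive ratios with right-skewed errors.

Two modelling choices deserve comment.

*Compact support.* The Gaussian bumps are truncated at ±2.5 sd. Far from any
feature the noise-free profile is then *exactly* flat, and on the default
genome more than 10% of probes are feature-free. Consequently the 0.10
quantile of a noise-free profile equals the background level in every allele,
the decile factors are exactly 1, and the three normalized profiles
superimpose exactly at shared background peaks — the property the decile
normalization is designed to exploit, here made a provable contract rather
than an approximation.

*Axis-site placement.* One axis site flanks each block, displaced from the
block center by a uniform draw in ±[2, 8] kb, with strength equal to the
block's heat (axis occupancy scales with local DSB activity). With 3600
blocks the mean center spacing (~3.4 kb) is smaller than the maximal offset,
so an unconstrained draw would regularly drop a strong axis site onto a weak
foreign hotspot center, inverting the allele ordering there. Axis attachment
sites are physically distinct loci from hotspot centers, so the generator
keeps them separated: a candidate must lie ≥2 kb from every block center;
where block density leaves no such position, a contamination budget applies
instead (summed axis-bump intensity at any center ≤ 0.5× that block's unit
heat, and summed hotspot-bump intensity at the site ≤ 0.25× the site's
strength). Combined with compact support this makes both ordering contracts
— `8A > WT > 8D` at every hotspot center and `8D > WT > 8A` at every axis
site, noise off — hold deterministically wherever a compliant position
exists. On the default genome a single site out of 3600 has no compliant
position; it is kept with a warning.

**Background peaks.** DSB-unspecific peaks, identical across alleles, are
placed near chromosome ends and in a pericentric window (taken at the
chromosome midpoint; no centromere coordinates are assumed), with a 2.5 kb
clearance from hotspot/axis features so their apexes carry no
allele-specific signal.

**What the generator does not emulate.** Probe-level array artifacts,
GC/sequence bias, replication-timing structure, chromatin-loop geometry, and
the detailed shape of real occupancy footprints (real 8D profiles can dip
below the local baseline at hotspots; the synthetic 8D hotspot bump stays
above background, which is why the inverse profile `1/8D` carries no
callable peaks on synthetic data). Passing tests therefore demonstrate that
the *analysis stack* is correct and sensitive under a controlled model — not
that any particular biological conclusion transfers to real arrays.

## Processing stack

**Smoothing.** Nadaraya–Watson regression with a Gaussian kernel, evaluated
at the probe positions, independently per chromosome. The kernel sd is
`0.25·bandwidth/qnorm(0.75) ≈ 0.3706·bandwidth` — kernel quartiles at
±bandwidth/4, the convention of `stats::ksmooth(kernel = "normal")`, so a
bandwidth of 500 bp means what it means in the classical yeast tiling
literature (working range 250–1000 bp). Weights beyond 8 kernel sds
(relative weight < 1.3×10⁻¹⁴) are dropped; a test verifies agreement with an
untruncated direct convolution at 10⁻⁹ relative and with `ksmooth` itself at
its own (coarser) truncation. Smoothing is linear, preserves constants, and
never leaves the input range.

**Decile normalization.** One factor per profile, `F = 1/q₀.₁₀`, the
reciprocal of the 0.10 quantile of all intensities genome-wide. "0.1
percentile" in the method's classical description is read as the first
decile — the 0.001 quantile of a noisy positive profile would be an unstable
extreme order statistic, and the method's own name says decile. The quantile
uses linear interpolation (`stats::quantile` type 7). The pipeline estimates
`F` on the raw probe intensities and smooths afterwards; because the
smoother is linear the processed profile differs from the
smooth-then-normalize order only through which decile defines `F`, and the
raw-probe estimate makes noise-free factors exactly 1 in every allele. The
order is configurable (`smoothing$normalize_after_smoothing`).

**Ratio and inverse profiles.** Elementwise division on identical probe
grids (no implicit resampling), with the denominator floored at 0.25 on the
normalized scale to prevent spurious ratio maxima where the denominator
approaches zero. The floor value is a guard, not a fitted parameter; the
classical description is silent on it.

**Peak calling.** The cited original peak caller is not published in detail,
so this package defines its own minimal automatic scheme and exposes every
knob: a probe is a candidate if it is the strict maximum within ±500 bp
(default: the smoothing bandwidth) and at least 1.1 on the normalized scale;
candidates closer than 1 kb merge keeping the higher apex; strength is apex
height (ratio-profile amplitudes, not widths, carry the allele signal); ties
break to the leftmost coordinate so output is deterministic. Height
filtering precedes top-N selection.

**Colocalization statistics.** The distance of a peak to a hotspot block is
the distance to the nearer block *edge* (`start` or `end − 1`), even when
the peak lies inside the block — preserved verbatim from the method this
reimplements, unusual as it is. A flag (`inside_is_zero`) switches to plain
interval distance for sensitivity analyses and for ground-truth recovery
checks, where "within 600 bp of a block" should count peaks inside the block
as recovered rather than penalize block width. The cumulative fraction of
peaks against distance is evaluated on a 0–5000 bp grid (100 bp steps). The
null model places the same number of peaks uniformly over the genome
(chromosome weighted by length), maps them identically, and repeats 100
times; pointwise 2%/98% percentiles of the null curves form the plotted
envelope. Matched/unmatched counts at 600 bp are compared against the
integer-rounded null expectation with a two-sided Fisher's exact test
(`stats::fisher.test`; an exhaustive hypergeometric enumeration oracle
verifies it over every 2×2 table with total ≤ 30 in the test suite). No
multiple-testing correction is applied — single tests per comparison, as in
the original analysis.

**Axis-domain classifier.** At each axis site, the `8D/8A` ratio value at
the nearest probe is compared with a strict threshold of 0.5: label 1 if
exceeded, else 0 (a value exactly at the threshold is 0).

## Numerical and degenerate-input conventions

Coordinates are 0-based, half-open (BED convention) in files and memory.
Empty chromosomes pass through smoothing untouched; profiles need ≥10 probes
for normalization; zero peaks are rejected by the distance/fraction
operations but tolerated by the pipeline (a comparison with no callable
peaks is recorded as empty rather than failing the run). All stochastic
operations take explicit seeds; the pipeline derives per-stage seeds from
one global seed by fixed offsets, and a (config, seed) pair reproduces every
artifact byte-identically (summaries carry no timestamps; the run log does).

## SCD scanning

An [S/T]Q motif at 0-based position *i* means residue *i* ∈ {S, T} with Q at
*i* + 1. A cluster domain requires ≥3 motifs within a tract of ≤100
residues; the tract is measured from the first motif's S/T to the last
motif's Q, inclusive — the strictest natural reading of "within a tract of
100 residues or less". Qualifying motifs are grouped by a left-to-right
greedy maximal-run decomposition: regions never overlap, each satisfies both
bounds exactly, and nested qualifying windows are reported once. (A pure
union of overlapping qualifying windows could chain into a region longer
than the tract bound, which would violate the definition it reports.)

## Problem sizes used in the checks

The test suite exercises the full default conditions where the quantitative
claims live: a 16-chromosome 12.07 Mb genome, 3600 blocks, 50 bp probes
(241,434 per profile), 100-repetition nulls. Unit tests of individual
operations use the toy genome or single-chromosome fixtures of a few
hundred probes, where brute-force oracles (direct convolution, exhaustive
pairwise distances, hypergeometric enumeration) are affordable. The
end-to-end default run — three profiles simulated, processed, four ratios,
peaks, nulls, Fisher tests — completes in well under a minute.

## Known limitations

* The heat distribution and the axis-strength/heat proportionality are
  stand-ins; the published block map reports widths, not a heat model.
* The synthetic 8D hotspot signal never dips below background, so
  inverse-profile (`1/8D`) analyses are structurally uninformative on
  synthetic data (see above).
* The peak caller is deliberately minimal; model-based or HMM segmentation
  callers are out of scope.
* Real-array percentages from the original study (e.g. 62% of the 500
  strongest ratio peaks matching the 500 strongest DSB blocks) require the
  original microarray data, which has no public accession; the package's
  recovery checks substitute ground-truth-based properties on synthetic
  data.
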
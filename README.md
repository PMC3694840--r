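# chipcoloc

Tiling ChIP (ChIP-chip) profile processing and DSB-hotspot colocalization
statistics for meiotic recombination studies — with a calibrated
synthetic-data generator so the entire analysis stack can be validated
against known ground truth.

## What problem it addresses

In yeast meiosis, Spo11 catalyzes DNA double-strand breaks (DSBs) at
hotspots, while accessory proteins such as Rec114 occupy axis sites flanking
them. Phospho-site alleles of Rec114 shift occupancy in opposite directions
at the two site classes: a non-phosphorylatable allele (`8A`) raises hotspot
occupancy, a phospho-mimetic one (`8D`) suppresses it, and the ordering
reverses at axis sites. Detecting and quantifying such shifts genome-wide
from tiling ChIP/WCE intensity profiles takes a specific statistical chain,
which this package implements end to end:

* **Smoothing** — Nadaraya–Watson regression with a Gaussian kernel of
  sd `0.25·bandwidth/qnorm(0.75)` (the `ksmooth` "normal" convention;
  bandwidths 250–1000 bp), per chromosome.
* **Decile normalization** — one factor per profile, `F = 1/q₀.₁₀` (the
  reciprocal first decile of all intensities), which superimposes parallel
  profiles at shared DSB-unspecific background peaks.
* **Ratio profiles** — elementwise allele ratios (e.g. `8A/8D`) with a
  floored denominator; their maxima mark differential-occupancy positions.
* **Peak calling** — strict local maxima above a height threshold, merged
  by a minimum-separation rule and ranked by apex height.
* **Colocalization statistics** — for the top-N peaks vs the top-M hotspot
  blocks: nearest-block-edge distances (inside a block still counts to the
  nearer edge), cumulative distance curves, the matched fraction at 600 bp,
  a 100-repetition uniform random-placement null with 2%/98% percentile
  envelopes, and a two-sided Fisher's exact test of matched/unmatched
  counts against the null expectation:

  curve(d) = #{peaks with dist ≤ d} / N,  p = Fisher(matched, unmatched;
  null-expected matched, unmatched)

* **Axis-domain classification** — binary labels at axis sites by a strict
  threshold (default 0.5) on an `8D/8A` ratio profile.
* **[S/T]Q / SCD scanning** — the ATM/ATR substrate signature: SQ/TQ
  dipeptide motifs and cluster domains (≥3 motifs within ≤100 residues).

The synthetic generator emulates a 16-chromosome 12.07 Mb genome; 3600
disjoint hotspot blocks whose lognormal widths (`meanlog log(180)`,
`sdlog 0.82`) reproduce the published block-map statistics (median 180 bp,
mean ≈252 bp, 0.9 quantile ≈507 bp); heats coupled to widths through a
Gaussian copula; axis sites flanking each block; shared background peaks;
and per-allele profiles with multiplicative lognormal noise. See the
methods vignette (`vignettes/chipcoloc-methods.Rmd`) for the model and the
design decisions.

## Worked example

```r
library(chipcoloc)

genome <- make_genome("sk1-like")
blocks <- generate_hotspots(genome, hotspot_config(seed = 1))
axis   <- generate_axis_sites(genome, blocks, seed = 2)
bg     <- generate_background_peaks(genome, n = 64, seed = 3,
                                    blocks = blocks, axis_sites = axis)

cfg <- allele_config(seed = 4)
p8A <- simulate_profile(genome, blocks, axis, bg, "8A", cfg)
p8D <- simulate_profile(genome, blocks, axis, bg, "8D", cfg)

prep  <- function(p) smooth_profile(decile_normalize(p), bandwidth = 500)
ratio <- ratio_profile(prep(p8A), prep(p8D))
peaks <- call_peaks(ratio)

result <- compare_top_n(peaks, blocks, genome,
                        n_peaks = 500, n_blocks = 500, seed = 5)
result
#> # colocalization: top 500 peaks vs top 500 blocks at 600 bp
#> #   matched: 432/500 (86.4%); null mean 6.9%; Fisher p = 6.34e-160

glance(result)
#> # A tibble: 1 × 8
#>   n_peaks n_blocks match_distance matched unmatched fraction null_fraction
#>     <dbl>    <dbl>          <dbl>   <int>     <int>    <dbl>         <dbl>
#> 1     500      500            600     432        68    0.864        0.0692
#> # ℹ 1 more variable: p_value <dbl>
```

86.4% of the 500 strongest `8A/8D` ratio peaks fall within 600 bp of the
nearest edge of one of the 500 hottest planted blocks, against a chance
level of 6.9% — the planted differential-occupancy structure is recovered
with overwhelming significance. `tidy(result)` returns the cumulative curve
with its null envelope and `autoplot(result)` plots it.

`run_pipeline(pipeline_config(seed = 1), out_dir = "run1")` executes the
whole chain (simulate → normalize → smooth → four ratio profiles → peaks →
colocalization → axis-domain labels) and writes bedGraph/BED/TSV artifacts
plus a JSON summary; re-running with the same config and seed reproduces
them byte-identically. A thin command-line wrapper lives at
`inst/scripts/chipcoloc` (`run-all` and `scd` subcommands).

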
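# replichip

Replication copy-number profiling and internal-standard ChIP-seq
normalization for stalled-fork analysis in budding yeast.

## The scientific problem

When yeast enters S phase in hydroxyurea (HU), replication forks stall a few
kilobases from the origins that fired. Two questions follow:

1. **How far did forks travel, and which origins fired?** Sequencing the
   HU-arrested sample against a G1 reference gives a per-bin copy number
   between 1N (unreplicated) and 2N (replicated in every cell). The method:
   compute the per-bin ratio *r<sub>i</sub> = S<sub>i</sub>/G<sub>i</sub>*,
   define 1N as the mean ratio over *dormant regions* (10-kb windows centred
   between adjacent late/dormant origin pairs, which no fork reaches under
   HU), rescale to the absolute 1N–2N scale, and mask artefact bins above
   2.2N.
2. **How much of a fork protein is at the stalled forks, across strains?**
   Between-strain ChIP comparisons need an anchor that survives library-size
   and IP-efficiency differences. A centromeric histone carrying the same
   epitope tag as the ChIP target is such an anchor: its centromeric signal
   is strain-invariant, so dividing each track by its mean count within
   ±500 bp of the centromere midpoints (one joint scalar across all
   centromeres) puts all strains on a common scale. A background track from
   an untagged-target strain is then divided out (or subtracted) to isolate
   the target's signal.

The package also builds origin-centred heatmaps sorted by replication timing,
average profiles, and peak-position tracking across timepoints, and ships a
synthetic-data generator with exact ground truth (Poisson read noise around
known copy-number plateaus and fork peaks) used to validate every step. See
`vignette("replichip-methods")` for the full model.

## Worked example

Simulate an HU-arrested study on a toy 2-Mb genome and recover its parameters:

```r
library(replichip)

ann     <- simulate_annotations(seed = 42)          # genome, origins, centromeres
origins <- classify_origins(ann$origins)            # early vs late/dormant (75th pct)
cfg     <- simulation_config(seed = 1)              # forks stalled 2 kb, lambda = 100
truth   <- simulate_copy_number(origins, ann$genome, cfg, ann$centromeres)
dormant <- select_dormant_regions(origins, ann$genome)

# 4-step copy-number method: ratio, 1N calibration, rescale, mask
g1 <- sample_reads(truth, cfg, "G1")
s  <- sample_reads(truth, cfg, "S")
calibrated <- calibrate_to_1n(ratio_track(s, g1), dormant)

# fork extents are walked on the pre-mask profile
fe <- estimate_fork_extent(calibrated, truth$fired_origins)
head(fe, 3)
#> # A tibble: 3 × 4
#>   chrom   pos extent low_confidence
#>   <chr> <int>  <dbl> <lgl>
#> 1 chrI  35123   2023 FALSE
#> 2 chrI  67700   2000 FALSE
#> 3 chrI  95910   2090 FALSE
mean(abs(fe$extent - cfg$fork_distance) <= 100)
#> [1] 0.9666667

glance(apply_mask(calibrated))
#> # A tibble: 1 × 6
#>   n_bins n_masked bin_width one_n_value calibrated max_n
#>    <int>    <int>     <int>       <dbl> <lgl>      <dbl>
#> 1  20000      555       100        1.00 TRUE         2.2

# centromeric internal-standard ChIP normalization
chip <- cen_scale(sample_reads(truth, cfg, "chip_tagged"), ann$centromeres)
ctrl <- cen_scale(sample_reads(truth, cfg, "chip_untagged"), ann$centromeres)
norm <- background_normalize(chip, ctrl)

# origin-centred heatmap (rows sorted by t_rep) and fork-peak tracking
hm <- build_heatmap(norm, origins)
profiles <- list(t60 = average_profile(hm))

cfg90   <- simulation_config(seed = 2, fork_distance = 3000)
truth90 <- simulate_copy_number(origins, ann$genome, cfg90, ann$centromeres)
norm90  <- background_normalize(
  cen_scale(sample_reads(truth90, cfg90, "chip_tagged"), ann$centromeres),
  cen_scale(sample_reads(truth90, cfg90, "chip_untagged"), ann$centromeres))
profiles$t90 <- average_profile(build_heatmap(norm90, origins))

track_signal_position(profiles)
#> # A tibble: 2 × 3
#>   timepoint peak_offset flat
#>   <chr>           <dbl> <lgl>
#> 1 t60              2000 FALSE
#> 2 t90              3000 FALSE
```

Every container is a tibble (or carries tibbles) with `tidy()`, `glance()`,
and `ggplot2::autoplot()` methods.

For file-based workflows, `run_simulate()` writes a complete bedGraph sample
set with ground truth and a checksum manifest, and `run_analysis()` runs the
whole pipeline from a `run_config()` (YAML-serializable), writing tracks,
figures, and a JSON report.

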
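---
title: "Methods: replication copy number and internal-standard ChIP normalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: replication copy number and internal-standard ChIP normalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replichip)
```

# Scientific setting

When budding yeast enters S phase in hydroxyurea (HU), dNTP depletion stalls
replication forks a few kilobases from the origins that fired. Two
quantitative readouts describe this state:

1. **Replication copy number.** Sequencing an HU-arrested S-phase sample
   against a G1 reference gives, per genomic bin, the fraction of cells in
   which that bin has replicated: 1N where no fork has passed, up to 2N inside
   fully replicated intervals around fired origins. The spatial extent of the
   2N plateau measures how far forks travelled before stalling.
2. **Protein occupancy at stalled forks.** ChIP-seq of a checkpoint or
   replisome protein shows paired peaks flanking each fired origin at the
   stalled-fork positions. Comparing occupancy *between strains* (e.g. a
   recruitment-defective mutant against wild type) requires a normalization
   that survives differences in library size and IP efficiency.

`replichip` implements both readouts, an internal-standard normalization for
the second, origin-centred visualisation of the results, and a synthetic-data
generator with known ground truth used to validate every step.

# The copy-number method

For S-phase track $S_i$ and G1 track $G_i$ (fragment counts in 100-bp bin
$i$), the method has four steps:

1. **Ratio**: $r_i = S_i / G_i$, undefined (masked) where $G_i$ falls below
   `min_g1_count`. The G1 sample is a constant-copy-number reference, so
   dividing by it cancels mappability and copy-number-independent coverage
   biases shared between the samples.
2. **1N calibration**: the mean of $r_i$ over *dormant regions* defines the
   1N level, and $c_i = r_i / \widehat{1N}$. Dormant regions are 10-kb
   windows centred between pairs of late/dormant origins that are adjacent in
   the full origin map with no intervening origin of any class; the ten pairs
   with the largest inter-origin gaps are used (`select_dormant_regions()`).
   Under HU arrest no fork reaches these windows, so their true copy number is
   1N by construction. Requiring adjacency in the *full* origin set matters:
   a late–late pair with an early origin between them would be replicated at
   its centre and would corrupt the calibration.
3. **Relative copy number**: $c_i$ is reported on the absolute 1N–2N scale.
4. **Masking**: bins with $c_i > 2.2$ are set to missing
   (`apply_mask(max_n = 2.2)`). With a maximum true value of 2N, values
   above 2.2N indicate repeats, collapsed duplications, or alignment
   artefacts rather than replication.

`estimate_fork_extent()` then walks outward from each fired origin along the
calibrated profile for as long as bins stay at the replicated level, giving a
per-origin fork-travel distance.

A deliberate convention: the ratio is oriented S over G1, so dormant (1N)
regions sit at 1 and replicated regions approach 2 *before* calibration.
`check_profile_orientation()` warns when a profile looks inverted (most bins
below `floor_n = 0.7`), which catches accidentally swapped inputs.

# Internal-standard ChIP normalization

Comparing ChIP signal across strains needs an invariant anchor. The package
uses a centromeric internal standard: a centromeric histone carrying the same
epitope tag as the ChIP target produces a strong, strain-invariant signal at
every centromere in every IP. `cen_scale()` divides each track by the mean
raw count over bins whose midpoints lie within ±500 bp of a centromere
midpoint, computed **jointly across all centromeres as one scalar** (not per
centromere, which would let noisy individual windows distort the genome-wide
scale). After scaling, the centromeric-window mean is exactly 1, and any
global multiplicative factor — sequencing depth, IP efficiency — cancels.

`background_normalize()` then compares the scaled signal track to a scaled
control (e.g. an untagged-target strain that still carries the tagged
standard): `ratio` mode computes $s_i / (b_i + \epsilon)$ with
$\epsilon$ defaulting to half the genome-wide median of the background, which
stabilises empty bins without distorting occupied ones; `subtract` mode
computes the plain difference $s_i - b_i$. Negative values are **kept** in
subtract mode: truncating at zero would add a positive bias of order the
per-bin noise wherever true signal is low, which measurably distorts
low-occupancy comparisons such as attenuated mutants. Centromeric windows are
masked in the output, since there the internal standard itself dominates both
tracks. `locus_normalize()` offers the classical alternative — scaling by the
mean over one fixed (typically unreplicated) locus — and agrees with
`cen_scale()` up to a single global constant on any given track.

# Origin-centred metaprofiles

`build_heatmap()` extracts a ±5-kb window (101 columns at 100-bp bins)
around every origin and sorts rows by ascending replication timing
(`t_rep`), so early-firing origins appear at the top; windows running off a
chromosome end are masked, not zero-filled. `average_profile()` takes
missing-value-aware column means and records how many origins contribute to
each offset. `track_signal_position()` locates the peak signal offset in a
series of average profiles (symmetrising left/right arms first, since fork
structure is mirror-symmetric about the origin) and flags flat profiles; on a
timecourse this tracks fork movement away from origins.

# The synthetic-data generator

`simulate_annotations()` builds a toy two-chromosome genome (1.2 Mb + 0.8 Mb,
60 origins, one point centromere per chromosome). Replication times span
15–45 min and are *spatially autocorrelated*: each chromosome carries a
smooth late-replicating Gaussian domain over an early baseline plus small
jitter. This mirrors real timing profiles and is load-bearing — with
independent random timings, late origins rarely form adjacent pairs and
dormant-region selection has no valid raw material.

`simulate_copy_number()` turns classified origins into ground truth. Under
the default `sld3A_dbf4A` regime every origin fires (emulating the
checkpoint-blind background used to equalise fork positions across strains);
under `wildtype`, only origins with `t_rep <= firing_cutoff`. Each fired
origin replicates `[pos − d, pos + d)` with stall distance `d = 2000` bp;
overlapping intervals merge so copy number saturates at 2.

`sample_reads()` draws per-bin Poisson counts around `expected_rate()`:

| Sample | Expected rate per bin |
|---|---|
| G1 | `depth_lambda` (default 100) |
| S | `depth_lambda ×` true copy number |
| tagged ChIP | `chip_background` (5) + Gaussian fork peaks + centromeric term |
| untagged ChIP | `chip_background` + centromeric term |

Fork peaks are unit-height Gaussians of width `peak_sigma = 200` bp at each
stalled-fork position, scaled by `fork_enrichment = 30` and by
`enrichment_attenuation` ∈ [0, 1] (0.1 emulates a recruitment-defective
mutant). The centromeric term adds `cen_amplitude = 50` within ±500 bp of
each centromere midpoint, using the same window definition as `cen_scale()`.
Each sample kind draws from an independent RNG stream derived from
`(seed, kind)`, so samples are mutually independent and reproducible
regardless of draw order.

Known limits: Poisson noise only (no overdispersion, GC bias, or mappability
structure); rectangular replication plateaus rather than sigmoid fork-density
edges; fixed stall distance for all origins; point centromeres. These keep
ground truth exact so recovery tolerances are attributable to the method, not
the generator.

# Numerical and design choices

- **Coordinates** are 0-based half-open throughout; conversion to the 1-based
  closed convention happens only at the `rtracklayer` I/O boundary.
- **Binning** assigns each fragment to the bin containing its midpoint —
  unambiguous for fragments spanning bin edges and exactly invertible for
  synthetic data.
- **bedGraph reading** re-bins arbitrary intervals by length-weighted overlap
  and rejects overlapping input intervals, which are ill-defined on a
  coverage track.
- The toy problem size (2 Mb, 20,000 bins, 60 origins, λ = 100) is the
  package's own default: large enough that Poisson averaging meets the
  documented tolerances, small enough that the full test suite runs in
  about a minute.

# Validation

`tests/testthat/test-acceptance.R` checks end-to-end parameter recovery on
the generator: exact 1N calibration on dormant bins; 2N/1N levels recovered
within ±0.1/±0.05; fork extents within ±100 bp of the simulated stall
distance for ≥90% of origins; exact invariance of normalized tracks to
global count scaling; recovery of a 10× fork-signal attenuation within
±0.05; agreement of binning and dormant-pair selection with brute-force
oracles; and heatmap peak positions at the fork offsets. The script
`scripts/acceptance.R` recomputes the headline quantities against the
installed package for any seed.
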
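# Replication copy-number profiling. Four steps: (1) per-bin S/G1 ratio,
# (2) take the mean ratio over the dormant-region set as 1N, (3) express
# every bin relative to 1N, (4) mask bins above a 2.2N ceiling. Dormant
# regions between distant late origins are assumed unreplicated after 1 h
# of fork stalling, which is what makes them a valid 1N anchor.

new_cn_profile <- function(bins, genome, bin_width, one_n_value = NA_real_,
                           calibrated = FALSE, max_n = NA_real_) {
  structure(
    bins,
    genome = as_tibble(genome[c("chrom", "length")]),
    bin_width = bin_width,
    one_n_value = one_n_value,
    calibrated = calibrated,
    max_n = max_n,
    class = c("copy_number_profile", class(tibble())))
}

#' @export
print.copy_number_profile <- function(x, ...) {
  cat(sprintf(
    "# A copy-number profile: %d bins (%d masked)%s\n",
    nrow(x), sum(is.na(x$value)),
    if (attr(x, "calibrated"))
      sprintf(", 1N = %.6g raw ratio", attr(x, "one_n_value")) else " [uncalibrated]"
  ))
  NextMethod()
}

#' Per-bin S/G1 ratio track
#'
#' Divides S-phase by G1 counts per bin. Bins whose G1 count is below
#' `min_g1_count` are masked (`NA`): with no pseudocount, unmappable or
#' empty G1 bins cannot fabricate signal. The copy-number calibration that
#' follows is only coherent for a quantity that increases with replication,
#' so the ratio is S over G1; the inverse orientation is available for
#' auditing via `orientation = "g1_over_s"`.
#'
#' @param s_track,g1_track Binned tracks on the same grid.
#' @param min_g1_count Minimum denominator count for a bin to be kept.
#' @param orientation `"s_over_g1"` (default) or `"g1_over_s"`.
#' @return An uncalibrated copy-number profile with a `value` column
#'   (`NA` = masked).
#' @export
ratio_track <- function(s_track, g1_track, min_g1_count = 1,
                        orientation = c("s_over_g1", "g1_over_s")) {
  orientation <- match.arg(orientation)
  check_same_grid(s_track, g1_track)
  num <- if (orientation == "s_over_g1") s_track$count else g1_track$count
  den <- if (orientation == "s_over_g1") g1_track$count else s_track$count
  low <- g1_track$count < min_g1_count | den == 0
  value <- ifelse(low, NA_real_, num / den)
  bins <- tibble(chrom = s_track$chrom, start = s_track$start,
                 end = s_track$end, value = value)
  new_cn_profile(bins, track_genome(s_track), track_bin_width(s_track))
}

#' Calibrate a ratio track to 1N using the dormant-region set
#'
#' The mean of the unmasked raw ratios over all dormant-region bins is
#' taken as 1N, and the whole profile is expressed as a multiple of it.
#' After calibration the mean over unmasked dormant bins is exactly 1 and
#' any global rescaling of either library cancels. Bins are counted as
#' dormant when fully contained in a dormant region.
#'
#' @param raw An (uncalibrated or calibrated) copy-number profile.
#' @param dormant Dormant-region tibble from [select_dormant_regions()].
#' @param min_bins Minimum unmasked dormant bins required (default 10).
#' @return A calibrated profile; `glance()` reports `one_n_value`.
#' @export
calibrate_to_1n <- function(raw, dormant, min_bins = 10) {
  in_dormant <- bins_within_regions(raw, dormant)
  vals <- raw$value[in_dormant & !is.na(raw$value)]
  if (length(vals) == 0) abort("no unmasked bins in the dormant-region set")
  if (length(vals) < min_bins) {
    abort(sprintf("only %d unmasked dormant bins (need >= %d)",
                  length(vals), min_bins))
  }
  one_n <- mean(vals)
  bins <- tibble(chrom = raw$chrom, start = raw$start, end = raw$end,
                 value = raw$value / one_n)
  prior <- attr(raw, "one_n_value")
  new_cn_profile(bins, track_genome(raw), track_bin_width(raw),
                 one_n_value = if (is.na(prior)) one_n else prior * one_n,
                 calibrated = TRUE)
}

#' Mask bins above a copy-number ceiling
#'
#' Bins strictly greater than `max_n` (default 2.2N) are masked; already
#' masked bins stay masked. Values equal to the ceiling are retained.
#'
#' @param profile A calibrated copy-number profile.
#' @param max_n Ceiling in N units.
#' @return The profile with the ceiling applied.
#' @export
apply_mask <- function(profile, max_n = 2.2) {
  if (!isTRUE(attr(profile, "calibrated"))) {
    abort("apply_mask() expects a calibrated profile")
  }
  bins <- tibble(chrom = profile$chrom, start = profile$start,
                 end = profile$end,
                 value = ifelse(!is.na(profile$value) & profile$value > max_n,
                                NA_real_, profile$value))
  new_cn_profile(bins, track_genome(profile), track_bin_width(profile),
                 one_n_value = attr(profile, "one_n_value"),
                 calibrated = TRUE, max_n = max_n)
}

#' Estimate how far forks have travelled from an origin
#'
#' Walks outward from the origin's bin on each side while contiguous bins
#' stay at or above `threshold_n`, and reports the larger of the two
#' distances from the origin position to the far edge of the last
#' qualifying bin. A profile flat at 1N returns 0. If the origin's own bin
#' is masked the result is flagged low-confidence.
#'
#' @param profile A calibrated copy-number profile.
#' @param origins Origin tibble (one or more rows).
#' @param threshold_n Copy-number threshold separating replicated from
#'   unreplicated bins (default 1.5).
#' @return A tibble with one row per origin: `chrom`, `pos`, `extent`
#'   (bp), and `low_confidence`.
#' @export
estimate_fork_extent <- function(profile, origins, threshold_n = 1.5) {
  if (!isTRUE(attr(profile, "calibrated"))) {
    abort("estimate_fork_extent() expects a calibrated profile")
  }
  bw <- track_bin_width(profile)
  purrr::map_dfr(seq_len(nrow(origins)), function(i) {
    chr <- as.character(origins$chrom[i])
    pos <- origins$pos[i]
    bi <- which(as.character(profile$chrom) == chr)
    if (length(bi) == 0) abort(paste0("origin chromosome missing from profile: ", chr))
    vals <- profile$value[bi]
    center <- pos %/% bw + 1L
    ok <- !is.na(vals) & vals >= threshold_n
    low_conf <- is.na(vals[center])
    extent <- 0
    if (isTRUE(ok[center])) {
      right <- center
      while (right < length(ok) && ok[right + 1L]) right <- right + 1L
      left <- center
      while (left > 1L && ok[left - 1L]) left <- left - 1L
      extent <- max(profile$end[bi[right]] - pos, pos - profile$start[bi[left]])
    }
    tibble(chrom = chr, pos = pos, extent = as.numeric(extent),
           low_confidence = low_conf)
  })
}

#' Sanity-check the orientation of a calibrated profile
#'
#' Copy number cannot fall below 1N except by noise, so a substantial
#' fraction of bins far below 1 indicates the S and G1 samples were swapped
#' (or the audit `g1_over_s` orientation was used on real data): the
#' dormant regions then sit at the top of the ratio distribution instead of
#' its floor. Warns, and returns the offending fraction invisibly.
#'
#' @param profile A calibrated copy-number profile.
#' @param floor_n Values below this count as sub-1N (default 0.7).
#' @param max_fraction Warning threshold on the sub-1N fraction (default 0.05).
#' @return The sub-1N fraction, invisibly.
#' @export
check_profile_orientation <- function(profile, floor_n = 0.7,
                                      max_fraction = 0.05) {
  vals <- profile$value[!is.na(profile$value)]
  frac <- mean(vals < floor_n)
  if (frac > max_fraction) {
    warn(sprintf(
      paste0("%.1f%% of unmasked bins are below %.2gN: the dormant-region ",
             "mean exceeds much of the genome, suggesting the S and G1 ",
             "samples are swapped or the ratio orientation is inverted"),
      100 * frac, floor_n))
  }
  invisible(frac)
}

#' @export
glance.copy_number_profile <- function(x, ...) {
  tibble(
    n_bins = nrow(x),
    n_masked = sum(is.na(x$value)),
    bin_width = attr(x, "bin_width"),
    one_n_value = attr(x, "one_n_value"),
    calibrated = attr(x, "calibrated"),
    max_n = attr(x, "max_n")
  )
}

#' @export
tidy.copy_number_profile <- function(x, ...) {
  as_tibble(x) %>% mutate(masked = is.na(.data$value))
}

#' Write a calibrated profile as bedGraph plus a mask BED
#'
#' Masked bins are omitted from the bedGraph and written to a companion
#' BED3 file instead.
#'
#' @param profile A copy-number profile.
#' @param path Output bedGraph path.
#' @param mask_path Output BED path for masked bins (default: `path` with a
#'   `.mask.bed` suffix).
#' @return The bedGraph path, invisibly.
#' @export
write_profile <- function(profile, path, mask_path = paste0(path, ".mask.bed")) {
  write_bedgraph(profile, path, value_col = "value")
  masked <- profile[is.na(profile$value), c("chrom", "start", "end")]
  masked$chrom <- as.character(masked$chrom)
  readr::write_tsv(masked, mask_path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
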
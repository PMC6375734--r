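# ChIP-seq normalization with a centromeric internal standard. A
# centromeric histone carrying the same epitope tag as the ChIP target
# produces an invariant centromeric signal in every IP, so scaling each
# sample by its mean count within +/-halfwidth of the centromere midpoints
# removes library-size and IP-efficiency differences (a spike-in analogue).
# Cross-strain comparison then divides (or subtracts) a tagged-standard-only
# background track, with centromeric windows masked in the result.

new_chip_track <- function(bins, genome, bin_width, cen_scale_factor,
                           background_mode = "none", epsilon = NA_real_,
                           cen_masked = FALSE) {
  structure(
    bins,
    genome = as_tibble(genome[c("chrom", "length")]),
    bin_width = bin_width,
    cen_scale_factor = cen_scale_factor,
    background_mode = background_mode,
    epsilon = epsilon,
    cen_masked = cen_masked,
    class = c("normalized_chip_track", class(tibble())))
}

#' @export
print.normalized_chip_track <- function(x, ...) {
  cat(sprintf(
    "# A normalized ChIP track: %d bins, cen scale factor %.6g, background '%s'\n",
    nrow(x), attr(x, "cen_scale_factor"), attr(x, "background_mode")))
  NextMethod()
}

#' Scale a ChIP track by its centromeric internal standard
#'
#' Divides every bin by the mean raw count over the centromeric windows
#' (bins whose midpoint lies within `halfwidth` of a centromere midpoint),
#' computed jointly across all centromeres as a single scalar. After
#' scaling, the mean over centromeric windows is exactly 1.
#'
#' @param track A binned ChIP track.
#' @param centromeres Centromere tibble (one per chromosome).
#' @param halfwidth Window half-width in bp (default 500).
#' @return A normalized ChIP track; `glance()` reports `cen_scale_factor`.
#' @export
cen_scale <- function(track, centromeres, halfwidth = 500) {
  genome <- track_genome(track)
  validate_centromeres(centromeres, genome)
  in_cen <- cen_window_flags(track, centromeres, halfwidth)
  total <- sum(track$count[in_cen])
  if (!any(in_cen) || total <= 0) {
    abort("no centromeric reads: internal standard absent")
  }
  factor <- mean(track$count[in_cen])
  bins <- tibble(chrom = track$chrom, start = track$start, end = track$end,
                 value = track$count / factor)
  out <- new_chip_track(bins, genome, track_bin_width(track), factor)
  attr(out, "centromeres") <- centromeres
  attr(out, "cen_halfwidth") <- halfwidth
  out
}

#' Normalize a cen-scaled ChIP track against a background track
#'
#' Cross-strain comparison against the internal-standard-only strain (or
#' any control IP): `ratio` mode divides by `background + epsilon`;
#' `subtract` mode takes the plain difference (negative values are kept:
#' truncating them at zero would bias low-signal regions upward).
#' Centromeric windows are masked in the output, since there the internal
#' standard itself dominates both tracks.
#'
#' @param signal,background Cen-scaled tracks on the same grid.
#' @param mode `"ratio"` (default) or `"subtract"`.
#' @param epsilon Stabilizer for ratio mode; defaults to half the
#'   genome-wide median of the background track, preventing blow-ups in
#'   empty bins.
#' @return A normalized ChIP track with centromeric windows masked.
#' @export
background_normalize <- function(signal, background,
                                 mode = c("ratio", "subtract"),
                                 epsilon = NULL) {
  mode <- match.arg(mode)
  check_same_grid(signal, background)
  if (is.null(epsilon)) {
    epsilon <- 0.5 * median(background$value, na.rm = TRUE)
  }
  value <- switch(mode,
    ratio = signal$value / (background$value + epsilon),
    subtract = signal$value - background$value
  )
  cens <- attr(signal, "centromeres")
  halfwidth <- attr(signal, "cen_halfwidth")
  if (!is.null(cens)) {
    value[cen_window_flags(signal, cens, halfwidth)] <- NA_real_
  }
  bins <- tibble(chrom = signal$chrom, start = signal$start,
                 end = signal$end, value = value)
  out <- new_chip_track(bins, track_genome(signal), track_bin_width(signal),
                        attr(signal, "cen_scale_factor"),
                        background_mode = mode, epsilon = epsilon,
                        cen_masked = TRUE)
  attr(out, "centromeres") <- cens
  attr(out, "cen_halfwidth") <- halfwidth
  out
}

#' Normalize a ChIP track to the mean count over a fixed locus
#'
#' Alternative to the centromeric standard: scales every bin by the mean
#' raw count over a single (typically unreplicated) locus. Agrees with
#' [cen_scale()] up to one global constant on any fixed track.
#'
#' @param track A binned ChIP track.
#' @param chrom,start,end The locus (0-based half-open).
#' @return A normalized ChIP track.
#' @export
locus_normalize <- function(track, chrom, start, end) {
  sel <- as.character(track$chrom) == chrom &
    track$start >= start & track$end <= end
  if (!any(sel)) abort("locus covers no bins")
  m <- mean(track$count[sel])
  if (m <= 0) abort("no reads at the normalization locus")
  bins <- tibble(chrom = track$chrom, start = track$start, end = track$end,
                 value = track$count / m)
  new_chip_track(bins, track_genome(track), track_bin_width(track), m,
                 background_mode = "unreplicated_locus")
}

#' @export
glance.normalized_chip_track <- function(x, ...) {
  tibble(
    n_bins = nrow(x),
    n_masked = sum(is.na(x$value)),
    bin_width = attr(x, "bin_width"),
    cen_scale_factor = attr(x, "cen_scale_factor"),
    background_mode = attr(x, "background_mode"),
    epsilon = attr(x, "epsilon")
  )
}

#' @export
tidy.normalized_chip_track <- function(x, ...) {
  as_tibble(x) %>% mutate(masked = is.na(.data$value))
}

#' Write a normalized ChIP track with a provenance sidecar
#'
#' Writes the track as bedGraph (masked bins omitted) plus a JSON sidecar
#' recording the scale factor, background mode, and epsilon.
#'
#' @param track A normalized ChIP track.
#' @param path Output bedGraph path.
#' @return The path, invisibly.
#' @export
write_chip_track <- function(track, path) {
  write_bedgraph(track, path, value_col = "value")
  side <- list(
    cen_scale_factor = attr(track, "cen_scale_factor"),
    background_mode = attr(track, "background_mode"),
    epsilon = attr(track, "epsilon")
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
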
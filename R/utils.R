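# Shared helpers: genome-wide bin grids, coordinate checks, track attribute
# plumbing. All coordinates package-wide are 0-based, half-open (BED).

#' Fixed-width bin grid for a genome
#'
#' Expands a genome index into the per-chromosome grid of fixed-width bins
#' used by every track in the package. The trailing partial bin at each
#' chromosome end is retained (its `end` is clipped to the chromosome length).
#'
#' @param genome A genome index tibble (see [read_chrom_sizes()]).
#' @param bin_width Bin width in base pairs.
#' @return A tibble with columns `chrom`, `start`, `end`, one row per bin,
#'   ordered by genome chromosome order then position.
#' @export
genome_bins <- function(genome, bin_width) {
  stopifnot(bin_width > 0)
  genome <- validate_genome(genome)
  purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    starts <- seq.int(0L, len - 1L, by = bin_width)
    tibble(
      chrom = genome$chrom[i],
      start = as.integer(starts),
      end = as.integer(pmin(starts + bin_width, len))
    )
  }) %>%
    mutate(chrom = factor(.data$chrom, levels = genome$chrom))
}

validate_genome <- function(genome) {
  if (!all(c("chrom", "length") %in% names(genome))) {
    abort("genome index must have columns 'chrom' and 'length'")
  }
  if (anyDuplicated(genome$chrom)) {
    abort("duplicate chromosome names in genome index")
  }
  if (any(genome$length <= 0)) {
    abort("chromosome lengths must be positive")
  }
  as_tibble(genome)
}

chrom_length <- function(genome, chrom) {
  len <- genome$length[match(as.character(chrom), genome$chrom)]
  if (anyNA(len)) {
    missing <- unique(as.character(chrom)[is.na(len)])
    abort(paste0("chromosome not in genome index: ", paste(missing, collapse = ", ")))
  }
  len
}

# Constructor for the per-bin count track ("BinnedTrack").
new_binned_track <- function(bins, genome, bin_width, sample_id = NA_character_) {
  structure(
    bins,
    genome = as_tibble(genome[c("chrom", "length")]),
    bin_width = bin_width,
    sample_id = sample_id,
    class = c("binned_track", class(tibble())))
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf(
    "# A binned track: %d bins of %d bp across %d chromosome(s)%s\n",
    nrow(x), attr(x, "bin_width"), nrow(attr(x, "genome")),
    if (!is.na(attr(x, "sample_id"))) paste0(" [", attr(x, "sample_id"), "]") else ""
  ))
  NextMethod()
}

track_genome <- function(track) attr(track, "genome")
track_bin_width <- function(track) attr(track, "bin_width")

# Two tracks live on the same grid iff genome + bin width + bin table agree.
check_same_grid <- function(a, b) {
  if (!identical(track_bin_width(a), track_bin_width(b)) ||
      !identical(as.character(a$chrom), as.character(b$chrom)) ||
      !identical(a$start, b$start)) {
    abort("tracks are on mismatched bin grids (genome or bin width differ)")
  }
  invisible(TRUE)
}

# Bins whose midpoint lies within `halfwidth` bp of a centromere midpoint.
# Shared by the simulator's centromeric rate term and the ChIP internal
# standard so that the two agree exactly on window membership.
cen_window_flags <- function(bins, centromeres, halfwidth) {
  mid <- (bins$start + bins$end) / 2
  flags <- rep(FALSE, nrow(bins))
  for (i in seq_len(nrow(centromeres))) {
    cen_mid <- (centromeres$start[i] + centromeres$end[i]) / 2
    on_chrom <- as.character(bins$chrom) == as.character(centromeres$chrom[i])
    flags <- flags | (on_chrom & abs(mid - cen_mid) <= halfwidth)
  }
  flags
}

# Flags for bins fully contained in any of a set of half-open intervals
# (same chromosome). Used for dormant-region bin membership.
bins_within_regions <- function(bins, regions) {
  flags <- rep(FALSE, nrow(bins))
  for (i in seq_len(nrow(regions))) {
    on_chrom <- as.character(bins$chrom) == as.character(regions$chrom[i])
    flags <- flags |
      (on_chrom & bins$start >= regions$start[i] & bins$end <= regions$end[i])
  }
  flags
}
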
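# Fragment binning: aligned fragments -> fixed-width per-bin counts.

#' Bin aligned fragments into fixed-width windows
#'
#' Each fragment is assigned to exactly one bin by its midpoint,
#' `floor((start + end) / 2)`, so total counts are conserved. The trailing
#' partial bin at each chromosome end is retained.
#'
#' @param fragments Tibble of 0-based half-open intervals
#'   (`chrom`, `start`, `end`).
#' @param genome Genome index tibble.
#' @param bin_width Bin width in bp (default 100).
#' @param sample_id Optional label stored on the track.
#' @return A binned track with integer `count` per bin.
#' @export
bin_fragments <- function(fragments, genome, bin_width = 100L,
                          sample_id = NA_character_) {
  genome <- validate_genome(genome)
  if (bin_width <= 0) abort("bin_width must be positive")
  bins <- genome_bins(genome, bin_width)
  bins$count <- 0
  if (nrow(fragments) > 0) {
    unknown <- setdiff(unique(fragments$chrom), genome$chrom)
    if (length(unknown) > 0) {
      abort(paste0("fragment chromosome not in genome index: ",
                   paste(unknown, collapse = ", ")))
    }
    if (any(fragments$start >= fragments$end)) {
      bad <- which(fragments$start >= fragments$end)[1]
      abort(sprintf("fragment with start >= end at row %d (%s:%d-%d)", bad,
                    fragments$chrom[bad], fragments$start[bad], fragments$end[bad]))
    }
    len <- chrom_length(genome, fragments$chrom)
    if (any(fragments$start < 0) || any(fragments$end > len)) {
      abort("fragment outside chromosome bounds")
    }
    mid <- floor((fragments$start + fragments$end) / 2)
    bin_idx <- mid %/% bin_width
    # per-chromosome offset into the genome-wide bin table
    n_bins <- ceiling(genome$length / bin_width)
    offset <- cumsum(c(0, n_bins[-length(n_bins)]))
    names(offset) <- genome$chrom
    flat <- offset[as.character(fragments$chrom)] + bin_idx + 1
    tab <- tabulate(flat, nbins = nrow(bins))
    bins$count <- as.numeric(tab)
  }
  new_binned_track(bins, genome, as.integer(bin_width), sample_id)
}
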
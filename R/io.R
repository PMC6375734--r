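# File input/output. BED and bedGraph go through rtracklayer; the 1-based
# closed GRanges coordinates are converted to the package's 0-based half-open
# convention at this boundary and nowhere else.

gr_to_tibble <- function(gr, value_col = NULL) {
  out <- tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  if (!is.null(value_col)) out[[value_col]] <- GenomicRanges::mcols(gr)$score
  out
}

tibble_to_gr <- function(tbl, value_col = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(tbl$chrom),
    ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end)
  )
  if (!is.null(value_col)) GenomicRanges::mcols(gr)$score <- tbl[[value_col]]
  gr
}

#' Read a chromosome-sizes table
#'
#' @param path Two-column TSV (chromosome name, length in bp), no header.
#' @return A genome index tibble with columns `chrom` and `length`; the row
#'   order defines the chromosome order used by all downstream tracks.
#' @export
read_chrom_sizes <- function(path) {
  tbl <- readr::read_tsv(path, col_names = c("chrom", "length"),
                         col_types = "ci", progress = FALSE)
  validate_genome(tbl)
}

#' Read an origin annotation (BED3 + t_rep, optional class column)
#'
#' Columns: chrom, start, end (0-based half-open), t_rep in minutes, and an
#' optional fifth column with an explicit "early"/"late" class label.
#'
#' @param path Path to the origins file.
#' @return A tibble with columns `chrom`, `start`, `end`, `pos` (interval
#'   midpoint), `t_rep`, and `fire_class` (`NA` unless an explicit class
#'   column was present).
#' @export
read_origins_bed <- function(path) {
  lines <- readr::read_tsv(path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                           comment = "#", progress = FALSE)
  if (ncol(lines) < 4) abort("origins file needs at least 4 columns (BED3 + t_rep)")
  t_rep <- suppressWarnings(as.numeric(lines[[4]]))
  if (anyNA(t_rep)) {
    bad <- which(is.na(t_rep))[1]
    abort(sprintf("non-numeric t_rep '%s' at origins row %d", lines[[4]][bad], bad))
  }
  out <- tibble(
    chrom = lines[[1]],
    start = as.integer(lines[[2]]),
    end = as.integer(lines[[3]]),
    t_rep = t_rep
  ) %>%
    mutate(pos = as.integer(floor((.data$start + .data$end) / 2)))
  out$fire_class <- if (ncol(lines) >= 5) {
    cls <- lines[[5]]
    ifelse(grepl("^late", cls, ignore.case = TRUE), "late_dormant", "early")
  } else {
    NA_character_
  }
  out[c("chrom", "start", "end", "pos", "t_rep", "fire_class")]
}

#' Read a BED3 file
#'
#' @param path Path to a BED file.
#' @return A tibble with `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed3 <- function(path) {
  gr_to_tibble(rtracklayer::import(path, format = "BED"))
}

#' Read a bedGraph file onto a fixed-width bin grid
#'
#' Intervals that tile the grid exactly are read back bit-exactly; other
#' intervals are re-binned by length-weighted averaging (each bin receives
#' `sum(value * overlap) / bin_length`).
#'
#' @param path Path to a bedGraph file.
#' @param genome Genome index tibble.
#' @param bin_width Bin width in bp.
#' @param sample_id Optional sample label stored on the track.
#' @return A [binned track][bin_fragments] with a `count` column.
#' @export
read_bedgraph <- function(path, genome, bin_width, sample_id = NA_character_) {
  if (!file.exists(path)) abort(paste0("bedGraph file not found: ", path))
  genome <- validate_genome(genome)
  ivs <- gr_to_tibble(rtracklayer::import(path, format = "bedGraph"), "value")
  unknown <- setdiff(unique(ivs$chrom), genome$chrom)
  if (length(unknown) > 0) {
    abort(paste0("bedGraph chromosome not in genome index: ",
                 paste(unknown, collapse = ", ")))
  }
  # overlapping intervals are ill-defined on a coverage track
  ov <- ivs %>%
    arrange(factor(.data$chrom, levels = genome$chrom), .data$start) %>%
    group_by(.data$chrom) %>%
    mutate(clash = .data$start < lag(.data$end, default = -1L)) %>%
    ungroup()
  if (any(ov$clash)) abort("overlapping bedGraph intervals")

  bins <- genome_bins(genome, bin_width)
  bins$count <- 0
  for (chr in unique(ivs$chrom)) {
    bi <- which(as.character(bins$chrom) == chr)
    ii <- which(ivs$chrom == chr)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(bins$start[bi] + 1L, bins$end[bi]),
      IRanges::IRanges(ivs$start[ii] + 1L, ivs$end[ii])
    )
    if (length(hits) == 0) next
    b <- bi[S4Vectors::queryHits(hits)]
    v <- ii[S4Vectors::subjectHits(hits)]
    overlap <- pmin(bins$end[b], ivs$end[v]) - pmax(bins$start[b], ivs$start[v])
    contrib <- ivs$value[v] * overlap / (bins$end[b] - bins$start[b])
    agg <- tapply(contrib, b, sum)
    idx <- as.integer(names(agg))
    bins$count[idx] <- bins$count[idx] + as.numeric(agg)
  }
  new_binned_track(bins, genome, bin_width, sample_id)
}

#' Write a per-bin track as bedGraph
#'
#' Adjacent bins with identical values are merged into single intervals;
#' bins with `NA` (masked) values are omitted.
#'
#' @param track A tibble with `chrom`, `start`, `end` and a value column.
#' @param path Output path.
#' @param value_col Name of the value column (default `count`, falling back
#'   to `value`).
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(track, path, value_col = NULL) {
  if (is.null(value_col)) {
    value_col <- if ("count" %in% names(track)) "count" else "value"
  }
  tbl <- tibble(chrom = as.character(track$chrom), start = track$start,
                end = track$end, value = track[[value_col]]) %>%
    filter(!is.na(.data$value))
  # merge runs of equal value on the same chromosome into one interval
  if (nrow(tbl) > 0) {
    run <- cumsum(
      c(TRUE, tbl$chrom[-1] != tbl$chrom[-nrow(tbl)] |
          tbl$start[-1] != tbl$end[-nrow(tbl)] |
          tbl$value[-1] != tbl$value[-nrow(tbl)])
    )
    tbl <- tbl %>%
      group_by(run = run) %>%
      summarise(chrom = .data$chrom[1], start = min(.data$start),
                end = max(.data$end), value = .data$value[1], .groups = "drop") %>%
      select(-"run")
  }
  rtracklayer::export(tibble_to_gr(tbl, "value"), path, format = "bedGraph")
  invisible(path)
}

#' Write fragments as BED3
#'
#' @param fragments Tibble with `chrom`, `start`, `end`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  rtracklayer::export(tibble_to_gr(fragments), path, format = "BED")
  invisible(path)
}

#' Export dormant regions as BED6
#'
#' The score column carries the flanking-origin gap size in bp.
#'
#' @param regions Dormant-region tibble from [select_dormant_regions()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dormant_bed <- function(regions, path) {
  out <- tibble(
    chrom = as.character(regions$chrom),
    start = regions$start,
    end = regions$end,
    name = sprintf("dormant_%02d", seq_len(nrow(regions))),
    score = regions$gap,
    strand = "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
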
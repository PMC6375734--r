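# Annotation loading and validation: genome index, replication origins with
# their normal replication time (t_rep), centromeres, and the dormant-region
# set used to anchor copy-number calibration.

#' Load and validate genome, origin, and centromere annotations
#'
#' @param genome_path Two-column chrom-sizes TSV.
#' @param origins_path Origins file: BED3 + t_rep (minutes) + optional
#'   "early"/"late" class column.
#' @param centromeres_path BED3 with exactly one centromere per chromosome.
#' @return A list with elements `genome`, `origins` (sorted by chromosome
#'   order then position), and `centromeres`.
#' @export
load_annotations <- function(genome_path, origins_path, centromeres_path) {
  for (p in c(genome_path, origins_path, centromeres_path)) {
    if (!file.exists(p)) abort(paste0("annotation file not found: ", p))
  }
  genome <- read_chrom_sizes(genome_path)
  origins <- validate_origins(read_origins_bed(origins_path), genome)
  centromeres <- validate_centromeres(read_bed3(centromeres_path), genome)
  list(genome = genome, origins = origins, centromeres = centromeres)
}

validate_origins <- function(origins, genome) {
  genome <- validate_genome(genome)
  unknown <- setdiff(unique(origins$chrom), genome$chrom)
  if (length(unknown) > 0) {
    abort(paste0("origin chromosome not in genome index: ",
                 paste(unknown, collapse = ", ")))
  }
  len <- chrom_length(genome, origins$chrom)
  bad <- which(origins$pos < 0 | origins$pos >= len)
  if (length(bad) > 0) {
    abort(sprintf("origin out of chromosome bounds: %s:%d",
                  origins$chrom[bad[1]], origins$pos[bad[1]]))
  }
  if (anyNA(origins$t_rep) || any(!is.finite(origins$t_rep))) {
    abort("t_rep must be finite for all origins")
  }
  origins <- origins %>%
    arrange(factor(.data$chrom, levels = genome$chrom), .data$pos)
  dup <- duplicated(origins[c("chrom", "pos")])
  if (any(dup)) {
    d <- origins[dup, ]
    abort(sprintf("duplicate origin position: %s:%d", d$chrom[1], d$pos[1]))
  }
  origins
}

validate_centromeres <- function(centromeres, genome) {
  genome <- validate_genome(genome)
  unknown <- setdiff(unique(centromeres$chrom), genome$chrom)
  if (length(unknown) > 0) {
    abort(paste0("centromere chromosome not in genome index: ",
                 paste(unknown, collapse = ", ")))
  }
  counts <- table(factor(centromeres$chrom, levels = genome$chrom))
  if (any(counts != 1)) {
    bad <- names(counts)[counts != 1][1]
    abort(sprintf("expected exactly one centromere per chromosome; '%s' has %d",
                  bad, counts[[bad]]))
  }
  centromeres %>%
    arrange(factor(.data$chrom, levels = genome$chrom), .data$start)
}

#' Classify origins as early or late/dormant by t_rep
#'
#' Origins with `t_rep >= late_threshold` are labelled `late_dormant`, the
#' rest `early`. When the origin annotation carried an explicit class column
#' it takes precedence and the threshold is not applied (unless
#' `override = TRUE`).
#'
#' @param origins Origin tibble (from [load_annotations()]).
#' @param late_threshold Minutes; defaults to the 75th percentile of the
#'   input t_rep distribution.
#' @param override Reclassify even where an explicit class is present.
#' @return The origin tibble with `fire_class` filled in.
#' @export
classify_origins <- function(origins, late_threshold = NULL, override = FALSE) {
  if (anyNA(origins$t_rep)) abort("t_rep must be present for all origins")
  if (is.null(late_threshold)) {
    late_threshold <- unname(quantile(origins$t_rep, 0.75, type = 7))
  }
  needs <- if (override) rep(TRUE, nrow(origins)) else is.na(origins$fire_class)
  origins$fire_class[needs] <-
    ifelse(origins$t_rep[needs] >= late_threshold, "late_dormant", "early")
  origins
}

#' Select dormant replicative regions between distant late/dormant origins
#'
#' Considers, per chromosome, pairs of late/dormant origins that are
#' adjacent in the full origin set (no origin of any class between them --
#' an intervening early origin would fire under stress and replicate the
#' gap, voiding the assumption that the region stays unreplicated); ranks
#' all pairs genome-wide by gap size (descending), takes the top `n_pairs`,
#' and returns for each the `width`-bp window centred on the gap midpoint
#' -- the point farthest from either origin and hence least likely to have
#' been replicated under fork stalling. Ties in gap size are broken by
#' chromosome order, then start.
#'
#' @param origins Classified origin tibble.
#' @param genome Genome index.
#' @param n_pairs Number of regions to select (default 10).
#' @param width Region width in bp (default 10000).
#' @return A tibble with `chrom`, `start`, `end`, `gap`, and the flanking
#'   origin positions `origin_left`, `origin_right`.
#' @export
select_dormant_regions <- function(origins, genome, n_pairs = 10, width = 10000) {
  genome <- validate_genome(genome)
  if (anyNA(origins$fire_class)) abort("origins must be classified first")
  pairs <- origins %>%
    arrange(factor(.data$chrom, levels = genome$chrom), .data$pos) %>%
    group_by(.data$chrom) %>%
    mutate(next_pos = lead(.data$pos), next_class = lead(.data$fire_class)) %>%
    ungroup() %>%
    filter(.data$fire_class == "late_dormant",
           .data$next_class == "late_dormant",
           !is.na(.data$next_pos)) %>%
    mutate(gap = .data$next_pos - .data$pos) %>%
    filter(.data$gap >= width)
  if (nrow(pairs) < n_pairs) {
    abort(sprintf("need %d eligible late/dormant origin pairs, found %d",
                  n_pairs, nrow(pairs)))
  }
  pairs %>%
    mutate(
      mid = floor((.data$pos + .data$next_pos) / 2),
      start = as.integer(.data$mid - floor(width / 2)),
      end = as.integer(.data$start + width),
      chrom_rank = match(as.character(.data$chrom), genome$chrom)
    ) %>%
    arrange(dplyr::desc(.data$gap), .data$chrom_rank, .data$start) %>%
    head(n_pairs) %>%
    select("chrom", "start", "end", "gap",
           origin_left = "pos", origin_right = "next_pos")
}
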
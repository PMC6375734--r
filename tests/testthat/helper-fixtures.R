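# Shared fixtures and independent oracles, built in code at test time.

toy_genome <- function() {
  tibble::tibble(chrom = c("chrA", "chrB"), length = c(100000L, 60000L))
}

# Origin tibble in the package's column layout.
make_origins <- function(chrom, pos, t_rep, fire_class = NA_character_) {
  tibble::tibble(
    chrom = chrom, start = as.integer(pos - 100L), end = as.integer(pos + 100L),
    pos = as.integer(pos), t_rep = t_rep,
    fire_class = rep_len(fire_class, length(pos))
  )
}

make_centromeres <- function(genome) {
  tibble::tibble(
    chrom = genome$chrom,
    start = as.integer(genome$length %/% 2L - 60L),
    end = as.integer(genome$length %/% 2L + 60L)
  )
}

# A flat binned track with a given count everywhere.
constant_track <- function(genome, bin_width, count) {
  bins <- replichip::genome_bins(genome, bin_width)
  bins$count <- count
  replichip:::new_binned_track(bins, genome, as.integer(bin_width))
}

# Write a full annotation file set; returns the three paths.
write_annotation_files <- function(ann, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  genome_path <- file.path(dir, "genome.chrom.sizes")
  readr::write_tsv(ann$genome, genome_path, col_names = FALSE, progress = FALSE)
  origins_path <- file.path(dir, "origins.bed")
  org <- ann$origins
  cols <- list(org$chrom, org$start, org$end, org$t_rep)
  if (!all(is.na(org$fire_class))) {
    cols <- c(cols, list(ifelse(org$fire_class == "late_dormant", "late", "early")))
  }
  readr::write_tsv(as.data.frame(cols), origins_path, col_names = FALSE,
                   progress = FALSE)
  cen_path <- file.path(dir, "centromeres.bed")
  readr::write_tsv(ann$centromeres, cen_path, col_names = FALSE, progress = FALSE)
  list(genome = genome_path, origins = origins_path, centromeres = cen_path)
}

# Independent oracle: exhaustive enumeration of dormant-region candidates.
# Walks every adjacent origin pair with a plain loop and sorts with order().
oracle_dormant_regions <- function(origins, genome, n_pairs, width) {
  origins <- origins[order(match(origins$chrom, genome$chrom), origins$pos), ]
  rows <- list()
  for (i in seq_len(nrow(origins) - 1)) {
    same <- origins$chrom[i] == origins$chrom[i + 1]
    both_late <- identical(origins$fire_class[i], "late_dormant") &&
      identical(origins$fire_class[i + 1], "late_dormant")
    if (same && both_late) {
      gap <- origins$pos[i + 1] - origins$pos[i]
      if (gap >= width) {
        mid <- floor((origins$pos[i] + origins$pos[i + 1]) / 2)
        rows[[length(rows) + 1]] <- data.frame(
          chrom = origins$chrom[i], start = as.integer(mid - floor(width / 2)),
          gap = gap, stringsAsFactors = FALSE)
      }
    }
  }
  cand <- do.call(rbind, rows)
  if (is.null(cand)) return(cand)
  ord <- order(-cand$gap, match(cand$chrom, genome$chrom), cand$start)
  head(cand[ord, ], n_pairs)
}

# Independent oracle: per-fragment binning loop.
oracle_bin_counts <- function(fragments, genome, bin_width) {
  bins <- replichip::genome_bins(genome, bin_width)
  counts <- numeric(nrow(bins))
  for (i in seq_len(nrow(fragments))) {
    mid <- floor((fragments$start[i] + fragments$end[i]) / 2)
    j <- which(as.character(bins$chrom) == fragments$chrom[i] &
                 bins$start <= mid & mid < bins$end)
    counts[j] <- counts[j] + 1
  }
  counts
}

# A classified annotation set plus ground truth and sampled tracks, on the
# default toy study conditions.
sim_study <- function(seed, ...) {
  ann <- simulate_annotations(seed = 42)
  org <- classify_origins(ann$origins)
  cfg <- simulation_config(seed = seed, ...)
  truth <- simulate_copy_number(org, ann$genome, cfg, ann$centromeres)
  list(ann = ann, origins = org, cfg = cfg, truth = truth)
}
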
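# Synthetic-data generator. Emulates the statistical structure of
# hydroxyurea-arrested replication experiments: ~1N G1 coverage, 2N plateaus
# extending ~2 kb around fired origins in S phase, checkpoint-kinase ChIP
# peaks at the two stalled-fork positions per fired origin, strong
# centromeric internal-standard (Cse4) peaks in all tagged-IP samples, and
# Poisson read noise per bin. Ground truth (fired origins, fork positions,
# per-bin copy number) is retained so analysis results can be checked by
# parameter recovery.

#' Simulation configuration
#'
#' Defaults mirror the experimental regime the analysis targets: 100-bp
#' bins, ~100 expected fragments per 1N bin, all origins firing (the
#' checkpoint-blind `sld3A_dbf4A` background used to equalise fork positions
#' across strains), forks stalled ~2 kb from the origin after 1 h in
#' hydroxyurea, smooth fork peaks of amplitude 30 fragments/bin over a
#' background of 5, and a centromeric internal-standard amplitude of 50
#' within +/-500 bp of each centromere midpoint.
#'
#' @param seed Integer RNG seed; each sample kind draws from an independent
#'   stream derived from it.
#' @param bin_width Bin width, bp.
#' @param depth_lambda Expected fragments per 1N bin.
#' @param firing_regime `"sld3A_dbf4A"` (all origins fire) or `"wildtype"`
#'   (only origins with `t_rep <= firing_cutoff` fire).
#' @param firing_cutoff Minutes; used only under the wildtype regime.
#' @param fork_distance Distance (bp) each fork has travelled from its origin.
#' @param chip_background Expected ChIP fragments per bin away from peaks.
#' @param fork_enrichment Fork-peak amplitude, fragments per bin.
#' @param enrichment_attenuation Multiplier in \[0, 1\] applied to the fork
#'   enrichment of the tagged sample; emulates a mutant that fails to recruit
#'   the ChIP target to forks (cdc45-2A-like).
#' @param peak_sigma Gaussian fork-peak width, bp.
#' @param cen_amplitude Centromeric peak amplitude, fragments per bin.
#' @param cen_halfwidth Half-width of the centromeric window, bp.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              bin_width = 100L,
                              depth_lambda = 100,
                              firing_regime = c("sld3A_dbf4A", "wildtype"),
                              firing_cutoff = 25,
                              fork_distance = 2000L,
                              chip_background = 5,
                              fork_enrichment = 30,
                              enrichment_attenuation = 1,
                              peak_sigma = 200,
                              cen_amplitude = 50,
                              cen_halfwidth = 500) {
  firing_regime <- match.arg(firing_regime)
  cfg <- list(
    seed = as.integer(seed), bin_width = as.integer(bin_width),
    depth_lambda = depth_lambda, firing_regime = firing_regime,
    firing_cutoff = firing_cutoff, fork_distance = as.integer(fork_distance),
    chip_background = chip_background, fork_enrichment = fork_enrichment,
    enrichment_attenuation = enrichment_attenuation, peak_sigma = peak_sigma,
    cen_amplitude = cen_amplitude, cen_halfwidth = cen_halfwidth
  )
  rates <- c("depth_lambda", "chip_background", "fork_enrichment",
             "cen_amplitude", "peak_sigma", "cen_halfwidth")
  if (any(unlist(cfg[rates]) < 0)) abort("simulation rates must be >= 0")
  if (cfg$enrichment_attenuation < 0 || cfg$enrichment_attenuation > 1) {
    abort("enrichment_attenuation must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' Generate a toy annotation set
#'
#' Builds a small genome with evenly spaced, jittered origins and one
#' narrow point centromere per chromosome at its midpoint. Replication
#' times span the 15-45 min range of normal yeast timing and are spatially
#' autocorrelated, as real timing profiles are: each chromosome carries a
#' smooth late-replicating domain (a Gaussian bump in t_rep centred at
#' ~35% of its length) over an early baseline, plus small independent
#' jitter. Late/dormant origins therefore cluster into contiguous domains,
#' so adjacent late-origin pairs -- the raw material for dormant-region
#' selection -- exist as they do in the real genome.
#'
#' @param n_origins Total origins across the genome.
#' @param chrom_lengths Named or unnamed vector of chromosome lengths (bp).
#' @param seed RNG seed.
#' @param t_rep_range Range of t_rep values, minutes.
#' @return A list with `genome`, `origins` (unclassified), `centromeres`.
#' @export
simulate_annotations <- function(n_origins = 60,
                                 chrom_lengths = c(chrI = 1200000L, chrII = 800000L),
                                 seed = 1L,
                                 t_rep_range = c(15, 45)) {
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  genome <- tibble(chrom = names(chrom_lengths),
                   length = as.integer(chrom_lengths))
  per_chrom <- round(n_origins * chrom_lengths / sum(chrom_lengths))
  per_chrom[1] <- n_origins - sum(per_chrom[-1])
  origins <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(genome)), function(i) {
      k <- per_chrom[i]
      len <- genome$length[i]
      spacing <- len / (k + 1)
      pos <- round(spacing * seq_len(k) +
                     stats::runif(k, -0.1 * spacing, 0.1 * spacing))
      domain_center <- 0.35 * len
      domain_sigma <- 0.12 * len
      t_rep <- t_rep_range[1] + 2 +
        (diff(t_rep_range) - 6) * exp(-(pos - domain_center)^2 / (2 * domain_sigma^2)) +
        stats::rnorm(k, 0, 1.5)
      tibble(
        chrom = genome$chrom[i],
        pos = as.integer(pos),
        t_rep = round(pmin(pmax(t_rep, t_rep_range[1]), t_rep_range[2]), 1)
      )
    })
  })
  origins <- origins %>%
    mutate(start = .data$pos - 100L, end = .data$pos + 100L,
           fire_class = NA_character_) %>%
    select("chrom", "start", "end", "pos", "t_rep", "fire_class")
  centromeres <- genome %>%
    mutate(mid = .data$length %/% 2L,
           start = .data$mid - 60L, end = .data$mid + 60L) %>%
    select("chrom", "start", "end")
  list(genome = genome,
       origins = validate_origins(origins, genome),
       centromeres = centromeres)
}

#' Simulate the copy-number ground truth of an HU-arrested S phase
#'
#' Under the `sld3A_dbf4A` regime every origin fires; under `wildtype` only
#' origins with `t_rep <= firing_cutoff` fire. Each fired origin contributes
#' a replicated interval `[pos - fork_distance, pos + fork_distance)`
#' (clipped to the chromosome); overlapping intervals are merged before
#' per-bin copy number is assigned, so copy number never exceeds 2.
#'
#' @param origins Classified origin tibble.
#' @param genome Genome index.
#' @param cfg A [simulation_config()].
#' @param centromeres Optional centromere tibble, carried along so ChIP
#'   samples can be drawn from the same ground truth.
#' @return A `ground_truth` list: `fired_origins`, `replicated_intervals`
#'   (merged), `fork_positions`, `copy_number` (per-bin track of 1s and 2s),
#'   plus the genome, centromeres and config used.
#' @export
simulate_copy_number <- function(origins, genome, cfg, centromeres = NULL) {
  genome <- validate_genome(genome)
  fired <- switch(cfg$firing_regime,
    sld3A_dbf4A = origins,
    wildtype = filter(origins, .data$t_rep <= cfg$firing_cutoff)
  )
  len <- if (nrow(fired) > 0) chrom_length(genome, fired$chrom) else integer()
  raw_iv <- tibble(
    chrom = fired$chrom,
    start = pmax(0L, fired$pos - cfg$fork_distance),
    end = pmin(len, fired$pos + cfg$fork_distance)
  )
  # merge overlaps per chromosome so copy number saturates at 2N
  merged <- purrr::map_dfr(unique(raw_iv$chrom), function(chr) {
    iv <- filter(raw_iv, .data$chrom == chr)
    red <- IRanges::reduce(IRanges::IRanges(iv$start + 1L, iv$end))
    tibble(chrom = chr, start = IRanges::start(red) - 1L,
           end = IRanges::end(red))
  })
  if (nrow(merged) == 0) {
    merged <- tibble(chrom = character(), start = integer(), end = integer())
  }
  fork_positions <- tibble(
    chrom = rep(fired$chrom, each = 2),
    pos = as.integer(rbind(fired$pos - cfg$fork_distance,
                           fired$pos + cfg$fork_distance)),
    origin_pos = rep(fired$pos, each = 2)
  ) %>%
    filter(.data$pos >= 0, .data$pos < chrom_length(genome, .data$chrom))

  bins <- genome_bins(genome, cfg$bin_width)
  cn <- rep(1L, nrow(bins))
  for (chr in unique(merged$chrom)) {
    bi <- which(as.character(bins$chrom) == chr)
    iv <- filter(merged, .data$chrom == chr)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(bins$start[bi] + 1L, bins$end[bi]),
      IRanges::IRanges(iv$start + 1L, iv$end)
    )
    cn[bi[unique(S4Vectors::queryHits(hits))]] <- 2L
  }
  bins$count <- cn
  structure(
    list(
      fired_origins = fired,
      replicated_intervals = merged,
      fork_positions = fork_positions,
      copy_number = new_binned_track(bins, genome, cfg$bin_width, "true_copy_number"),
      genome = genome,
      centromeres = centromeres,
      cfg = cfg
    ),
    class = "ground_truth"
  )
}

.sample_kinds <- c("G1", "S", "chip_tagged", "chip_untagged")

#' Expected per-bin fragment rate for a sample kind
#'
#' The noise-free rate function underlying [sample_reads()]: G1 is flat at
#' `depth_lambda`; S multiplies it by the true copy number; the tagged ChIP
#' adds Gaussian fork peaks (amplitude `fork_enrichment *
#' enrichment_attenuation`, width `peak_sigma`) and the centromeric
#' internal-standard term to `chip_background`; the untagged control has
#' background plus the centromeric term only.
#'
#' @inheritParams sample_reads
#' @return Numeric vector of expected counts, one per genome bin.
#' @export
expected_rate <- function(truth, cfg, sample_kind) {
  if (!sample_kind %in% .sample_kinds) {
    abort(paste0("unknown sample kind: ", sample_kind))
  }
  bins <- truth$copy_number
  mid <- (bins$start + bins$end) / 2
  switch(sample_kind,
    G1 = rep(cfg$depth_lambda, nrow(bins)),
    S = cfg$depth_lambda * bins$count,
    chip_tagged = chip_rate(bins, mid, truth, cfg, tagged = TRUE),
    chip_untagged = chip_rate(bins, mid, truth, cfg, tagged = FALSE)
  )
}

chip_rate <- function(bins, mid, truth, cfg, tagged) {
  rate <- rep(cfg$chip_background, nrow(bins))
  if (tagged && cfg$fork_enrichment > 0 && nrow(truth$fork_positions) > 0) {
    fp <- truth$fork_positions
    peak <- numeric(nrow(bins))
    for (chr in unique(fp$chrom)) {
      bi <- which(as.character(bins$chrom) == chr)
      for (p in fp$pos[fp$chrom == chr]) {
        peak[bi] <- peak[bi] + exp(-((mid[bi] - p)^2) / (2 * cfg$peak_sigma^2))
      }
    }
    rate <- rate + cfg$fork_enrichment * cfg$enrichment_attenuation * peak
  }
  if (!is.null(truth$centromeres) && cfg$cen_amplitude > 0) {
    in_cen <- cen_window_flags(bins, truth$centromeres, cfg$cen_halfwidth)
    rate[in_cen] <- rate[in_cen] + cfg$cen_amplitude
  }
  rate
}

#' Draw a Poisson read-count track for one sample
#'
#' Per-bin counts are Poisson with the [expected_rate()] of the sample kind.
#' Each kind draws from an independent RNG stream derived from
#' `(cfg$seed, sample_kind)`, so samples are mutually independent and each
#' is reproducible regardless of the order in which kinds are drawn.
#'
#' @param truth Ground truth from [simulate_copy_number()].
#' @param cfg The [simulation_config()].
#' @param sample_kind One of `"G1"`, `"S"`, `"chip_tagged"`, `"chip_untagged"`.
#' @return A binned track of simulated counts.
#' @export
sample_reads <- function(truth, cfg, sample_kind) {
  rate <- expected_rate(truth, cfg, sample_kind)
  kind_seed <- (cfg$seed + 7919L * match(sample_kind, .sample_kinds)) %%
    .Machine$integer.max
  counts <- withr::with_seed(kind_seed, rpois(length(rate), rate))
  bins <- truth$copy_number
  bins$count <- as.numeric(counts)
  new_binned_track(bins, truth$genome, cfg$bin_width, sample_kind)
}

#' Expand a binned count track into per-fragment BED intervals
#'
#' Places `count` fragments of `frag_length` bp uniformly within each bin
#' (clipped to the chromosome end). Exists to exercise the fragment-binning
#' reader: re-binning the output reproduces the input counts exactly.
#'
#' @param track A binned track with integer counts.
#' @param frag_length Fragment length in bp (default 50).
#' @param seed RNG seed for the uniform placement.
#' @return A fragment tibble (`chrom`, `start`, `end`).
#' @export
track_to_fragments <- function(track, frag_length = 50L, seed = 1L) {
  genome <- track_genome(track)
  nz <- track[track$count > 0, ]
  if (nrow(nz) == 0) return(tibble(chrom = character(), start = integer(), end = integer()))
  counts <- as.integer(nz$count)
  chrom <- rep(as.character(nz$chrom), counts)
  bstart <- rep(nz$start, counts)
  bend <- rep(nz$end, counts)
  len <- chrom_length(genome, chrom)
  # fragment midpoint uniform within the bin so midpoint binning round-trips
  mid <- withr::with_seed(seed, {
    floor(bstart + stats::runif(length(bstart)) * (bend - bstart))
  })
  start <- pmax(0, mid - floor(frag_length / 2))
  end <- pmin(len, start + frag_length)
  tibble(chrom = chrom, start = as.integer(start), end = as.integer(end)) %>%
    arrange(.data$chrom, .data$start)
}

#' Write the simulation ground truth as a TSV sidecar
#'
#' One row per fired origin with its two fork positions; used by tests and
#' downstream parameter-recovery checks.
#'
#' @param truth Ground truth from [simulate_copy_number()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ground_truth_tsv <- function(truth, path) {
  fired <- truth$fired_origins
  out <- tibble(
    chrom = fired$chrom, origin_pos = fired$pos, t_rep = fired$t_rep,
    fork_left = fired$pos - truth$cfg$fork_distance,
    fork_right = fired$pos + truth$cfg$fork_distance
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
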
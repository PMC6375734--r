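# End-to-end orchestration: a serializable run configuration, a simulation
# driver that writes a complete sample set with ground truth, and an
# analysis driver that runs annotation -> coverage -> copy number -> ChIP
# normalization -> metaprofiles and writes tracks, figures, and a JSON
# report of every stage's key scalars.

#' Build a run configuration
#'
#' All parameters of every stage in one serializable list. `write_run_config()`
#' / `read_run_config()` round-trip it through YAML; both drivers write the
#' configuration they actually used into the output directory.
#'
#' @param genome,origins,centromeres Annotation file paths.
#' @param tracks Named list of bedGraph paths (`g1`, `s`, `chip_tagged`,
#'   `chip_untagged`, optionally `chip_tagged_attenuated`); filled in by
#'   [run_simulate()].
#' @param out_dir Output directory.
#' @param seed Integer seed for all simulation randomness.
#' @param bin_width Bin width in bp.
#' @param late_threshold t_rep cutoff (minutes) for late/dormant origins;
#'   `NULL` = 75th percentile of the input t_rep distribution.
#' @param n_pairs,dormant_width Dormant-region selection parameters.
#' @param min_g1_count,orientation,max_n Copy-number profiling parameters.
#' @param cen_halfwidth,background_mode,epsilon ChIP normalization
#'   parameters (`epsilon = NULL` uses the background-median default).
#' @param window Metaprofile half-window in bp.
#' @param mutant_attenuation Fork-enrichment multiplier for the simulated
#'   recruitment-defective ChIP sample.
#' @param sim A [simulation_config()]; its seed and bin width are kept in
#'   step with `seed` and `bin_width`.
#' @param force Overwrite an existing output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(genome = NULL, origins = NULL, centromeres = NULL,
                       tracks = list(), out_dir = "replichip_out",
                       seed = 1L, bin_width = 100L, late_threshold = NULL,
                       n_pairs = 10L, dormant_width = 10000L,
                       min_g1_count = 1, orientation = "s_over_g1",
                       max_n = 2.2, cen_halfwidth = 500,
                       background_mode = "ratio", epsilon = NULL,
                       window = 5000L, mutant_attenuation = 0.1,
                       sim = simulation_config(), force = FALSE) {
  sim$seed <- as.integer(seed)
  sim$bin_width <- as.integer(bin_width)
  structure(
    list(genome = genome, origins = origins, centromeres = centromeres,
         tracks = tracks, out_dir = out_dir, seed = as.integer(seed),
         bin_width = as.integer(bin_width), late_threshold = late_threshold,
         n_pairs = n_pairs, dormant_width = dormant_width,
         min_g1_count = min_g1_count, orientation = orientation,
         max_n = max_n, cen_halfwidth = cen_halfwidth,
         background_mode = background_mode, epsilon = epsilon,
         window = window, mutant_attenuation = mutant_attenuation,
         sim = unclass(sim), force = force),
    class = "run_config")
}

#' @rdname run_config
#' @param cfg A run configuration.
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- run_config()
  for (nm in intersect(names(raw), names(base))) base[[nm]] <- raw[[nm]]
  base$seed <- as.integer(base$seed)
  base$sim <- do.call(simulation_config, c(
    raw$sim[intersect(names(raw$sim), names(formals(simulation_config)))]))
  base$sim <- unclass(base$sim)
  base
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("[stage %s] %s", name, conditionMessage(e)))
  })
}

prepare_out_dir <- function(out_dir, force) {
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force) {
    abort(paste0("output directory exists (use force = TRUE): ", out_dir))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
}

msg <- function(...) message(format(Sys.time(), "%H:%M:%S "), sprintf(...))

#' Simulate a complete sample set with ground truth
#'
#' Generates G1, S (HU-arrested), tagged ChIP, attenuated-mutant ChIP,
#' untagged-control ChIP, and true-copy-number tracks for the configured
#' annotations, writes them as bedGraph together with a ground-truth TSV,
#' the configuration used, and a checksum manifest.
#'
#' @param cfg A [run_config()] whose annotation paths are set.
#' @param quiet Suppress progress messages.
#' @return The updated config (with `tracks` filled in), invisibly.
#' @export
run_simulate <- function(cfg, quiet = FALSE) {
  if (quiet) {
    return(suppressMessages(run_simulate(cfg, quiet = FALSE)))
  }
  ann <- stage("annotations",
               load_annotations(cfg$genome, cfg$origins, cfg$centromeres))
  prepare_out_dir(cfg$out_dir, cfg$force)
  origins <- classify_origins(ann$origins, cfg$late_threshold)
  sim <- do.call(simulation_config, cfg$sim)
  truth <- stage("simulate",
                 simulate_copy_number(origins, ann$genome, sim, ann$centromeres))
  msg("simulate: %d/%d origins fired (%s regime)",
      nrow(truth$fired_origins), nrow(origins), sim$firing_regime)

  paths <- list()
  out <- function(f) file.path(cfg$out_dir, f)
  for (kind in c("G1", "S", "chip_tagged", "chip_untagged")) {
    tr <- sample_reads(truth, sim, kind)
    paths[[tolower(kind)]] <- out(paste0(tolower(kind), ".bedgraph"))
    write_bedgraph(tr, paths[[tolower(kind)]])
  }
  sim_att <- sim
  sim_att$enrichment_attenuation <- cfg$mutant_attenuation
  att <- sample_reads(truth, sim_att, "chip_tagged")
  paths$chip_tagged_attenuated <- out("chip_tagged_attenuated.bedgraph")
  write_bedgraph(att, paths$chip_tagged_attenuated)
  paths$true_copy_number <- out("true_copy_number.bedgraph")
  write_bedgraph(truth$copy_number, paths$true_copy_number)
  write_ground_truth_tsv(truth, out("ground_truth.tsv"))

  cfg$tracks <- list(
    g1 = paths$g1, s = paths$s, chip_tagged = paths$chip_tagged,
    chip_untagged = paths$chip_untagged,
    chip_tagged_attenuated = paths$chip_tagged_attenuated
  )
  write_run_config(cfg, out("config.yaml"))
  files <- sort(list.files(cfg$out_dir, full.names = TRUE))
  # config.yaml embeds run-local paths, so it is excluded from the data
  # checksums: two runs with the same seed must yield identical manifests
  files <- files[!basename(files) %in% c("manifest.json", "config.yaml")]
  manifest <- list(
    files = setNames(as.list(unname(tools::md5sum(files))), basename(files)),
    n_fired = nrow(truth$fired_origins), seed = sim$seed
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)
  msg("simulate: wrote %d files to %s", length(files) + 1, cfg$out_dir)
  invisible(cfg)
}

#' Run the analysis pipeline on a sample set
#'
#' Annotation loading and classification, dormant-region selection,
#' bedGraph reading, S/G1 copy-number profiling (calibration, orientation
#' sanity check, 2.2N mask), centromeric internal-standard ChIP
#' normalization with background comparison, and origin-centered
#' heatmap/metaprofile construction. Writes all tracks, matrices, figures,
#' and a JSON report of the stage scalars needed to reproduce and audit
#' the run. The analysis path involves no randomness: identical inputs
#' give identical outputs.
#'
#' @param cfg A [run_config()] with annotation and track paths set (e.g.
#'   the value returned by [run_simulate()]).
#' @param quiet Suppress progress messages.
#' @return A list of in-memory results (`profile`, `chip`, `heatmap`,
#'   `avg_profile`, `report`), invisibly.
#' @export
run_analysis <- function(cfg, quiet = FALSE) {
  if (quiet) {
    return(suppressMessages(run_analysis(cfg, quiet = FALSE)))
  }
  ann <- stage("annotations",
               load_annotations(cfg$genome, cfg$origins, cfg$centromeres))
  out_dir <- file.path(cfg$out_dir, "analysis")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(out_dir, f)

  origins <- classify_origins(ann$origins, cfg$late_threshold)
  dormant <- stage("dormant_regions",
                   select_dormant_regions(origins, ann$genome,
                                          n_pairs = cfg$n_pairs,
                                          width = cfg$dormant_width))
  write_dormant_bed(dormant, out("dormant_regions.bed"))
  msg("annotations: %d origins, %d dormant regions (min gap %d bp)",
      nrow(origins), nrow(dormant), min(dormant$gap))

  read_track <- function(key) {
    stage("coverage", read_bedgraph(cfg$tracks[[key]], ann$genome,
                                    cfg$bin_width, sample_id = key))
  }
  g1 <- read_track("g1")
  s <- read_track("s")

  raw <- stage("replication_profile",
               ratio_track(s, g1, min_g1_count = cfg$min_g1_count,
                           orientation = cfg$orientation))
  calibrated <- stage("replication_profile", calibrate_to_1n(raw, dormant))
  check_profile_orientation(calibrated)
  profile <- apply_mask(calibrated, max_n = cfg$max_n)
  pg <- glance(profile)
  msg("replication_profile: 1N = %.4f raw ratio, %d/%d bins masked",
      pg$one_n_value, pg$n_masked, pg$n_bins)
  write_profile(profile, out("copy_number.bedgraph"))

  chip_keys <- intersect(c("chip_tagged", "chip_tagged_attenuated"),
                         names(cfg$tracks))
  background <- stage("chip_normalize",
                      cen_scale(read_track("chip_untagged"), ann$centromeres,
                                halfwidth = cfg$cen_halfwidth))
  chip <- purrr::map(setNames(chip_keys, chip_keys), function(key) {
    scaled <- stage("chip_normalize",
                    cen_scale(read_track(key), ann$centromeres,
                              halfwidth = cfg$cen_halfwidth))
    norm <- stage("chip_normalize",
                  background_normalize(scaled, background,
                                       mode = cfg$background_mode,
                                       epsilon = cfg$epsilon))
    write_chip_track(norm, out(paste0(key, "_normalized.bedgraph")))
    msg("chip_normalize: %s cen_scale_factor = %.4f", key,
        attr(scaled, "cen_scale_factor"))
    norm
  })

  hm <- stage("metaprofile",
              build_heatmap(chip[["chip_tagged"]], origins, window = cfg$window))
  avg <- average_profile(hm)
  write_heatmap_tsv(hm, out("heatmap_chip_tagged.tsv"))
  readr::write_tsv(as_tibble(avg), out("average_profile_chip_tagged.tsv"),
                   progress = FALSE)
  ggplot2::ggsave(out("heatmap_chip_tagged.png"), autoplot(hm),
                  width = 6, height = 5, dpi = 120)
  ggplot2::ggsave(out("average_profile_chip_tagged.png"), autoplot(avg),
                  width = 6, height = 4, dpi = 120)

  report <- list(
    parameters = unclass(cfg),
    n_origins = nrow(origins),
    n_dormant_pairs = nrow(dormant),
    one_n_value = pg$one_n_value,
    n_masked_bins = pg$n_masked,
    n_bins = pg$n_bins,
    cen_scale_factor = c(
      list(chip_untagged = attr(background, "cen_scale_factor")),
      purrr::map(chip, ~ attr(.x, "cen_scale_factor"))
    ),
    background_mode = cfg$background_mode,
    heatmap = as.list(glance(hm))
  )
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  msg("analysis: report written to %s", out("report.json"))
  invisible(list(profile = profile, chip = chip, heatmap = hm,
                 avg_profile = avg, dormant = dormant, report = report))
}
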
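test_that("centromere scaling uses the joint window mean and normalizes it to 1", {
  st <- sim_study(seed = 1)
  chip <- sample_reads(st$truth, st$cfg, "chip_tagged")
  scaled <- cen_scale(chip, st$ann$centromeres)
  in_cen <- replichip:::cen_window_flags(chip, st$ann$centromeres, 500)

  expect_equal(attr(scaled, "cen_scale_factor"), mean(chip$count[in_cen]))
  expect_equal(mean(scaled$value[in_cen]), 1, tolerance = 1e-14)

  # a track constant on centromeric bins has that constant as its factor
  flat <- constant_track(st$ann$genome, 100, 7)
  expect_equal(attr(cen_scale(flat, st$ann$centromeres), "cen_scale_factor"), 7)

  zero <- constant_track(st$ann$genome, 100, 0)
  expect_error(cen_scale(zero, st$ann$centromeres), "internal standard absent")
})

test_that("normalized outputs are invariant to library size", {
  st <- sim_study(seed = 2)
  chip <- sample_reads(st$truth, st$cfg, "chip_tagged")
  ctrl <- sample_reads(st$truth, st$cfg, "chip_untagged")
  cs <- cen_scale(chip, st$ann$centromeres)
  cu <- cen_scale(ctrl, st$ann$centromeres)
  bn <- background_normalize(cs, cu, epsilon = 0.1)

  chip10 <- chip
  chip10$count <- chip10$count * 10
  cs10 <- cen_scale(chip10, st$ann$centromeres)
  expect_equal(cs10$value, cs$value, tolerance = 1e-12)
  bn10 <- background_normalize(cs10, cu, epsilon = 0.1)
  expect_equal(bn10$value, bn$value, tolerance = 1e-12)

  loc <- locus_normalize(chip, "chrI", 0, 100000)
  loc10 <- locus_normalize(chip10, "chrI", 0, 100000)
  expect_equal(loc10$value, loc$value, tolerance = 1e-12)
})

test_that("background normalization compares tracks and masks centromeres", {
  st <- sim_study(seed = 3)
  cs <- cen_scale(sample_reads(st$truth, st$cfg, "chip_tagged"),
                  st$ann$centromeres)
  same <- background_normalize(cs, cs, mode = "ratio", epsilon = 1e-9)
  # bins with zero counts in both tracks give 0/epsilon, so assert on the
  # bins that actually carry signal
  outside <- !is.na(same$value) & cs$value > 0
  expect_true(all(abs(same$value[outside] - 1) < 1e-6))
  # centromeric windows are masked in the output
  in_cen <- replichip:::cen_window_flags(cs, st$ann$centromeres, 500)
  expect_true(all(is.na(same$value[in_cen])))

  sub <- background_normalize(cs, cs, mode = "subtract")
  expect_true(all(sub$value[!is.na(sub$value)] == 0))

  other <- cen_scale(constant_track(st$ann$genome, 200, 1) |>
                       (\(x) { x$count <- x$count + 1; x })(),
                     st$ann$centromeres)
  expect_error(background_normalize(cs, other), "mismatched bin grids")
})

test_that("fork windows stand out over background after normalization", {
  hits <- c()
  for (seed in 1:5) {
    st <- sim_study(seed = seed)
    cs <- cen_scale(sample_reads(st$truth, st$cfg, "chip_tagged"),
                    st$ann$centromeres)
    cu <- cen_scale(sample_reads(st$truth, st$cfg, "chip_untagged"),
                    st$ann$centromeres)
    bn <- background_normalize(cs, cu, mode = "ratio")
    mid <- (bn$start + bn$end) / 2
    fp <- st$truth$fork_positions
    near <- rep(FALSE, nrow(bn))
    for (i in seq_len(nrow(fp))) {
      bi <- as.character(bn$chrom) == fp$chrom[i]
      near[bi] <- near[bi] | abs(mid[bi] - fp$pos[i]) <= 500
    }
    enrich <- mean(bn$value[near], na.rm = TRUE) /
      median(bn$value, na.rm = TRUE)
    hits <- c(hits, enrich)
  }
  expect_true(all(hits >= 3))
})

test_that("attenuated fork enrichment is recovered from normalized signal", {
  errs <- c()
  for (seed in 1:5) {
    st <- sim_study(seed = seed)
    cfg_att <- st$cfg
    cfg_att$enrichment_attenuation <- 0.1
    cu <- cen_scale(sample_reads(st$truth, st$cfg, "chip_untagged"),
                    st$ann$centromeres)
    full <- background_normalize(
      cen_scale(sample_reads(st$truth, st$cfg, "chip_tagged"),
                st$ann$centromeres), cu, mode = "subtract")
    att <- background_normalize(
      cen_scale(sample_reads(st$truth, cfg_att, "chip_tagged"),
                st$ann$centromeres), cu, mode = "subtract")
    mid <- (full$start + full$end) / 2
    fp <- st$truth$fork_positions
    near <- rep(FALSE, nrow(full))
    for (i in seq_len(nrow(fp))) {
      bi <- as.character(full$chrom) == fp$chrom[i]
      near[bi] <- near[bi] | abs(mid[bi] - fp$pos[i]) <= 500
    }
    ratio <- mean(att$value[near], na.rm = TRUE) /
      mean(full$value[near], na.rm = TRUE)
    errs <- c(errs, abs(ratio - 0.1))
  }
  expect_true(all(errs <= 0.05))
})

test_that("ratio and subtract modes rank fork windows concordantly", {
  # every fork carries the same simulated enrichment, so windows from a
  # single sample differ only by noise and their ranking is undefined;
  # instead rank a pooled set of full-enrichment and 10x-attenuated
  # windows, which spans a genuine signal gradient
  st <- sim_study(seed = 4)
  cfg_att <- st$cfg
  cfg_att$enrichment_attenuation <- 0.1
  cu <- cen_scale(sample_reads(st$truth, st$cfg, "chip_untagged"),
                  st$ann$centromeres)
  cs_full <- cen_scale(sample_reads(st$truth, st$cfg, "chip_tagged"),
                       st$ann$centromeres)
  cs_att <- cen_scale(sample_reads(st$truth, cfg_att, "chip_tagged"),
                      st$ann$centromeres)
  fp <- st$truth$fork_positions
  window_means <- function(track) {
    mid <- (track$start + track$end) / 2
    vapply(seq_len(nrow(fp)), function(i) {
      bi <- as.character(track$chrom) == fp$chrom[i] &
        abs(mid - fp$pos[i]) <= 500
      mean(track$value[bi], na.rm = TRUE)
    }, numeric(1))
  }
  pooled <- function(mode) {
    c(window_means(background_normalize(cs_full, cu, mode = mode)),
      window_means(background_normalize(cs_att, cu, mode = mode)))
  }
  rho <- cor(pooled("ratio"), pooled("subtract"), method = "spearman")
  expect_gt(rho, 0.95)
})

test_that("tagged and untagged internal standards scale with their expected rates", {
  st <- sim_study(seed = 5)
  bins <- st$truth$copy_number
  # on the expectation functions the ratio of cen scale factors equals the
  # ratio of total centromeric rates exactly
  exp_tag <- bins; exp_tag$count <- expected_rate(st$truth, st$cfg, "chip_tagged")
  exp_un <- bins; exp_un$count <- expected_rate(st$truth, st$cfg, "chip_untagged")
  exp_tag <- replichip:::new_binned_track(exp_tag, st$ann$genome, 100L)
  exp_un <- replichip:::new_binned_track(exp_un, st$ann$genome, 100L)
  in_cen <- replichip:::cen_window_flags(bins, st$ann$centromeres, 500)
  f_tag <- attr(cen_scale(exp_tag, st$ann$centromeres), "cen_scale_factor")
  f_un <- attr(cen_scale(exp_un, st$ann$centromeres), "cen_scale_factor")
  expect_equal(f_tag / f_un,
               sum(exp_tag$count[in_cen]) / sum(exp_un$count[in_cen]),
               tolerance = 1e-12)
  # and on sampled draws within sampling error
  s_tag <- cen_scale(sample_reads(st$truth, st$cfg, "chip_tagged"),
                     st$ann$centromeres)
  s_un <- cen_scale(sample_reads(st$truth, st$cfg, "chip_untagged"),
                    st$ann$centromeres)
  expect_equal(attr(s_tag, "cen_scale_factor") / attr(s_un, "cen_scale_factor"),
               f_tag / f_un, tolerance = 0.15)
})

test_that("locus normalization agrees with centromere scaling up to a constant", {
  st <- sim_study(seed = 6)
  chip <- sample_reads(st$truth, st$cfg, "chip_tagged")
  cs <- cen_scale(chip, st$ann$centromeres)
  loc <- locus_normalize(chip, "chrI", 200000, 240000)
  k <- cs$value / loc$value
  k <- k[is.finite(k)]
  expect_lt(diff(range(k)), 1e-9)

  flat <- constant_track(st$ann$genome, 100, 4)
  uni <- locus_normalize(flat, "chrI", 0, 100000)
  expect_true(all(uni$value == 1))
  expect_error(locus_normalize(constant_track(st$ann$genome, 100, 0),
                               "chrI", 0, 1000), "no reads")
})

test_that("chip tracks export with a provenance sidecar", {
  st <- sim_study(seed = 7)
  cs <- cen_scale(sample_reads(st$truth, st$cfg, "chip_tagged"),
                  st$ann$centromeres)
  cu <- cen_scale(sample_reads(st$truth, st$cfg, "chip_untagged"),
                  st$ann$centromeres)
  bn <- background_normalize(cs, cu)
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_chip_track(bn, path)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$background_mode, "ratio")
  expect_equal(side$cen_scale_factor, attr(bn, "cen_scale_factor"))
  g <- glance(bn)
  expect_equal(g$background_mode, "ratio")
  expect_gt(g$cen_scale_factor, 0)
})
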
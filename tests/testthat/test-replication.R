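flat_profile <- function(genome, bin_width, value) {
  s <- constant_track(genome, bin_width, value)
  g1 <- constant_track(genome, bin_width, 1)
  ratio_track(s, g1)
}

test_that("ratio track divides S by G1 and masks undefined bins", {
  gn <- toy_genome()
  s <- constant_track(gn, 100, 8)
  g1 <- constant_track(gn, 100, 8)
  same <- ratio_track(s, g1)
  expect_true(all(same$value == 1))

  g1$count[5] <- 0
  masked <- ratio_track(s, g1)
  expect_true(is.na(masked$value[5]))
  expect_true(all(!is.na(masked$value[-5])))

  # audit orientation inverts the ratio
  s$count[] <- 4
  g1$count[] <- 8
  expect_true(all(ratio_track(s, g1)$value == 0.5))
  expect_true(all(ratio_track(s, g1, orientation = "g1_over_s")$value == 2))

  g2 <- constant_track(gn, 200, 8)
  expect_error(ratio_track(s, g2), "mismatched bin grids")
})

test_that("replicated bins carry twice the dormant-bin ratio in simulation", {
  st <- sim_study(seed = 8)
  raw <- ratio_track(sample_reads(st$truth, st$cfg, "S"),
                     sample_reads(st$truth, st$cfg, "G1"))
  dorm <- select_dormant_regions(st$origins, st$ann$genome)
  in_dorm <- replichip:::bins_within_regions(raw, dorm)
  two_n <- st$truth$copy_number$count == 2
  ratio_of_means <- mean(raw$value[two_n], na.rm = TRUE) /
    mean(raw$value[in_dorm], na.rm = TRUE)
  expect_lt(abs(ratio_of_means / 2 - 1), 0.05)
})

test_that("1N calibration is exact, scale-invariant and idempotent", {
  st <- sim_study(seed = 12)
  dorm <- select_dormant_regions(st$origins, st$ann$genome)
  s <- sample_reads(st$truth, st$cfg, "S")
  g1 <- sample_reads(st$truth, st$cfg, "G1")
  cal <- calibrate_to_1n(ratio_track(s, g1), dorm)

  in_dorm <- replichip:::bins_within_regions(cal, dorm)
  expect_equal(mean(cal$value[in_dorm], na.rm = TRUE), 1, tolerance = 1e-14)

  # scale invariance: multiplying all S counts by 7 changes nothing
  s7 <- s
  s7$count <- s7$count * 7
  cal7 <- calibrate_to_1n(ratio_track(s7, g1), dorm)
  expect_equal(cal7$value, cal$value, tolerance = 1e-12)

  # constant raw ratio calibrates to exactly 1
  const <- calibrate_to_1n(flat_profile(st$ann$genome, 100, 3.7), dorm)
  expect_true(all(const$value == 1))

  # idempotence
  again <- calibrate_to_1n(cal, dorm)
  expect_equal(again$value, cal$value, tolerance = 1e-14)

  # no unmasked dormant bins -> error
  empty <- ratio_track(constant_track(st$ann$genome, 100, 1),
                       constant_track(st$ann$genome, 100, 0))
  expect_error(calibrate_to_1n(empty, dorm), "no unmasked bins")
})

test_that("copy number recovers the simulated 1N/2N structure", {
  st <- sim_study(seed = 42)
  dorm <- select_dormant_regions(st$origins, st$ann$genome)
  cal <- calibrate_to_1n(
    ratio_track(sample_reads(st$truth, st$cfg, "S"),
                sample_reads(st$truth, st$cfg, "G1")), dorm)
  two_n <- st$truth$copy_number$count == 2
  m2 <- mean(cal$value[two_n], na.rm = TRUE)
  m1 <- mean(cal$value[!two_n], na.rm = TRUE)
  expect_gt(m2, 1.9); expect_lt(m2, 2.1)
  expect_gt(m1, 0.95); expect_lt(m1, 1.05)
})

test_that("the copy-number ceiling masks strictly above the threshold", {
  gn <- tibble::tibble(chrom = "chrA", length = 500L)
  prof <- flat_profile(gn, 100, 1)
  prof$value <- c(0.9, 1.0, 2.1, 2.5, 3.0)
  cal <- calibrate_to_1n(prof, tibble::tibble(chrom = "chrA", start = 0L, end = 500L),
                         min_bins = 1)
  cal$value <- c(0.9, 1.0, 2.1, 2.5, 3.0) # exercise the mask on known values
  expect_equal(is.na(apply_mask(cal, 2.2)$value), c(F, F, F, T, T))

  cal$value <- c(2.2, 2.2000001, 1, 1, 1)
  masked <- apply_mask(cal, 2.2)
  expect_equal(masked$value[1], 2.2)     # equal to the ceiling is retained
  expect_true(is.na(masked$value[2]))    # strictly bigger is masked

  expect_identical(is.na(apply_mask(cal, Inf)$value), is.na(cal$value))

  # previously masked bins stay masked
  cal$value[3] <- NA
  expect_true(is.na(apply_mask(cal, 2.2)$value[3]))
})

test_that("calibration is invariant to library depth up to masked-bin identity", {
  st <- sim_study(seed = 3)
  dorm <- select_dormant_regions(st$origins, st$ann$genome)
  s <- sample_reads(st$truth, st$cfg, "S")
  g1 <- sample_reads(st$truth, st$cfg, "G1")
  cal <- calibrate_to_1n(ratio_track(s, g1), dorm)
  g1x <- g1
  g1x$count <- g1x$count * 3
  calx <- calibrate_to_1n(ratio_track(s, g1x), dorm)
  both <- !is.na(cal$value) & !is.na(calx$value)
  expect_equal(calx$value[both], cal$value[both], tolerance = 1e-12)
})

test_that("fork extent walks contiguous replicated bins from the origin", {
  gn <- tibble::tibble(chrom = "chrA", length = 20000L)
  org <- make_origins("chrA", 10000, t_rep = 20, fire_class = "early")
  dorm1 <- tibble::tibble(chrom = "chrA", start = 0L, end = 2000L)

  flat <- calibrate_to_1n(flat_profile(gn, 100, 1), dorm1)
  expect_equal(estimate_fork_extent(flat, org)$extent, 0)

  plateau <- flat
  plateau$value[ (10000 %/% 100 + 1) + (-10:10) ] <- 2
  expect_equal(estimate_fork_extent(plateau, org)$extent, 1100)
  expect_equal(estimate_fork_extent(plateau, org, threshold_n = 5)$extent, 0)

  holed <- plateau
  holed$value[(10000 %/% 100 + 1)] <- NA
  got <- estimate_fork_extent(holed, org)
  expect_true(got$low_confidence)
})

test_that("fork extent recovers the simulated stall distance", {
  ok <- logical(0)
  for (seed in 1:5) {
    st <- sim_study(seed = seed)
    dorm <- select_dormant_regions(st$origins, st$ann$genome)
    cal <- calibrate_to_1n(
      ratio_track(sample_reads(st$truth, st$cfg, "S"),
                  sample_reads(st$truth, st$cfg, "G1")), dorm)
    fe <- estimate_fork_extent(cal, st$truth$fired_origins)
    ok <- c(ok, abs(fe$extent - st$cfg$fork_distance) <= 100)
  }
  expect_gte(mean(ok), 0.9)
})

test_that("an inverted profile triggers the orientation sanity warning", {
  st <- sim_study(seed = 10)
  dorm <- select_dormant_regions(st$origins, st$ann$genome)
  s <- sample_reads(st$truth, st$cfg, "S")
  g1 <- sample_reads(st$truth, st$cfg, "G1")
  good <- calibrate_to_1n(ratio_track(s, g1), dorm)
  expect_no_warning(check_profile_orientation(good))
  swapped <- calibrate_to_1n(ratio_track(g1, s), dorm)
  expect_warning(check_profile_orientation(swapped), "swapped")
})

test_that("profiles export as bedGraph with a mask sidecar", {
  st <- sim_study(seed = 4)
  dorm <- select_dormant_regions(st$origins, st$ann$genome)
  cal <- apply_mask(calibrate_to_1n(
    ratio_track(sample_reads(st$truth, st$cfg, "S"),
                sample_reads(st$truth, st$cfg, "G1")), dorm))
  path <- withr::local_tempfile(fileext = ".bedgraph")
  write_profile(cal, path)
  n_masked <- sum(is.na(cal$value))
  expect_equal(length(readLines(paste0(path, ".mask.bed"))), n_masked)
  g <- glance(cal)
  expect_equal(g$n_masked, n_masked)
  expect_true(g$calibrated)
})
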
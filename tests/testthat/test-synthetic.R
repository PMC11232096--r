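test_that("profile sampling is reproducible and constraint-valid", {
  spec <- profile_spec(n_proteoforms = 100, seed = 9)
  t1 <- sample_profile(spec)
  t2 <- sample_profile(spec)
  expect_identical(t1, t2)
  k <- composition_constraints()
  ok <- vapply(seq_len(nrow(t1)), function(i) {
    validate_composition(glycan_composition(t1$H[i], t1$N[i], t1$F[i],
                                            t1$S[i]), k)$pass
  }, logical(1))
  expect_true(all(ok))
  # abundances are per-variant fractions
  sums <- tapply(t1$abundance, t1$variant, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("a degenerate spec yields the single specified proteoform", {
  spec <- profile_spec(variant_shares = c("AGP1*F1" = 1),
                       sa_distribution = c("16" = 1),
                       fucose_distribution = c("1" = 1),
                       antenna_distribution = c("27" = 1),
                       n_proteoforms = 1, seed = 1)
  t <- sample_profile(spec)
  expect_identical(nrow(t), 1L)
  expect_identical(t$composition, "H32N27F1S16")
  expect_equal(t$abundance, 1)
})

test_that("sampled distributions converge to their specification", {
  spec <- symmetric_sa_spec(n = 1000, seed = 31)
  truth <- sample_profile(spec)
  w <- truth$abundance * truth$variant_share
  mean_sa <- sum(truth$S * w) / sum(w)
  expect_equal(mean_sa, 16.0, tolerance = 0.2 / 16)
  # chi-square sanity check of the fucose distribution at n = 1000
  draws_per <- round(1000 * tapply(w / sum(w), truth$F, sum))
  counts <- rep(0, 5); names(counts) <- 0:4
  counts[names(draws_per)] <- draws_per
  p <- spec$fucose_distribution
  expect_gt(suppressWarnings(
    stats::chisq.test(counts, p = p)$p.value), 0.01)
})

test_that("infeasible sialylation constraints fail loudly", {
  spec <- profile_spec(sa_distribution = c("20" = 1),
                       antenna_distribution = triangular_weights(22, 25, 23),
                       n_proteoforms = 10, seed = 1)
  expect_error(sample_profile(spec), "sa_exceeds_antennae")
})

test_that("feature simulation reproduces the configured error model", {
  base <- data.frame(truth_id = 1L, variant = "AGP1*F1", H = 32L, N = 27L,
                     F = 0L, S = 16L, composition = "H32N27F0S16",
                     mods = "pyroglutamate",
                     theoretical_mass_Da = 35000.00, abundance = 1,
                     variant_share = 1)
  truth <- do.call(rbind, replicate(500, base, simplify = FALSE))
  truth$truth_id <- seq_len(nrow(truth))
  isp <- instrument_spec(mass_jitter_sd_Da = 0.2, seed = 13)
  f <- simulate_features(truth, isp)
  err <- f$mass_da - truth$theoretical_mass_Da
  expect_gt(stats::sd(err), 0.15)
  expect_lt(stats::sd(err), 0.25)
  # zero jitter and zero noise reproduce the theory exactly
  isp0 <- instrument_spec(mass_jitter_sd_Da = 0, area_noise_sd = 0,
                          seed = 13)
  f0 <- simulate_features(truth[1:3, ], isp0)
  expect_equal(f0$mass_da, truth$theoretical_mass_Da[1:3])
  expect_equal(f0$area, isp0$intensity_scale * truth$abundance[1:3] *
                 truth$variant_share[1:3])
})

test_that("near-isobars with different sialylation elute apart", {
  # H29N24F1S14 vs H31N26S12: 2.02 Da apart in mass, two SA counts apart
  truth <- data.frame(truth_id = 1:2, variant = "V1", H = c(29L, 31L),
                      N = c(24L, 26L), F = c(1L, 0L), S = c(14L, 12L),
                      composition = c("H29N24F1S14", "H31N26F0S12"),
                      mods = "pyroglutamate",
                      theoretical_mass_Da = c(33785.61, 33787.63),
                      abundance = 0.5, variant_share = 1)
  isp <- instrument_spec(seed = 17)
  f <- simulate_features(truth, isp)
  expect_gt(abs(diff(f$rt_min)), 4 * isp$rt_peak_sigma_min)
})

test_that("fixtures round-trip losslessly through disk", {
  spec <- profile_spec(n_proteoforms = 30, seed = 3)
  truth <- sample_profile(spec)
  isp <- instrument_spec(seed = 4)
  feats <- simulate_features(truth, isp)
  scans <- simulate_scans(truth[1:3, ], isp)
  dir <- withr::local_tempdir()
  paths <- write_fixture(truth, dir, features = feats, scans = scans)
  expect_true(all(file.exists(paths)))
  t2 <- read_truth_json(paths[["truth"]])
  expect_equal(t2$composition, truth$composition)
  expect_equal(t2$abundance, truth$abundance)
  shares <- tapply(truth$variant_share, truth$variant, `[`, 1)
  expect_equal(as.numeric(attr(t2, "variant_shares")[names(shares)]),
               as.numeric(shares))
  f2 <- read_features(paths[["features"]])
  expect_equal(f2$mass_da, feats$mass_da)
  s2 <- read_scan_csv(paths[["scans"]])
  expect_equal(s2$points, scans$points)
  # identical seeds give byte-identical scan CSVs
  scans_b <- simulate_scans(truth[1:3, ], isp)
  p2 <- file.path(dir, "scans2.csv")
  write_scan_csv(scans_b, p2)
  expect_identical(readLines(p2), readLines(paths[["scans"]]))
})

test_that("scan simulation inverts through the raw-signal chain", {
  truth <- data.frame(truth_id = 1L, variant = "V1", H = 29L, N = 24L,
                      F = 1L, S = 14L, composition = "H29N24F1S14",
                      mods = "pyroglutamate",
                      theoretical_mass_Da = 33785.6135, abundance = 1,
                      variant_share = 1)
  isp <- instrument_spec(mass_jitter_sd_Da = 0, area_noise_sd = 0,
                         noise_floor = 0, seed = 8)
  sc <- simulate_scans(truth, isp)
  win <- sa_windows_from_anchors(default_rt_anchor_map())
  f <- features_from_scans(sc, win)
  expect_identical(nrow(f), 1L)
  expect_equal(f$mass_da, 33785.6135, tolerance = 0.1)
  # area recovered within 1% of the injected amount
  expect_equal(f$area, isp$intensity_scale, tolerance = 0.01)
  # an acquisition range excluding every ladder position is refused
  isp_bad <- instrument_spec(mz_range = c(100, 200), seed = 8)
  expect_error(simulate_scans(truth, isp_bad), "acquisition range")
})

test_that("noise-only scans yield no assignments", {
  set.seed(77)
  pts <- data.frame(rt_min = rep(seq(16, 50, 0.5), each = 4),
                    mz = runif(276, 3000, 4500),
                    intensity = runif(276, 0, 5))
  sc <- scan_table(pts)
  win <- sa_windows_from_anchors(default_rt_anchor_map())
  f <- features_from_scans(sc, win)
  if (nrow(f)) {
    cal <- calibrate_rt_to_sa(default_rt_anchor_map()[, c("rt_min",
                                                          "sa_count")])
    asg <- assign_run(f, default_agp_registry(), composition_constraints(),
                      tol_Da = 1.0, calibration = cal, verbose = FALSE)
    expect_identical(sum(asg$status == "assigned"), 0L)
  } else {
    expect_identical(nrow(f), 0L)
  }
})

test_that("condition shifts tilt the distribution means as requested", {
  spec <- profile_spec(seed = 2)
  shifted <- condition_shift(spec, sa_mean_shift = 0.7,
                             antenna_mean_shift = 0.5,
                             afucosylated_shift = -0.05)
  mean_of <- function(w) sum(as.integer(names(w)) * w)
  expect_equal(mean_of(shifted$sa_distribution),
               mean_of(spec$sa_distribution) + 0.7, tolerance = 1e-6)
  expect_equal(mean_of(shifted$antenna_distribution),
               mean_of(spec$antenna_distribution) + 0.5, tolerance = 1e-6)
  expect_equal(shifted$fucose_distribution[["0"]],
               spec$fucose_distribution[["0"]] - 0.05)
  expect_equal(sum(shifted$fucose_distribution), 1)
  expect_error(condition_shift(spec, sa_mean_shift = 50), "support")
})
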
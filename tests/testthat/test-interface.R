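test_that("the native pipeline runs end to end and writes its bundle", {
  spec <- profile_spec(n_proteoforms = 60, seed = 5)
  truth <- sample_profile(spec)
  feats <- simulate_features(truth, instrument_spec(seed = 6))
  out <- withr::local_tempdir()
  cfg <- run_config(input = list(kind = "features", data = feats),
                    output_dir = out, workflow = "native",
                    condition = "standard", log_level = "quiet")
  res <- run_pipeline(cfg)
  expect_gt(res$counts$assigned, 0)
  sums <- tapply(res$quant$relative_abundance_percent,
                 paste(res$quant$variant, res$quant$condition), sum)
  expect_true(all(abs(sums - 100) < 1e-6))
  expect_true(all(file.exists(res$paths)))
  summ <- jsonlite::read_json(res$paths[["summary"]],
                              simplifyVector = TRUE)
  expect_identical(summ$workflow, "native")
  expect_identical(summ$counts$assigned, res$counts$assigned)
  # reruns with an identical config reproduce the tables exactly
  out2 <- withr::local_tempdir()
  cfg2 <- run_config(input = list(kind = "features", data = feats),
                     output_dir = out2, workflow = "native",
                     condition = "standard", log_level = "quiet")
  res2 <- run_pipeline(cfg2)
  expect_identical(readLines(res$paths[["quant"]]),
                   readLines(res2$paths[["quant"]]))
})

test_that("the desialylated workflow recovers variant shares", {
  spec <- profile_spec(sa_distribution = c("0" = 1),
                       n_proteoforms = 300, seed = 15)
  truth <- sample_profile(spec, constraints = composition_constraints())
  isp <- instrument_spec(
    variant_rt_map = c("AGP1*F1" = 10, "AGP1*F2" = 14, "AGP1*S" = 18,
                       "AGP2" = 22),
    rt_peak_sigma_min = 0.4, seed = 16)
  feats <- simulate_features(truth, isp)
  out <- withr::local_tempdir()
  cfg <- run_config(input = list(kind = "features", data = feats),
                    output_dir = out, workflow = "desialylated",
                    calibration = NULL, log_level = "quiet")
  res <- run_pipeline(cfg)
  rec <- unique(res$quant[, c("variant", "variant_share_percent")])
  truth_share <- 100 * tapply(truth$variant_share, truth$variant, `[`, 1)
  m <- merge(rec, data.frame(variant = names(truth_share),
                             true_share = as.numeric(truth_share)))
  expect_identical(nrow(m), length(truth_share))
  expect_lt(max(abs(m$variant_share_percent - m$true_share)), 2)
})

test_that("scan input flows through window deconvolution", {
  spec <- profile_spec(n_proteoforms = 15, seed = 25)
  truth <- sample_profile(spec)
  scans <- simulate_scans(truth, instrument_spec(seed = 26))
  out <- withr::local_tempdir()
  cfg <- run_config(input = list(kind = "scans", data = scans),
                    output_dir = out, log_level = "quiet")
  res <- run_pipeline(cfg)
  expect_gt(res$counts$assigned, 0)
  expect_gte(profile_recovery(res$quant, truth), 90)
})

test_that("invalid configuration is rejected before anything runs", {
  expect_error(run_config(input = list(kind = "nonsense", data = 1),
                          output_dir = "x"), "features|scans")
  expect_error(run_config(input = list(kind = "features", data = 1,
                                       typo = TRUE),
                          output_dir = "x"), "unknown input field")
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(workflow = "native", tolrance_Da = 2),
                       path, auto_unbox = TRUE)
  out <- file.path(withr::local_tempdir(), "never-created")
  expect_error(run_config_from_file(path), "unknown config key")
  expect_false(dir.exists(out))
})

test_that("config files round-trip through YAML", {
  spec <- profile_spec(n_proteoforms = 20, seed = 33)
  feats <- simulate_features(sample_profile(spec), instrument_spec(seed = 34))
  fdir <- withr::local_tempdir()
  fpath <- file.path(fdir, "features.csv")
  write_features(feats, fpath)
  cfgpath <- file.path(fdir, "run.yaml")
  yaml::write_yaml(list(input = list(kind = "features", path = fpath),
                        output_dir = file.path(fdir, "out"),
                        workflow = "native", tolerance_Da = 1.0,
                        log_level = "quiet"), cfgpath)
  cfg <- run_config_from_file(cfgpath)
  res <- run_pipeline(cfg)
  expect_gt(res$counts$assigned, 0)
})

test_that("run comparison reports zero deltas against itself and the
           generated contrast directions between shifted conditions", {
  base <- symmetric_sa_spec(n = 250, seed = 51)
  shifted <- condition_shift(base, sa_mean_shift = 0.7,
                             antenna_mean_shift = 0.4,
                             afucosylated_shift = -0.08, seed = 52)
  f1 <- simulate_features(sample_profile(base), instrument_spec(seed = 53))
  f2 <- simulate_features(sample_profile(shifted),
                          instrument_spec(seed = 54))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_pipeline(run_config(input = list(kind = "features", data = f1),
                                output_dir = d1, condition = "during",
                                log_level = "quiet"))
  r2 <- run_pipeline(run_config(input = list(kind = "features", data = f2),
                                output_dir = d2, condition = "after",
                                log_level = "quiet"))
  self <- compare_runs(r1, r1)
  expect_true(all(abs(self$d_mean_sa) < 1e-9))
  # shifted condition has higher sialylation and branching, lower
  # afucosylation: run1 - run2 deltas are negative / negative / positive
  cmp_dir <- withr::local_tempdir()
  d <- compare_runs(r1, r2, labels = c("during", "after"),
                    out_dir = cmp_dir)
  agg <- colMeans(d[, c("d_mean_sa", "d_mean_hexhexnac_units",
                        "d_pct_afucosylated")], na.rm = TRUE)
  expect_lt(agg[["d_mean_sa"]], 0)
  expect_lt(agg[["d_mean_hexhexnac_units"]], 0)
  expect_gt(agg[["d_pct_afucosylated"]], 0)
  expect_true(file.exists(file.path(cmp_dir, "comparison.tsv")))
  # comparison also works from the written output directories
  d_disk <- compare_runs(d1, d2, labels = c("during", "after"))
  expect_equal(d_disk$d_mean_sa, d$d_mean_sa, tolerance = 1e-6)
  expect_error(compare_runs(file.path(d1, "nope"), d2), "quant.tsv")
})
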
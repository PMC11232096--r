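test_that("enumeration finds exactly the candidates in a mass window", {
  reg <- fixture_registry()
  k <- composition_constraints()
  # zero-width window off every theoretical mass
  expect_identical(nrow(enumerate_candidates(reg, k, c(30000.5, 30000.5))),
                   0L)
  # the 14-sialic-acid window around 33785.61 holds one candidate
  got <- enumerate_candidates(reg, k, c(33785, 33786), sa_count = 14)
  expect_identical(got$composition, "H29N24F1S14")
  expect_equal(got$theoretical_mass_Da, 33785.61, tolerance = 0.01)
  # its 2 Da partner lives in the next window only at 12 sialic acids
  expect_identical(nrow(enumerate_candidates(reg, k, c(33785, 33786),
                                             sa_count = 12)), 0L)
  got12 <- enumerate_candidates(reg, k, c(33787, 33788), sa_count = 12)
  expect_identical(got12$composition, "H31N26F0S12")
  expect_equal(got12$theoretical_mass_Da, 33787.63, tolerance = 0.01)
})

test_that("enumeration equals the brute-force oracle on random registries", {
  set.seed(202)
  for (i in 1:30) {
    cs <- random_enumeration_case()
    got <- enumerate_candidates(cs$registry, cs$constraints, cs$window,
                                sa_count = cs$sa_count)
    want <- oracle_enumerate(cs$registry, cs$constraints, cs$window,
                             sa_count = cs$sa_count)
    expect_same_candidates(got, want)
  }
})

test_that("enumeration order is deterministic and stable", {
  reg <- default_agp_registry()
  k <- composition_constraints()
  a <- enumerate_candidates(reg, k, c(33000, 36000))
  b <- enumerate_candidates(reg, k, c(33000, 36000))
  expect_identical(a, b)
  ord <- order(a$variant, a$N, a$F, a$S)
  expect_identical(ord, seq_len(nrow(a)))
})

test_that("matching resolves the near-isobar pair only with the SA count", {
  reg <- fixture_registry()
  k <- composition_constraints()
  a <- match_feature(list(mass_da = 33785.61, sa_count = 14), reg, k,
                     tol_Da = 1.0, use_sa_constraint = TRUE)
  expect_identical(a$status, "assigned")
  expect_identical(a$top$composition, "H29N24F1S14")
  # without the chromatographic constraint the 2.02 Da pair co-survives
  b <- match_feature(list(mass_da = 33785.61, sa_count = 14), reg, k,
                     tol_Da = 2.5, use_sa_constraint = FALSE)
  expect_identical(b$status, "ambiguous")
  expect_true(all(c("H29N24F1S14", "H31N26F0S12") %in%
                    b$candidates$composition))
  # far below every candidate
  u <- match_feature(list(mass_da = 5000), reg, k, tol_Da = 1.0)
  expect_identical(u$status, "unassigned")
})

test_that("the SA constraint never increases the candidate count", {
  reg <- default_agp_registry()
  k <- composition_constraints()
  set.seed(7)
  for (i in 1:20) {
    mass <- runif(1, 33000, 38000)
    sa <- sample(10:19, 1)
    with_sa <- match_feature(list(mass_da = mass, sa_count = sa), reg, k,
                             tol_Da = 2.5, use_sa_constraint = TRUE)
    without <- match_feature(list(mass_da = mass, sa_count = sa), reg, k,
                             tol_Da = 2.5, use_sa_constraint = FALSE)
    expect_lte(nrow(with_sa$candidates), nrow(without$candidates))
  }
})

test_that("assign_run round-trips synthetic features through the truth", {
  spec <- profile_spec(n_proteoforms = 50, seed = 21)
  truth <- sample_profile(spec)
  feats <- simulate_features(truth, instrument_spec(mass_jitter_sd_Da = 0.2,
                                                    seed = 22))
  cal <- calibrate_rt_to_sa(default_rt_anchor_map()[, c("rt_min",
                                                        "sa_count")])
  asg <- assign_run(feats, default_agp_registry(),
                    composition_constraints(), tol_Da = 1.0,
                    calibration = cal, verbose = FALSE)
  expect_identical(nrow(asg), nrow(feats))
  acc <- assignment_accuracy(asg, attr(feats, "truth_map"))
  expect_gte(acc, 0.95)
  # disabling the SA constraint strictly increases ambiguity here
  asg2 <- assign_run(feats, default_agp_registry(),
                     composition_constraints(), tol_Da = 1.0,
                     use_sa_constraint = FALSE, verbose = FALSE)
  expect_gt(sum(asg2$status == "ambiguous"),
            sum(asg$status == "ambiguous"))
})

test_that("assign_run handles empty and degenerate inputs", {
  reg <- fixture_registry()
  k <- composition_constraints()
  empty <- assign_run(data.frame(rt_min = numeric(0), mass_da = numeric(0),
                                 area = numeric(0)),
                      reg, k, verbose = FALSE)
  expect_identical(nrow(empty), 0L)
  bad <- assign_run(data.frame(rt_min = 20, mass_da = NaN, area = 1),
                    reg, k, verbose = FALSE)
  expect_identical(bad$status, "rejected")
  expect_match(bad$reason, "non-finite")
})

test_that("desialylated mode forces S = 0 and uses retention clusters", {
  reg <- bare_registry()  # 20000.00 and 20150.00, no modifications
  k <- composition_constraints()
  m <- composition_mass("H32N27F0S0")
  f <- data.frame(rt_min = 10, mass_da = 20000.00 + m, area = 1)
  asg <- assign_desialylated(f, reg, k, tol_Da = 1.0, verbose = FALSE)
  expect_identical(asg$status, "assigned")
  expect_identical(asg$variant, "V1")
  expect_identical(asg$composition, "H32N27F0S0")
  # constructed collision: identical backbone masses, ambiguous without
  # clusters, resolved by the retention cluster
  twin <- bare_registry(c(A = 20000.00, B = 20000.00))
  f2 <- data.frame(rt_min = 12, mass_da = 20000.00 + m, area = 1)
  amb <- assign_desialylated(f2, twin, k, tol_Da = 1.0, verbose = FALSE)
  expect_identical(amb$status, "ambiguous")
  res <- assign_desialylated(f2, twin, k, tol_Da = 1.0,
                             rt_clusters = data.frame(rt_lo = 11, rt_hi = 13,
                                                      variant = "B"),
                             verbose = FALSE)
  expect_identical(res$status, "assigned")
  expect_identical(res$variant, "B")
  # no features in, none out
  none <- assign_desialylated(data.frame(rt_min = numeric(0),
                                         mass_da = numeric(0),
                                         area = numeric(0)),
                              reg, k, verbose = FALSE)
  expect_identical(nrow(none), 0L)
})

test_that("ambiguity report names the gap and the resolving constraint", {
  reg <- fixture_registry()
  k <- composition_constraints()
  # an all-unique run reports nothing
  f_ok <- data.frame(rt_min = 30, mass_da = 33785.61, area = 1,
                     sa_count = 14)
  asg_ok <- assign_run(f_ok, reg, k, tol_Da = 1.0, verbose = FALSE)
  expect_identical(nrow(ambiguity_report(asg_ok)), 0L)
  # the two-fucose/one-sialic-acid pair: top two candidates 1.02 Da apart
  pair_mid <- (33785.6135 + 2 * 146.14 - 291.26 + 33785.6135) / 2
  f <- data.frame(rt_min = 30, mass_da = pair_mid, area = 1)
  asg <- assign_run(f, reg, k, tol_Da = 2.5, use_sa_constraint = FALSE,
                    verbose = FALSE)
  rep <- ambiguity_report(asg)
  expect_identical(nrow(rep), 1L)
  expect_equal(rep$delta_pair_Da, 1.02, tolerance = 0.01)
  expect_identical(rep$hint, "sa_count")
  # exact isobars on two variants of equal configured mass
  twin <- bare_registry(c(A = 20000.00, B = 20000.00))
  f3 <- data.frame(rt_min = 5, mass_da = 20000.00 + composition_mass("H32N27F0S0"),
                   area = 1)
  asg3 <- assign_desialylated(f3, twin, k, tol_Da = 1.0, verbose = FALSE)
  rep3 <- ambiguity_report(asg3)
  expect_identical(rep3$hint, "unresolvable isobar")
})
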
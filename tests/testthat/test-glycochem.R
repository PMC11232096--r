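test_that("composition masses follow the average-mass residue table", {
  t <- residue_mass_table()
  expect_equal(composition_mass("H1N0F0S0", t), 162.14)
  expect_equal(composition_mass("H0N0F0S0", t), 0)
  # hand arithmetic: 29*162.14 + 24*203.20 + 1*146.14 + 14*291.26
  expect_equal(composition_mass("H29N24F1S14", t), 13802.64)
  expect_equal(composition_mass("H31N26F0S12", t), 13804.66)
  # the pair that differs by 2 Da on the intact protein
  expect_equal(composition_mass("H31N26F0S12", t) -
                 composition_mass("H29N24F1S14", t), 2.02)
})

test_that("composition construction and parsing are strict and canonical", {
  c1 <- glycan_composition(29, 24, 1, 14)
  expect_s3_class(c1, "GlycanComposition")
  expect_identical(format(c1), "H29N24F1S14")
  expect_true(parse_composition("H29N24F1S14") == c1)
  expect_error(glycan_composition(-1, 0, 0, 0), "non-negative")
  expect_error(glycan_composition(1.5, 0, 0, 0), "integer")
  expect_error(parse_composition("H2N1"), "canonical")
  add <- c1 + glycan_composition(1, 2, 0, 1)
  expect_identical(format(add), "H30N26F1S15")
})

test_that("composition mass is additive and strictly monotone", {
  t <- residue_mass_table()
  set.seed(11)
  for (i in 1:25) {
    a <- glycan_composition(sample(0:40, 1), sample(0:40, 1),
                            sample(0:4, 1), sample(0:20, 1))
    b <- glycan_composition(sample(0:40, 1), sample(0:40, 1),
                            sample(0:4, 1), sample(0:20, 1))
    expect_equal(composition_mass(a, t) + composition_mass(b, t),
                 composition_mass(a + b, t))
  }
  base <- glycan_composition(10, 10, 1, 5)
  for (field in c("H", "N", "F", "S")) {
    up <- base
    up[[field]] <- up[[field]] + 1L
    expect_gt(composition_mass(up, t), composition_mass(base, t))
  }
})

test_that("two fucoses and one sialic acid are near-isobaric (~1 Da)", {
  t <- residue_mass_table()
  gap <- abs(2 * t$fucose_Da - t$neuac_Da)
  expect_equal(gap, 1.02)
  expect_lt(gap, 2)  # below any realistic intact-protein tolerance
})

test_that("backbone mass from sequence sums residues plus one water", {
  expect_equal(backbone_mass_from_sequence("G"), 75.07, tolerance = 1e-4)
  expect_equal(backbone_mass_from_sequence(""), 18.02, tolerance = 1e-3)
  expect_equal(backbone_mass_from_sequence("GG"), 132.12, tolerance = 1e-4)
  err <- expect_error(backbone_mass_from_sequence("GXZG"), "position 2")
  expect_match(conditionMessage(err), "'X'")
})

test_that("modification deltas reproduce the ammonia loss and cysteine gain", {
  expect_equal(modification_delta("pyroglutamate"), -17.03, tolerance = 0.005)
  expect_equal(modification_delta("cysteinylation"), 119.14, tolerance = 0.005)
  expect_equal(modification_delta("none"), 0)
  expect_error(modification_delta("phospho"), "unknown modification")
})

test_that("proteoform mass is the strict sum of backbone, glycans and mods", {
  reg <- fixture_registry()
  bare <- proteoform_candidate("V1", "H0N0F0S0", mods = character(0),
                               registry = reg)
  expect_equal(bare$theoretical_mass_Da, 20000.00)
  p <- proteoform_candidate("V1", "H29N24F1S14", registry = reg)
  expect_equal(p$theoretical_mass_Da, 33785.61, tolerance = 0.01)
  # ordering of modifications never matters
  reg2 <- variant_registry(list(
    backbone_variant("AGP2", 20000.00,
                     modifications = c("pyroglutamate", "cysteinylation"))))
  p1 <- proteoform_candidate("AGP2", "H0N0F0S0",
                             mods = c("pyroglutamate", "cysteinylation"),
                             registry = reg2)
  p2 <- proteoform_candidate("AGP2", "H0N0F0S0",
                             mods = c("cysteinylation", "pyroglutamate"),
                             registry = reg2)
  expect_equal(p1$theoretical_mass_Da, p2$theoretical_mass_Da)
  expect_equal(p1$theoretical_mass_Da, 20102.11, tolerance = 0.01)
})

test_that("inapplicable modifications are rejected", {
  reg <- fixture_registry()  # V1 does not declare a free cysteine
  expect_error(
    proteoform_candidate("V1", "H0N0F0S0", mods = "cysteinylation",
                         registry = reg),
    "not applicable")
})

test_that("composition validation enforces every structural rule", {
  k <- composition_constraints()
  expect_true(validate_composition("H32N27F0S16", k)$pass)
  r1 <- validate_composition("H32N26F0S16", k)
  expect_false(r1$pass)
  expect_identical(r1$reasons, "hex_hexnac_offset")
  # core-only composition has zero antennae: no sialic acid is placeable
  r2 <- validate_composition("H15N10F0S1", k)
  expect_false(r2$pass)
  expect_true("sa_exceeds_antennae" %in% r2$reasons)
  r3 <- validate_composition(glycan_composition(14, 9, 5, 30), k)
  expect_setequal(r3$reasons, c("n_below_core", "sa_exceeds_antennae",
                                "fucose_above_max", "sa_out_of_range"))
  # disabling a rule removes exactly that rule
  k2 <- composition_constraints(enforce_sa_le_antennae = FALSE, sa_max = 30)
  expect_true(validate_composition("H15N10F0S1", k2)$pass)
})

test_that("backbone variant checks sequence mass agreement", {
  v <- backbone_variant("X", sequence = "GG")
  expect_equal(v$backbone_mass_Da, 132.12, tolerance = 1e-3)
  expect_error(backbone_variant("X", backbone_mass_Da = 132.20,
                                sequence = "GG"), "disagrees")
  expect_silent(backbone_variant("X", backbone_mass_Da = 132.119,
                                 sequence = "GG"))
})

test_that("registries load from JSON with overrides", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(
    residue_masses = list(hexose_Da = 162.0528),
    variants = list(
      list(name = "A", backbone_mass_Da = 21000.5,
           modifications = list("pyroglutamate"), prior_abundance = 0.9),
      list(name = "B", sequence = "GG", modifications = list("none"))
    )), path, auto_unbox = TRUE)
  reg <- registry_from_json(path)
  expect_named(reg$variants, c("A", "B"))
  expect_equal(reg$variants$A$backbone_mass_Da, 21000.5)
  expect_equal(reg$variants$B$backbone_mass_Da, 132.12, tolerance = 1e-3)
  # the shipped synthetic registry mirrors the built-in default
  shipped <- registry_from_json(system.file("extdata",
                                            "agp_registry_synthetic.json",
                                            package = "aexms"))
  def <- default_agp_registry()
  expect_named(shipped$variants, names(def$variants))
  for (nm in names(def$variants)) {
    expect_equal(shipped$variants[[nm]]$backbone_mass_Da,
                 def$variants[[nm]]$backbone_mass_Da)
  }
})
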
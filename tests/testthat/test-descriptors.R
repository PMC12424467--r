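# Physicochemical descriptors, EMDs and the 13-slot feature vector.

test_that("monoisotopic masses match the frozen independent oracle", {
  exp <- descriptor_expected()
  for (i in seq_len(nrow(exp))) {
    mol <- parse_smiles(exp$smiles[i])
    expect_equal(mol_monoisotopic_mass(mol), exp$mass[i],
                 tolerance = 1e-6, info = exp$name[i])
  }
})

test_that("HBD / HBA / TPSA match the frozen independent oracle", {
  exp <- descriptor_expected()
  for (i in seq_len(nrow(exp))) {
    pc <- compute_physchem(compound_record(exp$name[i], exp$smiles[i]))
    expect_equal(pc$hbd, exp$hbd[i], info = exp$name[i])
    expect_equal(pc$hba, exp$hba[i], info = exp$name[i])
    expect_equal(pc$tpsa, exp$tpsa[i], tolerance = 0.011,
                 info = exp$name[i])
  }
})

test_that("water and benzene hand checks hold", {
  w <- compute_physchem(compound_record("w", "O"))
  expect_equal(w$mw, 2 * 1.00782503207 + 15.9949146196, tolerance = 1e-9)
  expect_gte(w$hbd, 1)
  b <- compute_physchem(compound_record("b", "c1ccccc1"))
  expect_equal(b$hbd, 0)
  expect_equal(b$tpsa, 0)
})

test_that("precomputed values pass through verbatim, field by field", {
  rec <- compound_record("p", "CCO",
                         precomputed = list(mw = 123.4, xlogp = -1.1,
                                            tpsa = 55, hbd = 2, hba = 3))
  pc <- compute_physchem(rec)
  expect_equal(pc$mw, 123.4)
  expect_equal(pc$xlogp, -1.1)
  expect_equal(unname(pc$provenance), rep("precomputed", 5))

  # partial precomputation: only the missing fields are computed
  rec2 <- compound_record("q", "CCO", precomputed = list(mw = 50))
  pc2 <- compute_physchem(rec2)
  expect_equal(pc2$mw, 50)
  expect_equal(pc2$provenance[["mw"]], "precomputed")
  expect_equal(pc2$provenance[["xlogp"]], "surrogate")
  expect_equal(pc2$provenance[["tpsa"]], "computed")
})

test_that("unparseable SMILES raise a parse error carrying the id", {
  err <- expect_error(
    compute_physchem(compound_record("bad1", "C((C")),
    class = "mcl_parse_error")
  expect_equal(err$id, "bad1")
})

test_that("EMD units parse formulas and match hand-computed masses", {
  u <- emd_unit("CH2")
  expect_equal(u$exact_mass, 12 + 2 * 1.00782503207, tolerance = 1e-9)
  expect_equal(u$nominal_mass, 14L)
  expect_equal(emd_unit("CCl")$exact_mass, 46.96885268, tolerance = 1e-6)
  expect_equal(emd_unit("CN")$exact_mass, 26.0030740048, tolerance = 1e-9)
  expect_error(emd_unit("Xx2"), class = "mcl_config_error")
  expect_length(default_emd_units(), 6L)
})

test_that("EMD is zero at exact unit multiples and matches the formula", {
  for (lab in names(default_emd_units())) {
    u <- emd_unit(lab)
    for (k in c(1, 3, 17)) {
      expect_equal(elemental_mass_defect(k * u$exact_mass, u), 0,
                   tolerance = 1e-9, info = lab)
    }
  }
  # hexane against an independent recomputation from the mass table
  u <- emd_unit("CH2")
  mass <- formula_mass(c(C = 6, H = 14))
  scaled <- mass * 14L / (12 + 2 * 1.00782503207)
  expect_equal(elemental_mass_defect(mass, u), round(scaled) - scaled,
               tolerance = 1e-12)
})

test_that("CH2 homologues share the same defect; periodicity; range", {
  u <- emd_unit("CH2")
  hex <- mol_monoisotopic_mass(parse_smiles("CCCCCC"))
  hep <- mol_monoisotopic_mass(parse_smiles("CCCCCCC"))
  expect_equal(elemental_mass_defect(hex, u),
               elemental_mass_defect(hep, u), tolerance = 1e-9)
  # periodicity and range over random masses and every default unit
  set.seed(11)
  masses <- runif(200, 20, 1500)
  for (un in default_emd_units()) {
    d0 <- elemental_mass_defect(masses, un)
    d1 <- elemental_mass_defect(masses + un$exact_mass, un)
    expect_equal(d0, d1, tolerance = 1e-9, info = un$label)
    expect_true(all(d0 > -0.5 & d0 <= 0.5), info = un$label)
  }
  expect_error(elemental_mass_defect(-1, u), class = "mcl_domain_error")
})

test_that("assemble_features has a fixed, input-order-independent layout", {
  rec <- compound_record("z", "CCO")
  pc <- structure(list(mw = 0, xlogp = 0, tpsa = 0, hbd = 0, hba = 0,
                       provenance = NULL), class = "physchem")
  emds <- setNames(rep(0, 6), names(default_emd_units()))
  v <- assemble_features(rec, pc, emds, mobility_class = 2, log_ie = 0)
  expect_length(v, 13L)
  expect_equal(names(v), feature_names())
  expect_equal(unname(v[12:13]), c(2, 0))

  # shuffled EMD input order yields the identical vector
  v2 <- assemble_features(rec, pc, emds[c(4, 1, 6, 2, 5, 3)],
                          mobility_class = 2, log_ie = 0)
  expect_identical(v, v2)

  err <- expect_error(
    assemble_features(rec, pc, emds, mobility_class = 2, log_ie = NA),
    class = "mcl_assembly_error")
  expect_match(conditionMessage(err), "log_ie")
  expect_match(conditionMessage(err), "z")
})

test_that("featurize_table drops bad SMILES with one warning, strict fatal", {
  recs <- list(
    compound_record("ok1", "CCO", precomputed = list(mobility_class = 1,
                                                     log_ie = 2)),
    compound_record("bad", "C((C", precomputed = list(mobility_class = 2,
                                                      log_ie = 2)),
    compound_record("ok2", "O", precomputed = list(mobility_class = 3,
                                                   log_ie = 2)))
  expect_warning(tab <- featurize_table(recs), "1 record")
  expect_equal(tab$id, c("ok1", "ok2"))
  expect_equal(ncol(tab), 14L)  # id + 13 variables
  expect_error(suppressWarnings(featurize_table(recs, strict = TRUE)),
               class = "mcl_parse_error")
})
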
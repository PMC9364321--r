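# Ligand preparation: validation, protonation, embedding, charges, PDBQT.

test_that("validation accepts ordinary molecules and rejects by reason", {
  expect_true(validate_ligand("CCO"))
  expect_true(validate_ligand("CC(=O)Oc1ccccc1C(=O)O"))

  v <- validate_ligand("CC.Cl")
  expect_true(is_rejected(v))
  expect_identical(v$code, "MULTI_FRAGMENT")

  v <- validate_ligand("[CH3]")
  expect_true(is_rejected(v))
  expect_identical(v$code, "RADICAL")

  v <- validate_ligand("C[O]")            # methoxy radical
  expect_identical(v$code, "RADICAL")

  v <- validate_ligand("this is not smiles")
  expect_identical(v$code, "UNPARSEABLE")
  expect_identical(validate_ligand("")$code, "UNPARSEABLE")

  # hypervalent but closed-shell groups are not radicals
  expect_true(validate_ligand("CS(=O)(=O)C"))
  expect_true(validate_ligand("C[N+](=O)[O-]"))
})

test_that("protonation reflects the pH 7.4 majority microstate and is idempotent", {
  can <- function(s) canonical_smiles(s)
  # carboxylic acid (pKa ~4.8) deprotonates
  expect_identical(can(adjust_protonation("CC(=O)O")), can("CC(=O)[O-]"))
  # aliphatic amine (pKa ~10.6) protonates
  expect_identical(can(adjust_protonation("CCN")), can("CC[NH3+]"))
  # no ionizable group: unchanged
  expect_identical(can(adjust_protonation("c1ccccc1")), can("c1ccccc1"))

  # idempotence on a panel with assorted ionizable groups
  for (s in c("CC(=O)O", "CCN", "c1ccccc1", "NCC(=O)O", "CSc1ccccc1",
              "OC(=O)c1ccccc1N")) {
    once <- adjust_protonation(s)
    expect_identical(adjust_protonation(once), once, label = s)
  }
})

test_that("conformer embedding is deterministic and preserves stereocenters", {
  e1 <- embed_conformer("CC(=O)Oc1ccccc1C(=O)O", seed = 0L)
  e2 <- embed_conformer("CC(=O)Oc1ccccc1C(=O)O", seed = 0L)
  expect_false(is_rejected(e1))
  expect_identical(e1$coords, e2$coords)

  # defined stereocenter survives the 3D pipeline
  p <- prepare_ligand("C[C@H](N)C(=O)O")
  expect_s3_class(p, "prepared_ligand")
  expect_match(p$canonical_smiles, "@")

  # undefined stereocenter: identical assignment across runs
  u1 <- prepare_ligand("CC(N)C(=O)O")
  u2 <- prepare_ligand("CC(N)C(=O)O")
  expect_identical(u1$pdbqt, u2$pdbqt)
})

test_that("full preparation is byte-identical across invocations on a library", {
  lib <- fixture_library(12L)
  r1 <- prepare_library(lib)
  r2 <- prepare_library(lib)
  expect_identical(
    lapply(r1$prepared, `[[`, "pdbqt"),
    lapply(r2$prepared, `[[`, "pdbqt")
  )
  expect_gt(length(r1$prepared), 0L)
})

test_that("partial charges sum to the net formal charge within 0.01 e", {
  # neutral, cationic, anionic
  for (s in c("C", "CCO", "c1ccccc1", "[NH4+]", "CC(=O)[O-]")) {
    p <- prepare_ligand(s, engine = identity)   # skip pH shifts: test as-is
    expect_s3_class(p, "prepared_ligand")
    expect_lt(abs(sum(p$partial_charges) - p$net_charge), 0.01, label = s)
  }
  # and across a prepared fixture library (with pH adjustment on)
  r <- prepare_library(fixture_library(12L))
  for (p in r$prepared) {
    expect_lt(abs(sum(p$partial_charges) - p$net_charge), 0.01,
              label = p$canonical_smiles)
  }
})

test_that("symmetry-equivalent hydrogens of methane carry equal charge", {
  p <- prepare_ligand("C", engine = identity)
  h <- p$partial_charges[p$atom_elements == "H"]
  if (length(h) > 1L) expect_lt(diff(range(h)), 1e-6)
  # carbon charge balances the hydrogens
  expect_lt(abs(sum(p$partial_charges)), 0.01)
})

test_that("PDBQT serialization conserves heavy atoms and declares torsions", {
  p <- prepare_ligand("CCO")
  at <- sum(!(p$atom_elements %in% "H"))
  expect_identical(at, 3L)

  rigid <- prepare_ligand("c1ccccc1")
  expect_identical(pdbqt_torsion_count(rigid$pdbqt), 0L)

  # butane: torsion count in the PDBQT matches the rotatable-bond profile
  but <- prepare_ligand("CCCC")
  rb <- property_profile("CCCC")$RB
  expect_identical(pdbqt_torsion_count(but$pdbqt), as.integer(rb))
})

test_that("planted defects are rejected in exact numbers", {
  k <- 3L; m <- 2L
  lib <- generate_library(library_spec(30L, seed = 5L, n_radicals = k,
                                       n_multi_fragment = m))
  verdicts <- lapply(lib, validate_ligand)
  rejected <- Filter(is_rejected, verdicts)
  expect_length(rejected, k + m)
  codes <- vapply(rejected, `[[`, character(1), "code")
  expect_identical(sum(codes == "RADICAL"), as.integer(k))
  expect_identical(sum(codes == "MULTI_FRAGMENT"), as.integer(m))
})
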
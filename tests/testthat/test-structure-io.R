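make_pdb_lines <- function() c(
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 20.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00 20.00           C",
  "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00 20.00           C",
  "ATOM      4  N   GLY A   2       3.332   1.536   0.000  1.00 21.00           N",
  "ATOM      5  CA  GLY A   2       4.023   2.810   0.000  1.00 21.00           C",
  "ATOM      6  C   GLY A   2       5.530   2.600   0.000  1.00 21.00           C",
  "ATOM      7  N   PRO A   3       6.270   3.700   0.000  1.00 22.00           N",
  "ATOM      8  CA  PRO A   3       7.720   3.640   0.000  1.00 22.00           C",
  "ATOM      9  C   PRO A   3       8.320   5.040   0.000  1.00 22.00           C",
  "TER",
  "HETATM   10  O   HOH A 101      12.000  12.000  12.000  1.00 30.00           O",
  "END")

test_that("a minimal hand-written PDB parses into chains, residues and het flags", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(make_pdb_lines(), tf)
  s <- readStructure(tf)
  expect_s4_class(s, "MacroStructure")
  expect_identical(chainIds(s), "A")
  expect_identical(polymerResidueCount(s), 3L)
  expect_identical(sum(atomRecords(s)$het), 1L)  # the water, flagged not dropped
  expect_identical(chainSequence(s, "A"), "AGP")
})

test_that("water-only files are rejected as empty structures", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "HETATM    1  O   HOH A 101      12.000  12.000  12.000  1.00 30.00           O",
    "END"), tf)
  expect_error(readStructure(tf), "empty structure")
  expect_error(readStructure(tempfile(fileext = ".pdb")), "not found")
})

test_that("altloc conformers collapse to highest occupancy, ties by letter", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40 20.00           N",
    "ATOM      2  N  BALA A   1       9.000   0.000   0.000  0.60 20.00           N",
    "ATOM      3  CA AALA A   1       1.458   0.000   0.000  0.50 20.00           C",
    "ATOM      4  CA BALA A   1       8.000   0.000   0.000  0.50 20.00           C",
    "ATOM      5  C   ALA A   1       2.009   1.420   0.000  1.00 20.00           C",
    "END"), tf)
  s <- readStructure(tf)
  a <- atomRecords(s)
  expect_identical(nrow(a), 3L)
  expect_equal(a$x[a$atom == "N"], 9.0)    # occupancy 0.6 wins
  expect_equal(a$x[a$atom == "CA"], 1.458) # tie -> altloc A
})

test_that("mmCIF atom_site loops parse equivalently to PDB", {
  cif <- c(
    "data_test", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "ATOM 1 N N . ALA A 1 ? 0.000 0.000 0.000 1.00 20.00",
    "ATOM 2 C CA . ALA A 1 ? 1.458 0.000 0.000 1.00 20.00",
    "ATOM 3 C C . ALA A 1 ? 2.009 1.420 0.000 1.00 20.00",
    "HETATM 4 O O . HOH A 101 ? 9.0 9.0 9.0 1.00 30.00", "#")
  tf <- tempfile(fileext = ".cif")
  writeLines(cif, tf)
  s <- readStructure(tf)
  expect_identical(polymerResidueCount(s), 1L)
  expect_identical(sum(atomRecords(s)$het), 1L)
  expect_equal(atomRecords(s)$x[2], 1.458)
  bad <- tempfile(fileext = ".cif")
  writeLines("data_empty", bad)
  expect_error(readStructure(bad, format = "mmcif"), "mmCIF")
})

test_that("structures built in code round-trip through PDB text", {
  s <- buildPeptide("AGPAW", phi = -70, psi = 140,
                    omega = c(180, 180, 0, 180, 180), bfactor = 1:5)
  tf <- tempfile(fileext = ".pdb")
  writeStructurePDB(s, tf)
  back <- readStructure(tf)
  expect_identical(chainSequence(back, "A"), "AGPAW")
  tol_tor <- backboneTorsions(back, "A")
  expect_equal(tol_tor$omega[3], 0, tolerance = 0.1)  # PDB keeps 3 decimals
  expect_equal(atomRecords(back)$b[1], 1)
})

test_that("torsions honour termini, missing atoms, and chain breaks", {
  s <- buildPeptide("AG", phi = -57, psi = -47, omega = 180)
  tor <- backboneTorsions(s, "A")
  expect_true(is.na(tor$phi[1]) && is.na(tor$omega[1]))
  expect_true(is.na(tor$psi[2]))
  expect_false(is.na(tor$psi[1]) || is.na(tor$phi[2]))

  # translate the second half far away: break in the middle
  broken <- buildPeptide("AAAA", phi = -57, psi = -47, omega = 180)
  a <- atomRecords(broken)
  shift <- a$resno >= 3
  a$x[shift] <- a$x[shift] + 50
  broken@atoms <- a
  torb <- backboneTorsions(broken, "A")
  expect_true(is.na(torb$omega[3]) && is.na(torb$phi[3]) && is.na(torb$psi[2]))
  expect_false(is.na(torb$omega[2]))
  expect_error(backboneTorsions(broken, "Z"), "chain not found")
})
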
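test_that("a minimal one-atom file round-trips with no unit cell", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  SG  CYS A   2       1.000   2.000   3.000  1.00 10.00           S",
    "END"), f)
  s <- read_structure(f)
  expect_equal(nrow(s), 1)
  expect_equal(s$elety, "SG")
  expect_equal(s$resno, 2)
  expect_null(unit_cell(s))
  expect_equal(as.numeric(coords(s)), c(1, 2, 3))
})

test_that("write/read round-trip preserves counts, names and coordinates", {
  s <- backbone_from_dihedrals(rep(-120, 6), rep(130, 6),
                               sequence = "ACXDGY")   # includes Aib as X
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f)
  expect_equal(nrow(s2), nrow(s))
  expect_equal(s2$elety, s$elety)
  expect_equal(s2$resid, s$resid)
  expect_true("AIB" %in% s2$resid)
  expect_lt(max(abs(coords(s2) - coords(s))), 1e-3)
})

test_that("metals and unit cell survive a round trip", {
  s <- ideal_site()
  s2 <- as_structure(s, cell = c(30, 40, 50, 90, 90, 90),
                     space_group = "C 2 2 21")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s2, f)
  s3 <- read_structure(f)
  expect_equal(sum(s3$record == "HETATM"), 1)
  expect_equal(s3$elesy[s3$record == "HETATM"], "ZN")
  expect_equal(unit_cell(s3)[1:3], c(30, 40, 50))
  expect_equal(length(sym_ops(s3)), 8)   # C2221 with centering
})

test_that("altloc handling keeps the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA ACYS A   2      10.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BCYS A   2      20.000   0.000   0.000  0.60 10.00           C",
    "END"), f)
  s <- read_structure(f)
  expect_equal(nrow(s), 1)
  expect_equal(s$x, 20)
})

test_that("empty and oversized writes are refused", {
  empty <- as_structure(tibble::tibble(elety = character(), resid = character(),
                                       chain = character(), resno = integer(),
                                       x = numeric(), y = numeric(), z = numeric()))
  expect_error(write_structure(empty, tempfile()), "empty")
  big <- as_structure(tibble::tibble(
    elety = "CA", resid = "ALA", chain = "A", resno = seq_len(100000),
    x = 0, y = 0, z = 0))
  expect_error(write_structure(big, tempfile()), "99999")
})

test_that("unreadable and unknown-format input raises parse errors", {
  expect_error(read_structure(tempfile()), "not found")
})

test_that("mmCIF atom_site and cell/symmetry categories are read", {
  f <- withr::local_tempfile(fileext = ".cif")
  writeLines(c(
    "data_test",
    "_cell.length_a 30.0", "_cell.length_b 40.0", "_cell.length_c 50.0",
    "_cell.angle_alpha 90.0", "_cell.angle_beta 90.0", "_cell.angle_gamma 90.0",
    "_symmetry.space_group_name_H-M 'P 21'",
    "loop_",
    "_symmetry_equiv.pos_as_xyz",
    "  'x,y,z'",
    "  '-x,y+1/2,-z'",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x", "_atom_site.Cartn_y",
    "_atom_site.Cartn_z", "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . CYS A 1 2 ? 1.000 2.000 3.000 1.00 10.00 ? 2 CYS A CA 1",
    "ATOM 2 S SG . CYS A 1 2 ? 2.500 2.000 3.000 1.00 10.00 ? 2 CYS A SG 1"), f)
  s <- read_structure(f)
  expect_equal(nrow(s), 2)
  expect_equal(s$resno, c(2, 2))
  expect_equal(unit_cell(s)[1:3], c(30, 40, 50))
  expect_equal(length(sym_ops(s)), 2)
})

test_that("symmetry operator parsing matches hand-built matrices", {
  op <- parse_symop("-x,y,-z+1/2")
  expect_equal(op$R, matrix(c(-1, 0, 0, 0, 1, 0, 0, 0, -1), 3, 3, byrow = TRUE))
  expect_equal(op$t, c(0, 0, 0.5))
  expect_error(parse_symop("x,q,z"), "cannot parse")
})

test_that("P1 with a large cell yields no symmetry mates within 5 A", {
  s <- as_structure(tibble::tibble(elety = "CA", resid = "ALA", chain = "A",
                                   resno = 1L, x = 50, y = 50, z = 50),
                    cell = c(100, 100, 100, 90, 90, 90), space_group = "P 1")
  expect_length(expand_symmetry(s, radius = 5), 0)
})

test_that("symmetry mates match the hand-applied operator and are rigid", {
  atoms <- tibble::tibble(
    elety = c("CA", "CB", "SG"), resid = "CYS", chain = "A", resno = 1L,
    x = c(1, 2.2, 3.1), y = c(2, 2.8, 4.0), z = c(3, 4.1, 4.9))
  cell <- c(10, 12, 14, 90, 90, 90)
  s <- as_structure(atoms, cell = cell, sym_ops = list(
    parse_symop("x,y,z"), parse_symop("-x,y,-z+1/2")))
  mates <- expand_symmetry(s, radius = 50)
  expect_gt(length(mates), 0)
  # hand-apply (-x, y, -z+1/2) with zero lattice shift, orthorhombic cell
  hand <- cbind(-atoms$x, atoms$y, cell[3] / 2 - atoms$z)
  found <- FALSE
  for (m in mates) {
    if (max(abs(coords(m) - hand)) < 1e-6) found <- TRUE
    expect_rigid_copy(coords(s), coords(m), tol = 1e-6)
  }
  expect_true(found)
})

test_that("expand_symmetry requires cell and operators", {
  s <- as_structure(tibble::tibble(elety = "CA", resid = "A", chain = "A",
                                   resno = 1L, x = 0, y = 0, z = 0))
  expect_error(expand_symmetry(s), "unit cell")
})
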
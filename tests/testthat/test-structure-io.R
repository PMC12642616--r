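test_that("write-then-read round-trips coordinates at PDB precision", {
  g <- make_groove(groove_spec(length = 12, inner_radius = 8,
                               lattice_spacing = 2, jitter_sd = 0.3,
                               seed = 11))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(g$model, f)
  m2 <- read_structure(f)
  expect_equal(nrow(m2$atoms), nrow(g$model$atoms))
  # coordinates written at the format's 3-decimal precision round-trip exactly
  expect_equal(coords(m2), round(coords(g$model), 3), ignore_attr = TRUE)
  expect_equal(m2$atoms$resno, g$model$atoms$resno)
  expect_equal(m2$atoms$resid, g$model$atoms$resid)
})

test_that("only the first MODEL block of a multi-model file is read", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       1.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  GLY A   1       9.000   9.000   9.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       8.000   9.000   9.000  1.00  0.00           C",
    "ENDMDL",
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$atoms$x, c(0, 1))
})

test_that("unknown elements fall back to the default radius with a warning", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  X1  UNK A   1       0.000   0.000   0.000  1.00  0.00           X",
    "ATOM      2  CA  GLY A   2       3.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  expect_warning(m <- read_structure(f), "unknown element")
  expect_equal(m$atoms$vdw_radius, c(1.70, 1.70))
})

test_that("mmCIF input parses to the same model as PDB", {
  f_pdb <- withr::local_tempfile(fileext = ".pdb")
  g <- make_groove(groove_spec(length = 10, inner_radius = 8,
                               lattice_spacing = 2))
  write_structure(g$model, f_pdb)
  m_pdb <- read_structure(f_pdb)
  # minimal atom_site loop with the same atoms
  f_cif <- withr::local_tempfile(fileext = ".cif")
  a <- m_pdb$atoms
  writeLines(c(
    "data_synthetic",
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
    sprintf("ATOM %d C CA . %s A 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s A CA 1",
            a$serial, a$resid, a$resno, a$x, a$y, a$z, a$resno, a$resid)), f_cif)
  m_cif <- read_structure(f_cif)
  expect_equal(nrow(m_cif$atoms), nrow(m_pdb$atoms))
  expect_equal(coords(m_cif), coords(m_pdb), ignore_attr = TRUE)
  expect_equal(m_cif$atoms$resno, m_pdb$atoms$resno)
})

test_that("selections are 1-based inclusive and preserve author numbering", {
  # 20 residues, 3 atoms each, gapped numbering (101..110, 201..210)
  resno <- rep(c(101:110, 201:210), each = 3)
  n <- length(resno)
  m <- structure_model(data.frame(
    serial = seq_len(n), name = rep(c("N", "CA", "C"), 20), element = "C",
    resid = "GLY", chain = "A", resno = resno,
    x = seq_len(n), y = 0, z = 0, occupancy = 1, is_hetero = FALSE,
    vdw_radius = 1.7
  ))
  expect_equal(nrow(apply_selection(m, "A:101-110")$atoms), 30L)
  expect_equal(nrow(apply_selection(m, "A:105-105")$atoms), 3L)
  expect_equal(unique(apply_selection(m, "A:105-105")$atoms$resno), 105L)
  # wildcard identity
  expect_equal(nrow(apply_selection(m, "*")$atoms), n)
  # numbering untouched
  expect_equal(apply_selection(m, "A:201-210")$atoms$resno,
               rep(201:210, each = 3))
  # no atoms in the numbering gap
  expect_error(apply_selection(m, "A:111-150"), "empty selection")
})

test_that("selection is monotone: superset ranges give superset atoms", {
  g <- make_groove(groove_spec(length = 40, inner_radius = 10,
                               lattice_spacing = 2))
  small <- apply_selection(g$model, "A:10-60")
  big <- apply_selection(g$model, "A:5-120")
  expect_true(all(small$atoms$serial %in% big$atoms$serial))
  expect_gt(nrow(big$atoms), nrow(small$atoms))
})

test_that("selection parsing round-trips and rejects malformed input", {
  s <- parse_selection("B:2-3753,4000-4100")
  expect_equal(s$chain, "B")
  expect_equal(s$ranges, list(c(2L, 3753L), c(4000L, 4100L)))
  expect_equal(format_selection(s), "B:2-3753,4000-4100")
  expect_error(parse_selection("A:9-2"), "exceeds")
  expect_error(parse_selection("A:x-y"), "bad residue range")
  expect_error(selection("A", list(c(5, 1))), "exceeds")
})

test_that("radius assignment uses the shipped table and is idempotent", {
  m <- line_model(5)
  m$atoms$element <- c("C", "N", "O", "S", "P")
  m1 <- assign_radii(m)
  expect_equal(m1$atoms$vdw_radius, c(1.70, 1.55, 1.52, 1.80, 1.80))
  m2 <- assign_radii(m1)
  expect_identical(m1$atoms$vdw_radius, m2$atoms$vdw_radius)
  expect_error(assign_radii(m, "nosuchset"), "unknown radii set")
})

test_that("altloc handling keeps the highest-occupancy conformer", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AGLY A   1       0.000   0.000   0.000  0.30  0.00           C",
    "ATOM      2  CA BGLY A   1       5.000   0.000   0.000  0.70  0.00           C",
    "ATOM      3  CA  GLY A   2       9.000   0.000   0.000  1.00  0.00           C",
    "END"), f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 2L)
  expect_equal(m$atoms$x[1], 5)  # the 0.70-occupancy B conformer
})

test_that("missing files and empty models raise informative errors", {
  expect_error(read_structure("/no/such/file.pdb"), "file not found")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("END", f)
  expect_error(read_structure(f), "empty model|failed to parse")
})
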
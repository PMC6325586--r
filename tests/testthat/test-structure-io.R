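test_that("reader keeps only model 1, CA atoms and standard residues", {
  path <- tmp_pdb(c(
    "MODEL        1",
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    ca_line(2, "ALA", "A", 1, 11.639, 6.071, -5.147),
    ca_line(3, "GLY", "A", 2, 12.000, 7.000, -2.000),
    ca_line(4, "SER", "B", 1, 1.000, 2.000, 3.000),
    ca_line(5, "HOH", "B", 2, 9.000, 9.000, 9.000),
    "HETATM    6  CA  MSE B   3       8.000   8.000   8.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    ca_line(1, "ALA", "A", 1, 99.0, 99.0, 99.0),
    ca_line(2, "ALA", "C", 1, 98.0, 98.0, 98.0),
    "ENDMDL",
    "END"))
  rec <- read_structure(path)
  expect_s3_class(rec, "StructureRecord")
  expect_named(rec$chains, c("A", "B"))
  expect_equal(length(rec$chains$A), 2L)
  expect_equal(length(rec$chains$B), 1L)
  # model 2 coordinates never appear
  expect_false(any(rec$chains$A$xyz == 99.0))
  # seq_index contiguous from 0
  expect_equal(residue_points(rec$chains$A)$seq_index, c(0L, 1L))
})

test_that("altloc resolution keeps the highest-occupancy conformer", {
  path <- tmp_pdb(c(
    ca_line(1, "ALA", "A", 1, 1, 0, 0),
    ca_line(2, "GLY", "A", 2, 4.0, 0, 0, occ = 0.4, alt = "A"),
    ca_line(3, "GLY", "A", 2, 4.5, 0, 0, occ = 0.6, alt = "B"),
    ca_line(4, "LEU", "A", 3, 8, 0, 0),
    "END"))
  rec <- read_structure(path)
  expect_equal(length(rec$chains$A), 3L)
  expect_equal(rec$chains$A$xyz[2L, 1L], 4.5)  # occ 0.6 wins

  # tie -> first in file order
  path2 <- tmp_pdb(c(
    ca_line(1, "GLY", "A", 1, 4.0, 0, 0, occ = 0.5, alt = "A"),
    ca_line(2, "GLY", "A", 1, 4.5, 0, 0, occ = 0.5, alt = "B"),
    "END"))
  rec2 <- read_structure(path2)
  expect_equal(rec2$chains$A$xyz[1L, 1L], 4.0)
})

test_that("unparseable and protein-free files raise informative errors", {
  bad <- tempfile(fileext = ".pdb")
  writeLines("this is not a structure file", bad)
  expect_error(read_structure(bad), "parse|C-alpha")
  empty <- tmp_pdb(c(
    "ATOM      1  P     G A   1      11.000   6.000  -6.000  1.00  0.00           P",
    "END"))
  expect_error(read_structure(empty), "no protein chains")
  expect_error(read_structure(tempfile()), "not found")
})

test_that("mmCIF reading matches PDB reading and recovers sheet ranges", {
  cif <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_TEST", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA . SER A 1 1 ? 1.000 0.000 0.000 1.00 0.00 ? 2 SER A CA 1",
    "ATOM 2 C CA . ALA A 1 2 ? 4.800 0.000 0.000 1.00 0.00 ? 3 ALA A CA 1",
    "ATOM 3 C CA . VAL B 2 1 ? 0.000 5.000 0.000 1.00 0.00 ? 1 VAL B CA 1",
    "ATOM 4 C CA . VAL B 2 1 ? 9.000 9.000 9.000 1.00 0.00 ? 1 VAL B CA 2",
    "#", "loop_",
    "_struct_sheet_range.sheet_id", "_struct_sheet_range.id",
    "_struct_sheet_range.beg_auth_asym_id",
    "_struct_sheet_range.beg_auth_seq_id",
    "_struct_sheet_range.end_auth_asym_id",
    "_struct_sheet_range.end_auth_seq_id",
    "A 1 A 2 A 3", "#"), cif)
  rec <- read_structure(cif)
  expect_named(rec$chains, c("A", "B"))
  expect_equal(length(rec$chains$A), 2L)
  expect_equal(length(rec$chains$B), 1L)   # model 2 row dropped
  expect_equal(rec$chains$A$auth_seq_num, c(2L, 3L))
  expect_equal(rec$sheet_annotation,
               data.frame(chain_id = "A", beg = 2L, end = 3L,
                          stringsAsFactors = FALSE))
})

test_that("PDB SHEET records populate the sheet annotation", {
  path <- tmp_pdb(c(
    "SHEET    1   A 2 SER A   2  LEU A   4  0",
    ca_line(1, "SER", "A", 2, 0, 0, 0),
    ca_line(2, "ALA", "A", 3, 3.8, 0, 0),
    ca_line(3, "LEU", "A", 4, 7.6, 0, 0),
    "END"))
  rec <- read_structure(path)
  ann <- rec$sheet_annotation
  expect_equal(ann$chain_id, "A")
  expect_equal(ann$beg, 2L)
  expect_equal(ann$end, 4L)
})

test_that("write/read round trip preserves generator output to 1e-3 A", {
  for (spec in list(fibril_spec(2, 14), fibril_spec(5, 28, noise_sd = 0.3,
                                                    seed = 7))) {
    rec <- make_cross_beta(spec)
    path <- tempfile(fileext = ".pdb")
    write_structure(rec, path)
    back <- read_structure(path)
    expect_equal(names(back$chains), names(rec$chains))
    expect_equal(vapply(back$chains, length, 1L),
                 vapply(rec$chains, length, 1L))
    for (id in names(rec$chains))
      expect_equal(back$chains[[id]]$xyz, rec$chains[[id]]$xyz,
                   tolerance = 1e-3)
  }
})

test_that("writer errors on empty records and exhausted chain alphabet", {
  expect_error(write_structure(structure_record("x", list()), tempfile()),
               "no chains")
  many <- lapply(1:63, function(k)
    chain_trace(paste0("c", k), matrix(as.numeric(k), 1, 3)))
  expect_error(write_structure(structure_record("x", many), tempfile()),
               "alphabet exhausted")
})

test_that("coordinates are written at PDB fixed-width precision", {
  rec <- structure_record("x", list(
    chain_trace("A", rbind(c(1234.5678, 0, 0), c(1238.0, 0, 0)))))
  path <- tempfile(fileext = ".pdb")
  write_structure(rec, path)
  line1 <- readLines(path)[1L]
  expect_equal(substr(line1, 31, 38), "1234.568")
  back <- read_structure(path)
  expect_equal(back$chains$A$xyz[1L, 1L], 1234.568, tolerance = 1e-9)
})

test_that("split_on_breaks partitions a chain at large gaps", {
  straight <- chain_trace("A", cbind(0:9 * 3.8, 0, 0))
  expect_length(split_on_breaks(straight), 1L)

  gap_xyz <- cbind(c(0:4 * 3.8, 0:4 * 3.8 + 100), 0, 0)
  gapped <- chain_trace("A", gap_xyz)
  segs <- split_on_breaks(gapped)
  expect_length(segs, 2L)
  expect_equal(vapply(segs, length, 1L), c(5L, 5L), ignore_attr = TRUE)
  expect_equal(vapply(segs, function(s) s$offset, 1L), c(0L, 5L),
               ignore_attr = TRUE)
  # concatenation equals input
  expect_equal(do.call(rbind, lapply(segs, `[[`, "xyz")), gapped$xyz)

  single <- chain_trace("A", matrix(0, 1, 3))
  expect_length(split_on_breaks(single), 1L)

  # partition property over random gap patterns
  set.seed(42)
  for (trial in 1:20) {
    n <- sample(2:40, 1)
    steps <- sample(c(3.8, 12), n - 1L, replace = TRUE, prob = c(0.8, 0.2))
    xyz <- cbind(cumsum(c(0, steps)), 0, 0)
    ch <- chain_trace("Z", xyz)
    parts <- split_on_breaks(ch)
    expect_equal(sum(vapply(parts, length, 1L)), n)
    expect_length(parts, sum(steps > 4.5) + 1L)
  }
})
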
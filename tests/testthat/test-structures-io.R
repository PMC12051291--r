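# Reading/writing structures, ligand extraction, sequences, component orders.

write_toy_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1       1.000   2.000   3.000  1.00 10.00           N",
    "ATOM      2  CA  ALA A   1       2.000   2.000   3.000  1.00 10.00           C",
    "ATOM      3  CA  GLY A   2       3.000   2.000   3.000  1.00 10.00           C",
    "ATOM      4  CA  SER A   3       4.000   2.000   3.000  1.00 10.00           C",
    "ATOM      5  HA  SER A   3       4.500   2.000   3.000  1.00 10.00           H",
    "END"
  ), path)
  path
}

write_toy_cif <- function(path) {
  writeLines(c(
    "data_toy",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id", "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N . ALA A 1 1 ? 1.000 2.000 3.000 1.00 10.00 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.000 2.000 3.000 1.00 10.00 1 ALA A CA 1",
    "ATOM 3 C CA . GLY A 1 2 ? 3.000 2.000 3.000 1.00 10.00 2 GLY A CA 1",
    "ATOM 4 C CA . SER A 1 3 ? 4.000 2.000 3.000 1.00 10.00 3 SER A CA 1",
    "ATOM 5 H HA . SER A 1 3 ? 4.500 2.000 3.000 1.00 10.00 3 SER A HA 1"
  ), path)
  path
}

test_that("PDB and mmCIF parsing agree and drop hydrogens", {
  pdb <- read_structure(write_toy_pdb(tempfile(fileext = ".pdb")))
  cif <- read_structure(write_toy_cif(tempfile(fileext = ".cif")))
  expect_equal(length(unique(pdb$atoms$chain)), 1)
  expect_equal(length(unique(residue_uid <- paste(pdb$atoms$resno))), 3)
  # hydrogens dropped from both
  expect_equal(nrow(pdb$atoms), 4)
  expect_equal(nrow(cif$atoms), 4)
  expect_equal(pdb$atoms$elety, cif$atoms$elety)
  expect_equal(pdb$atoms[, c("x", "y", "z")], cif$atoms[, c("x", "y", "z")],
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(read_structure(tempfile()), "not found")
})

test_that("alternate locations resolve to the highest-occupancy conformer", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1       1.000   0.000   0.000  1.00 10.00           C",
    "ATOM      2  CA AGLY A   2       2.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CA BGLY A   2       2.500   0.000   0.000  0.40 10.00           C",
    "ATOM      4  CB AGLY A   2       3.000   0.000   0.000  0.40 10.00           C",
    "ATOM      5  CB BGLY A   2       3.500   0.000   0.000  0.60 10.00           C",
    "END"
  ), path)
  s <- read_structure(path)
  # one conformer per atom, each the higher-occupancy one
  expect_equal(nrow(s$atoms), 3)
  ca2 <- s$atoms[s$atoms$resno == 2 & s$atoms$elety == "CA", ]
  cb2 <- s$atoms[s$atoms$resno == 2 & s$atoms$elety == "CB", ]
  expect_equal(ca2$x, 2.0)   # occ 0.6 altloc A
  expect_equal(cb2$x, 3.5)   # occ 0.6 altloc B
})

test_that("ligand extraction separates copies and excludes water and ions", {
  base <- atom_row("CA", "ALA", 1, 0, 0, 0)
  nap1 <- atom_row(c("PA", "O1A"), "NAP", 101, c(5, 6), 0, 0,
                   type = "HETATM", elesy = c("P", "O"))
  nap2 <- atom_row(c("PA", "O1A"), "NAP", 102, c(8, 9), 0, 0,
                   type = "HETATM", elesy = c("P", "O"))
  wat <- atom_row("O", "HOH", 201, 20, 0, 0, type = "HETATM", elesy = "O")
  mg <- atom_row("MG", "MG", 301, 25, 0, 0, type = "HETATM", elesy = "MG")
  s <- new_structure(rbind(base, nap1, nap2, wat, mg))
  ligs <- extract_ligands(s)
  expect_length(ligs, 2)
  expect_equal(vapply(ligs, function(l) l$comp_id, ""), c("NAP", "NAP"))
  expect_equal(vapply(ligs, function(l) l$copy_key$resno, 1), c(101, 102))
  # keep the ion when the exclusion list is emptied
  expect_length(extract_ligands(s, exclude = character(0)), 3)
  # water is never a ligand
  comp_ids <- vapply(extract_ligands(s, exclude = character(0)),
                     function(l) l$comp_id, "")
  expect_false("HOH" %in% comp_ids)
  # no hetero groups at all
  expect_length(extract_ligands(new_structure(base)), 0)
})

test_that("chain_sequence returns ordered letters with an index", {
  rows <- rbind(atom_row("CA", "ALA", 1, 0, 0, 0),
                atom_row("CA", "GLY", 2, 1, 0, 0),
                atom_row("CA", "SER", 3, 2, 0, 0))
  s <- new_structure(rows)
  cs <- chain_sequence(s, "A")
  expect_equal(cs$seq, "AGS")
  expect_equal(cs$index$pos, 1:3)
  expect_equal(cs$index$resno, 1:3)
  expect_equal(nchar(cs$seq), nrow(cs$index))
  expect_error(chain_sequence(s, "B"), "available")

  # nonstandard residues go through the parent table, unknowns to X
  rows2 <- rbind(atom_row("CA", "MSE", 1, 0, 0, 0),
                 atom_row("CA", "SEP", 2, 1, 0, 0),
                 atom_row("CA", "ZZZ", 3, 2, 0, 0))
  expect_equal(chain_sequence(new_structure(rows2), "A")$seq, "MSX")
})

test_that("component atom order reads SDF and CCD files", {
  sdf <- tempfile(fileext = ".sdf")
  writeLines(c(
    "TOY", "  test", "",
    "  4  3  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.4000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
    "    2.8000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    3.8000    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0", "  2  3  1  0", "  3  4  1  0",
    "M  END", "$$$$"
  ), sdf)
  ord <- read_component_atom_order(sdf)
  # hydrogens excluded; per-element numbering in file order
  expect_equal(ord$atom_names, c("C1", "N1", "O1"))
  expect_equal(ord$elements, c("C", "N", "O"))

  cif <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_TOY", "loop_",
    "_chem_comp_atom.comp_id", "_chem_comp_atom.atom_id",
    "_chem_comp_atom.type_symbol",
    "TOY PA P", "TOY O1A O", "TOY H1 H", "TOY C2 C"
  ), cif)
  ord2 <- read_component_atom_order(cif)
  expect_equal(ord2$comp_id, "TOY")
  expect_equal(ord2$atom_names, c("PA", "O1A", "C2"))

  dup <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_TOY", "loop_",
    "_chem_comp_atom.comp_id", "_chem_comp_atom.atom_id",
    "_chem_comp_atom.type_symbol",
    "TOY PA P", "TOY PA P"
  ), dup)
  expect_error(read_component_atom_order(dup), "duplicate")
})

test_that("write/read round-trip preserves names, keys and coordinates", {
  fx <- make_toy_complex(fixture_spec(n_residues = 20, seed = 11),
                         dir = tempfile())
  path <- tempfile(fileext = ".pdb")
  write_structure_pdb(fx$structure, path)
  back <- read_structure(path)
  expect_equal(back$atoms$elety, fx$structure$atoms$elety)
  expect_equal(back$atoms$resno, fx$structure$atoms$resno)
  expect_equal(back$atoms$chain, fx$structure$atoms$chain)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               as.matrix(fx$structure$atoms[, c("x", "y", "z")]),
               tolerance = 1e-3, ignore_attr = TRUE)
  # ligand atoms never exceed hetero atoms
  ligs <- extract_ligands(back)
  expect_lte(sum(vapply(ligs, function(l) nrow(l$atoms), 1L)),
             sum(back$atoms$is_hetero))
})
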
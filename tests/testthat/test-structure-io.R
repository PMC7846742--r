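test_that("generated mmCIF round-trips through the parser", {
  f <- write_fixture(make_toy_complex(distance = 3.5))
  s <- read_structure(f)
  expect_s3_class(s, "neiss_structure")
  expect_identical(s$source_format, "mmcif")
  expect_identical(sort(unique(s$atoms$label_asym)), c("A", "B"))
  expect_identical(nrow(s$entities), 2L)
  expect_setequal(s$entities$sequence, c("ASE", "MKA"))
  expect_identical(nrow(s$assembly_gen), 1L)
  # coordinates written at 3 decimals come back exactly
  nz <- s$atoms[s$atoms$label_asym == "B" & s$atoms$atom == "NZ", ]
  ctc <- s$atoms[s$atoms$label_asym == "A" & s$atoms$atom == "C" &
                   s$atoms$auth_seq == 3, ]
  d <- euclidean(c(nz$x, nz$y, nz$z), c(ctc$x, ctc$y, ctc$z))
  expect_equal(d, 3.5, tolerance = 1e-9)
})

test_that("legacy PDB text of the same toy matches the mmCIF parse", {
  fc <- write_fixture(make_toy_complex(distance = 3.5))
  fp <- tempfile(fileext = ".pdb")
  writeLines(make_toy_complex(distance = 3.5, format = "pdb"), fp)
  sc <- read_structure(fc)
  sp <- suppressMessages(read_structure(fp))
  expect_identical(sp$source_format, "pdb")
  key <- function(s) s$atoms[order(s$atoms$label_asym, s$atoms$auth_seq, s$atoms$atom),
                             c("label_asym", "resname", "auth_seq", "atom")]
  expect_equal(as.data.frame(key(sp)), as.data.frame(key(sc)))
  xyz <- function(s) as.matrix(s$atoms[order(s$atoms$label_asym, s$atoms$auth_seq,
                                             s$atoms$atom), c("x", "y", "z")])
  expect_lt(max(abs(xyz(sp) - xyz(sc))), 1e-3)
  # PDB carries no assembly operators: single pseudo-assembly AU
  inst <- build_assemblies(sp)
  expect_identical(unique(inst$assembly_id), "AU")
  expect_identical(unique(inst$operator_id), "1")
})

test_that("model cap keeps the first models in file order", {
  f <- write_fixture(make_multimodel_fixture(n_models = 12))
  s <- read_structure(f)
  expect_identical(sort(unique(s$atoms$model)), 1:10)
  expect_identical(s$n_models_total, 12L)
  s5 <- read_structure(f, scan_config(max_models = 5))
  expect_identical(sort(unique(s5$atoms$model)), 1:5)
})

test_that("size gate is strict and can be disabled", {
  small <- tempfile()
  writeBin(raw(9437184), small)        # 9 MB
  exact <- tempfile()
  writeBin(raw(10485760), exact)       # exactly 10 MB
  expect_true(check_size_gate(small, scan_config()))
  expect_false(suppressMessages(check_size_gate(exact, scan_config())))
  expect_true(check_size_gate(exact, scan_config(max_file_bytes = Inf)))
  unlink(c(small, exact))
})

test_that("altloc resolution keeps the highest occupancy, ties to first id", {
  cif <- c(
    "data_ALT", "_entry.id ALT",
    "loop_", "_entity_poly.entity_id", "_entity_poly.type",
    "_entity_poly.pdbx_seq_one_letter_code_can",
    "1 'polypeptide(L)' A",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.auth_seq_id",
    "_atom_site.auth_asym_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 C CA A ALA A 1 1 1.0 0.0 0.0 0.40 1 A 1",
    "ATOM 2 C CA B ALA A 1 1 2.0 0.0 0.0 0.60 1 A 1",
    "ATOM 3 N N  A ALA A 1 1 3.0 0.0 0.0 0.50 1 A 1",
    "ATOM 4 N N  B ALA A 1 1 4.0 0.0 0.0 0.50 1 A 1"
  )
  s <- read_structure(write_fixture(cif))
  ca <- s$atoms[s$atoms$atom == "CA", ]
  expect_identical(nrow(ca), 1L)
  expect_equal(ca$x, 2.0)            # occupancy 0.60 wins
  nn <- s$atoms[s$atoms$atom == "N", ]
  expect_equal(nn$x, 3.0)            # tie -> lexicographically first altloc
})

test_that("parsing is deterministic and failures are informative", {
  f <- write_fixture(make_toy_complex(distance = 2.0, seed = 7))
  s1 <- read_structure(f)
  s2 <- read_structure(f)
  expect_identical(s1$atoms, s2$atoms)
  expect_identical(s1$entities, s2$entities)

  bad <- write_fixture(c("data_X", "loop_", "_atom_site.id", "_atom_site.x",
                         "1 2 3"))
  expect_error(read_structure(bad), class = "neiss_parse_error")
  expect_error(read_structure(tempfile(fileext = ".cif")),
               class = "neiss_parse_error")
})

test_that("non-polypeptide polymer chains are excluded from the chain stream", {
  cif <- c(
    "data_RNA", "_entry.id RNA",
    "loop_", "_entity_poly.entity_id", "_entity_poly.type",
    "_entity_poly.pdbx_seq_one_letter_code_can",
    "1 'polypeptide(L)' AG",
    "2 polyribonucleotide ACG",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.auth_seq_id",
    "_atom_site.auth_asym_id", "_atom_site.pdbx_PDB_model_num",
    "ATOM 1 N N  . ALA A 1 1 0.0 0.0 0.0 1.0 1 A 1",
    "ATOM 2 C CA . ALA A 1 1 1.5 0.0 0.0 1.0 1 A 1",
    "ATOM 3 C C  . ALA A 1 1 2.0 1.4 0.0 1.0 1 A 1",
    "ATOM 4 N N  . GLY A 1 2 3.8 0.0 0.0 1.0 2 A 1",
    "ATOM 5 C CA . GLY A 1 2 5.3 0.0 0.0 1.0 2 A 1",
    "ATOM 6 C C  . GLY A 1 2 5.8 1.4 0.0 1.0 2 A 1",
    "ATOM 7 P P    . A B 2 1 9.0 0.0 0.0 1.0 1 B 1",
    "ATOM 8 C \"C1'\" . A B 2 1 10.0 0.0 0.0 1.0 1 B 1"
  )
  s <- read_structure(write_fixture(cif))
  inst <- extract_polymer_chains(build_assemblies(s))
  expect_identical(inst$label_asym_id, "A")
  expect_identical(inst$sequence, "AG")
})

test_that("a structure without polymer chains raises the empty signal", {
  cif <- c(
    "data_EMP", "_entry.id EMP",
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.auth_seq_id",
    "_atom_site.auth_asym_id", "_atom_site.pdbx_PDB_model_num",
    "HETATM 1 O O . HOH A 1 1 0.0 0.0 0.0 1.0 1 A 1"
  )
  f <- write_fixture(cif)
  expect_error(read_structure(f), class = "neiss_empty_structure")
  res <- suppressMessages(scan_files(f))
  expect_identical(nrow(res$records), 0L)
  expect_identical(res$skipped$reason, "no_polymer")
})
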
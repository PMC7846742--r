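toy_records <- function(distance = 3.5, ...) {
  scan_structure(write_fixture(make_toy_complex(distance = distance, ...)))
}

test_that("chain-instance pairs classify by identity then sequence", {
  f <- write_fixture(make_homodimer_fixture(distance = 7.0))
  inst <- build_assemblies(read_structure(f))
  i1 <- inst[inst$operator_id == "1", ]
  i2 <- inst[inst$operator_id == "2", ]
  expect_identical(classify_pair(i1, i1), "intramolecular")
  expect_identical(classify_pair(i1, i2), "intermolecular_homomeric")

  fh <- write_fixture(make_toy_complex(distance = 3.5))
  ih <- build_assemblies(read_structure(fh))
  expect_identical(classify_pair(ih[1, ], ih[2, ]),
                   "intermolecular_heteromeric")
  i_other <- ih[2, ]
  i_other$assembly_id <- "2"
  expect_error(classify_pair(ih[1, ], i_other), "assemblies")
})

test_that("the toy heterodimer scan contains the constructed record set", {
  recs <- toy_records(3.5)
  het <- recs[recs$category == "intermolecular_heteromeric" &
                recs$target_kind == "lysine", ]
  expect_identical(nrow(het), 1L)
  expect_equal(het$distance, 3.5, tolerance = 1e-3)
  expect_identical(c(het$source_atom, het$target_atom), c("C", "NZ"))
  expect_identical(c(het$source_auth, het$target_auth), c("A", "B"))
  expect_false(het$covalent)
  # both chains also measure against both alpha-amines
  expect_identical(sum(recs$target_kind == "n_terminus"), 4L)
  expect_identical(het$n_pairs, 9L)
})

test_that("a single-chain structure yields only intramolecular records", {
  f <- write_fixture(make_homodimer_fixture(distance = 7.0))
  recs <- scan_structure(read_structure(f),
                         scan_config(assembly_mode = "asymmetric_unit"))
  expect_true(all(recs$category == "intramolecular"))
})

test_that("the covalent filter is strict at the 1.6 A boundary", {
  cfg <- scan_config()
  r159 <- toy_records(1.59)
  r160 <- toy_records(1.60)
  lys <- function(r) r[r$target_kind == "lysine" &
                         r$category == "intermolecular_heteromeric", ]
  expect_true(lys(r159)$covalent)
  expect_false(lys(r160)$covalent)
  kept159 <- suppressMessages(filter_covalent(r159, cfg))
  expect_false(any(kept159$distance < cfg$covalent_cutoff))
  expect_identical(nrow(filter_covalent(lys(r160), cfg)), 1L)
  expect_identical(nrow(filter_covalent(toy_records(3.5), cfg)),
                   nrow(toy_records(3.5)))
})

test_that("fixture geometry is recovered across the full pipeline", {
  for (d in c(1.0, 3.5, 9.99, 10.0, 49.9)) {
    het <- toy_records(d)
    het <- het[het$target_kind == "lysine" &
                 het$category == "intermolecular_heteromeric", ]
    expect_equal(het$distance, d, tolerance = 1e-3)
    expect_identical(het$covalent, d < 1.6)
  }
})

test_that("minima aggregate per category with the overall shortest marked", {
  recs <- toy_records(3.5, self_lysine_distance = 4.0)
  summ <- aggregate_minima(recs)
  expect_setequal(summ$category,
                  c("intramolecular", "intermolecular_heteromeric"))
  het <- summ[summ$category == "intermolecular_heteromeric", ]
  expect_equal(het$distance, 3.5, tolerance = 1e-3)
  expect_true(het$overall)
  expect_identical(sum(summ$overall), 1L)
  intra <- summ[summ$category == "intramolecular", ]
  expect_lte(intra$distance,
             min(recs$distance[recs$category == "intramolecular"]))
})

test_that("minima may come from any assembly and ignore record order", {
  base <- toy_records(4.0)
  a2 <- toy_records(3.0)
  a2$assembly_id <- "2"
  recs <- dplyr::bind_rows(base, a2)
  summ <- aggregate_minima(recs)
  het <- summ[summ$category == "intermolecular_heteromeric", ]
  expect_equal(het$distance, 3.0, tolerance = 1e-3)
  expect_identical(het$assembly_id, "2")
  # permutation invariance
  set.seed(1)
  shuffled <- recs[sample(nrow(recs)), ]
  expect_equal(as.data.frame(aggregate_minima(shuffled)),
               as.data.frame(summ))
})

test_that("same-residue pairs are flagged and excludable from minima", {
  # single chain ending in a lysine: Ct residue is its own target
  cif <- c(
    "data_SR", "_entry.id SR",
    "loop_", "_entity_poly.entity_id", "_entity_poly.type",
    "_entity_poly.pdbx_seq_one_letter_code_can",
    "1 'polypeptide(L)' AK",
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
    "ATOM 4 N N  . LYS A 1 2 3.8 0.0 0.0 1.0 2 A 1",
    "ATOM 5 C CA . LYS A 1 2 5.3 0.0 0.0 1.0 2 A 1",
    "ATOM 6 C C  . LYS A 1 2 5.8 1.4 0.0 1.0 2 A 1",
    "ATOM 7 N NZ . LYS A 1 2 7.0 -4.0 3.0 1.0 2 A 1"
  )
  recs <- scan_structure(write_fixture(cif))
  sr <- recs[recs$same_residue, ]
  expect_identical(nrow(sr), 1L)
  expect_identical(sr$category, "intramolecular")
  excl <- aggregate_minima(recs, include_same_residue = FALSE)
  expect_false(any(excl$same_residue))
})

test_that("an empty record set aggregates to an empty summary", {
  summ <- aggregate_minima(neissdist:::record_columns())
  expect_identical(nrow(summ), 0L)
  expect_true(all(c("n_records", "overall") %in% names(summ)))
})
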
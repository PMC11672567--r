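test_that("minimal PDB parses to one chain, one residue, one atom", {
  p <- write_residue_pdb(list(list(chain = "A", resno = 1, resid = "ALA",
                                   xyz = c(0, 0, 0))))
  st <- read_structure(p)
  expect_s3_class(st, "ab_structure")
  expect_equal(nrow(st$atoms), 1L)
  rt <- residue_table(st)
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$aa, "A")
  expect_equal(st$atoms$radius, 1.70)  # carbon, Bondi
})

test_that("altloc policy keeps the highest-occupancy copy, tie breaks to A", {
  lines <- c(
    pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0, occ = 0.6, altloc = "A"),
    pdb_line(2, "CA", "ALA", "A", 1, 1, 0, 0, occ = 0.4, altloc = "B"),
    "END")
  p <- tempfile(fileext = ".pdb"); writeLines(lines, p)
  st <- read_structure(p, altloc_policy = "highest_occupancy")
  expect_equal(nrow(st$atoms), 1L)
  expect_equal(st$atoms$x, 0)          # the A copy
  # tie in occupancy -> altloc 'A' retained
  lines2 <- c(
    pdb_line(1, "CA", "ALA", "A", 1, 5, 0, 0, occ = 0.5, altloc = "B"),
    pdb_line(2, "CA", "ALA", "A", 1, 9, 0, 0, occ = 0.5, altloc = "A"),
    "END")
  p2 <- tempfile(fileext = ".pdb"); writeLines(lines2, p2)
  st2 <- read_structure(p2)
  expect_equal(st2$atoms$x, 9)
  # keep-all policy retains both
  st3 <- read_structure(p2, altloc_policy = "all")
  expect_equal(nrow(st3$atoms), 2L)
})

test_that("filters drop exactly waters, heteroatoms and hydrogens, monotonically", {
  res <- list(
    list(chain = "A", resno = 1, resid = "ALA", xyz = c(0, 0, 0)),
    list(chain = "A", resno = 1, resid = "ALA", xyz = c(1, 0, 0),
         name = "H", element = "H"),
    list(chain = "A", resno = 2, resid = "HOH", xyz = c(5, 0, 0),
         name = "O", element = "O", record = "HETATM"),
    list(chain = "A", resno = 3, resid = "SO4", xyz = c(9, 0, 0),
         name = "S", element = "S", record = "HETATM"))
  p <- write_residue_pdb(res)
  all_in <- read_structure(p, drop_waters = FALSE, drop_hetero = FALSE,
                           drop_hydrogens = FALSE)
  expect_equal(nrow(all_in$atoms), 4L)
  no_w <- read_structure(p, drop_waters = TRUE, drop_hetero = FALSE,
                         drop_hydrogens = FALSE)
  expect_equal(setdiff(all_in$atoms$resid, no_w$atoms$resid), "HOH")
  default <- read_structure(p)
  expect_equal(nrow(default$atoms), 1L)
  expect_true(nrow(default$atoms) <= nrow(no_w$atoms))
  expect_true(nrow(no_w$atoms) <= nrow(all_in$atoms))
  # everything filtered out -> empty-structure error
  pw <- write_residue_pdb(res[3])
  expect_error(read_structure(pw), "empty")
})

test_that("chain sequences extract in order with X for non-standard residues", {
  res <- list(
    list(chain = "A", resno = 1, resid = "ALA", xyz = c(0, 0, 0)),
    list(chain = "A", resno = 2, resid = "SER", xyz = c(5, 0, 0)),
    list(chain = "A", resno = 3, resid = "ASN", xyz = c(10, 0, 0)))
  st <- read_structure(write_residue_pdb(res))
  expect_equal(extract_chain_sequence(st, "A"), "ASN")
  expect_error(extract_chain_sequence(st, "Z"), "chain")
  # MSE: X under strict mode, M through the alias table
  res2 <- list(
    list(chain = "A", resno = 1, resid = "ALA", xyz = c(0, 0, 0)),
    list(chain = "A", resno = 2, resid = "MSE", xyz = c(5, 0, 0),
         name = "SE", element = "SE", record = "HETATM"),
    list(chain = "A", resno = 3, resid = "GLY", xyz = c(10, 0, 0)))
  st2 <- read_structure(write_residue_pdb(res2), drop_hetero = FALSE)
  expect_equal(extract_chain_sequence(st2, "A", strict = TRUE), "AXG")
  expect_equal(extract_chain_sequence(st2, "A", strict = FALSE), "AMG")
})

test_that("numbering maps annotate regions and never touch coordinates", {
  p <- write_mini_fv()
  st <- read_structure(p)
  nm <- read_numbering_map(mini_fv_numbering_csv())
  ann <- apply_numbering(st, nm)
  expect_equal(ann$atoms$x, st$atoms$x)
  expect_equal(nrow(ann$atoms), nrow(st$atoms))
  rt <- residue_table(ann)
  expect_equal(rt$region[rt$scheme_label == "H97"], "CDR3")
  expect_equal(rt$region[rt$scheme_label == "L93"], "CDR3")
  expect_equal(rt$region[rt$scheme_label == "H31"], "CDR1")
  expect_equal(rt$region[rt$scheme_label == "H40"], "FR2")
  # empty map: everything 'other', no error
  st0 <- apply_numbering(st, NULL)
  expect_true(all(residue_table(st0)$region == "other"))
  # key absent from structure: strict errors, lenient warns
  nm_bad <- nm; nm_bad$resnum[1] <- 999
  expect_error(apply_numbering(st, nm_bad, strict = TRUE), "absent")
  expect_warning(apply_numbering(st, nm_bad, strict = FALSE), "absent")
})

test_that("Kabat boundaries place the CDR3 tryptophans and labels correctly", {
  expect_equal(kabat_region("H97"), "CDR3")
  expect_equal(kabat_region("H99"), "CDR3")
  expect_equal(kabat_region("L93"), "CDR3")
  expect_equal(kabat_region(c("H31", "H35", "H50", "H65", "L24", "L34",
                              "L50", "L56")),
               c("CDR1", "CDR1", "CDR2", "CDR2", "CDR1", "CDR1",
                 "CDR2", "CDR2"))
  expect_equal(kabat_region(c("H1", "H36", "H94", "H103", "L98")),
               c("FR1", "FR2", "FR3", "FR4", "FR4"))
  expect_equal(kabat_region("H100A"), "CDR3")  # insertion inherits region
  expect_equal(kabat_region("H120"), "constant")
  expect_equal(kabat_region("Q7"), "other")
})

test_that("PDB round-trip preserves residue keys, coordinates and B-factors", {
  res <- list(
    list(chain = "H", resno = 5, resid = "TRP", xyz = c(1.234, -2.5, 3.75),
         b = 12.34),
    list(chain = "H", resno = 6, resid = "GLY", xyz = c(4.1, 0.002, -9.999),
         b = 45.67),
    list(chain = "L", resno = 1, resid = "MET", xyz = c(0, 8, 0), b = 7.5))
  st <- read_structure(write_residue_pdb(res))
  out <- tempfile(fileext = ".pdb")
  write_structure(st, out)
  st2 <- read_structure(out)
  expect_equal(residue_table(st2)$key, residue_table(st)$key)
  expect_equal(st2$atoms$x, st$atoms$x, tolerance = 1e-8)
  expect_equal(st2$atoms$y, st$atoms$y, tolerance = 1e-8)
  expect_equal(st2$atoms$z, st$atoms$z, tolerance = 1e-8)
  expect_equal(st2$atoms$b, st$atoms$b, tolerance = 1e-8)
})

test_that("mmCIF atom_site loops parse equivalently to PDB", {
  cif <- c(
    "data_test", "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "ATOM 1 C CA ALA A 1 ? 0.000 0.000 0.000 1.00 10.00",
    "ATOM 2 C CA SER A 2 ? 3.800 0.000 0.000 1.00 20.00",
    "#")
  p <- tempfile(fileext = ".cif"); writeLines(cif, p)
  st <- read_structure(p, format = "mmCIF")
  expect_equal(nrow(st$atoms), 2L)
  expect_equal(extract_chain_sequence(st, "A"), "AS")
  expect_equal(st$atoms$b, c(10, 20))
  expect_equal(st$source_format, "mmCIF")
})
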
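# helpers -------------------------------------------------------------------

# a hand-assembled monomer with true insulin sequences and a controllable
# A6-A11 Sgamma-Sgamma distance (SG atoms placed mid-bridge)
io_monomer <- function(sg_sg = 2.04, resolution = 1.55, pdb_id = "SYNA") {
  a <- build_backbone("GIVEQCCTSICSLYQLENYCN", rep(-57, 21), rep(-47, 21),
                      chain = "A")
  b <- build_backbone("FVNQHLCGSHLVEALYLVCGERGFFYTPKT", rep(-120, 30),
                      rep(135, 30), chain = "B")
  b$x <- b$x + 40
  atoms <- rbind(a, b)
  if (!is.na(sg_sg)) {
    cb6 <- as.numeric(a[a$pos == 6 & a$elety == "CB", c("x", "y", "z")])
    cb11 <- as.numeric(a[a$pos == 11 & a$elety == "CB", c("x", "y", "z")])
    mid <- (cb6 + cb11) / 2
    u <- (cb11 - cb6) / sqrt(sum((cb11 - cb6)^2))
    sg <- function(pos, xyz) data.frame(chain = "A", pos = pos, resid = "CYS",
                                        elety = "SG", x = xyz[1], y = xyz[2],
                                        z = xyz[3], o = 1, b = 0, elesy = "S")
    atoms <- rbind(atoms, sg(6L, mid - u * sg_sg / 2), sg(11L, mid + u * sg_sg / 2))
  }
  insulin_monomer(atoms, pdb_id = pdb_id, resolution = resolution)
}

test_that("minimal and multi-model PDB files parse to the expected shape", {
  # one-residue fixture
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   ALA A   1       2.009   1.421   0.000  1.00  0.00           C",
    "ATOM      4  O   ALA A   1       1.251   2.390   0.000  1.00  0.00           O",
    "END"), tmp)
  sm <- parse_structure(tmp)
  expect_length(sm$models, 1)
  expect_length(sm$models[[1]], 1)
  expect_equal(nrow(sm$models[[1]][["A"]]), 4)
  # three MODEL blocks -> three models
  mon <- io_monomer()
  tmp3 <- tempfile(fileext = ".pdb")
  write_monomers_pdb(list(mon, mon, mon), tmp3, multi_model = TRUE)
  expect_length(parse_structure(tmp3)$models, 3)
  expect_error(parse_structure("no/such/file.pdb"), "unreadable")
})

test_that("PDB round trip preserves labels and coordinates to format precision", {
  mon <- io_monomer()
  tmp <- tempfile(fileext = ".pdb")
  write_monomers_pdb(mon, tmp)
  back <- identify_insulin_monomers(parse_structure(tmp))
  expect_length(back, 1)
  m2 <- back[[1]]
  expect_equal(m2$resolution, 1.55)
  for (sel in list(c("A", "CA"), c("B", "CA"), c("A", "O"))) {
    orig <- monomer_coords(mon, NULL, sel[2])
    orig <- orig[grepl(paste0("^", sel[1]), rownames(orig)), ]
    got <- monomer_coords(m2, NULL, sel[2])
    got <- got[grepl(paste0("^", sel[1]), rownames(got)), ]
    expect_equal(rownames(got), rownames(orig))
    expect_lt(max(abs(got - orig)), 1e-3)
  }
  expect_equal(unname(monomer_sequence(m2, "A")),
               strsplit("GIVEQCCTSICSLYQLENYCN", "")[[1]])
})

test_that("mmCIF files parse (atoms, models, resolution)", {
  mon <- io_monomer()
  ca <- monomer_coords(mon, "A1", "CA")
  cif <- c("data_TEST",
           "_refine.ls_d_res_high 1.80",
           "loop_",
           "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
           "_atom_site.label_atom_id", "_atom_site.label_comp_id",
           "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
           "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
           "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
           "_atom_site.pdbx_PDB_model_num",
           sprintf("ATOM %d %s %s %s A %d %.3f %.3f %.3f 1.00 0.00 %d",
                   1:4, c("N", "C", "C", "O"), c("N", "CA", "C", "O"),
                   "GLY", 1, c(0, 1.458, 2.009, 1.251),
                   c(0, 0, 1.421, 2.390), c(0, 0, 0, 0), 1))
  tmp <- tempfile(fileext = ".cif")
  writeLines(cif, tmp)
  sm <- parse_structure(tmp)
  expect_equal(sm$dialect, "mmcif")
  expect_equal(sm$resolution, 1.8)
  expect_equal(sm$pdb_id, "TEST")
  expect_equal(sm$models[[1]][["A"]]$x[2], 1.458)
  bad <- tempfile(fileext = ".cif")
  writeLines(c("data_X", "loop_", "_foo.bar", "1"), bad)
  expect_error(parse_structure(bad), "no _atom_site")
})

test_that("altloc resolution keeps the highest-occupancy conformer (ties to A)", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N  AALA A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BALA A   1       9.000   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA AALA A   1       1.458   0.000   0.000  0.50  0.00           C",
    "ATOM      4  CA BALA A   1       9.458   0.000   0.000  0.50  0.00           C",
    "END"), tmp)
  ch <- parse_structure(tmp)$models[[1]][["A"]]
  expect_equal(nrow(ch), 2)
  expect_equal(ch$x[ch$elety == "N"], 9.0)     # higher occupancy wins
  expect_equal(ch$x[ch$elety == "CA"], 1.458)  # tie -> altloc A
})

test_that("monomer identification pairs chains by A7-B7 proximity", {
  m1 <- io_monomer(pdb_id = "SYN1")
  m2 <- transform_monomer(io_monomer(pdb_id = "SYN1"),
                          translation = c(0, 80, 0))
  tmp <- tempfile(fileext = ".pdb")
  write_monomers_pdb(list(m1, m2), tmp, multi_model = FALSE)
  mons <- identify_insulin_monomers(parse_structure(tmp))
  expect_length(mons, 2)
  # pairing must match the construction: chains (A,B) and (C,D)
  pairs <- t(vapply(mons, function(m) unname(m$source_chains), character(2)))
  expect_setequal(paste(pairs[, 1], pairs[, 2]), c("A B", "C D"))
  # permutation invariance: chain order in the file must not matter
  lines <- readLines(tmp)
  atoms <- grep("^(ATOM|TER)", lines, value = TRUE)
  chains <- substr(atoms, 22, 22)
  reordered <- c(lines[1:2], atoms[chains == "D"], atoms[chains == "A"],
                 atoms[chains == "C"], atoms[chains == "B"], "END")
  tmp2 <- tempfile(fileext = ".pdb")
  writeLines(reordered, tmp2)
  mons2 <- identify_insulin_monomers(parse_structure(tmp2))
  pairs2 <- t(vapply(mons2, function(m) unname(m$source_chains), character(2)))
  expect_setequal(paste(pairs2[, 1], pairs2[, 2]), c("A B", "C D"))
  # no insulin-like chains -> empty list plus a warning
  junk <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"), junk)
  expect_warning(res <- identify_insulin_monomers(parse_structure(junk)),
                 "no insulin")
  expect_length(res, 0)
})

test_that("curation filters implement the survey rules strictly", {
  # resolution 1.55, Sg-Sg 2.04: passes
  expect_true(apply_curation_filters(io_monomer(2.04, 1.55))$passed)
  # resolution exactly at the cutoff fails ('better than' is strict)
  r <- apply_curation_filters(io_monomer(2.04, 2.8))
  expect_false(r$passed); expect_true("resolution_fail" %in% r$reasons)
  # Sg-Sg 1.90 outside [1.95, 2.05]
  r2 <- apply_curation_filters(io_monomer(1.90, 1.55))
  expect_false(r2$passed); expect_true("ss_bond_length_fail" %in% r2$reasons)
  expect_true(apply_curation_filters(io_monomer(1.95, 1.55))$passed)
  expect_true(apply_curation_filters(io_monomer(2.05, 1.55))$passed)
  # IDE-complex exclusion by id list
  r3 <- apply_curation_filters(io_monomer(2.04, 1.55, pdb_id = "2G54"),
                               exclude_ids = c("2G54"))
  expect_true("ide_complex_excluded" %in% r3$reasons)
  # missing SG atoms on a disulfide-less monomer: typed reason, no crash
  r4 <- apply_curation_filters(io_monomer(NA, 1.55))
  expect_false(r4$passed)
  expect_true("incomplete_backbone" %in% r4$reasons)
  # monotonicity: tightening the cutoff never adds passing monomers
  mons <- lapply(c(1.2, 2.0, 2.6, 2.79, 3.1), function(res)
    io_monomer(2.04, res))
  passed <- function(cut) vapply(mons, function(m)
    apply_curation_filters(m, resolution_cutoff = cut)$passed, logical(1))
  cuts <- c(3.2, 2.8, 2.0, 1.5)
  for (i in seq_len(length(cuts) - 1))
    expect_true(all(passed(cuts[i]) | !passed(cuts[i + 1])),
                label = "pass set shrinks with tighter cutoff")
})

test_that("survey tables are deterministic, rounded and re-parseable", {
  tmp <- tempfile(fileext = ".tsv")
  # zero records: header only
  write_survey(data.frame(pdb_id = character(0), ca_ca_a6a11 = numeric(0)), tmp)
  expect_length(readLines(tmp), 1)
  rec <- data.frame(pdb_id = c("B", "A"), model_no = c(1L, 1L),
                    ca_ca_a6a11 = c(4.77777, 5.16666),
                    chi1 = c(-60.123, 170.987))
  out <- write_survey(rec, tmp)
  back <- utils::read.delim(tmp)
  expect_equal(back$pdb_id, c("A", "B"))       # deterministic order
  expect_equal(back$ca_ca_a6a11, c(5.17, 4.78))  # 0.01 A precision
  expect_equal(back$chi1, c(171.0, -60.1))       # 0.1 deg precision
  expect_equal(nrow(back), 2)
})
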
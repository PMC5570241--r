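test_that("models numbered by target position map directly", {
  target <- target_sequence("t", "MKV")
  co <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE)
  m <- read_model(toy_pdb(c("MET", "LYS", "VAL"), 1:3, co), target)
  expect_identical(m$target_positions, 1:3)
  expect_identical(m$res_codes, c("M", "K", "V"))
  expect_equal(unname(m$ca), co)
})

test_that("misnumbered models map via the best ungapped offset", {
  target <- target_sequence("t", "AAAAMKVAA")
  co <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE)
  m <- read_model(toy_pdb(c("MET", "LYS", "VAL"), 101:103, co), target)
  expect_identical(m$target_positions, 5:7)
})

test_that("ambiguous offsets are an error naming both candidates", {
  target <- target_sequence("t", "MKAMK")
  co <- matrix(c(0, 0, 0, 3.8, 0, 0), 2, 3, byrow = TRUE)
  expect_error(read_model(toy_pdb(c("MET", "LYS"), 50:51, co), target),
               "ambiguous.*offsets.*-49.*-46|ambiguous.*offsets.*-46.*-49")
})

test_that("CA-only models are accepted with CA standing in for CB", {
  target <- target_sequence("t", "MKV")
  co <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE)
  m <- read_model(toy_pdb(c("MET", "LYS", "VAL"), 1:3, co), target)
  expect_equal(m$cb, m$ca)
  expect_false(any(m$cb_real))
  expect_identical(unname(unclass(assign_ss3(m))), rep("C", 3))
})

test_that("files without CA atoms are rejected", {
  target <- target_sequence("t", "MKV")
  line <- pdb_atom_line(1, "N", "MET", 1, 0, 0, 0)
  expect_error(read_model(c(line, "END"), target), "no CA atoms|no ATOM")
})

test_that("altloc resolves to the highest occupancy", {
  target <- target_sequence("t", "M")
  l1 <- pdb_atom_line(1, "CA", "MET", 1, 0, 0, 0, occ = 0.4, altloc = "A")
  l2 <- pdb_atom_line(2, "CA", "MET", 1, 9, 9, 9, occ = 0.6, altloc = "B")
  m <- read_model(c(l1, l2, "END"), target)
  expect_equal(unname(m$ca[1, ]), c(9, 9, 9))
})

test_that("selenomethionine maps to its parent letter", {
  target <- target_sequence("t", "MKV")
  lines <- c(pdb_atom_line(1, "CA", "MSE", 1, 0, 0, 0, record = "HETATM"),
             pdb_atom_line(2, "CA", "LYS", 2, 3.8, 0, 0),
             pdb_atom_line(3, "CA", "VAL", 3, 7.6, 0, 0), "END")
  m <- read_model(lines, target)
  expect_identical(m$res_codes[1], "M")
  expect_identical(m$target_positions, 1:3)
})

test_that("mapping never assigns two model residues to one target position", {
  ws <- ws_small()
  for (m in ws$models[1:3]) {
    expect_false(anyDuplicated(m$target_positions) > 0)
    expect_true(all(diff(m$target_positions) > 0))
  }
})

test_that("B-factor annotation writes %6.2f into columns 61-66", {
  target <- target_sequence("t", "MKV")
  co <- matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), 3, 3, byrow = TRUE)
  m <- read_model(toy_pdb(c("MET", "LYS", "VAL"), 1:3, co), target)
  err <- c(`1` = 3.90, `2` = 0.00, `3` = 12.25)
  out <- write_annotated_model(m, err)
  atom <- out[startsWith(out, "ATOM")]
  expect_identical(substr(atom[1], 61, 66), "  3.90")
  expect_identical(substr(atom[3], 61, 66), " 12.25")
  # all other columns unchanged
  expect_identical(substr(atom, 1, 60), substr(m$lines[1:3], 1, 60))
})

test_that("annotated models round-trip exactly", {
  ws <- ws_small()
  m <- ws$models[[2]]
  err <- stats::setNames(seq_along(m$target_positions) / 7,
                         m$target_positions)
  out <- write_annotated_model(m, err)
  m2 <- read_model(out, ws$target)
  expect_equal(m2$ca, m$ca)
  expect_identical(m2$target_positions, m$target_positions)
})

test_that("errors of 1000 A or more clamp to 999.99 with a warning", {
  target <- target_sequence("t", "M")
  m <- read_model(c(pdb_atom_line(1, "CA", "MET", 1, 0, 0, 0), "END"), target)
  expect_warning(out <- write_annotated_model(m, c(`1` = 12345)), "clamp")
  expect_identical(substr(out[1], 61, 66), "999.99")
})

test_that("a missing error value is an error, not a silent zero", {
  target <- target_sequence("t", "MK")
  co <- matrix(c(0, 0, 0, 3.8, 0, 0), 2, 3, byrow = TRUE)
  m <- read_model(toy_pdb(c("MET", "LYS"), 1:2, co), target)
  expect_error(write_annotated_model(m, c(`1` = 1.0)), "missing error")
})

test_that("multi-model NMR-style files score MODEL 1 only", {
  target <- target_sequence("t", "MK")
  co <- matrix(c(0, 0, 0, 3.8, 0, 0), 2, 3, byrow = TRUE)
  body <- toy_pdb(c("MET", "LYS"), 1:2, co)
  lines <- c("MODEL     1", body[1:2], "ENDMDL",
             "MODEL     2",
             pdb_atom_line(3, "CA", "MET", 1, 50, 0, 0),
             pdb_atom_line(4, "CA", "LYS", 2, 55, 0, 0),
             "ENDMDL", "END")
  m <- read_model(lines, target)
  expect_equal(nrow(m$ca), 2L)
  expect_equal(unname(m$ca[1, ]), c(0, 0, 0))
})

test_that("fasta round-trips the target sequence", {
  target <- target_sequence("toytarget", "MKVLAWY")
  path <- tempfile(fileext = ".fasta")
  write_fasta(target, path)
  t2 <- read_fasta(path)
  expect_identical(t2$id, target$id)
  expect_identical(t2$residues, target$residues)
})
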
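test_that("ATOM CA records are read back in file order", {
  lines <- c(atom_line(1, 1, 1, 0, 0, res3 = "GLY"),
             atom_line(2, 2, 2, 0, 0, res3 = "ALA"),
             atom_line(3, 3, 3, 0, 0, res3 = "LEU"),
             "END")
  tr <- read_calpha_trace(lines)
  expect_s3_class(tr, "calpha_trace")
  expect_equal(tr$residues$res_seq, 1:3)
  expect_equal(tr$residues$aa, c("G", "A", "L"))
  expect_equal(tr$residues$x, c(1, 2, 3))
  expect_equal(tr$chain_id, "A")
})

test_that("only the first-listed alternate location is kept", {
  lines <- c(atom_line(1, 5, 1.5, 0, 0, alt = "A"),
             atom_line(2, 5, 9.9, 0, 0, alt = "B"),
             atom_line(3, 6, 3.0, 0, 0),
             "END")
  tr <- read_calpha_trace(lines)
  expect_equal(nrow(tr$residues), 2L)
  expect_equal(tr$residues$x[tr$residues$res_seq == 5], 1.5)
})

test_that("first chain with CA atoms is the default; others selectable", {
  lines <- c(atom_line(1, 1, 1, 0, 0, chain = "B"),
             atom_line(2, 2, 2, 0, 0, chain = "B"),
             atom_line(3, 10, 5, 0, 0, chain = "C"),
             "END")
  expect_equal(read_calpha_trace(lines)$chain_id, "B")
  trc <- read_calpha_trace(lines, chain = "C")
  expect_equal(trc$residues$res_seq, 10L)
  expect_error(read_calpha_trace(lines, chain = "Z"), "empty chain")
})

test_that("HETATM records and later models are ignored", {
  lines <- c("MODEL        1",
             atom_line(1, 1, 1, 0, 0),
             atom_line(2, 2, 2, 0, 0),
             atom_line(3, 99, 9, 9, 9, record = "HETATM", res3 = "HOH"),
             "ENDMDL",
             "MODEL        2",
             atom_line(4, 1, 50, 0, 0),
             atom_line(5, 2, 51, 0, 0),
             "ENDMDL",
             "END")
  tr <- read_calpha_trace(lines)
  expect_equal(nrow(tr$residues), 2L)
  expect_equal(tr$residues$x, c(1, 2))
})

test_that("parsing tolerates missing trailing columns", {
  lines <- c(atom_line(1, 1, 1, 0, 0, trailing = ""),
             atom_line(2, 2, 2, 0, 0, trailing = ""))
  tr <- read_calpha_trace(lines)
  expect_equal(tr$residues$x, c(1, 2))
})

test_that("malformed coordinates and missing CA atoms are errors", {
  bad <- atom_line(1, 1, 1, 0, 0)
  substr(bad, 33, 35) <- "abc"
  expect_error(read_calpha_trace(c(bad, "END")), "malformed.*line 1")
  expect_error(read_calpha_trace(c("REMARK nothing", "END")),
               "no CA ATOM records")
})

test_that("trace_sequence translates residues, unknowns to X", {
  lines <- c(atom_line(1, 1, 1, 0, 0, res3 = "GLY"),
             atom_line(2, 2, 2, 0, 0, res3 = "ALA"),
             atom_line(3, 3, 3, 0, 0, res3 = "UNK"),
             "END")
  expect_equal(trace_sequence(read_calpha_trace(lines)), "GAX")
})

test_that("write/parse round trip preserves numbering, sequence, coords", {
  tr <- make_helix(12)
  tr$residues$aa <- strsplit("MKVLAGDERTYW", "")[[1]]
  lines <- write_trace_pdb(tr)
  back <- read_calpha_trace(lines)
  expect_equal(back$residues$res_seq, tr$residues$res_seq)
  expect_equal(back$residues$aa, tr$residues$aa)
  expect_equal(back$residues$x, round(tr$residues$x, 3))
  expect_equal(back$residues$z, round(tr$residues$z, 3))
})
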
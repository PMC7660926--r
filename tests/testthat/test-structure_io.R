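test_that("read_pdb rejects degenerate and malformed input", {
  expect_error(read_pdb(""), "empty input")
  expect_error(read_pdb("   \n  \n"), "empty input")
  # malformed fixed-column line: coordinate field is not numeric
  good <- write_pdb(tiny_helix(4))
  lines <- strsplit(good, "\n")[[1]]
  atom_line <- grep("^ATOM", lines)[2]
  substr(lines[atom_line], 31, 38) <- "  xx.yyy"
  expect_error(read_pdb(paste(lines, collapse = "\n")),
               "line 3.*coordinate")
})

test_that("write_pdb/read_pdb round-trip preserves structure to 1e-3 A", {
  h <- make_ideal_helix(20, strrep("A", 20))
  s <- read_pdb(write_pdb(h))
  expect_s3_class(s, "ddg_structure")
  expect_equal(n_residues(s), 20L)
  rt <- residue_table(s)
  expect_true(all(rt$n_atoms >= 4L))
  expect_true(all(rt$resolved))
  expect_equal(s$atoms$atom, h$atoms$atom)
  for (cc in c("x", "y", "z"))
    expect_lt(max(abs(s$atoms[[cc]] - h$atoms[[cc]])), 1e-3)
  # double round-trip is exact (identity on the quantised grid)
  s2 <- read_pdb(write_pdb(s))
  expect_identical(s2$atoms[c("x", "y", "z")], s$atoms[c("x", "y", "z")])
})

test_that("insertion codes and author numbering survive a round-trip", {
  h <- tiny_helix(6)
  h$atoms$icode[h$atoms$resno == 3L] <- "A"
  h$atoms$resno <- h$atoms$resno + 340L # FLCN-like author numbering
  s <- read_pdb(write_pdb(h))
  rt <- residue_table(s)
  expect_equal(rt$resno, 341:346)
  expect_equal(rt$icode[rt$resno == 343L], "A")
})

test_that("HETATM, waters and non-standard residues are dropped with warning", {
  txt <- paste(
    write_pdb(tiny_helix(5)),
    "HETATM 9999  O   HOH A 900      10.000  10.000  10.000  1.00  0.00           O",
    sep = "\n")
  expect_warning(s <- read_pdb(txt), "HETATM")
  expect_equal(n_residues(s), 5L)
})

test_that("altloc resolution honours the policy", {
  h <- tiny_helix(4)
  a <- h$atoms
  dup <- a[a$resno == 2L & a$atom == "CA", , drop = FALSE]
  a$altloc[a$resno == 2L & a$atom == "CA"] <- "A"
  a$occ[a$resno == 2L & a$atom == "CA"] <- 0.4
  dup$altloc <- "B"; dup$occ <- 0.6; dup$x <- dup$x + 5
  txt <- write_pdb(new_structure(rbind(a, dup), source_id = "altloc"))
  s_hi <- read_pdb(txt, altloc_policy = "highest_occupancy")
  s_first <- read_pdb(txt, altloc_policy = "first")
  ca_hi <- s_hi$atoms[s_hi$atoms$resno == 2L & s_hi$atoms$atom == "CA", ]
  ca_first <- s_first$atoms[s_first$atoms$resno == 2L &
                              s_first$atoms$atom == "CA", ]
  expect_equal(nrow(ca_hi), 1L)
  expect_equal(ca_hi$altloc, "B")          # occupancy 0.6 wins
  expect_equal(ca_first$altloc, "A")       # file order wins
})

test_that("residues missing backbone atoms are flagged, not dropped", {
  s <- flagged_helix()
  rt <- residue_table(s)
  expect_equal(nrow(rt), 12L)
  expect_false(rt$resolved[rt$resno == 5L])
  expect_equal(sum(rt$resolved), 11L)
  expect_true(5L %in% s$flagged$resno)
})

test_that("slice_domain selects ranges, errors and records gaps", {
  h <- make_ideal_helix(20, strrep("A", 20))
  expect_equal(n_residues(slice_domain(h, "A", 5, 5)), 1L)
  full <- slice_domain(h, "A", 1, 20)
  expect_equal(residue_table(full)$resno, residue_table(h)$resno)
  expect_error(slice_domain(h, "B", 1, 5), "chain 'B'")
  expect_error(slice_domain(h, "A", 30, 40), "empty slice")
  expect_error(slice_domain(h, "A", 10, 5), "start")
  g <- slice_domain(gapped_helix(), "A", 1, 20)
  expect_equal(n_residues(g), 19L)
  expect_equal(g$missing_positions, 10L)
  # a 341-566 style slice can never exceed 226 positions
  h2 <- tiny_helix(8)
  h2$atoms$resno <- h2$atoms$resno + 340L
  expect_lte(n_residues(slice_domain(h2, "A", 341, 566)), 226L)
})

test_that("nested slices compose", {
  h <- make_ideal_helix(20, strrep("A", 20))
  ab <- slice_domain(h, "A", 3, 18)
  inner1 <- slice_domain(ab, "A", 5, 12)
  inner2 <- slice_domain(h, "A", 5, 12)
  expect_equal(residue_table(inner1)[c("resno", "aa")],
               residue_table(inner2)[c("resno", "aa")])
})

test_that("empty structures cannot be written", {
  h <- tiny_helix(4)
  h$atoms <- h$atoms[0, , drop = FALSE]
  expect_error(write_pdb(h), "empty")
})

test_that("parsing preserves file order of residues", {
  h <- tiny_helix(6)
  s <- read_pdb(write_pdb(h))
  expect_equal(residue_table(s)$resno, residue_table(h)$resno)
})
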
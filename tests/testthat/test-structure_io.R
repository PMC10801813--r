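test_that("generated fixtures round-trip through the PDB reader", {
  pl <- data.frame(res_a = "A:2", res_b = "B:1", dist = 5.25,
                   plddt_a = 81.37, plddt_b = 62.04,
                   pae_ab = 9.5, pae_ba = 11.5)
  spec <- fixture_spec(c(A = 3, B = 4), planted = pl,
                       atoms_per_residue = 3)
  fx <- generate_fixture(spec, withr::local_tempdir())
  m <- read_structure(fx$structure_path)

  expect_s3_class(m, "afm_structure")
  expect_identical(m$chains, c("A", "B"))
  expect_identical(nrow(m$residues), 7L)
  expect_identical(m$residues$concat_idx, 1:7)
  expect_identical(nrow(m$atoms), 21L)
  # pLDDT to B-factor field precision (0.01)
  expect_equal(m$residues$plddt[m$residues$chain == "A" &
                                  m$residues$resno == 2], 81.37)
  expect_equal(m$residues$plddt[m$residues$chain == "B" &
                                  m$residues$resno == 1], 62.04)
  expect_true(all(m$residues$plddt[-c(2, 4)] == 40))
  # coordinates to PDB field precision (0.001)
  ca <- m$atoms[m$atoms$atom == "CA" & m$atoms$chain == "A" &
                  m$atoms$resno == 3, ]
  expect_equal(c(ca$x, ca$y, ca$z), c(40, 0, 0), tolerance = 1e-9)
})

test_that("mmCIF and PDB readers agree on the same fixture", {
  spec <- fixture_spec(c(A = 3, B = 3),
                       planted = data.frame(res_a = "A:1", res_b = "B:2",
                                            dist = 4.5, plddt_a = 70,
                                            plddt_b = 75, pae_ab = 3,
                                            pae_ba = 5))
  d <- withr::local_tempdir()
  fp <- generate_fixture(spec, d, basename = "p", format = "pdb")
  fc <- generate_fixture(spec, d, basename = "c", format = "mmcif")
  mp <- read_structure(fp$structure_path)
  mc <- read_structure(fc$structure_path)
  expect_identical(mc$chains, mp$chains)
  expect_equal(mc$residues$plddt, mp$residues$plddt)
  expect_equal(mc$residues$concat_idx, mp$residues$concat_idx)
  expect_equal(mc$atoms[, c("x", "y", "z")], mp$atoms[, c("x", "y", "z")])
})

test_that("uniform B-factors become the per-residue pLDDT verbatim", {
  atoms <- data.frame(chain = rep(c("A", "B"), each = 2),
                      resno = c(1, 2, 1, 2), resname = "ALA",
                      atom = "CA", element = "C",
                      x = c(0, 20, 0, 20), y = c(0, 0, 30, 30), z = 0,
                      plddt = 91.3)
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_file(atoms, p)
  m <- read_structure(p)
  expect_true(all(m$residues$plddt == 91.3))
})

test_that("reader rejects malformed or single-chain inputs", {
  d <- withr::local_tempdir()
  one <- data.frame(chain = "A", resno = 1:2, resname = "ALA", atom = "CA",
                    element = "C", x = c(0, 20), y = 0, z = 0, plddt = 50)
  p1 <- file.path(d, "one.pdb")
  write_pdb_file(one, p1)
  expect_error(read_structure(p1), "2 chains")
  expect_error(read_structure(file.path(d, "absent.pdb")), "not found")
  # zero-residue chains are unrepresentable in a coordinate file; the
  # generator refuses the spec outright
  expect_error(fixture_spec(c(A = 0, B = 3)))
})

test_that("pLDDT on a 0-1 scale is rescaled with a warning", {
  atoms <- data.frame(chain = rep(c("A", "B"), each = 1), resno = 1,
                      resname = "ALA", atom = "CA", element = "C",
                      x = 0, y = c(0, 30), z = 0, plddt = c(0.91, 0.55))
  p <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_file(atoms, p)
  expect_warning(m <- read_structure(p), "0-1 scale")
  expect_equal(m$residues$plddt, c(91, 55))
})

test_that("hydrogens are retained but flagged non-heavy", {
  spec <- fixture_spec(c(A = 2, B = 2), add_hydrogens = TRUE)
  fx <- generate_fixture(spec, withr::local_tempdir())
  m <- read_structure(fx$structure_path)
  expect_identical(sum(!m$atoms$heavy), 4L)
  expect_identical(sum(m$atoms$heavy), 4L)
  expect_true(all(m$atoms$element[!m$atoms$heavy] == "H"))
})

test_that("PAE reader handles both dialects and rejects bad arrays", {
  d <- withr::local_tempdir()
  # ColabFold dialect, directional values preserved
  p1 <- file.path(d, "cf.json")
  writeLines('{"pae": [[0,3],[4,0]], "max_pae": 31.75}', p1)
  m1 <- read_pae(p1)
  expect_identical(attr(m1, "size"), 2L)
  expect_equal(m1[1, 2], 3)
  expect_equal(m1[2, 1], 4)
  # AFDB dialect wrapped in a one-element list
  p2 <- file.path(d, "afdb.json")
  writeLines(paste0('[{"predicted_aligned_error": ',
                    '[[0,1,2],[1,0,1],[2,1,0]]}]'), p2)
  m2 <- read_pae(p2)
  expect_identical(attr(m2, "size"), 3L)
  # ragged array
  p3 <- file.path(d, "ragged.json")
  writeLines('{"pae": [[1,2],[3]]}', p3)
  expect_error(read_pae(p3), "ragged|square|2-D")
  # non-square
  p4 <- file.path(d, "nonsq.json")
  writeLines('{"pae": [[1,2,3],[4,5,6]]}', p4)
  expect_error(read_pae(p4), "square")
  # unknown dialect names the keys found
  p5 <- file.path(d, "alien.json")
  writeLines('{"distance_error": [[0]]}', p5)
  expect_error(read_pae(p5), "distance_error")
})

test_that("binding checks size and exposes directional PAE lookup", {
  spec <- fixture_spec(c(A = 3, B = 3))
  fx <- generate_fixture(spec, withr::local_tempdir())
  m <- read_structure(fx$structure_path)
  v <- matrix(0, 6, 6)
  v[1, 4] <- 7.5; v[4, 1] <- 9.5
  pae <- structure(v, size = 6L, class = c("pae_matrix", "matrix", "array"))
  pred <- bind_prediction(m, pae)
  # concat index: A residues 1-3, B residues 4-6
  expect_equal(pae_of(pred, "A:1", "B:1"), 7.5)
  expect_equal(pae_of(pred, "B:1", "A:1"), 9.5)
  bad <- structure(matrix(0, 5, 5), size = 5L,
                   class = c("pae_matrix", "matrix", "array"))
  expect_error(bind_prediction(m, bad), "PAE size 5 != 6 residues")
  # symmetric matrix: both directions agree
  sym <- structure(matrix(2, 6, 6), size = 6L,
                   class = c("pae_matrix", "matrix", "array"))
  ps <- bind_prediction(m, sym)
  expect_equal(pae_of(ps, "A:2", "B:3"), pae_of(ps, "B:3", "A:2"))
})

test_that("re-reading the same file leaves the concatenated index invariant", {
  spec <- fixture_spec(c(Q = 4, C = 3, A = 2))
  fx <- generate_fixture(spec, withr::local_tempdir())
  m1 <- read_structure(fx$structure_path)
  m2 <- read_structure(fx$structure_path)
  expect_identical(m1$residues, m2$residues)
  # chain order is file order, not alphabetical
  expect_identical(m1$chains, c("Q", "C", "A"))
})
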
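test_that("a planted residue pair passing all three filters is the one contact", {
  pl <- data.frame(res_a = "A:1", res_b = "B:1", dist = 5,
                   plddt_a = 80, plddt_b = 60, pae_ab = 10, pae_ba = 10)
  fx <- generate_fixture(fixture_spec(c(A = 3, B = 3), planted = pl),
                         withr::local_tempdir())
  pred <- read_fixture(fx)
  cs <- find_contacts(pred, c("A", "B"))
  expect_identical(n_contacts(cs), 1L)
  ct <- contacts_table(cs)
  expect_equal(ct$avg_plddt, 70)
  expect_equal(ct$min_pae, 10)
  expect_equal(ct$min_heavy_dist, 5, tolerance = 1e-3)
  expect_identical(cs$contacts$key, "A:1--B:1")
  # matches the brute-force all-pairs oracle
  expect_identical(sort(cs$contacts$key), brute_force_contact_keys(pred, c("A", "B")))
})

test_that("all three filter comparisons are strict", {
  d <- withr::local_tempdir()
  # pair-average pLDDT exactly at the threshold fails
  pl <- data.frame(res_a = "A:1", res_b = "B:1", dist = 5,
                   plddt_a = 50, plddt_b = 50, pae_ab = 10, pae_ba = 10)
  fx <- generate_fixture(fixture_spec(c(A = 3, B = 3), planted = pl), d,
                         basename = "plddt50")
  expect_identical(n_contacts(find_contacts(read_fixture(fx), c("A", "B"))), 0L)

  # atoms exactly 8.000 A apart fail "closer than 8"
  atoms <- data.frame(chain = c("A", "B"), resno = 1, resname = "ALA",
                      atom = "CA", element = "C",
                      x = c(0, 8), y = 0, z = 0, plddt = 80)
  p <- file.path(d, "exact8.pdb")
  write_pdb_file(atoms, p)
  pred <- bind_prediction(read_structure(p),
                          read_pae(write_pae_json(matrix(c(0, 5, 5, 0), 2),
                                                  file.path(d, "p8.json"))))
  expect_identical(n_contacts(find_contacts(pred, c("A", "B"))), 0L)
  # and 7.999 A passes
  atoms$x[2] <- 7.999
  write_pdb_file(atoms, p)
  pred <- bind_prediction(read_structure(p),
                          read_pae(file.path(d, "p8.json")))
  expect_identical(n_contacts(find_contacts(pred, c("A", "B"))), 1L)

  # minimum PAE exactly at the threshold fails
  pl2 <- data.frame(res_a = "A:1", res_b = "B:1", dist = 5,
                    plddt_a = 80, plddt_b = 80, pae_ab = 15, pae_ba = 15)
  fx2 <- generate_fixture(fixture_spec(c(A = 3, B = 3), planted = pl2), d,
                          basename = "pae15")
  expect_identical(n_contacts(find_contacts(read_fixture(fx2), c("A", "B"))), 0L)
})

test_that("minimum PAE takes the better of the two directions", {
  pl <- data.frame(res_a = "A:2", res_b = "B:2", dist = 5,
                   plddt_a = 80, plddt_b = 80, pae_ab = 22, pae_ba = 9)
  fx <- generate_fixture(fixture_spec(c(A = 3, B = 3), planted = pl),
                         withr::local_tempdir())
  cs <- find_contacts(read_fixture(fx), c("A", "B"))
  expect_identical(n_contacts(cs), 1L)
  expect_equal(cs$contacts$min_pae, 9)
})

test_that("random fixtures match the brute-force oracle key for key", {
  for (seed in 1:25) {
    fx <- generate_fixture(random_fixture_spec(seed),
                           withr::local_tempdir())
    pred <- read_fixture(fx)
    cs <- find_contacts(pred, c("A", "B"))
    expect_identical(sort(cs$contacts$key),
                     brute_force_contact_keys(pred, c("A", "B")),
                     label = paste("seed", seed))
  }
})

test_that("contact detection is independent of chain argument order", {
  fx <- generate_fixture(random_ensemble_spec(11)$base,
                         withr::local_tempdir())
  pred <- read_fixture(fx)
  ab <- find_contacts(pred, c("A", "B"))
  ba <- find_contacts(pred, c("B", "A"))
  expect_identical(ab$chain_pair, ba$chain_pair)
  expect_identical(sort(ab$contacts$key), sort(ba$contacts$key))
})

test_that("hydrogens never affect the contact set", {
  pl <- data.frame(res_a = c("A:1", "A:3"), res_b = c("B:2", "B:4"),
                   dist = c(4, 6.5), plddt_a = 80, plddt_b = 70,
                   pae_ab = 5, pae_ba = 8)
  d <- withr::local_tempdir()
  bare <- generate_fixture(fixture_spec(c(A = 4, B = 4), planted = pl),
                           d, basename = "bare")
  with_h <- generate_fixture(fixture_spec(c(A = 4, B = 4), planted = pl,
                                          add_hydrogens = TRUE),
                             d, basename = "withh")
  cs1 <- find_contacts(read_fixture(bare), c("A", "B"))
  cs2 <- find_contacts(read_fixture(with_h), c("A", "B"))
  expect_identical(cs1$contacts$key, cs2$contacts$key)
  expect_equal(cs1$contacts$min_heavy_dist, cs2$contacts$min_heavy_dist)
})

test_that("widening thresholds never removes contacts, narrowing never adds", {
  for (seed in c(3, 14, 27)) {
    fx <- generate_fixture(random_fixture_spec(seed, max_planted = 4),
                           withr::local_tempdir())
    pred <- read_fixture(fx)
    base <- find_contacts(pred, c("A", "B"))$contacts$key
    wide <- find_contacts(pred, c("A", "B"),
                          contact_thresholds(min_avg_plddt = 30,
                                             max_min_pae = 30,
                                             max_heavy_dist = 12))$contacts$key
    narrow <- find_contacts(pred, c("A", "B"),
                            contact_thresholds(min_avg_plddt = 70,
                                               max_min_pae = 8,
                                               max_heavy_dist = 5))$contacts$key
    expect_true(all(base %in% wide), label = paste("widen seed", seed))
    expect_true(all(narrow %in% base), label = paste("narrow seed", seed))
  }
})

test_that("unknown chains error and empty interfaces are valid", {
  fx <- generate_fixture(fixture_spec(c(A = 2, B = 2)),
                         withr::local_tempdir())
  pred <- read_fixture(fx)
  expect_error(find_contacts(pred, c("A", "Z")), "chain 'Z'")
  expect_error(find_contacts(pred, c("A", "A")), "inter-chain")
  cs <- find_contacts(pred, c("A", "B"))
  expect_identical(n_contacts(cs), 0L)
  expect_identical(contact_map(cs), list())
})

test_that("contact_map lists each residue's sorted partners twice per contact", {
  cs <- make_contact_set("m1", res_a = c("1", "1", "2", "3"),
                         res_b = c("3", "4", "3", "1"),
                         avg_plddt = rep(80, 4), min_pae = rep(5, 4))
  m <- contact_map(cs)
  expect_identical(m[["A:1"]], c("B:3", "B:4"))
  expect_identical(m[["B:3"]], c("A:1", "A:2"))
  expect_identical(sum(lengths(m)), 8L)
  one <- contact_map(make_contact_set("m1", "1", "3", 80, 5))
  expect_identical(one, list(`A:1` = "B:3", `B:3` = "A:1"))
})
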
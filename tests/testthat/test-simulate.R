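test_that("reference simulation is deterministic with controlled structure", {
  w1 <- simulate_reference_set(n_species = 6, gene_length = 500,
                               divergence = 0.1, seed = 17)
  w2 <- simulate_reference_set(n_species = 6, gene_length = 500,
                               divergence = 0.1, seed = 17)
  expect_identical(as.character(w1$db$seqs), as.character(w2$db$seqs))
  w3 <- simulate_reference_set(n_species = 6, gene_length = 500,
                               divergence = 0.1, seed = 18)
  expect_false(identical(as.character(w1$db$seqs), as.character(w3$db$seqs)))

  flat <- simulate_reference_set(n_species = 4, gene_length = 300,
                                 divergence = 0, near_pair = NULL, seed = 2)
  ss <- as.character(flat$db$seqs)
  expect_true(all(ss == ss[1]))
  expect_equal(pairwise_identity(ss[1], ss[2]), 100)
  expect_error(simulate_reference_set(n_species = 3,
                                      near_pair = list(i = 2, j = 5)),
               "out of range")
})

test_that("the planted near-pair differs at exactly the rounded site count", {
  w <- simulate_reference_set(n_species = 10, gene_length = 1550,
                              divergence = 0.1,
                              near_pair = list(i = 9, j = 10, identity = 99.5),
                              seed = 21)
  a <- strsplit(as.character(w$db$seqs[["ref_sp09"]]), "")[[1]]
  b <- strsplit(as.character(w$db$seqs[["ref_sp10"]]), "")[[1]]
  expect_equal(sum(a != b), round(0.005 * 1550))  # 8 sites
  ident <- pairwise_identity(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_lt(abs(ident - 99.5), 0.1 + 1e-9)
  # the twins share a genus; other species have their own
  expect_equal(w$tree["sp09", "parent_id"], w$tree["sp10", "parent_id"])
  expect_false(w$tree["sp01", "parent_id"] == w$tree["sp02", "parent_id"])
})

test_that("community simulation respects composition, purity, and errors", {
  w <- simulate_reference_set(n_species = 3, gene_length = 400,
                              divergence = 0.1, near_pair = NULL, seed = 3)
  pure <- simulate_community(w$db, c(sp01 = 1), 25, read_length = 100:120,
                             error_rate = 0, seed = 4)
  ref <- as.character(w$db$seqs[["ref_sp01"]])
  expect_true(all(vapply(pure$reads, function(r) grepl(r, ref, fixed = TRUE),
                         logical(1))))
  expect_true(all(pure$truth$length %in% 100:120))

  big <- simulate_community(w$db, c(sp01 = 0.7, sp02 = 0.3), 10000,
                            read_length = 100, error_rate = 0, seed = 5)
  frac <- mean(big$truth$taxon_id == "sp01")
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / 10000))

  noisy <- simulate_community(w$db, c(sp01 = 1), 20, read_length = 150,
                              error_rate = 0.1, seed = 6)
  expect_gt(sum(noisy$truth$n_errors), 0)
  expect_identical(
    simulate_community(w$db, c(sp01 = 1), 10, read_length = 100, seed = 7),
    simulate_community(w$db, c(sp01 = 1), 10, read_length = 100, seed = 7))
  expect_error(simulate_community(w$db, c(ghost = 1), 5, seed = 1),
               "not in db")
})

test_that("heavy read errors collapse assignments toward unassigned", {
  w <- simulate_reference_set(n_species = 3, gene_length = 400,
                              divergence = 0.1, near_pair = NULL, seed = 3)
  noisy <- simulate_community(w$db, c(sp01 = 1), 15, read_length = 170,
                              error_rate = 0.5, seed = 8)
  cls <- classify_dataset(noisy$reads, w$db, w$tree)
  expect_gt(cls$counts[["UNASSIGNED"]], 10)
})

test_that("coding pools plant recoverable domains with exact truth tables", {
  p1 <- calibrate_profile(domain_profile("DOMA", strrep("MKVLW", 6)), seed = 31)
  p2 <- calibrate_profile(domain_profile("DOMB", strrep("HTRGS", 6)), seed = 32)
  none <- simulate_coding_pool(10, list(p1, p2), plant_fraction = 0, seed = 33)
  expect_equal(nrow(none$truth), 0L)
  expect_identical(none, simulate_coding_pool(10, list(p1, p2),
                                              plant_fraction = 0, seed = 33))
  all_pl <- simulate_coding_pool(20, list(p1, p2), plant_fraction = 1, seed = 34)
  expect_equal(nrow(all_pl$truth), 20L)
  expect_setequal(unique(all_pl$truth$domain_id), c("DOMA", "DOMB"))
  # every planted read carries its consensus in the +1 frame
  for (k in seq_len(10)) {
    fr <- six_frame_translate(all_pl$reads[[all_pl$truth$read_id[k]]])
    cons <- if (all_pl$truth$domain_id[k] == "DOMA") p1$consensus else p2$consensus
    expect_true(grepl(cons, fr[["+1"]], fixed = TRUE))
  }
  expect_error(simulate_coding_pool(5, list(p1), plant_fraction = 1,
                                    orf_len = 10), "wider")
})
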
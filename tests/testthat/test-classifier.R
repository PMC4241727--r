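two_genus_tree <- function() {
  ranks <- tax_ranks()
  spine <- data.frame(id = paste0("L", 1:6), parent_id = c(NA, paste0("L", 1:5)),
                      rank = ranks[1:6], name = paste0("L", 1:6),
                      stringsAsFactors = FALSE)
  rest <- data.frame(id = c("gA", "gB", "sA1", "sA2", "sB1"),
                     parent_id = c("L6", "L6", "gA", "gA", "gB"),
                     rank = c("genus", "genus", "species", "species", "species"),
                     name = c("gA", "gB", "sA1", "sA2", "sB1"),
                     stringsAsFactors = FALSE)
  load_taxonomy(rbind(spine, rest))
}

hitdf <- function(bits, taxa) {
  data.frame(ref_id = sprintf("r%d", seq_along(bits)), taxon_id = taxa,
             bit_score = bits, stringsAsFactors = FALSE)
}

test_that("hit filtering applies the bit floor then the top-percent window", {
  p <- classifier_params(min_bit = 150, top_percent = 10)
  expect_equal(nrow(filter_hits(hitdf(numeric(0), character(0)), p)), 0L)
  h <- hitdf(c(200, 185, 179, 160, 149), rep("sA1", 5))
  kept <- filter_hits(h, p)
  # retention cutoff is 200 * 0.9 = 180 bits
  expect_equal(kept$bit_score, c(200, 185))
  set.seed(77)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    h <- hitdf(sort(runif(n, 0, 300), decreasing = TRUE),
               sample(c("sA1", "sA2", "sB1"), n, TRUE))
    mb <- runif(1, 0, 250); tp <- runif(1, 0.5, 100)
    p2 <- classifier_params(min_bit = mb, top_percent = tp)
    expect_equal(filter_hits(h, p2)$bit_score,
                 filter_oracle(h, mb, tp)$bit_score)
  }
})

test_that("narrowing the top-percent window never broadens the retained set", {
  set.seed(31)
  h <- hitdf(sort(runif(10, 100, 300), decreasing = TRUE), rep("sA1", 10))
  prev <- filter_hits(h, classifier_params(min_bit = 120, top_percent = 100))$ref_id
  for (tp in c(50, 25, 10, 5, 1)) {
    cur <- filter_hits(h, classifier_params(min_bit = 120, top_percent = tp))$ref_id
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("read assignment: single species, sibling LCA, unassigned", {
  tree <- two_genus_tree()
  p <- classifier_params(min_bit = 150, top_percent = 10)
  a <- assign_read(hitdf(200, "sA1"), tree, p)
  expect_equal(a$taxon_id, "sA1"); expect_equal(a$rank_achieved, "species")
  a <- assign_read(hitdf(c(200, 195), c("sA1", "sA2")), tree, p)
  expect_equal(a$taxon_id, "gA"); expect_equal(a$rank_achieved, "genus")
  a <- assign_read(hitdf(c(100, 90), c("sA1", "sA2")), tree, p)
  expect_equal(a$taxon_id, "UNASSIGNED")
  expect_equal(a$n_hits_retained, 0L)
})

test_that("assignment equals the brute-force filter + path-intersection oracle", {
  set.seed(53)
  tree <- two_genus_tree()
  sp <- c("sA1", "sA2", "sB1")
  for (i in 1:60) {
    n <- sample(0:8, 1)
    h <- hitdf(runif(n, 50, 300), sample(sp, n, TRUE))
    h <- h[order(-h$bit_score), , drop = FALSE]
    p <- classifier_params(min_bit = runif(1, 40, 250),
                           top_percent = runif(1, 1, 60))
    got <- assign_read(h, tree, p)
    kept <- filter_oracle(h, p$min_bit, p$top_percent)
    want <- if (nrow(kept) == 0) "UNASSIGNED" else lca_oracle(tree, kept$taxon_id)
    expect_identical(got$taxon_id, want)
  }
})

mk_assign <- function(taxa, tree) {
  data.frame(read_id = sprintf("r%03d", seq_along(taxa)), taxon_id = taxa,
             rank_achieved = ifelse(taxa == "UNASSIGNED", NA_character_,
                                    tree[taxa, "rank"]),
             n_hits_retained = 1L, stringsAsFactors = FALSE)
}

test_that("minimal support pushes reads up the hand-traced chain", {
  tree <- two_genus_tree()
  p1 <- classifier_params(min_support = 1)
  a <- mk_assign(rep("sA1", 19), tree)
  expect_identical(apply_min_support(a, tree, p1), a)

  # 19 reads on a species, support 20, nothing else under the lineage:
  # pushed through genus, family, ... up to the root
  p20 <- classifier_params(min_support = 20)
  out <- apply_min_support(a, tree, p20)
  expect_true(all(out$taxon_id == "L1"))
  expect_true(all(out$rank_achieved == "root"))

  # sibling species 12 + 9: both pushed to the shared genus (21 >= 20), stop
  b <- mk_assign(c(rep("sA1", 12), rep("sA2", 9)), tree)
  out <- apply_min_support(b, tree, p20)
  expect_true(all(out$taxon_id == "gA"))
  expect_true(all(out$rank_achieved == "genus"))

  # push-up never deepens a read's rank
  depths_in <- rank_depth(b$rank_achieved)
  depths_out <- rank_depth(out$rank_achieved)
  expect_true(all(depths_out <= depths_in))

  # discard mode removes instead of pushing
  out2 <- apply_min_support(mk_assign(rep("sA1", 5), tree), tree, p20,
                            mode = "discard")
  expect_true(all(out2$taxon_id == "UNASSIGNED"))
})

test_that("dataset classification conserves reads and flags foreign reads", {
  w <- simulate_reference_set(n_species = 5, gene_length = 300,
                              divergence = 0.12, near_pair = NULL, seed = 8)
  empty <- classify_dataset(character(0), w$db, w$tree)
  expect_equal(nrow(empty$assignments), 0L)
  expect_equal(sum(empty$counts), 0L)

  sim <- simulate_community(w$db, c(sp01 = 0.6, sp02 = 0.4), 40,
                            read_length = 120:150, error_rate = 0, seed = 2)
  foreign <- vapply(1:10, function(i) random_dna_chr(130), "")
  names(foreign) <- paste0("alien", 1:10)
  reads <- c(sim$reads, foreign)
  cls <- classify_dataset(reads, w$db, w$tree,
                          params = classifier_params(min_bit = 150, top_percent = 10))
  expect_equal(sum(cls$counts), length(reads))            # conservation
  expect_equal(unname(cls$counts["UNASSIGNED"]), 10L)     # aliens unreachable
  genuine <- cls$assignments[!grepl("^alien", cls$assignments$read_id), ]
  expect_true(all(genuine$taxon_id == sim$truth$taxon_id[
    match(genuine$read_id, sim$truth$read_id)]))
})
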
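profile_tree <- function() {
  ranks <- tax_ranks()
  spine <- data.frame(id = paste0("L", 1:4), parent_id = c(NA, paste0("L", 1:3)),
                      rank = ranks[1:4], name = paste0("L", 1:4),
                      stringsAsFactors = FALSE)
  rest <- data.frame(
    id = c("ordA", "ordB", "famA", "famB", "genA", "genB", "spA1", "spA2", "spB1"),
    parent_id = c("L4", "L4", "ordA", "ordB", "famA", "famB", "genA", "genA", "genB"),
    rank = c("order", "order", "family", "family", "genus", "genus",
             "species", "species", "species"),
    name = c("order A", "order B", "fam A", "fam B", "gen A", "gen B",
             "sp A1", "sp A2", "sp B1"),
    stringsAsFactors = FALSE)
  load_taxonomy(rbind(spine, rest))
}

test_that("subsampling is boundary-safe and seed-reproducible", {
  reads <- stats::setNames(rep("ACGT", 50), sprintf("r%02d", 1:50))
  expect_identical(subsample_reads(reads, 50, seed = 1), reads)
  expect_warning(out <- subsample_reads(reads, 60, seed = 1), "whole pool")
  expect_identical(out, reads)
  expect_length(subsample_reads(reads, 0, seed = 1), 0L)
  s1 <- subsample_reads(reads, 20, seed = 9)
  s2 <- subsample_reads(reads, 20, seed = 9)
  expect_identical(s1, s2)
  expect_length(s1, 20L)
  expect_true(all(names(s1) %in% names(reads)))
})

test_that("rank abundance pools reads assigned above the rank", {
  tree <- profile_tree()
  # all reads on one species -> 100% for its order
  ab <- rank_abundance(c(spA1 = 30L), tree, "order")
  expect_equal(unname(ab["ordA"]), 100)
  expect_equal(unname(ab["unclassified"]), 0)
  # 62 at order-resolvable depth, 38 stuck at domain level
  ab <- rank_abundance(c(spA1 = 62L, L2 = 38L), tree, "order")
  expect_equal(unname(ab["ordA"]), 62)
  expect_equal(unname(ab["unclassified"]), 38)
  expect_equal(sum(ab), 100)
  # separate mode distinguishes above-rank from unassigned
  ab <- rank_abundance(c(spA1 = 50L, L2 = 25L, UNASSIGNED = 25L), tree, "order",
                       unclassified = "separate")
  expect_equal(unname(ab["unclassified_above_rank"]), 25)
  expect_equal(unname(ab["unassigned"]), 25)
  expect_error(rank_abundance(c(spA1 = 10L), tree, "strain"), "unknown rank")
})

test_that("rank abundance equals a hand-rolled aggregation oracle", {
  tree <- profile_tree()
  nodes <- c("spA1", "spA2", "spB1", "genA", "famB", "ordA", "L2", "UNASSIGNED")
  set.seed(44)
  for (i in 1:15) {
    counts <- stats::setNames(as.integer(rpois(length(nodes), 6)) + 1L, nodes)
    for (rank in c("order", "family", "genus", "species")) {
      got <- rank_abundance(counts, tree, rank)
      want <- stats::setNames(numeric(0), character(0))
      uncls <- 0
      for (nd in names(counts)) {
        if (nd == "UNASSIGNED") { uncls <- uncls + counts[[nd]]; next }
        p <- tax_path(tree, nd)
        anc <- p[tree[p, "rank"] == rank]
        if (length(anc) == 0) uncls <- uncls + counts[[nd]]
        else want[anc] <- (if (anc %in% names(want)) want[[anc]] else 0) + counts[[nd]]
      }
      want <- c(want[order(names(want))], unclassified = uncls)
      expect_equal(got, 100 * want / sum(counts))
      expect_equal(sum(got), 100, tolerance = 1e-9)
    }
  }
})

test_that("species profile reports the species-level assigned fraction", {
  tree <- profile_tree()
  out <- species_profile(c(spA1 = 40L, spA2 = 18L, genA = 42L), tree)
  expect_equal(out$assigned_fraction, 0.58)
  expect_equal(unname(out$abundance["spA1"]), 40)
  expect_equal(unname(out$abundance["unclassified"]), 42)
  expect_equal(sum(out$abundance), 100)
  all_sp <- species_profile(c(spA1 = 10L, spB1 = 10L), tree)
  expect_equal(all_sp$assigned_fraction, 1)
  expect_error(species_profile(c(spA1 = 0L), tree), "no reads")
})

test_that("abundance tables align categories across samples and write TSV", {
  tree <- profile_tree()
  rows <- list(s1 = rank_abundance(c(spA1 = 3L, spB1 = 1L), tree, "order"),
               s2 = rank_abundance(c(spA2 = 2L, L2 = 2L), tree, "order"))
  tab <- abundance_table(rows)
  expect_equal(rownames(tab), c("s1", "s2"))
  expect_true(all(abs(rowSums(tab) - 100) < 1e-9))
  expect_equal(tab["s2", "ordB"], 0)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abundance(tab, path)
  back <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  expect_equal(back$sample, c("s1", "s2"))
})

test_that("subsampled profiles agree with the full pool within multinomial error", {
  tree <- profile_tree()
  set.seed(71)
  pool <- sample(c("spA1", "spA2", "spB1"), 10000, TRUE, prob = c(0.5, 0.3, 0.2))
  names(pool) <- sprintf("r%05d", seq_along(pool))
  full <- rank_abundance(stats::setNames(as.integer(table(pool)), names(table(pool))),
                         tree, "species")
  sub <- subsample_reads(pool, 2000, seed = 5)
  subab <- rank_abundance(stats::setNames(as.integer(table(sub)), names(table(sub))),
                          tree, "species")
  for (sp in c("spA1", "spA2", "spB1")) {
    p <- full[[sp]] / 100
    sd3 <- 3 * sqrt(p * (1 - p) / 2000) * 100
    expect_lt(abs(subab[[sp]] - full[[sp]]), sd3 + 1e-9)
  }
})
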
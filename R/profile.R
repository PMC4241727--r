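#' Subsample a read pool without replacement
#'
#' Community composition is typically summarized from a fixed-size random
#' subsample (e.g. 100 000 rRNA reads per sample) so samples of unequal
#' sequencing depth are comparable.
#'
#' @param reads named character vector or `DNAStringSet`.
#' @param n target number of reads; when `n` exceeds the pool size the whole
#'   pool is returned with a warning.
#' @param seed integer seed.
#' @return A read set of the same type as the input.
#' @export
subsample_reads <- function(reads, n, seed = 1L) {
  size <- length(reads)
  if (n >= size) {
    if (n > size) warning("requested ", n, " reads from a pool of ", size,
                          "; returning the whole pool")
    return(reads)
  }
  idx <- withr::with_seed(seed, sample.int(size, n, replace = FALSE))
  reads[sort(idx)]
}

ancestor_at_rank <- function(tree, id, rank) {
  path <- tax_path(tree, id)
  ranks <- tree[path, "rank"]
  hit <- which(ranks == rank)
  if (length(hit)) path[hit] else NA_character_
}

#' Relative abundance at one taxonomic rank
#'
#' Each classified read contributes to its assigned node's ancestor at
#' `rank`; reads assigned above `rank` (or unassigned) pool into an
#' `unclassified` category, so the row always sums to 100%.
#'
#' @param counts named per-taxon read counts (as `counts` from
#'   [classify_dataset()]), possibly including `UNASSIGNED`.
#' @param tree a `taxonomy_tree`.
#' @param rank target rank (one of [tax_ranks()] below `root`).
#' @param unclassified `"pool"` (default: one `unclassified` column) or
#'   `"separate"` (`unclassified_above_rank` vs `unassigned` columns).
#' @return Named numeric vector of percentages summing to 100.
#' @export
rank_abundance <- function(counts, tree, rank,
                           unclassified = c("pool", "separate")) {
  unclassified <- match.arg(unclassified)
  if (!rank %in% tax_ranks()[-1]) stop("unknown rank: ", rank)
  total <- sum(counts)
  if (total == 0) stop("no reads in count table")
  above <- 0; unassigned <- 0
  acc <- list()
  for (taxon in names(counts)) {
    k <- counts[[taxon]]
    if (taxon == UNASSIGNED) { unassigned <- unassigned + k; next }
    anc <- ancestor_at_rank(tree, taxon, rank)
    if (is.na(anc)) above <- above + k
    else acc[[anc]] <- (if (is.null(acc[[anc]])) 0 else acc[[anc]]) + k
  }
  vals <- unlist(acc)
  vals <- if (is.null(vals)) numeric(0) else vals[order(names(vals))]
  out <- if (unclassified == "pool") {
    c(vals, unclassified = above + unassigned)
  } else {
    c(vals, unclassified_above_rank = above, unassigned = unassigned)
  }
  100 * out / total
}

#' Species-level profile within one family
#'
#' Summarizes a family-restricted classifier run: the percentage of reads on
#' each species (plus an `unclassified` pool for reads above species rank or
#' unassigned) and the fraction of reads that reached species rank at all.
#'
#' @param counts named per-taxon read counts from the family-restricted run.
#' @param tree a `taxonomy_tree`.
#' @return List: `abundance` (named percentages summing to 100) and
#'   `assigned_fraction` (species-rank reads / all reads).
#' @export
species_profile <- function(counts, tree) {
  total <- sum(counts)
  if (total == 0) stop("no reads in count table")
  abundance <- rank_abundance(counts, tree, "species")
  taxa <- setdiff(names(counts), UNASSIGNED)
  at_species <- taxa[tree[taxa, "rank"] == "species"]
  list(abundance = abundance,
       assigned_fraction = sum(counts[at_species]) / total)
}

#' Assemble per-sample abundance rows into a table
#'
#' @param rows named list of per-sample abundance vectors (as from
#'   [rank_abundance()]); categories are unioned and missing entries set
#'   to 0.
#' @return Numeric matrix, samples x categories, rows summing to 100.
#' @export
abundance_table <- function(rows) {
  cats <- sort(unique(unlist(lapply(rows, names))))
  mat <- matrix(0, nrow = length(rows), ncol = length(cats),
                dimnames = list(names(rows), cats))
  for (s in names(rows)) mat[s, names(rows[[s]])] <- rows[[s]]
  mat
}

#' Write an abundance table to TSV (4 decimal places)
#' @param mat samples x categories percentage matrix.
#' @param path output path.
#' @export
write_abundance <- function(mat, path) {
  df <- data.frame(sample = rownames(mat), round(mat, 4), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
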
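#' Read-classification parameters
#'
#' The three knobs of the assignment scheme: a minimum bit score for a hit to
#' count at all, a top-percent window retaining hits scoring within the given
#' percentage of the best hit's bit score, and a minimal support below which a
#' taxon's reads are pushed up to its parent. Typical settings: rRNA
#' community profiling `min_bit = 150, top_percent = 10, min_support = 1`;
#' species-resolution runs tighten the window to `top_percent = 1` and raise
#' support to 20–50; mRNA classification lowers `min_bit` to 40.
#'
#' @param min_bit minimum bit score (>= 0).
#' @param top_percent window width as a percentage of the best bit score,
#'   in (0, 100].
#' @param min_support minimum reads per reported taxon (>= 1; 1 disables).
#' @return A `classifier_params` list.
#' @export
classifier_params <- function(min_bit = 150, top_percent = 10, min_support = 1L) {
  stopifnot(min_bit >= 0, top_percent > 0, top_percent <= 100, min_support >= 1)
  structure(list(min_bit = min_bit, top_percent = top_percent,
                 min_support = as.integer(min_support)),
            class = "classifier_params")
}

UNASSIGNED <- "UNASSIGNED"

#' Bit-score and top-percent filtering of an alignment hit list
#'
#' Drops hits below `min_bit`, then keeps the hits whose bit score is at least
#' `best_bit * (1 - top_percent/100)`.
#'
#' @param hits data.frame with a `bit_score` column (as from [search_db()]).
#' @param params a [classifier_params()].
#' @return The retained subset of `hits` (possibly 0-row), original order.
#' @export
filter_hits <- function(hits, params = classifier_params()) {
  if (nrow(hits) == 0L) return(hits)
  hits <- hits[hits$bit_score >= params$min_bit, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  cutoff <- max(hits$bit_score) * (1 - params$top_percent / 100)
  hits[hits$bit_score >= cutoff, , drop = FALSE]
}

#' Assign one read from its hit list
#'
#' Filters hits with [filter_hits()]; the read is placed at the lowest common
#' ancestor of the surviving hits' taxa, or `UNASSIGNED` when none survive.
#'
#' @param hits data.frame with `bit_score` and `taxon_id` columns.
#' @param tree a `taxonomy_tree`.
#' @param params a [classifier_params()].
#' @return List: `taxon_id` (node id or `"UNASSIGNED"`), `rank_achieved`
#'   (rank name or `NA`), `n_hits_retained`, `retained_taxa` (character).
#' @export
assign_read <- function(hits, tree, params = classifier_params()) {
  kept <- filter_hits(hits, params)
  if (nrow(kept) == 0L) {
    return(list(taxon_id = UNASSIGNED, rank_achieved = NA_character_,
                n_hits_retained = 0L, retained_taxa = character(0)))
  }
  node <- lca(tree, kept$taxon_id)
  list(taxon_id = node, rank_achieved = tax_rank(tree, node),
       n_hits_retained = nrow(kept),
       retained_taxa = sort(unique(kept$taxon_id)))
}

#' Minimal-support push-up over a set of assignments
#'
#' Working from the deepest rank upward, any node whose subtree (itself plus
#' descendants) holds fewer than `min_support` assigned reads has those reads
#' reassigned to its parent; the root is never pushed. With
#' `min_support = 1` the input is returned unchanged. `mode = "discard"`
#' instead marks reads of under-supported subtrees `UNASSIGNED`.
#'
#' @param assignments data.frame with columns `read_id`, `taxon_id`,
#'   `rank_achieved` (as from [classify_dataset()]).
#' @param tree a `taxonomy_tree`.
#' @param params a [classifier_params()].
#' @param mode `"pushup"` (default, preserves read counts) or `"discard"`.
#' @return The assignments data.frame with updated `taxon_id`/`rank_achieved`.
#' @export
apply_min_support <- function(assignments, tree, params = classifier_params(),
                              mode = c("pushup", "discard")) {
  mode <- match.arg(mode)
  if (params$min_support <= 1L || nrow(assignments) == 0L) return(assignments)
  taxon <- assignments$taxon_id
  depth <- rev(seq_along(tax_ranks()) - 1L)  # species first
  parent <- stats::setNames(tree$parent_id, tree$id)
  for (d in depth[depth > 0]) {
    nodes <- tree$id[rank_depth(tree$rank) == d]
    for (nd in nodes) {
      in_subtree <- taxon != UNASSIGNED &
        vapply(taxon, function(t) t != UNASSIGNED && nd %in% tax_path(tree, t), logical(1))
      n <- sum(in_subtree)
      if (n > 0L && n < params$min_support) {
        taxon[in_subtree] <- if (mode == "pushup") parent[[nd]] else UNASSIGNED
      }
    }
  }
  assignments$taxon_id <- taxon
  assignments$rank_achieved <- ifelse(taxon == UNASSIGNED, NA_character_,
                                      tree[taxon, "rank"])
  assignments
}

#' Classify a read set against a reference database
#'
#' Scores every read against every reference record (both strands), applies
#' the bit-score floor and top-percent window per read, places each read at
#' the lowest common ancestor of its retained hits, then applies the
#' dataset-level minimal-support push-up. Reads with no retained hit are
#' counted `UNASSIGNED`, so read counts are conserved.
#'
#' @param reads FASTA path, named character vector, or `DNAStringSet`.
#' @param db a `reference_db`.
#' @param tree a `taxonomy_tree`.
#' @param scheme a [scoring_scheme()].
#' @param params a [classifier_params()].
#' @param support_mode `"pushup"` or `"discard"` (see [apply_min_support()]).
#' @param both_strands align both strands (default `TRUE`).
#' @return List: `assignments` (data.frame `read_id`, `taxon_id`,
#'   `rank_achieved`, `n_hits_retained`), `counts` (named per-taxon read
#'   counts including `UNASSIGNED` when present), and `retained` (per-read
#'   list of the species retained in the score window, before push-up).
#' @export
classify_dataset <- function(reads, db, tree, scheme = scoring_scheme(),
                             params = classifier_params(),
                             support_mode = "pushup", both_strands = TRUE) {
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    reads <- read_fasta(reads)
  }
  if (!methods::is(reads, "XStringSet")) reads <- Biostrings::DNAStringSet(reads)
  if (length(reads) == 0L) {
    return(list(assignments = data.frame(read_id = character(0),
                                         taxon_id = character(0),
                                         rank_achieved = character(0),
                                         n_hits_retained = integer(0),
                                         stringsAsFactors = FALSE),
                counts = stats::setNames(integer(0), character(0)),
                retained = list()))
  }
  if (is.null(names(reads))) names(reads) <- sprintf("read%06d", seq_along(reads))
  sm <- score_matrix(reads, db, scheme, both_strands)
  bits <- bit_score(sm$raw, scheme)
  bits[sm$raw == 0] <- -Inf
  res <- vector("list", length(reads))
  for (i in seq_along(reads)) {
    b <- bits[i, ]
    ok <- b >= params$min_bit
    if (!any(ok)) {
      res[[i]] <- list(taxon_id = UNASSIGNED, rank_achieved = NA_character_,
                       n_hits_retained = 0L, retained_taxa = character(0))
      next
    }
    cutoff <- max(b[ok]) * (1 - params$top_percent / 100)
    kept <- ok & b >= cutoff
    taxa <- unique(unname(db$taxon[colnames(bits)[kept]]))
    node <- lca(tree, taxa)
    res[[i]] <- list(taxon_id = node, rank_achieved = tax_rank(tree, node),
                     n_hits_retained = sum(kept), retained_taxa = sort(taxa))
  }
  assignments <- data.frame(
    read_id = names(reads),
    taxon_id = vapply(res, `[[`, character(1), "taxon_id"),
    rank_achieved = vapply(res, `[[`, character(1), "rank_achieved"),
    n_hits_retained = vapply(res, `[[`, integer(1), "n_hits_retained"),
    stringsAsFactors = FALSE)
  assignments <- apply_min_support(assignments, tree, params, mode = support_mode)
  counts <- table(assignments$taxon_id)
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(assignments = assignments, counts = counts,
       retained = stats::setNames(lapply(res, `[[`, "retained_taxa"), names(reads)))
}

#' Write an assignment table to TSV
#' @param assignments assignment data.frame from [classify_dataset()].
#' @param path output path.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.table(assignments, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
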
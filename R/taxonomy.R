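#' Canonical rank ladder
#'
#' The eight ranks recognized by the package, from shallowest (`root`) to
#' deepest (`species`). Intermediate or unranked levels are rejected at load
#' time so lowest-common-ancestor calls and rank summaries are unambiguous.
#'
#' @return Character vector of the eight rank names in depth order.
#' @export
tax_ranks <- function() {
  c("root", "domain", "phylum", "class", "order", "family", "genus", "species")
}

#' Numeric depth of a rank (root = 0)
#' @param rank character vector of rank names.
#' @return Integer depth, 0 for root through 7 for species.
#' @export
rank_depth <- function(rank) {
  d <- match(rank, tax_ranks()) - 1L
  if (anyNA(d)) stop("unknown rank(s): ", paste(rank[is.na(d)], collapse = ", "))
  d
}

new_taxonomy <- function(df) {
  df <- df[order(df$id), , drop = FALSE]
  rownames(df) <- df$id
  structure(df, class = c("taxonomy_tree", "data.frame"))
}

validate_taxonomy <- function(df) {
  stopifnot(all(c("id", "parent_id", "rank", "name") %in% names(df)))
  if (anyDuplicated(df$id)) {
    stop("duplicate taxon id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  is_root <- is.na(df$parent_id)
  if (sum(is_root) != 1L) stop("taxonomy must have exactly one root, found ", sum(is_root))
  if (df$rank[is_root] != "root") stop("root node must carry rank 'root'")
  rank_depth(df$rank)  # validates rank vocabulary
  missing_parent <- !is_root & !(df$parent_id %in% df$id)
  if (any(missing_parent)) {
    stop("unknown parent id(s): ", paste(unique(df$parent_id[missing_parent]), collapse = ", "))
  }
  if (any(!is_root & df$parent_id == df$id)) stop("cycle detected: node is its own parent")
  dp <- rank_depth(df$rank)
  pdp <- dp[match(df$parent_id, df$id)]
  bad <- !is_root & !(pdp < dp)
  if (any(bad)) {
    stop("parent rank must be strictly shallower than child rank (offending id: ",
         df$id[which(bad)[1]], ")")
  }
  # strict rank ordering above already forbids cycles, but walk paths anyway so
  # a corrupted table fails loudly rather than hanging downstream
  idx <- match(df$parent_id, df$id)
  for (i in seq_len(nrow(df))) {
    seen <- integer(0); j <- i
    while (!is.na(idx[j])) {
      if (j %in% seen) stop("cycle detected involving id ", df$id[i])
      seen <- c(seen, j); j <- idx[j]
      if (length(seen) > nrow(df)) stop("cycle detected involving id ", df$id[i])
    }
  }
  invisible(df)
}

#' Load and validate a taxonomy table
#'
#' Reads a four-column TSV (`id`, `parent_id`, `rank`, `name`; `-` marks the
#' root's parent) into a validated rooted tree. Ranks must come from
#' [tax_ranks()] and every parent must sit strictly shallower than its child.
#'
#' @param table path to a TSV file, or a data.frame with the four columns.
#' @return A `taxonomy_tree`: a data.frame of nodes ordered by id.
#' @export
load_taxonomy <- function(table) {
  df <- if (is.character(table)) {
    utils::read.table(table, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                      colClasses = "character", quote = "", comment.char = "")
  } else {
    as.data.frame(table, stringsAsFactors = FALSE)
  }
  df <- df[, c("id", "parent_id", "rank", "name")]
  for (cc in names(df)) df[[cc]] <- as.character(df[[cc]])
  df$parent_id[df$parent_id %in% c("-", "")] <- NA_character_
  validate_taxonomy(df)
  new_taxonomy(df)
}

#' Write a taxonomy table to TSV
#' @param tree a `taxonomy_tree`.
#' @param path output path.
#' @export
write_taxonomy <- function(tree, path) {
  df <- as.data.frame(tree)
  df$parent_id[is.na(df$parent_id)] <- "-"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Path from the root to a node
#' @param tree a `taxonomy_tree`.
#' @param id a single node id.
#' @return Character vector of ids, root first, `id` last.
#' @export
tax_path <- function(tree, id) {
  if (!id %in% tree$id) stop("unknown taxon id: ", id)
  parent <- stats::setNames(tree$parent_id, tree$id)
  path <- id
  while (!is.na(parent[[path[1]]])) path <- c(parent[[path[1]]], path)
  path
}

#' Rank of a node
#' @inheritParams tax_path
#' @return Rank name of `id`.
#' @export
tax_rank <- function(tree, id) {
  if (!id %in% tree$id) stop("unknown taxon id: ", id)
  tree[id, "rank"]
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node that is ancestral to (or equal to) every taxon in the
#' input set — the placement a read receives when several reference hits
#' survive score filtering.
#'
#' @param tree a `taxonomy_tree`.
#' @param taxa non-empty character vector of node ids (duplicates allowed).
#' @return A single node id.
#' @export
lca <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) stop("lca of an empty taxon set is undefined")
  path <- tax_path(tree, taxa[1])
  for (t in taxa[-1]) {
    other <- tax_path(tree, t)
    n <- min(length(path), length(other))
    agree <- path[seq_len(n)] == other[seq_len(n)]
    k <- if (all(agree)) n else which(!agree)[1] - 1L
    path <- path[seq_len(k)]
  }
  path[length(path)]
}
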
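#' Read a (possibly wrapped) nucleotide FASTA
#' @param path FASTA file path.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write a nucleotide FASTA
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output path.
#' @param width line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (!methods::is(seqs, "XStringSet")) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

new_reference_db <- function(seqs, taxon) {
  structure(list(seqs = seqs, taxon = taxon), class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  cat(sprintf("<reference_db> %d sequence(s), %d species\n",
              length(x$seqs), length(unique(x$taxon))))
  invisible(x)
}

#' Number of records in a reference database
#' @param x a `reference_db`.
#' @export
ref_size <- function(x) length(x$seqs)

#' Species represented in a reference database
#' @param x a `reference_db`.
#' @return Character vector of distinct species node ids, in record order.
#' @export
ref_species <- function(x) unique(unname(x$taxon))

#' Build a species-labelled reference database
#'
#' Joins marker-gene sequences to species-rank taxonomy nodes via a
#' `seq_id -> taxon_id` map and validates the result: every sequence must be
#' mapped, every taxon must be a species in `tree`, and sequences must be
#' non-empty nucleotide strings.
#'
#' @param sequences FASTA path, named character vector, or `DNAStringSet`.
#' @param taxmap path to a two-column TSV (`seq_id`, `taxon_id`) or an
#'   equivalent data.frame / named character vector.
#' @param tree a `taxonomy_tree`.
#' @param allow_n allow `N` bases in reference sequences (default `FALSE`:
#'   references are expected to be unambiguous).
#' @return A `reference_db` preserving the input record order.
#' @export
build_refdb <- function(sequences, taxmap, tree, allow_n = FALSE) {
  seqs <- if (methods::is(sequences, "XStringSet")) {
    sequences
  } else if (is.character(sequences) && length(sequences) == 1L && file.exists(sequences)) {
    read_fasta(sequences)
  } else {
    Biostrings::DNAStringSet(sequences)
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs))) {
    stop("reference sequences must carry unique ids")
  }
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.character(taxmap) && length(taxmap) == 1L && file.exists(taxmap)) {
    tm <- utils::read.table(taxmap, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, colClasses = "character")
    taxmap <- stats::setNames(tm$taxon_id, tm$seq_id)
  } else if (is.data.frame(taxmap)) {
    taxmap <- stats::setNames(as.character(taxmap$taxon_id), taxmap$seq_id)
  }
  unmapped <- setdiff(names(seqs), names(taxmap))
  if (length(unmapped)) {
    stop("sequence id(s) missing from taxon map: ", paste(unmapped, collapse = ", "))
  }
  taxon <- taxmap[names(seqs)]
  unknown <- setdiff(taxon, tree$id)
  if (length(unknown)) stop("taxon id(s) not in tree: ", paste(unknown, collapse = ", "))
  not_sp <- taxon[tree[taxon, "rank"] != "species"]
  if (length(not_sp)) {
    stop("taxon id(s) are not species rank: ", paste(unique(not_sp), collapse = ", "))
  }
  if (any(Biostrings::width(seqs) == 0L)) stop("empty reference sequence(s)")
  freq <- Biostrings::alphabetFrequency(seqs)
  allowed <- c("A", "C", "G", "T", if (allow_n) "N")
  extra <- rowSums(freq[, setdiff(colnames(freq), allowed), drop = FALSE])
  if (any(extra > 0)) {
    stop("non-nucleotide characters in reference(s): ",
         paste(names(seqs)[extra > 0], collapse = ", "))
  }
  new_reference_db(seqs, taxon)
}

#' Percent identity of two nucleotide sequences
#'
#' Global (Needleman–Wunsch) alignment; identity is 100 x matched columns /
#' aligned columns, where terminal gap columns are excluded from the count
#' and an `N` never counts as a match. This is the usual definition under
#' which near-identical 16S genes of sister species score ~99.5%. The result
#' is symmetric in its arguments.
#'
#' @param a,b non-empty nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend scoring used to pick the
#'   alignment (defaults: +1/-1, gap open 2, extend 1; a gap of length L
#'   costs `gap_open + L * gap_extend`).
#' @return Percent identity in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, match = 1, mismatch = -1,
                              gap_open = 2, gap_extend = 1) {
  a <- as.character(a); b <- as.character(b)
  if (!nzchar(a) || !nzchar(b)) stop("pairwise_identity requires non-empty sequences")
  # canonical argument order makes the result exactly symmetric even when
  # several alignments tie for the optimal score
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = gap_open, gapExtension = gap_extend)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- pa == "-" | pb == "-"
  lead <- match(FALSE, gap) - 1L            # leading terminal gap columns
  trail <- match(FALSE, rev(gap)) - 1L      # trailing terminal gap columns
  keep <- seq.int(lead + 1L, length(pa) - trail)
  cols <- length(keep)
  if (cols == 0L) return(0)
  matches <- sum(pa[keep] == pb[keep] & pa[keep] %in% c("A", "C", "G", "T"))
  100 * matches / cols
}

#' Drop (and optionally merge) taxa from a reference database
#'
#' Removes the records of taxa whose marker genes are indistinguishable from a
#' retained partner, and optionally relabels the surviving partner with a
#' merged name (e.g. `"spA/spB"`), mirroring the practice of collapsing
#' unresolvable sister species into one reference label.
#'
#' @param db a `reference_db`.
#' @param taxa_to_drop character vector of species node ids to remove.
#' @param merge_into optional species id of the surviving partner to relabel.
#' @param merged_label optional new label for `merge_into` (applied to a copy
#'   of the tree returned as attribute `"tree"` only when `tree` is supplied).
#' @param tree optional `taxonomy_tree`; when given, the relabelled tree is
#'   attached as attribute `"tree"` of the result.
#' @return A `reference_db` without the dropped taxa.
#' @export
omit_taxa <- function(db, taxa_to_drop, merge_into = NULL, merged_label = NULL,
                      tree = NULL) {
  taxa_to_drop <- unique(as.character(taxa_to_drop))
  absent <- setdiff(taxa_to_drop, db$taxon)
  if (length(absent)) stop("taxa not present in db: ", paste(absent, collapse = ", "))
  keep <- !(db$taxon %in% taxa_to_drop)
  if (!any(keep)) stop("dropping these taxa would empty the database")
  out <- new_reference_db(db$seqs[keep], db$taxon[keep])
  if (!is.null(tree) && !is.null(merge_into) && !is.null(merged_label)) {
    tree[merge_into, "name"] <- merged_label
    attr(out, "tree") <- tree
  }
  out
}
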
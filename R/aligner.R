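#' Alignment scoring scheme with bit-score normalization
#'
#' Match/mismatch rewards, affine gap penalties, and Karlin–Altschul
#' parameters lambda and K that map raw local-alignment scores onto the bit
#' scale, so thresholds such as "bit score 150" (rRNA) or "bit score 40"
#' (mRNA) are meaningful. A gap of length L costs `gap_open + L * gap_extend`.
#' The defaults follow the classic ungapped blastn parameterization
#' (+2/-3, lambda 0.625 nats, K 0.41).
#'
#' @param match positive integer match reward.
#' @param mismatch negative integer mismatch penalty.
#' @param gap_open,gap_extend non-negative gap costs.
#' @param lambda,k positive Karlin–Altschul parameters.
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L, gap_open = 5L,
                           gap_extend = 2L, lambda = 0.625, k = 0.41) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0,
            lambda > 0, k > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
                 lambda = lambda, k = k),
            class = "scoring_scheme")
}

scheme_submat <- function(scheme) {
  Biostrings::nucleotideSubstitutionMatrix(match = scheme$match,
                                           mismatch = scheme$mismatch,
                                           baseOnly = FALSE)
}

check_nuc <- function(x, what = "sequence", allow_n = TRUE) {
  ok <- if (allow_n) grepl("^[ACGTN]+$", x) else grepl("^[ACGT]+$", x)
  if (!all(ok)) stop("non-nucleotide characters in ", what)
  invisible(x)
}

#' Convert a raw alignment score to bits
#'
#' `(lambda * raw - ln k) / ln 2`; strictly increasing in the raw score.
#'
#' @param raw_score non-negative raw score(s).
#' @param scheme a [scoring_scheme()].
#' @return Bit score(s).
#' @export
bit_score <- function(raw_score, scheme = scoring_scheme()) {
  stopifnot(all(raw_score >= 0))
  (scheme$lambda * raw_score - log(scheme$k)) / log(2)
}

#' Minimum raw score reaching a bit threshold
#' @keywords internal
raw_for_bits <- function(bits, scheme) {
  (bits * log(2) + log(scheme$k)) / scheme$lambda
}

#' Optimal local alignment of two nucleotide sequences
#'
#' Exact affine-gap Smith–Waterman (via the Biostrings dynamic-programming
#' engine). The query is aligned as given; use [search_db()] for two-strand
#' search. A score of 0 means no scoring local alignment exists.
#'
#' @param query,ref non-empty nucleotide strings (N allowed in the query).
#' @param scheme a [scoring_scheme()].
#' @return List with `raw_score`, `identity` (percent of aligned columns
#'   matched), and `aligned_length` (columns in the local alignment);
#'   `identity`/`aligned_length` are `NA`/0 when `raw_score` is 0.
#' @export
local_align <- function(query, ref, scheme = scoring_scheme()) {
  query <- as.character(query); ref <- as.character(ref)
  if (!nzchar(query) || !nzchar(ref)) stop("empty sequence")
  check_nuc(query, "query"); check_nuc(ref, "reference")
  aln <- Biostrings::pairwiseAlignment(query, ref, type = "local",
                                       substitutionMatrix = scheme_submat(scheme),
                                       gapOpening = scheme$gap_open,
                                       gapExtension = scheme$gap_extend)
  raw <- Biostrings::score(aln)
  if (raw <= 0) {
    return(list(raw_score = 0, identity = NA_real_, aligned_length = 0L))
  }
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  matches <- sum(pa == pb & pa %in% c("A", "C", "G", "T"))
  list(raw_score = raw,
       identity = 100 * matches / length(pa),
       aligned_length = length(pa))
}

#' Raw local-alignment scores of many queries against one reference
#'
#' Vectorized scoring core used by classification and benchmarking; scores
#' below 0 are clamped to 0 (no alignment).
#'
#' @keywords internal
batch_scores <- function(queries, ref, scheme) {
  s <- Biostrings::pairwiseAlignment(queries, ref, type = "local",
                                     substitutionMatrix = scheme_submat(scheme),
                                     gapOpening = scheme$gap_open,
                                     gapExtension = scheme$gap_extend,
                                     scoreOnly = TRUE)
  pmax(s, 0)
}

#' Score reads against every record of a reference database
#'
#' Both strands of each read are aligned (reads from unstranded cDNA can face
#' either way); the better strand's score is kept per (read, reference) pair.
#'
#' @param reads named character vector or `DNAStringSet`.
#' @param db a `reference_db`.
#' @param scheme a [scoring_scheme()].
#' @param both_strands align the reverse complement too (default `TRUE`).
#' @return List with `raw` (reads x refs raw-score matrix) and `strand`
#'   (matching matrix of `"+"`/`"-"`).
#' @keywords internal
score_matrix <- function(reads, db, scheme = scoring_scheme(), both_strands = TRUE) {
  if (!methods::is(reads, "XStringSet")) reads <- Biostrings::DNAStringSet(reads)
  fwd <- vapply(seq_along(db$seqs),
                function(j) batch_scores(reads, db$seqs[[j]], scheme),
                numeric(length(reads)))
  fwd <- matrix(fwd, nrow = length(reads),
                dimnames = list(names(reads), names(db$seqs)))
  strand <- matrix("+", nrow = nrow(fwd), ncol = ncol(fwd), dimnames = dimnames(fwd))
  if (both_strands) {
    rc <- Biostrings::reverseComplement(reads)
    rev <- vapply(seq_along(db$seqs),
                  function(j) batch_scores(rc, db$seqs[[j]], scheme),
                  numeric(length(reads)))
    rev <- matrix(rev, nrow = length(reads), dimnames = dimnames(fwd))
    strand[rev > fwd] <- "-"
    fwd <- pmax(fwd, rev)
  }
  list(raw = fwd, strand = strand)
}

#' Search one query against a reference database
#'
#' Every record is scored; hits at or above `min_bit` are returned sorted by
#' bit score (descending), ties broken by reference id for determinism.
#'
#' @param query a nucleotide string.
#' @param db a `reference_db`.
#' @param scheme a [scoring_scheme()].
#' @param min_bit minimum bit score to report (0 reports all scoring hits).
#' @param both_strands search both query strands.
#' @return A data.frame (possibly 0-row): `ref_id`, `taxon_id`, `raw_score`,
#'   `bit_score`, `identity`, `aligned_length`, `strand`.
#' @export
search_db <- function(query, db, scheme = scoring_scheme(), min_bit = 0,
                      both_strands = TRUE) {
  query <- as.character(query)
  check_nuc(query, "query")
  sm <- score_matrix(stats::setNames(query, "q"), db, scheme, both_strands)
  raw <- drop(sm$raw); strand <- drop(sm$strand)
  keep <- raw > 0 & bit_score(raw, scheme) >= min_bit
  hits <- data.frame(ref_id = names(db$seqs)[keep],
                     taxon_id = unname(db$taxon[keep]),
                     raw_score = unname(raw[keep]),
                     bit_score = bit_score(unname(raw[keep]), scheme),
                     strand = unname(strand[keep]),
                     stringsAsFactors = FALSE)
  if (nrow(hits)) {
    detail <- lapply(seq_len(nrow(hits)), function(i) {
      q <- if (hits$strand[i] == "-") {
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(query)))
      } else query
      local_align(q, as.character(db$seqs[[hits$ref_id[i]]]), scheme)
    })
    hits$identity <- vapply(detail, `[[`, numeric(1), "identity")
    hits$aligned_length <- vapply(detail, function(d) as.integer(d$aligned_length), integer(1))
    hits <- hits[order(-hits$bit_score, hits$ref_id), , drop = FALSE]
    rownames(hits) <- NULL
  } else {
    hits$identity <- numeric(0)
    hits$aligned_length <- integer(0)
  }
  hits
}
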
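#' Translate a nucleotide read in all six frames
#'
#' Frames `+1..+3` translate the read from offsets 0..2; frames `-1..-3`
#' translate the reverse complement likewise. Trailing partial codons are
#' dropped, stops are rendered `*`, and codons containing `N` that do not
#' resolve uniquely become `X`. Stop codons are those of the bacterial code
#' (TAA/TAG/TGA), identical to the standard table.
#'
#' @param nuc a nucleotide string (A/C/G/T/N).
#' @return Named character vector of six protein strings
#'   (`"+1" ... "-3"`); frames shorter than one codon are empty strings.
#' @export
six_frame_translate <- function(nuc) {
  nuc <- toupper(as.character(nuc))
  check_nuc(nuc, "read")
  fwd <- Biostrings::DNAString(nuc)
  rev <- Biostrings::reverseComplement(fwd)
  one <- function(s, off) {
    L <- length(s) - off
    L <- L - (L %% 3L)
    if (L < 3L) return("")
    as.character(Biostrings::translate(Biostrings::subseq(s, off + 1L, off + L),
                                       no.init.codon = TRUE,
                                       if.fuzzy.codon = "solve"))
  }
  c("+1" = one(fwd, 0L), "+2" = one(fwd, 1L), "+3" = one(fwd, 2L),
    "-1" = one(rev, 0L), "-2" = one(rev, 1L), "-3" = one(rev, 2L))
}

#' Extract open reading frames from translated frames
#'
#' Splits each frame at stop symbols (`*`) and keeps the stop-free segments
#' of at least `min_len` amino acids. No start codon is required: an "ORF"
#' here is any sufficiently long stop-free stretch, the appropriate notion
#' for fragmentary mRNA reads that rarely contain a gene start.
#'
#' @param frames named character vector of six translations (as from
#'   [six_frame_translate()]), or a named list of such vectors keyed by
#'   read id.
#' @param min_len minimum ORF length in amino acids (default 30).
#' @param read_id read identifier used when `frames` is a single vector.
#' @return data.frame: `orf_id`, `read_id`, `frame`, `aa_start`, `aa_end`
#'   (0-based half-open within the frame's translation), `aa_seq`.
#' @export
extract_orfs <- function(frames, min_len = 30L, read_id = "read") {
  if (!is.list(frames)) frames <- stats::setNames(list(frames), read_id)
  rows <- list()
  for (rid in names(frames)) {
    fr <- frames[[rid]]
    for (fname in names(fr)) {
      aa <- fr[[fname]]
      if (!nzchar(aa)) next
      segs <- strsplit(aa, "*", fixed = TRUE)[[1]]
      pos <- 0L
      for (seg in segs) {
        w <- nchar(seg)
        if (w >= min_len) {
          rows[[length(rows) + 1L]] <- data.frame(
            read_id = rid, frame = fname, aa_start = pos, aa_end = pos + w,
            aa_seq = seg, stringsAsFactors = FALSE)
        }
        pos <- pos + w + 1L  # skip the stop column
      }
    }
  }
  if (length(rows) == 0L) {
    out <- data.frame(orf_id = character(0), read_id = character(0),
                      frame = character(0), aa_start = integer(0),
                      aa_end = integer(0), aa_seq = character(0),
                      stringsAsFactors = FALSE)
    return(out)
  }
  out <- do.call(rbind, rows)
  out <- cbind(orf_id = sprintf("%s|%s|%d", out$read_id, out$frame, out$aa_start),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
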
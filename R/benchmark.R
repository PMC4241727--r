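#' Sample fixed-length fragments from a sequence
#'
#' Draws `n` substrings of length `length` with start positions uniform on
#' the admissible range (with replacement); `mode = "tiling"` instead lays
#' fragments end to end from position 1, cycling as needed. Fragmenting a
#' full-length 16S gene (~1550 nt) into 170-nt pieces emulates the short
#' read lengths of the benchmark.
#'
#' @param seq a nucleotide string.
#' @param n number of fragments (>= 0).
#' @param length fragment length in nt.
#' @param seed integer seed for reproducibility.
#' @param mode `"random"` (default) or `"tiling"`.
#' @return data.frame: `fragment_id`, `start` (0-based), `sequence`.
#' @export
fragment_sequence <- function(seq, n, length = 170L, seed = 1L,
                              mode = c("random", "tiling")) {
  mode <- match.arg(mode)
  seq <- as.character(seq)
  L <- nchar(seq)
  if (L < length) stop("sequence (", L, " nt) shorter than fragment length ", length)
  if (n == 0L) {
    return(data.frame(fragment_id = character(0), start = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  }
  starts <- if (mode == "random") {
    withr::with_seed(seed, sample.int(L - length + 1L, n, replace = TRUE) - 1L)
  } else {
    ((seq_len(n) - 1L) * length) %% (L - length + 1L)
  }
  data.frame(fragment_id = sprintf("frag%05d", seq_len(n)),
             start = starts,
             sequence = substring(seq, starts + 1L, starts + length),
             stringsAsFactors = FALSE)
}

#' Fragmentation benchmark of species-level resolution
#'
#' For each target species, samples `n` fragments of `length` nt from its
#' reference sequence(s), classifies them against `classify_db`
#' (self-inclusive by default: the source record stays in the database), and
#' tallies a confusion matrix whose rows are source species and whose columns
#' are every species in `classify_db` plus `higher_rank` (read placed above
#' species by the LCA) and `UNASSIGNED`.
#'
#' @param db `reference_db` supplying the fragment sources.
#' @param tree a `taxonomy_tree`.
#' @param target_taxa species ids to fragment (default: all species in `db`).
#' @param scheme a [scoring_scheme()].
#' @param params a [classifier_params()]; the default
#'   (`min_bit = 150, top_percent = 10, min_support = 1`) matches the
#'   package-wide rRNA classification defaults.
#' @param n fragments per source species.
#' @param length fragment length (nt).
#' @param seed integer seed.
#' @param classify_db database to classify against (default `db`); pass a
#'   merged/reduced database to measure how fragments of an omitted taxon map
#'   onto a surviving partner.
#' @return A `confusion_matrix`: integer matrix (sources x outcomes) with
#'   attributes `n_per_source` and `window_confusion` (sources x species
#'   fraction of fragments whose retained score window included that species).
#' @export
run_benchmark <- function(db, tree, target_taxa = ref_species(db),
                          scheme = scoring_scheme(),
                          params = classifier_params(min_bit = 150,
                                                     top_percent = 10,
                                                     min_support = 1),
                          n = 500L, length = 170L, seed = 1L,
                          classify_db = db) {
  target_taxa <- unique(as.character(target_taxa))
  absent <- setdiff(target_taxa, db$taxon)
  if (length(absent) > 0) stop("target taxa not in db: ", paste(absent, collapse = ", "))
  species_cols <- ref_species(classify_db)
  cols <- c(species_cols, "higher_rank", UNASSIGNED)
  cm <- matrix(0L, nrow = base::length(target_taxa), ncol = base::length(cols),
               dimnames = list(target_taxa, cols))
  wc <- matrix(0, nrow = base::length(target_taxa), ncol = base::length(species_cols),
               dimnames = list(target_taxa, species_cols))
  for (ti in seq_along(target_taxa)) {
    taxon <- target_taxa[ti]
    recs <- which(db$taxon == taxon)
    # one seed per (run seed, taxon) so per-taxon draws are independent
    tseed <- (seed * 1000L + ti) %% .Machine$integer.max
    src <- withr::with_seed(tseed,
                            recs[sample.int(length(recs), n, replace = TRUE)])
    frags <- character(n)
    for (k in seq_len(n)) {
      f <- fragment_sequence(as.character(db$seqs[[src[k]]]), 1L, length,
                             seed = (tseed + k) %% .Machine$integer.max)
      frags[k] <- f$sequence
    }
    names(frags) <- sprintf("%s_frag%05d", taxon, seq_len(n))
    cls <- classify_dataset(frags, classify_db, tree, scheme, params)
    a <- cls$assignments
    for (i in seq_len(nrow(a))) {
      out <- a$taxon_id[i]
      col <- if (out == UNASSIGNED) UNASSIGNED
        else if (out %in% species_cols) out
        else "higher_rank"
      cm[taxon, col] <- cm[taxon, col] + 1L
    }
    for (r in cls$retained) {
      hit <- intersect(r, species_cols)
      wc[taxon, hit] <- wc[taxon, hit] + 1
    }
    wc[taxon, ] <- wc[taxon, ] / n
  }
  structure(cm, n_per_source = as.integer(n), window_confusion = wc,
            class = c("confusion_matrix", class(cm)))
}

#' Per-species recovery report from a confusion matrix
#'
#' Splits each source row into four fractions: `recovery` (assigned to the
#' correct species), `fp` (assigned to a wrong species), `higher_rank`
#' (pushed above species rank), and `unassigned`; the four sum to 1.
#'
#' @param cm a `confusion_matrix` from [run_benchmark()].
#' @param correct optional named map source taxon -> taxon counted as
#'   correct (defaults to identity; set after a merge so fragments of an
#'   omitted twin count its surviving partner as correct).
#' @return data.frame: `taxon_id`, `recovery`, `fp`, `higher_rank`,
#'   `unassigned`, `n`; attribute `any_false_positive` flags a nonzero
#'   wrong-species cell anywhere.
#' @export
recovery_report <- function(cm, correct = NULL) {
  if (nrow(cm) == 0L) stop("empty confusion matrix")
  species_cols <- setdiff(colnames(cm), c("higher_rank", UNASSIGNED))
  out <- data.frame(taxon_id = rownames(cm), recovery = NA_real_, fp = NA_real_,
                    higher_rank = NA_real_, unassigned = NA_real_,
                    n = as.integer(rowSums(cm)), stringsAsFactors = FALSE)
  any_fp <- FALSE
  for (i in seq_len(nrow(cm))) {
    src <- rownames(cm)[i]
    tgt <- if (!is.null(correct) && src %in% names(correct)) correct[[src]] else src
    total <- sum(cm[i, ])
    good <- if (tgt %in% species_cols) cm[i, tgt] else 0L
    wrong <- sum(cm[i, setdiff(species_cols, tgt)])
    out$recovery[i] <- good / total
    out$fp[i] <- wrong / total
    out$higher_rank[i] <- cm[i, "higher_rank"] / total
    out$unassigned[i] <- cm[i, UNASSIGNED] / total
    any_fp <- any_fp || wrong > 0
  }
  attr(out, "any_false_positive") <- any_fp
  out
}

#' Recommend merging indistinguishable reference taxa
#'
#' Flags unordered species pairs whose references are nearly identical
#' (pairwise identity at or above `identity_threshold`, default 99.5%) and —
#' when a benchmark confusion matrix is supplied — pairs whose fragments
#' mutually retain the other species in the top-percent score window for at
#' least `confusion_min` of fragments. Such pairs cannot be resolved at the
#' benchmark's fragment length and are candidates for a merged label.
#'
#' @param db a `reference_db` with at least two species.
#' @param identity_threshold percent identity cutoff (default 99.5).
#' @param cm optional `confusion_matrix` carrying `window_confusion`.
#' @param confusion_min mutual cross-window fraction (default 0.25).
#' @param tol slack (percentage points, default 0.1) applied below
#'   `identity_threshold`: substitution counts are discrete, so a pair
#'   constructed at a nominal identity can realize up to ~half a
#'   substitution below it.
#' @return data.frame: `taxon_a`, `taxon_b` (a < b), `identity`,
#'   `rationale`; ordered by taxon ids.
#' @export
recommend_merges <- function(db, identity_threshold = 99.5, cm = NULL,
                             confusion_min = 0.25, tol = 0.1) {
  sp <- sort(ref_species(db))
  if (length(sp) < 2L) stop("need at least two species to compare")
  best_ident <- function(a, b) {
    ia <- which(db$taxon == a); ib <- which(db$taxon == b)
    max(vapply(ia, function(i) {
      max(vapply(ib, function(j) {
        pairwise_identity(as.character(db$seqs[[i]]), as.character(db$seqs[[j]]))
      }, numeric(1)))
    }, numeric(1)))
  }
  rows <- list()
  wc <- if (!is.null(cm)) attr(cm, "window_confusion") else NULL
  for (i in seq_len(length(sp) - 1L)) {
    for (j in (i + 1L):length(sp)) {
      a <- sp[i]; b <- sp[j]
      ident <- best_ident(a, b)
      by_ident <- ident >= identity_threshold - tol
      by_conf <- FALSE
      if (!is.null(wc) && a %in% rownames(wc) && b %in% rownames(wc) &&
          a %in% colnames(wc) && b %in% colnames(wc)) {
        by_conf <- min(wc[a, b], wc[b, a]) >= confusion_min
      }
      if (by_ident || by_conf) {
        rationale <- paste(c(if (by_ident) sprintf("identity %.2f%% (threshold %.2f%%)",
                                                   ident, identity_threshold),
                             if (by_conf) sprintf("mutual window confusion >= %.0f%%",
                                                  100 * confusion_min)),
                           collapse = "; ")
        rows[[length(rows) + 1L]] <- data.frame(
          taxon_a = a, taxon_b = b, identity = ident, rationale = rationale,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(taxon_a = character(0), taxon_b = character(0),
                      identity = numeric(0), rationale = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$taxon_a, out$taxon_b), , drop = FALSE]
}
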
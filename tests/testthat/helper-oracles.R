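# Independent brute-force oracles used across the suite. These deliberately
# re-derive results from first principles (plain dynamic programming, path
# intersection, codon walking, closed-form statistics) and never call the
# package functions they check.

# --- affine-gap Smith-Waterman, score only (gap of length L costs
# --- open + L*ext), floor at 0
sw_oracle <- function(a, b, match = 2, mismatch = -3, open = 5, ext = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(-Inf, n + 1, m + 1)  # gap in a (consumes b)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      X[i, j] <- max(M[i - 1, j] - (open + ext), X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - (open + ext), Y[i, j - 1] - ext)
      M[i, j] <- max(0, M[i - 1, j - 1] + s, X[i - 1, j - 1] + s, Y[i - 1, j - 1] + s)
      best <- max(best, M[i, j])
    }
  }
  best
}

# --- LCA by explicit root-path intersection
lca_oracle <- function(tree, taxa) {
  paths <- lapply(unique(taxa), function(t) tax_path(tree, t))
  common <- Reduce(intersect, paths)
  common[length(common)]
}

# --- random ranked tree with <= n_max nodes (parent always strictly
# --- shallower); returns a taxonomy_tree
random_tree <- function(n_max = 50L) {
  ranks <- tax_ranks()
  nodes <- data.frame(id = "n1", parent_id = NA_character_, rank = "root",
                      name = "root", stringsAsFactors = FALSE)
  n <- sample(2:n_max, 1)
  for (k in 2:n) {
    cand <- which(match(nodes$rank, ranks) < length(ranks))
    p <- cand[sample.int(length(cand), 1)]
    pd <- match(nodes$rank[p], ranks)
    depths <- (pd + 1):length(ranks)            # candidate child depth indices
    d <- depths[sample.int(length(depths), 1)]
    nodes <- rbind(nodes, data.frame(
      id = paste0("n", k), parent_id = nodes$id[p], rank = ranks[d],
      name = paste0("node ", k), stringsAsFactors = FALSE))
  }
  load_taxonomy(nodes)
}

# --- hit-list filter: bit floor then top-percent window
filter_oracle <- function(hits, min_bit, top_percent) {
  h <- hits[hits$bit_score >= min_bit, , drop = FALSE]
  if (nrow(h) == 0) return(h)
  h[h$bit_score >= max(h$bit_score) * (1 - top_percent / 100), , drop = FALSE]
}

# --- codon-by-codon translation oracle (standard/bacterial code, stops
# --- identical between the two tables)
CODON_TABLE <- c(
  TTT="F",TTC="F",TTA="L",TTG="L",CTT="L",CTC="L",CTA="L",CTG="L",
  ATT="I",ATC="I",ATA="I",ATG="M",GTT="V",GTC="V",GTA="V",GTG="V",
  TCT="S",TCC="S",TCA="S",TCG="S",CCT="P",CCC="P",CCA="P",CCG="P",
  ACT="T",ACC="T",ACA="T",ACG="T",GCT="A",GCC="A",GCA="A",GCG="A",
  TAT="Y",TAC="Y",TAA="*",TAG="*",CAT="H",CAC="H",CAA="Q",CAG="Q",
  AAT="N",AAC="N",AAA="K",AAG="K",GAT="D",GAC="D",GAA="E",GAG="E",
  TGT="C",TGC="C",TGA="*",TGG="W",CGT="R",CGC="R",CGA="R",CGG="R",
  AGT="S",AGC="S",AGA="R",AGG="R",GGT="G",GGC="G",GGA="G",GGG="G")

revcomp_chr <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

translate_frame_oracle <- function(nuc, offset) {
  chars <- strsplit(nuc, "")[[1]]
  usable <- length(chars) - offset
  ncod <- usable %/% 3
  if (ncod < 1) return("")
  aa <- character(ncod)
  for (c_i in seq_len(ncod)) {
    codon <- paste(chars[(offset + 3 * (c_i - 1) + 1):(offset + 3 * c_i)], collapse = "")
    aa[c_i] <- if (codon %in% names(CODON_TABLE)) CODON_TABLE[[codon]] else "X"
  }
  paste(aa, collapse = "")
}

six_frame_oracle <- function(nuc) {
  rc <- revcomp_chr(nuc)
  c("+1" = translate_frame_oracle(nuc, 0), "+2" = translate_frame_oracle(nuc, 1),
    "+3" = translate_frame_oracle(nuc, 2), "-1" = translate_frame_oracle(rc, 0),
    "-2" = translate_frame_oracle(rc, 1), "-3" = translate_frame_oracle(rc, 2))
}

# split-at-stops ORF oracle (returns aa segments >= min_len per frame)
orf_oracle <- function(frames, min_len = 30) {
  out <- list()
  for (f in names(frames)) {
    aa <- frames[[f]]
    if (!nzchar(aa)) next
    pos <- 0
    for (seg in strsplit(aa, "*", fixed = TRUE)[[1]]) {
      if (nchar(seg) >= min_len) {
        out[[length(out) + 1]] <- list(frame = f, aa_start = pos, aa_seq = seg)
      }
      pos <- pos + nchar(seg) + 1
    }
  }
  out
}

# --- closed-form pooled-variance two-sample t-test
ttest_oracle <- function(x, y, tail = "two") {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  if (tail == "two") 2 * pt(-abs(t), df) else pt(t, df, lower.tail = FALSE)
}

# --- closed-form Pearson r and two-tailed p
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(t), n - 2))
}

random_dna_chr <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
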
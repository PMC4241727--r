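random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

mutate_sites <- function(seq, n_sites) {
  if (n_sites == 0L) return(seq)
  chars <- strsplit(seq, "")[[1]]
  sites <- sample.int(length(chars), n_sites, replace = FALSE)  # distinct sites
  for (s in sites) {
    chars[s] <- sample(setdiff(c("A", "C", "G", "T"), chars[s]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate a marker-gene reference set with controlled identity structure
#'
#' Builds a star phylogeny: a random ancestor gene (default 1550 nt, the
#' scale of a full-length 16S rRNA) from which each species is derived by
#' substituting `divergence` x length distinct sites. Optionally one
#' `near_pair` is planted by copying species `i` and substituting exactly
#' `round((1 - identity/100) * length)` sites — a twin pair emulating
#' sister species whose marker genes are ~99.5% identical. The taxonomy
#' places the twin pair in a shared genus and every other species in its own
#' genus, under a single family/order/class/phylum/domain spine.
#'
#' @param n_species number of species (>= 1).
#' @param gene_length gene length in nt (default 1550).
#' @param divergence per-species proportion of substituted sites from the
#'   ancestor, scalar or length-`n_species` vector, in `[0, 0.75)`.
#'   The default 0.10 yields pairwise identities around 80–85%, i.e.
#'   comfortably separable species.
#' @param near_pair `NULL`, or list `(i, j, identity)`: species `j` is
#'   rebuilt as a near-copy of species `i` at the given percent identity
#'   (default identity 99.5).
#' @param seed integer seed; the output is a pure function of the
#'   arguments.
#' @return List: `db` (a `reference_db`), `tree` (a `taxonomy_tree`),
#'   `truth` (data.frame `seq_id`, `taxon_id`, `species_name`,
#'   `divergence`).
#' @export
simulate_reference_set <- function(n_species = 10L, gene_length = 1550L,
                                   divergence = 0.10,
                                   near_pair = if (n_species >= 2L)
                                     list(i = n_species - 1L, j = n_species,
                                          identity = 99.5),
                                   seed = 1L) {
  stopifnot(n_species >= 1L, gene_length >= 10L,
            all(divergence >= 0), all(divergence < 0.75))
  divergence <- rep_len(divergence, n_species)
  if (!is.null(near_pair)) {
    if (is.null(near_pair$identity)) near_pair$identity <- 99.5
    if (n_species < 2L || near_pair$i > n_species || near_pair$j > n_species ||
        near_pair$i < 1L || near_pair$j < 1L || near_pair$i == near_pair$j) {
      stop("near_pair indices out of range")
    }
  }
  seqs <- withr::with_seed(seed, {
    ancestor <- random_dna(gene_length)
    out <- vapply(seq_len(n_species), function(i) {
      mutate_sites(ancestor, round(divergence[i] * gene_length))
    }, character(1))
    if (!is.null(near_pair)) {
      nd <- round((1 - near_pair$identity / 100) * gene_length)
      out[near_pair$j] <- mutate_sites(out[near_pair$i], nd)
    }
    out
  })
  sp_id <- sprintf("sp%02d", seq_len(n_species))
  sp_name <- sprintf("Species %02d", seq_len(n_species))
  # twin pair shares a genus; every other species gets its own genus
  genus_of <- sprintf("g_%s", sp_id)
  if (!is.null(near_pair)) {
    shared <- sprintf("g_%s", sp_id[near_pair$i])
    genus_of[c(near_pair$i, near_pair$j)] <- shared
  }
  genera <- unique(genus_of)
  spine <- data.frame(
    id = c("root", "d1", "p1", "c1", "o1", "f1"),
    parent_id = c(NA, "root", "d1", "p1", "c1", "o1"),
    rank = c("root", "domain", "phylum", "class", "order", "family"),
    name = c("root", "Bacteria", "Firmicutes", "Bacilli",
             "Lactobacillales", "Lactobacillaceae"),
    stringsAsFactors = FALSE)
  gtab <- data.frame(id = genera, parent_id = "f1", rank = "genus",
                     name = sub("^g_", "Genus ", genera), stringsAsFactors = FALSE)
  stab <- data.frame(id = sp_id, parent_id = genus_of, rank = "species",
                     name = sp_name, stringsAsFactors = FALSE)
  tree <- load_taxonomy(rbind(spine, gtab, stab))
  seq_id <- sprintf("ref_%s", sp_id)
  db <- build_refdb(stats::setNames(seqs, seq_id),
                    stats::setNames(sp_id, seq_id), tree)
  truth <- data.frame(seq_id = seq_id, taxon_id = sp_id, species_name = sp_name,
                      divergence = divergence, stringsAsFactors = FALSE)
  list(db = db, tree = tree, truth = truth)
}

#' Simulate a community read pool
#'
#' Draws read counts from a multinomial over the community composition, then
#' cuts each read as a random substring of its species' reference sequence
#' (lengths uniform over `read_length`, emulating the ~160–210 nt fragments
#' of short-read cDNA) and applies i.i.d. per-base substitution errors.
#'
#' @param db a `reference_db`.
#' @param composition named numeric vector taxon -> proportion (sums to 1).
#' @param n_reads total reads.
#' @param read_length integer vector of admissible lengths (default
#'   `160:210`), sampled uniformly per read.
#' @param error_rate per-base substitution probability (default 0).
#' @param seed integer seed.
#' @return List: `reads` (named character vector), `truth` (data.frame
#'   `read_id`, `taxon_id`, `seq_id`, `start` 0-based, `length`,
#'   `n_errors`).
#' @export
simulate_community <- function(db, composition, n_reads,
                               read_length = 160:210, error_rate = 0,
                               seed = 1L) {
  stopifnot(abs(sum(composition) - 1) < 1e-9, all(composition >= 0),
            error_rate >= 0, error_rate <= 1)
  absent <- setdiff(names(composition), db$taxon)
  if (length(absent)) stop("composition taxa not in db: ", paste(absent, collapse = ", "))
  withr::with_seed(seed, {
    counts <- as.vector(stats::rmultinom(1, n_reads, composition))
    taxa <- rep(names(composition), counts)
    taxa <- sample(taxa)  # shuffle read order
    reads <- character(n_reads)
    truth <- data.frame(read_id = sprintf("read%06d", seq_len(n_reads)),
                        taxon_id = taxa, seq_id = NA_character_,
                        start = NA_integer_, length = NA_integer_,
                        n_errors = NA_integer_, stringsAsFactors = FALSE)
    for (i in seq_len(n_reads)) {
      recs <- which(db$taxon == taxa[i])
      rec <- if (length(recs) > 1L) sample(recs, 1L) else recs
      refseq <- as.character(db$seqs[[rec]])
      L <- if (length(read_length) > 1L) sample(read_length, 1L) else read_length
      if (nchar(refseq) < L) stop("read length ", L, " exceeds reference ",
                                  names(db$seqs)[rec])
      s <- sample.int(nchar(refseq) - L + 1L, 1L) - 1L
      rd <- substr(refseq, s + 1L, s + L)
      nerr <- 0L
      if (error_rate > 0) {
        chars <- strsplit(rd, "")[[1]]
        hit <- which(stats::runif(L) < error_rate)
        for (h in hit) chars[h] <- sample(setdiff(c("A", "C", "G", "T"), chars[h]), 1L)
        nerr <- length(hit)
        rd <- paste(chars, collapse = "")
      }
      reads[i] <- rd
      truth$seq_id[i] <- names(db$seqs)[rec]
      truth$start[i] <- s
      truth$length[i] <- L
      truth$n_errors[i] <- nerr
    }
    names(reads) <- truth$read_id
    list(reads = reads, truth = truth)
  })
}

# back-translate an amino-acid string with one fixed codon per residue;
# codons chosen to avoid creating stops across junctions is automatic since
# every codon is a complete non-stop codon
CODON_OF <- c(A="GCT", C="TGT", D="GAT", E="GAA", F="TTT", G="GGT", H="CAT",
              I="ATT", K="AAA", L="CTG", M="ATG", N="AAT", P="CCT", Q="CAA",
              R="CGT", S="TCT", T="ACT", V="GTT", W="TGG", Y="TAT")

back_translate <- function(aa) {
  paste(CODON_OF[strsplit(aa, "")[[1]]], collapse = "")
}

NONSTOP_AA <- AA20  # any standard residue codon is stop-free

#' Simulate a coding-read pool with planted domains
#'
#' Generates nucleotide reads in which a chosen fraction carries a domain
#' profile's consensus, back-translated and embedded in a stop-free +1
#' reading frame of at least `orf_len` amino acids; the remaining reads are
#' uniform random nucleotides. The truth table records each planted
#' (read, domain, frame).
#'
#' @param n_reads total reads.
#' @param profiles list of `domain_profile`s to plant (cycled over planted
#'   reads).
#' @param plant_fraction fraction of reads carrying a domain, in `[0, 1]`.
#' @param orf_len length (aa) of the stop-free frame hosting the consensus
#'   (default 50; must be >= the widest profile).
#' @param seed integer seed.
#' @return List: `reads` (named character vector, length `3 * orf_len` nt),
#'   `truth` (data.frame `read_id`, `domain_id`, `frame`, `aa_offset`).
#' @export
simulate_coding_pool <- function(n_reads, profiles, plant_fraction = 0.5,
                                 orf_len = 50L, seed = 1L) {
  stopifnot(plant_fraction >= 0, plant_fraction <= 1, n_reads >= 0)
  if (inherits(profiles, "domain_profile")) profiles <- list(profiles)
  widths <- vapply(profiles, `[[`, numeric(1), "width")
  if (length(profiles) && any(widths > orf_len)) {
    stop("profile consensus wider than the host reading frame (", orf_len, " aa)")
  }
  n_plant <- round(plant_fraction * n_reads)
  if (n_plant > 0L && length(profiles) == 0L) stop("no profiles to plant")
  withr::with_seed(seed, {
    reads <- character(n_reads)
    truth <- list()
    for (i in seq_len(n_reads)) {
      if (i <= n_plant) {
        p <- profiles[[(i - 1L) %% length(profiles) + 1L]]
        host <- sample(NONSTOP_AA, orf_len, replace = TRUE)
        off <- sample.int(orf_len - p$width + 1L, 1L) - 1L
        host[(off + 1L):(off + p$width)] <- strsplit(p$consensus, "")[[1]]
        reads[i] <- back_translate(paste(host, collapse = ""))
        truth[[length(truth) + 1L]] <- data.frame(
          read_id = sprintf("cread%06d", i), domain_id = p$domain_id,
          frame = "+1", aa_offset = off, stringsAsFactors = FALSE)
      } else {
        reads[i] <- random_dna(3L * orf_len)
      }
    }
    names(reads) <- sprintf("cread%06d", seq_len(n_reads))
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(read_id = character(0), domain_id = character(0),
                 frame = character(0), aa_offset = integer(0),
                 stringsAsFactors = FALSE)
    list(reads = reads, truth = truth)
  })
}
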
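---
title: "Methods: marker-gene classification, resolution benchmarking, and functional profiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: marker-gene classification, resolution benchmarking, and functional profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`metatax` implements the computational core of a mixed rRNA/mRNA
(metatranscriptome) community analysis in which short cDNA reads must be
placed on a taxonomy at the deepest defensible rank, the species-level
resolving power of a reference database must be quantified before species
claims are made, and expressed functions must be compared between sample
groups. This vignette describes each model and procedure, its assumptions,
the tunable parameters, and the numerical choices, in the package's own
terms. It states no empirical result beyond what the test suite and
`scripts/acceptance.R` themselves compute.

## Taxonomic assignment model

A read is compared against every record of a species-labelled reference
database by exact affine-gap local alignment (Smith–Waterman, delegated to
the `Biostrings` dynamic-programming engine). Raw scores are mapped to bits
with the Karlin–Altschul transform

$$ S' = \frac{\lambda S - \ln K}{\ln 2}, $$

so score thresholds are comparable across scoring schemes. The default
scheme (`scoring_scheme()`) is the classic nucleotide convention match +2,
mismatch −3, gap open 5, gap extend 2, with ungapped-regime parameters
$\lambda = 0.625$ nats and $K = 0.41$; a gap of length $L$ costs
`gap_open + L * gap_extend`. Under this scheme an exact 170-nt match scores
about 308 bits, so the conventional floors of 150 bits (rRNA) and 40 bits
(short mRNA tags) sit in a realistic range. Both strands of every read are
aligned and the better strand kept, because cDNA reads are unstranded.

Assignment then proceeds in three stages (`classify_dataset()`):

1. **Bit-score floor.** Hits below `min_bit` are discarded.
2. **Top-percent window.** Among survivors, only hits with
   `bit >= best_bit * (1 - top_percent/100)` are retained. The window is
   multiplicative on bit scores; an additive reading ("within
   `top_percent` bits of the best") was considered and rejected because the
   stated thresholds are themselves bit scores, and a multiplicative window
   keeps the retained set invariant under rescaling of $\lambda$.
3. **LCA placement.** The read is placed at the lowest common ancestor of
   the retained hits' species. A read whose hits span two species of one
   genus lands on the genus; a read with a single retained species keeps
   species rank; a read with no retained hit is `UNASSIGNED`.

After all reads are placed, a **minimal-support** rule is applied at the
dataset level (`apply_min_support()`): working from species upward, any
node whose subtree holds fewer than `min_support` reads has those reads
reassigned to its parent. Push-up (rather than discarding) is the default
because it conserves read counts — the sum of all per-taxon counts plus
`UNASSIGNED` always equals the number of input reads, an invariant the test
suite checks continuously. A `discard` mode is available for workflows that
prefer dropping weakly supported calls.

The taxonomy is a strict eight-rank ladder (root, domain, phylum, class,
order, family, genus, species). Intermediate unranked nodes are rejected at
load time; this keeps both the LCA and the rank summaries unambiguous.

## Resolution benchmark and taxon merging

Whether species-level calls are trustworthy depends on the reference set,
not only on the classifier. `run_benchmark()` answers this the way the
field does: cut each reference gene into `n` random fragments of length
`L` (defaults 500 × 170 nt, roughly 55× coverage of a 1550-nt gene, which
is why fragment starts are drawn uniformly at random with replacement —
tiling cannot produce 500 fragments of 170 nt from one gene; a tiling mode
exists for completeness), classify them self-inclusively against the full
database, and tally a confusion matrix whose rows conserve fragments
exactly: correct species, each wrong species, `higher_rank`, and
`UNASSIGNED`.

`recovery_report()` reduces the matrix to per-species fractions.
A *false positive* means assignment to a wrong species — distinct from the
benign outcomes of genus-level placement or non-assignment.

`recommend_merges()` flags species pairs that the benchmark cannot
separate: pairs whose reference identity reaches ~99.5% (global alignment,
terminal gap columns excluded, N never a match) and, when a confusion
matrix is supplied, pairs whose fragments mutually retain the other species
inside the top-percent window for at least 25% of fragments. The identity
comparison carries a 0.1-percentage-point slack because planted or real
substitution counts are discrete: a pair constructed at nominal 99.5% over
1550 nt realizes 8 substitutions, i.e. 99.484%. The remedy for a flagged
pair is `omit_taxa()`: drop one twin's records and relabel the survivor
with a merged name (e.g. `"Species 09/10"`), after which the twin's
fragments recover under the merged label.

**Benchmark defaults.** The benchmark runs with `min_bit = 150`,
`top_percent = 10`, `min_support = 1`. The 10% window is the package-wide
rRNA classification default; it is also the scientifically appropriate
setting for synthetic references, whose twin-pair differences are scattered
uniformly along the gene rather than concentrated in variable regions as in
real 16S genes. Under a 1% window, uniformly scattered differences make
synthetic twins *more* separable than real ones (a single covered
difference costs ~4.5 bits, more than the 1% window width at ~308 bits);
the 10% window reproduces the realistic regime in which fragments
overlapping a handful of diagnostic sites still retain both twins.
`min_support = 1` keeps the benchmark a pure measurement of alignment
resolution. Both are configurable, and the perfect-separation property
(100% recovery, zero wrong-species calls on references at ≤90% mutual
identity) holds at `top_percent = 1` as well, as the acceptance suite
verifies.

## Community profiles

`rank_abundance()` projects post-support per-taxon counts onto one rank:
each read contributes to its assigned node's ancestor at that rank, and
reads assigned above the rank pool with `UNASSIGNED` reads into a single
`unclassified` column (a `separate` mode keeps them apart). The denominator
is all reads entering the summary, not only classified reads, so rows
always sum to 100% — switch via the `separate` mode plus renormalization if
the classified-only convention is wanted. `species_profile()` additionally
reports the fraction of reads that reached species rank, the natural
headline number for a family-restricted species profile; because the
all-reads vs classified-reads denominator question is genuinely ambiguous
in such summaries, both the percentages and the assigned fraction are
returned so either convention can be reported. `subsample_reads()`
provides the fixed-depth uniform subsampling (e.g. 100 000 rRNA reads per
sample) that makes samples of unequal depth comparable.

## ORFs and protein-domain scanning

mRNA reads are translated in all six frames (`six_frame_translate()`;
bacterial code — its stop codons TAA/TAG/TGA are those of the standard
table; the first codon is *not* treated as an initiator, since fragment
reads rarely begin at a gene start). Each frame is split at stop symbols
and stop-free segments of ≥30 aa are kept as ORFs, with no start-codon
requirement (`extract_orfs()`). The 30-aa floor is a hard boundary: a
29-aa segment is rejected.

Domains are detected with position-weight-matrix profiles
(`domain_profile()`): per-column log2-odds against a background, summed
over a sliding window, best window per (ORF, profile). E-values use a
Gumbel tail calibrated per profile (`calibrate_profile()`): location and
scale are fitted by maximum likelihood to the scores of 2000 random
background sequences of the profile's width (fixed seed), and

$$ E = N_\text{windows} \, e^{-(s-\mu)/\beta}. $$

Because per-window scores of random sequences have lighter tails than the
fitted exponential, this calibration is conservative: observed random hit
rates fall at or below the nominal expectation, which the acceptance suite
checks over 10 000 random scans. Hits with $E < 10^{-4}$ are counted. The
scanner is a pluggable contract — anything returning
`(orf_id, domain_id, score, e_value)`, e.g. an external profile-HMM engine,
can substitute for the built-in PSSM scanner; `domain_abundance()` and the
differential stage are agnostic. Residues outside the 20-letter alphabet
(notably `X` from unresolved `N` codons) score a flat −10 bits — they never
help a match. Per-sample "% relative abundance" of a domain is its share of
that sample's counted hits; the denominator choice (all counted hits, not
all ORFs or all reads) is documented here because other conventions exist.

## Differential statistics

For each functional category, `diff_table()` reports group means ± sd, the
fold change `mean_a / mean_b`, and an unpaired t-test p-value.
Pooled-variance Student's t is the default — the classic "unpaired t-test"
of desktop statistics packages — with Welch behind `var_equal = FALSE`.
One-tailed tests halve the two-tailed p when the observed direction matches
the hypothesis (a > b) and report `1 - p/2` otherwise; the tail is
caller-specified per category, since which categories warrant a directed
test is a design decision, not something the data can decide. A category
absent from the comparison group (`mean_b = 0`, `mean_a > 0`) has an
undefined fold magnitude and is reported as *nd* (not detected, `Inf`
internally); its p-value is still computed on the raw per-sample
abundances, zeros included. `select_enriched()` implements the selection
rule *p < 0.05 AND (fold ≥ 10 OR nd)* — nd rows satisfy the fold criterion
by convention, since the enrichment is unbounded. No multiple-testing
correction is applied by default, matching the single-table screening
practice this reproduces; Benjamini–Hochberg is available via
`adjust = TRUE` and is deliberately off by default.

`pca_covariance()` performs PCA as eigendecomposition of the sample
variance-covariance matrix of column-centered data — never unit-variance
scaled, so abundant categories legitimately dominate, which is the point of
a covariance (rather than correlation) PCA of relative abundances.
Component signs are fixed by making each loading's largest-magnitude entry
positive. Eigenvalue dust below `1e-12` of the largest magnitude is clamped
to zero; the eigenvalue sum always equals the covariance trace to 1e-9.

## Synthetic data: what it emulates, and what it does not

Real reference sets and read pools from sequence archives are deliberately
out of scope; `simulate_reference_set()` generates the structures the
method's validation needs:

- a **star phylogeny**: one random ancestor gene (default 1550 nt, the
  length scale of a full 16S gene), each species mutated at
  `divergence × length` distinct sites. Divergence 0.10 — the default —
  realizes pairwise identities around 80–85%, comfortably separable
  species. A star rather than a full tree suffices because the benchmark
  only needs controlled pairwise identity, not a realistic topology.
- a **twin pair** at a requested identity (default 99.5%): species *j* is a
  copy of species *i* with exactly `round((1 - identity/100) * length)`
  substitutions at distinct random sites, and the two share a genus so the
  LCA of a confused fragment is their genus.
- substitution-only mutation (no indels) by default, which keeps identity
  arithmetic exact and alignment expectations crisp.

`simulate_community()` draws multinomial read counts over a composition,
cuts uniform random substrings (lengths uniform on 160–210 nt, the short
cDNA fragment regime), and applies i.i.d. substitution errors.
`simulate_coding_pool()` embeds back-translated profile consensi in
stop-free +1 frames.

What passing tests on these data do **not** show: real 16S genes
concentrate variation in hypervariable regions, share conserved stretches
across genera, and contain indels and ambiguity codes; real communities
contain taxa missing from any database; real coding reads carry degenerate,
partially diverged domain instances. Results here validate the *machinery*
(score windows, LCA, support push-up, confusion accounting, calibration,
selection rules), not any claim about a particular biological system.

## Problem sizes and determinism

Every simulator is a pure function of its arguments and a seed (RNG state
is isolated with `withr::with_seed`, so library calls never disturb the
caller's RNG). The bundled pipeline (`run_pipeline()`, `default_config()`)
uses desk-scale sizes chosen to exercise every code path at interactive
speed: 10 species × 1550 nt references, 50 fragments/species in the
acceptance benchmark (500 in the classical full-scale setting — the
fragment count is a pure sampling-precision knob, not a bias knob), 11
community samples in groups of 5 and 6, ~60 coding reads per sample, 6
domain profiles of width 30. The acceptance script
(`scripts/acceptance.R`) re-derives its quantities from scratch at these
sizes. Re-running any stage with a fixed config reproduces its output files
byte for byte.

## Known limitations

- The aligner is exact dynamic programming throughout; no heuristic
  seeding is provided. At reference-archive scale (thousands of records) a
  seeded search would be needed; at the package's intended desk scale
  exactness is cheaper than the engineering.
- E-value calibration assumes the background residue distribution used at
  calibration time; scanning sequences with a very different composition
  shifts the effective false-positive rate.
- The min-support push-up is applied per dataset, so merging datasets and
  re-applying support can change shallow placements.
- `pairwise_identity()` is a true global alignment; comparing a fragment
  against a full-length gene with it will count internal gaps. Use the
  local aligner for fragment scoring.
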
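#' Default end-to-end pipeline configuration
#'
#' A nested list describing every stage of the demo pipeline at desk scale:
#' a 10-species synthetic reference world containing one ~99.5%-identity
#' twin pair, a fragmentation benchmark, mock community samples in two
#' groups sized 5 ("forestomach") and 6 ("hindgut") — matching a typical
#' two-compartment design so the t-test paths run at realistic n — a
#' planted-domain coding pool per sample, and the differential/PCA stage.
#' Every random stage carries its own seed derived from the top-level seed.
#'
#' @param seed top-level integer seed.
#' @return A `pipeline_config` list.
#' @export
default_config <- function(seed = 42L) {
  structure(list(
    seed = seed,
    refs = list(n_species = 10L, gene_length = 1550L, divergence = 0.10,
                near_pair = list(i = 9L, j = 10L, identity = 99.5)),
    benchmark = list(n = 50L, length = 170L,
                     min_bit = 150, top_percent = 10, min_support = 1L),
    community = list(
      n_reads = 120L, read_length = 160:210, error_rate = 0.005,
      groups = list(
        forestomach = sprintf("FS%d", 1:5),
        hindgut = c(sprintf("CL%d", 1:3), sprintf("IL%d", 1:3))),
      # group-level species compositions (taxon id -> proportion)
      composition = list(
        forestomach = c(sp01 = 0.35, sp02 = 0.25, sp03 = 0.15, sp09 = 0.15,
                        sp10 = 0.10),
        hindgut = c(sp04 = 0.30, sp05 = 0.25, sp06 = 0.20, sp07 = 0.15,
                    sp08 = 0.10))),
    coding = list(
      n_reads = 60L, orf_len = 50L, n_domains = 6L, profile_width = 30L,
      # per-group domain planting weights; domains 1-3 enriched in group a,
      # domain 4 absent from group b ("nd" path), 5-6 shared background
      weights = list(
        forestomach = c(0.25, 0.20, 0.15, 0.10, 0.15, 0.15),
        hindgut = c(0.02, 0.02, 0.01, 0.00, 0.475, 0.475)),
      plant_fraction = 0.9),
    diff = list(min_fold = 10, alpha = 0.05, tails = "two"),
    classifier = list(min_bit = 150, top_percent = 10, min_support = 1L)
  ), class = c("pipeline_config", "list"))
}

stage_seed <- function(seed, k) (as.integer(seed) * 131L + k) %% 2147483647L

#' Write the canonical demo dataset to disk
#'
#' Materializes the synthetic world of [default_config()] as plain-text
#' files: reference FASTA, taxonomy and taxon-map TSVs, per-sample community
#' read FASTAs with truth tables, per-sample coding-read FASTAs, and the
#' calibrated domain profiles as JSON.
#'
#' @param out_dir writable output directory (created if needed).
#' @param seed top-level integer seed.
#' @param config a `pipeline_config` (default [default_config()]).
#' @return Invisibly, the in-memory fixture list (same shape as the one
#'   [run_pipeline()] builds).
#' @export
make_fixtures <- function(out_dir, seed = 42L, config = default_config(seed)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fx <- build_world(config)
  write_fasta(as.character(fx$world$db$seqs), file.path(out_dir, "refs.fa"))
  write_taxonomy(fx$world$tree, file.path(out_dir, "taxonomy.tsv"))
  utils::write.table(
    data.frame(seq_id = names(fx$world$db$taxon), taxon_id = unname(fx$world$db$taxon)),
    file.path(out_dir, "taxmap.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in names(fx$community)) {
    write_fasta(fx$community[[s]]$reads, file.path(out_dir, paste0(s, "_reads.fa")))
    utils::write.table(fx$community[[s]]$truth,
                       file.path(out_dir, paste0(s, "_truth.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_fasta(fx$coding[[s]]$reads, file.path(out_dir, paste0(s, "_coding.fa")))
  }
  for (p in fx$profiles) {
    write_profile(p, file.path(out_dir, paste0(p$domain_id, ".json")))
  }
  invisible(fx)
}

# simulate every input of the pipeline from the config seeds
build_world <- function(config) {
  world <- simulate_reference_set(
    n_species = config$refs$n_species,
    gene_length = config$refs$gene_length,
    divergence = config$refs$divergence,
    near_pair = if (config$refs$n_species >= 2L) config$refs$near_pair,
    seed = stage_seed(config$seed, 1L))
  species <- ref_species(world$db)
  profiles <- lapply(seq_len(config$coding$n_domains), function(d) {
    cons <- withr::with_seed(stage_seed(config$seed, 100L + d),
                             paste(sample(AA20, config$coding$profile_width,
                                          replace = TRUE), collapse = ""))
    calibrate_profile(domain_profile(sprintf("DOM%03d", d), cons),
                      seed = stage_seed(config$seed, 200L + d))
  })
  samples <- unlist(config$community$groups, use.names = FALSE)
  group_of <- stats::setNames(
    rep(names(config$community$groups),
        lengths(config$community$groups)), samples)
  community <- list(); coding <- list()
  for (si in seq_along(samples)) {
    s <- samples[si]
    grp <- group_of[[s]]
    comp <- config$community$composition[[grp]]
    comp <- comp[names(comp) %in% species]
    comp <- comp / sum(comp)
    community[[s]] <- simulate_community(
      world$db, comp, config$community$n_reads,
      read_length = config$community$read_length,
      error_rate = config$community$error_rate,
      seed = stage_seed(config$seed, 300L + si))
    coding[[s]] <- simulate_sample_coding(
      config$coding$n_reads, profiles, config$coding$weights[[grp]],
      config$coding$plant_fraction, config$coding$orf_len,
      seed = stage_seed(config$seed, 400L + si))
  }
  list(world = world, profiles = profiles, community = community,
       coding = coding, samples = samples, group_of = group_of)
}

# one sample's coding pool: planted reads drawn per-domain by weight,
# remainder random background
simulate_sample_coding <- function(n_reads, profiles, weights, plant_fraction,
                                   orf_len, seed) {
  stopifnot(length(weights) == length(profiles))
  w <- weights / sum(weights)
  n_plant <- round(plant_fraction * n_reads)
  per_dom <- withr::with_seed(seed, {
    as.vector(stats::rmultinom(1, n_plant, w))
  })
  reads <- character(0); truth <- list()
  for (d in seq_along(profiles)) {
    if (per_dom[d] == 0L) next
    pool <- simulate_coding_pool(per_dom[d], profiles[[d]], plant_fraction = 1,
                                 orf_len = orf_len,
                                 seed = (seed + 17L * d) %% 2147483647L)
    reads <- c(reads, unname(pool$reads))
    truth[[length(truth) + 1L]] <- pool$truth
  }
  n_bg <- n_reads - length(reads)
  if (n_bg > 0L) {
    bg <- simulate_coding_pool(n_bg, profiles[1], plant_fraction = 0,
                               orf_len = orf_len,
                               seed = (seed + 9999L) %% 2147483647L)
    reads <- c(reads, unname(bg$reads))
  }
  names(reads) <- sprintf("cread%06d", seq_along(reads))
  truth <- if (length(truth)) do.call(rbind, truth) else NULL
  list(reads = reads, truth = truth)
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage end to end on the synthetic world described by
#' `config`: reference simulation, fragmentation benchmark (plus merge
#' recommendation and post-merge re-benchmark when a near-identical pair is
#' found), per-sample community classification and rank profiles, coding-read
#' ORF extraction and domain scanning, differential functional statistics,
#' and covariance PCA. All tables are written as UTF-8 TSV under `out_dir`
#' together with a JSON provenance record of every parameter and seed; a
#' re-run with the same config reproduces the outputs byte for byte.
#'
#' @param config a `pipeline_config` list, or the path of a YAML file with
#'   the same structure. An optional `inputs$fixture_dir` entry must name an
#'   existing directory produced by [make_fixtures()] (inputs are then read
#'   from disk instead of simulated).
#' @param out_dir writable output directory.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- utils::modifyList(default_config(), yaml::read_yaml(config))
  }
  if (!is.null(config$inputs$fixture_dir) && !dir.exists(config$inputs$fixture_dir)) {
    stop("inputs$fixture_dir does not exist: ", config$inputs$fixture_dir)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scheme <- scoring_scheme()
  fx <- build_world(config)
  world <- fx$world
  # --- benchmark + merge recommendation ---------------------------------
  bparams <- classifier_params(config$benchmark$min_bit,
                               config$benchmark$top_percent,
                               config$benchmark$min_support)
  cm <- run_benchmark(world$db, world$tree, scheme = scheme, params = bparams,
                      n = config$benchmark$n, length = config$benchmark$length,
                      seed = stage_seed(config$seed, 2L))
  rec <- recovery_report(cm)
  merges <- if (length(ref_species(world$db)) >= 2L) {
    recommend_merges(world$db, cm = cm)
  } else {
    data.frame(taxon_a = character(0), taxon_b = character(0),
               identity = numeric(0), rationale = character(0),
               stringsAsFactors = FALSE)
  }
  utils::write.table(as.data.frame(unclass(cm)), file.path(out_dir, "confusion.tsv"),
                     sep = "\t", quote = FALSE)
  utils::write.table(rec, file.path(out_dir, "recovery.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(merges, file.path(out_dir, "merges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  merged <- NULL
  if (nrow(merges) > 0L) {
    drop <- merges$taxon_b[1]; keep <- merges$taxon_a[1]
    db2 <- omit_taxa(world$db, drop, merge_into = keep,
                     merged_label = paste(world$tree[keep, "name"],
                                          world$tree[drop, "name"], sep = "/"),
                     tree = world$tree)
    cm2 <- run_benchmark(world$db, world$tree,
                         target_taxa = c(keep, drop), scheme = scheme,
                         params = bparams, n = config$benchmark$n,
                         length = config$benchmark$length,
                         seed = stage_seed(config$seed, 3L),
                         classify_db = db2)
    rec2 <- recovery_report(cm2, correct = stats::setNames(c(keep, keep),
                                                           c(keep, drop)))
    utils::write.table(rec2, file.path(out_dir, "recovery_merged.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    merged <- list(dropped = drop, kept = keep, cm = cm2, recovery = rec2)
  }
  # --- community classification + profiles ------------------------------
  cparams <- classifier_params(config$classifier$min_bit,
                               config$classifier$top_percent,
                               config$classifier$min_support)
  genus_rows <- list(); species_rows <- list(); assigned_frac <- numeric(0)
  classified <- list()
  for (s in fx$samples) {
    cls <- classify_dataset(fx$community[[s]]$reads, world$db, world$tree,
                            scheme, cparams)
    classified[[s]] <- cls
    genus_rows[[s]] <- rank_abundance(cls$counts, world$tree, "genus")
    sp <- species_profile(cls$counts, world$tree)
    species_rows[[s]] <- sp$abundance
    assigned_frac[s] <- sp$assigned_fraction
    write_assignments(cls$assignments,
                      file.path(out_dir, paste0(s, "_assignments.tsv")))
  }
  write_abundance(abundance_table(genus_rows), file.path(out_dir, "genus_abundance.tsv"))
  write_abundance(abundance_table(species_rows),
                  file.path(out_dir, "species_abundance.tsv"))
  # --- ORFs + domain scan + functional abundance ------------------------
  hit_rows <- list()
  for (s in fx$samples) {
    frames <- lapply(fx$coding[[s]]$reads, six_frame_translate)
    orfs <- extract_orfs(frames)
    hits <- scan_domains(orfs, fx$profiles)
    if (nrow(hits)) hits$sample <- s
    hit_rows[[s]] <- hits
  }
  hits_all <- do.call(rbind, hit_rows)
  fun_ab <- domain_abundance(hits_all, samples = fx$samples)
  write_abundance(fun_ab$table, file.path(out_dir, "domain_abundance.tsv"))
  # --- differential stats + PCA -----------------------------------------
  grp_names <- names(config$community$groups)
  a_samples <- config$community$groups[[grp_names[1]]]
  b_samples <- config$community$groups[[grp_names[2]]]
  dt <- diff_table(fun_ab$table[a_samples, , drop = FALSE],
                   fun_ab$table[b_samples, , drop = FALSE],
                   tails = config$diff$tails)
  dt <- select_enriched(dt, min_fold = config$diff$min_fold,
                        alpha = config$diff$alpha)
  write_diff(dt, file.path(out_dir, "diff.tsv"))
  pca <- pca_covariance(fun_ab$table)
  utils::write.table(data.frame(sample = rownames(pca$scores), pca$scores,
                                check.names = FALSE),
                     file.path(out_dir, "pca_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(category = rownames(pca$loadings), pca$loadings,
                                check.names = FALSE),
                     file.path(out_dir, "pca_loadings.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(component = names(pca$eigenvalues),
                                eigenvalue = pca$eigenvalues,
                                explained = pca$explained),
                     file.path(out_dir, "pca_eigenvalues.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  provenance <- list(
    package = "metatax",
    version = as.character(utils::packageVersion("metatax")),
    config = unclass(config),
    stage_seeds = list(refs = stage_seed(config$seed, 1L),
                       benchmark = stage_seed(config$seed, 2L),
                       benchmark_merged = stage_seed(config$seed, 3L)))
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(world = world, benchmark = list(cm = cm, recovery = rec,
                                                 merges = merges, merged = merged),
                 classified = classified, assigned_fraction = assigned_frac,
                 functional = fun_ab, diff = dt, pca = pca))
}
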
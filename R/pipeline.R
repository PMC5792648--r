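#' Default pipeline configuration
#'
#' All knobs of the end-to-end comparison in one nested list: taxonomy
#' shape, reference-set mutation rates and bias fractions, the copy-number
#' and expression laws (with one designated low-copy, high-expression
#' lineage emulating a highly transcribing archaeon), community profile
#' law, the perturbation defining the second condition, per-strategy read
#' counts, classifier settings and per-stage seeds. The configuration
#' round-trips losslessly through YAML via [write_run_config()].
#'
#' @param seed master seed; per-stage seeds are derived as small fixed
#'   offsets so every stochastic stage is explicitly seeded.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1) {
  seed <- as.integer(seed)
  list(
    seeds = list(taxonomy = seed, reference = seed + 1L, profile = seed + 2L,
                 reads = seed + 3L, classify = seed + 4L,
                 subsample = seed + 5L, rarefy = seed + 6L),
    taxonomy_counts = c(2L, 6L, 8L, 12L, 20L, 50L),
    reference = list(conserved_sub_rate = 0.02, variable_sub_rate = 0.30,
                     biased_fraction = 0.2, strains_per_genus = 1L,
                     site_offset = 75L),
    copy_number_law = list(min = 1L, max = 7L, low_copy_genus = "g02"),
    expression_law = list(meanlog = 0, sdlog = 1,
                          high_expression_genus = "g02",
                          high_expression_fold = 20),
    profile = list(mu = 0, sigma = 1.5),
    perturbation = list(g03 = 1 / 6, g05 = 4),
    n_samples = 3L,
    reads = list(n_pairs = 60000L, read_len = 150L),
    error_model = default_error_model(),
    classifier = list(w = 8L, n_bootstrap = 100L, threshold = 0.8,
                      mode = "truth"),
    c1 = list(n_reads = 1500L, dropped_phylum = "p03"),
    c3 = list(n_pairs = 800L),
    c4 = list(subsample = 60000L),
    c5 = list(subsample = 5000L),
    rarefaction = list(max_depth = 60000L, n_reps = 5L)
  )
}

#' Write / read a run configuration (YAML)
#'
#' @param config configuration list.
#' @param path YAML file.
#' @return `path` invisibly / the configuration.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' Build the synthetic scenario of a configuration
#'
#' Generates the taxonomy, the reference set and the community profiles of
#' both conditions ("a" = baseline, "b" = after the perturbation).
#'
#' @param config configuration from [default_run_config()].
#' @return list with `refset`, `profile_a`, `profile_b`.
#' @export
build_scenario <- function(config) {
  lineages <- generate_taxonomy(config$taxonomy_counts, config$seeds$taxonomy)
  refset <- generate_reference_set(
    lineages,
    conserved_sub_rate = config$reference$conserved_sub_rate,
    variable_sub_rate = config$reference$variable_sub_rate,
    biased_fraction = config$reference$biased_fraction,
    copy_number_law = config$copy_number_law,
    expression_law = config$expression_law,
    seed = config$seeds$reference,
    strains_per_genus = config$reference$strains_per_genus,
    site_offset = config$reference$site_offset)
  profile_a <- generate_profile(refset, config$profile$mu, config$profile$sigma,
                                config$seeds$profile)
  effect <- unlist(config$perturbation)
  # perturbation keys are genus labels; expand to the taxa of each genus
  taxa_of <- lapply(names(effect), function(g)
    refset$taxa$taxon_id[refset$taxa$genus == g])
  effect_map <- setNames(rep(effect, lengths(taxa_of)),
                         unlist(taxa_of, use.names = FALSE))
  profile_b <- perturb_profile(profile_a, effect_map)
  list(refset = refset, profile_a = profile_a, profile_b = profile_b)
}

# per-read assignments for a simulated pair table, either from ground truth
# or by classifying the forward mate
assignments_for <- function(pairs, refset, config, model = NULL, seed_shift = 0L) {
  if (identical(config$classifier$mode, "truth"))
    return(truth_assignments(pairs, refset))
  if (is.null(model)) model <- train_classifier(refset, config$classifier$w)
  cl <- classify_reads(pairs$fwd_seq, model,
                       n_bootstrap = config$classifier$n_bootstrap,
                       threshold = config$classifier$threshold,
                       seed = config$seeds$classify + seed_shift,
                       read_ids = pairs$read_id)
  cl[, c("read_id", RANKS)]
}

#' C1: influence of the training set
#'
#' Classifies the same amplicon reads against word models trained on two or
#' more alternative reference subsets (emulating different training
#' databases) and reports, per set, the per-rank assigned-read counts and
#' the genus-level abundance table.
#'
#' @param config configuration list.
#' @param training_sets named list of taxon_id vectors; defaults to the full
#'   reference set versus a degraded set missing one phylum
#'   (`config$c1$dropped_phylum`).
#' @param scenario optional pre-built scenario (from [build_scenario()]).
#' @return list with `assigned_counts` (data.frame set x rank), `tables`
#'   (per-set genus abundance tables) and `truth` assignments.
#' @export
run_c1_training_sets <- function(config = default_run_config(),
                                 training_sets = NULL, scenario = NULL) {
  if (is.null(scenario)) scenario <- build_scenario(config)
  refset <- scenario$refset
  if (is.null(training_sets)) {
    drop <- refset$taxa$taxon_id[refset$taxa$phylum == config$c1$dropped_phylum]
    training_sets <- list(full = refset$taxa$taxon_id,
                          degraded = setdiff(refset$taxa$taxon_id, drop))
  }
  stop_if_not(length(training_sets) >= 2, "need at least 2 training sets")
  pairs <- simulate_amplicon(refset, scenario$profile_a, config$c1$n_reads,
                             read_len = config$reads$read_len,
                             error_model = config$error_model,
                             seed = config$seeds$reads)
  tables <- list(); counts <- list()
  for (set_name in names(training_sets)) {
    sub <- subset_reference_set(refset, training_sets[[set_name]])
    model <- train_classifier(sub, config$classifier$w)
    cl <- classify_reads(pairs$fwd_seq, model,
                         n_bootstrap = config$classifier$n_bootstrap,
                         threshold = config$classifier$threshold,
                         seed = config$seeds$classify, read_ids = pairs$read_id)
    counts[[set_name]] <- data.frame(
      set = set_name, rank = RANKS,
      n_assigned = vapply(RANKS, function(r) sum(!is.na(cl[[r]])), numeric(1L)),
      row.names = NULL)
    tables[[set_name]] <- abundance_table(cl, "genus", method = "amplicon")
  }
  list(assigned_counts = do.call(rbind, counts), tables = tables,
       truth = truth_assignments(pairs, refset))
}

#' C2: influence of the number of reads (rarefaction)
#'
#' Simulates one amplicon sample, assigns its reads and runs the stepwise
#' rarefaction of taxon discovery.
#'
#' @param config configuration list.
#' @param scenario optional pre-built scenario.
#' @return list with `curve` (a `RarefactionCurve`) and `schedule`.
#' @export
run_c2_rarefaction <- function(config = default_run_config(), scenario = NULL) {
  if (is.null(scenario)) scenario <- build_scenario(config)
  pairs <- simulate_amplicon(scenario$refset, scenario$profile_a,
                             config$reads$n_pairs,
                             read_len = config$reads$read_len,
                             error_model = config$error_model,
                             seed = config$seeds$reads)
  asn <- assignments_for(pairs, scenario$refset, config)
  schedule <- default_schedule(min(config$rarefaction$max_depth, nrow(asn)),
                               config$rarefaction$n_reps)
  list(curve = rarefy(asn, schedule, config$seeds$rarefy), schedule = schedule)
}

#' C3: merged pairs versus concordance of independent mates
#'
#' Classifies (i) overlap-merged amplicon pairs and (ii) the two mates
#' independently followed by a concordance merge, then reports the per-rank
#' agreement between the two routes. Pairs that fail the overlap merge fall
#' back to the concordance route only.
#'
#' @param config configuration list.
#' @param scenario optional pre-built scenario.
#' @return list with `agreement` (per-rank data.frame), `n_pairs`,
#'   `n_merged`.
#' @export
run_c3_merge_vs_separate <- function(config = default_run_config(),
                                     scenario = NULL) {
  if (is.null(scenario)) scenario <- build_scenario(config)
  refset <- scenario$refset
  pairs <- simulate_amplicon(refset, scenario$profile_a, config$c3$n_pairs,
                             read_len = config$reads$read_len,
                             error_model = config$error_model,
                             seed = config$seeds$reads)
  merged <- merge_pair_table(pairs, default_merge_params("amplicon"))
  model <- train_classifier(refset, config$classifier$w)
  cl_args <- list(model = model, n_bootstrap = config$classifier$n_bootstrap,
                  threshold = config$classifier$threshold)
  clF <- do.call(classify_reads, c(list(pairs$fwd_seq, read_ids = pairs$read_id,
                                        seed = config$seeds$classify), cl_args))
  clR <- do.call(classify_reads, c(list(pairs$rev_seq, read_ids = pairs$read_id,
                                        seed = config$seeds$classify + 1L), cl_args))
  conc <- concordance_merge_table(clF, clR)
  ok <- merged$merged
  clM <- do.call(classify_reads, c(list(merged$sequence[ok],
                                        read_ids = merged$read_id[ok],
                                        seed = config$seeds$classify + 2L), cl_args))
  agreement <- do.call(rbind, lapply(RANKS, function(r) {
    a <- clM[[r]]
    b <- conc[[r]][match(clM$read_id, conc$read_id)]
    both <- !is.na(a) & !is.na(b)
    data.frame(rank = r, n = sum(both),
               agree = if (sum(both) > 0) mean(a[both] == b[both]) else NA_real_)
  }))
  list(agreement = agreement, n_pairs = nrow(pairs), n_merged = sum(ok),
       merged_table = clM, concordance = conc)
}

#' C4/C5: comparison between sequencing strategies
#'
#' Simulates the three strategies from the same community, subsamples each
#' to a common depth, assigns reads, and emits log2-ratio tables at phylum
#' and genus rank for every method pair (C4). The C5 variant repeats the
#' amplicon versus shotgun RNA comparison on overlap-merged pairs at its
#' own subsample size. The shotgun strategies are simulated directly from
#' their 16S-derived read pools (the comparisons operate downstream of rRNA
#' read selection).
#'
#' @param config configuration list.
#' @param scenario optional pre-built scenario.
#' @param condition `"a"` or `"b"`.
#' @return list with `tables` (method -> rank -> `abundance_table`),
#'   `log2` (method-pair -> rank -> data.frame) and `c5` (amplicon vs RNA
#'   on merged pairs).
#' @export
run_c4_c5_method_comparison <- function(config = default_run_config(),
                                        scenario = NULL, condition = "a") {
  if (is.null(scenario)) scenario <- build_scenario(config)
  refset <- scenario$refset
  profile <- if (condition == "a") scenario$profile_a else scenario$profile_b
  n <- config$reads$n_pairs
  stop_if_not(config$c4$subsample <= n && config$c5$subsample <= n,
              "subsample size exceeds the simulated read count")
  sims <- list(
    amplicon = simulate_amplicon(refset, profile, n,
                                 read_len = config$reads$read_len,
                                 error_model = config$error_model,
                                 seed = config$seeds$reads),
    shotgun_dna = simulate_shotgun_dna(refset, profile, n,
                                       rrna_read_fraction = 1,
                                       read_len = config$reads$read_len,
                                       error_model = config$error_model,
                                       seed = config$seeds$reads + 1L),
    shotgun_rna = simulate_shotgun_rna(refset, profile, n,
                                       rrna_read_fraction = 1,
                                       read_len = config$reads$read_len,
                                       error_model = config$error_model,
                                       seed = config$seeds$reads + 2L))
  model <- NULL
  tables <- list()
  for (m in names(sims)) {
    sub <- subsample(sims[[m]], config$c4$subsample,
                     seed = config$seeds$subsample)
    asn <- assignments_for(sub, refset, config, model)
    tables[[m]] <- list(phylum = abundance_table(asn, "phylum", method = m),
                        genus = abundance_table(asn, "genus", method = m))
  }
  pairs_of <- list(c("amplicon", "shotgun_rna"), c("amplicon", "shotgun_dna"),
                   c("shotgun_rna", "shotgun_dna"))
  log2 <- list()
  for (p in pairs_of) {
    key <- paste(p, collapse = "_vs_")
    log2[[key]] <- list(
      phylum = log2_ratio_table(tables[[p[1]]]$phylum, tables[[p[2]]]$phylum),
      genus = log2_ratio_table(tables[[p[1]]]$genus, tables[[p[2]]]$genus))
  }
  # C5: merged paired-ends, amplicon vs shotgun RNA only
  c5 <- list()
  for (m in c("amplicon", "shotgun_rna")) {
    sub <- subsample(sims[[m]], config$c5$subsample,
                     seed = config$seeds$subsample + 1L)
    mp <- default_merge_params(if (m == "amplicon") "amplicon" else "shotgun")
    mg <- merge_pair_table(sub, mp)
    keep <- sub[mg$merged, , drop = FALSE]
    asn <- assignments_for(keep, refset, config, model, seed_shift = 1L)
    c5[[m]] <- list(phylum = abundance_table(asn, "phylum", method = m),
                    genus = abundance_table(asn, "genus", method = m),
                    n_merged = sum(mg$merged))
  }
  c5$log2 <- list(
    phylum = log2_ratio_table(c5$amplicon$phylum, c5$shotgun_rna$phylum),
    genus = log2_ratio_table(c5$amplicon$genus, c5$shotgun_rna$genus))
  list(tables = tables, log2 = log2, c5 = c5)
}

#' Write a run manifest
#'
#' Records the configuration, package version and timestamp next to the
#' outputs of a pipeline run, so a run can be regenerated from its
#' manifest.
#'
#' @param config configuration list.
#' @param out_dir output directory.
#' @return manifest path, invisibly.
#' @export
write_manifest <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(out_dir, "manifest.yml")
  yaml::write_yaml(list(package = "rrnabias",
                        version = as.character(utils::packageVersion("rrnabias")),
                        config = config), path)
  invisible(path)
}
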
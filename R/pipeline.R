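#' Default pipeline configuration
#'
#' A complete, serializable configuration for [run_pipeline()] describing
#' the default synthetic ZW/ZZ scenario and every stage parameter. All
#' randomness derives from `seed` via a documented counter scheme
#' (stage i uses `(seed + 7919*i) mod (2^31-1)`), so stages can be re-run
#' independently and identical configs give identical outputs.
#'
#' The default planted scenario: five families spanning roughly 0.5-2.5%
#' of the genome each — three autosomal, one Z-linked (half the female
#' dose), one W-linked (female-only) — in 400 kb of background per sex,
#' sequenced at 8000 read pairs per library (2 x 250 bp).
#'
#' @param seed Master seed.
#' @return A nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1L) {
  cfg <- list(
    version = "1.0",
    seed = as.integer(seed),
    simulate = list(
      background_length_per_sex = 400000L,
      n_read_pairs = 8000L,
      read_length = 250L,
      insert_mean = 500L, insert_sd = 25L,
      per_base_error_rate = 0.001,
      families = list(
        list(family_id = "famA", monomer_length = 60L,
             copies_female = 180L, copies_male = 180L, n_arrays = 3L,
             per_copy_substitution_rate = 0.02, linkage = "autosomal"),
        list(family_id = "famZ", monomer_length = 50L,
             copies_female = 40L, copies_male = 80L, n_arrays = 2L,
             per_copy_substitution_rate = 0.02, linkage = "Z"),
        list(family_id = "famB", monomer_length = 80L,
             copies_female = 45L, copies_male = 45L, n_arrays = 2L,
             per_copy_substitution_rate = 0.03, linkage = "autosomal"),
        list(family_id = "famC", monomer_length = 45L,
             copies_female = 45L, copies_male = 45L, n_arrays = 1L,
             per_copy_substitution_rate = 0.02, linkage = "autosomal"),
        list(family_id = "famW", monomer_length = 70L,
             copies_female = 60L, copies_male = 0L, n_arrays = 2L,
             per_copy_substitution_rate = 0.02, linkage = "W"))),
    discovery = list(round0_n = 2000L, max_rounds = 8L, k = 13L,
                     min_kmer_share = 0.2, min_cluster_size = 5L,
                     min_match_fraction = 0.7, mask_identity = 0.8),
    catalog = list(prefix = "X", pad = 3L,
                   thresholds = list(variant = 0.95, family = 0.80,
                                     superfamily = 0.40)),
    quantify = list(n = "min", min_identity = 0.7, min_len = 20L,
                    bin_width = 1, top_k = 31L),
    monomer_net = list(enabled = TRUE, drop_singletons = TRUE,
                       min_identity = 0.8),
    w_ratio_threshold = 3)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A `pipeline_config`.
#' @return `read_config` returns the config; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Materialize family_spec objects from config, drawing random monomers
# (mutually dissimilar, <70% circular identity) when none are given.
.config_family_specs <- function(sim_cfg, seed) {
  set.seed(stage_seed(seed, 11L))
  specs <- list()
  monomers <- character(0)
  for (f in sim_cfg$families) {
    mono <- f[["monomer"]]
    if (is.null(mono)) {
      repeat {
        mono <- random_dna(f$monomer_length)
        if (!length(monomers) ||
            max(vapply(monomers, function(m) circular_identity(mono, m),
                       numeric(1))) < 0.7) break
      }
    }
    monomers <- c(monomers, mono)
    specs[[length(specs) + 1L]] <- family_spec(
      family_id = f$family_id, monomer = mono,
      copies_female = f$copies_female, copies_male = f$copies_male,
      n_arrays = if (is.null(f$n_arrays)) 1L else f$n_arrays,
      per_copy_substitution_rate =
        if (is.null(f$per_copy_substitution_rate)) 0
        else f$per_copy_substitution_rate,
      indel_rate = if (is.null(f$indel_rate)) 0 else f$indel_rate,
      linkage = f$linkage)
  }
  specs
}

#' Run the full satellitome pipeline on a configuration
#'
#' Orchestrates simulate -> discover -> catalog -> quantify ->
#' monomer-net -> report. Every stage draws its seed from the master seed,
#' so identical configs produce identical outputs (and identical
#' manifests). When `out_dir` is given, the stage outputs are written
#' there (catalog FASTA, hierarchy/abundance/landscape/candidate TSVs,
#' MST GraphML/DOT, truth TSV, run manifest JSON).
#'
#' @param config A `pipeline_config` (see [default_config()]).
#' @param out_dir Optional output directory.
#' @return A result bundle: `genome`, `reads`, `calls`, `hierarchy`,
#'   `catalog`, `quant` (abundance table, hits, landscapes, candidates),
#'   `mst`, `truth_eval` (W-call precision/recall against planted truth),
#'   `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  seed <- config$seed
  # --- simulate -------------------------------------------------------
  specs <- .config_family_specs(config$simulate, seed)
  genome <- plant_satellites(specs,
                             config$simulate$background_length_per_sex,
                             seed = stage_seed(seed, 1L))
  cfg_reads <- read_sim_config(
    read_length = config$simulate$read_length,
    insert_mean = config$simulate$insert_mean,
    insert_sd = config$simulate$insert_sd,
    n_read_pairs = config$simulate$n_read_pairs,
    per_base_error_rate = config$simulate$per_base_error_rate,
    seed = stage_seed(seed, 2L))
  sim <- simulate_reads(genome, cfg_reads)
  # --- discover -------------------------------------------------------
  d <- config$discovery
  calls <- run_discovery_loop(sim$female, sim$male,
                              round0_n = d$round0_n,
                              max_rounds = d$max_rounds,
                              seed = stage_seed(seed, 3L),
                              min_kmer_share = d$min_kmer_share, k = d$k,
                              min_cluster_size = d$min_cluster_size,
                              min_match_fraction = d$min_match_fraction,
                              mask_identity = d$mask_identity)
  if (!nrow(calls)) stop("pipeline stage 'discover' found no satellites")
  # --- catalog --------------------------------------------------------
  thr <- unlist(config$catalog$thresholds)
  hier <- group_hierarchy(setNames(calls$monomer,
                                   sprintf("var%03d", seq_len(nrow(calls)))),
                          thresholds = thr)
  # --- quantify -------------------------------------------------------
  q <- config$quantify
  eq <- subsample_equal(sim$female, sim$male, n = q$n,
                        seed = stage_seed(seed, 4L))
  variant_cat <- setNames(hier$consensus, hier$variant_id)
  fam_of_variant <- sprintf("fg%02d", hier$family_group)
  hf <- align_to_catalog(eq$female, variant_cat, families = fam_of_variant,
                         min_identity = q$min_identity, min_len = q$min_len)
  hm <- align_to_catalog(eq$male, variant_cat, families = fam_of_variant,
                         min_identity = q$min_identity, min_len = q$min_len)
  hfv <- hf; hfv$family_id <- hfv$variant_id
  hmv <- hm; hmv$family_id <- hmv$variant_id
  ab_var_f <- abundance(hfv, eq$female, hier$variant_id)
  ab_var_m <- abundance(hmv, eq$male, hier$variant_id)
  cat_named <- build_catalog(hier, ab_var_f, ab_var_m,
                             prefix = config$catalog$prefix,
                             pad = config$catalog$pad)
  # rename family-group hits to catalog names
  fg_name <- setNames(cat_named$families$family_id,
                      sprintf("fg%02d", cat_named$families$family_group))
  hf$family_id <- unname(fg_name[hf$family_id])
  hm$family_id <- unname(fg_name[hm$family_id])
  fams <- setNames(cat_named$families$consensus,
                   cat_named$families$family_id)
  ab_f <- abundance(hf, eq$female, names(fams))
  ab_m <- abundance(hm, eq$male, names(fams))
  tab <- data.frame(
    family_id = names(fams),
    consensus = unname(fams),
    rul = cat_named$families$rul,
    at_content = cat_named$families$at_content,
    n_variants = cat_named$families$n_variants,
    abundance_female = unname(ab_f), abundance_male = unname(ab_m),
    divergence_female = vapply(names(fams), function(f)
      family_divergence(hf[hf$family_id == f, , drop = FALSE]), numeric(1)),
    divergence_male = vapply(names(fams), function(f)
      family_divergence(hm[hm$family_id == f, , drop = FALSE]), numeric(1)),
    fm_ratio = fm_ratio(unname(ab_f), unname(ab_m)),
    stringsAsFactors = FALSE)
  candidates <- rank_candidates(tab, min(q$top_k, nrow(tab)))
  land_f <- build_landscape(hf, eq$female, bin_width = q$bin_width)
  land_m <- build_landscape(hm, eq$male, bin_width = q$bin_width)
  land_sub <- subtract_landscapes(land_f, land_m)
  # --- monomer net for the top-ranked candidate -----------------------
  mst <- NULL
  if (isTRUE(config$monomer_net$enabled) && nrow(candidates)) {
    top_fam <- candidates$family_id[1L]
    cons <- fams[[top_fam]]
    pool <- join_reads(eq$female, eq$male)
    mono <- tryCatch(
      harvest_monomers(pool, cons,
                       min_identity = config$monomer_net$min_identity),
      error = function(e) NULL)
    if (!is.null(mono) && nrow(mono)) {
      haps <- collapse_haplotypes(
        mono, drop_singletons = isTRUE(config$monomer_net$drop_singletons))
      if (nrow(haps)) mst <- build_mst(haps)
    }
  }
  # --- truth-aware report --------------------------------------------
  truth_eval <- .score_w_calls(tab, genome, config$w_ratio_threshold)
  bundle <- list(config = config, genome = genome, reads = sim,
                 calls = calls, hierarchy = hier, catalog = cat_named,
                 quant = list(table = tab, candidates = candidates,
                              hits_female = hf, hits_male = hm,
                              landscape_female = land_f,
                              landscape_male = land_m,
                              landscape_subtractive = land_sub),
                 mst = mst, truth_eval = truth_eval)
  if (!is.null(out_dir)) bundle$manifest <- .write_bundle(bundle, out_dir)
  bundle
}

# Map discovered families to planted truth by circular identity and score
# W-linkage calls (ratio above threshold or absent-in-male = W call).
.score_w_calls <- function(tab, genome, threshold, match_identity = 0.8) {
  truth <- genome$truth
  planted <- genome$monomers
  match_fam <- vapply(seq_len(nrow(tab)), function(i) {
    ids <- vapply(planted, circular_identity, numeric(1),
                  a = tab$consensus[i])
    if (max(ids) >= match_identity) names(planted)[which.max(ids)]
    else NA_character_
  }, character(1))
  called_w <- tab$fm_ratio > threshold # Inf > threshold is TRUE
  truth_w <- truth$family_id[truth$linkage == "W"]
  matched_w <- match_fam[called_w]
  tp <- length(intersect(matched_w[!is.na(matched_w)], truth_w))
  precision <- if (any(called_w)) tp / sum(called_w) else NA_real_
  recall <- if (length(truth_w)) {
    length(intersect(truth_w, matched_w)) / length(truth_w)
  } else NA_real_
  list(matched_family = match_fam, called_w = called_w,
       precision = precision, recall = recall)
}

.write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  wt <- function(d, f) {
    write.table(d, p(f), sep = "\t", row.names = FALSE, quote = FALSE)
    p(f)
  }
  files <- character(0)
  files <- c(files, wt(bundle$genome$truth, "truth.tsv"))
  write_catalog_fasta(bundle$catalog, p("catalog.fasta"))
  files <- c(files, p("catalog.fasta"))
  hier_out <- bundle$catalog$variants[, c("variant_id", "family_id",
                                          "sf_group", "rul", "at_content")]
  files <- c(files, wt(hier_out, "hierarchy.tsv"))
  files <- c(files, wt(bundle$quant$table, "abundance.tsv"))
  files <- c(files, wt(bundle$quant$candidates, "candidates.tsv"))
  files <- c(files, wt(bundle$quant$landscape_female, "landscape_female.tsv"))
  files <- c(files, wt(bundle$quant$landscape_male, "landscape_male.tsv"))
  files <- c(files, wt(bundle$quant$landscape_subtractive,
                       "landscape_subtractive.tsv"))
  if (!is.null(bundle$mst)) {
    export_graph(bundle$mst, p("mst.graphml"), p("mst.dot"))
    files <- c(files, p("mst.graphml"), p("mst.dot"))
  }
  manifest <- list(
    version = bundle$config$version,
    seed = bundle$config$seed,
    parameters = unclass(bundle$config),
    n_discovered = nrow(bundle$calls),
    w_precision = bundle$truth_eval$precision,
    w_recall = bundle$truth_eval$recall,
    checksums = as.list(tools::md5sum(files)))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  manifest
}
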
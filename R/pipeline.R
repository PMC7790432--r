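# End-to-end orchestration: simulate/ingest -> sample filter -> global
# threshold -> trophic annotation -> relative abundance -> peak screening ->
# environmentally constrained ordination, with a machine-readable summary,
# per-stage TSV outputs and a digest MANIFEST.

#' Pipeline run configuration
#'
#' Bundles every stage's tunables with their survey-convention defaults:
#' samples need 10,000 reads; OTUs need 0.001% (1e-5) of the unfiltered
#' grand total; peaks must reach 10% of a series' maximum; blooms need 10%
#' relative abundance; parasitoid peaks may lag host peaks by up to 14 days;
#' simultaneity means lag 0; constraint entry needs `p < 0.05`.
#'
#' @param scenario a [scenario_config()] to simulate, or `NULL` to read
#'   tables from `otu_path`/`taxonomy_path`/`lookup_path`/`env_path`.
#' @param otu_path,taxonomy_path,lookup_path,env_path input files (used when
#'   `scenario` is `NULL`).
#' @param pairs optional candidate pair `data.frame` (`host_id`,
#'   `parasitoid_id`); default: parasitoid-labelled OTUs crossed with the
#'   `n_host_candidates` most abundant non-parasitoid OTUs.
#' @param min_sample_reads sample retention threshold (reads).
#' @param threshold_fraction global OTU threshold fraction of total reads.
#' @param min_fraction_of_max peak rule threshold.
#' @param bloom_abs_threshold absolute-abundance bloom threshold.
#' @param max_lag_days peak-matching window (days).
#' @param case2_tolerance_days lag still counted as simultaneous.
#' @param alpha,n_perm ordination forward-selection settings.
#' @param n_host_candidates hosts screened when `pairs` is `NULL`.
#' @param run_ordination logical; skip the ordination stage if `FALSE`.
#' @param seed integer master seed.
#' @param out_dir output directory (created if needed).
#' @return list of class `run_config`.
#' @export
run_config <- function(scenario = NULL, otu_path = NULL, taxonomy_path = NULL,
                       lookup_path = NULL, env_path = NULL, pairs = NULL,
                       min_sample_reads = 10000, threshold_fraction = 1e-5,
                       min_fraction_of_max = 0.10, bloom_abs_threshold = 0.10,
                       max_lag_days = 14, case2_tolerance_days = 0,
                       alpha = 0.05, n_perm = 199, n_host_candidates = 10,
                       run_ordination = TRUE, seed = 1,
                       out_dir = tempfile("parascreen_run_")) {
  for (p in c(threshold_fraction, min_fraction_of_max, bloom_abs_threshold))
    if (p < 0 || p > 1) stop_validation("proportions must lie in [0, 1]")
  if (is.null(scenario) && is.null(otu_path))
    stop_validation("need either a scenario or input table paths")
  structure(as.list(environment()), class = "run_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_validation("pipeline stage '", name, "' failed: ", conditionMessage(e))
  })
}

write_manifest <- function(out_dir, status = "complete", failed_stage = NULL) {
  files <- setdiff(list.files(out_dir), "MANIFEST.tsv")
  md5 <- if (length(files)) unname(tools::md5sum(file.path(out_dir, files)))
         else character()
  mf <- data.frame(file = files, md5 = md5, stringsAsFactors = FALSE)
  header <- c(paste0("# status: ", status),
              if (!is.null(failed_stage)) paste0("# failed_stage: ", failed_stage))
  con <- file.path(out_dir, "MANIFEST.tsv")
  writeLines(c(header, "file\tmd5",
               if (nrow(mf)) paste(mf$file, mf$md5, sep = "\t")), con)
  invisible(con)
}

#' Run the full screening pipeline
#'
#' Executes simulate/ingest, sample filtering, the global OTU threshold
#' (referred to the unfiltered grand total), trophic annotation, relative
#' abundance, peak/bloom screening of candidate host-parasitoid pairs and
#' (optionally) forward-selected constrained ordination. Writes per-stage
#' TSVs, a JSON summary (no timestamps, so reruns with the same config and
#' seed are byte-identical) and a MANIFEST of content digests; on a stage
#' failure the partial outputs are retained and the MANIFEST marks the run
#' incomplete and names the stage.
#'
#' @param config a [run_config()].
#' @return the summary (list), invisibly; also written as `summary.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  summary <- list(seed = config$seed)
  on_fail <- function(stage, e) {
    write_manifest(config$out_dir, status = "incomplete", failed_stage = stage)
    stop(e)
  }
  stage <- "ingest"
  tryCatch({
    if (!is.null(config$scenario)) {
      sc <- simulate_scenario(config$scenario)
      tab <- sc$table; taxonomy <- sc$taxonomy
      lookup <- sc$lookup; env <- sc$env
      summary$scenario_seed <- config$scenario$seed
    } else {
      tab <- read_otu_table(config$otu_path)
      taxonomy <- read_taxonomy(config$taxonomy_path)
      lookup <- read_trophic_lookup(config$lookup_path)
      env <- if (!is.null(config$env_path)) read_env_table(config$env_path)
             else NULL
    }
    summary$n_samples_input <- ncol(tab$counts)
    summary$n_otus_input <- nrow(tab$counts)
    summary$total_reads_input <- otu_grand_total(tab)

    stage <- "sample_filter"
    grand_total_unfiltered <- otu_grand_total(tab)
    tab_f <- filter_samples_min_reads(tab, config$min_sample_reads)
    summary$n_samples_retained <- ncol(tab_f$counts)

    stage <- "global_threshold"
    tab_t <- apply_global_threshold(tab_f, config$threshold_fraction,
                                    total_reads = grand_total_unfiltered)
    summary$global_min_count <- global_threshold_min_count(
      grand_total_unfiltered, config$threshold_fraction)
    summary$n_otus_retained <- nrow(tab_t$counts)
    write_otu_table(tab_t, file.path(config$out_dir, "otu_table_filtered.tsv"))

    stage <- "annotate"
    ann <- annotate_trophic(taxonomy, lookup)
    ann_f <- ann[ann$otu_id %in% otu_ids(tab_t), , drop = FALSE]
    summ_ann <- annotation_summary(ann_f$label)
    summary$annotation <- unclass(summ_ann)
    utils::write.table(ann, file.path(config$out_dir, "trophic_annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "relative_abundance"
    par_ids <- ann_f$otu_id[ann_f$label == "parasitoid"]
    par_ids <- intersect(par_ids, otu_ids(tab_t))
    host_ids <- if (!is.null(config$pairs)) unique(config$pairs$host_id)
    else {
      nonpar <- setdiff(otu_ids(tab_t), par_ids)
      tot <- rowSums(tab_t$counts[nonpar, , drop = FALSE])
      utils::head(nonpar[order(-tot)], config$n_host_candidates)
    }
    series <- relative_abundance(tab_t, subjects = union(host_ids, par_ids))
    summary$n_parasitoid_otus_screened <- length(par_ids)
    summary$n_host_candidates_screened <- length(host_ids)

    stage <- "pair_screening"
    pair_table <- screen_pairs(series[host_ids], series[par_ids],
                               pairs = config$pairs,
                               min_fraction_of_max = config$min_fraction_of_max,
                               max_lag_days = config$max_lag_days,
                               case2_tolerance_days = config$case2_tolerance_days)
    out_pairs <- pair_table
    attr(out_pairs, "classifications") <- NULL
    utils::write.table(out_pairs,
                       file.path(config$out_dir, "pair_classifications.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$pairs <- out_pairs

    stage <- "ordination"
    if (isTRUE(config$run_ordination) && !is.null(env)) {
      env_use <- env[match(tab_t$sample_dates, env$date), , drop = FALSE]
      par_ra <- colSums(tab_t$counts[par_ids, , drop = FALSE]) /
        pmax(colSums(tab_t$counts), 1)
      cand <- data.frame(
        temperature = env_use$temperature, salinity = env_use$salinity,
        secchi_depth = env_use$secchi_depth,
        tide = factor(env_use$tide, levels = c("low", "high")),
        sunshine = env_use$sunshine, silicate = env_use$silicate,
        phosphate = env_use$phosphate, nitrate = env_use$nitrate,
        season = assign_season(tab_t$sample_dates),
        parasitoid_ra = par_ra)
      comm <- t(tab_t$counts)
      comm <- sweep(comm, 1, pmax(rowSums(comm), 1), "/")   # relative abundances
      sel <- forward_select(comm, cand, alpha = config$alpha,
                            n_perm = config$n_perm, seed = config$seed)
      summary$ordination <- list(
        n_samples_used = sel$n_samples_used,
        n_samples_dropped = sel$n_samples_dropped,
        selected = sel$selected,
        trace = sel$trace)
      if (!is.null(sel$model)) {
        summary$ordination$total_inertia <- sel$model$total_inertia
        summary$ordination$constrained_inertia <- sel$model$constrained_inertia
        summary$ordination$pct_constrained <- round_half_away(
          100 * sel$model$constrained_inertia / sel$model$total_inertia, 1)
        utils::write.table(
          data.frame(sample = rownames(sel$model$site_scores),
                     sel$model$site_scores, check.names = FALSE),
          file.path(config$out_dir, "site_scores.tsv"),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
      utils::write.table(sel$trace,
                         file.path(config$out_dir, "selection_trace.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "report"
    jsonlite::write_json(summary,
                         file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "columns", null = "null")
    write_manifest(config$out_dir, status = "complete")
    invisible(summary)
  }, error = function(e) on_fail(stage, e))
}
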
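#' @title End-to-end pipeline: ingest -> preprocess -> differential ->
#'   classification -> sets -> clustering
#'
#' @description
#' Runs all analysis stages in a fixed order from a single configuration and
#' returns a machine-readable run report whose counts are consistent with
#' the emitted tables. Re-running with an identical configuration (including
#' the seed) reproduces identical outputs.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' All stage parameters at the analysis defaults: identification at >= 2
#' unique peptides, at most 6 missing of 18 samples, kNN imputation with
#' k = 10, quantile normalization, contrasts 5/10/15 min versus resting,
#' FDR 0.05 with |log2FC| >= 1.5, raft enrichment 1.5 / response 1.0,
#' detection at >= 1 replicate, cluster count chosen by silhouette.
#'
#' @param seed RNG seed used by simulation (if any) and clustering.
#' @param simulate either `NULL` or a [simulation_params()] list; when set,
#'   the input table and design are simulated instead of read.
#' @param protein_groups,design_file input paths (ignored when `simulate`
#'   is set).
#' @param out_dir output directory, or `NULL` for no file output.
#' @param run_clustering whether to run the clustering stage (default TRUE;
#'   skipped automatically when fewer than 10 proteins are significant).
#' @param min_unique_peptides,max_missing,knn_k,normalization stage
#'   parameters of the ingest and preprocessing steps.
#' @param alpha,fc_threshold,enrich_threshold,response_threshold,min_replicates
#'   stage parameters of the differential, classification and detection steps.
#' @param k cluster count, or `"auto"` to select by silhouette over `k_range`.
#' @param k_range candidate cluster counts for `k = "auto"`.
#' @return a `raft_config` list.
#' @export
raft_config <- function(seed = 1L,
                        simulate = NULL,
                        protein_groups = NULL, design_file = NULL,
                        out_dir = NULL,
                        min_unique_peptides = 2L,
                        max_missing = 6L,
                        knn_k = 10L,
                        normalization = "quantile",
                        alpha = 0.05, fc_threshold = 1.5,
                        enrich_threshold = 1.5, response_threshold = 1.0,
                        min_replicates = 1L,
                        run_clustering = TRUE,
                        k = "auto", k_range = 2:30) {
  if (is.null(simulate) && (is.null(protein_groups) || is.null(design_file))) {
    stop("config needs either a simulate block or input file paths")
  }
  structure(as.list(environment()), class = "raft_config")
}

#' Run the full analysis pipeline
#'
#' Stage order is fixed: ingest (read or simulate), identification filter,
#' detection-presence sets (on the raw filtered table), preprocessing
#' (log2 -> missingness filter -> kNN imputation -> quantile normalization),
#' moderated-t differential enrichment, significance calling, raft-resident
#' classification, and (optionally) temporal k-means clustering of the
#' significant union. When `config$out_dir` is set, every stage's table is
#' written as TSV and the report as JSON.
#'
#' @param config a [raft_config()].
#' @return list with the stage outputs (`table`, `identified`, `matrix`,
#'   `differential`, `significant`, `classification`, `presence`, `sets`,
#'   `clustering`, `truth` when simulated) and `report`, a list of per-stage
#'   counts and the parameter echo.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "raft_config"))
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim <- simulate_experiment(config$simulate)
    table <- sim$table
    design <- sim$design
    truth <- sim$truth
  } else {
    design <- read_design(config$design_file)
    table <- read_protein_groups(config$protein_groups, design)
  }

  identified <- filter_identified(table, config$min_unique_peptides)

  presence <- detect_condition_presence(identified, design,
                                        config$min_replicates)
  sets <- exclusive_sets(presence)

  m <- preprocess(identified, max_missing = config$max_missing,
                  knn_k = config$knn_k,
                  normalization = config$normalization)

  diff_rows <- moderated_t(m, design, contrasts = default_contrasts(),
                           alpha = config$alpha,
                           fc_threshold = config$fc_threshold)
  sig <- call_significant(diff_rows)

  classification <- classify_raft_resident(
    m, design,
    enrich_threshold = config$enrich_threshold,
    response_threshold = config$response_threshold)

  clustering <- NULL
  if (isTRUE(config$run_clustering) && length(sig$union) >= 10) {
    fc <- fc_profile_matrix(diff_rows, sig$union)
    if (identical(config$k, "auto")) {
      sel <- select_k(fc, k_range = config$k_range, seed = config$seed)
      k_use <- sel$k_star
      validity <- sel$validity
    } else {
      k_use <- as.integer(config$k)
      validity <- NULL
    }
    clustering <- list(result = kmeans_profiles(fc, k_use,
                                                seed = config$seed),
                       k = k_use, validity = validity)
  }

  report <- list(
    parameters = config[setdiff(names(config), c("simulate"))],
    seed = config$seed,
    version = as.character(utils::packageVersion("raftquant")),
    counts = list(
      input_rows = nrow(table),
      identified = nrow(identified),
      post_missingness = nrow(m$values),
      significant_per_contrast =
        as.list(sig$counts[setdiff(names(sig$counts),
                                   c("union", "intersection"))]),
      significant_union = length(sig$union),
      significant_intersection = length(sig$intersection),
      raft_resident = sum(classification$label == "raft_resident"),
      stimulation_responsive =
        sum(classification$label == "stimulation_responsive"),
      common_to_all = length(sets$sets$common_to_all),
      resting_only = length(sets$sets$resting_only),
      activated_only = length(sets$sets$activated_only),
      all_activation_not_controls =
        length(sets$sets$all_activation_not_controls),
      chosen_k = if (is.null(clustering)) NA_integer_ else clustering$k
    )
  )

  out <- list(table = table, identified = identified, matrix = m,
              design = design, differential = diff_rows, significant = sig,
              classification = classification, presence = presence,
              sets = sets, clustering = clustering, truth = truth,
              report = report)

  if (!is.null(config$out_dir)) .write_pipeline_outputs(out, config$out_dir)
  out
}

.write_pipeline_outputs <- function(out, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_protein_groups(out$identified, file.path(dir, "identified.tsv"))
  vals <- data.frame(protein_id = rownames(out$matrix$values),
                     out$matrix$values, check.names = FALSE)
  tsv(vals, "normalized_log2_matrix.tsv")
  prov <- data.frame(protein_id = rownames(out$matrix$values),
                     ifelse(out$matrix$imputed, "imputed", "observed"),
                     check.names = FALSE)
  names(prov)[-1] <- colnames(out$matrix$values)
  tsv(prov, "provenance_mask.tsv")
  tsv(out$differential, "differential.tsv")
  tsv(out$classification, "raft_classification.tsv")
  pres <- data.frame(protein_id = rownames(out$presence),
                     out$presence * 1L, check.names = FALSE)
  tsv(pres, "presence_matrix.tsv")
  tsv(out$sets$patterns, "presence_patterns.tsv")
  if (!is.null(out$clustering)) {
    tsv(data.frame(protein_id = names(out$clustering$result$cluster),
                   cluster = out$clustering$result$cluster),
        "cluster_assignments.tsv")
    tsv(data.frame(cluster = seq_len(out$clustering$k),
                   out$clustering$result$centroids, check.names = FALSE),
        "cluster_centroids.tsv")
    if (!is.null(out$clustering$validity)) {
      tsv(out$clustering$validity, "cluster_validity.tsv")
    }
  }
  jsonlite::write_json(out$report, file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       na = "null")
  invisible(dir)
}

#' Score pipeline recovery against planted ground truth
#'
#' For a simulated run: the fraction of planted responders recovered in the
#' significant union, the observed false discovery rate of the union (calls
#' whose planted class is not a responder), and sensitivity/precision of the
#' raft-resident classification.
#'
#' @param result output of [run_pipeline()] on a simulated configuration.
#' @return list with `responder_recovery`, `observed_fdr`,
#'   `raft_sensitivity`, `raft_precision`, plus the underlying counts.
#' @export
score_recovery <- function(result) {
  truth <- result$truth
  if (is.null(truth)) stop("recovery scoring needs a simulated run")
  responders <- truth$protein_id[grepl("^responder_", truth$class)]
  called <- result$significant$union
  tp <- length(intersect(called, responders))
  recovery <- if (length(responders)) tp / length(responders) else NA_real_
  fdr <- if (length(called)) 1 - tp / length(called) else 0

  rafts <- truth$protein_id[truth$class == "raft_resident"]
  called_raft <- result$classification$protein_id[
    result$classification$label == "raft_resident"]
  tp_raft <- length(intersect(called_raft, rafts))
  sens <- if (length(rafts)) tp_raft / length(rafts) else NA_real_
  prec <- if (length(called_raft)) tp_raft / length(called_raft) else NA_real_

  list(responder_recovery = recovery, observed_fdr = fdr,
       raft_sensitivity = sens, raft_precision = prec,
       n_responders = length(responders), n_called = length(called),
       n_rafts = length(rafts), n_called_raft = length(called_raft))
}
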
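#' @title Raft-resident classification, ranking and detection-set algebra
#'
#' @description
#' Proteins constitutively at the closest vicinity of the raft-targeted
#' peroxidase are already biotinylated at basal enzyme activity (the no-H2O2
#' control) and label very efficiently once H2O2 is added. The classifier
#' encodes that reading: step 1 keeps proteins enriched at least
#' `enrich_threshold` log2 units in resting biotinylated cells over the
#' no-H2O2 control; step 2 removes those that respond to IgM stimulation by
#' at least `response_threshold` log2 units at any time point. Survivors are
#' `raft_resident`, the step-2 removals `stimulation_responsive`, the rest
#' `other`.
#'
#' Detection-based set algebra (which proteins are seen in which condition)
#' is computed on the raw, pre-imputation table only.
#'
#' @name classify_sets
NULL

#' Classify raft-resident versus stimulation-responsive proteins
#'
#' @param m a complete [intensity_matrix()] (the imputed, normalized matrix
#'   used for differential analysis).
#' @param design an [experiment_design()]; must contain `CTRL_NO_H2O2`,
#'   `ACT_0` and at least one activation time point.
#' @param enrich_threshold minimum baseline log2 fold change (resting
#'   biotinylated vs no-H2O2 control) for step 1; inclusive (default 1.5).
#' @param response_threshold log2-fold-change magnitude (activation vs
#'   resting) above which a protein counts as stimulation-responsive;
#'   inclusive (default 1.0).
#' @param response_rule `"absolute"` (default): responders by `|FC| >=
#'   response_threshold` in either direction; `"signed"`: positive responses
#'   only.
#' @param activation_conditions the post-resting time points to screen
#'   (default every `ACT_*` condition in the design except `ACT_0`).
#' @return a `data.frame` with `protein_id`, `label` (one of `raft_resident`,
#'   `stimulation_responsive`, `other`; the labels partition the proteins),
#'   `baseline_fc`, `max_response_fc` (largest-magnitude activation-vs-resting
#'   fold change, sign kept).
#' @export
classify_raft_resident <- function(m, design, enrich_threshold = 1.5,
                                   response_threshold = 1.0,
                                   response_rule = c("absolute", "signed"),
                                   activation_conditions = NULL) {
  response_rule <- match.arg(response_rule)
  for (cc in c("CTRL_NO_H2O2", "ACT_0")) {
    if (!cc %in% design$condition) {
      stop("design lacks required condition ", cc)
    }
  }
  if (is.null(activation_conditions)) {
    activation_conditions <- intersect(ACTIVATION_CONDITIONS, design$condition)
    activation_conditions <- setdiff(activation_conditions, "ACT_0")
  }
  if (length(activation_conditions) == 0) {
    stop("design lacks an activation time point beyond ACT_0")
  }
  baseline_fc <- group_log2fc(m, design, contrast("ACT_0", "CTRL_NO_H2O2"))
  resp <- sapply(activation_conditions, function(cc) {
    group_log2fc(m, design, contrast(cc, "ACT_0"))
  })
  resp <- matrix(resp, nrow = nrow(m$values),
                 dimnames = list(rownames(m$values), activation_conditions))
  # largest-magnitude response, sign preserved
  idx_max <- max.col(abs(resp), ties.method = "first")
  max_response_fc <- resp[cbind(seq_len(nrow(resp)), idx_max)]
  responded <- if (response_rule == "absolute") {
    abs(max_response_fc) >= response_threshold
  } else {
    apply(resp >= response_threshold, 1, any)
  }
  enriched <- baseline_fc >= enrich_threshold
  label <- ifelse(enriched & !responded, "raft_resident",
                  ifelse(enriched & responded, "stimulation_responsive",
                         "other"))
  data.frame(protein_id = rownames(m$values), label = label,
             baseline_fc = baseline_fc, max_response_fc = max_response_fc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Rank proteins by baseline intensity difference
#'
#' Mean intensity in resting biotinylated cells minus mean in the no-H2O2
#' control, sorted non-increasing; exposes the proteins most efficiently
#' labeled upon triggering of biotinylation. Ties keep input order.
#'
#' @param m an [intensity_matrix()] (any stage; means skip missing values).
#' @param design an [experiment_design()].
#' @param top_n number of proteins to return (default 10).
#' @param numerator,denominator condition pair (defaults `ACT_0` vs
#'   `CTRL_NO_H2O2`).
#' @return `data.frame` with `protein_id`, `difference`, sorted descending.
#' @export
rank_by_baseline_difference <- function(m, design, top_n = 10L,
                                        numerator = "ACT_0",
                                        denominator = "CTRL_NO_H2O2") {
  num <- condition_samples(design, numerator)
  den <- condition_samples(design, denominator)
  x <- m$values
  diff <- rowMeans(x[, num, drop = FALSE], na.rm = TRUE) -
    rowMeans(x[, den, drop = FALSE], na.rm = TRUE)
  ord <- order(-diff)
  out <- data.frame(protein_id = rownames(x)[ord], difference = diff[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  utils::head(out, top_n)
}

#' Detection presence of each protein in each condition
#'
#' A protein is present in a condition iff its raw intensity is nonzero in at
#' least `min_replicates` replicates of that condition. Computed on the raw,
#' pre-imputation table.
#'
#' @param table a [protein_quant_table()].
#' @param design an [experiment_design()].
#' @param min_replicates detection threshold (default 1).
#' @return logical matrix proteins x conditions with attribute
#'   `min_replicates`.
#' @export
detect_condition_presence <- function(table, design, min_replicates = 1L) {
  x <- table_intensities(table)
  conditions <- unique(design$condition)
  pm <- vapply(conditions, function(cc) {
    s <- condition_samples(design, cc)
    rowSums(x[, s, drop = FALSE] > 0) >= min_replicates
  }, logical(nrow(x)))
  pm <- matrix(pm, nrow = nrow(x), ncol = length(conditions),
               dimnames = list(rownames(x), conditions))
  attr(pm, "min_replicates") <- min_replicates
  pm
}

#' Condition-exclusive protein sets (upset-style)
#'
#' Enumerates all presence patterns over the conditions and reports the
#' preset sets of interest:
#' \itemize{
#'   \item `common_to_all`: present in every condition;
#'   \item `resting_only`: present at `ACT_0`, absent from every activation
#'     time point;
#'   \item `activated_only`: present in at least one activation time point,
#'     absent from `ACT_0` and from all controls;
#'   \item `all_activation_not_controls`: present in every activation time
#'     point and absent from every non-activated condition (resting and
#'     controls).
#' }
#'
#' @param pm presence matrix from [detect_condition_presence()].
#' @param activation_conditions activation time points beyond resting
#'   (default the `ACT_*` columns except `ACT_0`).
#' @param control_conditions the non-biotinylated / control columns (default
#'   `CTRL_NO_H2O2`, `CTRL_NO_BP` where present).
#' @param resting_condition resting biotinylated condition (default `ACT_0`).
#' @return list with `patterns` (a `data.frame` of pattern bitmask strings and
#'   counts over all observed presence patterns) and `sets` (named list of
#'   protein-id vectors for the presets).
#' @export
exclusive_sets <- function(pm,
                           activation_conditions = NULL,
                           control_conditions = NULL,
                           resting_condition = "ACT_0") {
  conds <- colnames(pm)
  if (is.null(activation_conditions)) {
    activation_conditions <- setdiff(intersect(ACTIVATION_CONDITIONS, conds),
                                     resting_condition)
  }
  if (is.null(control_conditions)) {
    control_conditions <- intersect(c("CTRL_NO_H2O2", "CTRL_NO_BP"), conds)
  }
  unknown <- setdiff(c(activation_conditions, control_conditions,
                       resting_condition), conds)
  if (length(unknown)) {
    stop("unknown condition(s): ", paste(unknown, collapse = ", "))
  }
  ids <- rownames(pm)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(pm)))

  pattern <- apply(pm, 1, function(r) paste(as.integer(r), collapse = ""))
  observed <- rowSums(pm) > 0
  tab <- table(pattern[observed])
  patterns <- data.frame(pattern = names(tab), count = as.integer(tab),
                         stringsAsFactors = FALSE, row.names = NULL)

  act <- pm[, activation_conditions, drop = FALSE]
  ctl <- pm[, control_conditions, drop = FALSE]
  rest <- pm[, resting_condition]
  sets <- list(
    common_to_all = ids[rowSums(pm) == ncol(pm)],
    resting_only = ids[rest & rowSums(act) == 0],
    activated_only = ids[rowSums(act) > 0 & !rest & rowSums(ctl) == 0],
    all_activation_not_controls =
      ids[rowSums(act) == ncol(act) & !rest & rowSums(ctl) == 0]
  )
  list(patterns = patterns, sets = sets,
       condition_order = conds)
}

#' Overlap of a protein set with a reference list
#'
#' Reports the overlap count, the fraction of the query covered, and the
#' hypergeometric upper-tail probability `P(X >= n_overlap)` of drawing at
#' least that many reference proteins when sampling `|query|` proteins
#' without replacement from a universe containing `|reference|` reference
#' members.
#'
#' @param query_set,reference_set character vectors of protein identifiers
#'   (duplicates removed).
#' @param universe_size size of the identifier universe; must be at least
#'   `|query U reference|`.
#' @return list with `n_overlap`, `fraction_of_query`, `p_value`.
#' @export
overlap_with_reference <- function(query_set, reference_set, universe_size) {
  query_set <- unique(query_set)
  reference_set <- unique(reference_set)
  if (universe_size < length(union(query_set, reference_set))) {
    stop("universe_size smaller than |query U reference|")
  }
  n_overlap <- length(intersect(query_set, reference_set))
  frac <- if (length(query_set)) n_overlap / length(query_set) else NA_real_
  p <- stats::phyper(n_overlap - 1, m = length(reference_set),
                     n = universe_size - length(reference_set),
                     k = length(query_set), lower.tail = FALSE)
  list(n_overlap = n_overlap, fraction_of_query = frac, p_value = p)
}
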
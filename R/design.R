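#' Condition labels of the six-condition raft proximity-labeling layout
#'
#' Two biotinylation controls (no H2O2, no biotin-phenol) and four
#' anti-IgM activation time points (0, 5, 10, 15 min), each measured in
#' replicate.
#'
#' @export
RAFT_CONDITIONS <- c("CTRL_NO_H2O2", "CTRL_NO_BP",
                     "ACT_0", "ACT_5", "ACT_10", "ACT_15")

#' Activation conditions (the biotin-phenol + H2O2 samples)
#' @export
ACTIVATION_CONDITIONS <- c("ACT_0", "ACT_5", "ACT_10", "ACT_15")

#' Construct an experiment design table
#'
#' Maps sample identifiers to experimental conditions and replicate labels.
#' Arbitrary balanced layouts are accepted; the default is the 6-condition x
#' 3-replicate (18-sample) layout of the raft-APEX2 experiment.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param condition character vector of condition labels, one per sample.
#' @param replicate integer vector of replicate labels, unique within a
#'   condition.
#' @return A `data.frame` of class `experiment_design` with columns
#'   `sample_id`, `condition`, `replicate`.
#' @export
experiment_design <- function(sample_id, condition, replicate) {
  if (length(sample_id) != length(condition) ||
      length(sample_id) != length(replicate)) {
    stop("sample_id, condition and replicate must have equal length")
  }
  if (anyDuplicated(sample_id)) {
    stop("sample ids must be unique")
  }
  replicate <- as.integer(replicate)
  if (any(replicate < 1L)) stop("replicate labels must be positive integers")
  if (anyDuplicated(paste(condition, replicate))) {
    stop("replicate labels must be unique within a condition")
  }
  out <- data.frame(sample_id = as.character(sample_id),
                    condition = as.character(condition),
                    replicate = replicate,
                    stringsAsFactors = FALSE)
  class(out) <- c("experiment_design", "data.frame")
  out
}

#' Default 18-sample design (6 conditions x 3 replicates)
#'
#' @param n_replicates replicates per condition (default 3).
#' @return An [experiment_design()] with samples named
#'   `<condition>_R<replicate>`.
#' @export
default_design <- function(n_replicates = 3L) {
  cond <- rep(RAFT_CONDITIONS, each = n_replicates)
  repl <- rep(seq_len(n_replicates), times = length(RAFT_CONDITIONS))
  experiment_design(sample_id = paste0(cond, "_R", repl),
                    condition = cond, replicate = repl)
}

#' Sample ids belonging to a condition
#' @param design an [experiment_design()].
#' @param condition condition label.
#' @return character vector of sample ids.
#' @export
condition_samples <- function(design, condition) {
  if (!condition %in% design$condition) {
    stop("condition '", condition, "' not present in design")
  }
  design$sample_id[design$condition == condition]
}

#' Read / write a design table (tab-separated)
#'
#' @param path file path.
#' @return [read_design()] returns an [experiment_design()].
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("sample_id", "condition", "replicate")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stop("design file lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  experiment_design(d$sample_id, d$condition, d$replicate)
}

#' @rdname read_design
#' @param design an [experiment_design()].
#' @export
write_design <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
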
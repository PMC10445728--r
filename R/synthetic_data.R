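#' @title Synthetic proximity-proteomics experiments with planted truth
#'
#' @description
#' Generates proteinGroups-style tables with the statistical structure the
#' pipeline assumes: log-normal protein abundances (normal on the log2
#' scale), condition-specific log2 effects for planted protein classes,
#' replicate noise, and a dropout model combining intensity-dependent
#' detection (missing not at random: detection probability is logistic in
#' the log2 intensity) with a uniform missing-completely-at-random rate.
#' Condition-exclusive classes are produced by shifting their means below
#' the detection midpoint, so absence emerges from the dropout model rather
#' than being hard-coded.
#'
#' Planted classes:
#' \itemize{
#'   \item `background`: same mean in every condition;
#'   \item `raft_resident`: `+raft_baseline_effect` in every biotinylated
#'     condition (`ACT_*`) relative to the controls, non-responsive to
#'     stimulation;
#'   \item `responder_up_<t>` / `responder_down_<t>`: `+/- responder_effect`
#'     at activation time point `t` relative to resting;
#'   \item `resting_exclusive`: detectable in controls and at resting, below
#'     detection at every activation time point;
#'   \item `activated_exclusive`: below detection in resting cells and both
#'     controls, detectable at every activation time point.
#' }
#'
#' @name synthetic_data
NULL

#' Simulation parameters with the study-layout defaults
#'
#' Defaults emulate the 6-condition x 3-replicate label-free experiment:
#' baseline log2 abundance N(25, 2) (raw-intensity scale of Orbitrap
#' label-free data), raft baseline effect +2.5 log2, responder effect +/-2.0
#' log2 at the planted time point, replicate noise sd 0.3 log2 units,
#' logistic detection with midpoint 18 and slope 1 (dropout confined to the
#' low-abundance tail), MCAR rate 0.02.
#'
#' @param n_proteins number of genuine (non-decoy) proteins.
#' @param prop_raft,prop_responder,prop_resting_exclusive,prop_activated_exclusive
#'   class proportions; responders are split evenly over up/down x time
#'   point; the remainder is background.
#' @param baseline_mean,baseline_sd log2 abundance distribution.
#' @param raft_baseline_effect,responder_effect planted log2 effects.
#' @param noise_sd replicate noise sd (log2).
#' @param dropout_midpoint,dropout_slope logistic detection-probability
#'   parameters on the log2 scale (`dropout_midpoint = -Inf` disables MNAR
#'   dropout).
#' @param mcar_rate probability of losing any cell completely at random.
#' @param exclusion_depth log2 units below the detection midpoint at which
#'   excluded-condition means sit.
#' @param peptide_lambda unique peptides per protein are
#'   `1 + Poisson(peptide_lambda)`.
#' @param contaminant_rate,reverse_rate spike-in rates for flagged decoy /
#'   contaminant rows (relative to `n_proteins`).
#' @param n_replicates replicates per condition.
#' @param seed RNG seed.
#' @return a validated parameter list of class `simulation_params`.
#' @export
simulation_params <- function(n_proteins = 2000L,
                              prop_raft = 0.05,
                              prop_responder = 0.05,
                              prop_resting_exclusive = 0.01,
                              prop_activated_exclusive = 0.01,
                              baseline_mean = 25, baseline_sd = 2,
                              raft_baseline_effect = 2.5,
                              responder_effect = 2.0,
                              noise_sd = 0.3,
                              dropout_midpoint = 18, dropout_slope = 1,
                              mcar_rate = 0.02,
                              exclusion_depth = 4,
                              peptide_lambda = 5,
                              contaminant_rate = 0.02, reverse_rate = 0.02,
                              n_replicates = 3L,
                              seed = 1L) {
  props <- c(prop_raft, prop_responder, prop_resting_exclusive,
             prop_activated_exclusive)
  if (any(props < 0) || sum(props) > 1) {
    stop("class proportions must be non-negative and sum to at most 1")
  }
  if (baseline_sd <= 0 || noise_sd < 0) stop("sds must be positive")
  if (mcar_rate < 0 || mcar_rate > 1 ||
      contaminant_rate < 0 || reverse_rate < 0) {
    stop("rates must be probabilities")
  }
  structure(as.list(environment()), class = "simulation_params")
}

#' Simulate a proximity-biotinylation label-free experiment
#'
#' @param params a [simulation_params()] list.
#' @return list with `table` (a [protein_quant_table()] including spiked
#'   contaminant/reverse rows), `truth` (per-protein class label, baseline
#'   and planted effect, plus the true per-condition mean log2 intensities),
#'   and `design` (the [experiment_design()] used). Fully reproducible from
#'   `params$seed`.
#' @export
simulate_experiment <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  design <- default_design(params$n_replicates)
  conds <- RAFT_CONDITIONS
  timepoints <- c("ACT_5", "ACT_10", "ACT_15")
  n <- params$n_proteins

  n_raft <- round(n * params$prop_raft)
  n_resp <- round(n * params$prop_responder)
  n_rex <- round(n * params$prop_resting_exclusive)
  n_aex <- round(n * params$prop_activated_exclusive)
  resp_classes <- as.vector(outer(c("responder_up", "responder_down"),
                                  c(5, 10, 15), paste, sep = "_"))
  class <- c(rep("raft_resident", n_raft),
             rep(resp_classes, length.out = n_resp),
             rep("resting_exclusive", n_rex),
             rep("activated_exclusive", n_aex))
  class <- c(class, rep("background", n - length(class)))

  baseline <- stats::rnorm(n, params$baseline_mean, params$baseline_sd)
  low <- params$dropout_midpoint - params$exclusion_depth

  # true per-condition mean log2 intensity
  mu <- matrix(rep(baseline, length(conds)), nrow = n,
               dimnames = list(NULL, conds))
  is_raft <- class == "raft_resident"
  mu[is_raft, ACTIVATION_CONDITIONS] <-
    mu[is_raft, ACTIVATION_CONDITIONS] + params$raft_baseline_effect
  for (tp in c(5, 10, 15)) {
    cc <- paste0("ACT_", tp)
    up <- class == paste0("responder_up_", tp)
    dn <- class == paste0("responder_down_", tp)
    mu[up, cc] <- mu[up, cc] + params$responder_effect
    mu[dn, cc] <- mu[dn, cc] - params$responder_effect
  }
  mu[class == "resting_exclusive", timepoints] <- low
  mu[class == "activated_exclusive",
     c("CTRL_NO_H2O2", "CTRL_NO_BP", "ACT_0")] <- low

  effect <- numeric(n)
  effect[is_raft] <- params$raft_baseline_effect
  effect[grepl("^responder_up", class)] <- params$responder_effect
  effect[grepl("^responder_down", class)] <- -params$responder_effect

  protein_id <- sprintf("SYN%04d", seq_len(n))
  truth <- data.frame(protein_id = protein_id, class = class,
                      baseline = baseline, effect = effect,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(mu))

  # replicate values, detection, recorded linear intensities
  sample_cond <- design$condition
  vals <- mu[, sample_cond, drop = FALSE] +
    matrix(stats::rnorm(n * nrow(design), 0, params$noise_sd),
           nrow = n)
  colnames(vals) <- design$sample_id
  p_detect <- stats::plogis(params$dropout_slope *
                              (vals - params$dropout_midpoint))
  detected <- matrix(stats::runif(length(vals)) < p_detect, nrow = n) &
    matrix(stats::runif(length(vals)) >= params$mcar_rate, nrow = n)
  intensities <- ifelse(detected, 2^vals, 0)
  colnames(intensities) <- design$sample_id

  unique_peptides <- 1L + stats::rpois(n, params$peptide_lambda)
  is_rev <- rep(FALSE, n)
  is_con <- rep(FALSE, n)

  # spiked contaminant / decoy rows, background-like intensities
  n_con <- round(n * params$contaminant_rate)
  n_rev <- round(n * params$reverse_rate)
  n_spike <- n_con + n_rev
  if (n_spike > 0) {
    sp_base <- stats::rnorm(n_spike, params$baseline_mean, params$baseline_sd)
    sp_vals <- matrix(rep(sp_base, nrow(design)), nrow = n_spike) +
      matrix(stats::rnorm(n_spike * nrow(design), 0, params$noise_sd),
             nrow = n_spike)
    sp_det <- matrix(stats::runif(length(sp_vals)) <
                       stats::plogis(params$dropout_slope *
                                       (sp_vals - params$dropout_midpoint)),
                     nrow = n_spike)
    sp_int <- ifelse(sp_det, 2^sp_vals, 0)
    colnames(sp_int) <- design$sample_id
    spike_id <- c(sprintf("CON__%04d", seq_len(n_con)),
                  sprintf("REV__%04d", seq_len(n_rev)))
    protein_id <- c(protein_id, spike_id)
    intensities <- rbind(intensities, sp_int)
    unique_peptides <- c(unique_peptides,
                         1L + stats::rpois(n_spike, params$peptide_lambda))
    is_con <- c(is_con, rep(c(TRUE, FALSE), c(n_con, n_rev)))
    is_rev <- c(is_rev, rep(c(FALSE, TRUE), c(n_con, n_rev)))
  }

  table <- protein_quant_table(protein_id = protein_id,
                               gene_name = protein_id,
                               unique_peptides = unique_peptides,
                               is_reverse = is_rev,
                               is_contaminant = is_con,
                               intensities = intensities)
  list(table = table, truth = truth, design = design)
}

#' Expected missingness of a simulated experiment
#'
#' Analytic expectation of the dropout probability averaged over planted
#' replicate intensities: for replicate value x ~ N(mu, noise),
#' P(missing) = 1 - (1 - mcar) * E[logistic(slope * (x - midpoint))],
#' integrated numerically over the noise distribution.
#'
#' @param params a [simulation_params()].
#' @param truth the `truth` component of [simulate_experiment()].
#' @param design the design used.
#' @return expected fraction of zero cells among genuine proteins.
#' @export
expected_missingness <- function(params, truth, design) {
  mu <- as.matrix(truth[, RAFT_CONDITIONS])[, design$condition, drop = FALSE]
  m <- as.vector(mu)
  if (params$noise_sd == 0) {
    p_obs <- stats::plogis(params$dropout_slope *
                             (m - params$dropout_midpoint))
  } else {
    # vectorized quadrature over the replicate-noise distribution
    z <- seq(-8, 8, length.out = 201)
    w <- stats::dnorm(z) * (z[2] - z[1])
    x <- outer(m, z * params$noise_sd, "+")
    p_obs <- as.vector(
      stats::plogis(params$dropout_slope * (x - params$dropout_midpoint)) %*% w)
  }
  mean(1 - (1 - params$mcar_rate) * p_obs)
}

#' Simulate flow-cytometry measurement sets with a known DRI
#'
#' Builds `n` four-channel measurement sets whose noiseless detergent
#' resistance index equals `true_dri`, then adds Gaussian noise per channel.
#' Negative draws are clipped to 0 and flagged.
#'
#' @param true_dri target index in \[0, 1\].
#' @param noise_sd per-channel Gaussian noise sd (a.u.).
#' @param n number of measurement sets.
#' @param seed RNG seed.
#' @param flbg,fl_max noiseless background and labeled-cell fluorescence
#'   (defaults 10 and 110 a.u., giving a dynamic range of 100).
#' @return `data.frame` with columns `fl_det`, `flbg_det`, `fl_max`, `flbg`
#'   and logical `clipped`.
#' @export
simulate_flow <- function(true_dri, noise_sd = 0, n = 1L, seed = 1L,
                          flbg = 10, fl_max = 110) {
  if (true_dri < 0 || true_dri > 1) stop("true_dri must lie in [0, 1]")
  set.seed(seed)
  base <- data.frame(fl_det = flbg + true_dri * (fl_max - flbg),
                     flbg_det = flbg, fl_max = fl_max, flbg = flbg)
  out <- base[rep(1L, n), , drop = FALSE]
  noisy <- as.matrix(out) + matrix(stats::rnorm(4 * n, 0, noise_sd), nrow = n)
  clipped <- rowSums(noisy < 0) > 0
  noisy[noisy < 0] <- 0
  out <- as.data.frame(noisy)
  rownames(out) <- NULL
  out$clipped <- clipped
  out
}
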
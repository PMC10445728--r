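#' @title Moderated-t differential enrichment with BH FDR
#'
#' @description
#' Per-protein differential enrichment between activation time points and the
#' resting state, using the empirical-Bayes moderated t statistic: each
#' protein's residual variance \eqn{s^2} (pooled across all design groups,
#' residual df \eqn{d}) is shrunk toward a prior \eqn{(d_0, s_0^2)} estimated
#' from all proteins by method of moments on \eqn{\log s^2}, giving
#' \deqn{\tilde{s}^2 = (d_0 s_0^2 + d s^2) / (d_0 + d),\quad
#'       t = \Delta / (\tilde{s} \sqrt{1/n_1 + 1/n_2})}
#' with \eqn{d + d_0} degrees of freedom. P-values are two-sided and adjusted
#' by Benjamini-Hochberg within each contrast.
#'
#' Setting `prior_df = 0` disables shrinkage and recovers the ordinary
#' pooled-variance t test; `prior_df = Inf` shrinks fully to \eqn{s_0^2}.
#'
#' @name differential
NULL

#' Define a two-condition contrast
#'
#' @param numerator,denominator condition labels; a positive log2 fold change
#'   means higher in the numerator.
#' @param name contrast label (default `"numerator_vs_denominator"`).
#' @return a list of class `raft_contrast`.
#' @export
contrast <- function(numerator, denominator,
                     name = paste0(numerator, "_vs_", denominator)) {
  if (identical(numerator, denominator)) {
    stop("numerator and denominator must differ")
  }
  structure(list(name = name, numerator = numerator,
                 denominator = denominator),
            class = "raft_contrast")
}

#' Default activation contrasts: 5, 10, 15 min versus resting (0 min)
#' @export
default_contrasts <- function() {
  list(contrast("ACT_5", "ACT_0"),
       contrast("ACT_10", "ACT_0"),
       contrast("ACT_15", "ACT_0"))
}

#' Per-protein log2 fold change between two condition groups
#'
#' Mean log2 intensity over numerator replicates minus mean over denominator
#' replicates; antisymmetric under contrast reversal.
#'
#' @param m a complete [intensity_matrix()].
#' @param design an [experiment_design()].
#' @param ctr a [contrast()].
#' @return named numeric vector, one value per protein.
#' @export
group_log2fc <- function(m, design, ctr) {
  num <- condition_samples(design, ctr$numerator)
  den <- condition_samples(design, ctr$denominator)
  x <- m$values
  rowMeans(x[, num, drop = FALSE]) - rowMeans(x[, den, drop = FALSE])
}

# residual variance of the one-way group-means model: pooled within-group
# variance across the given conditions; returns list(s2, df, n_per_group)
.pooled_residual_variance <- function(x, design, conditions) {
  groups <- lapply(conditions, function(cc) condition_samples(design, cc))
  rss <- 0
  df <- 0
  for (g in groups) {
    sub <- x[, g, drop = FALSE]
    rss <- rss + rowSums((sub - rowMeans(sub))^2)
    df <- df + length(g) - 1L
  }
  if (df <= 0) stop("zero residual degrees of freedom")
  list(s2 = rss / df, df = df)
}

#' Method-of-moments prior for the variance distribution
#'
#' Fits the scaled-F model for observed residual variances: given per-protein
#' \eqn{s^2} with common df \eqn{d}, estimates prior df \eqn{d_0} and prior
#' variance \eqn{s_0^2} by matching the mean and variance of \eqn{\log s^2}
#' to the theoretical moments (digamma/trigamma), inverting the trigamma
#' function by Newton iteration.
#'
#' @param s2 positive numeric vector of residual variances.
#' @param df residual degrees of freedom (scalar).
#' @return list with `df_prior` (possibly `Inf`) and `s2_prior`.
#' @export
fit_variance_prior <- function(s2, df) {
  if (any(s2 <= 0)) {
    # guard: degenerate zero-variance rows get the smallest positive value
    s2 <- pmax(s2, min(s2[s2 > 0], na.rm = TRUE) * 1e-6)
  }
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * .trigamma_inverse(evar)
    s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    df_prior <- Inf
    s2_prior <- exp(emean)
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

.trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (iter in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

#' Empirical-Bayes moderated t tests for a set of contrasts
#'
#' @param m a complete [intensity_matrix()].
#' @param design an [experiment_design()].
#' @param contrasts list of [contrast()]s (default the three activation time
#'   points versus resting).
#' @param alpha FDR level for the `significant` flag (default 0.05).
#' @param fc_threshold absolute log2-fold-change cut for the `strong_change`
#'   flag (default 1.5).
#' @param pool `"all"` (default): residual variance pooled across every
#'   design group in a single one-way model; `"pair"`: pooled over the two
#'   contrasted groups only.
#' @param prior_df override for the prior df: `NULL` (default) estimates it
#'   from the data; `0` gives the ordinary pooled-variance t; `Inf` shrinks
#'   fully to the prior variance.
#' @return a `data.frame` with one row per protein x contrast: `protein_id`,
#'   `contrast`, `log2fc`, `t_mod`, `df_total`, `p`, `adj_p`, `significant`,
#'   `strong_change`.
#' @export
moderated_t <- function(m, design, contrasts = default_contrasts(),
                        alpha = 0.05, fc_threshold = 1.5,
                        pool = c("all", "pair"), prior_df = NULL) {
  pool <- match.arg(pool)
  x <- m$values
  if (anyNA(x)) stop("matrix contains missing values; impute first")
  for (ctr in contrasts) {
    for (cc in c(ctr$numerator, ctr$denominator)) {
      n_rep <- length(condition_samples(design, cc))
      if (n_rep < 2) stop("condition ", cc, " has fewer than 2 replicates")
    }
  }

  all_conditions <- unique(design$condition[design$sample_id %in% colnames(x)])
  fit_for <- function(conditions) {
    rv <- .pooled_residual_variance(x, design, conditions)
    if (is.null(prior_df)) {
      pri <- fit_variance_prior(rv$s2, rv$df)
    } else if (prior_df == 0) {
      pri <- list(df_prior = 0, s2_prior = NA_real_)
    } else if (is.infinite(prior_df)) {
      pri <- fit_variance_prior(rv$s2, rv$df)
      pri$df_prior <- Inf
    } else {
      pri <- fit_variance_prior(rv$s2, rv$df)
      pri$df_prior <- prior_df
    }
    c(rv, pri)
  }
  fit_all <- if (pool == "all") fit_for(all_conditions) else NULL

  rows <- lapply(contrasts, function(ctr) {
    fit <- if (pool == "all") {
      fit_all
    } else {
      fit_for(c(ctr$numerator, ctr$denominator))
    }
    s2_post <- if (fit$df_prior == 0) {
      fit$s2
    } else if (is.infinite(fit$df_prior)) {
      rep(fit$s2_prior, length(fit$s2))
    } else {
      (fit$df_prior * fit$s2_prior + fit$df * fit$s2) /
        (fit$df_prior + fit$df)
    }
    df_total <- fit$df + fit$df_prior
    n1 <- length(condition_samples(design, ctr$numerator))
    n2 <- length(condition_samples(design, ctr$denominator))
    fc <- group_log2fc(m, design, ctr)
    tval <- fc / sqrt(s2_post * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(tval), df = df_total)
    adj <- bh_adjust(p)
    data.frame(protein_id = rownames(x), contrast = ctr$name,
               log2fc = fc, t_mod = tval,
               df_total = df_total, p = p, adj_p = adj,
               significant = adj <= alpha,
               strong_change = abs(fc) >= fc_threshold,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Standard step-up adjusted p-values, order preserved, clipped to 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Significance calling across contrasts
#'
#' Per contrast, the significant set is `{adjusted p <= alpha AND |log2fc| >=
#' fc_threshold}` (the flags computed by [moderated_t()]); the union and the
#' all-contrast intersection are reported with counts.
#'
#' @param rows output of [moderated_t()].
#' @return list with `per_contrast` (named list of protein-id vectors),
#'   `union`, `intersection`, and `counts` (named integer vector).
#' @export
call_significant <- function(rows) {
  if (nrow(rows) == 0) {
    return(list(per_contrast = list(), union = character(0),
                intersection = character(0),
                counts = c(union = 0L, intersection = 0L)))
  }
  hit <- rows$significant & rows$strong_change
  per_contrast <- split(rows$protein_id[hit], rows$contrast[hit])
  # keep empty contrasts in the listing
  all_contrasts <- unique(rows$contrast)
  per_contrast <- stats::setNames(
    lapply(all_contrasts, function(cc) {
      out <- per_contrast[[cc]]
      if (is.null(out)) character(0) else out
    }),
    all_contrasts)
  uni <- Reduce(union, per_contrast, accumulate = FALSE)
  inter <- Reduce(intersect, per_contrast)
  counts <- c(vapply(per_contrast, length, integer(1)),
              union = length(uni), intersection = length(inter))
  list(per_contrast = per_contrast, union = uni, intersection = inter,
       counts = counts)
}
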
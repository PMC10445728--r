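#' @title From raw intensities to a complete, normalized log2 matrix
#'
#' @description
#' Label-free intensities are log2-transformed (zeros become missing),
#' proteins with too many missing values are removed, the remaining holes are
#' filled by row-wise k-nearest-neighbour imputation, and the columns are
#' quantile-normalized. The pipeline order is fixed: log -> missingness
#' filter -> impute -> normalize; [preprocess()] enforces it.
#'
#' Missingness in label-free MS is dominated by low-abundance dropout
#' (missing not at random), which is why imputation borrows values from
#' proteins with similar intensity profiles rather than from a global
#' distribution.
#'
#' @name preprocess
NULL

#' Construct an intensity matrix with per-cell provenance
#'
#' @param values numeric matrix (proteins x samples) of log2 intensities;
#'   `NA` marks a missing (not quantified) entry.
#' @param imputed logical matrix of the same dimension; `TRUE` where the value
#'   was filled in by imputation. Defaults to all-`FALSE` (all observed).
#' @return An object of class `intensity_matrix`: a list with elements
#'   `values` and `imputed`.
#' @export
intensity_matrix <- function(values, imputed = NULL) {
  values <- as.matrix(values)
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(values), ncol(values),
                      dimnames = dimnames(values))
  }
  imputed <- as.matrix(imputed)
  stopifnot(identical(dim(values), dim(imputed)))
  if (any(imputed & is.na(values))) {
    stop("a cell cannot be both imputed and missing")
  }
  structure(list(values = values, imputed = imputed),
            class = "intensity_matrix")
}

#' @export
dim.intensity_matrix <- function(x) dim(x$values)

#' @export
print.intensity_matrix <- function(x, ...) {
  cat(sprintf("intensity_matrix: %d proteins x %d samples (%d missing, %d imputed)\n",
              nrow(x$values), ncol(x$values), sum(is.na(x$values)),
              sum(x$imputed)))
  invisible(x)
}

#' Log2-transform raw intensities
#'
#' Positive intensities map to `log2(intensity)`; zeros map to missing
#' (`NA`). All entries are flagged observed.
#'
#' @param table a [protein_quant_table()], or a non-negative numeric matrix.
#' @return an [intensity_matrix()].
#' @export
log_transform <- function(table) {
  m <- if (inherits(table, "protein_quant_table")) {
    table_intensities(table)
  } else {
    as.matrix(table)
  }
  if (any(m < 0, na.rm = TRUE)) stop("negative intensity encountered")
  vals <- ifelse(is.na(m) | m == 0, NA_real_, log2(m))
  dimnames(vals) <- dimnames(m)
  intensity_matrix(vals)
}

#' Filter proteins by missingness
#'
#' Keeps exactly the proteins with at most `max_missing` missing entries
#' (the boundary is inclusive: a protein missing in `max_missing` samples is
#' retained, one missing in `max_missing + 1` is dropped). Row order is
#' preserved.
#'
#' @param m an [intensity_matrix()].
#' @param max_missing maximum number of missing entries per protein
#'   (default 6 of the 18-sample layout, i.e. present in >= 12 samples).
#' @return the filtered [intensity_matrix()].
#' @export
filter_missingness <- function(m, max_missing = 6L) {
  keep <- rowSums(is.na(m$values)) <= max_missing
  intensity_matrix(m$values[keep, , drop = FALSE],
                   m$imputed[keep, , drop = FALSE])
}

#' k-nearest-neighbour imputation of missing log2 intensities
#'
#' Each missing cell (protein p, sample s) is replaced by the mean, over the
#' k proteins nearest to p that are observed in s, of their values in s.
#' Distance between two proteins is the Euclidean distance over their
#' co-observed samples, scaled by `sqrt(n_samples / n_co_observed)` so that
#' sparsely overlapping rows are not spuriously close. Observed entries are
#' never altered; imputed cells are flagged in the provenance matrix.
#'
#' Neighbour ties are broken by input row order, so the result is
#' deterministic.
#'
#' If fewer than `k` neighbours are observed in sample s, the mean over the
#' eligible neighbours is used; if none is, the protein's own observed row
#' mean is used. Both fallbacks emit a warning.
#'
#' @param m an [intensity_matrix()]; every protein must have at least one
#'   observed value (run after [filter_missingness()]).
#' @param k number of neighbours (default 10).
#' @return a complete [intensity_matrix()].
#' @export
knn_impute <- function(m, k = 10L) {
  x <- m$values
  n <- nrow(x)
  p <- ncol(x)
  obs <- !is.na(x)
  if (any(rowSums(obs) == 0)) {
    bad <- rownames(x)[rowSums(obs) == 0][1]
    stop("protein with no observed values: ",
         if (is.null(bad)) "<unnamed>" else bad)
  }
  if (k < 1) stop("k must be >= 1")
  if (!anyNA(x)) return(m)

  # pairwise scaled Euclidean distances over co-observed samples, in one
  # set of matrix products: d2_ij = (sum_co x_i^2 + sum_co x_j^2 - 2 x_i.x_j)
  #                                 * p / n_co
  x0 <- x
  x0[!obs] <- 0
  obs_n <- obs * 1
  cross <- x0 %*% t(x0)
  sq <- x0^2
  a <- sq %*% t(obs_n)                 # sum over co-observed of x_i^2
  co <- obs_n %*% t(obs_n)             # co-observed counts
  d2 <- (a + t(a) - 2 * cross) * (p / pmax(co, 1))
  d2[co == 0] <- Inf
  diag(d2) <- Inf
  d2[d2 < 0] <- 0                      # numerical noise

  vals <- x
  imput <- m$imputed
  fallback_partial <- FALSE
  fallback_rowmean <- FALSE
  for (i in which(rowSums(!obs) > 0)) {
    ord <- order(d2[i, ], na.last = TRUE)   # stable: ties keep row order
    ord <- ord[is.finite(d2[i, ord])]
    for (j in which(!obs[i, ])) {
      donors <- ord[obs[ord, j]]
      if (length(donors) >= k) {
        vals[i, j] <- mean(x[donors[seq_len(k)], j])
      } else if (length(donors) > 0) {
        fallback_partial <- TRUE
        vals[i, j] <- mean(x[donors, j])
      } else {
        fallback_rowmean <- TRUE
        vals[i, j] <- mean(x[i, obs[i, ]])
      }
      imput[i, j] <- TRUE
    }
  }
  if (fallback_partial) {
    warning("fewer than k eligible neighbours for some cells; ",
            "used mean over eligible neighbours")
  }
  if (fallback_rowmean) {
    warning("no eligible neighbour for some cells; used row mean")
  }
  intensity_matrix(vals, imput)
}

#' Quantile-normalize a complete intensity matrix
#'
#' Each column's order statistics are replaced by the across-column means of
#' order statistics, so all columns share the same empirical distribution
#' afterwards. Ties within a column receive the mean of the reference
#' quantiles they span (ties = "average"). Within-column rank order is
#' preserved and the transform is idempotent.
#'
#' @param m a complete [intensity_matrix()] (run after imputation), or a
#'   numeric matrix.
#' @return the normalized object, same class as the input.
#' @export
quantile_normalize <- function(m) {
  is_im <- inherits(m, "intensity_matrix")
  x <- if (is_im) m$values else as.matrix(m)
  if (anyNA(x)) {
    stop("missing values present; quantile normalization requires a complete ",
         "matrix (impute first)")
  }
  n <- nrow(x)
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    r <- rank(col, ties.method = "average")
    # integer ranks index the reference directly; fractional ranks (ties)
    # average the two spanned reference quantiles
    lo <- ref[floor(r)]
    hi <- ref[ceiling(r)]
    (lo + hi) / 2
  })
  dimnames(out) <- dimnames(x)
  if (is_im) intensity_matrix(out, m$imputed) else out
}

#' Run the fixed preprocessing pipeline
#'
#' log2 transform -> missingness filter -> kNN imputation -> quantile
#' normalization (normalization skippable via `normalization = "none"`).
#'
#' @param table a [protein_quant_table()].
#' @param max_missing per-protein missing-value cap (default 6).
#' @param knn_k imputation neighbours (default 10).
#' @param normalization `"quantile"` (default) or `"none"`.
#' @return a complete [intensity_matrix()].
#' @export
preprocess <- function(table, max_missing = 6L, knn_k = 10L,
                       normalization = c("quantile", "none")) {
  normalization <- match.arg(normalization)
  m <- log_transform(table)
  m <- filter_missingness(m, max_missing = max_missing)
  m <- knn_impute(m, k = knn_k)
  if (normalization == "quantile") m <- quantile_normalize(m)
  m
}
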
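# shared toy builders and independent oracles

# brute-force BH step-up: sort, multiply, cumulative min from the top, unsort
bh_oracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- p[ord] * n / seq_len(n)
  for (i in (n - 1):1) if (n > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[ord] <- adj
  out
}

# small two-condition design: g1/g2 with n replicates each
two_group_design <- function(n = 3L) {
  experiment_design(sample_id = c(paste0("g1_", 1:n), paste0("g2_", 1:n)),
                    condition = rep(c("g1", "g2"), each = n),
                    replicate = rep(1:n, 2))
}

# complete intensity_matrix with named rows from a plain matrix
im <- function(x) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("P", seq_len(nrow(x)))
  intensity_matrix(x)
}

# tiny proteinGroups fixture written to a temp file; returns the path
write_pg_fixture <- function(path, design,
                             ids = c("P1", "P2", "P3"),
                             drop_sample = NULL) {
  cols <- c("Protein IDs", "Gene names", "Unique peptides", "Reverse",
            "Potential contaminant",
            sprintf("Intensity %s", setdiff(design$sample_id, drop_sample)))
  rows <- lapply(seq_along(ids), function(i) {
    intens <- rep(1000 * i, length(design$sample_id))
    names(intens) <- design$sample_id
    intens <- intens[setdiff(design$sample_id, drop_sample)]
    c(ids[i], paste0("Gene", i), as.character(i + 1),
      "", if (i == 3) "+" else "", as.character(intens))
  })
  lines <- c(paste(cols, collapse = "\t"),
             vapply(rows, paste, character(1), collapse = "\t"))
  writeLines(lines, path)
  path
}

# hand-loop mean silhouette width (independent of cluster::silhouette)
silhouette_oracle <- function(x, cl) {
  d <- as.matrix(dist(x))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    a <- if (length(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(unique(cl), cl[i]), function(k) {
      mean(d[i, cl == k])
    }, numeric(1)))
    s[i] <- if (length(own)) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# brute-force Dunn index: explicit loops over all pairs
dunn_oracle <- function(x, cl) {
  d <- as.matrix(dist(x))
  n <- nrow(d)
  min_between <- Inf
  max_within <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (cl[i] == cl[j]) max_within <- max(max_within, d[i, j])
    else min_between <- min(min_between, d[i, j])
  }
  min_between / max_within
}

# brute-force connectivity: per point, rank neighbours, sum 1/rank for
# cross-cluster neighbours among the first L
connectivity_oracle <- function(x, cl, L = 2) {
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  total <- 0
  for (i in seq_len(nrow(d))) {
    nn <- order(d[i, ])
    for (r in seq_len(L)) {
      if (cl[nn[r]] != cl[i]) total <- total + 1 / r
    }
  }
  total
}
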
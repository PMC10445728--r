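test_that("group log2 fold change is the difference of group means and is
           antisymmetric", {
  design <- two_group_design()
  x <- rbind(P1 = c(10, 10, 10, 8, 8, 8), P2 = rep(5, 6))
  colnames(x) <- design$sample_id
  m <- im(x)
  fc <- group_log2fc(m, design, contrast("g1", "g2"))
  expect_equal(unname(fc), c(2, 0))
  expect_equal(group_log2fc(m, design, contrast("g2", "g1")), -fc)
  expect_error(group_log2fc(m, design, contrast("g1", "nope")), "nope")
})

test_that("with prior df forced to 0 the moderated t equals the textbook
           pooled-variance two-sample t", {
  set.seed(2)
  design <- two_group_design()
  x <- matrix(rnorm(5 * 6, 20), 5, 6, dimnames = list(paste0("P", 1:5),
                                                      design$sample_id))
  rows <- moderated_t(im(x), design, list(contrast("g1", "g2")),
                      prior_df = 0)
  for (i in 1:5) {
    tt <- t.test(x[i, 1:3], x[i, 4:6], var.equal = TRUE)
    expect_equal(rows$t_mod[i], unname(tt$statistic), tolerance = 1e-9)
    expect_equal(rows$p[i], tt$p.value, tolerance = 1e-9)
    expect_equal(rows$df_total[i], 4)
  }
})

test_that("moderated t agrees with the limma reference implementation", {
  set.seed(8)
  n <- 200
  design <- default_design()
  # heterogeneous true variances so the prior df is finite and informative
  s2 <- 0.09 * 4 / rchisq(n, df = 4)
  mu <- rnorm(n, 24, 2)
  x <- matrix(rnorm(n * 18, rep(mu, 18), rep(sqrt(s2), 18)), n, 18,
              dimnames = list(paste0("P", 1:n), design$sample_id))
  rows <- moderated_t(im(x), design, default_contrasts())

  groups <- factor(design$condition, levels = RAFT_CONDITIONS)
  dm <- model.matrix(~ 0 + groups)
  colnames(dm) <- levels(groups)
  fit <- limma::lmFit(x, dm)
  cm <- limma::makeContrasts(ACT_5 - ACT_0, ACT_10 - ACT_0, ACT_15 - ACT_0,
                             levels = dm)
  eb <- limma::eBayes(limma::contrasts.fit(fit, cm))
  for (j in 1:3) {
    ours <- rows[rows$contrast == default_contrasts()[[j]]$name, ]
    expect_equal(ours$log2fc, unname(eb$coefficients[, j]), tolerance = 1e-9)
    expect_equal(ours$t_mod, unname(eb$t[, j]), tolerance = 1e-6)
    expect_equal(ours$p, unname(eb$p.value[, j]), tolerance = 1e-6)
    expect_equal(unique(ours$df_total),
                 unname(unique(eb$df.total)), tolerance = 1e-6)
  }
})

test_that("t is antisymmetric under contrast reversal with invariant p", {
  set.seed(4)
  design <- two_group_design()
  x <- matrix(rnorm(30, 15), 5, 6, dimnames = list(paste0("P", 1:5),
                                                   design$sample_id))
  fwd <- moderated_t(im(x), design, list(contrast("g1", "g2")))
  rev <- moderated_t(im(x), design, list(contrast("g2", "g1")))
  expect_equal(fwd$t_mod, -rev$t_mod)
  expect_equal(fwd$p, rev$p)
})

test_that("shrinkage pulls |t| toward the prior monotonically in prior df
           when s2 is below the prior variance", {
  design <- two_group_design()
  set.seed(6)
  x <- matrix(rnorm(20 * 6, 10, 1), 20, 6,
              dimnames = list(paste0("P", 1:20), design$sample_id))
  x[1, ] <- c(10.0, 10.05, 9.95, 11.0, 11.05, 10.95)  # tiny s2, real shift
  t_for <- function(d0) {
    rows <- moderated_t(im(x), design, list(contrast("g2", "g1")),
                        prior_df = d0)
    abs(rows$t_mod[1])
  }
  ts <- vapply(c(0, 1, 4, 16, 64), t_for, numeric(1))
  expect_true(all(diff(ts) < 0))
})

test_that("BH adjustment reproduces the worked example and basic identities", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.3, 5)), rep(0.3, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(12)
  for (rep in 1:20) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
})

test_that("adjusted p never falls below raw p and respects the alpha flag", {
  set.seed(13)
  design <- two_group_design()
  x <- matrix(rnorm(50 * 6, 12), 50, 6,
              dimnames = list(paste0("P", 1:50), design$sample_id))
  rows <- moderated_t(im(x), design, list(contrast("g1", "g2")))
  expect_true(all(rows$adj_p >= rows$p - 1e-12))
  expect_true(all(rows$adj_p <= 1))
  expect_equal(rows$significant, rows$adj_p <= 0.05)
})

test_that("significance calling matches predicate enumeration on a toy", {
  rows <- data.frame(
    protein_id = rep(paste0("P", 1:6), 2),
    contrast = rep(c("c1", "c2"), each = 6),
    log2fc = c(2, -2, 1, 2, 0.2, 1.6, 2, 1.7, 0.3, -1.8, 2.5, 0.1),
    adj_p = c(0.01, 0.2, 0.01, 0.04, 0.01, 0.03,
              0.02, 0.01, 0.01, 0.03, 0.2, 0.01),
    stringsAsFactors = FALSE)
  rows$significant <- rows$adj_p <= 0.05
  rows$strong_change <- abs(rows$log2fc) >= 1.5
  sig <- call_significant(rows)
  # hand truth table: c1 -> P1 (sig+strong), P4, P6; P2 strong not sig,
  # P3/P5 sig not strong; c2 -> P1, P2, P4
  expect_setequal(sig$per_contrast$c1, c("P1", "P4", "P6"))
  expect_setequal(sig$per_contrast$c2, c("P1", "P2", "P4"))
  expect_setequal(sig$union, c("P1", "P2", "P4", "P6"))
  expect_setequal(sig$intersection, c("P1", "P4"))
  expect_equal(unname(sig$counts[c("union", "intersection")]), c(4L, 2L))
  # empty input -> empty sets
  empty <- call_significant(rows[0, ])
  expect_length(empty$union, 0)
})
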
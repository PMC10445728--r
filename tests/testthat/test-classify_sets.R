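# complete 18-sample matrix with chosen per-condition means for each protein
make_condition_matrix <- function(means_by_protein, design = default_design()) {
  x <- t(vapply(means_by_protein,
                function(mu) unname(mu[design$condition]),
                numeric(nrow(design))))
  colnames(x) <- design$sample_id
  rownames(x) <- names(means_by_protein)
  intensity_matrix(x)
}

cond_means <- function(ctrl = 20, act0 = 20, act5 = act0, act10 = act0,
                       act15 = act0) {
  c(CTRL_NO_H2O2 = ctrl, CTRL_NO_BP = ctrl, ACT_0 = act0,
    ACT_5 = act5, ACT_10 = act10, ACT_15 = act15)
}

test_that("raft classification applies the two-step rule with inclusive
           boundaries and partitions the proteins", {
  design <- default_design()
  m <- make_condition_matrix(list(
    boundary = cond_means(ctrl = 20, act0 = 21.5),            # FC exactly 1.5
    resident = cond_means(ctrl = 20, act0 = 23),
    responder = cond_means(ctrl = 20, act0 = 23, act5 = 24.2), # resp 1.2
    weak = cond_means(ctrl = 20, act0 = 21),                   # FC 1.0 < 1.5
    down_responder = cond_means(ctrl = 20, act0 = 23, act10 = 21.9)
  ), design)
  cls <- classify_raft_resident(m, design)
  lab <- setNames(cls$label, cls$protein_id)
  expect_equal(unname(lab["boundary"]), "raft_resident")
  expect_equal(unname(lab["resident"]), "raft_resident")
  expect_equal(unname(lab["responder"]), "stimulation_responsive")
  expect_equal(unname(lab["weak"]), "other")
  # |FC| rule: a -1.1 response is also responsive
  expect_equal(unname(lab["down_responder"]), "stimulation_responsive")
  # signed mode ignores the downward response
  cls_signed <- classify_raft_resident(m, design, response_rule = "signed")
  expect_equal(cls_signed$label[cls_signed$protein_id == "down_responder"],
               "raft_resident")
  # labels partition the set
  expect_equal(sum(table(cls$label)), nrow(m$values))
  expect_equal(cls$baseline_fc[cls$protein_id == "boundary"], 1.5)
  # missing required condition is a configuration error
  d2 <- two_group_design()
  expect_error(classify_raft_resident(im(matrix(1, 1, 6)), d2), "CTRL_NO_H2O2")
})

test_that("planted raft residents are recovered with high sensitivity and
           precision on synthetic defaults", {
  params <- simulation_params(n_proteins = 1000L, seed = 33L)
  sim <- simulate_experiment(params)
  m <- preprocess(filter_identified(sim$table))
  cls <- classify_raft_resident(m, sim$design)
  truth_raft <- sim$truth$protein_id[sim$truth$class == "raft_resident"]
  called <- cls$protein_id[cls$label == "raft_resident"]
  tp <- length(intersect(called, truth_raft))
  expect_gte(tp / length(truth_raft), 0.90)
  expect_gte(tp / length(called), 0.95)
})

test_that("baseline-difference ranking matches a manual sort", {
  design <- default_design()
  m <- make_condition_matrix(list(
    a = cond_means(ctrl = 20, act0 = 21),
    b = cond_means(ctrl = 20, act0 = 25),
    c = cond_means(ctrl = 20, act0 = 19),
    d = cond_means(ctrl = 20, act0 = 23)
  ), design)
  rk <- rank_by_baseline_difference(m, design, top_n = 4)
  expect_equal(rk$protein_id, c("b", "d", "a", "c"))
  expect_equal(rk$difference, c(5, 3, 1, -1))
  expect_true(all(diff(rk$difference) <= 0))
  # identical conditions: all-zero differences, stable input order
  m0 <- make_condition_matrix(list(a = cond_means(), b = cond_means()), design)
  rk0 <- rank_by_baseline_difference(m0, design)
  expect_equal(rk0$protein_id, c("a", "b"))
  expect_equal(rk0$difference, c(0, 0))
})

test_that("detection presence follows the min-replicates rule on raw data", {
  design <- default_design()
  intens <- matrix(100, 3, 18, dimnames = list(NULL, design$sample_id))
  intens[2, ] <- 0
  intens[2, "ACT_5_R1"] <- 50            # 1 of 3 replicates
  intens[3, c("ACT_0_R1", "ACT_0_R2")] <- 0
  tab <- protein_quant_table(paste0("P", 1:3), paste0("G", 1:3), rep(3L, 3),
                             rep(FALSE, 3), rep(FALSE, 3), intens)
  pm1 <- detect_condition_presence(tab, design, min_replicates = 1)
  expect_true(all(pm1["P1", ]))
  expect_equal(unname(pm1["P2", ]), colnames(pm1) == "ACT_5")
  expect_true(pm1["P3", "ACT_0"])        # 1 of 3 nonzero suffices
  pm2 <- detect_condition_presence(tab, design, min_replicates = 2)
  expect_false(pm2["P2", "ACT_5"])
  expect_false(pm2["P3", "ACT_0"])
  # empty table -> empty matrix
  empty <- tab[0, ]
  attr(empty, "sample_ids") <- table_samples(tab)
  class(empty) <- class(tab)
  expect_equal(nrow(detect_condition_presence(empty, design)), 0L)
})

test_that("exclusive sets match a hand truth table and counts are conserved", {
  conds <- RAFT_CONDITIONS
  pm <- rbind(
    everywhere = rep(TRUE, 6),
    resting_only = conds %in% c("CTRL_NO_H2O2", "CTRL_NO_BP", "ACT_0"),
    activated_one = conds %in% "ACT_10",
    activated_all = conds %in% c("ACT_5", "ACT_10", "ACT_15"),
    nowhere = rep(FALSE, 6)
  )
  colnames(pm) <- conds
  sets <- exclusive_sets(pm)
  expect_equal(sets$sets$common_to_all, "everywhere")
  expect_equal(sets$sets$resting_only, "resting_only")
  expect_setequal(sets$sets$activated_only,
                  c("activated_one", "activated_all"))
  expect_equal(sets$sets$all_activation_not_controls, "activated_all")
  # pattern counts sum to the number of proteins present somewhere
  expect_equal(sum(sets$patterns$count), 4L)
  expect_error(exclusive_sets(pm, activation_conditions = "ACT_99"), "ACT_99")
})

test_that("hypergeometric overlap matches exhaustive enumeration on a small
           universe", {
  universe <- paste0("u", 1:10)
  reference <- universe[1:4]
  query <- universe[c(1, 2, 5, 6, 7)]
  res <- overlap_with_reference(query, reference, 10)
  expect_equal(res$n_overlap, 2L)
  expect_equal(res$fraction_of_query, 0.4)
  # oracle: all 10-choose-5 draws, fraction overlapping reference >= 2
  draws <- combn(10, 5)
  overlaps <- colSums(draws <= 4)
  expect_equal(res$p_value, mean(overlaps >= 2))
  # identities
  expect_equal(overlap_with_reference(query, query, 10)$fraction_of_query, 1)
  disjoint <- overlap_with_reference(universe[1:3], universe[4:6], 10)
  expect_equal(disjoint$n_overlap, 0L)
  expect_equal(disjoint$p_value, 1)
  expect_error(overlap_with_reference(universe, reference, 5), "universe")
})
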
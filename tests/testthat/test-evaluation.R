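# docking-power metrics

toy_sets <- function(df) {
  sp <- scored_poses(data.frame(df, is_crystal = FALSE,
                                pose_id = sprintf("p%d", seq_len(nrow(df)))),
                     df$score, drop_crystal = FALSE)
  sp
}

test_that("AUROC: perfect order, constant scores, hand-counted oracle", {
  expect_equal(auroc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)), 0.5)
  # 6-pose pooled toy: count concordant/tied pairs by hand
  s <- c(0.9, 0.7, 0.7, 0.4, 0.3, 0.1)
  pos <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  # pairs (pos, neg): (1,2)W (1,4)W (1,6)W (3,2)T (3,4)W (3,6)W (5,2)L (5,4)L (5,6)W
  expect_equal(auroc(s, pos), (6 + 0.5) / 9)
  expect_error(auroc(c(1, 2), c(TRUE, TRUE)), "both classes")
})

test_that("AUROC agrees with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (rep in 1:20) {
    y <- sample(c(TRUE, FALSE), 40, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    s <- rnorm(40) + y * runif(1, 0, 2)
    ref <- as.numeric(suppressMessages(
      pROC::auc(pROC::roc(response = y, predictor = s, quiet = TRUE,
                          direction = "<"))))
    expect_equal(auroc(s, y), ref, tolerance = 1e-12)
  }
})

test_that("inter metrics pool all poses; intra metrics average complexes", {
  df <- data.frame(
    complex_id = rep(c("a", "b"), each = 4),
    dock_rank = rep(1:4, 2),
    rmsd = c(0.5, 3, 4, 5, 1.0, 2.5, 3.5, 6),
    score = c(0.9, 0.2, 0.15, 0.1, 0.3, 0.8, 0.25, 0.05))
  sets <- toy_sets(df)
  im <- inter_metrics(sets)
  expect_equal(unname(im["inter_auroc"]),
               auroc(sets$score, sets$label == "positive"))
  expect_equal(unname(im["inter_rs"]),
               cor(sets$score, sets$rmsd, method = "spearman"))
  # complex a perfectly ranked (AUROC 1), complex b has its positive second
  intra <- intra_metrics(sets)
  expect_equal(unname(intra["intra_auroc"]), mean(c(1, 2 / 3)))
})

test_that("undefined complexes are skipped and counted in intra metrics", {
  df <- data.frame(
    complex_id = c(rep("good", 4), rep("allneg", 3)),
    dock_rank = c(1:4, 1:3),
    rmsd = c(0.5, 3, 4, 5, 4, 5, 6),
    score = c(0.9, 0.5, 0.4, 0.2, 0.7, 0.6, 0.5))
  intra <- intra_metrics(toy_sets(df))
  expect_equal(unname(intra["intra_auroc"]), 1)
  expect_equal(attr(intra, "n_skipped_auroc"), 1)
  all_neg <- toy_sets(df[df$complex_id == "allneg", ])
  expect_error(intra_metrics(all_neg), "no evaluable")
  expect_error(inter_metrics(all_neg), "single class")
})

test_that("success rates count top-k near-native hits with tie rules", {
  df <- data.frame(
    complex_id = rep(c("a", "b", "c"), each = 3),
    dock_rank = rep(1:3, 3),
    rmsd = c(1.0, 4, 5,  2.5, 4, 5,  0.4, 3, 6),
    score = rep(c(0.9, 0.5, 0.1), 3))
  sets <- toy_sets(df)
  expect_equal(success_rate(sets, 1), 2 / 3)
  expect_equal(ceiling_rate(sets), 2 / 3)
  # third-ranked pose at 1.8 rescues a complex at k = 3
  df2 <- data.frame(complex_id = "a", dock_rank = 1:3,
                    rmsd = c(4, 5, 1.8), score = c(0.9, 0.5, 0.1))
  expect_equal(success_rate(toy_sets(df2), 1), 0)
  expect_equal(success_rate(toy_sets(df2), 3), 1)
  # score ties break by dock_rank
  df3 <- data.frame(complex_id = "a", dock_rank = c(2, 1),
                    rmsd = c(0.5, 4), score = c(0.7, 0.7))
  expect_equal(success_rate(toy_sets(df3), 1), 0)  # rank 1 (rmsd 4) wins the tie
  expect_error(success_rate(toy_sets(df3), 0), "k must be")
})

test_that("SR1 <= SR2 <= SR3 <= ceiling over 1000 random fixtures", {
  for (seed in 1:1000) {
    sets <- random_scored_sets(seed, n_cx = 4, max_poses = 6)
    s1 <- success_rate(sets, 1); s2 <- success_rate(sets, 2)
    s3 <- success_rate(sets, 3); cl <- ceiling_rate(sets)
    expect_true(s1 <= s2 && s2 <= s3 && s3 <= cl)
  }
})

test_that("metrics are invariant under strictly monotone score transforms", {
  sets <- random_scored_sets(4, n_cx = 10)
  tf <- function(x) exp(3 * x) + 1
  sets2 <- sets; sets2$score <- tf(sets2$score)
  expect_equal(inter_metrics(sets2), inter_metrics(sets))
  expect_equal(as.numeric(intra_metrics(sets2)), as.numeric(intra_metrics(sets)))
  expect_equal(success_rate(sets2, 1), success_rate(sets, 1))
  expect_equal(success_rate(sets2, 3), success_rate(sets, 3))
  expect_equal(funnel_analysis(sets2), funnel_analysis(sets))
})

test_that("funnel analysis matches a hand-computed Spearman per window", {
  df <- data.frame(complex_id = "a", dock_rank = 1:5,
                   rmsd = c(0.5, 1.2, 1.8, 2.6, 7.0),
                   score = c(0.9, 0.6, 0.7, 0.3, 0.1))
  sets <- toy_sets(df)
  fu <- funnel_analysis(sets)
  expect_equal(unname(fu["rs_0_2"]),
               cor(c(0.9, 0.6, 0.7), c(0.5, 1.2, 1.8), method = "spearman"))
  expect_equal(unname(fu["rs_0_3"]),
               cor(df$score[1:4], df$rmsd[1:4], method = "spearman"))
  expect_equal(unname(fu["rs_0_10"]),
               cor(df$score, df$rmsd, method = "spearman"))
  # a window holding a single pose is skipped (NA when nothing is evaluable)
  df_one <- data.frame(complex_id = "b", dock_rank = 1:3,
                       rmsd = c(1.0, 5, 6), score = c(0.8, 0.4, 0.2))
  expect_true(is.na(funnel_analysis(toy_sets(df_one))["rs_0_2"]))
  # strictly monotone scoring gives |Rs| = 1 in every evaluable window
  mono <- toy_sets(data.frame(complex_id = "a", dock_rank = 1:6,
                              rmsd = c(0.4, 1.1, 1.9, 2.8, 4.5, 9),
                              score = c(6, 5, 4, 3, 2, 1) / 10))
  fu <- funnel_analysis(mono)
  expect_true(all(abs(fu[!is.na(fu)] + 1) < 1e-12))
})

test_that("ensemble pooling judges success on the selected pose's own RMSD", {
  # ligand L docked into 2 receptors; best score sits in receptor r2 where
  # the pose is near-native
  df <- data.frame(
    complex_id = c("r1", "r1", "r2", "r2"),
    dock_rank = c(1, 2, 1, 2),
    rmsd = c(4.0, 5.0, 1.0, 6.0),
    score = c(0.6, 0.2, 0.9, 0.1))
  sets <- toy_sets(df)
  pooled <- ensemble_pool(sets, c(r1 = "L", r2 = "L"))
  expect_equal(length(unique(pooled$complex_id)), 1)
  expect_equal(nrow(pooled), 4)
  expect_equal(success_rate(pooled, 1), 1)      # top pose (0.9) is near-native
  # flip scores so the top pose across receptors is a decoy
  sets2 <- sets; sets2$score <- c(0.9, 0.2, 0.6, 0.1)
  expect_equal(success_rate(ensemble_pool(sets2, c(r1 = "L", r2 = "L")), 1), 0)
  # pooling a single set changes nothing
  one <- toy_sets(df[df$complex_id == "r1", ])
  expect_equal(success_rate(ensemble_pool(one, c(r1 = "L")), 1),
               success_rate(one, 1))
  expect_error(ensemble_pool(sets, c(r1 = "L")), "no ligand id")
})

test_that("bootstrap resamples complexes with a seeded generator", {
  sets <- random_scored_sets(21, n_cx = 12)
  b1 <- bootstrap_metric(function(s) success_rate(s, 1), sets, n_boot = 200,
                         seed = 5)
  b2 <- bootstrap_metric(function(s) success_rate(s, 1), sets, n_boot = 200,
                         seed = 5)
  expect_identical(b1, b2)
  # constant statistic: sd 0
  bc <- bootstrap_metric(function(s) 0.7, sets, n_boot = 50, seed = 1)
  expect_equal(unname(bc), c(0.7, 0))
  # bootstrap mean close to the point estimate
  pt <- success_rate(sets, 1)
  b <- bootstrap_metric(function(s) success_rate(s, 1), sets, n_boot = 1000,
                        seed = 2)
  expect_lte(abs(b["mean"] - pt), 3 * max(b["sd"], 1e-3))
})

test_that("paired Wilcoxon comparison flags real differences only", {
  x <- c(0.61, 0.55, 0.70, 0.64, 0.58, 0.66, 0.72, 0.60)
  same <- compare_methods(x, x)
  expect_equal(same$p_value, 1)
  expect_false(same$significant)
  set.seed(2)
  a <- runif(30, 0.5, 0.9)
  res <- compare_methods(a + 0.05, a)
  expect_lt(res$p_value, 0.05)
  expect_true(res$significant)
  expect_warning(compare_methods(c(1, 2), c(0.5, 1.5)), "underpowered")
})

test_that("crystal poses are dropped from test sets; AUROC barely moves", {
  ds <- planted_signal_dataset(n_complexes = 8, seed = 62, n_poses = 12,
                               include_crystal = TRUE)
  tab <- do.call(rbind, lapply(ds$pose_sets, label_pose_set))
  score <- -tab$rmsd + rnorm(nrow(tab), 0, 0.4)  # a decent scorer
  with_x <- scored_poses(tab, score, drop_crystal = FALSE)
  no_x <- scored_poses(tab, score, drop_crystal = TRUE)
  expect_equal(sum(with_x$is_crystal), 8)
  expect_equal(sum(no_x$is_crystal), 0)
  expect_equal(nrow(no_x), nrow(with_x) - 8)
  expect_lte(abs(unname(inter_metrics(with_x)["inter_auroc"] -
                          inter_metrics(no_x)["inter_auroc"])), 0.05)
})

test_that("evaluation reports aggregate and serialize", {
  sets <- random_scored_sets(8, n_cx = 10)
  rep_ <- evaluate_report(sets, n_boot = 100, seed = 3)
  expect_true(rep_$success_rates["sr1"] <= rep_$success_rates["sr3"])
  expect_true(rep_$success_rates["sr3"] <= rep_$ceiling)
  f <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep_, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$success_rates$sr1, unname(rep_$success_rates["sr1"]))
  expect_equal(back$ceiling, rep_$ceiling)
})
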
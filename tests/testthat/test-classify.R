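# Tight, well-separated clusters: any sane classifier should be near-perfect.
separable_features <- function(n = 40, sd = 0.01, seed = 1) {
  set.seed(seed)
  centers <- rbind(modal = c(0, 0), breathy = c(1, 0), pressed = c(0, 1))
  do.call(rbind, lapply(rownames(centers), function(cl)
    data.frame(F1 = rnorm(n, centers[cl, 1], sd),
               F2 = rnorm(n, centers[cl, 2], sd),
               label = cl)))
}

test_that("all five classifiers are near-perfect on separable clusters", {
  feats <- separable_features(n = 40, seed = 21)
  for (kind in c("ld", "dt", "svm", "knn")) {
    e <- train_eval_cv(feats, kind, seed = 22, feature_cols = c("F1", "F2"))
    expect_gte(e$accuracy, 0.99)
  }
  e <- train_eval_nn(feats, seed = 23, feature_cols = c("F1", "F2"))
  expect_gte(e$accuracy, 0.99)
})

test_that("permuted labels give chance-level accuracy", {
  feats <- separable_features(n = 40, seed = 24)
  accs <- vapply(1:10, function(i) {
    set.seed(500 + i)
    feats$label <- sample(feats$label)
    train_eval_cv(feats, "knn", seed = 600 + i,
                  feature_cols = c("F1", "F2"))$accuracy
  }, 0)
  expect_lt(abs(mean(accs) - 1 / 3), 0.05)
})

test_that("evaluation is deterministic under a fixed seed", {
  feats <- simulate_feature_cohort(25, seed = 25)
  a <- train_eval_cv(feats, "svm", seed = 26)
  b <- train_eval_cv(feats, "svm", seed = 26)
  expect_identical(a$accuracy, b$accuracy)
  expect_identical(a$confusion, b$confusion)
  n1 <- train_eval_nn(feats, seed = 27)
  n2 <- train_eval_nn(feats, seed = 27)
  expect_identical(n1$accuracy_repeats, n2$accuracy_repeats)
})

test_that("confusion rows are normalized and accuracy is the weighted trace", {
  feats <- simulate_feature_cohort(30, seed = 28)
  e <- train_eval_cv(feats, "ld", seed = 29)
  expect_equal(unname(rowSums(e$confusion)), rep(1, 3), tolerance = 1e-9)
  w <- rowSums(e$counts) / sum(e$counts)
  expect_equal(sum(w * diag(e$confusion)), e$accuracy, tolerance = 1e-12)
  expect_true(all(e$metrics$TPR >= 0 & e$metrics$TPR <= 1))
  expect_true(all(e$metrics$FPR >= 0 & e$metrics$FPR <= 1))
  expect_true(all(e$metrics$AUC >= 0 & e$metrics$AUC <= 1))
})

test_that("per-type metrics match direct arithmetic and the AUC oracle", {
  m <- per_type_metrics(rbind(c(8, 2), c(3, 7)))
  expect_equal(m$TPR, c(0.8, 0.7))
  expect_equal(m$FPR, c(0.3, 0.2))
  # perfect classifier
  p <- per_type_metrics(diag(c(5, 7, 9)))
  expect_true(all(p$TPR == 1) && all(p$FPR == 0))
  # rank-statistic AUC agrees with an independent implementation
  set.seed(30)
  sc <- rnorm(200)
  y <- rbinom(200, 1, plogis(2 * sc))
  expect_equal(auc_rank(sc, y == 1),
               as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
  # label-independent scores hover at 0.5
  aucs <- vapply(1:20, function(i) {
    set.seed(700 + i)
    auc_rank(rnorm(300), sample(c(TRUE, FALSE), 300, replace = TRUE))
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("chi-square comparison behaves at both extremes", {
  mk_eval <- function(n_correct, n) {
    structure(list(classifier = "x", n_correct = n_correct, n = n),
              class = "vt_eval")
  }
  # identical performance: statistic 0, p = 1
  r <- chi_square_compare(list(a = mk_eval(50, 100), b = mk_eval(50, 100)))
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)
  # chance vs perfect at n = 300: overwhelming evidence
  r2 <- chi_square_compare(list(chance = mk_eval(100, 300),
                                perfect = mk_eval(300, 300)))
  expect_lt(r2$p_value, 0.001)
  expect_true(r2$significant)
})

test_that("the subset plan has the right shapes", {
  plan <- feature_subset_plan()
  expect_equal(length(plan), 10)
  lofo <- plan[grepl("^-", names(plan))]
  expect_true(all(vapply(lofo, length, 0L) == 6))
  expect_setequal(plan$spectral, c("H1", "H2", "H3", "H4", "SE"))
  expect_setequal(plan$stability, c("Jr", "Sr"))
  expect_equal(length(plan$full), 7)
})

test_that("the evaluation grid covers subsets x classifiers with averages", {
  feats <- simulate_feature_cohort(25, seed = 31)
  plan <- feature_subset_plan()[c("full", "-Sr", "stability")]
  rep <- run_lofo(feats, classifiers = c("ld", "knn"), plan = plan,
                  seed = 32)
  expect_equal(dim(rep$accuracy), c(3L, 2L))
  expect_equal(rep$per_set$mean, unname(rowMeans(rep$accuracy)))
  expect_equal(rep$per_classifier$mean, unname(colMeans(rep$accuracy)))
  expect_equal(length(rep$entries), 6)
})

test_that("an uninformative extra feature barely moves accuracy", {
  feats <- simulate_feature_cohort(100, noise_feature = TRUE, seed = 33)
  full <- feature_subset_plan(c("H1", "H2", "H3", "H4", "SE", "Jr", "Sr",
                                "X0"), lofo = FALSE, spectral = FALSE,
                              stability = FALSE)
  plan <- c(full, list(`-X0` = setdiff(full$full, "X0")))
  rep <- run_lofo(feats, classifiers = c("ld", "svm"), plan = plan,
                  seed = 34)
  expect_lt(abs(mean(rep$accuracy["full", ]) - mean(rep$accuracy["-X0", ])),
            0.02)
})

test_that("single-feature baseline reports a confusion matrix per feature", {
  feats <- simulate_feature_cohort(40, seed = 35)
  sf <- single_feature_ld(feats, feature_names = c("H1", "SE", "Sr"),
                          seed = 36)
  expect_named(sf, c("H1", "SE", "Sr"))
  for (e in sf) {
    expect_equal(unname(rowSums(e$confusion)), rep(1, 3), tolerance = 1e-9)
    expect_gt(e$accuracy, 1 / 3)   # all three are informative features
  }
})
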
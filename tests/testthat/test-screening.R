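test_that("Fleiss kappa is 1 for unanimous panels", {
  expect_equal(fleiss_kappa(rbind(c(5, 0, 0, 0), c(5, 0, 0, 0))), 1)
  # perfect agreement with two categories used
  expect_equal(fleiss_kappa(rbind(c(5, 0, 0, 0), c(0, 5, 0, 0))), 1)
})

test_that("Fleiss kappa matches the long-hand oracle on small matrices", {
  counts <- rbind(c(3, 0), c(2, 1), c(1, 2))
  expect_equal(fleiss_kappa(counts), oracle_fleiss(counts),
               tolerance = 1e-12)
  set.seed(6)
  for (i in 1:5) {
    m <- t(rmultinom(8, 4, prob = runif(3)))
    expect_equal(fleiss_kappa(m), oracle_fleiss(m), tolerance = 1e-12)
  }
})

test_that("kappa is near zero for chance-level panels and within [-1, 1]", {
  spec <- panel_spec(rater_confusion = matrix(0.25, 4, 4))
  tab <- simulate_panel(rep(c("modal", "breathy", "pressed", "none"), 200),
                        spec, seed = 10)
  k <- fleiss_kappa(tab)
  expect_lt(abs(k), 0.05)
  expect_gte(k, -1)
  expect_lte(k, 1)
})

test_that("kappa rejects unbalanced panels", {
  tab <- data.frame(sample_id = c("a", "a", "b"),
                    rater_id = c("r1", "r2", "r1"),
                    category = c("modal", "modal", "breathy"))
  expect_error(fleiss_kappa(tab), "unbalanced")
})

test_that("ICC(2,1) matches a long-hand ANOVA decomposition", {
  m <- rbind(c(9, 2, 5), c(6, 1, 3), c(8, 4, 6), c(7, 1, 2))
  # long-hand two-way decomposition
  n <- 4; k <- 3
  gm <- mean(m)
  msr <- k * sum((rowMeans(m) - gm)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - gm)^2) / (k - 1)
  mse <- (sum((m - gm)^2) - (n - 1) * msr - (k - 1) * msc) /
    ((n - 1) * (k - 1))
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(icc_two_way_random(m), icc_oracle, tolerance = 1e-12)
})

test_that("ICC is 1 for identical raters and penalizes constant offsets", {
  m <- cbind(c(1, 5, 9, 3), c(1, 5, 9, 3))
  expect_equal(icc_two_way_random(m), 1)
  off <- cbind(c(1, 5, 9, 3), c(3, 7, 11, 5))
  expect_lt(icc_two_way_random(off), 1)
  expect_gt(icc_two_way_random(off), 0)
  expect_error(icc_two_way_random(cbind(c(1, 1), c(1, 1))), "variance")
})

test_that("pure-sample filtering follows the 4-of-5 confidence-gated rule", {
  mk <- function(cats, confs)
    data.frame(sample_id = "s1", rater_id = paste0("r", 1:5),
               category = cats, confidence = confs)
  # unanimous, confident -> pure
  s <- filter_pure(mk(rep("breathy", 5), rep(0.9, 5)))
  expect_equal(unname(s$pure_labels["s1"]), "breathy")
  # 4 of 5 agree but one agreeing rater below the gate -> rejected
  s <- filter_pure(mk(c(rep("modal", 4), "none"),
                      c(0.9, 0.9, 0.9, 0.7, 0.95)))
  expect_equal(length(s$pure_labels), 0)
  # 3-2 split -> rejected
  s <- filter_pure(mk(c(rep("pressed", 3), rep("modal", 2)), rep(0.95, 5)))
  expect_equal(length(s$pure_labels), 0)
  # "none" majority is never pure
  s <- filter_pure(mk(rep("none", 5), rep(0.99, 5)))
  expect_equal(length(s$pure_labels), 0)
})

test_that("pure filtering is monotone in both thresholds", {
  spec <- panel_spec(rater_confusion =
                       0.7 * diag(4) + 0.3 * matrix(0.25, 4, 4))
  tab <- simulate_panel(rep(c("modal", "breathy", "pressed"), 60), spec,
                        seed = 12)
  n_pure <- function(agree, conf)
    length(filter_pure(tab, agree, conf)$pure_labels)
  base <- n_pure(4, 0.8)
  expect_lte(n_pure(5, 0.8), base)
  expect_lte(n_pure(4, 0.9), base)
  expect_lte(n_pure(5, 0.95), base)
  expect_gte(n_pure(3, 0.5), base)
})

test_that("identity-confusion panels screen to 100% pure with true labels", {
  truth <- stats::setNames(rep(c("modal", "breathy", "pressed"), 20),
                           sprintf("t%02d", 1:60))
  tab <- simulate_panel(truth, panel_spec(confidence = 0.95), seed = 13)
  s <- filter_pure(tab)
  expect_equal(length(s$rejected_ids), 0)
  expect_equal(unname(s$pure_labels[names(truth)]), unname(truth))
})

test_that("panel simulation is reproducible and validates inputs", {
  a <- simulate_panel(c("modal", "breathy", "pressed"), panel_spec(),
                      seed = 14)
  b <- simulate_panel(c("modal", "breathy", "pressed"), panel_spec(),
                      seed = 14)
  expect_identical(a, b)
  expect_error(panel_spec(rater_confusion = matrix(1, 4, 4)),
               "row-stochastic")
  expect_error(simulate_panel(c("modal", "weird"), panel_spec()),
               "labels")
})

test_that("intra-rater reliability is perfect for error-free raters", {
  truth <- stats::setNames(rep(c("modal", "breathy", "pressed"), 10),
                           sprintf("u%02d", 1:30))
  tab <- simulate_panel(truth, panel_spec(n_duplicates = 10,
                                          confidence = 0.9), seed = 15)
  irr <- intra_rater_reliability(tab)
  expect_equal(nrow(irr), 5)
  expect_true(all(irr$kappa == 1))
  expect_true(all(irr$n_pairs == 10))
})
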
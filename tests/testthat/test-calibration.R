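test_that("yield classification applies cultivar cut-offs with ties high", {
  expect_equal(as.character(classify_yield(18000, "Prata")), "high")
  expect_equal(as.character(classify_yield(17500, "Prata")), "high")
  expect_equal(as.character(classify_yield(17499, "Prata")), "low")
  expect_equal(as.character(classify_yield(24999, "Cavendish")), "low")
  expect_equal(as.character(classify_yield(25000, "Cavendish")), "high")
  expect_error(classify_yield(10000, "Gros Michel"), "Gros Michel")
  expect_error(classify_yield(-5, "Prata"), "positive")
})

test_that("AUC follows the Mann-Whitney pair counting", {
  expect_equal(compute_auc(c(0.9, 0.7, 0.3, 0.1), c("high", "high", "low", "low")), 1)
  expect_equal(compute_auc(rep(0.5, 6), rep(c("high", "low"), 3)), 0.5)
  # brute-force oracle over all positive-negative pairs
  scores <- c(0.9, 0.8, 0.4, 0.2)
  labels <- c("high", "low", "high", "low")
  pairs <- expand.grid(p = which(labels == "high"),
                       n = which(labels == "low"))
  brute <- mean(ifelse(scores[pairs$p] > scores[pairs$n], 1,
                       ifelse(scores[pairs$p] == scores[pairs$n], 0.5, 0)))
  expect_equal(brute, 0.75)
  expect_equal(compute_auc(scores, labels), 0.75)
  # agreement with an established implementation on random data incl. ties
  set.seed(20)
  s <- round(stats::runif(60), 1)
  y <- sample(c("high", "low"), 60, replace = TRUE)
  expect_equal(compute_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(
                 response = y, predictor = s, levels = c("low", "high"),
                 direction = "<", quiet = TRUE))))
  # invariance under strictly monotone transforms
  expect_equal(compute_auc(exp(3 * s), y), compute_auc(s, y))
  expect_error(compute_auc(s, rep("high", 60)), "both classes")
})

test_that("confusion quadrants follow the yield-by-prediction semantics", {
  actual <- factor(c("high", "low", "low", "high"),
                   levels = c("low", "high"))
  predicted <- factor(c("high", "high", "low", "low"),
                      levels = c("low", "high"))
  expect_equal(as.character(partition_confusion(actual, predicted)),
               c("TN", "FN", "TP", "FP"))
})

test_that("classification accuracy and the uniformity test match hand values", {
  expect_equal(classification_accuracy(c(TN = 2, FN = 1, TP = 1, FP = 0)),
               0.75)
  expect_equal(classification_accuracy(c(TN = 9, FN = 0, TP = 0, FP = 0)), 1)
  expect_equal(classification_accuracy(c(TN = 3, FN = 3, TP = 3, FP = 3)),
               0.5)
  expect_error(classification_accuracy(c(TN = 0, FN = 0, TP = 0, FP = 0)),
               "no records")
  expect_equal(chi_square_uniform(c(10, 10, 10, 10))$statistic, 0)
  # hand computation: E = 10; 90 + 10 + 10 + 10
  expect_equal(chi_square_uniform(c(40, 0, 0, 0))$statistic, 120)
  set.seed(21)
  cnt <- rpois(4, 30)
  res <- chi_square_uniform(cnt)
  e <- sum(cnt) / 4
  expect_equal(res$statistic, sum((cnt - e)^2 / e))
  expect_equal(res$p_value, stats::pchisq(res$statistic, df = 3,
                                          lower.tail = FALSE))
})

test_that("cross-validated probabilities are deterministic and calibrated", {
  rec <- small_dataset(n_prata = 120, n_cav = 0, seed = 30L)
  p1 <- fit_yield_classifier(rec, folds = 5, seed = 99)
  p2 <- fit_yield_classifier(rec, folds = 5, seed = 99)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))
  # shuffled labels destroy the signal
  shuffled <- rec
  set.seed(31)
  shuffled$yield <- sample(shuffled$yield)
  auc_null <- compute_auc(fit_yield_classifier(shuffled, folds = 5,
                                               seed = 99),
                          classify_yield(shuffled$yield,
                                         shuffled$cultivar))
  expect_lt(abs(auc_null - 0.5), 0.12)
  high_only <- rec[classify_yield(rec$yield, rec$cultivar) == "high", ]
  expect_error(fit_yield_classifier(high_only), "each yield class")
  expect_error(fit_yield_classifier(rec, features = "altitude"),
               "unknown feature")
})

test_that("a separable signal yields near-perfect cross-validated AUC", {
  # yield class a deterministic function of the tissue K level
  rec <- small_dataset(n_prata = 120, n_cav = 0, seed = 32L)
  clr_k <- cndiag:::records_clr_matrix(rec)[, "K"]
  rec$yield <- ifelse(clr_k > stats::median(clr_k), 30000, 5000)
  p <- fit_yield_classifier(rec, folds = 5, seed = 7)
  expect_gte(compute_auc(p, classify_yield(rec$yield, rec$cultivar)), 0.95)
})

test_that("the nnet learner is available behind the same contract", {
  rec <- small_dataset(n_prata = 100, n_cav = 0, seed = 33L)
  p1 <- fit_yield_classifier(rec, learner = "nnet", folds = 4, seed = 5)
  p2 <- fit_yield_classifier(rec, learner = "nnet", folds = 4, seed = 5)
  expect_identical(p1, p2)
  auc <- compute_auc(p1, classify_yield(rec$yield, rec$cultivar))
  expect_gt(auc, 0.5)
})

test_that("clr norms summarize the qualifying specimens", {
  rec <- small_dataset(n_prata = 60, n_cav = 0, seed = 34L)
  # identical specimens: degenerate SDs, means equal that specimen's clr
  one <- rec[rep(3, 5), ]
  one$record_id <- paste0("dup_", 1:5)
  expect_warning(ns <- compute_clr_norms(one, "Prata"), "degenerate")
  expect_equal(unname(ns$clr_sd), rep(0, 14))
  expect_equal(unname(ns$clr_mean),
               unname(cndiag:::records_clr_matrix(one)[1, ]))
  expect_error(compute_clr_norms(rec[1:2, ], "Prata"), "at least 3")
  # TN and TN+FN policies coincide when FN is empty
  q <- factor(rep("TN", nrow(rec)), levels = c("TN", "FN", "TP", "FP"))
  a <- compute_clr_norms(rec, "Prata", q, policy = "TN")
  b <- compute_clr_norms(rec, "Prata", q, policy = "TN+FN")
  expect_equal(a$clr_mean, b$clr_mean)
  expect_equal(a$clr_sd, b$clr_sd)
  expect_lt(abs(sum(a$clr_mean)), 1e-9)
})

test_that("compatibility intervals use linear-interpolation quartiles", {
  base <- record_from_composition(banana_median_composition("Prata"))
  rec <- base[rep(1, 5), ]
  rec$N <- 1:5
  rec$record_id <- paste0("r", 1:5)
  ci <- compute_compatibility_intervals(rec, "Prata")
  expect_equal(ci$q25[ci$component == "N"], 2)
  expect_equal(ci$q75[ci$component == "N"], 4)
  expect_equal(ci$q25[ci$component == "K"], ci$q75[ci$component == "K"])
  expect_error(compute_compatibility_intervals(rec[1:3, ], "Prata"),
               "at least 4")
})

test_that("full calibration conserves counts and accuracy", {
  rec <- small_dataset(n_prata = 150, n_cav = 60, seed = 35L)
  cfg <- pipeline_config(classifier = list(folds = 5, seed = 3))
  cal <- calibrate(rec, cfg)
  counts <- unlist(cal$report$counts)
  expect_equal(sum(counts), nrow(rec))
  expect_equal(cal$report$ca, classification_accuracy(counts))
  expect_equal(as.character(cal$quadrants),
               as.character(partition_confusion(cal$actual,
                                                cal$predicted)))
  for (cv in c("Prata", "Cavendish")) {
    expect_s3_class(cal$norms[[cv]], "norm_set")
    expect_lt(abs(sum(cal$norms[[cv]]$clr_mean)), 1e-9)
    expect_true(all(cal$intervals[[cv]]$q25 <= cal$intervals[[cv]]$q75))
  }
})
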
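test_that("ROC AUC matches hand-derived and degenerate cases", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(1, 0, 1, 0)), 1)
  # 3 concordant of 4 positive x negative pairs
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.2), c(1, 0, 1, 0)), 0.75)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(roc_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("AUCs agree with enumeration oracles on random instances", {
  withr::with_seed(11, {
    for (i in 1:100) {
      n <- sample(5:30, 1)
      labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      scores <- round(stats::runif(n), sample(1:3, 1)) # force ties
      expect_equal(roc_auc(scores, labels), oracle_roc_auc(scores, labels),
                   tolerance = 1e-12)
      expect_equal(pr_auc(scores, labels), oracle_pr_auc(scores, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("ROC AUC agrees with an independent package implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(12, {
    for (i in 1:5) {
      labels <- c(0, 1, sample(0:1, 28, replace = TRUE))
      scores <- stats::runif(30)
      expect_equal(roc_auc(scores, labels),
                   as.numeric(pROC::auc(labels, scores, quiet = TRUE)),
                   tolerance = 1e-12)
    }
  })
})

test_that("best-F1 operating point scans thresholds correctly", {
  op <- best_f1_operating_point(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(op$f1, 1)
  expect_equal(op$sensitivity, 1)
  expect_equal(op$specificity, 1)
  expect_equal(op$accuracy, 1)

  op2 <- best_f1_operating_point(c(0.9, 0.6, 0.4), c(1, 1, 0))
  expect_equal(op2$threshold, 0.6)
  expect_equal(op2$f1, 1)

  # degenerate: everything predicted positive at the lowest threshold
  op3 <- best_f1_operating_point(c(0.5, 0.5, 0.5, 0.9), c(1, 1, 1, 0))
  expect_equal(op3$accuracy, 0.75)

  withr::with_seed(13, {
    for (i in 1:50) {
      labels <- c(0, 1, sample(0:1, 10, replace = TRUE))
      scores <- round(stats::runif(12), 2)
      or <- oracle_best_f1(scores, labels)
      op <- best_f1_operating_point(scores, labels)
      expect_equal(op$f1, or$f1, tolerance = 1e-12)
      expect_equal(op$threshold, or$threshold)
    }
  })
})

test_that("Cohen's kappa matches arithmetic and formula oracles", {
  d <- diag(c(5, 3, 2, 7, 1, 4))
  expect_equal(cohens_kappa(d)$estimate, 1)
  expect_equal(cohens_kappa(d, "quadratic")$estimate, 1)

  # hand arithmetic: po = 0.85, marginals (0.30, 0.70) x (0.35, 0.65)
  # so pe = 0.30*0.35 + 0.70*0.65 = 0.56
  cm <- matrix(c(25, 10, 5, 60), 2) # rows reference: [[25,5],[10,60]]
  k <- cohens_kappa(cm)
  expect_equal(k$estimate, (0.85 - 0.56) / (1 - 0.56), tolerance = 1e-12)
  expect_equal(k$estimate, 0.659, tolerance = 1e-3)
  # CI via SE = sqrt(po(1-po)/n)/(1-pe)
  se <- sqrt(0.85 * 0.15 / 100) / (1 - 0.56)
  expect_equal(k$ci_low, k$estimate - stats::qnorm(0.975) * se,
               tolerance = 1e-12)

  # independence: rows proportional to column marginals
  ind <- outer(c(10, 20, 30), c(2, 3, 5))
  expect_equal(cohens_kappa(ind)$estimate, 0, tolerance = 1e-12)

  withr::with_seed(14, {
    for (i in 1:100) {
      K <- sample(2:6, 1)
      cm <- matrix(stats::rpois(K * K, 4), K)
      cm[1, 1] <- cm[1, 1] + 5 # keep total > 0 and po != pe almost surely
      expect_equal(cohens_kappa(cm)$estimate, oracle_kappa(cm),
                   tolerance = 1e-12)
      expect_equal(cohens_kappa(cm, "quadratic")$estimate,
                   oracle_kappa(cm, quadratic = TRUE), tolerance = 1e-12)
      k <- cohens_kappa(cm)
      expect_lte(k$ci_low, k$estimate)
      expect_gte(k$ci_high, k$estimate)
    }
  })
  expect_error(cohens_kappa(matrix(0, 3, 3)), "empty")
})

test_that("quadratic weights degenerate on 2x2 matrices and respect symmetry", {
  withr::with_seed(15, {
    for (i in 1:30) {
      cm <- matrix(stats::rpois(4, 6) + 1, 2)
      expect_equal(cohens_kappa(cm, "quadratic")$estimate,
                   cohens_kappa(cm, "none")$estimate, tolerance = 1e-12)
    }
    # consistent relabelling leaves unweighted kappa unchanged
    for (i in 1:30) {
      cm <- matrix(stats::rpois(36, 3), 6)
      perm <- sample(6)
      expect_equal(cohens_kappa(cm[perm, perm])$estimate,
                   cohens_kappa(cm)$estimate, tolerance = 1e-12)
    }
  })
})

test_that("accuracy confidence interval is the clipped normal approximation", {
  ci <- accuracy_ci(50, 100)
  expect_equal(ci$estimate, 0.5)
  expect_equal(ci$ci_high - ci$estimate, 0.098, tolerance = 1e-3)
  expect_equal(accuracy_ci(100, 100)$ci_high, 1)
  expect_equal(accuracy_ci(0, 10)$ci_low, 0)
  expect_error(accuracy_ci(1, 0))
})

test_that("evaluation report combines the agreement statistics", {
  withr::with_seed(16, {
    pred <- tibble::tibble(reference = sample(0:5, 60, replace = TRUE))
    pred$predicted <- ifelse(stats::runif(60) < 0.7, pred$reference,
                             sample(0:5, 60, replace = TRUE))
    ev <- evaluate_predictions(pred)
    expect_equal(sum(ev$confusion), 60)
    expect_equal(ev$accuracy$estimate, mean(pred$reference == pred$predicted))
    expect_equal(ev$kappa$estimate, oracle_kappa(ev$confusion),
                 tolerance = 1e-12)
    expect_equal(ev$kappa_quad$estimate,
                 oracle_kappa(ev$confusion, quadratic = TRUE),
                 tolerance = 1e-12)
    td <- tidy(ev)
    expect_equal(td$statistic, c("accuracy", "kappa", "kappa_quad"))
    path <- tempfile(fileext = ".json")
    write_eval_json(ev, path)
    js <- jsonlite::read_json(path, simplifyVector = TRUE)
    expect_equal(js$kappa$estimate, ev$kappa$estimate)
  })
})
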
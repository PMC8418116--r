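# Published validation table for an index of this family: six rows of
# (TP, TN, FP, FN) with the metrics they imply at 1-decimal rounding.
published_rows <- list(
  list(cm = c(53, 125, 21, 3), expected = c(88.1, 94.6, 85.6, 71.6, 97.7)),
  list(cm = c(43, 137, 9, 13), expected = c(89.1, 76.8, 93.8, 82.7, 91.3)),
  list(cm = c(28, 76, 9, 1), expected = c(91.2, 96.6, 89.4, 75.7, 98.7)),
  list(cm = c(26, 78, 7, 3), expected = c(91.2, 89.7, 91.8, 78.8, 96.3)),
  list(cm = c(24, 56, 5, 3), expected = c(90.9, 88.9, 91.8, 82.8, 94.9)),
  list(cm = c(17, 59, 2, 10), expected = c(86.4, 63.0, 96.7, 89.5, 85.5))
)

test_that("confusion metrics reproduce the published validation table rows", {
  for (row in published_rows) {
    m <- confusion_metrics(do.call(confusion_matrix, as.list(row$cm)))
    got <- round(c(m$accuracy, m$sensitivity, m$specificity, m$ppv, m$npv), 1)
    expect_equal(got, row$expected)
  }

  perfect <- confusion_metrics(confusion_matrix(10, 10, 0, 0))
  expect_equal(unlist(perfect[1, 1:5]), rep(100, 5), ignore_attr = TRUE)

  # undefined metrics are NA, never 0
  no_pos <- confusion_metrics(confusion_matrix(0, 10, 0, 0))
  expect_true(is.na(no_pos$sensitivity))
  expect_true(is.na(no_pos$ppv))
  expect_equal(no_pos$specificity, 100)
})

test_that("classification uses the 'value <= cutoff is positive' convention", {
  idx <- c(0.70, 0.85, 0.85, 0.70)
  ref <- c(0.70, 0.70, 0.90, 0.90)
  cm <- classify(idx, ref, index_cutoff = 0.80, reference_cutoff = 0.80)
  expect_equal(c(cm$tp, cm$fn, cm$tn, cm$fp), c(1, 1, 1, 1))

  same <- classify(idx, idx, 0.80, 0.80)
  expect_equal(c(same$fp, same$fn), c(0, 0))

  # boundary: values exactly at the cutoff count as positive
  at <- classify(c(0.80, 0.81), c(0.80, 0.81), 0.80, 0.80)
  expect_equal(c(at$tp, at$tn), c(1, 1))

  expect_error(classify(1:3, 1:2, 0.8), class = "smartffr_invalid_argument")
})

test_that("Pearson correlation passes its sanity cases", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(1, 2, 3, 5)), 0.9827, tolerance = 1e-4)
  expect_error(pearson_r(x, rep(1, 4)), class = "smartffr_undefined_correlation")
  expect_error(pearson_r(1:2, 1:2), class = "smartffr_invalid_argument")
})

test_that("Bland-Altman bias, limits and antisymmetry are correct", {
  y <- c(0.8, 0.9, 0.7)
  same <- bland_altman(y, y)
  expect_equal(c(same$bias, same$sd_diff, same$loa_low, same$loa_high),
               c(0, 0, 0, 0))

  x <- y + c(0.1, -0.1, 0.3)
  ba <- bland_altman(x, y)
  expect_equal(ba$bias, 0.1, tolerance = 1e-12)
  expect_equal(ba$sd_diff, 0.2, tolerance = 1e-12)
  expect_equal(ba$loa_low, -0.292, tolerance = 1e-3)
  expect_equal(ba$loa_high, 0.492, tolerance = 1e-3)

  rev <- bland_altman(y, x)
  expect_equal(rev$bias, -ba$bias)
  expect_equal(rev$loa_low, -ba$loa_high)
  expect_equal(rev$loa_high, -ba$loa_low)

  expect_error(bland_altman(1:2, 1:2), class = "smartffr_invalid_argument")
})

test_that("Bland-Altman limits cover ~95% of large Gaussian samples", {
  set.seed(2024)
  n <- 1e4
  x <- rnorm(n, 0.85, 0.05)
  y <- x + rnorm(n, 0.01, 0.04)
  ba <- bland_altman(x, y)
  d <- x - y
  coverage <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_gt(coverage, 0.93)
  expect_lt(coverage, 0.97)
})

test_that("ROC analysis matches enumeration on its worked cases", {
  perfect <- roc_youden(c(0.70, 0.75, 0.85, 0.90), c(1, 1, 0, 0))
  expect_equal(perfect$auc, 1)
  expect_equal(perfect$youden_cutoff, 0.75)
  expect_equal(perfect$youden_j, 1)

  mixed <- roc_youden(c(0.78, 0.84, 0.82, 0.90), c(1, 1, 0, 0))
  expect_equal(mixed$auc, 0.75)
  expect_equal(mixed$youden_cutoff, 0.84) # tie broken upward
  expect_equal(mixed$youden_j, 0.5)

  ties <- roc_youden(rep(0.8, 6), c(1, 1, 1, 0, 0, 0))
  expect_equal(ties$auc, 0.5)

  expect_error(roc_youden(c(0.7, 0.8), c(1, 1)), class = "smartffr_invalid_argument")
})

test_that("ROC AUC and Youden cutoff agree with brute force on random instances", {
  set.seed(17)
  for (i in 1:25) {
    n <- sample(6:30, 1)
    values <- round(runif(n, 0.5, 1), 2) # rounding forces ties
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) == 0 || sum(labels) == n) next
    r <- roc_youden(values, labels)
    expect_identical(r$auc, brute_force_auc(values, labels))
    bf <- brute_force_youden(values, labels)
    expect_identical(r$youden_cutoff, bf$cutoff)
    expect_equal(r$youden_j, bf$j, tolerance = 1e-12)
  }
})

test_that("ROC AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(19)
  values <- runif(60, 0.5, 1)
  labels <- rbinom(60, 1, 0.4)
  ours <- roc_youden(values, labels)
  theirs <- suppressMessages(pROC::roc(labels, values, direction = ">"))
  expect_equal(ours$auc, as.numeric(pROC::auc(theirs)), tolerance = 1e-12)
})

test_that("DeLong comparison handles degeneracy, symmetry and a brute-force toy", {
  scores <- c(0.7, 0.8, 0.75, 0.9, 0.85, 0.95)
  labels <- c(1, 1, 1, 0, 0, 0)
  same <- delong_compare(scores, scores, labels)
  expect_identical(same$z_statistic, 0)
  expect_identical(same$p_value, 1)

  other <- c(0.72, 0.9, 0.7, 0.88, 0.8, 0.93)
  a <- delong_compare(scores, other, labels)
  b <- delong_compare(-scores, -other, labels)
  expect_equal(abs(a$z_statistic), abs(b$z_statistic), tolerance = 1e-12)
  expect_equal(a$auc_1, 1 - b$auc_1, tolerance = 1e-12)

  # brute-force placement-value oracle on the 3-vs-3 toy
  oracle_components <- function(sc) {
    x <- -sc[labels == 1]
    y <- -sc[labels == 0]
    psi <- matrix(0, 3, 3)
    for (i in 1:3) {
      for (j in 1:3) {
        psi[i, j] <- if (x[i] > y[j]) 1 else if (x[i] == y[j]) 0.5 else 0
      }
    }
    list(auc = mean(psi), v10 = rowMeans(psi), v01 = colMeans(psi))
  }
  o1 <- oracle_components(scores)
  o2 <- oracle_components(other)
  expect_equal(a$auc_1, o1$auc)
  expect_equal(a$auc_2, o2$auc)
  expect_equal(a$var_1, var(o1$v10) / 3 + var(o1$v01) / 3, tolerance = 1e-12)
  expect_equal(a$cov_12,
               cov(cbind(o1$v10, o2$v10))[1, 2] / 3 +
                 cov(cbind(o1$v01, o2$v01))[1, 2] / 3,
               tolerance = 1e-12)
})

test_that("DeLong z agrees with pROC's paired test", {
  skip_if_not_installed("pROC")
  set.seed(23)
  n <- 50
  labels <- rbinom(n, 1, 0.4)
  if (sum(labels) < 2) labels[1:2] <- 1
  s1 <- runif(n, 0.5, 1) - 0.1 * labels
  s2 <- runif(n, 0.5, 1) - 0.05 * labels
  ours <- delong_compare(s1, s2, labels)
  r1 <- suppressMessages(pROC::roc(labels, s1, direction = ">"))
  r2 <- suppressMessages(pROC::roc(labels, s2, direction = ">"))
  theirs <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  expect_equal(abs(ours$z_statistic), abs(unname(theirs$statistic)), tolerance = 1e-9)
  expect_equal(ours$p_value, theirs$p.value, tolerance = 1e-9)
})

test_that("evaluate_index bundles the validation layer coherently", {
  set.seed(29)
  ffr <- runif(80, 0.6, 1)
  data <- tibble::tibble(smartffr = pmin(1, ffr + rnorm(80, 0, 0.02)),
                         ffr_measured = ffr)
  ev <- evaluate_index(data)
  expect_s3_class(ev, "diagnostic_evaluation")
  expect_equal(ev$roc$youden_cutoff, ev$index_cutoff)
  expect_equal(ev$n, 80)
  g <- glance(ev)
  expect_equal(g$auc, ev$roc$auc)
  expect_true(all(c("accuracy", "sensitivity", "specificity") %in% names(g)))
})
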
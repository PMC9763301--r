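# Evaluation protocol: confusion counts, Sn/Sp/Acc/MCC, AUC.

test_that("confusion counts enumerate correctly", {
  expect_equal(confusion_counts(c(1, 1, 0, 0), c(1, 0, 0, 1)),
               list(TP = 1L, TN = 1L, FP = 1L, FN = 1L))
  expect_equal(confusion_counts(c(1, 0, 1), c(1, 0, 1)),
               list(TP = 2L, TN = 1L, FP = 0L, FN = 0L))
  balanced <- c(rep(1, 5), rep(0, 5))
  allpos <- confusion_counts(balanced, rep(1, 10))
  expect_equal(allpos$FP, 5L)
  expect_error(confusion_counts(c(1, 0), c(1)), "length")
  expect_error(confusion_counts(c(1, 2), c(1, 0)), "0/1")
})

test_that("metrics from counts follow the standard definitions", {
  perfect <- compute_metrics(list(TP = 50L, TN = 50L, FP = 0L, FN = 0L))
  expect_equal(perfect$Sn, 1); expect_equal(perfect$Sp, 1)
  expect_equal(perfect$Acc, 1); expect_equal(perfect$MCC, 1)

  chance <- compute_metrics(list(TP = 25L, TN = 25L, FP = 25L, FN = 25L))
  expect_equal(chance$Acc, 0.5); expect_equal(chance$MCC, 0)
})

test_that("independent-benchmark confusion counts reproduce the published metric row", {
  # 106 positives, 106 negatives; counts inverted from Sn = 0.9151, Sp = 0.8490
  m <- compute_metrics(list(TP = 97L, FN = 9L, TN = 90L, FP = 16L))
  expect_equal(round(m$Sn, 4), 0.9151)
  expect_equal(round(m$Sp, 4), 0.8491)
  expect_equal(round(m$Acc, 4), 0.8821)
  expect_equal(round(m$MCC, 4), 0.7658)
})

test_that("degenerate MCC denominators report 0 with a flag", {
  expect_warning(m <- compute_metrics(list(TP = 10L, FN = 0L, TN = 0L, FP = 5L)),
                 "MCC")
  expect_equal(m$MCC, 0)
  expect_true(m$mcc_degenerate)
})

test_that("metrics agree with a brute-force per-sample recount on random vectors", {
  set.seed(66)
  for (rep in 1:100) {
    n <- sample(4:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))  # both classes present
    preds <- sample(0:1, n, replace = TRUE)
    got <- compute_metrics(confusion_counts(labels, preds))
    ref <- oracle_metrics(labels, preds)
    for (f in c("Sn", "Sp", "Acc", "MCC"))
      expect_equal(got[[f]], ref[[f]], tolerance = 1e-12)
  }
})

test_that("MCC symmetry: joint class swap preserves it, prediction negation negates it", {
  set.seed(77)
  for (rep in 1:20) {
    n <- 30
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    preds <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    m <- compute_metrics(confusion_counts(labels, preds))$MCC
    m_swap <- compute_metrics(confusion_counts(1 - labels, 1 - preds))$MCC
    m_neg <- compute_metrics(confusion_counts(labels, 1 - preds))$MCC
    expect_equal(m_swap, m, tolerance = 1e-12)
    expect_equal(m_neg, -m, tolerance = 1e-12)
  }
})

test_that("accuracy on balanced data equals (Sn + Sp) / 2", {
  set.seed(88)
  for (rep in 1:20) {
    n <- 40
    labels <- rep(0:1, each = n / 2)
    preds <- sample(0:1, n, replace = TRUE)
    m <- compute_metrics(confusion_counts(labels, preds))
    expect_equal(m$Acc, (m$Sn + m$Sp) / 2, tolerance = 1e-12)
  }
})

test_that("AUC handles perfect, reversed, and partially discordant rankings", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.3, 0.1)), 1.0)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9)), 0.0)
  # one of four positive-negative pairs discordant
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_error(roc_auc(c(1, 1), c(0.5, 0.6)), "both classes")
})

test_that("AUC equals the brute-force pairwise estimator exactly, including ties", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(5:200, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 2)     # rounding induces ties
    expect_identical(roc_auc(labels, scores) == oracle_auc(labels, scores), TRUE)
  }
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(123)
  labels <- sample(0:1, 80, replace = TRUE)
  labels[1:2] <- 0:1
  scores <- runif(80)
  ref <- as.numeric(suppressMessages(pROC::auc(labels, scores,
                                               levels = c(0, 1), direction = "<")))
  expect_equal(roc_auc(labels, scores), ref, tolerance = 1e-12)
})

test_that("metrics_table renders 4-decimal rows with the requested label column", {
  rows <- list(A = metrics_report(c(1, 1, 0, 0), c(0.9, 0.4, 0.2, 0.6)))
  tab <- metrics_table(rows, label_col = "Data")
  expect_equal(names(tab), c("Data", "Sn", "Sp", "Acc", "MCC", "AUC"))
  expect_equal(tab$Data, "A")
  expect_equal(tab$Sn, 0.5)
  path <- tempfile(fileext = ".tsv")
  write_metrics_tsv(tab, path)
  back <- read.delim(path)
  expect_equal(back$Acc, tab$Acc)
})
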
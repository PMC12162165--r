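test_that("confusion matrices count true-by-predicted pairs", {
  m <- confusion_matrix(c("a", "a", "b"), c("a", "b", "b"))
  expect_equal(m["a", "a"], 1L)
  expect_equal(m["a", "b"], 1L)
  expect_equal(m["b", "b"], 1L)
  expect_equal(m["b", "a"], 0L)

  y <- c("x", "y", "z", "x")
  md <- confusion_matrix(y, y)
  expect_true(all(md[upper.tri(md)] == 0) && all(md[lower.tri(md)] == 0))

  set.seed(1)
  for (i in 1:5) {
    n <- sample(10:200, 1)
    yt <- sample(letters[1:4], n, replace = TRUE)
    yp <- sample(letters[1:4], n, replace = TRUE)
    expect_equal(sum(confusion_matrix(yt, yp, letters[1:4])), n)
  }
  expect_error(confusion_matrix("a", "q", classes = c("a", "b")),
               "outside")
  expect_error(confusion_matrix(c("a", "a"), "a"), "equal length")
})

test_that("row normalization gives each true class 1.00 samples", {
  m <- confusion_matrix(rep(c("a", "b", "c"), c(10, 5, 0)),
                        c(rep("a", 8), "b", "c", rep("b", 5)),
                        classes = c("a", "b", "c"))
  nm <- normalize_rows(m)
  expect_equal(unname(rowSums(nm)[c("a", "b")]), c(1, 1),
               tolerance = 1e-12)
  expect_equal(attr(nm, "zero_rows"), "c")
  expect_equal(unname(nm["a", ]), c(0.8, 0.1, 0.1))

  r <- matrix(c(2, 6, 2), 1)
  m1 <- confusion_matrix(rep("a", 10),
                         rep(c("a", "b", "c"), c(2, 6, 2)),
                         classes = c("a", "b", "c"))
  expect_equal(unname(normalize_rows(m1)["a", ]), c(0.2, 0.6, 0.2))
})

test_that("one-vs-rest collapse follows the TP/TN/FP/FN definitions", {
  m <- confusion_matrix(rep(c("p", "n"), c(10, 10)),
                        rep(c("p", "n", "p", "n"), c(8, 2, 1, 9)),
                        classes = c("p", "n"))
  bc <- binary_counts(m, "p")
  expect_equal(bc$TP, 8); expect_equal(bc$FN, 2)
  expect_equal(bc$FP, 1); expect_equal(bc$TN, 9)

  md <- confusion_matrix(letters[1:3], letters[1:3])
  for (cl in letters[1:3]) {
    b <- binary_counts(md, cl)
    expect_equal(b$FP + b$FN, 0)
  }

  set.seed(2)
  yt <- sample(letters[1:4], 80, replace = TRUE)
  yp <- sample(letters[1:4], 80, replace = TRUE)
  mm <- confusion_matrix(yt, yp, letters[1:4])
  pos_totals <- vapply(letters[1:4], function(cl) {
    b <- binary_counts(mm, cl); b$TP + b$FN
  }, 0)
  expect_equal(sum(pos_totals), 80)
  expect_error(binary_counts(mm, "z"), "unknown")
})

test_that("metrics reproduce hand arithmetic and flag zero denominators", {
  m <- confusion_matrix(rep(c("p", "n"), c(10, 10)),
                        rep(c("p", "n", "p", "n"), c(8, 2, 1, 9)),
                        classes = c("p", "n"))
  met <- classification_metrics(binary_counts(m, "p"))
  expect_equal(unname(met["accuracy"]), 0.85)
  expect_equal(unname(met["precision"]), 8 / 9, tolerance = 1e-12)
  expect_equal(unname(met["sensitivity"]), 0.80)
  expect_equal(unname(met["specificity"]), 0.90)
  expect_equal(unname(met["f1"]), 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8),
               tolerance = 1e-12)
  expect_equal(unname(round(met["f1"], 4)), 0.8421)

  perfect <- classification_metrics(
    binary_counts(confusion_matrix(c("p", "n"), c("p", "n")), "p"))
  expect_true(all(unclass(perfect) == 1))

  # no positive predictions and no positive truths: precision undefined
  m0 <- confusion_matrix(rep("n", 5), rep("n", 5), classes = c("p", "n"))
  met0 <- classification_metrics(binary_counts(m0, "p"))
  expect_true(is.na(met0["precision"]))
  expect_true("precision" %in% attr(met0, "undefined"))
  expect_equal(unname(met0["specificity"]), 1)
})

test_that("macro averaging is symmetric and hits chance level", {
  md <- confusion_matrix(letters[1:3], letters[1:3])
  mm <- macro_metrics(md)
  expect_true(all(unclass(mm) == 1))

  set.seed(3)
  yt <- sample(smell_classes(), 5000, replace = TRUE)
  yp <- sample(smell_classes(), 5000, replace = TRUE)
  m5 <- confusion_matrix(yt, yp, smell_classes())
  mac <- macro_metrics(m5)
  expect_lt(abs(unname(mac["sensitivity"]) - 0.2), 0.02)

  # invariance to class-order permutation
  m5p <- confusion_matrix(yt, yp, rev(smell_classes()))
  expect_equal(c(unclass(macro_metrics(m5p))), c(unclass(mac)),
               tolerance = 1e-12)

  expect_error(macro_metrics(confusion_matrix("a", "a")), "2 classes")
})

test_that("binary macro metrics average the two one-vs-rest views and
           accuracy equals trace/n", {
  set.seed(4)
  yt <- sample(c("p", "n"), 60, replace = TRUE)
  yp <- sample(c("p", "n"), 60, replace = TRUE)
  m <- confusion_matrix(yt, yp, c("p", "n"))
  mac <- macro_metrics(m)
  a <- unclass(classification_metrics(binary_counts(m, "p")))
  b <- unclass(classification_metrics(binary_counts(m, "n")))
  expect_equal(c(unclass(mac)), c((a + b) / 2), tolerance = 1e-12)
  expect_equal(unname(a["accuracy"]), sum(diag(m)) / sum(m))
})

test_that("metrics agree with caret to numerical precision on random
           matrices", {
  suppressWarnings(suppressMessages(library(caret)))
  set.seed(5)
  for (i in 1:100) {
    C <- sample(3:5, 1)
    classes <- letters[1:C]
    n <- sample(30:80, 1)
    yt <- sample(classes, n, replace = TRUE)
    yp <- sample(classes, n, replace = TRUE)
    m <- confusion_matrix(yt, yp, classes)
    ref <- caret::confusionMatrix(factor(yp, classes), factor(yt, classes))
    for (cl in classes) {
      ours <- unclass(classification_metrics(binary_counts(m, cl)))
      theirs <- ref$byClass[paste0("Class: ", cl), ]
      pairs <- c(sensitivity = "Sensitivity", specificity = "Specificity",
                 precision = "Precision", f1 = "F1")
      for (k in names(pairs)) {
        o <- ours[[k]]; t <- unname(theirs[[pairs[[k]]]])
        if (is.na(o) || is.na(t)) {
          # caret codes 0/0 cases as NA too; both must agree it is undefined
          expect_true(is.na(o) && is.na(t))
        } else {
          expect_equal(o, t, tolerance = 1e-12)
        }
      }
    }
    expect_equal(sum(diag(m)) / sum(m),
                 unname(ref$overall["Accuracy"]), tolerance = 1e-12)
  }
})
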
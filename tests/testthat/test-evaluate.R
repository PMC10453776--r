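test_that("confusion counts the four cells with diabetic as positive", {
  cm <- confusion(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_equal(unclass(cm)[c("tp", "fn", "fp", "tn")],
               list(tp = 2L, fn = 0L, fp = 0L, tn = 2L))
  cm2 <- confusion(c(1, 0), c(0, 0))
  expect_equal(unlist(unclass(cm2)), c(tp = 0L, fn = 1L, fp = 0L, tn = 1L))
  withr::with_seed(3, {
    truth <- rbinom(70, 1, 0.3); pred <- rbinom(70, 1, 0.5)
  })
  cm3 <- confusion(truth, pred)
  expect_equal(cm3$tp + cm3$fn + cm3$fp + cm3$tn, 70L)
  expect_error(confusion(c(1, 0), c(1, 0, 0)), class = "microdiab_shape_error")
})

test_that("the metric suite reproduces the worked confusion-matrix examples", {
  r <- metrics(confusion_cells(18, 2, 4, 46))
  expect_equal(r$accuracy, 64 / 70, tolerance = 1e-12)
  expect_equal(r$recall, 0.90)
  expect_equal(r$precision, 18 / 22, tolerance = 1e-12)
  expect_equal(r$f1, 36 / 42, tolerance = 1e-12)
  expect_equal(r$jaccard, 0.75)
  expect_equal(r$mcc, 0.79796, tolerance = 1e-4)
  expect_equal(r$kappa, 0.79612, tolerance = 1e-4)
  expect_equal(r$accuracy + r$error_rate, 1)

  perfect <- metrics(confusion_cells(20, 0, 0, 50))
  expect_equal(unlist(perfect[c("accuracy", "recall", "precision", "f1",
                                "jaccard", "mcc", "kappa")]),
               rep(1, 7), ignore_attr = TRUE)

  mid <- metrics(confusion_cells(12, 8, 16, 34))
  expect_equal(mid$mcc, 0.25820, tolerance = 2e-4)
  expect_equal(mid$kappa, 0.25, tolerance = 1e-12)
})

test_that("zero-division cells are reported as 0 with a flag", {
  r <- metrics(confusion_cells(0, 0, 0, 10)) # no positives, none predicted
  expect_equal(r$recall, 0)
  expect_equal(r$precision, 0)
  expect_true(all(c("recall", "precision") %in% attr(r, "zero_division")))
  expect_error(metrics(confusion_cells(0, 0, 0, 0)), class = "microdiab_domain_error")
})

test_that("metric inversion recovers the unique integer confusion matrix", {
  # exhaustive oracle: enumerate all (tp, tn) with 20 positives / 50 negatives
  exhaustive <- function(acc, rec) {
    hits <- list()
    for (tp in 0:20) for (tn in 0:50) {
      if (abs(tp / 20 - rec) < 5e-3 && abs((tp + tn) / 70 - acc) < 5e-3) {
        hits[[length(hits) + 1L]] <- c(tp, tn)
      }
    }
    hits
  }
  for (case in list(c(0.914285, 0.90, 18, 2, 4, 46),
                    c(0.657142, 0.60, 12, 8, 16, 34),
                    c(1.0, 1.0, 20, 0, 0, 50))) {
    hits <- exhaustive(case[1], case[2])
    expect_length(hits, 1L)
    cm <- invert_metrics(case[1], case[2], 20, 50)
    expect_equal(unlist(unclass(cm)),
                 c(tp = case[3], fn = case[4], fp = case[5], tn = case[6]),
                 ignore_attr = TRUE)
  }
  expect_error(invert_metrics(0.9107, 0.9, 20, 50),
               class = "microdiab_inversion_error") # 0.9107 * 70 is not integral
})

test_that("accuracy and recall round-trip through inversion and metrics", {
  withr::with_seed(5, {
    for (i in 1:50) {
      tp <- sample(0:20, 1); tn <- sample(0:50, 1)
      acc <- (tp + tn) / 70; rec <- tp / 20
      cm <- invert_metrics(acc, rec, 20, 50)
      r <- metrics(cm)
      expect_equal(r$accuracy, acc, tolerance = 1e-12)
      expect_equal(r$recall, rec, tolerance = 1e-12)
    }
  })
})

test_that("jaccard equals F1/(2 - F1) on random confusion matrices", {
  withr::with_seed(11, {
    cells <- matrix(sample(0:60, 4 * 1e4, replace = TRUE), ncol = 4)
  })
  for (i in seq_len(nrow(cells))) {
    if (sum(cells[i, ]) == 0) next
    r <- metrics(confusion_cells(cells[i, 1], cells[i, 2], cells[i, 3], cells[i, 4]))
    expect_equal(r$jaccard, r$f1 / (2 - r$f1), tolerance = 1e-12)
  }
})

test_that("kappa is centred at zero for label-independent predictors", {
  withr::with_seed(13, {
    kappas <- vapply(seq_len(1e5), function(i) {
      tp <- rbinom(1, 20, 0.4); fn <- 20 - tp
      fp <- rbinom(1, 50, 0.4); tn <- 50 - fp
      metrics(confusion_cells(tp, fn, fp, tn))$kappa
    }, numeric(1))
  })
  expect_lt(abs(mean(kappas)), 0.01)
})

test_that("mean squared error follows its definition", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(0, 1), c(1, 0)), 1)
  withr::with_seed(17, { a <- rnorm(30); b <- rnorm(30) })
  expect_equal(mse(a, b), sum((a - b)^2) / 30, tolerance = 1e-12)
  expect_error(mse(1:3, 1:4), class = "microdiab_length_error")
  expect_error(mse(numeric(0), numeric(0)), class = "microdiab_length_error")
})

test_that("stratified folds partition the cohort with (2, 5) fold composition", {
  x <- generate_cohort(synthetic_config(n_genes = 60, n_pos = 20, n_neg = 50,
                                        n_informative = 0, seed = 19))
  spec <- pipeline_spec(reduction = reduction_config("dfa", n_out = 6),
                        kind = "lr")
  res <- kfold_evaluate(x, spec, k = 10, seed = 7)
  expect_identical(sort(unique(res$fold)), 1:10)
  expect_true(all(table(res$fold) == 7L))
  for (f in 1:10) {
    expect_identical(sum(x$labels[res$fold == f] == 1L), 2L)
    expect_identical(sum(x$labels[res$fold == f] == 0L), 5L)
  }
  # pooled report equals the metrics of the summed per-fold confusion cells
  fold_cms <- lapply(1:10, function(f) {
    confusion(res$truth[res$fold == f], res$predictions[res$fold == f])
  })
  summed <- Reduce(function(a, b) confusion_cells(a$tp + b$tp, a$fn + b$fn,
                                                  a$fp + b$fp, a$tn + b$tn),
                   fold_cms)
  expect_equal(unclass(res$report), unclass(metrics(summed)), ignore_attr = TRUE)
})

test_that("a collapsed-decision classifier scores the majority-class accuracy", {
  x <- generate_cohort(synthetic_config(n_genes = 60, n_pos = 20, n_neg = 50,
                                        n_informative = 0, seed = 23))
  spec <- pipeline_spec(reduction = reduction_config("dfa", n_out = 6),
                        kind = "svm_rbf",
                        params = list(gamma = 1e-10, C = 1, class_weight_pos = 1))
  res <- kfold_evaluate(x, spec, k = 10, seed = 3)
  expect_equal(res$report$accuracy, 50 / 70, tolerance = 1e-12)
})
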
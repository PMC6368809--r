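test_that("the per-protein metrics evaluate their closed forms", {
  expect_equal(recall(3, 4), 0.75)
  expect_equal(precision(3, 6), 0.5)
  expect_equal(f_value(0.5, 0.75), 0.6)
  expect_equal(f_value(0, 0), 0)
  expect_error(recall(3, 0), class = "pl_undefined_metric")
  expect_error(precision(1, 0), class = "pl_undefined_metric")
  expect_error(recall(5, 4), class = "pl_bad_arg")
})

test_that("the F-value lies between precision and recall", {
  withr::with_seed(99, {
    p <- stats::runif(500, 0.01, 1)
    r <- stats::runif(500, 0.01, 1)
    f <- f_value(p, r)
    expect_true(all(f >= pmin(p, r) - 1e-12))
    expect_true(all(f <= pmax(p, r) + 1e-12))
  })
})

test_that("evaluate scores set overlaps per protein and macro-averages", {
  gold <- tibble::tibble(protein = c("p1", "p1", "p2", "p2"),
                         category = c("a", "c", "x", "y"))
  pred <- tibble::tibble(protein = c("p1", "p1", "p2", "p2"),
                         category = c("a", "b", "x", "y"))
  ev <- evaluate(pred, gold)
  per <- tidy(ev)
  expect_equal(per$c_p, c(1L, 2L))
  expect_equal(per$n_p, c(2L, 2L))
  expect_equal(per$m_p, c(2L, 2L))
  expect_equal(per$recall, c(0.5, 1))
  expect_equal(glance(ev)$macro_recall, 0.75)
  expect_equal(glance(ev)$macro_f, mean(c(0.5, 1)))

  # perfect predictions
  evp <- evaluate(gold, gold)
  expect_equal(glance(evp)$macro_f, 1)

  # invariant to row order and duplicates
  ev2 <- evaluate(pred[c(4, 1, 3, 2, 1, 1), ], gold[4:1, ])
  expect_equal(glance(ev2), glance(ev))

  # proteins without predictions are skipped with a warning
  expect_warning(ev3 <- evaluate(pred[pred$protein == "p1", ], gold),
                 "skipping")
  expect_equal(glance(ev3)$n_skipped, 1L)
  expect_equal(glance(ev3)$macro_recall, 0.5)

  expect_error(evaluate(tibble::tibble(protein = "zz", category = "a"), gold),
               class = "pl_missing_gold")
})

test_that("k-fold assignment is balanced and reproducible", {
  f10 <- kfold_split(sprintf("p%02d", 1:10), k = 5, seed = 1)
  expect_equal(as.integer(sort(table(f10$fold))), rep(2L, 5L))
  expect_identical(f10, kfold_split(sprintf("p%02d", 1:10), k = 5, seed = 1))
  expect_false(identical(f10$protein,
                         kfold_split(sprintf("p%02d", 1:10), k = 5, seed = 2)$protein))

  f11 <- kfold_split(sprintf("p%02d", 1:11), k = 5, seed = 1)
  expect_equal(as.integer(sort(table(f11$fold), decreasing = TRUE)),
               c(3L, 2L, 2L, 2L, 2L))
  # union of folds is the full set; folds disjoint by construction
  expect_setequal(f11$protein, sprintf("p%02d", 1:11))

  expect_error(kfold_split(c("a", "b"), k = 1), class = "pl_bad_arg")
  expect_error(kfold_split(c("a", "b"), k = 3), class = "pl_bad_arg")
})
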
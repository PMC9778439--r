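test_that("confusion matrices follow the GT-rows / P-columns convention", {
  cm <- confusion(c("a", "b", "a"), c("a", "b", "a"), c("a", "b"))
  expect_equal(unname(diag(cm)), c(2, 1))
  expect_equal(sum(cm) - sum(diag(cm)), 0)

  t1 <- reference_benchmarks()$tables$texture3
  expect_equal(unname(rowSums(t1)), c(635, 280, 25))

  tr <- c("a", "b", "a", "b"); pr <- c("a", "a", "b", "b")
  expect_equal(unclass(confusion(tr, pr, c("a", "b"))),
               t(unclass(confusion(pr, tr, c("a", "b")))), ignore_attr = TRUE)
  expect_error(confusion("a", "z", class_names = c("a", "b")),
               "outside class_names")
})

test_that("overall accuracy reproduces the printed table values", {
  tabs <- reference_benchmarks()$tables
  expect_equal(round_half_up(overall_accuracy(tabs$overall5), 2), 0.93)
  expect_equal(overall_accuracy(tabs$overall5), 871 / 940)
  expect_equal(round_half_up(overall_accuracy(tabs$sparse2), 2), 0.84)
  expect_equal(overall_accuracy(confusion_matrix(diag(3))), 1)
  expect_error(overall_accuracy(confusion_matrix(matrix(0, 2, 2))), "empty")
})

test_that("balanced accuracy matches the printed expressions in both modes", {
  tabs <- reference_benchmarks()$tables
  expect_equal(balanced_accuracy(tabs$texture3),
               (631 / 635 + 270 / 280 + 18 / 25) / 3)
  expect_equal(round_half_up(balanced_accuracy(tabs$texture3), 2), 0.89)
  expect_equal(balanced_accuracy(tabs$overall5, round_recalls_first = TRUE),
               (0.98 + 0.69 + 0.96 + 0.76 + 0.94) / 5)
  expect_equal(balanced_accuracy(confusion_matrix(diag(4))), 1)
  expect_equal(balanced_accuracy(confusion_matrix(diag(4)),
                                 round_recalls_first = TRUE), 1)
  bad <- confusion_matrix(matrix(c(3, 1, 0, 0), 2, byrow = TRUE),
                          c("x", "y"))
  expect_error(balanced_accuracy(bad), "y")
})

test_that("rounding the recalls first only changes table 4 at two decimals", {
  tabs <- reference_benchmarks()$tables
  for (nm in c("texture3", "rare2", "sparse2"))
    expect_lt(abs(balanced_accuracy(tabs[[nm]]) -
                    balanced_accuracy(tabs[[nm]], TRUE)), 0.01)
  expect_equal(round_half_up(balanced_accuracy(tabs$overall5), 2), 0.86)
  expect_equal(round_half_up(balanced_accuracy(tabs$overall5, TRUE), 2), 0.87)
})

test_that("support-weighted F1 reproduces the printed values", {
  tabs <- reference_benchmarks()$tables
  expect_equal(round(weighted_f1(tabs$rare2), 4), 0.9221)
  expect_equal(round_half_up(weighted_f1(tabs$sparse2), 2), 0.86)
  expect_equal(round_half_up(weighted_f1(tabs$overall5), 2), 0.92)
  expect_equal(weighted_f1(confusion_matrix(diag(5))), 1)

  # 2-class balanced matrix with symmetric errors: weighted F1 = plain F1
  sym <- confusion_matrix(matrix(c(45, 5, 5, 45), 2, byrow = TRUE))
  f1 <- 2 * 0.9 * 0.9 / 1.8
  expect_equal(weighted_f1(sym), f1)
})

test_that("metrics are 1 on diagonal matrices and bounded in [0,1]", {
  withr::with_seed(2, for (i in 1:20) {
    k <- sample(2:5, 1)
    m <- matrix(rpois(k * k, 5) + diag(k), k)
    cm <- confusion_matrix(m)
    for (v in c(overall_accuracy(cm), balanced_accuracy(cm), weighted_f1(cm)))
      expect_true(v >= 0 && v <= 1)
  })
})

test_that("size error reports implement the printed formulas", {
  same <- size_error_report(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$E_bar, 0)
  expect_equal(same$RMSD, 0)
  expect_equal(same$cc, 1)

  dup <- size_error_report(c(5, 5), c(5.16, 5.16))
  expect_equal(dup$E_bar, 0.16)

  pair <- size_error_report(c(4, 5), c(5, 4))
  expect_equal(pair$RMSD, 1)
  expect_equal(pair$E_bar, 1)
  expect_equal(pair$R2, 1 - 2 / 0.5)

  expect_error(size_error_report(c(0, 5), c(1, 5)), "positive")
  expect_error(size_error_report(5, 5.1))   # N >= 2
})

test_that("retrieval rate is the plain percentage", {
  expect_equal(retrieval_rate(940, 1270), 940 * 100 / 1270)
  expect_gt(retrieval_rate(940, 1270), 74)
})
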
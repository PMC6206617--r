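test_that("confusion_matrix scores the four quadrants and skips excluded rows", {
  # one gold exemplar per quadrant
  gold <- tibble::tibble(
    assay_id = c("CHEMBL985321", "CHEMBL843578", "CHEMBL851918",
                 "CHEMBL2020189"),
    curator_positive = c(TRUE, FALSE, FALSE, TRUE))
  pred <- tibble::tibble(
    assay_id = gold$assay_id,
    annotated = c(TRUE, FALSE, TRUE, FALSE))
  cm <- confusion_matrix(pred, gold)
  expect_equal(cm[c("tp", "tn", "fp", "fn")],
               list(tp = 1L, tn = 1L, fp = 1L, fn = 1L),
               ignore_attr = TRUE)

  all_pos <- tibble::tibble(assay_id = letters[1:5],
                            curator_positive = TRUE)
  cm2 <- confusion_matrix(
    tibble::tibble(assay_id = letters[1:5], annotated = TRUE), all_pos)
  expect_equal(unlist(cm2[c("tp", "fn", "fp", "tn")]),
               c(tp = 5, fn = 0, fp = 0, tn = 0))

  gold$excluded <- c(FALSE, TRUE, FALSE, FALSE)
  cm3 <- confusion_matrix(pred, gold)
  expect_equal(cm3$n_scored, 3)
  expect_equal(cm3$n_excluded, 1)
  expect_equal(cm3$tn, 0)

  expect_error(confusion_matrix(pred, dplyr::bind_rows(gold, gold[1, ])),
               "duplicate")
})

test_that("the packaged validation exemplars score their labelled quadrants", {
  ann <- annotate_corpus(validation_corpus(), seed_dictionary())
  gold <- example_gold()
  cm <- confusion_matrix(ann$summary, gold)
  quad <- table(gold$quadrant)
  expect_equal(cm$tp, unname(quad["TP"]), ignore_attr = TRUE)
  expect_equal(cm$tn, unname(quad["TN"]), ignore_attr = TRUE)
  expect_equal(cm$fp, unname(quad["FP"]), ignore_attr = TRUE)
  expect_equal(cm$fn, unname(quad["FN"]), ignore_attr = TRUE)
})

test_that("missing predictions default to negative with a warning, or error in strict mode", {
  gold <- tibble::tibble(assay_id = c("a", "b"),
                         curator_positive = c(TRUE, FALSE))
  pred <- tibble::tibble(assay_id = "a", annotated = TRUE)
  expect_warning(cm <- confusion_matrix(pred, gold), "predicted-negative")
  expect_equal(cm$tn, 1)
  expect_error(confusion_matrix(pred, gold, strict_missing = TRUE), "b")
})

test_that("confusion matrix cells are invariant to gold-row order", {
  out <- generate_corpus(corpus_spec(200, seed = 9L))
  gold <- generate_gold(out$truth, flip_fp = 5, flip_fn = 5, seed = 2L)
  ann <- annotate_corpus(identify_corpus(out$records)$accepted,
                         seed_dictionary())
  cm1 <- confusion_matrix(ann$summary, gold)
  cm2 <- confusion_matrix(ann$summary, gold[rev(seq_len(nrow(gold))), ])
  expect_identical(unclass(cm1), unclass(cm2))
  # brute-force four-way tally
  scored <- gold[!gold$excluded, ]
  p <- setNames(ann$summary$annotated, ann$summary$assay_id)[scored$assay_id]
  expect_equal(cm1$tp, sum(p & scored$curator_positive))
  expect_equal(cm1$fn, sum(!p & scored$curator_positive))
  expect_equal(cm1$fp, sum(p & !scored$curator_positive))
  expect_equal(cm1$tn, sum(!p & !scored$curator_positive))
})

test_that("classification statistics match their closed forms", {
  s <- classification_stats(confusion_cells(10, 0, 0, 10))
  expect_equal(unlist(unclass(s)), c(sensitivity = 1, specificity = 1,
                                     precision = 1, f1 = 1))
  s2 <- classification_stats(confusion_cells(7, 3, 2, 8))
  expect_equal(s2$sensitivity, 0.7)
  expect_equal(s2$specificity, 0.8)
  expect_equal(s2$precision, 7 / 9)
  expect_equal(s2$f1, 14 / 19)
})

test_that("undefined denominators are reported as NA, never zero", {
  s <- classification_stats(confusion_cells(0, 0, 0, 10))
  expect_true(is.na(s$sensitivity))
  expect_true(is.na(s$precision))
  expect_true(is.na(s$f1) || s$f1 == 0)  # 2TP+FP+FN == 0 here
  expect_equal(s$specificity, 1)
})

test_that("F1 is the harmonic mean of precision and sensitivity (random matrices)", {
  set.seed(101)
  for (i in 1:50) {
    cells <- as.list(sample(0:50, 4, replace = TRUE))
    names(cells) <- c("tp", "fn", "fp", "tn")
    s <- classification_stats(do.call(confusion_cells, cells))
    if (!anyNA(c(s$precision, s$sensitivity, s$f1)) &&
        (s$precision + s$sensitivity) > 0) {
      expect_equal(s$f1, 2 * s$precision * s$sensitivity /
                           (s$precision + s$sensitivity))
    }
  }
})

test_that("swapping curator labels permutes the matrix cells as expected", {
  set.seed(77)
  ids <- sprintf("A%03d", 1:120)
  gold <- tibble::tibble(assay_id = ids,
                         curator_positive = runif(120) < 0.6)
  pred <- tibble::tibble(assay_id = ids, annotated = runif(120) < 0.5)
  cm <- confusion_matrix(pred, gold)
  flipped <- dplyr::mutate(gold, curator_positive = !curator_positive)
  cmf <- confusion_matrix(pred, flipped)
  expect_equal(c(cmf$tp, cmf$fn, cmf$fp, cmf$tn),
               c(cm$fp, cm$tn, cm$tp, cm$fn))
})
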
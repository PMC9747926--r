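test_that("segmentation metrics follow their defining formulas", {
  rep <- segmentation_metrics(confusion_counts(3, 0, 1, 1))
  expect_equal(rep$precision, 0.75)
  expect_equal(rep$recall, 0.75)
  expect_equal(rep$f1, 0.75)
  expect_equal(rep$iou, 0.60)

  zero <- segmentation_metrics(confusion_counts(0, 0, 0, 0))
  expect_equal(c(zero$recall, zero$precision, zero$f1, zero$iou),
               c(0, 0, 0, 0))
  expect_true(all(c("recall", "precision", "f1") %in% zero$degenerate))

  # the overall candidate accuracy is reported separately from recall
  rep2 <- segmentation_metrics(confusion_counts(2, 5, 1, 2))
  expect_equal(rep2$candidate_accuracy, 0.7)
  expect_equal(rep2$recall, 0.5)
})

test_that("F1 and IoU satisfy their algebraic identities", {
  set.seed(91)
  for (i in 1:50) {
    cc <- confusion_counts(sample(0:50, 1), sample(0:50, 1),
                           sample(0:50, 1), sample(0:50, 1))
    rep <- segmentation_metrics(cc)
    if (!length(rep$degenerate)) {
      expect_equal(rep$f1, 2 * rep$iou / (1 + rep$iou), tolerance = 1e-12)
      expect_lte(rep$iou, rep$precision + 1e-12)
      expect_lte(rep$iou, rep$recall + 1e-12)
    }
  }
})

test_that("metrics are invariant under scaling all counts", {
  cc1 <- segmentation_metrics(confusion_counts(3, 7, 2, 5))
  cc4 <- segmentation_metrics(confusion_counts(12, 28, 8, 20))
  expect_equal(cc1$recall, cc4$recall)
  expect_equal(cc1$precision, cc4$precision)
  expect_equal(cc1$f1, cc4$f1)
  expect_equal(cc1$iou, cc4$iou)
})

test_that("classification metrics follow their defining formulas", {
  rep <- classification_metrics(confusion_counts(44, 45, 5, 6,
                                                 level = "image"))
  expect_equal(rep$sensitivity, 44 / 50)
  expect_equal(rep$specificity, 45 / 50)
  expect_equal(rep$ppv, 44 / 49)
  expect_equal(rep$accuracy, 89 / 100)

  perfect <- classification_metrics(confusion_counts(10, 10, 0, 0,
                                                     level = "image"))
  expect_equal(c(perfect$sensitivity, perfect$specificity,
                 perfect$ppv, perfect$accuracy), rep(1, 4))

  allneg <- classification_metrics(confusion_counts(0, 10, 0, 10,
                                                    level = "image"))
  expect_equal(allneg$sensitivity, 0)
  expect_equal(allneg$specificity, 1)
  expect_true("ppv" %in% allneg$degenerate)
})

test_that("blob matching counts overlaps and missed lesions", {
  dm <- c(20L, 20L)
  gt <- matrix(FALSE, dm[1], dm[2])
  gt[3:8, 3:8] <- TRUE          # lesion A
  gt[14:18, 14:18] <- TRUE      # lesion B, never touched

  # no candidates at all: only the missed components count
  none <- label_blobs(matrix(FALSE, dm[1], dm[2]))
  cc <- match_blobs(none, character(0), gt)
  expect_equal(c(cc$tp, cc$tn, cc$fp, cc$fn), c(0, 0, 0, 2))

  # empty ground truth, no candidates: all zeros
  cc0 <- match_blobs(none, character(0), matrix(FALSE, dm[1], dm[2]))
  expect_equal(c(cc0$tp, cc0$tn, cc0$fp, cc0$fn), c(0, 0, 0, 0))

  # one candidate fully inside lesion A, classified hemorrhagic:
  # tp = 1, and lesion B alone remains a false negative
  cand <- matrix(FALSE, dm[1], dm[2]); cand[4:6, 4:6] <- TRUE
  blobs <- label_blobs(cand)
  cc1 <- match_blobs(blobs, "hemorrhagic", gt)
  expect_equal(c(cc1$tp, cc1$tn, cc1$fp, cc1$fn), c(1, 0, 0, 1))

  # same candidate classified nonhemorrhagic: fn from both the blob and
  # the untouched lesion
  cc2 <- match_blobs(blobs, "nonhemorrhagic", gt)
  expect_equal(c(cc2$tp, cc2$tn, cc2$fp, cc2$fn), c(0, 0, 0, 2))

  # candidate with under-threshold overlap is a false positive when
  # called hemorrhagic
  off <- matrix(FALSE, dm[1], dm[2]); off[7:12, 7:12] <- TRUE
  cc3 <- match_blobs(label_blobs(off), "hemorrhagic", gt)
  expect_equal(cc3$fp, 1)

  expect_error(match_blobs(blobs, "hemorrhagic", matrix(FALSE, 5, 5)),
               "shape")
})

test_that("the large-hemorrhage rule is strict at 3.5%", {
  retina <- matrix(TRUE, 100, 100)  # 10000 retina pixels
  mk <- function(n) { m <- matrix(FALSE, 100, 100); m[seq_len(n)] <- TRUE; m }
  expect_false(is_large_hemorrhage(mk(300), retina))   # 3%
  expect_false(is_large_hemorrhage(mk(350), retina))   # exactly 3.5%
  expect_true(is_large_hemorrhage(mk(400), retina))    # 4%
  expect_error(is_large_hemorrhage(mk(10), matrix(FALSE, 100, 100)),
               "empty")
})

test_that("the retina mask estimate recovers the synthetic field of view", {
  sc <- generate_scene(scene_params(seed = 3, size = c(96L, 95L)))
  est <- estimate_retina_mask(sc$image)
  jac <- sum(est & sc$retina_mask) / sum(est | sc$retina_mask)
  expect_gte(jac, 0.98)
})
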
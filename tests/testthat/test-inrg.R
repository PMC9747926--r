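test_that("NICK threshold matches the brute-force window evaluation", {
  set.seed(61)
  for (rep in 1:10) {
    g <- matrix(runif(18 * 22), 18, 22)
    for (N in c(9L, 25L)) {
      expect_identical(nick_threshold(g, -0.2, N), naive_nick(g, -0.2, N))
      expect_identical(nick_threshold(g, -0.1, N), naive_nick(g, -0.1, N))
    }
  }
})

test_that("NICK edge cases: constants, kappa = 0, dark impulse", {
  expect_false(any(nick_threshold(matrix(0.6, 12, 12), -0.2, 9L)))

  # kappa = 0 reduces the threshold to the local mean
  set.seed(67)
  g <- matrix(runif(15 * 15), 15, 15)
  avg <- average_filter(g, 3)
  expect_identical(nick_threshold(g, 0, 9L), g < avg)

  # single dark pixel on a bright background is detected
  g <- matrix(1, 9, 9); g[5, 5] <- 0
  pts <- nick_threshold(g, -0.2, 9L)
  expect_true(pts[5, 5])
  expect_identical(pts, naive_nick(g, -0.2, 9L))
})

test_that("NICK rejects windows that do not fit the image", {
  g <- matrix(runif(10 * 10), 10, 10)
  expect_error(nick_threshold(g, -0.2, 121L), "larger than the image")
  expect_error(nick_threshold(g, -0.2, 10L), "perfect square")
})

test_that("region averaging and replacement behave as set operations", {
  g <- matrix(seq(0, 1, length.out = 20), 4, 5)
  one <- cbind(2, 3)
  expect_equal(avg_green(g, one), g[2, 3])
  two <- rbind(c(1, 1), c(4, 5))
  expect_equal(avg_green(g, two), mean(c(g[1, 1], g[4, 5])))
  expect_error(avg_green(g, matrix(integer(0), 0, 2)), "empty")

  expect_identical(replace_region(g, matrix(FALSE, 4, 5), 0.5), g)
  allpts <- matrix(TRUE, 4, 5)
  expect_true(all(replace_region(g, allpts, 0.5) == 0.5))
  r1 <- replace_region(g, one, 0)
  expect_equal(sum(r1 != g), 1L)
  expect_equal(r1[2, 3], 0)
})

test_that("INRG with a single pass is exactly NICK thresholding", {
  set.seed(71)
  for (rep in 1:5) {
    g <- matrix(runif(30 * 28), 30, 28)
    expect_identical(inrg(g, -0.2, 25L, n_pass = 1), nick_threshold(g, -0.2, 25L))
  }
})

test_that("INRG region sets grow monotonically and stop on convergence", {
  f <- two_shade_disk()
  det <- inrg(f$gray, -0.2, 361L, n_pass = 5, delta = 0.1, details = TRUE)
  for (t in seq_along(det$history)[-1])
    expect_true(all(det$history[[t]][det$history[[t - 1]]]))
  expect_true(all(diff(det$sizes) >= 0))
  # with a huge delta exactly one growth pass runs and is kept
  det2 <- inrg(f$gray, -0.2, 361L, n_pass = 5, delta = 1e9, details = TRUE)
  expect_length(det2$history, 2L)
  expect_true(all(det2$points[nick_threshold(f$gray, -0.2, 361L)]))
})

test_that("INRG recovers the full two-shade lesion that one pass misses", {
  f <- two_shade_disk()
  nt <- nick_threshold(f$gray, -0.2, 361L)
  expect_true(all(nt[f$core]))          # the dark core is caught at once
  expect_gt(sum(f$ring & !nt), 0)       # part of the lighter ring is not
  grown <- inrg(f$gray, -0.2, 361L, n_pass = 3, delta = 0.1)
  expect_true(all(grown[f$lesion]))     # core and ring fully recovered
  expect_false(any(grown & !f$lesion))  # with no background spillover
  # pixel recall strictly improves over the single pass
  expect_gt(sum(grown & f$lesion) / sum(f$lesion),
            sum(nt & f$lesion) / sum(f$lesion))
})

test_that("INRG on an empty initial set returns an empty set", {
  g <- matrix(0.5, 20, 20)
  expect_false(any(inrg(g, -0.2, 25L, n_pass = 3)))
})

test_that("blob labeling uses 8-connectivity and moment ellipses", {
  empty <- label_blobs(matrix(FALSE, 5, 5))
  expect_equal(nrow(empty), 0L)

  diag2 <- matrix(FALSE, 5, 5); diag2[2, 2] <- TRUE; diag2[3, 3] <- TRUE
  expect_equal(nrow(label_blobs(diag2)), 1L)

  disk <- disk_mask(41, 10)
  b <- label_blobs(disk)
  expect_equal(nrow(b), 1L)
  expect_gte(b$axis_ratio, 1)
  expect_lte(b$axis_ratio, 1.1)
  expect_equal(b$centroid_row, 21)
  expect_equal(b$area, sum(disk))

  single <- matrix(FALSE, 5, 5); single[3, 3] <- TRUE
  expect_equal(label_blobs(single)$axis_ratio, 1)
})

test_that("vessel removal drops elongated blobs and keeps the rest intact", {
  m <- matrix(FALSE, 40, 130)
  m[10:12, 11:110] <- TRUE                     # 100x3 bar: a vessel
  m[(row(m) - 28)^2 + (col(m) - 60)^2 <= 64] <- TRUE  # disk: a lesion
  blobs <- label_blobs(m)
  expect_equal(nrow(blobs), 2L)
  kept <- remove_vessels(blobs, 6.4)
  expect_equal(nrow(kept), 1L)
  expect_lt(kept$axis_ratio, 2)
  expect_length(attr(kept, "removed"), 1L)
  # survivors are unaltered
  surv <- blobs[blobs$blob_id == kept$blob_id, ]
  expect_equal(kept$area, surv$area)
  expect_equal(kept$axis_ratio, surv$axis_ratio)
  # the boundary is inclusive: ratio exactly at the threshold is kept
  blobs$axis_ratio[blobs$axis_ratio > 6.4] <- 6.4
  expect_equal(nrow(remove_vessels(blobs, 6.4)), 2L)
  # removal never increases blob count
  expect_lte(nrow(remove_vessels(blobs, 6.4)), nrow(blobs))
})
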
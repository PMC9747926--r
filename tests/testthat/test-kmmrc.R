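test_that("brightness partition handles constant and two-level planes", {
  const <- matrix(0.4, 6, 6)
  part <- kmeans_segment_brightness(const, K = 1)
  expect_equal(part$K, 1L)
  expect_true(all(part$labels == 1L))
  expect_equal(part$region_means, 0.4)

  # two distinct values, K = 2: the optimal 1-D clustering is the two
  # value groups themselves (any mixed cluster has higher within-SS)
  V <- cbind(matrix(0.2, 8, 4), matrix(0.8, 8, 4))
  part <- kmeans_segment_brightness(V, K = 2, seed = 1)
  expect_true(all(part$labels[V == 0.2] == 1L))
  expect_true(all(part$labels[V == 0.8] == 2L))
  expect_equal(part$region_means, c(0.2, 0.8))
})

test_that("brightness partition is disjoint, exhaustive and deterministic", {
  set.seed(23)
  V <- matrix(runif(40 * 30), 40, 30)
  part <- kmeans_segment_brightness(V, K = 5, seed = 9)
  expect_true(all(part$labels %in% 1:5))
  expect_equal(sum(part$sizes), length(V))
  for (i in 1:5)
    expect_equal(part$region_means[i], mean(V[part$labels == i]))
  expect_true(all(diff(part$region_means) > 0))
  part2 <- kmeans_segment_brightness(V, K = 5, seed = 9)
  expect_identical(part$labels, part2$labels)
})

test_that("K falls back to the number of distinct values with a warning", {
  V <- matrix(rep(c(0.1, 0.5, 0.9), each = 12), 6, 6)
  expect_warning(part <- kmeans_segment_brightness(V, K = 5, seed = 1),
                 "distinct")
  expect_equal(part$K, 3L)
})

test_that("KMMRC stretch is the region-anchored linear map", {
  # flat RGB (gray) image: V equals the channel value, one region
  V <- cbind(matrix(0.4, 10, 5), matrix(0.6, 10, 5))
  img <- array(rep(V, 3), c(10, 10, 3))
  out <- kmmrc_enhance(img, K = 1, beta = 1.5)
  Vp <- img2hsv(out)$V
  expect_equal(Vp[V == 0.4], rep(0.35, 50), tolerance = 1e-12)
  expect_equal(Vp[V == 0.6], rep(0.65, 50), tolerance = 1e-12)

  # beta = 1 leaves brightness unchanged
  set.seed(3)
  img <- array(runif(90, 0.2, 0.8), c(5, 6, 3))
  out1 <- kmmrc_enhance(img, K = 3, beta = 1)
  expect_equal(img2hsv(out1)$V, img2hsv(img)$V, tolerance = 1e-12)

  # constant-brightness region is a fixed point for any beta
  flat <- array(rep(c(0.3, 0.55, 0.2), each = 36), c(6, 6, 3))
  expect_equal(kmmrc_enhance(flat, K = 1, beta = 2.5), flat,
               tolerance = 1e-12)
})

test_that("KMMRC never alters hue or saturation", {
  set.seed(17)
  img <- array(runif(14 * 11 * 3, 0.15, 0.85), c(14, 11, 3))
  before <- img2hsv(img)
  after <- img2hsv(kmmrc_enhance(img, K = 4, beta = 1.5, seed = 2))
  expect_lt(max(abs(after$H - before$H)), 1e-9)
  expect_lt(max(abs(after$S - before$S)), 1e-9)
})

test_that("KMMRC preserves region means and order when nothing clips", {
  set.seed(29)
  img <- array(runif(20 * 20 * 3, 0.3, 0.7), c(20, 20, 3))
  planes <- img2hsv(img)
  part <- kmeans_segment_brightness(planes$V, K = 3, seed = 5)
  out <- img2hsv(kmmrc_enhance(img, K = 3, beta = 1.5, seed = 5))
  for (i in 1:3) {
    sel <- part$labels == i
    expect_equal(mean(out$V[sel]), part$region_means[i], tolerance = 1e-9)
    # monotone within region
    ord <- order(planes$V[sel])
    expect_true(all(diff(out$V[sel][ord]) >= -1e-12))
  }
})

test_that("CLAHE is identity on constants and contrast-expanding on a checkerboard", {
  const <- matrix(0.37, 16, 16)
  expect_equal(clahe_enhance(const), const)

  board <- matrix(rep(c(0.45, 0.55), 8 * 8), 16, 16)
  out <- clahe_enhance(board, clip = 0.5, tiles = c(2, 2))
  expect_true(all(out >= 0 & out <= 1))
  expect_gt(diff(range(out)), diff(range(board)))
  # ordering preserved: dark cells stay no brighter than light cells
  expect_lte(max(out[board == 0.45]), min(out[board == 0.55]) + 1e-9)

  set.seed(31)
  rnd <- matrix(runif(24 * 40), 24, 40)
  out <- clahe_enhance(rnd)
  expect_true(all(out >= 0 & out <= 1))
})

test_that("average filter matches direct convolution", {
  const <- matrix(0.42, 9, 9)
  expect_equal(average_filter(const, 5), const)
  set.seed(41)
  g <- matrix(runif(63), 7, 9)
  expect_identical(average_filter(g, 1), g)
  imp <- matrix(0, 9, 9); imp[5, 5] <- 1
  out <- average_filter(imp, 3)
  expect_equal(out[4:6, 4:6], matrix(1 / 9, 3, 3), tolerance = 1e-12)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  expect_error(average_filter(g, 4), "odd")
})

test_that("neutralized preprocessing reduces to the green channel", {
  set.seed(43)
  img <- array(runif(32 * 32 * 3, 0.2, 0.8), c(32, 32, 3))
  p <- hemseg_params(beta = 1, clahe_clip = 0, filter_window = 1)
  expect_equal(preprocess_fundus(img, p), extract_green_gray(img),
               tolerance = 1e-12)
})

test_that("preprocessing is deterministic and exposes its stages", {
  set.seed(47)
  img <- array(runif(40 * 40 * 3, 0.1, 0.9), c(40, 40, 3))
  p <- hemseg_params(filter_window = 3)
  g1 <- preprocess_fundus(img, p)
  g2 <- preprocess_fundus(img, p, keep_stages = TRUE)
  expect_equal(g1, g2, ignore_attr = TRUE)
  st <- attr(g2, "stages")
  expect_named(st, c("kmmrc", "green", "clahe", "avgfilter"))
  expect_identical(st$green, extract_green_gray(st$kmmrc))
  expect_equal(st$avgfilter, average_filter(st$clahe, 3))
})
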
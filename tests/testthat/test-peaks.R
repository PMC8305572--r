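test_that("second difference of affine and quadratic sequences is exact", {
  expect_equal(second_derivative(c(0, 1, 2, 3, 4)), c(0, 0, 0, 0, 0))
  i <- 0:6
  expect_equal(second_derivative(i^2), c(0, rep(2, 5), 0))
  expect_error(second_derivative(c(1, 2)), "3 points")
})

test_that("curvature of a sampled Lorentzian is negative exactly between
           the analytic inflection points", {
  # analytic second derivative of A*lam/(lam^2+(x-x0)^2) changes sign at
  # x0 +/- lam/sqrt(3)
  A <- 3; lam <- 25; x0 <- 500
  x <- 0:999
  y <- lorentz_ref(x, A, lam, x0)
  d2 <- second_derivative(y)
  inner <- abs(x - x0) < lam / sqrt(3) - 1   # strictly inside
  outer <- abs(x - x0) > lam / sqrt(3) + 1 & x > 0 & x < 999
  expect_true(all(d2[inner] < 0))
  expect_true(all(d2[outer] > 0))
})

test_that("a single Lorentzian yields exactly one triplet at its maximum", {
  s <- point_spectrum(data.frame(A = 1, lambda = 20, x0 = 500), 1000)
  tt <- detect_triplets(s)
  expect_equal(nrow(tt), 1L)
  expect_lte(abs(tt$i_middle - 500), 1)
  expect_lt(tt$i_left, tt$i_middle)
  expect_lt(tt$i_middle, tt$i_right)

  # brute-force oracle: the center condition over all indices
  d2 <- second_derivative(s)
  centers <- which(vapply(2:999, function(j) {
    d2[j] < 0 && d2[j + 1] > d2[j] && d2[j] <= d2[j - 1]
  }, logical(1))) + 1L
  expect_equal(tt$i_middle + 1L, centers)
})

test_that("well-separated and strongly overlapping pairs both give 2 triplets", {
  far <- point_spectrum(data.frame(A = c(1, 1), lambda = 20,
                                   x0 = c(400, 600)), 1000)
  expect_equal(nrow(detect_triplets(far)), 2L)

  # centers 1 lambda apart: no resolved maxima, but two curvature minima
  near <- point_spectrum(data.frame(A = c(1, 1), lambda = 20,
                                    x0 = c(500, 520)), 1000)
  tt <- detect_triplets(near)
  expect_equal(nrow(tt), 2L)
  # inner flanks lie between the two centers
  expect_gt(tt$i_right[1], tt$i_middle[1])
  expect_lt(tt$i_right[1], 520)
  expect_gt(tt$i_left[2], 500)
})

test_that("triplet centers are unique and all satisfy the center condition", {
  set.seed(5)
  for (k in c(2, 5, 8)) {
    x0 <- sort(sample(seq(100, 1900, by = 150), k))
    s <- point_spectrum(data.frame(A = runif(k, 0.5, 3), lambda = 15,
                                   x0 = x0), 2048)
    tt <- detect_triplets(s)
    expect_equal(nrow(tt), k)
    expect_false(any(duplicated(tt$i_middle)))
    d2 <- second_derivative(s)
    for (c1 in tt$i_middle + 1L) {
      expect_lt(d2[c1], 0)
      expect_gt(d2[c1 + 1], d2[c1])
      expect_lte(d2[c1], d2[c1 - 1])
    }
  }
})

test_that("triplets centered in an excluded region are dropped", {
  s <- point_spectrum(data.frame(A = c(1, 1), lambda = 20,
                                 x0 = c(400, 600)), 1000)
  ppm_center <- s$ppm[601]  # excluded window around the second peak
  s2 <- remove_water(s, c(ppm_center - 0.3, ppm_center + 0.3))
  tt <- detect_triplets(s2)
  expect_equal(nrow(tt), 1L)
  expect_lte(abs(tt$i_middle - 400), 1)
})

test_that("noise filtering keeps real signals and discards noise triplets", {
  peaks <- data.frame(A = c(40, 60), lambda_ppm = 0.02, x0_ppm = c(3, 7))
  sim <- synthetic_spectrum(peaks, n_points = 8192, ppm_range = c(10, 0),
                            noise_sd = 0.01, seed = 9)
  pre <- preprocess(sim$spectrum)
  tt <- detect_triplets(pre)
  expect_gt(nrow(tt), 2L)  # noise creates spurious triplets

  kept <- score_and_filter(tt, pre, delta = 5, noise_region = c(8.5, 9.8))
  # every survivor sits at a real line (within a few lambda of a
  # center) and both lines keep at least one triplet; the distant
  # baseline-noise triplets are gone
  d_ppm <- outer(pts_to_ppm(pre, kept$i_middle), c(3, 7), function(a, b) {
    abs(a - b)
  })
  expect_true(all(apply(d_ppm, 1, min) < 8 * 0.02))
  expect_true(all(apply(d_ppm, 2, min) < 8 * 0.02))
  expect_lt(nrow(kept), nrow(tt))
  expect_true(all(kept$score > attr(kept, "threshold")))

  # delta = 0 keeps everything scoring above the noise mean
  kept0 <- suppressWarnings(
    score_and_filter(tt, pre, delta = 0, noise_region = c(8.5, 9.8)))
  d2 <- second_derivative(pre)
  expect_equal(nrow(kept0), sum(-tt$d2_middle > mean(-d2[
    pre$ppm >= 8.5 & pre$ppm <= 9.8])))

  # an absurd threshold removes everything
  expect_equal(nrow(score_and_filter(tt, pre, delta = 1e6,
                                     noise_region = c(8.5, 9.8))), 0L)

  # empty input stays empty
  empty <- tt[0, ]
  expect_equal(nrow(score_and_filter(empty, pre, 1, c(8.5, 9.8))), 0L)
})

test_that("curvature score rejects tail-riding triplets the intensity
           score keeps", {
  # one strong line; noise wiggles on its tail sit far above the noise
  # floor in intensity but at noise level in curvature
  peaks <- data.frame(A = 300, lambda_ppm = 0.02, x0_ppm = 5)
  sim <- synthetic_spectrum(peaks, n_points = 16384, ppm_range = c(10, 0),
                            noise_sd = 2e-3, seed = 21)
  pre <- preprocess(sim$spectrum)
  tt <- detect_triplets(pre)
  on_tail <- abs(pts_to_ppm(pre, tt$i_middle) - 5) > 0.05 &
    abs(pts_to_ppm(pre, tt$i_middle) - 5) < 0.5
  expect_gt(sum(on_tail), 0L)

  by_int <- suppressWarnings(
    score_and_filter(tt, pre, 5, c(8.5, 9.8), score = "intensity"))
  by_curv <- suppressWarnings(
    score_and_filter(tt, pre, 5, c(8.5, 9.8), score = "curvature"))
  ppm_kept_int <- abs(pts_to_ppm(pre, by_int$i_middle) - 5)
  ppm_kept_curv <- abs(pts_to_ppm(pre, by_curv$i_middle) - 5)
  n_tail_int <- sum(ppm_kept_int > 0.05 & ppm_kept_int < 0.5)
  n_tail_curv <- sum(ppm_kept_curv > 0.05 & ppm_kept_curv < 0.5)
  expect_gt(n_tail_int, 10L)
  expect_lt(n_tail_curv, n_tail_int / 5)
})

test_that("a too-small noise region warns but proceeds", {
  s <- point_spectrum(data.frame(A = 1, lambda = 20, x0 = 500), 1000)
  tt <- detect_triplets(s)
  expect_warning(score_and_filter(tt, s, 1, c(9.9, 10)), "fewer than 30")
})

test_that("bucket counts match the standard binning arithmetic", {
  expect_identical(count_buckets(c(0.50, 4.60), 0.01), 410L)
  expect_identical(count_buckets(c(0, 1), 0.5), 2L)
  expect_identical(count_buckets(c(0, 1), 0.3), 3L)
  expect_error(count_buckets(c(0, 1), 0), "positive")
  expect_error(count_buckets(c(2, 1), 0.1), "lower < upper")
})
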
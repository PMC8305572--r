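test_that("lorentz_eval matches the defining identities", {
  A <- 4; lam <- 2.5; x0 <- 120
  expect_equal(lorentz_eval(x0, A, lam, x0), A / lam)
  expect_equal(lorentz_eval(x0 + lam, A, lam, x0), A / (2 * lam))
  expect_equal(lorentz_eval(x0 - lam, A, lam, x0), A / (2 * lam))
  d <- seq(0.1, 30, by = 0.7)
  expect_equal(lorentz_eval(x0 + d, A, lam, x0),
               lorentz_eval(x0 - d, A, lam, x0))
  expect_error(lorentz_eval(1, 1, 0, 0), "lambda")
})

test_that("half-height triplet of an exact Lorentzian solves exactly", {
  # y(x0) = A/lam = 200 and y(x0 +/- lam) = 100 with lam = 1 force A = 200
  tr <- list(i_left = 299, i_middle = 300, i_right = 301,
             y_left = 100, y_middle = 200, y_right = 100)
  p <- solve_triplet(tr)
  expect_equal(p$A, 200)
  expect_equal(p$lambda_pts, 1)
  expect_equal(p$x0_pts, 300)
})

test_that("an asymmetric triplet from a pure Lorentzian recovers the truth", {
  A <- 5; lam <- 3; x0 <- 50
  xs <- c(47, 50.5, 55)
  ys <- lorentz_ref(xs, A, lam, x0)
  p <- solve_triplet(list(i_left = xs[1], i_middle = xs[2], i_right = xs[3],
                          y_left = ys[1], y_middle = ys[2], y_right = ys[3]))
  expect_equal(p$A, A, tolerance = 1e-9)
  expect_equal(p$lambda_pts, lam, tolerance = 1e-9)
  expect_equal(p$x0_pts, x0, tolerance = 1e-9)
})

test_that("random exact triplets solve to >= 9 significant digits", {
  set.seed(123)
  for (i in 1:200) {
    A <- 10^runif(1, -2, 4)
    lam <- runif(1, 0.5, 50)
    x0 <- runif(1, 0, 130000)
    xs <- sort(x0 + runif(3, -3, 3) * lam)
    if (anyDuplicated(xs)) next
    ys <- lorentz_ref(xs, A, lam, x0)
    p <- solve_triplet(list(i_left = xs[1], i_middle = xs[2],
                            i_right = xs[3], y_left = ys[1],
                            y_middle = ys[2], y_right = ys[3]))
    expect_equal(p$A, A, tolerance = 1e-9)
    expect_equal(p$lambda_pts, lam, tolerance = 1e-9)
    expect_equal(abs(p$x0_pts - x0) / max(1, abs(x0)), 0, tolerance = 1e-9)
    # substitution residuals of the three Lorentz equations
    resid <- lorentz_ref(xs, p$A, p$lambda_pts, p$x0_pts) - ys
    expect_lt(max(abs(resid) / ys), 1e-9)
  }
})

test_that("degenerate triplets are dropped with a warning", {
  expect_warning(
    out <- solve_triplet(list(i_left = 10, i_middle = 10, i_right = 12,
                              y_left = 1, y_middle = 2, y_right = 1)),
    "degenerate")
  expect_null(out)
  expect_warning(
    out2 <- solve_triplet(list(i_left = 9, i_middle = 10, i_right = 11,
                               y_left = 0, y_middle = 2, y_right = 1)),
    "degenerate")
  expect_null(out2)
})

test_that("reconstruct is the linear superposition of its peaks", {
  s <- point_spectrum(data.frame(A = 1, lambda = 20, x0 = 500), 1000)
  expect_equal(reconstruct(data.frame(A = numeric(), lambda_pts = numeric(),
                                      x0_pts = numeric()), s),
               numeric(1000))
  one <- data.frame(A = 2, lambda_pts = 15, x0_pts = 300)
  two <- data.frame(A = 1, lambda_pts = 25, x0_pts = 700)
  expect_equal(reconstruct(one, s), lorentz_eval(0:999, 2, 15, 300))
  expect_equal(reconstruct(rbind(one, two), s),
               reconstruct(one, s) + reconstruct(two, s))
  # excluded points are zeroed
  s2 <- remove_water(s, c(4, 6))
  r <- reconstruct(one, s2)
  expect_true(all(r[s2$excluded] == 0))
})

test_that("normalized MSE is scale-invariant and hand-checkable", {
  s <- spectrum1d(c(4, 3, 2, 1), c(1, 0, 0, 0))
  expect_equal(normalized_mse(s, c(1, 0, 0, 0)), 0)
  expect_equal(normalized_mse(s, c(7, 0, 0, 0)), 0)  # scaling cancels
  # both normalize to unit vectors differing in 2 of 4 positions
  expect_equal(normalized_mse(s, c(0, 1, 0, 0)), (1 + 1) / 4)
  expect_error(normalized_mse(s, c(0, 0, 0, 0)), "zero total")
  expect_error(normalized_mse(s, c(1, 1)), "length")
})

test_that("an isolated exact peak is a fixed point of the iteration", {
  s <- point_spectrum(data.frame(A = 1, lambda = 20, x0 = 500), 1000)
  tt <- detect_triplets(s)
  fit <- iterate_fit(s, tt, n_iter = 10)
  expect_length(fit$mse_trace, 11L)
  expect_lt(fit$mse_trace[1], 1e-20)
  expect_equal(fit$best_iteration, which.min(fit$mse_trace) - 1L)
  expect_equal(fit$peaks$A, 1, tolerance = 1e-10)
  expect_equal(fit$peaks$lambda_pts, 20, tolerance = 1e-10)
  expect_equal(fit$peaks$x0_pts, 500, tolerance = 1e-10)
})

test_that("zero iterations returns the initial analytic solves verbatim", {
  s <- point_spectrum(data.frame(A = c(1, 2), lambda = 20,
                                 x0 = c(400, 650)), 1000)
  tt <- detect_triplets(s)
  fit0 <- iterate_fit(s, tt, n_iter = 0)
  expect_length(fit0$mse_trace, 1L)
  expect_equal(fit0$best_iteration, 0L)
  manual <- lapply(seq_len(nrow(tt)), function(k) solve_triplet(tt[k, ]))
  expect_equal(fit0$peaks$A, vapply(manual, `[[`, 1, "A"))
  expect_equal(fit0$peaks$lambda_pts,
               vapply(manual, `[[`, 1, "lambda_pts"))
})

test_that("height adjustment untangles two overlapping Lorentzians", {
  # centers 2*lambda apart: initial independent solves overshoot, the
  # apportionment recovers the truth within 5% and reduces the MSE
  truth <- data.frame(A = c(1, 1), lambda = 20, x0 = c(2000, 2040))
  s <- point_spectrum(truth, 4096)
  tt <- detect_triplets(s)
  expect_equal(nrow(tt), 2L)
  fit <- iterate_fit(s, tt, n_iter = 10)
  expect_lt(min(fit$mse_trace), fit$mse_trace[1])
  expect_lte(min(fit$mse_trace), fit$mse_trace[1])  # best <= iteration 0
  p <- fit$peaks[order(fit$peaks$x0_pts), ]
  expect_equal(p$A, truth$A, tolerance = 0.05)
  expect_equal(p$lambda_pts, rep(20, 2), tolerance = 0.05)
  expect_equal(p$x0_pts, truth$x0, tolerance = 0.05)
})

test_that("all-degenerate input fails loudly", {
  s <- point_spectrum(data.frame(A = 1, lambda = 20, x0 = 500), 1000)
  bad <- data.frame(i_left = 10, i_middle = 10, i_right = 12,
                    y_left = 1, y_middle = 2, y_right = 1)
  expect_error(suppressWarnings(iterate_fit(s, bad, 5)), "no fittable")
  expect_error(iterate_fit(s, bad[0, ], 5), "empty")
})

test_that("duplicate initial solves collapse to the strongest triplet", {
  x0 <- c(100.2, 100.9, 101.1, 250)
  strength <- c(5, 9, 2, 1)
  keep <- nmrdecon:::dedupe_centers(x0, strength)
  expect_equal(keep, c(FALSE, TRUE, FALSE, TRUE))
  # chains are transitive: pairwise gaps below tolerance merge across
  keep2 <- nmrdecon:::dedupe_centers(c(1, 2, 3, 10), c(1, 3, 2, 1))
  expect_equal(keep2, c(FALSE, TRUE, FALSE, TRUE))
})

test_that("fits are equivariant under intensity scaling and ppm shifts", {
  truth <- data.frame(A = c(1, 2), lambda = c(15, 22), x0 = c(700, 1400))
  s <- point_spectrum(truth, 2048)
  base <- iterate_fit(s, detect_triplets(s), 5)$peaks

  for (c_scale in c(0.25, 3, 1000)) {
    s2 <- spectrum1d(s$ppm, s$intensity * c_scale)
    scaled <- iterate_fit(s2, detect_triplets(s2), 5)$peaks
    expect_equal(scaled$A, base$A * c_scale, tolerance = 1e-9)
    expect_equal(scaled$lambda_pts, base$lambda_pts, tolerance = 1e-9)
    expect_equal(scaled$x0_pts, base$x0_pts, tolerance = 1e-9)
  }

  # shifting the ppm axis moves every x0_ppm by the shift and nothing else
  sim <- synthetic_spectrum(data.frame(A = 1, lambda_ppm = 0.01, x0_ppm = 4),
                            n_points = 4096, ppm_range = c(10, 0))
  f1 <- deconvolve(sim$spectrum, delta = 1, noise_region = c(8.5, 9.5),
                   smooth_passes = 0, verbose = FALSE)
  shifted <- spectrum1d(sim$spectrum$ppm + 1.5, sim$spectrum$intensity)
  f2 <- deconvolve(shifted, delta = 1, noise_region = c(10, 11),
                   smooth_passes = 0, verbose = FALSE)
  expect_equal(f2$peaks$x0_ppm, f1$peaks$x0_ppm + 1.5, tolerance = 1e-8)
  expect_equal(f2$peaks$A, f1$peaks$A, tolerance = 1e-9)
  expect_equal(f2$peaks$lambda_pts, f1$peaks$lambda_pts, tolerance = 1e-9)
})
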
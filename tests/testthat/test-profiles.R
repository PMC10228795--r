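test_that("aggregate_tracks averages, scales to max 1, and carries SEM", {
  # 15 identical tracks with max 200
  tr <- matrix(rep(c(50, 200, 100), each = 15), nrow = 15)
  p <- aggregate_tracks(track_set(tr, position = c(0, 0.5, 1)))
  expect_equal(p$intensity, c(0.25, 1, 0.5))
  expect_true(p$scaled)
  expect_equal(p$sem, c(0, 0, 0))
  # two-track arithmetic: mean (1,2,3) -> scaled (1/3, 2/3, 1)
  p2 <- aggregate_tracks(track_set(rbind(c(0, 2, 4), c(2, 2, 2))))
  expect_equal(p2$intensity, c(1, 2, 3) / 3)
  # single track is just rescaled
  p3 <- aggregate_tracks(track_set(matrix(c(1, 4, 2), 1)))
  expect_equal(p3$intensity, c(0.25, 1, 0.5))
  # all-zero tracks cannot be scaled
  expect_error(aggregate_tracks(track_set(matrix(0, 3, 5))), "undefined")
})

test_that("idempotence: aggregating an already-scaled single track", {
  x <- seq(0, 1, length.out = 50)
  y <- (1 + sin(3 * x)) / max(1 + sin(3 * x))
  p <- aggregate_tracks(track_set(matrix(y, 1), position = x))
  expect_equal(p$intensity, y)
  expect_equal(p$position, x)
})

test_that("tracks with unequal spacing are resampled to a common grid", {
  t1 <- cbind(c(0, 10, 20, 40), c(1, 2, 3, 5))     # pixel-ish distances
  t2 <- cbind(c(0, 5, 30, 40), c(2, 2, 4, 6))
  ts <- track_set(list(t1, t2), grid_points = 50)
  expect_equal(dim(ts$tracks), c(2, 50))
  expect_equal(ts$tracks[1, 1], 1)
  expect_equal(ts$tracks[1, 50], 5)
})

test_that("loess_smooth reproduces constants and straight lines", {
  x <- seq(0, 1, length.out = 60)
  pc <- reporter_profile(x, rep(0.4, 60))
  expect_equal(loess_smooth(pc)$intensity, rep(0.4, 60), tolerance = 1e-10)
  pl <- reporter_profile(x, 0.2 + 0.6 * x)
  expect_equal(loess_smooth(pl)$intensity, 0.2 + 0.6 * x, tolerance = 1e-8)
  expect_error(loess_smooth(pl, span = 0), "span")
  expect_error(loess_smooth(pl, span = 1.5), "span")
  expect_error(loess_smooth(reporter_profile(x[1:5], rep(1, 5))), "10")
})

test_that("loess reduces noise against the known generator", {
  spec <- synthetic_profile_spec(noise_sd = 0.05, n_tracks = 1,
                                 points_per_track = 100, seed = 21,
                                 orientation = "increasing")
  x <- seq(0, 1, length.out = 100)
  truth <- profile_shape(spec, x)
  noisy <- generate_tracks(spec)$tracks[1, ]
  p <- reporter_profile(x, noisy)
  sm <- loess_smooth(p, span = 0.8)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(sm$intensity, truth), rmse(noisy, truth))
  expect_lt(rmse(sm$intensity, truth), 0.05)
  # variance-shrink property
  expect_lte(var(sm$intensity - truth), var(noisy - truth))
  # confidence band brackets the (unclamped) fit
  expect_true(all(attr(sm, "ci_lower") <= attr(sm, "fit") + 1e-12))
  expect_true(all(attr(sm, "ci_upper") >= attr(sm, "fit") - 1e-12))
})

test_that("masks exclude regions from scaling, smoothing and correlation", {
  x <- seq(0, 1, length.out = 100)
  # spike inside the mask carried the global max
  y <- 0.5 + 0.5 * exp(-((x - 0.05) / 0.02)^2)
  p <- reporter_profile(x, y / max(y), scaled = TRUE)
  pm <- apply_mask(p, c(0, 0.1))
  keep <- profile_unmasked(pm)
  expect_equal(max(pm$intensity[keep]), 1)  # rescaled to unmasked max
  # mask monotonicity: surviving values unchanged up to the common factor
  pm2 <- apply_mask(pm, c(0, 0.2))
  keep2 <- profile_unmasked(pm2)
  ratio <- pm2$intensity[keep2] / pm$intensity[keep2]
  expect_lt(diff(range(ratio)), 1e-12)
  # a zero-width mask off the grid excludes nothing and changes nothing
  p0 <- apply_mask(p, c(0.5, 0.5))
  expect_equal(sum(!profile_unmasked(p0)), 0)
  expect_equal(p0$intensity, p$intensity)
  expect_error(apply_mask(p, c(0, 1)), "whole profile")
  # classifier ignores masked positions
  ref <- generate_reference_pair(n_grid = 100)
  ref_masked <- list(JNK = apply_mask(ref$JNK, c(0, 0.1)),
                     JAK = ref$JAK)
  field <- list(JNK = ref$JNK$intensity, JAK = ref$JAK$intensity)
  r <- classify_observed(field, ref_masked)
  expect_true(r$observed)  # still perfectly correlated on surviving points
})

test_that("track and profile CSV round-trips are value-exact", {
  ts <- generate_tracks(synthetic_profile_spec(seed = 4, n_tracks = 3,
                                               points_per_track = 20))
  f <- tempfile(fileext = ".csv")
  write_tracks(ts, f)
  ts2 <- read_tracks(f)
  expect_equal(ts2$tracks, ts$tracks)
  expect_equal(ts2$position, ts$position)
  p <- aggregate_tracks(ts)
  f2 <- tempfile(fileext = ".csv")
  write_profile(p, f2)
  p2 <- read_profile(f2)
  expect_equal(p2$intensity, p$intensity)
  expect_equal(p2$sem, p$sem)
})
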
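test_that("windowed RMSF counts windows and recovers closed-form amplitudes", {
  # static trajectory: zero fluctuation everywhere
  static <- toy_trajectory(rep(random_frames(1, 8, seed = 61), 20))
  rw <- windowed_rmsf(static, 10)
  expect_equal(max(abs(rw$rmsf)), 0, tolerance = 1e-10)

  # 150 frames split into 25-frame fragments: exactly 6 windows
  frames150 <- random_frames(150, 6, scale = 0.2, seed = 62)
  expect_equal(nrow(windowed_rmsf(toy_trajectory(frames150), 25)$rmsf), 6L)
  # trailing partial window dropped
  expect_equal(nrow(windowed_rmsf(toy_trajectory(frames150[1:149]), 25)$rmsf), 5L)

  # butterfly mode: four square corners alternate +/- a in z with zero net
  # translation/rotation, so every bead's RMSF is exactly a
  a <- 0.05
  square <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  up <- square; up[, 3] <- c(a, -a, a, -a)
  dn <- square; dn[, 3] <- c(-a, a, -a, a)
  bf <- toy_trajectory(rep(list(up, dn), 10))
  rwb <- windowed_rmsf(bf, 10, selection = "all")
  expect_equal(unname(rwb$rmsf[1, ]), rep(a, 4), tolerance = 1e-9)

  expect_error(windowed_rmsf(static, 50), class = "input_error")
  expect_error(windowed_rmsf(static, 1), class = "input_error")
})

test_that("RMSF is invariant to per-frame rigid translations", {
  frames <- random_frames(30, 6, scale = 0.2, seed = 63)
  shifted <- lapply(seq_along(frames), function(i)
    sweep(frames[[i]], 2, c(i * 0.3, -i * 0.1, 0.5), `+`))
  r1 <- windowed_rmsf(toy_trajectory(frames), 15)$rmsf
  r2 <- windowed_rmsf(toy_trajectory(shifted), 15)$rmsf
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("quieting a region after the transition shows as negative RMSF drift", {
  set.seed(64)
  base <- make_anchor("extended", 10)$coords
  frames <- lapply(1:60, function(t) {
    sigma <- rep(0.05, 10)
    if (t > 30) sigma[4:6] <- 0.005    # the region stabilises
    base + matrix(rnorm(30), 10, 3) * sigma
  })
  rw <- windowed_rmsf(toy_trajectory(frames), 30, selection = "all")
  expect_true(all(rw$pct_diff_vs_first[2, c("4", "5", "6")] < -50))
})

test_that("DCCM matches direct covariance sums and stays in [-1, 1]", {
  frames <- random_frames(10, 5, scale = 0.15, seed = 65)
  tr <- toy_trajectory(frames)
  C <- dccm(tr, selection = "all")

  expect_equal(unname(diag(C)), rep(1, 5))
  expect_true(all(C >= -1 & C <= 1))
  expect_lt(max(abs(C - t(C))), 1e-9)

  # brute-force oracle: explicit covariance sums on the superposed stack
  X <- confshift:::superpose_to_mean(confshift:::flatten_frames(tr, 1:5))
  mu <- colMeans(X)
  dev <- lapply(1:10, function(f) matrix(X[f, ] - mu, 5, 3, byrow = TRUE))
  for (i in 1:5) for (j in 1:5) {
    cij <- mean(sapply(dev, function(d) sum(d[i, ] * d[j, ])))
    cii <- mean(sapply(dev, function(d) sum(d[i, ]^2)))
    cjj <- mean(sapply(dev, function(d) sum(d[j, ]^2)))
    expect_equal(unname(C[i, j]), cij / sqrt(cii * cjj), tolerance = 1e-9)
  }

  # zero-variance residues are masked as NA, not reported as 0
  static <- toy_trajectory(rep(frames[1], 5))
  Cs <- dccm(static, selection = "all")
  expect_true(all(is.na(Cs)))

  expect_error(dccm(toy_trajectory(frames[1])), class = "input_error")
})

test_that("DCCM agrees with the reference implementation on a toy", {
  skip_if_not_installed("bio3d")
  # internal motion only: no rigid drift, so the fitting reference cannot matter
  set.seed(66)
  base <- matrix(rnorm(24, sd = 0.5), 8, 3)
  frames <- lapply(1:50, function(t) base + matrix(rnorm(24, sd = 0.03), 8, 3))
  tr <- toy_trajectory(frames)
  C <- dccm(tr, selection = "all")

  xyz <- confshift:::array_to_xyz(tr$coords)
  fitted <- suppressWarnings(bio3d::fit.xyz(fixed = colMeans(xyz), mobile = xyz))
  Cref <- suppressWarnings(bio3d::dccm(fitted))
  expect_equal(unname(C), unname(as.matrix(Cref)), tolerance = 0.02)
})

test_that("inter-region distances obey definitions and mode ordering", {
  f <- matrix(0, 4, 3); f[2, ] <- c(2, 0, 0); f[3, ] <- c(0, 5, 0); f[4, ] <- c(2, 5, 0)
  tr <- toy_trajectory(list(f, f))
  expect_equal(region_distance_series(tr, 1, 2), c(2, 2))
  expect_lte(region_distance_series(tr, 1:2, 3:4, "min_atom")[1],
             region_distance_series(tr, 1:2, 3:4, "centroid")[1])
  expect_error(region_distance_series(tr, 1:2, 2:3), class = "input_error")
})

test_that("contact probability counts frames strictly below the cutoff", {
  mk <- function(d) { f <- matrix(0, 2, 3); f[2, 1] <- d; f }
  # contact (0.1 nm) in exactly 5 of 10 frames
  tr <- toy_trajectory(c(lapply(rep(0.1, 5), mk), lapply(rep(0.5, 5), mk)))
  cp <- contact_probability(tr, 1, 2, cutoff = 0.24)
  expect_equal(cp$probability, 0.5)
  expect_equal(cp$pair_map$frequency, 0.5)

  expect_equal(contact_probability(toy_trajectory(lapply(rep(0.1, 3), mk)),
                                   1, 2)$probability, 1)
  expect_equal(contact_probability(toy_trajectory(lapply(rep(0.5, 3), mk)),
                                   1, 2)$probability, 0)
  # strict inequality at the boundary
  expect_equal(contact_probability(toy_trajectory(list(mk(0.24))),
                                   1, 2, cutoff = 0.24)$probability, 0)
  expect_error(contact_probability(tr, 1, 2, cutoff = 0),
               class = "input_error")
})
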
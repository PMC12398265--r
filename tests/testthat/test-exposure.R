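test_that("Shrake-Rupley SASA matches closed forms for isolated and buried atoms", {
  # isolated atom: whole expanded sphere accessible
  a <- shrake_rupley(matrix(0, 1, 3), radii = 0.15)
  expect_equal(a, 4 * pi * 0.29^2, tolerance = 0.005)

  # small atom fully inside a much larger sphere
  two <- shrake_rupley(rbind(c(0, 0, 0), c(0, 0, 0.05)),
                       radii = c(0.1, 0.5))
  expect_equal(two[1], 0)

  expect_error(shrake_rupley(matrix(0, 1, 3), 0.15, probe_radius = -1),
               class = "input_error")
  expect_error(shrake_rupley(matrix(0, 1, 3), 0.15, n_points = 10),
               class = "input_error")
})

test_that("overlapping-sphere SASA agrees with a Monte-Carlo point oracle", {
  coords <- rbind(c(0, 0, 0), c(0.2, 0, 0))
  radii <- c(0.15, 0.15); probe <- 0.14
  area <- shrake_rupley(coords, radii, probe, n_points = 960)

  # oracle: 1e6 uniform points on each expanded sphere, count those outside
  # the neighbour's expanded sphere
  set.seed(99)
  n <- 1e6
  z <- runif(n, -1, 1); phi <- runif(n, 0, 2 * pi); r <- sqrt(1 - z^2)
  pts <- cbind(r * cos(phi), r * sin(phi), z)
  for (i in 1:2) {
    j <- 3 - i
    ext_i <- radii[i] + probe; ext_j <- radii[j] + probe
    p <- sweep(pts * ext_i, 2, coords[i, ], `+`)
    d2 <- rowSums(sweep(p, 2, coords[j, ])^2)
    mc <- 4 * pi * ext_i^2 * mean(d2 >= ext_j^2)
    expect_equal(area[i], mc, tolerance = 0.02)
  }
})

test_that("SASA is stable under sphere-point refinement and rigid rotation", {
  set.seed(98)
  coords <- matrix(rnorm(150, sd = 0.3), 50, 3)
  radii <- rep(0.17, 50)
  a960 <- sum(shrake_rupley(coords, radii, n_points = 960))
  a1920 <- sum(shrake_rupley(coords, radii, n_points = 1920))
  expect_lt(abs(a1920 - a960) / a960, 0.005)

  # rotation invariance, bounded by test-point anisotropy: the 960-point
  # sphere is anisotropic at the 0.2% level on this 50-atom blob; refining
  # the sphere brings the bound under 0.1%
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rot <- sum(shrake_rupley(coords %*% R, radii, n_points = 960))
  expect_lt(abs(rot - a960) / a960, 0.0025)
  a_hi <- sum(shrake_rupley(coords, radii, n_points = 3840))
  rot_hi <- sum(shrake_rupley(coords %*% R, radii, n_points = 3840))
  expect_lt(abs(rot_hi - a_hi) / a_hi, 0.001)
})

test_that("residue and region aggregation conserve the per-atom total", {
  frames <- random_frames(3, 8, scale = 0.25, seed = 55)
  tr <- toy_trajectory(frames)
  atom <- shrake_rupley(frames[[1]], tr$topology$atoms$radius, n_points = 240)
  res <- residue_sasa(atom, tr$topology)
  expect_equal(sum(res), sum(atom))
  expect_equal(unname(res["3"]), atom[3])   # one atom per residue here

  ss <- sasa_series(tr, n_points = 240)
  expect_equal(dim(ss$values), c(3L, 8L))
  regions <- region_set(a = "1-3", b = "4-6", ab = "1-6")
  rs <- region_series(ss, regions)
  expect_equal(rs[, "ab"], rs[, "a"] + rs[, "b"])
  expect_equal(rs[, "a"][1], sum(ss$values[1, 1:3]))
  expect_error(region_series(ss, region_set(z = "7-12")),
               class = "input_error")

  static <- toy_trajectory(rep(frames[1], 4))
  sstatic <- sasa_series(static, n_points = 240)
  expect_equal(sd(region_series(sstatic, region_set(a = "1-3"))[, 1]), 0)
})

test_that("delta tables reproduce a hand-computed toy exactly", {
  # two regions, 6 frames, clusters: 1,1,1 (reference) and 2,2,2
  series <- cbind(r1 = c(2, 2, 2, 4, 4, 4), r2 = c(1, 2, 3, 1, 2, 3))
  asg <- structure(list(labels = rep(1:2, each = 3), k = 2L, n_pc = 2L,
                        linkage = "average"), class = "ClusterAssignment")
  dt <- as.data.frame(delta_table(series, asg, reference_cluster = 1L))

  row_r1c2 <- dt[dt$region == "r1" & dt$cluster == "2", ]
  expect_equal(row_r1c2$mean, 4)
  expect_equal(row_r1c2$pct_diff, 100)      # mean doubled => +100%
  expect_equal(row_r1c2$sem, 0)

  row_r2c2 <- dt[dt$region == "r2" & dt$cluster == "2", ]
  expect_equal(row_r2c2$pct_diff, 0)        # same distribution => 0%
  # SEM of each 3-frame sample: sd(1,2,3)/sqrt(3) = 1/sqrt(3)
  expect_equal(row_r2c2$sem, 1 / sqrt(3))
  # quadrature propagation: 100 * |m2/m1| * sqrt((s2/m2)^2 + (s1/m1)^2)
  expect_equal(row_r2c2$pct_diff_sem,
               100 * 1 * sqrt(2 * (1 / sqrt(3) / 2)^2))

  ref_rows <- dt[dt$is_reference, ]
  expect_true(all(ref_rows$pct_diff == 0))

  # cross-group rows use the first group's mean as denominator
  groups <- rep(c("WT", "CL"), 3)
  asg2 <- structure(list(labels = rep(1L, 6), k = 1L, n_pc = 2L,
                         linkage = "average"), class = "ClusterAssignment")
  dt2 <- as.data.frame(delta_table(cbind(r = c(2, 3, 2, 3, 2, 3)), asg2,
                                   1L, group_of = groups))
  cross <- dt2[dt2$comparison == "vs_group_WT", ]
  expect_equal(cross$pct_diff, 100 * (3 - 2) / 2)

  expect_error(delta_table(cbind(r = rep(0, 6)), asg, 1L),
               class = "undefined_ratio")
})

test_that("residue profiles flag planted exposure changes by sign", {
  a <- make_shielded_anchor("ring", 20, shield_len = 4, over = 5, label = "O")
  sp <- synthetic_spec(20, list(list(anchor = "O", dwell = 60)),
                       noise_sigma = 0.01, seed = 12)
  g <- generate_trajectory(sp, list(a))
  tr <- plant_exposure_change(g$trajectory, 17:20, 5:8, 2.0, 31)
  ss <- sasa_series(tr, n_points = 240)

  prof <- residue_profile(ss, baseline_frames = 1:30)
  target <- as.character(5:8)
  untouched <- as.character(c(2, 3, 11, 12))
  expect_true(all(prof[target] > 0.05))          # unburied residues gain SASA
  expect_true(all(abs(prof[untouched]) < 0.02))  # far residues unchanged

  expect_equal(unname(residue_profile(ss, seq_len(n_frames(tr)))),
               rep(0, 20), tolerance = 1e-12)
  expect_length(prof, 20)
  expect_error(residue_profile(ss, integer(0)), class = "input_error")
})
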
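test_that("coordinate PCA spans the data and conserves variance", {
  # rank-1 data: frames along one internal-motion direction (rigid-body
  # translations and infinitesimal rotations projected out so superposition
  # cannot reshape the line)
  set.seed(40)
  base <- make_anchor("ring", 6)$coords   # non-degenerate reference geometry
  rigid <- cbind(
    as.vector(t(matrix(rep(c(1, 0, 0), 6), 6, 3, byrow = TRUE))),
    as.vector(t(matrix(rep(c(0, 1, 0), 6), 6, 3, byrow = TRUE))),
    as.vector(t(matrix(rep(c(0, 0, 1), 6), 6, 3, byrow = TRUE))),
    as.vector(t(t(sapply(1:6, function(i) c(0, -base[i, 3], base[i, 2]))))),
    as.vector(t(t(sapply(1:6, function(i) c(base[i, 3], 0, -base[i, 1]))))),
    as.vector(t(t(sapply(1:6, function(i) c(-base[i, 2], base[i, 1], 0))))))
  d <- rnorm(18)
  d <- d - qr.Q(qr(rigid)) %*% crossprod(qr.Q(qr(rigid)), d)
  d <- d / sqrt(sum(d^2))
  dirn <- matrix(d, 6, 3, byrow = TRUE)
  frames <- lapply(seq(-1, 1, length.out = 9), function(t) base + t * 0.1 * dirn)
  model <- fit_landscape(list(x = toy_trajectory(frames)), selection = "all")
  ev <- model$eigenvalues
  expect_gt(ev[1] / sum(ev), 0.9999)
  expect_equal(variance_explained(model, length(ev)), 1.0)

  # orthonormal eigenvectors, descending eigenvalues
  V <- model$eigenvectors
  expect_lt(max(abs(crossprod(V) - diag(ncol(V)))), 1e-8)
  expect_true(all(diff(ev) <= 1e-12))

  # eigenvalue conservation: sum of eigenvalues = total variance
  frames2 <- random_frames(12, 5, scale = 0.3, seed = 41)
  m2 <- fit_landscape(list(x = toy_trajectory(frames2)), selection = "all")
  X <- m2$projections
  expect_equal(sum(m2$eigenvalues), sum(apply(X, 2, var)), tolerance = 1e-8)

  # reconstruction oracle: mean + projections through the full basis
  # rebuilds every input frame up to rigid motion
  mu <- as.vector(t(m2$mean_structure))
  for (i in c(1, 5, 12)) {
    recon <- matrix(mu + as.vector(m2$eigenvectors %*% m2$projections[i, ]),
                    5, 3, byrow = TRUE)
    expect_lt(superposed_rmsd(recon, frames2[[i]]), 1e-8)
  }
  expect_error(fit_landscape(list(x = toy_trajectory(frames2[1])), "all"),
               class = "input_error")
})

test_that("clustering separates planted anchors and is deterministic", {
  anchors <- list(make_anchor("ring", 15, label = "A"),
                  make_anchor("extended", 15, label = "B"))
  sp <- synthetic_spec(15, list(list(anchor = "A", dwell = 30, interp = 0),
                                list(anchor = "B", dwell = 30)),
                       noise_sigma = 0.03, seed = 6)
  g <- generate_trajectory(sp, anchors)
  model <- fit_landscape(list(x = g$trajectory))
  asg <- cluster_frames(model, n_pc = 2, k = 2)
  expect_equal(adjusted_rand_index(asg$labels, g$labels), 1.0)

  # determinism
  asg2 <- cluster_frames(model, n_pc = 2, k = 2)
  expect_identical(asg$labels, asg2$labels)

  # k = 1 puts everything together
  expect_true(all(cluster_frames(model, k = 1)$labels == 1L))
  expect_error(cluster_frames(model, k = 1000), class = "input_error")

  # a duplicated frame always lands with its twin
  frames <- random_frames(10, 6, scale = 0.5, seed = 42)
  frames[[10]] <- frames[[3]]
  m <- fit_landscape(list(x = toy_trajectory(frames)), selection = "all")
  a <- cluster_frames(m, n_pc = 3, k = 4)
  expect_equal(a$labels[10], a$labels[3])
})

test_that("population tables are percentages that sum as stated", {
  asg <- structure(list(labels = c(rep(1L, 10), rep(2L, 6)), k = 2L,
                        n_pc = 2L, linkage = "average"),
                   class = "ClusterAssignment")
  groups <- c(rep("WT", 6), rep("CL", 4), rep("WT", 2), rep("CL", 4))
  # cluster 1 holds 6 WT + 4 CL
  pops <- population_table(asg, groups)
  expect_equal(pops$cluster_share_by_group["1", "WT"], 60)
  expect_equal(pops$cluster_share_by_group["1", "CL"], 40)
  expect_equal(unname(rowSums(pops$cluster_share_by_group)), c(100, 100),
               tolerance = 1e-9)
  expect_equal(unname(colSums(pops$group_composition)), c(100, 100),
               tolerance = 1e-9)

  one <- population_table(asg, rep("only", 16))
  expect_true(all(one$cluster_share_by_group == 100))
  expect_error(population_table(asg, groups[1:3]), class = "input_error")
})

test_that("local density peaks at duplicated points and matches a kernel-sum oracle", {
  set.seed(43)
  frames <- c(random_frames(20, 5, scale = 0.5, seed = 44),
              rep(random_frames(1, 5, scale = 0.5, seed = 45), 10))
  model <- fit_landscape(list(x = toy_trajectory(frames)), selection = "all")
  dens <- local_density(model, n_pc = 2)
  expect_true(all(dens > 0 & dens <= 1))
  expect_true(which.max(dens) > 20)   # one of the duplicated frames

  # independent oracle: direct double-sum Gaussian KDE with Scott's rule
  P <- model$projections[, 1:2]
  n <- nrow(P)
  h <- apply(P, 2, sd) * n^(-1 / 6)
  ref <- sapply(seq_len(n), function(i) {
    mean(dnorm((P[i, 1] - P[, 1]) / h[1]) / h[1] *
           dnorm((P[i, 2] - P[, 2]) / h[2]) / h[2])
  })
  expect_equal(dens, ref / max(ref), tolerance = 1e-10)

  flat <- toy_trajectory(rep(random_frames(1, 5, seed = 46), 5))
  mflat <- fit_landscape(list(x = flat), selection = "all")
  expect_error(local_density(mflat), class = "degeneracy_error")
})

test_that("representative frames minimise distance to the cluster centroid", {
  frames <- random_frames(15, 5, scale = 0.5, seed = 47)
  model <- fit_landscape(list(x = toy_trajectory(frames)), selection = "all")
  asg <- cluster_frames(model, n_pc = 2, k = 3)
  for (c in 1:3) {
    members <- which(asg$labels == c)
    if (!length(members)) next
    rf <- representative_frame(model, asg, c)
    P <- model$projections[, 1:2, drop = FALSE]
    centroid <- colMeans(P[members, , drop = FALSE])
    d <- sqrt(rowSums(sweep(P[members, , drop = FALSE], 2, centroid)^2))
    expect_equal(as.integer(rf), members[which.min(d)])  # brute-force oracle
    if (length(members) == 1L) expect_equal(as.integer(rf), members)
  }
  expect_error(representative_frame(model, asg, 99), class = "input_error")
})

test_that("convergence frames flag when a repeat settles into its final state", {
  anchors <- list(make_anchor("ring", 12, label = "A"),
                  make_anchor("extended", 12, label = "B"))
  mk <- function(dwellA, total = 80, seed = 8) {
    sp <- synthetic_spec(12, list(list(anchor = "A", dwell = dwellA, interp = 0),
                                  list(anchor = "B", dwell = total - dwellA)),
                         noise_sigma = 0.02, seed = seed)
    generate_trajectory(sp, anchors)$trajectory
  }
  late <- mk(60); early <- mk(15, seed = 9)
  model <- fit_landscape(list(late = late, early = early))
  conv <- convergence_analysis(model, k = 2, window = 10, n_pc = 2, seed = 1)
  expect_lt(conv["early"], conv["late"])

  # constant trajectory converges at the first window
  static <- toy_trajectory(rep(random_frames(1, 12, seed = 10), 30))
  m1 <- fit_landscape(list(s = static, late = late))
  c1 <- convergence_analysis(m1, k = 2, window = 5, n_pc = 2, seed = 1)
  expect_equal(unname(c1["s"]), 1L)

  # window 1: convergence frame equals the switch frame
  sw <- mk(40)
  m2 <- fit_landscape(list(sw = sw))
  c2 <- convergence_analysis(m2, k = 2, window = 1, n_pc = 2, seed = 1)
  expect_equal(unname(c2["sw"]), 41L)

  expect_error(convergence_analysis(model, window = 1000),
               class = "input_error")
})
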
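# Conformational landscape: coordinate PCA over a combined trajectory,
# hierarchical clustering of frames into conformational states, cluster
# populations, local point density, representative frames, and a K-means
# rolling-window convergence analysis.

# Superpose every row-frame of X (frames x 3n) onto ref (n x 3); returns X.
superpose_stack <- function(X, ref) {
  n <- ncol(X) / 3L
  for (i in seq_len(nrow(X))) {
    fr <- matrix(X[i, ], n, 3, byrow = TRUE)
    X[i, ] <- t(kabsch_superpose(fr, ref)$coords)
  }
  X
}

row_to_frame <- function(v) matrix(v, length(v) / 3L, 3L, byrow = TRUE)

#' Fit a conformational landscape by coordinate PCA
#'
#' All trajectories are combined into one frame stack, superposed to an
#' iteratively refined mean structure (two refinement passes), and the
#' covariance of the 3N coordinate space is eigen-decomposed (via SVD of
#' the centred frame matrix, which handles both frames > 3N and frames <
#' 3N). Eigenvalues are the per-component variances (nm^2), sorted
#' descending.
#'
#' @param trajectories A named list of `Trajectory` objects sharing one
#'   topology, or a single `Trajectory`.
#' @param selection Atom selection, see [select_atoms()].
#' @return Object of class `LandscapeModel`: `mean_structure` (n x 3, nm),
#'   `eigenvectors` (3n x m, orthonormal columns), `eigenvalues` (nm^2),
#'   `projections` (frames x m, nm), `frame_index` (data frame mapping row
#'   to trajectory name and frame number), `atom_index`.
#' @export
fit_landscape <- function(trajectories, selection = "calpha") {
  if (inherits(trajectories, "Trajectory"))
    trajectories <- list(combined = trajectories)
  nms <- names(trajectories)
  if (is.null(nms)) nms <- paste0("traj", seq_along(trajectories))
  idx <- select_atoms(trajectories[[1]], selection)
  X <- do.call(rbind, lapply(trajectories, flatten_frames, idx = idx))
  fi <- do.call(rbind, lapply(seq_along(trajectories), function(i) {
    data.frame(traj = nms[i], frame = seq_len(n_frames(trajectories[[i]])),
               stringsAsFactors = FALSE)
  }))
  if (nrow(X) < 2L) cs_stop("need at least 2 frames in total", "input_error")

  # iterative-mean superposition: align to frame 1, then twice to the mean
  ref <- row_to_frame(X[1, ])
  X <- superpose_stack(X, ref)
  for (pass in 1:2) {
    ref <- row_to_frame(colMeans(X))
    X <- superpose_stack(X, ref)
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  s <- svd(Xc)
  eig <- s$d^2 / (nrow(X) - 1L)
  keep <- seq_len(min(dim(Xc)))
  V <- s$v[, keep, drop = FALSE]
  # deterministic sign: largest-|.| loading positive
  for (j in seq_len(ncol(V))) {
    piv <- which.max(abs(V[, j]))
    if (V[piv, j] < 0) V[, j] <- -V[, j]
  }
  proj <- Xc %*% V
  colnames(proj) <- paste0("PC", seq_len(ncol(proj)))
  structure(list(mean_structure = row_to_frame(mu),
                 eigenvectors = V,
                 eigenvalues = eig[keep],
                 projections = proj,
                 frame_index = fi,
                 atom_index = idx),
            class = "LandscapeModel")
}

#' @export
print.LandscapeModel <- function(x, ...) {
  cat(sprintf("<LandscapeModel> %d frames, %d coordinates; PC1-4 cover %.1f%% of variance\n",
              nrow(x$projections), nrow(x$eigenvectors),
              100 * variance_explained(x, min(4L, length(x$eigenvalues)))))
  invisible(x)
}

#' Fraction of total variance covered by the first m components
#' @param model A `LandscapeModel`.
#' @param m Number of leading components.
#' @return Fraction in (0, 1].
#' @export
variance_explained <- function(model, m) {
  sum(model$eigenvalues[seq_len(m)]) / sum(model$eigenvalues)
}

#' Cluster frames into conformational states
#'
#' Agglomerative clustering (default "average" linkage) on Euclidean
#' distance in the first `n_pc` principal components, cut to exactly `k`
#' groups. Cluster ids are relabelled 1..k in order of first appearance
#' along the combined trajectory, so labels are deterministic given the
#' input order.
#'
#' @param model A `LandscapeModel`.
#' @param n_pc Number of leading PCs to cluster in (default 4).
#' @param k Number of clusters (default 5).
#' @param linkage `hclust` linkage method (default `"average"`).
#' @return Object of class `ClusterAssignment`: `labels` (per-frame id in
#'   1..k), `k`, `n_pc`, `linkage`.
#' @export
cluster_frames <- function(model, n_pc = 4, k = 5, linkage = "average") {
  P <- model$projections
  n_pc <- min(n_pc, ncol(P))
  if (k > nrow(P)) cs_stop("k exceeds the number of frames", "input_error")
  if (k == 1L) {
    raw <- rep(1L, nrow(P))
  } else {
    hc <- hclust(dist(P[, seq_len(n_pc), drop = FALSE]), method = linkage)
    raw <- cutree(hc, k = k)
  }
  first <- order(vapply(seq_len(k), function(g) which(raw == g)[1], numeric(1)))
  relab <- integer(k); relab[first] <- seq_len(k)
  structure(list(labels = relab[raw], k = as.integer(k),
                 n_pc = as.integer(n_pc), linkage = linkage),
            class = "ClusterAssignment")
}

#' Cluster population tables
#'
#' Two complementary percentage tables: the share of each cluster
#' contributed by each group (each cluster row sums to 100%), and the
#' composition of each group across clusters (each group column sums to
#' 100%).
#'
#' @param assignment A `ClusterAssignment`.
#' @param group_of Character vector, one group label per frame.
#' @return List with matrices `cluster_share_by_group` and
#'   `group_composition` (clusters x groups, percent).
#' @export
population_table <- function(assignment, group_of) {
  lab <- assignment$labels
  if (length(group_of) != length(lab))
    cs_stop("group_of must give one group per frame", "input_error")
  tab <- table(cluster = factor(lab, levels = seq_len(assignment$k)),
               group = group_of)
  share <- 100 * sweep(tab, 1, pmax(rowSums(tab), 1), `/`)
  comp <- 100 * sweep(tab, 2, colSums(tab), `/`)
  list(cluster_share_by_group = as.matrix(unclass(share)),
       group_composition = as.matrix(unclass(comp)))
}

#' Local point density in PC space
#'
#' Gaussian product-kernel density estimate of each frame's projection
#' among all projections, using Scott's rule per dimension when
#' `bandwidth = "auto"`. Densities are normalised to a maximum of 1.
#'
#' @param model A `LandscapeModel`.
#' @param n_pc Number of leading PCs (default 2, as for a PC1-vs-PC2 map).
#' @param bandwidth `"auto"` (Scott's rule) or a numeric vector of per-PC
#'   bandwidths, nm.
#' @return Numeric vector in (0, 1], one value per frame.
#' @export
local_density <- function(model, n_pc = 2, bandwidth = "auto") {
  P <- model$projections[, seq_len(min(n_pc, ncol(model$projections))), drop = FALSE]
  nf <- nrow(P)
  if (nf < 2L) cs_stop("need at least 2 frames", "input_error")
  sds <- apply(P, 2, sd)
  if (any(sds < 1e-12))
    cs_stop("zero variance in the chosen PCs", "degeneracy_error")
  h <- if (identical(bandwidth, "auto")) sds * nf^(-1 / (ncol(P) + 4)) else rep(bandwidth, length.out = ncol(P))
  kern <- matrix(1, nf, nf)
  for (d in seq_len(ncol(P))) {
    u <- outer(P[, d], P[, d], `-`) / h[d]
    kern <- kern * dnorm(u) / h[d]
  }
  dens <- rowMeans(kern)
  dens / max(dens)
}

#' Representative (mid-point) frame of a cluster
#'
#' The member frame closest to the cluster centroid in the first `n_pc`
#' PCs; ties broken by the lowest frame index.
#'
#' @param model A `LandscapeModel`.
#' @param assignment A `ClusterAssignment` on the same frames.
#' @param cluster_id Cluster id in 1..k.
#' @return Row index into `model$frame_index` (also carries the trajectory
#'   name and frame number as attributes `traj` and `frame`).
#' @export
representative_frame <- function(model, assignment, cluster_id) {
  members <- which(assignment$labels == cluster_id)
  if (length(members) == 0L) cs_stop("cluster is empty", "input_error")
  P <- model$projections[, seq_len(assignment$n_pc), drop = FALSE]
  centroid <- colMeans(P[members, , drop = FALSE])
  d2 <- rowSums(sweep(P[members, , drop = FALSE], 2, centroid)^2)
  best <- members[which.min(d2)]   # which.min takes the first on ties
  attr(best, "traj") <- model$frame_index$traj[best]
  attr(best, "frame") <- model$frame_index$frame[best]
  best
}

majority_label <- function(v, k) {
  counts <- tabulate(v, nbins = k)
  which.max(counts)   # ties broken toward the smaller label
}

#' Rolling-window K-means convergence analysis
#'
#' K-means (k-means++-style multiple restarts, fixed seed) is run on the
#' combined projections; for each trajectory the convergence frame is the
#' start of the earliest rolling window after which every window's majority
#' cluster equals the final window's majority cluster. Earlier convergence
#' means the repeat settled into its final conformational state sooner.
#' Frames are 1-based: a trajectory that never leaves one cluster converges
#' at frame 1.
#'
#' @param model A `LandscapeModel`.
#' @param k Number of K-means clusters (default 5).
#' @param window Rolling window length in frames (default 10).
#' @param n_pc Number of leading PCs (default 4).
#' @param seed RNG seed for the K-means restarts.
#' @return Named integer vector: convergence frame per trajectory.
#' @export
convergence_analysis <- function(model, k = 5, window = 10, n_pc = 4, seed = 1L) {
  if (window < 1L) cs_stop("window must be >= 1", "input_error")
  P <- model$projections[, seq_len(min(n_pc, ncol(model$projections))), drop = FALSE]
  lens <- table(model$frame_index$traj)
  if (any(lens < window))
    cs_stop("every trajectory must be at least one window long", "input_error")
  labels <- with_preserved_seed(seed, {
    kmeans(P, centers = min(k, nrow(unique(P))), nstart = 10,
           iter.max = 100)$cluster
  })
  out <- vapply(split(labels, model$frame_index$traj), function(lab) {
    L <- length(lab)
    starts <- seq_len(L - window + 1L)
    maj <- vapply(starts, function(t) majority_label(lab[t:(t + window - 1L)], k),
                  numeric(1))
    target <- maj[length(maj)]
    ok <- rev(cumprod(rev(maj == target))) == 1
    as.integer(starts[which(ok)[1]])
  }, integer(1))
  out
}

# Evaluate expr under set.seed(seed), restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
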
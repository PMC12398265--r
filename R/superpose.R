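# Rigid-body superposition and shape metrics: the metric layer under the
# path-similarity, landscape and flexibility analyses.

#' Resolve an atom selection on a topology
#'
#' @param model A `MolecularModel` (or the topology of a `Trajectory`).
#' @param selection `"calpha"` (default: CA atoms, the standard choice for
#'   backbone shape comparison), `"all"`, an integer vector of residue
#'   numbers, or a single region from a [region_set()] given as an integer
#'   vector.
#' @return Integer vector of atom indices.
#' @export
select_atoms <- function(model, selection = "calpha") {
  if (inherits(model, "Trajectory")) model <- model$topology
  at <- model$atoms
  idx <- if (is.character(selection) && length(selection) == 1L) {
    switch(selection,
           all = seq_len(nrow(at)),
           calpha = {
             ca <- which(at$name == "CA")
             if (length(ca) == 0L) seq_len(nrow(at)) else ca
           },
           cs_stop(sprintf("unknown selection '%s'", selection), "input_error"))
  } else {
    which(at$resno %in% as.integer(selection))
  }
  if (length(idx) == 0L) cs_stop("selection matches no atoms", "input_error")
  idx
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Finds the rotation and translation minimising the (weighted) RMSD of
#' `mobile` onto `reference`, with the standard reflection correction: when
#' the cross-covariance determinant is negative the smallest singular
#' vector's sign is flipped so the returned rotation is proper
#' (determinant +1).
#'
#' @param mobile,reference n x 3 coordinate matrices, nm; equal atom counts,
#'   n >= 3, not all points collinear.
#' @param weights Optional non-negative per-atom weights.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length-3,
#'   nm), `rmsd` (nm) and `coords` (the transformed mobile coordinates).
#'   The transform maps mobile points p to `p %*% rotation + translation`.
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)))
    cs_stop("mobile and reference must have identical dimensions", "input_error")
  n <- nrow(mobile)
  if (n < 3L) cs_stop("superposition needs at least 3 atoms", "input_error")
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || sum(weights) <= 0)
    cs_stop("weights must be non-negative with positive sum", "input_error")
  w <- weights / sum(weights)
  cm <- colSums(mobile * w); cr <- colSums(reference * w)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  # collinearity check: a degenerate point cloud leaves the rotation
  # under-determined about the line
  if (svd(B * sqrt(w))$d[2] < 1e-10 && svd(A * sqrt(w))$d[2] < 1e-10)
    cs_stop("degenerate (collinear) geometry: rotation is not unique",
            "degeneracy_error")
  H <- t(A * w) %*% B
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$u %*% D %*% t(s$v)
  fitted <- A %*% R
  rmsd <- sqrt(sum(w * rowSums((fitted - B)^2)))
  list(rotation = R,
       translation = as.numeric(cr - cm %*% R),
       rmsd = rmsd,
       coords = sweep(fitted, 2, cr, `+`))
}

#' RMSD between two coordinate sets after optimal superposition
#' @inheritParams kabsch_superpose
#' @return RMSD in nm.
#' @export
superposed_rmsd <- function(mobile, reference, weights = NULL) {
  kabsch_superpose(mobile, reference, weights)$rmsd
}

#' All-vs-all frame RMSD matrix
#'
#' Every frame is used as a reference and every other frame is superposed
#' onto it, giving a symmetric matrix with zero diagonal.
#'
#' @param traj A `Trajectory`.
#' @param selection Atom selection, see [select_atoms()].
#' @return Symmetric frames x frames matrix, nm.
#' @export
pairwise_rmsd_matrix <- function(traj, selection = "calpha") {
  if (n_frames(traj) < 2L) cs_stop("need at least 2 frames", "input_error")
  idx <- select_atoms(traj, selection)
  X <- flatten_frames(traj, idx)
  M <- cpp_rmsd_grid(X, X)
  M <- (M + t(M)) / 2   # enforce exact symmetry against round-off
  diag(M) <- 0
  M
}

# frames x 3n matrix (rows are flattened frames) for a selection
flatten_frames <- function(traj, idx) {
  array_to_xyz(traj$coords[, idx, , drop = FALSE])
}

#' Radius of gyration of one conformation
#'
#' Mass-weighted root-mean-square distance of atoms from the centre of
#' mass; uniform masses when none are given.
#'
#' @param coords n x 3 matrix, nm.
#' @param masses Optional positive per-atom masses.
#' @return Rg in nm.
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3)
  n <- nrow(coords)
  if (n < 1L) cs_stop("need at least one atom", "input_error")
  if (is.null(masses)) masses <- rep(1, n)
  if (any(masses <= 0)) cs_stop("masses must be positive", "input_error")
  w <- masses / sum(masses)
  com <- colSums(coords * w)
  sqrt(sum(w * rowSums(sweep(coords, 2, com)^2)))
}

#' Per-frame radius-of-gyration series with a plateau diagnostic
#'
#' Used to check that repeats have settled: the slope of a least-squares
#' line over the final third of the series is attached as attribute
#' `plateau_slope` (nm per frame; near zero once the trajectory has
#' plateaued).
#'
#' @param traj A `Trajectory`.
#' @param selection Atom selection, see [select_atoms()].
#' @param masses Optional per-atom masses (for the selected atoms).
#' @return Numeric vector, one Rg per frame, with attribute `plateau_slope`.
#' @export
rg_series <- function(traj, selection = "all", masses = NULL) {
  idx <- select_atoms(traj, selection)
  rg <- vapply(seq_len(n_frames(traj)),
               function(i) radius_of_gyration(traj$coords[i, idx, ], masses),
               numeric(1))
  nf <- length(rg)
  slope <- 0
  if (nf >= 2L) {
    ti <- seq(nf - max(2L, ceiling(nf / 3)) + 1L, nf)
    slope <- unname(coef(lm(rg[ti] ~ ti))[2])
  }
  attr(rg, "plateau_slope") <- slope
  rg
}
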
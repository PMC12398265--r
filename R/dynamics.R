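# Flexibility and correlated-motion analyses: windowed RMSF, dynamic
# cross-correlation matrices, inter-region distances and contact
# probabilities.

# Superpose the frames x 3n stack to its own (iteratively refined) mean.
superpose_to_mean <- function(X) {
  X <- superpose_stack(X, row_to_frame(X[1, ]))
  for (pass in 1:2) X <- superpose_stack(X, row_to_frame(colMeans(X)))
  X
}

#' Windowed per-residue RMSF
#'
#' The trajectory is split into consecutive non-overlapping windows of
#' `window` frames (a trailing partial window is dropped). Each window is
#' superposed to its own mean before computing
#' `RMSF_i = sqrt(mean |r_i(t) - <r_i>|^2)`, so the values measure local
#' flexibility rather than drift. A percent-difference table of every later
#' window against window 1 is attached: negative values mean the selection
#' has become more rigid over time.
#'
#' @param traj A `Trajectory`.
#' @param window Window length in frames (>= 2).
#' @param selection Atom selection, see [select_atoms()].
#' @return Object of class `RmsfWindows`: `rmsf` (windows x residues
#'   matrix, nm), `pct_diff_vs_first` (same shape, window 1 row is 0),
#'   `window`.
#' @export
windowed_rmsf <- function(traj, window, selection = "calpha") {
  nf <- n_frames(traj)
  if (window < 2L) cs_stop("window must span at least 2 frames", "input_error")
  if (window > nf) cs_stop("window exceeds trajectory length", "input_error")
  idx <- select_atoms(traj, selection)
  resno <- traj$topology$atoms$resno[idx]
  nw <- nf %/% window
  n <- length(idx)
  rmsf <- matrix(0, nw, n, dimnames = list(NULL, resno))
  for (w in seq_len(nw)) {
    rows <- ((w - 1L) * window + 1L):(w * window)
    X <- superpose_to_mean(flatten_frames(traj, idx)[rows, , drop = FALSE])
    mu <- colMeans(X)
    dev2 <- sweep(X, 2, mu)^2
    # per-atom squared fluctuation = sum over x,y,z of mean squared dev
    per_axis <- colMeans(dev2)
    rmsf[w, ] <- sqrt(per_axis[seq(1, 3 * n, 3)] + per_axis[seq(2, 3 * n, 3)] +
                        per_axis[seq(3, 3 * n, 3)])
  }
  pct <- sweep(rmsf, 2, rmsf[1, ], function(a, b) 100 * (a - b) / b)
  structure(list(rmsf = rmsf, pct_diff_vs_first = pct,
                 window = as.integer(window)),
            class = "RmsfWindows")
}

#' Dynamic cross-correlation matrix
#'
#' Normalised covariance of per-residue displacement vectors about their
#' mean position after superposing the trajectory to its mean:
#' `C_ij = <dr_i . dr_j> / sqrt(<|dr_i|^2><|dr_j|^2>)` (scalar-product,
#' isotropic convention). Values lie in \[-1, 1\] with unit diagonal;
#' residues with zero variance are reported as NA rather than 0.
#'
#' @param traj A `Trajectory` with at least 2 frames.
#' @param selection Atom selection, see [select_atoms()].
#' @return residue x residue matrix with residue numbers as dimnames.
#' @export
dccm <- function(traj, selection = "calpha") {
  if (n_frames(traj) < 2L) cs_stop("need at least 2 frames", "input_error")
  idx <- select_atoms(traj, selection)
  resno <- traj$topology$atoms$resno[idx]
  X <- superpose_to_mean(flatten_frames(traj, idx))
  D <- sweep(X, 2, colMeans(X))
  n <- length(idx)
  xs <- D[, seq(1, 3 * n, 3), drop = FALSE]
  ys <- D[, seq(2, 3 * n, 3), drop = FALSE]
  zs <- D[, seq(3, 3 * n, 3), drop = FALSE]
  cov <- (crossprod(xs) + crossprod(ys) + crossprod(zs)) / nrow(D)
  v <- diag(cov)
  C <- cov / sqrt(outer(v, v))
  C[v < 1e-20, ] <- NA_real_
  C[, v < 1e-20] <- NA_real_
  diag(C)[v >= 1e-20] <- 1
  C <- pmin(pmax(C, -1), 1)
  dimnames(C) <- list(resno, resno)
  C
}

region_atom_idx <- function(traj, region) {
  which(traj$topology$atoms$resno %in% as.integer(region))
}

#' Per-frame distance between two regions
#'
#' @param traj A `Trajectory`.
#' @param regionA,regionB Integer vectors of residue numbers (disjoint).
#' @param mode `"centroid"` (distance between unweighted region centroids)
#'   or `"min_atom"` (minimum atom-pair distance).
#' @return Numeric vector, one distance per frame, nm.
#' @export
region_distance_series <- function(traj, regionA, regionB,
                                   mode = c("centroid", "min_atom")) {
  mode <- match.arg(mode)
  if (length(intersect(regionA, regionB)))
    cs_stop("regions overlap", "input_error")
  ia <- region_atom_idx(traj, regionA); ib <- region_atom_idx(traj, regionB)
  if (!length(ia) || !length(ib)) cs_stop("empty region selection", "input_error")
  vapply(seq_len(n_frames(traj)), function(i) {
    fa <- traj$coords[i, ia, , drop = FALSE][1, , , drop = TRUE]
    fb <- traj$coords[i, ib, , drop = FALSE][1, , , drop = TRUE]
    if (length(ia) == 1L) fa <- matrix(fa, 1, 3)
    if (length(ib) == 1L) fb <- matrix(fb, 1, 3)
    if (mode == "centroid") {
      sqrt(sum((colMeans(fa) - colMeans(fb))^2))
    } else {
      d2 <- outer(rowSums(fa^2), rowSums(fb^2), `+`) - 2 * fa %*% t(fb)
      sqrt(max(0, min(d2)))
    }
  }, numeric(1))
}

#' Inter-region contact probability
#'
#' A frame is "in contact" when any atom of region A lies strictly below
#' `cutoff` from any atom of region B (a frame counts once no matter how
#' many pairs are in contact). Also returns a residue-pair contact
#' frequency map preserving per-pair multiplicity across frames.
#'
#' @param traj A `Trajectory`.
#' @param regionA,regionB Integer vectors of residue numbers.
#' @param cutoff Contact cutoff, nm; 0.24 is the close-contact convention.
#' @return List: `probability` (fraction of frames in contact),
#'   `pair_map` (data frame res_a, res_b, frequency = fraction of frames in
#'   which that residue pair has any atom pair below cutoff).
#' @export
contact_probability <- function(traj, regionA, regionB, cutoff = 0.24) {
  if (cutoff <= 0) cs_stop("cutoff must be positive", "input_error")
  ia <- region_atom_idx(traj, regionA); ib <- region_atom_idx(traj, regionB)
  if (!length(ia) || !length(ib)) cs_stop("empty region selection", "input_error")
  ra <- traj$topology$atoms$resno[ia]; rb <- traj$topology$atoms$resno[ib]
  nf <- n_frames(traj)
  pair_key <- outer(ra, rb, paste, sep = "_")
  counts <- setNames(numeric(length(unique(as.vector(pair_key)))),
                     unique(as.vector(pair_key)))
  hit <- logical(nf)
  for (i in seq_len(nf)) {
    fa <- matrix(traj$coords[i, ia, ], length(ia), 3)
    fb <- matrix(traj$coords[i, ib, ], length(ib), 3)
    d2 <- outer(rowSums(fa^2), rowSums(fb^2), `+`) - 2 * fa %*% t(fb)
    inc <- d2 < cutoff^2
    hit[i] <- any(inc)
    if (any(inc)) {
      touched <- unique(pair_key[inc])
      counts[touched] <- counts[touched] + 1
    }
  }
  parts <- do.call(rbind, strsplit(names(counts), "_", fixed = TRUE))
  pair_map <- data.frame(res_a = as.integer(parts[, 1]),
                         res_b = as.integer(parts[, 2]),
                         frequency = as.numeric(counts) / nf,
                         stringsAsFactors = FALSE)
  list(probability = mean(hit), pair_map = pair_map)
}
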
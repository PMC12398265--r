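# Rigid-body orientation scanning for inter-domain affinity analysis,
# contact-specificity ranking, and the flat-bottom ring-closure restraint.

#' Principal axis of a coordinate set
#'
#' The eigenvector of the coordinate covariance with the largest
#' eigenvalue — used as the "main axis" of a domain pair for orientation
#' generation.
#'
#' @param coords n x 3 matrix, nm.
#' @return Unit 3-vector.
#' @export
principal_axis <- function(coords) {
  coords <- as.matrix(coords)
  e <- eigen(stats::cov(coords), symmetric = TRUE)
  v <- e$vectors[, 1]
  if (v[which.max(abs(v))] < 0) v <- -v
  v / sqrt(sum(v^2))
}

rotation_about_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Generate rigid-body orientations of a mobile domain around a target axis
#'
#' Poses are the grid of `n_axial` anchor points evenly spaced along the
#' target axis times `n_angles` rotations evenly spaced in \[0, 360)
#' degrees about that axis. At angle 0 each pose is the input orientation
#' translated so the mobile centroid sits at the axial point; every pose
#' preserves the mobile's internal geometry exactly. The defaults (3 x 8 =
#' 24 orientations) are the standard scan density for a two-domain affinity
#' analysis.
#'
#' @param mobile A `MolecularModel` (the domain to reposition).
#' @param axis Unit 3-vector (the target's main axis, see
#'   [principal_axis()]).
#' @param anchor 3-vector: centre of the axial span, nm.
#' @param n_axial Axial positions (default 3).
#' @param n_angles Rotation angles (default 8).
#' @param axial_span Length of the sampled axial segment, nm; positions
#'   are spread symmetrically about `anchor` (a single position sits at
#'   `anchor`).
#' @return Object of class `PoseSet`: list with `poses` (each a list
#'   `rotation`, `translation`, `axial_index`, `angle`), `n_axial`,
#'   `n_angles`. Apply a pose with [apply_pose()].
#' @export
generate_orientations <- function(mobile, axis, anchor = c(0, 0, 0),
                                  n_axial = 3, n_angles = 8, axial_span = 1) {
  if (sqrt(sum(axis^2)) < 1e-12) cs_stop("axis must be non-zero", "input_error")
  if (n_axial < 1L || n_angles < 1L)
    cs_stop("n_axial and n_angles must be >= 1", "input_error")
  axis <- axis / sqrt(sum(axis^2))
  offsets <- if (n_axial == 1L) 0 else seq(-axial_span / 2, axial_span / 2,
                                           length.out = n_axial)
  angles <- 2 * pi * (seq_len(n_angles) - 1L) / n_angles
  poses <- list()
  for (a in seq_len(n_axial)) {
    point <- anchor + offsets[a] * axis
    for (g in seq_len(n_angles)) {
      # pose transform: y = (x - centroid) %*% R + point, i.e. translate the
      # mobile centroid onto the axial point, then rotate about the axis
      # through that point
      poses[[length(poses) + 1L]] <- list(
        rotation = rotation_about_axis(axis, angles[g]),
        translation = point,
        axial_index = a, angle = angles[g])
    }
  }
  structure(list(poses = poses, n_axial = as.integer(n_axial),
                 n_angles = as.integer(n_angles), axis = axis,
                 anchor = anchor),
            class = "PoseSet")
}

#' Apply one pose of a `PoseSet` to the mobile coordinates
#'
#' @param pose_set A `PoseSet` from [generate_orientations()].
#' @param i Pose index.
#' @param mobile The same `MolecularModel` used to build the poses.
#' @return n x 3 matrix of transformed coordinates, nm.
#' @export
apply_pose <- function(pose_set, i, mobile) {
  p <- pose_set$poses[[i]]
  centred <- sweep(mobile$coords, 2, colMeans(mobile$coords))
  sweep(centred %*% p$rotation, 2, p$translation, `+`)
}

#' Rank residue-pair contacts by specificity across poses
#'
#' For every residue pair seen in any pose's contact map: total frequency
#' summed across poses, and specificity = (largest single-pose frequency) /
#' (total frequency). A pair contacting in exactly one pose scores 1; a
#' pair contacting equally in all n poses scores 1/n. Ranked by specificity
#' descending, total frequency as tie-break.
#'
#' @param contact_maps List (one per pose) of data frames with columns
#'   `res_a`, `res_b`, `frequency` — the `pair_map` of
#'   [contact_probability()].
#' @return Data frame `res_a`, `res_b`, `total_frequency`, `max_pose`,
#'   `specificity`, ranked; zero rows (with a warning) when all maps are
#'   empty.
#' @export
rank_contact_specificity <- function(contact_maps) {
  if (length(contact_maps) < 1L) cs_stop("need at least one pose map", "input_error")
  all_rows <- do.call(rbind, lapply(seq_along(contact_maps), function(i) {
    m <- contact_maps[[i]]
    m <- m[m$frequency > 0, , drop = FALSE]
    if (nrow(m) == 0L) return(NULL)
    m$pose <- i
    m
  }))
  if (is.null(all_rows) || nrow(all_rows) == 0L) {
    warning("all contact maps are empty; returning an empty ranking")
    return(data.frame(res_a = integer(0), res_b = integer(0),
                      total_frequency = numeric(0), max_pose = integer(0),
                      specificity = numeric(0)))
  }
  key <- paste(all_rows$res_a, all_rows$res_b, sep = "_")
  split_rows <- split(all_rows, key)
  out <- do.call(rbind, lapply(split_rows, function(g) {
    tot <- sum(g$frequency)
    top <- which.max(g$frequency)
    data.frame(res_a = g$res_a[1], res_b = g$res_b[1],
               total_frequency = tot, max_pose = g$pose[top],
               specificity = g$frequency[top] / tot)
  }))
  out <- out[order(-out$specificity, -out$total_frequency, out$res_a, out$res_b), ]
  rownames(out) <- NULL
  out
}

#' Flat-bottom restraint energy and force
#'
#' Zero between the walls; half-harmonic outside:
#' `E = k/2 (d - upper)^2` beyond the upper wall and `E = k/2 (lower - d)^2`
#' below the lower wall (the 1/2 prefactor convention is recorded here so a
#' user matching the plain-k convention can double `k`). The returned force
#' is the restoring force `-dE/dd` (signed along increasing distance); it
#' is continuous and zero at both walls.
#'
#' @param distance Distance(s) between the restrained atoms, nm (>= 0).
#' @param k Force constant, kJ/mol/nm^2 (default 1000).
#' @param lower,upper Wall positions, nm (defaults 0.15 and 0.4, the
#'   ring-closure restraint used between a lysine amino nitrogen and a
#'   glutamate carboxyl carbon).
#' @return Data frame with columns `distance`, `energy` (kJ/mol) and
#'   `force` (kJ/mol/nm).
#' @export
flat_bottom_energy <- function(distance, k = 1000, lower = 0.15, upper = 0.4) {
  if (k <= 0) cs_stop("force constant must be positive", "input_error")
  if (lower >= upper) cs_stop("lower wall must lie below upper wall", "input_error")
  if (any(distance < 0)) cs_stop("distance must be non-negative", "input_error")
  over <- pmax(distance - upper, 0)
  under <- pmax(lower - distance, 0)
  energy <- 0.5 * k * (over^2 + under^2)
  force <- -k * over + k * under
  data.frame(distance = distance, energy = energy, force = force)
}
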
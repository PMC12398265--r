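# Synthetic coarse-grained trajectories with planted ground truth: anchor
# conformations (ring / hook / extended), dwell-and-transition schedules,
# Gaussian coordinate noise, planted shield-displacement exposure changes
# and planted correlated inter-residue motions. This is a statistical
# stand-in for MD output, not a physics engine: no forces, no thermostat.

#' Build an anchor conformation
#'
#' One bead per residue. `"ring"` places beads on a circle whose chord
#' between consecutive beads equals `bond_length` (so the first and last
#' bead are also one bond apart: the closed, compact state). `"hook"` is a
#' straight stem flowing into a semicircular hook (a J-like open state).
#' `"extended"` is collinear.
#'
#' @param shape_name One of `"ring"`, `"hook"`, `"extended"`.
#' @param n_beads Number of beads (>= 4).
#' @param bond_length Consecutive-bead distance, nm; 0.38 is the
#'   C-alpha - C-alpha virtual bond.
#' @param label Anchor label; defaults to the shape name.
#' @return Object of class `AnchorConformation`: `label`, `coords`
#'   (n x 3, nm).
#' @export
make_anchor <- function(shape_name, n_beads, bond_length = 0.38,
                        label = shape_name) {
  if (n_beads < 4L) cs_stop("anchors need at least 4 beads", "input_error")
  b <- bond_length
  coords <- switch(shape_name,
    extended = cbind((seq_len(n_beads) - 1L) * b, 0, 0),
    ring = {
      theta <- 2 * pi / n_beads
      R <- b / (2 * sin(theta / 2))       # chord = bond_length exactly
      ang <- (seq_len(n_beads) - 1L) * theta
      cbind(R * cos(ang), R * sin(ang), 0)
    },
    hook = {
      n_stem <- max(2L, floor(n_beads * 0.55))
      stem <- cbind(0, (seq_len(n_stem) - 1L) * b, 0)
      n_arc <- n_beads - n_stem
      r <- b / (2 * sin(pi / (2 * n_arc)))  # hook arc spans a semicircle
      phi <- 2 * asin(b / (2 * r))          # chord on the arc = bond_length
      # circle centred beside the stem tip, tangent to the stem direction
      centre <- stem[n_stem, ] + c(r, 0, 0)
      ang0 <- pi                           # stem tip sits on the circle
      ang <- ang0 - seq_len(n_arc) * phi
      arc <- cbind(centre[1] + r * cos(ang), centre[2] + r * sin(ang), 0)
      rbind(stem, arc)
    },
    cs_stop(sprintf("unknown shape '%s'", shape_name), "config_error")
  )
  structure(list(label = label, coords = unname(coords)),
            class = "AnchorConformation")
}

#' Build an anchor whose tail caps (buries) a target segment
#'
#' The first `n_beads - shield_len` beads take the requested base shape;
#' the final `shield_len` beads are lifted out of the chain and placed
#' `gap` nm above the beads starting at `over` — a shield that buries the
#' target segment the way a blocking domain buries an epitope. Because the
#' cap sits at the same relative position in every shape, burial is
#' controlled purely by [plant_exposure_change()] displacement, not by the
#' conformational state itself.
#'
#' @param shape_name Base shape for the core beads (see [make_anchor()]).
#' @param n_beads Total beads including the shield.
#' @param shield_len Number of trailing shield beads.
#' @param over First residue the cap covers (cap bead k sits above core
#'   bead `over + k - 1`).
#' @param gap Cap height above the covered beads, nm (default 0.45:
#'   within occlusion range of a 0.19 nm bead probed at 0.14 nm).
#' @param bond_length Consecutive-bead distance of the core, nm.
#' @param label Anchor label.
#' @return An `AnchorConformation`.
#' @export
make_shielded_anchor <- function(shape_name, n_beads, shield_len = 6L,
                                 over = 9L, gap = 0.45, bond_length = 0.38,
                                 label = shape_name) {
  n_core <- n_beads - shield_len
  core <- make_anchor(shape_name, n_core, bond_length)$coords
  if (over + shield_len - 1L > n_core)
    cs_stop("cap extends past the core beads", "config_error")
  cap <- core[over:(over + shield_len - 1L), , drop = FALSE]
  cap[, 3] <- cap[, 3] + gap
  structure(list(label = label, coords = rbind(core, cap)),
            class = "AnchorConformation")
}

bead_topology <- function(n_beads, bead_radius = 0.19) {
  atoms <- data.frame(
    serial = seq_len(n_beads), name = "CA", element = "C",
    resno = seq_len(n_beads), resid = "ALA", chain = "A",
    stringsAsFactors = FALSE)
  molecular_model(atoms, matrix(0, n_beads, 3),
                  radii = rep(bead_radius, n_beads))
}

#' Specification for a synthetic trajectory
#'
#' @param n_beads Beads per frame.
#' @param schedule List of segments, each
#'   `list(anchor = <label>, dwell = <frames>, interp = <frames>)`:
#'   `dwell` frames at the anchor, then `interp` frames linearly blended
#'   towards the next segment's anchor. Noise is added to every frame.
#' @param noise_sigma Isotropic Gaussian noise per bead coordinate, nm.
#'   The default 0.03 nm is a realistic thermal-fluctuation scale for a
#'   coarse-grained bead.
#' @param bead_radius Bead radius for SASA, nm (0.19 approximates a
#'   C-alpha pseudo-atom with implicit side chain mass).
#' @param seed Integer RNG seed; identical (spec, seed) pairs give
#'   bit-identical trajectories.
#' @return A `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_beads, schedule, noise_sigma = 0.03,
                           bead_radius = 0.19, seed = 1L) {
  if (noise_sigma < 0) cs_stop("noise_sigma must be >= 0", "input_error")
  total <- sum(vapply(schedule, function(s) s$dwell + (s$interp %||% 0L),
                      numeric(1)))
  if (total < 2L) cs_stop("schedule must produce at least 2 frames", "input_error")
  structure(list(n_beads = as.integer(n_beads), schedule = schedule,
                 noise_sigma = noise_sigma, bead_radius = bead_radius,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic trajectory with per-frame ground truth
#'
#' Dwell frames are the anchor coordinates plus isotropic Gaussian noise;
#' interpolation frames are a linear blend of the flanking anchors plus the
#' same noise. Interpolation frames are labelled `"transition:<a>-<b>"`.
#'
#' @param spec A [synthetic_spec()].
#' @param anchors List of `AnchorConformation`s covering every label the
#'   schedule references; all must share `spec$n_beads` beads.
#' @param frame_interval Time per frame, ps (default 100, the usual
#'   coordinate-saving interval).
#' @return List: `trajectory` (a `Trajectory`), `labels` (ground-truth
#'   label per frame).
#' @export
generate_trajectory <- function(spec, anchors, frame_interval = 100) {
  amap <- setNames(anchors, vapply(anchors, `[[`, character(1), "label"))
  for (a in amap)
    if (nrow(a$coords) != spec$n_beads)
      cs_stop(sprintf("anchor '%s' has %d beads, spec expects %d",
                      a$label, nrow(a$coords), spec$n_beads), "config_error")
  segs <- spec$schedule
  for (s in segs)
    if (!s$anchor %in% names(amap))
      cs_stop(sprintf("schedule references unknown anchor '%s'", s$anchor),
              "config_error")

  frames <- list(); labels <- character(0)
  with_preserved_seed(spec$seed, {
    for (si in seq_along(segs)) {
      s <- segs[[si]]
      A <- amap[[s$anchor]]$coords
      for (f in seq_len(s$dwell)) {
        frames[[length(frames) + 1L]] <- A + noise_mat(spec)
        labels <- c(labels, s$anchor)
      }
      ni <- s$interp %||% 0L
      if (ni > 0L && si < length(segs)) {
        Bmat <- amap[[segs[[si + 1L]]$anchor]]$coords
        for (f in seq_len(ni)) {
          w <- f / (ni + 1L)
          frames[[length(frames) + 1L]] <- (1 - w) * A + w * Bmat + noise_mat(spec)
          labels <- c(labels,
                      sprintf("transition:%s-%s", s$anchor, segs[[si + 1L]]$anchor))
        }
      }
    }
  })
  co <- array(0, dim = c(length(frames), spec$n_beads, 3L))
  for (i in seq_along(frames)) co[i, , ] <- frames[[i]]
  traj <- trajectory(bead_topology(spec$n_beads, spec$bead_radius), co,
                     frame_interval)
  list(trajectory = traj, labels = labels)
}

noise_mat <- function(spec) {
  if (spec$noise_sigma == 0) return(matrix(0, spec$n_beads, 3))
  matrix(rnorm(3L * spec$n_beads, sd = spec$noise_sigma), spec$n_beads, 3)
}

#' Plant an exposure change by displacing a shield region
#'
#' From `switch_frame` on, the shield beads are rigidly translated by
#' `displacement` nm along the direction from the target centroid to the
#' shield centroid (i.e. directly away from the target). Target coordinates
#' are untouched, so any change in the target's SASA or inter-region
#' distance is attributable to the shield's departure — the synthetic
#' analogue of one domain unblocking a buried epitope.
#'
#' @param traj A `Trajectory`.
#' @param shield,target Disjoint integer vectors of residue numbers.
#' @param displacement Rigid displacement, nm (0 = identity).
#' @param switch_frame First frame (1-based) at which the shield is
#'   displaced; must be in 1..n_frames.
#' @return The modified `Trajectory`.
#' @export
plant_exposure_change <- function(traj, shield, target, displacement,
                                  switch_frame) {
  if (length(intersect(shield, target)))
    cs_stop("shield and target regions must be disjoint", "config_error")
  nf <- n_frames(traj)
  if (switch_frame < 1L || switch_frame > nf)
    cs_stop("switch_frame must lie within the trajectory", "input_error")
  if (displacement == 0) return(traj)
  is_ <- region_atom_idx(traj, shield); it <- region_atom_idx(traj, target)
  if (!length(is_) || !length(it)) cs_stop("region matches no atoms", "input_error")
  ref <- switch_frame
  cs_ <- colMeans(matrix(traj$coords[ref, is_, ], length(is_), 3))
  ct <- colMeans(matrix(traj$coords[ref, it, ], length(it), 3))
  u <- cs_ - ct
  u <- u / sqrt(sum(u^2))
  shift <- displacement * u
  for (i in ref:nf)
    traj$coords[i, is_, ] <- sweep(matrix(traj$coords[i, is_, ], length(is_), 3),
                                   2, shift, `+`)
  traj
}

#' Plant correlated motion between bead pairs
#'
#' Adds a shared zero-mean scalar drive s(t) ~ N(0, amplitude^2) along a
#' fixed unit direction to bead i and `sign * s(t)` to bead j, so the
#' downstream cross-correlation of the pair approaches +1 or -1 when the
#' amplitude dominates the background noise.
#'
#' @param traj A `Trajectory`.
#' @param pairs List of `c(i, j, sign)` triples (sign +1 or -1).
#' @param amplitude Drive standard deviation, nm (> 0).
#' @param seed Integer RNG seed.
#' @return The modified `Trajectory`.
#' @export
plant_correlated_motion <- function(traj, pairs, amplitude, seed = 1L) {
  if (amplitude <= 0) cs_stop("amplitude must be positive", "input_error")
  nf <- n_frames(traj)
  with_preserved_seed(seed, {
    for (p in pairs) {
      i <- p[1]; j <- p[2]; sgn <- p[3]
      if (i == j) cs_stop("correlated pair must involve two distinct beads",
                          "config_error")
      u <- rnorm(3); u <- u / sqrt(sum(u^2))
      s <- rnorm(nf, sd = amplitude)
      ii <- region_atom_idx(traj, i); jj <- region_atom_idx(traj, j)
      for (f in seq_len(nf)) {
        traj$coords[f, ii, ] <- traj$coords[f, ii, ] + s[f] * u
        traj$coords[f, jj, ] <- traj$coords[f, jj, ] + sgn * s[f] * u
      }
    }
  })
  traj
}

#' Write a ground-truth label table
#'
#' @param labels Per-frame ground-truth labels.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(labels, path) {
  write_table(data.frame(frame = seq_along(labels), label = labels), path)
}
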
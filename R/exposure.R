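# Solvent-accessible surface area over trajectories, region aggregation and
# percent-difference tables against a reference conformational state — the
# epitope-exposure computation at the centre of the pipeline.

#' Shrake-Rupley SASA of one conformation
#'
#' Test points are placed on a deterministic golden-spiral sphere of
#' `n_points` around every atom at radius r + probe; a point is accessible
#' when it lies outside every neighbour's expanded sphere. Neighbour search
#' is restricted to atoms within r_i + r_j + 2*probe. Area per atom is
#' `4*pi*(r+probe)^2 * accessible/n_points`.
#'
#' @param coords n x 3 matrix, nm.
#' @param radii Per-atom radii, nm (see [element_radii()]).
#' @param probe_radius Solvent probe radius, nm; 0.14 is the standard water
#'   probe.
#' @param n_points Test points per atom (default 960).
#' @return Per-atom SASA, nm^2.
#' @export
shrake_rupley <- function(coords, radii, probe_radius = 0.14, n_points = 960) {
  coords <- as.matrix(coords)
  if (probe_radius < 0) cs_stop("probe radius must be non-negative", "input_error")
  if (n_points < 24) cs_stop("n_points must be at least 24", "input_error")
  if (length(radii) != nrow(coords))
    cs_stop("one radius per atom required", "input_error")
  if (any(radii <= 0)) cs_stop("radii must be positive", "input_error")
  as.numeric(cpp_sasa(coords, radii, probe_radius, as.integer(n_points)))
}

#' Sum per-atom SASA into per-residue SASA
#'
#' @param atom_sasa Per-atom SASA, nm^2.
#' @param model The `MolecularModel` the atoms belong to.
#' @return Named numeric vector (names are residue numbers), nm^2.
#' @export
residue_sasa <- function(atom_sasa, model) {
  res <- vapply(split(atom_sasa, model$atoms$resno), sum, numeric(1))
  res[order(as.integer(names(res)))]
}

#' Per-residue SASA over every frame of a trajectory
#'
#' @param traj A `Trajectory`.
#' @param probe_radius,n_points See [shrake_rupley()].
#' @return Object of class `SasaSeries`: `values` (frames x residues
#'   matrix, nm^2, residue numbers as column names), `probe_radius`,
#'   `n_points`.
#' @export
sasa_series <- function(traj, probe_radius = 0.14, n_points = 960) {
  radii <- traj$topology$atoms$radius
  resno <- traj$topology$atoms$resno
  nf <- n_frames(traj)
  vals <- t(vapply(seq_len(nf), function(i) {
    a <- shrake_rupley(frame_coords(traj, i), radii, probe_radius, n_points)
    residue_sasa(a, traj$topology)
  }, numeric(length(unique(resno)))))
  structure(list(values = vals, probe_radius = probe_radius,
                 n_points = as.integer(n_points)),
            class = "SasaSeries")
}

#' Per-frame total SASA of each region
#'
#' @param sasa A `SasaSeries`.
#' @param regions A `RegionSet`.
#' @return frames x regions matrix, nm^2.
#' @export
region_series <- function(sasa, regions) {
  vals <- sasa$values
  have <- as.integer(colnames(vals))
  out <- vapply(regions, function(resids) {
    missing <- setdiff(resids, have)
    if (length(missing))
      cs_stop(sprintf("region residues not in topology: %s",
                      paste(missing, collapse = ",")), "input_error")
    rowSums(vals[, as.character(resids), drop = FALSE])
  }, numeric(nrow(vals)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(regions)))
  out
}

sem <- function(x) stats::sd(x) / sqrt(length(x))

#' Per-region, per-cluster delta table against a reference state
#'
#' For each group g, conformational cluster c and region r the table
#' reports the mean metric and its SEM over member frames, plus the percent
#' difference from the group's reference cluster:
#' `100 * (mean_gcr - mean_g,ref,r) / mean_g,ref,r`, with the SEM of the
#' ratio propagated in quadrature. With two groups, cross-group rows
#' (same cluster, second group vs first, first-group mean as denominator)
#' are appended. SEM treats frames as independent samples; `block` > 1
#' switches to a block-averaged SEM (means of consecutive blocks of frames
#' as samples), which is more honest for autocorrelated MD frames.
#'
#' @param series frames x regions matrix (e.g. from [region_series()], or
#'   any per-frame per-region metric such as inter-region distances).
#' @param assignment A `ClusterAssignment` for the same frames.
#' @param reference_cluster Cluster id (or name in `cluster_names`) used as
#'   the reference state.
#' @param group_of Optional character vector, one group per frame; a single
#'   group is assumed when absent.
#' @param cluster_names Optional character names for cluster ids 1..k.
#' @param block Block length in frames for the block-averaged SEM
#'   (default 1 = plain SEM over frames).
#' @return A data frame of class `DeltaTable` with columns `region`,
#'   `cluster`, `group`, `comparison`, `n_frames`, `mean`, `sem`,
#'   `pct_diff`, `pct_diff_sem`, `is_reference`.
#' @export
delta_table <- function(series, assignment, reference_cluster = 1L,
                        group_of = NULL, cluster_names = NULL, block = 1L) {
  series <- as.matrix(series)
  lab <- assignment$labels
  if (nrow(series) != length(lab))
    cs_stop("series rows must match assignment frames", "input_error")
  if (is.null(group_of)) group_of <- rep("all", nrow(series))
  if (is.null(cluster_names)) cluster_names <- as.character(seq_len(assignment$k))
  if (is.character(reference_cluster))
    reference_cluster <- match(reference_cluster, cluster_names)
  ref <- as.integer(reference_cluster)

  blocked <- function(x) {
    if (block <= 1L || length(x) < 2L * block) return(x)
    nb <- floor(length(x) / block)
    vapply(seq_len(nb), function(b) mean(x[((b - 1L) * block + 1L):(b * block)]),
           numeric(1))
  }
  groups <- unique(group_of)
  rows <- list()
  stats_for <- function(g, c, r) {
    x <- blocked(series[group_of == g & lab == c, r])
    list(n = length(x), mean = mean(x), sem = if (length(x) > 1) sem(x) else NA_real_)
  }
  for (g in groups) {
    if (!any(group_of == g & lab == ref))
      cs_stop(sprintf("reference cluster empty within group '%s'", g),
              "input_error")
    for (r in colnames(series)) {
      base <- stats_for(g, ref, r)
      for (c in sort(unique(lab[group_of == g]))) {
        st <- stats_for(g, c, r)
        if (c == ref) {
          pd <- 0; pdsem <- NA_real_
        } else {
          if (abs(base$mean) < 1e-12)
            cs_stop(sprintf("reference mean is zero for region '%s' in group '%s'", r, g),
                    "undefined_ratio")
          pd <- 100 * (st$mean - base$mean) / base$mean
          pdsem <- 100 * abs(st$mean / base$mean) *
            sqrt((st$sem / st$mean)^2 + (base$sem / base$mean)^2)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          region = r, cluster = cluster_names[c], group = g,
          comparison = "vs_reference_cluster", n_frames = st$n,
          mean = st$mean, sem = st$sem, pct_diff = pd, pct_diff_sem = pdsem,
          is_reference = c == ref, stringsAsFactors = FALSE)
      }
    }
  }
  # cross-group: same cluster, later groups vs the first group
  if (length(groups) > 1L) {
    g0 <- groups[1]
    for (g in groups[-1]) {
      for (r in colnames(series)) {
        for (c in intersect(sort(unique(lab[group_of == g0])),
                            sort(unique(lab[group_of == g])))) {
          a <- stats_for(g0, c, r); b <- stats_for(g, c, r)
          if (abs(a$mean) < 1e-12) next
          pd <- 100 * (b$mean - a$mean) / a$mean
          pdsem <- 100 * abs(b$mean / a$mean) *
            sqrt((b$sem / b$mean)^2 + (a$sem / a$mean)^2)
          rows[[length(rows) + 1L]] <- data.frame(
            region = r, cluster = cluster_names[c], group = g,
            comparison = paste0("vs_group_", g0), n_frames = b$n,
            mean = b$mean, sem = b$sem, pct_diff = pd, pct_diff_sem = pdsem,
            is_reference = FALSE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("DeltaTable", class(out))
  out
}

#' Per-residue average SASA difference from a baseline
#'
#' Mean SASA of every residue over all frames minus its mean over the
#' baseline frames (e.g. the starting conformational state).
#'
#' @param sasa A `SasaSeries`.
#' @param baseline_frames Integer vector of frame indices.
#' @return Named numeric vector, one value per residue, nm^2.
#' @export
residue_profile <- function(sasa, baseline_frames) {
  if (length(baseline_frames) == 0L)
    cs_stop("baseline must contain at least one frame", "input_error")
  colMeans(sasa$values) -
    colMeans(sasa$values[baseline_frames, , drop = FALSE])
}
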
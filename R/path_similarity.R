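# Path-similarity analysis: trajectories compared as sets of conformations
# under the Hausdorff distance, with superposed C-alpha RMSD as the frame
# metric. Higher values mean increasingly dissimilar trajectories.

psa_grid <- function(P, Q, selection) {
  if (n_frames(P) < 1L || n_frames(Q) < 1L)
    cs_stop("trajectories must be non-empty", "input_error")
  ip <- select_atoms(P, selection); iq <- select_atoms(Q, selection)
  if (length(ip) != length(iq))
    cs_stop("selections have different atom counts in P and Q", "input_error")
  cpp_rmsd_grid(flatten_frames(P, ip), flatten_frames(Q, iq))
}

#' Directed Hausdorff distance between two trajectories
#'
#' max over frames p of P of (min over frames q of Q of superposed
#' RMSD(p, q)): the RMSD between one frame of P and its least similar
#' nearest neighbour in Q.
#'
#' @param P,Q `Trajectory` objects over the same topology.
#' @param selection Atom selection, see [select_atoms()].
#' @return Distance in nm.
#' @export
directed_hausdorff <- function(P, Q, selection = "calpha") {
  g <- psa_grid(P, Q, selection)
  max(apply(g, 1, min))
}

#' Symmetric Hausdorff distance between two trajectories
#'
#' `max(directed(P|Q), directed(Q|P))`. The symmetric form is a
#' pseudometric on trajectories and is the default throughout; the directed
#' form is available via [directed_hausdorff()].
#'
#' @inheritParams directed_hausdorff
#' @return Distance in nm.
#' @export
hausdorff <- function(P, Q, selection = "calpha") {
  g <- psa_grid(P, Q, selection)
  max(max(apply(g, 1, min)), max(apply(g, 2, min)))
}

#' All-vs-all path-similarity matrix across repeat trajectories
#'
#' Computes the (symmetric by default) Hausdorff distance between every
#' pair of named trajectories. When `groups` is given, the mean
#' off-diagonal value within each group is attached so two groups (e.g.
#' wild-type vs clipped repeats) can be compared on a common scale.
#'
#' @param trajectories Named list of `Trajectory` objects (>= 2).
#' @param selection Atom selection, see [select_atoms()].
#' @param method `"hausdorff-symmetric"` (default) or
#'   `"hausdorff-directed"` (the directed values; the matrix is then not
#'   symmetric in general).
#' @param groups Optional named character vector mapping trajectory name to
#'   group label.
#' @return Matrix with `labels` as dimnames, attribute `method`, and, when
#'   groups are given, attribute `group_means` (mean off-diagonal
#'   within-group distance).
#' @export
psa_matrix <- function(trajectories, selection = "calpha",
                       method = c("hausdorff-symmetric", "hausdorff-directed"),
                       groups = NULL) {
  method <- match.arg(method)
  nms <- names(trajectories)
  if (length(trajectories) < 2L)
    cs_stop("need at least 2 trajectories", "input_error")
  if (is.null(nms) || anyDuplicated(nms))
    cs_stop("trajectories must have unique names", "input_error")
  n <- length(trajectories)
  M <- matrix(0, n, n, dimnames = list(nms, nms))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      g <- psa_grid(trajectories[[i]], trajectories[[j]], selection)
      dij <- max(apply(g, 1, min)); dji <- max(apply(g, 2, min))
      if (method == "hausdorff-symmetric") {
        M[i, j] <- M[j, i] <- max(dij, dji)
      } else {
        M[i, j] <- dij; M[j, i] <- dji
      }
    }
  }
  attr(M, "method") <- method
  if (!is.null(groups)) {
    gm <- vapply(unique(groups), function(g) {
      sel <- nms[nms %in% names(groups)[groups == g]]
      sub <- M[sel, sel, drop = FALSE]
      mean(sub[upper.tri(sub) | lower.tri(sub)])
    }, numeric(1))
    attr(M, "group_means") <- gm
  }
  M
}
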
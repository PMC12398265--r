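# Shared fixtures and small independent oracles, all built in code.

# minimal PDB text: one CA atom per residue at the given nm coordinates
toy_pdb <- function(coords_nm, resno = seq_len(nrow(coords_nm)),
                    chain = "A", name = "CA", element = "C") {
  ang <- coords_nm * 10
  paste(sprintf(
    "ATOM  %5d  %-3s ALA %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
    seq_len(nrow(ang)), name, chain, resno, ang[, 1], ang[, 2], ang[, 3],
    element), collapse = "\n")
}

multi_model_pdb <- function(frames_nm) {
  blocks <- vapply(seq_along(frames_nm), function(i) {
    paste0(sprintf("MODEL     %4d\n", i), toy_pdb(frames_nm[[i]]), "\nENDMDL")
  }, character(1))
  paste(c(blocks, "END"), collapse = "\n")
}

# trajectory straight from a list of n x 3 frames
toy_trajectory <- function(frames_nm, bead_radius = 0.19) {
  co <- array(0, dim = c(length(frames_nm), nrow(frames_nm[[1]]), 3))
  for (i in seq_along(frames_nm)) co[i, , ] <- frames_nm[[i]]
  trajectory(confshift:::bead_topology(nrow(frames_nm[[1]]), bead_radius), co)
}

random_frames <- function(n_frames, n_atoms, scale = 1, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_frames), function(i) matrix(rnorm(n_atoms * 3, sd = scale),
                                               n_atoms, 3))
}

# adjusted Rand index between two labelings (independent of any clustering code)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# brute-force per-offset motif comparison, written independently of the
# package's scanner
brute_motif_forward <- function(res, cls, pattern_syms, max_mm) {
  m <- length(pattern_syms)
  hits <- NULL
  for (o in seq_len(length(res) - m + 1)) {
    mm <- 0
    for (j in seq_len(m)) {
      s <- pattern_syms[j]
      k <- o + j - 1
      bad <- if (s == "x") FALSE
      else if (s == "n" || s == "p") cls[k] != s
      else res[k] != s
      if (bad) mm <- mm + 1
    }
    if (mm <= max_mm) hits <- rbind(hits, c(o, o + m - 1, mm))
  }
  hits
}
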
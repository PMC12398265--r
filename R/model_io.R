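# Structure/trajectory/region I/O.
#
# Unit conventions for the whole package:
#   * coordinates are nanometres internally (PDB files are Angstrom; the
#     readers and writers convert),
#   * residue numbering is 1-based mature-protein numbering, region spans
#     are inclusive on both ends,
#   * time is picoseconds (frame_interval).

#' Van der Waals radii by element
#'
#' The radius table used for Shrake-Rupley SASA, in nm. Hydrogens are kept
#' as explicit atoms (0.120 nm) when present in the input; they are never
#' merged into heavy atoms. Elements not listed fall back to the carbon
#' radius.
#'
#' @return Named numeric vector of radii in nm.
#' @export
element_radii <- function() {
  c(C = 0.170, N = 0.155, O = 0.152, S = 0.180, H = 0.120,
    P = 0.180, F = 0.147, CL = 0.175, BR = 0.185, I = 0.198)
}

radius_for_element <- function(element) {
  tab <- element_radii()
  r <- tab[toupper(element)]
  r[is.na(r)] <- tab[["C"]]
  unname(r)
}

#' Construct a molecular model
#'
#' A `MolecularModel` holds one conformation: an atom table (serial, name,
#' element, residue number/name, chain) plus an n x 3 coordinate matrix in
#' nm and a per-atom radius vector in nm.
#'
#' @param atoms Data frame with columns `serial`, `name`, `element`,
#'   `resno`, `resid`, `chain`.
#' @param coords Numeric n x 3 matrix, nm.
#' @param radii Optional per-atom radii, nm; assigned from
#'   [element_radii()] when missing.
#' @return Object of class `MolecularModel`.
#' @export
molecular_model <- function(atoms, coords, radii = NULL) {
  coords <- as.matrix(coords)
  dimnames(coords) <- NULL
  if (nrow(atoms) == 0L) cs_stop("model must contain at least one atom", "empty_input")
  if (nrow(coords) != nrow(atoms) || ncol(coords) != 3L)
    cs_stop("coords must be an n x 3 matrix matching the atom table", "input_error")
  if (any(!is.finite(coords)))
    cs_stop("coordinates must be finite", "input_error")
  if (is.null(radii)) radii <- radius_for_element(atoms$element)
  if (any(radii <= 0)) cs_stop("atomic radii must be positive", "input_error")
  atoms$radius <- radii
  structure(list(atoms = atoms, coords = coords), class = "MolecularModel")
}

#' @export
print.MolecularModel <- function(x, ...) {
  cat(sprintf("<MolecularModel> %d atoms, %d residues, chains: %s\n",
              nrow(x$atoms), length(unique(x$atoms$resno)),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

#' Number of atoms in a model or trajectory
#' @param x A `MolecularModel` or `Trajectory`.
#' @return Integer atom count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "Trajectory")) nrow(x$topology$atoms) else nrow(x$atoms)
}

aa321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
           GLU = "E", GLY = "G", HIS = "H", HSD = "H", HSE = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P", SER = "S",
           THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' One-letter sequence of a model
#'
#' Derived per chain from residue names; unknown residue names become `X`.
#'
#' @param model A `MolecularModel`.
#' @return Named character vector, one sequence string per chain.
#' @export
model_sequence <- function(model) {
  at <- model$atoms
  out <- vapply(split(at, at$chain), function(ch) {
    res <- ch[!duplicated(ch$resno), , drop = FALSE]
    res <- res[order(res$resno), , drop = FALSE]
    one <- aa321[toupper(res$resid)]
    one[is.na(one)] <- "X"
    paste(one, collapse = "")
  }, character(1))
  out
}

# ---- PDB reading -----------------------------------------------------------

parse_pdb_atoms <- function(lines) {
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_atom))
    cs_stop("no ATOM/HETATM records found in PDB input", "empty_input")
  al <- lines[is_atom]
  num <- function(s) suppressWarnings(as.numeric(s))
  fld <- function(from, to) trimws(substr(al, from, to))
  x <- num(fld(31, 38)); y <- num(fld(39, 46)); z <- num(fld(47, 54))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad))
    cs_stop(sprintf("unparseable ATOM record (line %d of atom records): '%s'",
                    bad[1], al[bad[1]]), "format_error")
  element <- fld(77, 78)
  name <- fld(13, 16)
  # element column may be absent in minimal files; fall back to atom name
  guess <- sub("^[0-9]*", "", name)
  element[element == ""] <- substr(guess[element == ""], 1, 1)
  atoms <- data.frame(
    serial  = num(fld(7, 11)),
    name    = name,
    element = element,
    resno   = as.integer(num(fld(23, 26))),
    resid   = fld(18, 20),
    chain   = substr(al, 22, 22),
    stringsAsFactors = FALSE
  )
  atoms$chain[atoms$chain == " "] <- "A"  # single-chain assumption for blank ids
  list(atoms = atoms, coords_ang = cbind(x, y, z))
}

#' Read a structure from PDB text or file
#'
#' Parses ATOM/HETATM records, converts coordinates from Angstrom to nm and
#' assigns per-atom radii from [element_radii()]. Only the first MODEL of a
#' multi-model file is returned; use [read_trajectory()] for all frames.
#'
#' @param pdb PDB text (single string or character vector of lines) or a
#'   path to a PDB file.
#' @return A `MolecularModel`.
#' @export
read_structure <- function(pdb) {
  lines <- pdb_lines(pdb)
  # keep only the first model when MODEL records are present
  m <- grep("^ENDMDL", lines)
  if (length(m)) lines <- lines[seq_len(m[1])]
  p <- parse_pdb_atoms(lines)
  molecular_model(p$atoms, p$coords_ang / 10)
}

pdb_lines <- function(pdb) {
  if (length(pdb) == 1L && !grepl("\n", pdb) && file.exists(pdb)) {
    readLines(pdb, warn = FALSE)
  } else if (length(pdb) == 1L) {
    strsplit(pdb, "\n", fixed = TRUE)[[1]]
  } else {
    pdb
  }
}

#' Construct a trajectory
#'
#' @param topology A `MolecularModel` shared by all frames.
#' @param coords Numeric array of dimension (frames, atoms, 3), nm.
#' @param frame_interval Time between saved frames, ps.
#' @return Object of class `Trajectory`.
#' @export
trajectory <- function(topology, coords, frame_interval = 100) {
  stopifnot(inherits(topology, "MolecularModel"))
  if (length(dim(coords)) != 3L || dim(coords)[2] != nrow(topology$atoms) ||
      dim(coords)[3] != 3L)
    cs_stop("coords must be a (frames x atoms x 3) array matching the topology",
            "topology_mismatch")
  if (frame_interval <= 0) cs_stop("frame_interval must be positive", "input_error")
  structure(list(topology = topology, coords = coords,
                 frame_interval = frame_interval),
            class = "Trajectory")
}

#' @export
print.Trajectory <- function(x, ...) {
  cat(sprintf("<Trajectory> %d frames x %d atoms, %.0f ps/frame\n",
              n_frames(x), n_atoms(x), x$frame_interval))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A `Trajectory`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' Coordinates of one frame
#' @param traj A `Trajectory`.
#' @param i Frame index (1-based).
#' @return n x 3 matrix, nm.
#' @export
frame_coords <- function(traj, i) {
  traj$coords[i, , , drop = TRUE]
}

#' Read a trajectory from multi-model PDB or DCD
#'
#' Multi-model PDB is parsed natively (Angstrom to nm). DCD files are read
#' through the `bio3d` adapter, which accepts both big- and little-endian
#' CHARMM-style headers; DCD requires a `topology` because the format
#' carries no atom identities.
#'
#' @param source Path to a `.pdb`/`.dcd` file, or PDB text.
#' @param topology Optional `MolecularModel`; required for DCD.
#' @param frame_interval Time between frames, ps.
#' @return A `Trajectory`.
#' @export
read_trajectory <- function(source, topology = NULL, frame_interval = 100) {
  is_dcd <- length(source) == 1L && grepl("\\.dcd$", source, ignore.case = TRUE)
  if (is_dcd) {
    if (is.null(topology))
      cs_stop("DCD input requires a topology MolecularModel", "input_error")
    xyz <- bio3d::read.dcd(source, verbose = FALSE)   # Angstrom, frames x 3N
    if (ncol(xyz) != 3L * nrow(topology$atoms))
      cs_stop("DCD atom count does not match topology", "topology_mismatch")
    co <- xyz_to_array(xyz / 10)
    return(trajectory(topology, co, frame_interval))
  }
  lines <- pdb_lines(source)
  starts <- grep("^MODEL", lines)
  if (length(starts) == 0L) {
    model <- read_structure(lines)
    co <- array(model$coords, dim = c(1L, nrow(model$coords), 3L))
    return(trajectory(model, co, frame_interval))
  }
  ends <- grep("^ENDMDL", lines)
  if (length(ends) < length(starts)) ends <- c(ends, length(lines))
  blocks <- lapply(seq_along(starts), function(i) {
    parse_pdb_atoms(lines[starts[i]:ends[i]])
  })
  counts <- vapply(blocks, function(b) nrow(b$atoms), integer(1))
  if (length(unique(counts)) != 1L)
    cs_stop(sprintf("atom count differs between models (%s)",
                    paste(unique(counts), collapse = " vs ")),
            "topology_mismatch")
  topo <- molecular_model(blocks[[1]]$atoms, blocks[[1]]$coords_ang / 10)
  co <- array(0, dim = c(length(blocks), counts[1], 3L))
  for (i in seq_along(blocks)) co[i, , ] <- blocks[[i]]$coords_ang / 10
  trajectory(topo, co, frame_interval)
}

xyz_to_array <- function(xyz) {
  nf <- nrow(xyz); na3 <- ncol(xyz)
  co <- array(0, dim = c(nf, na3 / 3L, 3L))
  for (k in 1:3) co[, , k] <- xyz[, seq(k, na3, by = 3L), drop = FALSE]
  co
}

array_to_xyz <- function(co) {
  nf <- dim(co)[1]; na <- dim(co)[2]
  xyz <- matrix(0, nf, 3L * na)
  for (k in 1:3) xyz[, seq(k, 3L * na, by = 3L)] <- co[, , k]
  xyz
}

#' Write a model or trajectory as (multi-model) PDB
#'
#' Coordinates are converted back to Angstrom. A trajectory is written as
#' one MODEL/ENDMDL block per frame.
#'
#' @param x A `MolecularModel` or `Trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "Trajectory")) {
    topo <- x$topology
    frames <- lapply(seq_len(n_frames(x)), function(i) frame_coords(x, i))
  } else {
    topo <- x
    frames <- list(x$coords)
  }
  at <- topo$atoms
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(frames) > 1L
  for (i in seq_along(frames)) {
    if (multi) writeLines(sprintf("MODEL     %4d", i), con)
    ang <- frames[[i]] * 10
    writeLines(sprintf(
      "ATOM  %5d %-4s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      at$serial, formatC(at$name, width = -4), at$resid, at$chain, at$resno,
      ang[, 1], ang[, 2], ang[, 3], at$element), con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# ---- regions ---------------------------------------------------------------

parse_span <- function(span, name) {
  m <- regmatches(span, regexec("^\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", span))[[1]]
  if (length(m) != 3L) {
    single <- suppressWarnings(as.integer(span))
    if (!is.na(single)) return(single)
    cs_stop(sprintf("region '%s': cannot parse span '%s'", name, span),
            "config_error")
  }
  a <- as.integer(m[2]); b <- as.integer(m[3])
  if (a > b)
    cs_stop(sprintf("region '%s': span start %d exceeds end %d", name, a, b),
            "range_error")
  a:b
}

#' Build a region set
#'
#' Named 1-based inclusive residue ranges — the peptides of interest for
#' exposure, distance and flexibility analyses.
#'
#' @param ... Named spans, each either an integer vector of residue numbers
#'   or a string `"start-end"` (both endpoints included).
#' @return Object of class `RegionSet`: a named list of integer vectors.
#' @examples
#' region_set(epitope = "39-43", linker = 63:67)
#' @export
region_set <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.list(args[[1]]) && is.null(names(args)[1]))
    args <- args[[1]]
  nms <- names(args)
  if (is.null(nms) || any(nms == ""))
    cs_stop("every region must be named", "config_error")
  if (anyDuplicated(nms))
    cs_stop(sprintf("duplicate region name '%s'", nms[duplicated(nms)][1]),
            "config_error")
  out <- lapply(seq_along(args), function(i) {
    v <- args[[i]]
    v <- if (is.character(v)) parse_span(v, nms[i]) else as.integer(v)
    if (length(v) == 0L)
      cs_stop(sprintf("region '%s' is empty", nms[i]), "config_error")
    sort(unique(v))
  })
  names(out) <- nms
  structure(out, class = "RegionSet")
}

#' Load regions from a YAML config
#'
#' The config maps region names to `"start-end"` spans, e.g.
#' `epitope: 39-43`. Spans expand to inclusive residue sets.
#'
#' @param config YAML text or path to a YAML file.
#' @return A `RegionSet`.
#' @export
load_regions <- function(config) {
  txt <- if (length(config) == 1L && !grepl("\n", config) && file.exists(config))
    paste(readLines(config, warn = FALSE), collapse = "\n") else paste(config, collapse = "\n")
  keys <- regmatches(strsplit(txt, "\n")[[1]],
                     regexec("^([A-Za-z0-9_.-]+)\\s*:", strsplit(txt, "\n")[[1]]))
  keys <- vapply(keys[lengths(keys) == 2L], `[`, character(1), 2L)
  if (anyDuplicated(keys))
    cs_stop(sprintf("duplicate region name '%s' in config",
                    keys[duplicated(keys)][1]), "config_error")
  parsed <- yaml::yaml.load(txt)
  if (!is.list(parsed) || length(parsed) == 0L)
    cs_stop("region config is empty", "config_error")
  parsed <- lapply(parsed, function(v) if (is.numeric(v)) as.integer(v) else as.character(v))
  region_set(parsed)
}

# ---- tables ----------------------------------------------------------------

#' Write a result table as TSV
#'
#' Header + one row per record, tab-separated, locale-independent decimal
#' point. SEM-style uncertainty columns are written as their own columns
#' (the on-disk format never embeds the plus-minus sign in a value cell).
#'
#' @param table Data frame of results (e.g. a delta table).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    cs_stop("refusing to write an empty table", "empty_input")
  old <- Sys.getlocale("LC_NUMERIC")
  on.exit(suppressWarnings(Sys.setlocale("LC_NUMERIC", old)), add = TRUE)
  suppressWarnings(Sys.setlocale("LC_NUMERIC", "C"))
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
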
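# Residue-class (polar / nonpolar) motif scanning for the amphipathic
# epitope pattern family. Patterns are strings over:
#   "n" (or Greek phi)  — nonpolar class
#   "p" (or Greek zeta) — polar class
#   "x"                 — any residue
#   uppercase letter    — literal residue (e.g. F, C)
# Scans run forward and in reverse (the reversed pattern read high-to-low,
# as epitope motifs can present in either chain direction on a surface).

PHI <- "\u03d5"; ZETA <- "\u03b6"

#' Default polar/nonpolar residue-class alphabet
#'
#' Nonpolar: A V L I M F W C G P. Polar: S T N Q Y H K R D E. F and C are
#' nonpolar (which is what lets the F/C-anchored pattern variants collapse
#' onto the simplified all-class pattern); the remainder follows the common
#' hydropathy partition and can be overridden.
#'
#' @return Named character vector mapping one-letter codes to `"n"`
#'   (nonpolar) or `"p"` (polar).
#' @export
default_class_alphabet <- function() {
  c(A = "n", V = "n", L = "n", I = "n", M = "n", F = "n", W = "n",
    C = "n", G = "n", P = "n",
    S = "p", T = "p", N = "p", Q = "p", Y = "p", H = "p", K = "p",
    R = "p", D = "p", E = "p")
}

#' The amphipathic epitope motif family
#'
#' Two literal-anchored patterns (`nnnppFxn`, `nnnppFxC`) and the
#' simplified all-class pattern `nnnppnxn` they collapse to, since F and C
#' are nonpolar.
#'
#' @return Named character vector of pattern strings.
#' @export
motif_patterns <- function() {
  c(canonical = "nnnppFxn", cys_anchored = "nnnppFxC", simplified = "nnnppnxn")
}

normalize_pattern <- function(pattern) {
  syms <- strsplit(pattern, "")[[1]]
  syms[syms %in% c(PHI, "\u03c6")] <- "n"
  syms[syms == ZETA] <- "p"
  if (length(syms) < 2L) cs_stop("pattern must have length >= 2", "input_error")
  ok <- syms %in% c("n", "p", "x") | grepl("^[A-Z]$", syms)
  if (!all(ok))
    cs_stop(sprintf("invalid pattern symbol '%s'", syms[!ok][1]), "input_error")
  syms
}

#' Classify a protein sequence into polarity classes
#'
#' @param sequence One-letter protein sequence (string).
#' @param alphabet Class alphabet, see [default_class_alphabet()]. `X` is
#'   tolerated and maps to the wildcard class.
#' @return Character vector of `"n"`/`"p"` (and `"x"` for X), one per
#'   residue.
#' @export
classify_sequence <- function(sequence, alphabet = default_class_alphabet()) {
  if (nchar(sequence) == 0L) cs_stop("sequence is empty", "input_error")
  res <- strsplit(toupper(sequence), "")[[1]]
  cls <- alphabet[res]
  cls[res == "X"] <- "x"
  if (any(is.na(cls)))
    cs_stop(sprintf("residue '%s' is not in the class alphabet",
                    res[is.na(cls)][1]), "alphabet_error")
  unname(cls)
}

#' Display a class vector with the conventional Greek symbols
#' @param classes Character vector from [classify_sequence()].
#' @return Single string using the phi/zeta symbols.
#' @export
class_string <- function(classes) {
  paste(ifelse(classes == "n", PHI, ifelse(classes == "p", ZETA, "x")),
        collapse = "")
}

match_at <- function(res, cls, syms, offset) {
  m <- length(syms)
  mm <- 0L
  for (j in seq_len(m)) {
    s <- syms[j]; k <- offset + j - 1L
    ok <- if (s == "x") TRUE
    else if (s %in% c("n", "p")) cls[k] == s || cls[k] == "x"
    else res[k] == s
    if (!ok) mm <- mm + 1L
  }
  mm
}

#' Scan a sequence for a class motif
#'
#' The forward scan matches the pattern left-to-right at every offset; the
#' reverse scan matches the reversed pattern (i.e. the motif read
#' high-to-low along the sequence). Every position failing its symbol adds
#' one mismatch; matches with more than `max_mismatch` mismatches are
#' dropped. Matches with identical span found in both directions are
#' deduplicated, keeping the lower-mismatch direction (forward on ties).
#'
#' @param sequence One-letter protein sequence.
#' @param pattern Pattern string (see [motif_patterns()]; Greek phi/zeta
#'   accepted).
#' @param max_mismatch Maximum tolerated mismatches (default 0).
#' @param direction `"both"` (default), `"forward"` or `"reverse"`.
#' @param alphabet Class alphabet.
#' @return Data frame: `start`, `end` (1-based inclusive, start <= end),
#'   `direction`, `mismatches`, `classes` (the span's class string in
#'   phi/zeta symbols).
#' @export
scan_motif <- function(sequence, pattern, max_mismatch = 0,
                       direction = c("both", "forward", "reverse"),
                       alphabet = default_class_alphabet()) {
  direction <- match.arg(direction)
  res <- strsplit(toupper(sequence), "")[[1]]
  cls <- classify_sequence(sequence, alphabet)
  syms <- normalize_pattern(pattern)
  m <- length(syms)
  if (m > length(res)) cs_stop("pattern longer than sequence", "input_error")
  hits <- list()
  add <- function(start, dir, mm) {
    span <- start:(start + m - 1L)
    hits[[length(hits) + 1L]] <<- data.frame(
      start = start, end = start + m - 1L, direction = dir, mismatches = mm,
      classes = class_string(cls[span]), stringsAsFactors = FALSE)
  }
  offsets <- seq_len(length(res) - m + 1L)
  if (direction %in% c("both", "forward")) {
    for (o in offsets) {
      mm <- match_at(res, cls, syms, o)
      if (mm <= max_mismatch) add(o, "forward", mm)
    }
  }
  if (direction %in% c("both", "reverse")) {
    rsyms <- rev(syms)
    for (o in offsets) {
      mm <- match_at(res, cls, rsyms, o)
      if (mm <= max_mismatch) add(o, "reverse", mm)
    }
  }
  if (length(hits) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      direction = character(0), mismatches = integer(0),
                      classes = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  # same span in both directions: keep the lower-mismatch one (forward wins ties)
  out <- out[order(out$start, out$mismatches, out$direction != "forward"), ]
  out <- out[!duplicated(out[, c("start", "end")]), ]
  rownames(out) <- NULL
  out
}

#' Scan with the whole motif family and report distinct loci
#'
#' Runs [scan_motif()] for every pattern in `patterns` (both directions),
#' keeps each span's best (lowest-mismatch) hit across patterns, and then
#' collapses overlapping spans into distinct loci, keeping the
#' lowest-mismatch span per locus (earliest span on ties). This mirrors how
#' a motif table is read: one row per sequence locus, annotated with the
#' family member and direction that fits it best.
#'
#' @param sequence One-letter protein sequence.
#' @param patterns Named character vector of patterns
#'   (default [motif_patterns()]).
#' @param max_mismatch Maximum mismatches per pattern (default 2: "closely
#'   related" family members).
#' @param alphabet Class alphabet.
#' @return Data frame as [scan_motif()] plus a `pattern` column, one row
#'   per locus, ordered by `start`.
#' @export
scan_motif_family <- function(sequence, patterns = motif_patterns(),
                              max_mismatch = 2,
                              alphabet = default_class_alphabet()) {
  hits <- do.call(rbind, lapply(names(patterns), function(nm) {
    h <- scan_motif(sequence, patterns[[nm]], max_mismatch, "both", alphabet)
    h$pattern <- rep(nm, nrow(h))
    h
  }))
  if (is.null(hits) || nrow(hits) == 0L) return(hits)
  # best hit per span across patterns
  hits <- hits[order(hits$start, hits$mismatches, hits$direction != "forward"), ]
  hits <- hits[!duplicated(hits[, c("start", "end")]), ]
  # collapse overlapping spans into loci, keeping the best span per locus
  hits <- hits[order(hits$mismatches, hits$start), ]
  kept <- hits[0, ]
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    overlaps <- nrow(kept) > 0L && any(h$start <= kept$end & h$end >= kept$start)
    if (!overlaps) kept <- rbind(kept, h)
  }
  kept <- kept[order(kept$start), ]
  rownames(kept) <- NULL
  kept
}

match_at_anchored <- function(res, cls, syms, offset) {
  # literal symbols are hard constraints; returns NA when a literal fails,
  # otherwise the count of class mismatches and the matched anchor positions
  m <- length(syms)
  mm <- 0L; anchors <- integer(0)
  for (j in seq_len(m)) {
    s <- syms[j]; k <- offset + j - 1L
    if (s == "x") next
    if (s %in% c("n", "p")) {
      if (cls[k] != s && cls[k] != "x") mm <- mm + 1L
    } else {
      if (res[k] != s) return(NULL)
      anchors <- c(anchors, k)
    }
  }
  list(mm = mm, anchors = anchors)
}

#' Scan for the epitope motif family with anchored matching
#'
#' The reproduction recipe for the amphipathic epitope motif table: the
#' literal-anchored family members (`nnnppFxn` and `nnnppFxC`, scanned in
#' both directions, plus the C-terminally anchored relative `nnnppnxC`,
#' scanned forward since its only anchor is terminal) are matched with the
#' literal F/C anchors as hard constraints and up to `max_mismatch`
#' mismatches on the class positions. Matches are then reduced to one best
#' match per anchor residue: lowest mismatch count first, doubly anchored
#' (F and C) matches beating singly anchored ones on ties, earliest span
#' last. By default the scan covers domain I and the DI-DII interlinker
#' (residues 1-72), the segment whose exposure the conformational
#' transition controls.
#'
#' @param sequence One-letter protein sequence (full DI-DII is fine; see
#'   `region`).
#' @param region Length-2 integer vector: first and last residue scanned.
#' @param max_mismatch Class-position mismatch tolerance (default 3, the
#'   loosest "closely related" family member).
#' @param alphabet Class alphabet.
#' @return Data frame: `start`, `end`, `direction`, `mismatches`,
#'   `classes`, `pattern`, `anchors`, ordered by `start`.
#' @export
scan_epitope_motifs <- function(sequence, region = c(1L, 72L),
                                max_mismatch = 3,
                                alphabet = default_class_alphabet()) {
  res <- strsplit(toupper(sequence), "")[[1]]
  cls <- classify_sequence(sequence, alphabet)
  lo <- region[1]; hi <- min(region[2], length(res))
  fam <- list(list(p = "nnnppFxn", dirs = c("forward", "reverse")),
              list(p = "nnnppFxC", dirs = c("forward", "reverse")),
              list(p = "nnnppnxC", dirs = "forward"))
  hits <- list()
  for (f in fam) {
    syms <- normalize_pattern(f$p)
    m <- length(syms)
    for (dir in f$dirs) {
      ss <- if (dir == "forward") syms else rev(syms)
      for (o in lo:(hi - m + 1L)) {
        r <- match_at_anchored(res, cls, ss, o)
        if (!is.null(r) && r$mm <= max_mismatch)
          hits[[length(hits) + 1L]] <- data.frame(
            start = o, end = o + m - 1L, direction = dir,
            mismatches = r$mm, classes = class_string(cls[o:(o + m - 1L)]),
            pattern = f$p, anchors = paste(res[r$anchors], r$anchors,
                                           sep = "", collapse = ","),
            n_anchors = length(r$anchors), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) return(NULL)
  h <- do.call(rbind, hits)
  # one best match per anchor residue
  h <- h[order(h$mismatches, -h$n_anchors, h$start), ]
  taken <- integer(0); keep <- logical(nrow(h))
  for (i in seq_len(nrow(h))) {
    a <- as.integer(gsub("[A-Z]", "", strsplit(h$anchors[i], ",")[[1]]))
    if (!any(a %in% taken)) { keep[i] <- TRUE; taken <- c(taken, a) }
  }
  h <- h[keep, ]
  # a span can surface once through two family members; keep the best
  h <- h[!duplicated(h[, c("start", "end")]), ]
  h$n_anchors <- NULL
  h <- h[order(h$start), ]
  rownames(h) <- NULL
  h
}

#' Join motif matches with exposure and flexibility results
#'
#' One row per motif match carrying the exposure percent differences of the
#' matching region (rows of a [delta_table()] whose `region` equals
#' `"start-end"`) and, when given, the mean RMSF percent difference of the
#' span's residues per window.
#'
#' @param matches Data frame from [scan_motif()] / [scan_motif_family()].
#' @param exposure_delta Optional `DeltaTable` computed over regions named
#'   `"start-end"` for the match spans.
#' @param rmsf_windows Optional `RmsfWindows` over the same residue
#'   numbering.
#' @return Data frame, one row per (match, cluster) or per match.
#' @export
motif_report <- function(matches, exposure_delta = NULL, rmsf_windows = NULL) {
  if (nrow(matches) == 0L) return(matches)
  matches$region <- paste0(matches$start, "-", matches$end)
  out <- matches
  if (!is.null(exposure_delta)) {
    missing <- setdiff(matches$region, exposure_delta$region)
    if (length(missing))
      cs_stop(sprintf("no exposure rows for region(s): %s",
                      paste(missing, collapse = ", ")), "join_error")
    out <- merge(matches, as.data.frame(exposure_delta), by = "region",
                 all.x = TRUE, sort = FALSE)
  }
  if (!is.null(rmsf_windows)) {
    resn <- as.integer(colnames(rmsf_windows$rmsf))
    for (w in seq_len(nrow(rmsf_windows$pct_diff_vs_first))) {
      out[[paste0("rmsf_pct_w", w)]] <- vapply(seq_len(nrow(out)), function(i) {
        span <- out$start[i]:out$end[i]
        if (!all(span %in% resn))
          cs_stop(sprintf("residues %s absent from RMSF windows",
                          paste(setdiff(span, resn), collapse = ",")),
                  "join_error")
        mean(rmsf_windows$pct_diff_vs_first[w, as.character(span)])
      }, numeric(1))
    }
  }
  out
}

#' Read the first sequence from a FASTA file
#'
#' @param path FASTA file path.
#' @return Sequence string.
#' @export
read_fasta_sequence <- function(path) {
  fa <- bio3d::read.fasta(path)
  paste(fa$ali[1, fa$ali[1, ] != "-"], collapse = "")
}
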
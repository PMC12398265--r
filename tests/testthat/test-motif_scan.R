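test_that("sequence classification follows the polarity alphabet", {
  expect_equal(classify_sequence("AF"), c("n", "n"))
  expect_equal(classify_sequence("KN"), c("p", "p"))
  expect_equal(classify_sequence("AXK"), c("n", "x", "p"))
  expect_error(classify_sequence("A?"), class = "alphabet_error")
  expect_error(classify_sequence(""), class = "input_error")
  expect_equal(class_string(c("n", "p", "x")), "ϕζx")
})

test_that("motif scanning finds constructed matches in both directions", {
  # AVLSTAGA classifies as nnnppnxn: one exact forward match of the
  # simplified pattern over residues 1-8
  h <- scan_motif("AVLSTAGA", "nnnppnxn")
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 1L); expect_equal(h$end, 8L)
  expect_equal(h$direction, "forward"); expect_equal(h$mismatches, 0L)

  # an F-anchored motif on the reversed sequence is found in reverse over
  # the same (mirrored) residues; the anchor breaks the forward reading
  rev_seq <- paste(rev(strsplit("AVLSTFGA", "")[[1]]), collapse = "")
  hr <- scan_motif(rev_seq, "nnnppFxn")
  expect_equal(nrow(hr), 1L)
  expect_equal(hr$direction, "reverse")
  expect_equal(c(hr$start, hr$end), c(1L, 8L))

  # Greek symbols are accepted as pattern input
  hg <- scan_motif("AVLSTAGA", "ϕϕϕζζϕxϕ")
  expect_equal(hg$start, 1L)

  # literal symbols must match the residue exactly
  expect_equal(nrow(scan_motif("AVLSTFGA", "nnnppFxn")), 1L)
  expect_equal(nrow(scan_motif("AVLSTAGA", "nnnppFxn")), 0L)

  # palindromic-class span: both directions match; deduplicated to one row
  hp <- scan_motif("AAAA", "nnnn")
  expect_equal(nrow(hp), 1L)
  expect_equal(hp$direction, "forward")

  expect_error(scan_motif("AV", "nnnppnxn"), class = "input_error")
})

test_that("raising the mismatch budget never removes a match", {
  set.seed(81)
  aas <- names(default_class_alphabet())
  for (rep in 1:10) {
    s <- paste(sample(aas, 30, replace = TRUE), collapse = "")
    prev <- 0L
    for (mm in 0:3) {
      h <- scan_motif(s, "nnnppFxn", max_mismatch = mm)
      expect_gte(nrow(h), prev)
      prev <- nrow(h)
    }
  }
})

test_that("scan equals brute-force per-offset comparison on random 50-mers", {
  set.seed(82)
  aas <- names(default_class_alphabet())
  for (rep in 1:10) {
    s <- paste(sample(aas, 50, replace = TRUE), collapse = "")
    res <- strsplit(s, "")[[1]]
    cls <- classify_sequence(s)
    for (pat in c("nnnppnxn", "nnnppFxC")) {
      syms <- strsplit(pat, "")[[1]]
      h <- scan_motif(s, pat, max_mismatch = 1, direction = "forward")
      ref <- brute_motif_forward(res, cls, syms, 1)
      if (is.null(ref)) {
        expect_equal(nrow(h), 0L)
      } else {
        expect_equal(h$start, ref[, 1])
        expect_equal(h$mismatches, ref[, 3])
      }
      # reverse scan = forward scan of the reversed pattern
      hr <- scan_motif(s, pat, max_mismatch = 1, direction = "reverse")
      refr <- brute_motif_forward(res, cls, rev(syms), 1)
      expect_equal(nrow(hr), if (is.null(refr)) 0L else nrow(refr))
    }
  }
})

test_that("forward matches mirror reverse matches on the reversed sequence", {
  set.seed(83)
  aas <- names(default_class_alphabet())
  for (rep in 1:10) {
    s <- paste(sample(aas, 30, replace = TRUE), collapse = "")
    sr <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
    f <- scan_motif(s, "nnnppFxn", max_mismatch = 1, direction = "forward")
    r <- scan_motif(sr, "nnnppFxn", max_mismatch = 1, direction = "reverse")
    # a forward match at [a, b] on s is a reverse match at the mirrored
    # span [n - b + 1, n - a + 1] on reversed s
    expect_equal(sort(31L - f$end), sort(r$start))
    expect_equal(nrow(f), nrow(r))
  }
})

test_that("the epitope motif table is reproduced on the bundled sequence", {
  fa <- system.file("extdata", "b2gpi_di_dii.fasta", package = "confshift")
  seqs <- read_fasta_sequence(fa)
  expect_equal(nchar(seqs), 120L)

  hits <- scan_epitope_motifs(seqs)
  expect_equal(nrow(hits), 5L)
  expect_equal(hits$start, c(10L, 16L, 40L, 53L, 65L))
  expect_equal(hits$end, c(17L, 23L, 47L, 60L, 72L))
  expect_equal(hits$direction,
               c("reverse", "forward", "forward", "forward", "reverse"))
  expect_equal(hits$mismatches, c(0L, 1L, 0L, 0L, 3L))
})

test_that("motif reports join exposure and flexibility values by span", {
  matches <- data.frame(start = c(1L, 5L), end = c(4L, 8L),
                        direction = "forward", mismatches = 0L,
                        classes = "xxxx", stringsAsFactors = FALSE)
  dt <- data.frame(region = c("1-4", "1-4", "5-8", "5-8"),
                   cluster = c("1", "2", "1", "2"), group = "all",
                   comparison = "vs_reference_cluster", n_frames = 3L,
                   mean = c(1, 2, 3, 4.5), sem = 0.1,
                   pct_diff = c(0, 100, 0, 50), pct_diff_sem = NA,
                   is_reference = c(TRUE, FALSE, TRUE, FALSE))
  class(dt) <- c("DeltaTable", class(dt))
  rep_ <- motif_report(matches, dt)
  expect_equal(nrow(rep_), 4L)   # 2 matches x 2 clusters
  expect_equal(rep_$pct_diff[rep_$region == "5-8" & rep_$cluster == "2"], 50)

  # missing exposure rows are a join error naming the offender
  bad <- matches; bad$start[2] <- 6L
  expect_error(motif_report(bad, dt), class = "join_error")

  # no matches: empty result, not an error
  expect_equal(nrow(motif_report(matches[0, ], dt)), 0L)

  rmsf <- structure(list(
    rmsf = matrix(0.1, 2, 8, dimnames = list(NULL, 1:8)),
    pct_diff_vs_first = matrix(c(rep(0, 8), rep(-25, 8)), 2, 8, byrow = TRUE,
                               dimnames = list(NULL, 1:8)),
    window = 10L), class = "RmsfWindows")
  rep2 <- motif_report(matches, rmsf_windows = rmsf)
  expect_equal(rep2$rmsf_pct_w2, c(-25, -25))
})
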
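# Sequence I/O, pairwise alignment and position mapping.

test_that("read_fasta parses records in order and validates residues", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1 some description", "ACDE", ">s2", "GGHHK"), f)
  seqs <- read_fasta(f)
  expect_length(seqs, 2L)
  expect_equal(names(seqs), c("s1", "s2"))
  expect_equal(seqs$s1$residues, "ACDE")
  expect_equal(seqs$s1$length, 4L)
  expect_equal(seqs$s2$residues, "GGHHK")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACBDE"), bad)
  expect_error(read_fasta(bad), "s1.*position 3|position 3.*s1")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "empty")
})

test_that("self-alignment is gapless with identity 1 and diagonal score", {
  s <- protein_sequence("s", "ACDEFGHIK")
  aln <- align_pair(s, s, "global")
  expect_equal(aln$aligned_query, "ACDEFGHIK")
  expect_equal(aln$aligned_target, "ACDEFGHIK")
  diag_sum <- sum(vapply(strsplit("ACDEFGHIK", "")[[1]],
                         function(ch) blosum62[ch, ch], 0))
  expect_equal(aln$score, diag_sum)
  expect_equal(percent_identity(aln), 1.0)
})

test_that("a single deletion aligns as one gap column at the right place", {
  aln <- align_pair(protein_sequence("a", "ACDEFG"),
                    protein_sequence("b", "ACEFG"), "global")
  expect_equal(aln$aligned_query, "ACDEFG")
  expect_equal(aln$aligned_target, "AC-EFG")
  # oracle: best over exhaustive enumeration of alignments
  expect_equal(aln$score, enum_align_score("ACDEFG", "ACEFG"))
})

test_that("alignment score is optimal against enumeration and plain-R DP", {
  set.seed(42)
  for (rep in 1:12) {
    a <- random_aa(sample(1:5, 1))
    b <- random_aa(sample(1:5, 1))
    got <- align_pair(protein_sequence("a", a), protein_sequence("b", b),
                      "global")$score
    expect_equal(got, enum_align_score(a, b),
                 info = sprintf("enumeration: %s vs %s", a, b))
  }
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (rep in 1:25) {
    a <- random_aa(sample(4:8, 1), alphabet = aa20)
    b <- random_aa(sample(4:8, 1), alphabet = aa20)
    got <- align_pair(protein_sequence("a", a), protein_sequence("b", b),
                      "global")$score
    expect_equal(got, gotoh_score(a, b),
                 info = sprintf("gotoh: %s vs %s", a, b))
  }
})

test_that("empty sequences are rejected", {
  expect_no_error(protein_sequence("x", ""))  # empty sequence object is legal
  expect_error(align_pair(protein_sequence("x", ""),
                          protein_sequence("y", "ACD")), "empty")
})

test_that("map_position maps identity, gaps and flags unaligned columns", {
  a <- protein_sequence("a", "ACDEFG")
  b <- protein_sequence("b", "ACEFG")
  aln <- align_pair(a, b, "global")
  m <- map_position(aln, 2)
  expect_equal(m$target_pos, 2L)
  expect_true(m$column_identical)
  m3 <- map_position(aln, 3)   # the deleted D
  expect_true(m3$unaligned)
  expect_true(is.na(m3$target_pos))
  expect_equal(m3$flank_before, 2L)
  expect_equal(m3$flank_after, 3L)
  expect_error(map_position(aln, 99), "outside")
  # identity mapping on a self-alignment
  self <- align_pair(a, a, "global")
  for (p in c(1, 4, 6)) {
    ms <- map_position(self, p)
    expect_equal(ms$target_pos, p)
    expect_true(ms$column_identical)
  }
})

test_that("mapping round-trips through the transposed alignment and is monotone", {
  fam <- gen_family(ancestor_length = 120, n_descendants = 3,
                    substitution_rate = 0.1, indel_rate = 0.04, seed = 11)
  for (k in seq_along(fam$descendants)) {
    d <- fam$descendants[[k]]
    fwd <- align_pair(d, fam$reference, "global")
    rev <- align_pair(fam$reference, d, "global")
    mapped <- vapply(seq_len(d$length), function(p) {
      m <- map_position(fwd, p)
      if (m$unaligned) NA_integer_ else m$target_pos
    }, integer(1))
    # strictly increasing over aligned positions
    expect_true(all(diff(mapped[!is.na(mapped)]) > 0))
    # round trip
    for (p in which(!is.na(mapped))) {
      back <- map_position(rev, mapped[p])
      if (!back$unaligned) expect_equal(back$target_pos, p)
    }
  }
})

test_that("alignment mapping recovers the generator's true position map", {
  fam <- gen_family(ancestor_length = 200, n_descendants = 4,
                    substitution_rate = 0.05, indel_rate = 0, seed = 3)
  for (k in seq_along(fam$descendants)) {
    aln <- align_pair(fam$descendants[[k]], fam$reference, "global")
    tab <- mapping_table(aln)
    expect_equal(tab$target_pos, fam$maps[[k]]$ref_pos)  # identity map
  }
  # with indels, accuracy of mapped positions stays >= 99%
  fam2 <- gen_family(ancestor_length = 300, n_descendants = 5,
                     substitution_rate = 0.05, indel_rate = 0.02, seed = 7)
  acc <- vapply(seq_along(fam2$descendants), function(k) {
    truth <- fam2$maps[[k]]
    aln <- align_pair(fam2$descendants[[k]], fam2$reference, "global")
    got <- vapply(truth$desc_pos, function(p) {
      m <- map_position(aln, p)
      if (m$unaligned) NA_integer_ else m$target_pos
    }, integer(1))
    comparable <- !is.na(truth$ref_pos)
    mean(!is.na(got[comparable]) & got[comparable] == truth$ref_pos[comparable])
  }, 0)
  expect_true(all(acc >= 0.99))
})

test_that("percent identity counts identical over aligned columns", {
  aln <- align_pair(protein_sequence("a", "AAAA"),
                    protein_sequence("b", "AAAT"), "global")
  expect_equal(percent_identity(aln), 0.75)
})

test_that("conservation profile matches generator ground truth", {
  ref <- protein_sequence("ref", "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQ")
  expect_equal(conservation_profile(ref, list(ref)), rep(1, ref$length))
  # single substitution at position 7
  chars <- strsplit(ref$residues, "")[[1]]
  chars[7] <- if (chars[7] == "W") "Y" else "W"
  other <- protein_sequence("mut", paste(chars, collapse = ""))
  prof <- conservation_profile(ref, list(other))
  expect_equal(prof[7], 0)
  expect_equal(prof[-7], rep(1, ref$length - 1))
  # simulated family: substituted columns drop below 1 exactly as recorded
  fam <- gen_family(ancestor_length = 150, n_descendants = 6,
                    substitution_rate = 0.08, indel_rate = 0, seed = 5)
  prof <- conservation_profile(fam$reference, fam$descendants)
  n <- length(fam$descendants)
  expected <- vapply(seq_len(fam$reference$length), function(p) {
    1 - mean(vapply(fam$substituted, function(s) p %in% s, TRUE))
  }, 0)
  expect_equal(prof, expected)
})
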
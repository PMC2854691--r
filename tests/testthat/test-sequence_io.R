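test_that("seq_record cleans residues and computes composition", {
  r <- seq_record("x", "acgtRYn")
  expect_equal(r$residues, "ACGTNNN")
  expect_equal(r$length, 7L)
  expect_equal(r$p, 0.5)

  expect_equal(unname(base_composition("AATGC")["p"]), 0.6)
  expect_equal(unname(base_composition("AANNT")["p"]), 1.0)  # N excluded
  expect_error(base_composition("NNNN"), "undefined")
})

test_that("FASTA read handles empty, single-record and malformed input", {
  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_identical(read_fasta(empty), list())

  one <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACGT"), one)
  recs <- read_fasta(one)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$id, "x")
  expect_equal(recs[[1]]$length, 4L)
  expect_equal(recs[[1]]$p, 0.5)

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACGT", ">x"), bad)
  expect_error(read_fasta(bad), "line 1")
  expect_error(read_fasta(file.path(tempdir(), "missing.fa")), "no such")
})

test_that("FASTA write/read round trip is identical", {
  rec <- random_sequence(10000, 0.45, seed = 11, id = "roundtrip")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(rec, path)
  back <- read_fasta(path)
  expect_length(back, 1L)
  expect_identical(back[[1]]$id, rec$id)
  expect_identical(back[[1]]$residues, rec$residues)
})

test_that("shuffling permutes the exact residue multiset, deterministically", {
  expect_equal(shuffle_matching_random("AAAA", seed = 1)$residues, "AAAA")

  rec <- seq_record("x", paste(c(rep("A", 30), rep("C", 20), rep("G", 10),
                                 rep("T", 25), rep("N", 5)), collapse = ""))
  sh <- shuffle_matching_random(rec, seed = 42)
  expect_equal(sh$length, rec$length)
  expect_equal(letter_counts_test(sh$residues),
               letter_counts_test(rec$residues))
  expect_identical(shuffle_matching_random(rec, seed = 42)$residues,
                   sh$residues)
  expect_false(identical(shuffle_matching_random(rec, seed = 43)$residues,
                         sh$residues))
})

test_that("random sequence generators hit target length and composition", {
  r <- random_sequence(1e5, 0.5, seed = 3)
  expect_equal(r$length, 1e5)
  # binomial SD of p-hat is ~0.0016 at n = 1e5
  expect_lt(abs(r$p - 0.5), 3 * sqrt(0.25 / 1e5))

  ex <- exact_composition_sequence(1e4, 0.7, seed = 3)
  expect_equal(ex$p, 0.7)
})

test_that("concatenates splice in order without reverse-complementing", {
  rec <- seq_record("chr", "AACCGGTT")
  iv <- annotation_intervals("chr", c(0L, 4L), c(2L, 6L), "gene")
  cc <- build_concatenate(rec, iv, "gene")
  expect_equal(cc$residues, "AAGG")
  expect_equal(cc$length, sum(iv$end - iv$start))

  # whole-sequence interval is the identity
  whole <- build_concatenate(rec, annotation_intervals("chr", 0L, 8L,
                                                       "exon"), "exon")
  expect_equal(whole$residues, rec$residues)

  # minus-strand segments keep forward-strand reading
  minus <- build_concatenate(seq_record("chr2", "ACGTTT"),
                             annotation_intervals("chr2", 0L, 3L, "gene",
                                                  strand = "-"), "gene")
  expect_equal(minus$residues, "ACG")

  # overlapping annotations are merged, no base counted twice
  ovl <- build_concatenate(rec, annotation_intervals("chr", c(0L, 2L),
                                                     c(4L, 6L), "gene"),
                           "gene")
  expect_equal(ovl$residues, "AACCGG")

  expect_error(build_concatenate(rec, annotation_intervals("chr", 0L, 99L,
                                                           "gene"), "gene"),
               "out of range")
  expect_error(build_concatenate(rec, iv, "intron"), "no intervals")
})

test_that("interval complement yields the intergenic gaps", {
  iv <- annotation_intervals("chr", c(2L, 6L), c(4L, 8L), "gene")
  ig <- complement_intervals(iv, 10L)
  expect_equal(ig$start, c(0L, 4L, 8L))
  expect_equal(ig$end, c(2L, 6L, 10L))
  expect_true(all(ig$category == "intergene"))
})
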
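test_that("minimal constructed cases are detected as specified", {
  s <- find_str_regions("TTACACACACTT")
  expect_length(s$regions, 1L)
  r <- s$regions[[1]]
  expect_equal(r$motif, "AC")
  expect_equal(r$repeat_count, 4L)
  expect_equal(r$start, 2L)  # 0-based

  # an interruption of one base splits a run into two regions
  s2 <- find_str_regions(paste0("ACACACAC", "G", "ACACACAC"), min_repeats = 4L)
  expect_length(s2$regions, 2L)
  expect_equal(vapply(s2$regions, `[[`, integer(1), "repeat_count"), c(4L, 4L))
  expect_equal(s2$spacers, 1L)

  # flanking runs shorter than min_repeats are dropped
  s3 <- find_str_regions(paste0("ACACAC", "G", "ACACACAC"), min_repeats = 4L)
  expect_length(s3$regions, 1L)
})

test_that("motifs are canonicalized to the minimal unit and homopolymers excluded", {
  # (ACAC)x4 is reported as (AC)x8
  s <- find_str_regions(paste0("TT", strrep("AC", 8), "TT"))
  expect_equal(s$regions[[1]]$unit_size, 2L)
  expect_equal(s$regions[[1]]$repeat_count, 8L)
  # homopolymer runs are never reported at any unit size
  expect_length(find_str_regions("GGTAAAAAAAAAAAATGG")$regions, 0L)
})

test_that("detector equals the brute-force enumeration oracle on random sequences", {
  set.seed(401)
  for (i in 1:60) {
    n <- sample(40:200, 1)
    seq <- if (i %% 3 == 0) {
      # salt with planted repeats so non-trivial structures are common
      paste0(random_dna(sample(10:40, 1)),
             strrep(sample(c("AC", "AAT", "GATA"), 1), sample(2:9, 1)),
             random_dna(sample(10:40, 1)))
    } else {
      random_dna(n)
    }
    for (mr in c(2L, 3L, 4L)) {
      got <- structure_to_df(find_str_regions(seq, mr))
      want <- brute_str_regions(seq, mr)
      expect_equal(got[c("start", "unit", "copies", "motif")],
                   want[c("start", "unit", "copies", "motif")],
                   ignore_attr = TRUE,
                   info = sprintf("seq=%s min_repeats=%d", seq, mr))
    }
  }
})

test_that("detection is deterministic and rejects non-ACGT input", {
  seq <- paste0(random_dna(50), strrep("GATA", 6), random_dna(50))
  expect_identical(find_str_regions(seq), find_str_regions(seq))
  expect_error(find_str_regions("ACGTNACGTACGTACGT"), "non-ACGT")
})

test_that("boundary harmonization re-phases rotation-equivalent motifs", {
  # ATCT x5, then TCTA x6 trailed by TCT so a +3 phase shift to ATCT x6
  # is supported by the sequence without changing the count
  seq <- paste0("GG", strrep("ATCT", 5), "CC", strrep("TCTA", 6), "TCTGG")
  s <- find_str_regions(seq, min_repeats = 4L)
  expect_equal(vapply(s$regions, `[[`, character(1), "motif"), c("ATCT", "TCTA"))
  h <- harmonize_boundaries(s, seq)
  expect_equal(vapply(h$regions, `[[`, character(1), "motif"), c("ATCT", "ATCT"))
  expect_equal(vapply(h$regions, `[[`, integer(1), "repeat_count"),
               vapply(s$regions, `[[`, integer(1), "repeat_count"))
  # the shifted copy must be supported by the sequence
  r2 <- h$regions[[2]]
  expect_equal(substr(seq, r2$start + 1L, r2$end),
               strrep("ATCT", r2$repeat_count))
})

test_that("harmonization is a no-op for single regions and unrelated motifs", {
  seq1 <- paste0("GG", strrep("GATA", 5), "CC")
  s1 <- find_str_regions(seq1)
  expect_equal(harmonize_boundaries(s1, seq1), s1)
  seq2 <- paste0("GG", strrep("GATA", 5), "CAG", strrep("CTTT", 5), "AA")
  s2 <- find_str_regions(seq2)
  expect_equal(harmonize_boundaries(s2, seq2), s2)
})

test_that("harmonization never changes total repeats on random structures", {
  set.seed(402)
  for (i in 1:40) {
    seq <- paste0(random_dna(20), strrep("ATCT", sample(4:8, 1)),
                  random_dna(sample(1:6, 1)),
                  strrep("TCTA", sample(4:8, 1)), random_dna(20))
    s <- find_str_regions(seq, 3L)
    expect_equal(total_repeats(harmonize_boundaries(s, seq)), total_repeats(s))
  }
})

test_that("total_repeats sums regions and handles the empty structure", {
  expect_equal(total_repeats(str_structure()), 0L)
  seq <- paste0("TT", strrep("AC", 8), "TT")
  expect_equal(total_repeats(find_str_regions(seq)), 8L)
  two <- str_structure(list(str_region(0, 20, "GATA", 5),
                            str_region(30, 58, "CTTT", 7)))
  expect_equal(total_repeats(two), 12L)
})

test_that("structure concordance classifies the documented variant types", {
  mk <- function(chimp_block, human_block) {
    c_seq <- paste0("GGATGCCGAT", chimp_block, "TGACCTGACG")
    h_seq <- paste0("GGATGCCGAT", human_block, "TGACCTGACG")
    list(c_seq = c_seq, h_seq = h_seq,
         cs = find_str_regions(c_seq, 2L), hs = find_str_regions(h_seq, 2L))
  }
  # same motif, different counts, both >= 4: identical
  x <- mk(strrep("AC", 9), strrep("AC", 11))
  cmp <- compare_structures(x$cs, x$hs, x$c_seq, x$h_seq)
  expect_equal(cmp$class, "identical")
  expect_equal(cmp$affected_species, "none")

  # a disrupting point mutation splits one species' array
  x <- mk(strrep("GATA", 10), paste0(strrep("GATA", 4), "G", strrep("GATA", 5)))
  cmp <- compare_structures(x$cs, x$hs, x$c_seq, x$h_seq)
  expect_equal(cmp$class, "disrupted_variant")
  expect_equal(cmp$affected_species, "human")

  # same position, different expanded motif: discordant
  x <- mk(strrep("TACC", 8), strrep("TGTC", 8))
  cmp <- compare_structures(x$cs, x$hs, x$c_seq, x$h_seq)
  expect_equal(cmp$class, "discordant")

  # three- and two-repeat variants
  x <- mk(strrep("GATA", 3), strrep("GATA", 12))
  expect_equal(compare_structures(x$cs, x$hs, x$c_seq, x$h_seq)$class,
               "three_repeat_variant")
  x <- mk(strrep("GATA", 2), strrep("GATA", 12))
  cmp <- compare_structures(x$cs, x$hs, x$c_seq, x$h_seq)
  expect_equal(cmp$class, "two_repeat_variant")
  expect_equal(cmp$affected_species, "chimpanzee")

  # no STR at all in one species
  x <- mk("", strrep("GATA", 12))
  cmp <- compare_structures(x$cs, x$hs, x$c_seq, x$h_seq)
  expect_equal(cmp$class, "no_str")
  expect_equal(cmp$affected_species, "none")
})

test_that("concordance checks alignment coverage when an alignment is supplied", {
  c_seq <- paste0("GGATGCCGAT", strrep("AC", 6), "TGACCTGACG")
  h_seq <- paste0("GGATGCCGAT", strrep("AC", 8), "TGACCTGACG")
  cs <- find_str_regions(c_seq, 2L)
  hs <- find_str_regions(h_seq, 2L)
  aln <- align_orthologs(c_seq, h_seq, cs, hs)
  expect_equal(compare_structures(cs, hs, c_seq, h_seq, aln)$class, "identical")
  truncated <- aln
  truncated$aligned_chimp <- substr(aln$aligned_chimp, 1, 10)
  truncated$aligned_human <- substr(aln$aligned_human, 1, 10)
  expect_error(compare_structures(cs, hs, c_seq, h_seq, truncated), "cover")
})
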
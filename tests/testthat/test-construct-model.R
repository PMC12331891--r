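# Genotype algebra and module-design model.

test_that("build_reference enforces the alternating lox layout", {
  d7 <- small_design()
  ref <- render_sequence(d7, parental_genotype(d7))
  expect_equal(Biostrings::countPattern(LOXPSYM,
                                        Biostrings::DNAString(ref)), 8L)

  d1 <- build_reference(data.frame(order = 1, segment_id = 1,
                                   name = "GENE1", role = "gene_cassette"),
                        segment_length = 120L, flank_length = 60L)
  ref1 <- render_sequence(d1, parental_genotype(d1))
  expect_equal(Biostrings::countPattern(LOXPSYM,
                                        Biostrings::DNAString(ref1)), 2L)
  expect_identical(ref1, paste0(d1$left_flank, LOXPSYM,
                                d1$segments$sequence[1], LOXPSYM,
                                d1$right_flank))
})

test_that("build_reference rejects invalid designs", {
  layout2 <- data.frame(order = 1:2, segment_id = 1:2,
                        name = c("A", "A"), role = "gene_cassette")
  expect_error(build_reference(layout2, segment_length = 100,
                               flank_length = 60),
               "duplicate")
  layout <- data.frame(order = 1, segment_id = 1, name = "A",
                       role = "gene_cassette")
  bad_seq <- setNames(paste0("ACGT", LOXPSYM, "ACGT"), "A")
  expect_error(build_reference(layout, sequences = bad_seq,
                               flank_length = 60),
               "lox site")
  expect_error(build_reference(data.frame(order = 1, segment_id = 2,
                                          name = "A",
                                          role = "gene_cassette"),
                               segment_length = 100, flank_length = 60),
               "consecutive")
})

test_that("render_sequence matches its definition and length formula", {
  d <- three_seg_design()
  expect_identical(render_sequence(d, integer(0)),
                   paste0(d$left_flank, LOXPSYM, d$right_flank))
  expect_identical(render_sequence(d, c(2L) * -1L),
                   paste0(d$left_flank, LOXPSYM,
                          revcomp(d$segments$sequence[2]), LOXPSYM,
                          d$right_flank))
  # length formula on many random genotypes
  keys <- random_genotypes(d, 30, max_events = 5, seed = 11)
  for (k in keys) {
    g <- parse_key(k)
    expect_identical(nchar(render_sequence(d, g)), amplicon_length(d, g))
  }
  expect_error(render_sequence(d, c(1L, 9L)), "unknown segment_id")
})

test_that("apply_event implements deletion, inversion and duplication", {
  g <- c(1L, 2L, 3L)
  expect_identical(apply_event(g, recombination_event("inversion", 0, 3)),
                   c(-3L, -2L, -1L))
  expect_identical(apply_event(g, recombination_event("deletion", 1, 2)),
                   c(1L, 3L))
  expect_identical(apply_event(g, recombination_event("duplication", 0, 2)),
                   c(1L, 2L, 1L, 2L, 3L))
  expect_error(recombination_event("deletion", 2, 2), "i < j")
  expect_error(apply_event(g, recombination_event("deletion", 0, 4)),
               "out of range")
})

test_that("events preserve the alternating layout and expected counts", {
  d <- three_seg_design()
  keys <- random_genotypes(d, 20, max_events = 4, seed = 3)
  for (k in keys) {
    g <- parse_key(k)
    m <- length(g)
    ev <- applicable_events(g)
    row <- ev[((sum(utf8ToInt(k))) %% nrow(ev)) + 1L, ]
    e <- recombination_event(row$event_type, row$i, row$j)
    g2 <- apply_event(g, e)
    delta <- switch(row$event_type, deletion = -(row$j - row$i),
                    inversion = 0L, duplication = row$j - row$i)
    expect_identical(length(g2), m + delta)
    # rendered sequence keeps lox count = element count + 1
    expect_equal(Biostrings::countPattern(
      LOXPSYM, Biostrings::DNAString(render_sequence(d, g2))),
      length(g2) + 1L)
    # inversion is an involution
    if (row$event_type == "inversion")
      expect_identical(apply_event(g2, e), g)
  }
})

test_that("applicable_events enumerates site pairs times types", {
  expect_equal(nrow(applicable_events(1:2)), 9L)
  expect_equal(nrow(applicable_events(integer(0))), 0L)
  expect_equal(nrow(applicable_events(1:7, "deletion")), 28L)
})

test_that("copy numbers and TU counts follow the genotype", {
  d <- small_design()
  g <- parental_genotype(d)
  expect_identical(unname(copy_numbers(g, d)), rep(1L, 7))
  expect_identical(tu_count(g, d), 7L)
  dup5 <- apply_event(g, recombination_event("duplication", 4, 5))
  expect_identical(unname(copy_numbers(dup5, d)["HIS5"]), 2L)
  expect_identical(tu_count(dup5, d), 8L)
  expect_identical(unname(copy_numbers(integer(0), d)), rep(0L, 7))
  # sums to element count (all segments are gene cassettes here)
  for (k in random_genotypes(d, 10, seed = 5))
    expect_identical(sum(copy_numbers(parse_key(k), d)),
                     length(parse_key(k)))
})

test_that("canonical keys are exact and orientation-sensitive", {
  expect_identical(canonical_key(c(1L, -2L)), "+1,-2")
  expect_identical(canonical_key(integer(0)), "")
  expect_false(canonical_key(c(1L, 2L)) == canonical_key(c(-2L, -1L)))
  for (k in random_genotypes(small_design(), 10, seed = 9))
    expect_identical(canonical_key(parse_key(k)), k)
})

test_that("design round-trips through FASTA/TSV/YAML files", {
  d <- three_seg_design()
  dir <- withr::local_tempdir()
  paths <- write_design(d, dir)
  d2 <- read_design(paths["fasta"], paths["layout"], paths["config"])
  expect_identical(d2$segments$sequence, d$segments$sequence)
  expect_identical(d2$left_anchor, d$left_anchor)
  expect_identical(render_sequence(d2, parental_genotype(d2)),
                   render_sequence(d, parental_genotype(d)))
})
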
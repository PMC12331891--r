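# Pool simulation, selection, read synthesis and the genome fixture.

test_that("induction without events returns only the parental genotype", {
  d <- three_seg_design()
  p <- simulate_induction(parental_genotype(d), d,
                          pool_config(n_cells = 500, lambda_events = 0,
                                      p_cre_active = 1), seed = 1)
  expect_identical(p$key, canonical_key(parental_genotype(d)))
  expect_equal(p$abundance, 500)
})

test_that("reporter state follows Cre activity and leak settings", {
  d <- three_seg_design()
  p0 <- simulate_induction(parental_genotype(d), d,
                           pool_config(n_cells = 500, p_cre_active = 0,
                                       p_leak = 0), seed = 1)
  expect_true(all(p0$gfp_fraction == 0))
  expect_error(facs_gate(p0), "empty")
  p1 <- simulate_induction(parental_genotype(d), d,
                           pool_config(n_cells = 500, p_cre_active = 1,
                                       p_reporter_flip = 1), seed = 1)
  expect_true(all(p1$gfp_fraction == 1))
})

test_that("rearranged fraction matches the Poisson event model", {
  d <- small_design()
  cfg <- pool_config(n_cells = 10000, lambda_events = 1.5,
                     p_cre_active = 1, p_reporter_flip = 1)
  p <- simulate_induction(parental_genotype(d), d, cfg, seed = 42)
  parental_key <- canonical_key(parental_genotype(d))
  non_parental <- 1 - pool_frequencies(p)[parental_key]
  # fraction of cells with >= 1 event is 1 - exp(-1.5); identity-restoring
  # event chains are rare enough to sit inside the tolerance
  expect_equal(unname(non_parental), 1 - exp(-1.5), tolerance = 0.02)
})

test_that("induction is bit-reproducible given a seed", {
  d <- three_seg_design()
  cfg <- pool_config(n_cells = 300)
  p1 <- simulate_induction(parental_genotype(d), d, cfg, seed = 99)
  p2 <- simulate_induction(parental_genotype(d), d, cfg, seed = 99)
  expect_identical(p1, p2)
  p3 <- simulate_induction(parental_genotype(d), d, cfg, seed = 100)
  expect_false(identical(p1, p3))
})

test_that("facs_gate reweights by GFP fraction and shrinks total mass", {
  d <- three_seg_design()
  p <- simulate_induction(parental_genotype(d), d,
                          pool_config(n_cells = 1000), seed = 2)
  gated <- facs_gate(p)
  expect_lt(sum(gated$abundance), sum(p$abundance))
  expect_true(all(gated$gfp_fraction == 1))
  expect_identical(facs_gate(gated)$abundance, gated$abundance)
  expect_true(all(gated$key %in% p$key))
})

test_that("grow_select follows closed-form exponential growth", {
  d <- small_design()
  parental <- canonical_key(parental_genotype(d))
  dup5 <- canonical_key(apply_event(parental_genotype(d),
                                    recombination_event("duplication", 4, 5)))
  pool <- structure(data.frame(key = c(dup5, parental),
                               abundance = c(1, 1), gfp_fraction = 1),
                    class = c("scramble_pool", "data.frame"))
  # mu ratio 2:1 over 10 generations shifts the abundance ratio by 2^5
  fm <- fitness_model(mu_of_copy = c("1" = 0.5, "2" = 1.0))
  sel <- grow_select(pool, d, fm, generations = 10)
  ratio <- sel$abundance[sel$key == dup5] / sel$abundance[sel$key == parental]
  expect_equal(ratio, 2^5)
  # generations = 0 leaves the pool unchanged
  expect_equal(grow_select(pool, d, fm, generations = 0)$abundance,
               pool$abundance)
  # deleting an essential gene removes the genotype in minus_his
  del3 <- canonical_key(apply_event(parental_genotype(d),
                                    recombination_event("deletion", 2, 3)))
  pool2 <- structure(data.frame(key = c(parental, del3),
                                abundance = c(1, 5), gfp_fraction = 1),
                     class = c("scramble_pool", "data.frame"))
  sel2 <- grow_select(pool2, d, fitness_model(), generations = 5)
  expect_false(del3 %in% sel2$key)
  expect_true(all(sel2$key %in% pool2$key))  # no new keys
  expect_error(grow_select(pool2[pool2$key == del3, ], d, fitness_model()),
               "zero fitness")
})

test_that("pcr_sample converges to pool frequencies without length bias", {
  d <- three_seg_design()
  parental <- canonical_key(parental_genotype(d))
  short <- "+1"
  pool <- structure(data.frame(key = c(parental, short),
                               abundance = c(0.7, 0.3), gfp_fraction = 1),
                    class = c("scramble_pool", "data.frame"))
  draws <- pcr_sample(pool, d, 50000, length_bias_beta = 0, seed = 8)
  expect_equal(mean(draws == parental), 0.7, tolerance = 0.01)
  # positive beta enriches the shorter amplicon
  biased <- pcr_sample(pool, d, 50000, length_bias_beta = 2, seed = 8)
  expect_gt(mean(biased == short), mean(draws == short))
  # single-genotype pool: every draw identical
  one <- pool[1, , drop = FALSE]
  expect_true(all(pcr_sample(one, d, 100, seed = 1) == parental))
})

test_that("error-free synthesis reproduces the amplicon or its revcomp", {
  d <- three_seg_design()
  key <- canonical_key(parental_genotype(d))
  reads <- synthesize_reads(rep(key, 20), d, error_free(), seed = 3)
  amplicon <- render_sequence(d, parental_genotype(d))
  expect_true(all(reads$sequence %in% c(amplicon, revcomp(amplicon))))
  expect_true(any(reads$strand == "+") && any(reads$strand == "-"))
  expect_identical(nchar(reads$quality), nchar(reads$sequence))
})

test_that("substitution load matches the binomial expectation", {
  d <- small_design(segment_length = 1400)  # ~10 kb amplicon
  key <- canonical_key(parental_genotype(d))
  em <- error_model(sub_rate = 0.03, ins_rate = 0, del_rate = 0,
                    p_truncate = 0)
  reads <- synthesize_reads(rep(key, 12), d, em, seed = 4)
  amplicon <- render_sequence(d, parental_genotype(d))
  rc <- revcomp(amplicon)
  dists <- vapply(seq_along(reads$id), function(i) {
    tmpl <- if (reads$strand[i] == "+") amplicon else rc
    scrambleseq:::banded_edit_distance(reads$sequence[i], tmpl, 200)
  }, numeric(1))
  expected <- 0.03 * nchar(amplicon)
  expect_equal(mean(dists), expected, tolerance = 0.15)
})

test_that("truncation always shortens reads", {
  d <- three_seg_design()
  key <- canonical_key(parental_genotype(d))
  em <- error_model(sub_rate = 0, ins_rate = 0, del_rate = 0,
                    p_truncate = 1)
  reads <- synthesize_reads(rep(key, 20), d, em, seed = 5)
  expect_true(all(nchar(reads$sequence) < amplicon_length(d, parental_genotype(d))))
})

test_that("error model validates its rates", {
  expect_error(error_model(sub_rate = 0.3), "0.25")
  expect_error(pool_config(p_cre_active = 1.2), "\\[0, 1\\]")
  expect_error(pool_config(type_weights = c(deletion = 1, inversion = 0.5,
                                            duplication = 0)), "sum to 1")
})

test_that("FASTQ round-trips through write_fastq/read_fastq", {
  d <- three_seg_design()
  reads <- synthesize_reads(rep(canonical_key(parental_genotype(d)), 5), d,
                            error_model(), seed = 6)
  path <- file.path(withr::local_tempdir(), "r.fastq.gz")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_identical(back$sequence, reads$sequence)
  expect_identical(back$id, reads$id)
  expect_identical(reads_truth(back), reads$truth)
})

test_that("genome fixture has 23 bp landing pads and in-bounds features", {
  d <- three_seg_design()
  fx <- make_genome_fixture(d, n_filler_genes = 2, seed = 10)
  lp <- fx$gff[fx$gff$type == "landing_pad"]
  expect_length(lp, 3L)
  expect_true(all(IRanges::width(lp) == 23L))
  lens <- setNames(Biostrings::width(fx$fasta), names(fx$fasta))
  for (i in seq_along(fx$gff)) {
    ctg <- as.character(GenomicRanges::seqnames(fx$gff[i]))
    expect_gte(GenomicRanges::start(fx$gff[i]), 1L)
    expect_lte(GenomicRanges::end(fx$gff[i]), lens[[ctg]])
  }
  # different seed: different sequence, same structure
  fx2 <- make_genome_fixture(d, n_filler_genes = 2, seed = 11)
  expect_false(identical(as.character(fx$fasta), as.character(fx2$fasta)))
  expect_identical(as.data.frame(fx$gff), as.data.frame(fx2$gff))
})

test_that("iterative rounds report per-round summaries", {
  d <- three_seg_design()
  fm <- fitness_model(essential_segments = c("GENA", "GENB", "GENC"),
                      dosage_gene = "GENB")
  res <- run_iterative_rounds(parental_genotype(d), d,
                              pool_config(n_cells = 2000),
                              fm, n_rounds = 2, seed = 12)
  expect_length(res$pools, 2L)
  expect_identical(res$summary$round, c(1L, 2L))
  expect_true(all(res$summary$dominant_freq > 0 &
                    res$summary$dominant_freq <= 1))
})
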
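# Pool genotyper: anchor detection, read filtering, segment annotation,
# genotype calls and summary statistics.

test_that("anchors are found in error-free reads on both strands", {
  d <- three_seg_design()
  amplicon <- render_sequence(d, parental_genotype(d))
  a <- find_anchors(amplicon, d)
  expect_true(a$full_length)
  expect_identical(a$strand, "+")
  expect_true(all(a$hits$edit_distance == 0))
  expect_true(all(a$hits$start0 >= 0 & a$hits$end0 <= nchar(amplicon)))
  ar <- find_anchors(revcomp(amplicon), d)
  expect_true(ar$full_length)
  expect_identical(ar$strand, "-")
  # right flank removed: not full length
  broken <- substr(amplicon, 1, nchar(amplicon) - nchar(d$right_flank))
  expect_false(find_anchors(broken, d)$full_length)
})

test_that("filter_reads counts removals per rule on the toy read set", {
  d <- three_seg_design()
  amplicon <- render_sequence(d, parental_genotype(d))
  inv <- render_sequence(d, c(-3L, -2L, -1L))
  del <- render_sequence(d, c(1L, 3L))
  no_left <- substr(amplicon, nchar(d$left_flank) + 1L, nchar(amplicon))
  no_right <- substr(amplicon, 1L, nchar(amplicon) - nchar(d$right_flank))
  short_anchored <- paste0(d$left_anchor, LOXPSYM, d$right_anchor)
  reads <- setNames(c(amplicon, inv, del, no_left, no_right, short_anchored),
                    paste0("r", 1:6))
  res <- filter_reads(reads, d)
  expect_identical(res$qc$rule, c("missing_anchor", "too_short"))
  expect_identical(res$qc$n_removed, c(2L, 1L))
  expect_identical(attr(res$qc, "n_kept"), 3L)
  expect_identical(res$reads$id, c("r1", "r2", "r3"))
  # min_length = 0 keeps every anchored read
  res0 <- filter_reads(reads, d, min_length = 0)
  expect_identical(attr(res0$qc, "n_kept"), 4L)
  expect_error(filter_reads(character(0), d), "empty")
})

test_that("annotate_segments recovers order, strand and identity", {
  d <- three_seg_design()
  hits <- annotate_segments(render_sequence(d, parental_genotype(d)), d)
  expect_identical(hits$segment_id, 1:3)
  expect_true(all(hits$strand == "+"))
  expect_true(all(hits$identity == 1))
  inv <- annotate_segments(render_sequence(d, c(-3L, -2L, -1L)), d)
  expect_identical(inv$segment_id, c(3L, 2L, 1L))
  expect_true(all(inv$strand == "-"))
})

test_that("most true segments are recovered from noisy reads", {
  d <- small_design()
  keys <- random_genotypes(d, 8, seed = 21)
  em <- error_model(sub_rate = 0.05, ins_rate = 0, del_rate = 0,
                    p_truncate = 0)
  reads <- synthesize_reads(rep(keys, each = 5), d, em, seed = 22)
  recovered <- 0L; total <- 0L
  for (i in seq_along(reads$id)) {
    a <- find_anchors(reads$sequence[i], d)
    hits <- annotate_segments(orient_read(reads$sequence[i], a$strand), d)
    truth <- parse_key(reads$truth[i])
    called <- hits$segment_id * ifelse(hits$strand == "+", 1L, -1L)
    total <- total + length(truth)
    # count true elements present in the call (order-insensitive tally)
    tt <- table(truth); ct <- table(called)
    common <- intersect(names(tt), names(ct))
    recovered <- recovered + sum(pmin(tt[common], ct[common]))
  }
  expect_gte(recovered / total, 0.95)
})

test_that("calls are invariant to read strand", {
  d <- three_seg_design()
  keys <- random_genotypes(d, 6, seed = 31)
  for (k in keys) {
    amp <- render_sequence(d, parse_key(k))
    c1 <- call_genotype(amp, d)
    c2 <- call_genotype(revcomp(amp), d)
    expect_identical(c1$key, c2$key)
    expect_identical(c1$key, k)
  }
})

test_that("raising min_identity never increases accepted hits", {
  d <- small_design()
  em <- error_model()
  reads <- synthesize_reads(rep(canonical_key(parental_genotype(d)), 3),
                            d, em, seed = 41)
  for (i in 1:3) {
    a <- find_anchors(reads$sequence[i], d)
    oriented <- orient_read(reads$sequence[i], a$strand)
    n_hits <- vapply(c(0.5, 0.7, 0.9, 0.95, 0.99), function(mi) {
      nrow(annotate_segments(oriented, d, caller_params(min_identity = mi)))
    }, numeric(1))
    expect_true(all(diff(n_hits) <= 0))
  }
})

test_that("error-free round trip recovers exact keys (small design)", {
  d <- three_seg_design()
  keys <- random_genotypes(d, 10, seed = 51)
  reads <- synthesize_reads(rep(keys, each = 5), d, error_free(), seed = 52)
  res <- call_reads(reads, d)
  expect_identical(attr(res$qc, "n_kept"), length(reads))
  expect_equal(call_accuracy(reads, res$calls), 1)
})

test_that("empty and duplicated genotypes are called correctly", {
  d <- three_seg_design()
  g <- parental_genotype(d)
  dup <- apply_event(g, recombination_event("duplication", 1, 2))
  cd <- call_genotype(render_sequence(d, dup), d)
  expect_identical(cd$key, "+1,+2,+2,+3")
  ce <- call_genotype(render_sequence(d, integer(0)), d)
  expect_identical(ce$key, "")
  expect_identical(ce$n_hits, 0L)
  expect_identical(ce$qc_flags, "")
})

test_that("aggregate_calls normalises, sorts and totals correctly", {
  calls <- data.frame(
    read_id = sprintf("r%d", 1:10),
    key = rep(c("+1,+2", "+1", "-2"), c(6, 3, 1)),
    n_hits = 1L, mean_identity = 1, qc_flags = "")
  tab <- aggregate_calls(calls)
  expect_equal(tab$frequency, c(0.6, 0.3, 0.1))
  expect_identical(attr(tab, "n_reads"), 10L)
  expect_identical(attr(tab, "n_distinct"), 3L)
  expect_equal(sum(tab$frequency), 1, tolerance = 1e-9)
  one <- aggregate_calls(calls[calls$key == "+1", ])
  expect_identical(nrow(one), 1L)
  expect_equal(one$frequency, 1)
  flagged <- transform(calls, qc_flags = "gap")
  expect_error(aggregate_calls(flagged, drop_flagged = TRUE), "flagged")
  expect_identical(attr(aggregate_calls(flagged), "n_reads"), 10L)
})

test_that("summary stats give TU histogram, duplication and deletion rates", {
  d <- small_design()
  parental <- canonical_key(parental_genotype(d))
  dup5 <- "+1,+2,+3,+4,+5,+5,+6,+7"
  calls <- data.frame(
    read_id = sprintf("r%d", 1:10),
    key = rep(c(dup5, parental), c(9, 1)),
    n_hits = 7L, mean_identity = 1, qc_flags = "")
  st <- summary_stats(aggregate_calls(calls), d)
  expect_equal(st$duplication_frequency[["HIS5"]], 0.9)
  expect_equal(sum(st$tu_histogram$frequency), 1)
  expect_equal(st$tu_histogram$frequency[st$tu_histogram$tu == 8], 0.9)
  expect_true(all(st$deletion_frequency == 0))
  # spectrum is nested inside the duplication frequency
  expect_true(all(rowSums(st$copy_spectrum[, c("copy3", "copy4", "copy5plus")])
                  <= st$duplication_frequency + 1e-12))
  # parental-only table: all mass at 7 TUs
  st2 <- summary_stats(aggregate_calls(calls[calls$key == parental, ]), d)
  expect_equal(st2$tu_histogram$tu, 7L)
  expect_equal(st2$tu_histogram$frequency, 1)
  expect_true(all(st2$duplication_frequency == 0))
})
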
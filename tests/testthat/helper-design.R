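# Shared fixtures, built in code: a scaled-down seven-gene module (short
# segments, same layout/chemistry as the full-size default) keeps unit
# tests fast; the full-size default design is used where amplicon scale
# matters.

small_design <- function(segment_length = 300L, flank_length = 80L) {
  default_his_design(segment_length = segment_length,
                     flank_length = flank_length)
}

three_seg_design <- function() {
  build_reference(
    data.frame(order = 1:3, segment_id = 1:3,
               name = c("GENA", "GENB", "GENC"), role = "gene_cassette"),
    segment_length = 200L, flank_length = 60L, seed = 7L)
}

error_free <- function() {
  error_model(sub_rate = 0, ins_rate = 0, del_rate = 0, p_truncate = 0)
}

# Random non-empty genotypes obtained by applying random event chains to
# the parental arrangement (capped element count).
random_genotypes <- function(design, n, max_events = 4L, max_elements = 12L,
                             seed = 1L) {
  parental <- parental_genotype(design)
  out <- character(0)
  with_seed(seed, {
    while (length(out) < n) {
      g <- parental
      for (e in seq_len(sample.int(max_events, 1L))) {
        m <- length(g)
        if (m == 0L) break
        ev <- applicable_events(g)
        row <- ev[sample.int(nrow(ev), 1L), ]
        g2 <- apply_event(g, recombination_event(row$event_type, row$i, row$j))
        if (length(g2) <= max_elements) g <- g2
      }
      if (length(g) > 0L) out <- unique(c(out, canonical_key(g)))
    }
  })
  out[seq_len(n)]
}

call_accuracy <- function(reads, calls) {
  truth <- reads_truth(reads)[match(calls$read_id, reads$id)]
  mean(calls$key == truth)
}
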
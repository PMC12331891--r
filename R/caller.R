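#' Genotype-caller parameters
#'
#' Tunable thresholds of the pool genotyper. Anchors and lox sites are
#' located by bit-parallel semiglobal (infix) edit-distance search; read
#' chunks between located lox sites are assigned to a candidate segment
#' and strand by exact k-mer voting and verified by banded global
#' alignment against the segment sequence.
#'
#' @param max_edit_frac Maximum anchor edit distance as a fraction of
#'   anchor length (full-length detection).
#' @param lox_max_edit_frac Maximum lox-site edit distance as a fraction
#'   of lox length.
#' @param min_identity Minimum alignment identity
#'   (`1 - dist / max(chunk, segment)`) for an accepted segment hit.
#' @param min_coverage Minimum fraction of the segment length covered by
#'   the chunk.
#' @param gap_max Maximum unannotated interior run (bp) before a read is
#'   flagged (not rejected).
#' @param kmer k-mer size of the segment vote.
#' @param min_votes Minimum k-mer votes to consider a chunk assignable.
#' @param min_chunk Chunks shorter than this (bp) are ignored as
#'   lox-adjacent debris.
#' @param band_slack Extra half-width (bp) of the alignment band beyond
#'   the chunk/segment length difference.
#' @return A list of class `caller_params`.
#' @export
caller_params <- function(max_edit_frac = 0.2, lox_max_edit_frac = 0.2,
                          min_identity = 0.70, min_coverage = 0.80,
                          gap_max = 500L, kmer = 13L, min_votes = 10L,
                          min_chunk = 25L, band_slack = 150L) {
  stopifnot(max_edit_frac >= 0, max_edit_frac < 1,
            lox_max_edit_frac >= 0, lox_max_edit_frac < 1,
            min_identity >= 0, min_identity <= 1,
            min_coverage >= 0, min_coverage <= 1)
  structure(list(max_edit_frac = max_edit_frac,
                 lox_max_edit_frac = lox_max_edit_frac,
                 min_identity = min_identity, min_coverage = min_coverage,
                 gap_max = as.integer(gap_max), kmer = as.integer(kmer),
                 min_votes = as.integer(min_votes),
                 min_chunk = as.integer(min_chunk),
                 band_slack = as.integer(band_slack)),
            class = "caller_params")
}

# Best infix hit of `pattern` in `text`: 1-based [start, end] interval
# (start is the conservative lower bound end - m - dist + 1) and distance.
best_infix_hit <- function(pattern, text) {
  d <- myers_end_dists(pattern, text)
  j <- which.min(d)
  dist <- d[j]
  m <- nchar(pattern)
  list(start = max(1L, j - m - dist + 1L), end = j, dist = dist)
}

#' Locate primer anchors and orient a read
#'
#' Searches the read for the left and right primer anchors of the design
#' and for their reverse complements by semiglobal edit-distance matching.
#' A read is *full length* iff both anchors are found within
#' `max_edit_frac` of their length, in a single consistent orientation and
#' in the expected order. For minus-strand reads the reported strand is
#' `"-"`; [orient_read()] returns the sequence reverse-complemented so the
#' left anchor leads.
#'
#' @param read Character scalar (one read sequence).
#' @param design A `module_design`.
#' @param max_edit_frac Maximum anchor edit distance as a fraction of
#'   anchor length.
#' @return A list: `full_length` (logical), `strand` (`"+"`, `"-"` or
#'   `NA`), and `hits`, a data frame of per-anchor intervals
#'   (0-based half-open `start0`/`end0`) and edit distances.
#' @export
find_anchors <- function(read, design, max_edit_frac = 0.2) {
  stopifnot(is.character(read), length(read) == 1L)
  la <- design$left_anchor
  ra <- design$right_anchor
  max_l <- ceiling(max_edit_frac * nchar(la))
  max_r <- ceiling(max_edit_frac * nchar(ra))
  if (nchar(read) < max(nchar(la), nchar(ra)))
    return(list(full_length = FALSE, strand = NA_character_,
                hits = NULL))
  hL <- best_infix_hit(la, read)
  hR <- best_infix_hit(ra, read)
  hLr <- best_infix_hit(revcomp(la), read)
  hRr <- best_infix_hit(revcomp(ra), read)
  fwd_ok <- hL$dist <= max_l && hR$dist <= max_r && hL$end < hR$start
  rev_ok <- hRr$dist <= max_r && hLr$dist <= max_l && hRr$end < hLr$start
  strand <- if (fwd_ok && rev_ok) {
    if (hL$dist + hR$dist <= hLr$dist + hRr$dist) "+" else "-"
  } else if (fwd_ok) "+" else if (rev_ok) "-" else NA_character_
  hits <- if (is.na(strand)) NULL else if (strand == "+") {
    data.frame(anchor = c("left", "right"), strand = "+",
               start0 = c(hL$start, hR$start) - 1L,
               end0 = c(hL$end, hR$end),
               edit_distance = c(hL$dist, hR$dist))
  } else {
    data.frame(anchor = c("right", "left"), strand = "-",
               start0 = c(hRr$start, hLr$start) - 1L,
               end0 = c(hRr$end, hLr$end),
               edit_distance = c(hRr$dist, hLr$dist))
  }
  list(full_length = !is.na(strand), strand = strand, hits = hits)
}

#' Re-orient a read so the left anchor leads
#'
#' @param read Character scalar.
#' @param strand `"+"` or `"-"` from [find_anchors()].
#' @return Character scalar (reverse-complemented when `strand == "-"`).
#' @export
orient_read <- function(read, strand) {
  if (identical(strand, "-")) revcomp(read) else read
}

#' Filter reads to anchored, full-length candidates
#'
#' Applies the two pool-genotyping read filters: (1) both primer anchors
#' present in consistent orientation ([find_anchors()]); (2) read length
#' at least `min_length`, which defaults to the empty-genotype amplicon
#' (`|left_flank| + |right_flank| + 2 |lox|`), the smallest possible
#' product. Every removal is counted per rule; no read is dropped
#' silently.
#'
#' @param reads A `scramble_reads`, `DNAStringSet` or named character
#'   vector.
#' @param design A `module_design`.
#' @param min_length Minimum read length (bp); `NULL` for the default.
#' @param max_edit_frac Anchor tolerance, as in [find_anchors()].
#' @return A list: `reads` (kept subset, a `scramble_reads`), `strand`
#'   (per kept read), and `qc`, a data frame of per-rule removal counts
#'   (`rule`, `n_removed`) plus counts in/out as attributes.
#' @export
filter_reads <- function(reads, design, min_length = NULL,
                         max_edit_frac = 0.2) {
  reads <- as_reads(reads)
  if (length(reads) == 0L) stop("empty read input")
  min_length <- min_length %||%
    (nchar(design$left_flank) + nchar(design$right_flank) +
       2L * nchar(design$lox_sequence))
  anchors <- lapply(reads$sequence, find_anchors, design = design,
                    max_edit_frac = max_edit_frac)
  anchored <- vapply(anchors, `[[`, logical(1), "full_length")
  long_enough <- nchar(reads$sequence) >= min_length
  keep <- anchored & long_enough
  qc <- data.frame(
    rule = c("missing_anchor", "too_short"),
    n_removed = c(sum(!anchored), sum(anchored & !long_enough)))
  out <- list(
    reads = reads[keep],
    strand = vapply(anchors[keep], `[[`, character(1), "strand"),
    qc = qc)
  attr(out$qc, "n_in") <- length(reads)
  attr(out$qc, "n_kept") <- sum(keep)
  out
}

# Precompute the per-design data the annotator needs: both-strand segment
# sequences for voting/alignment.
segment_bank <- function(design) {
  n <- nrow(design$segments)
  list(
    seqs = c(design$segments$sequence, design$segments$rc_sequence),
    segment_id = rep(design$segments$segment_id, 2L),
    strand = rep(c("+", "-"), each = n)
  )
}

# Locate lox sites in an oriented read; returns 0-based half-open
# intervals of accepted sites. Candidate end positions within the edit
# threshold are accepted greedily by increasing distance subject to a
# minimum separation (no two genuine sites can sit closer than one
# segment), which suppresses near-duplicate and spurious matches.
locate_lox <- function(read, design, params) {
  lox <- design$lox_sequence
  max_d <- ceiling(params$lox_max_edit_frac * nchar(lox))
  min_sep <- max(params$min_chunk,
                 floor(0.4 * min(design$segments$length)))
  d <- myers_end_dists(lox, read)
  cand <- which(d <= max_d)
  if (length(cand) == 0L) return(NULL)
  ord <- cand[order(d[cand], cand)]
  ends <- integer(0)
  for (j in ord)
    if (!length(ends) || all(abs(ends - j) >= min_sep)) ends <- c(ends, j)
  ends <- sort(ends)
  dists <- d[ends]
  data.frame(start0 = pmax(0L, ends - nchar(lox) - dists),
             end0 = ends, dist = dists)
}

#' Annotate signed segment content of an oriented read
#'
#' Splits the read at located lox sites and assigns each resulting chunk
#' to a segment and strand by exact k-mer voting, verified by banded
#' global edit-distance alignment. Hits failing `min_identity` or
#' `min_coverage` are discarded; should accepted hits ever overlap, they
#' are resolved greedily by score (then longer, then leftmost) allowing
#' at most 20% overlap of the shorter hit.
#'
#' @param read Character scalar, oriented so the left anchor leads (see
#'   [orient_read()]).
#' @param design A `module_design`.
#' @param params A [caller_params()].
#' @return A data frame of accepted hits in read order: `segment_id`,
#'   `name`, `strand`, `start0`, `end0`, `identity`, `coverage`, `score`;
#'   with attribute `n_unassigned` counting assignable-width chunks that
#'   found no segment.
#' @export
annotate_segments <- function(read, design, params = caller_params()) {
  bank <- segment_bank(design)
  lox_len <- nchar(design$lox_sequence)
  lox_hits <- locate_lox(read, design, params)
  empty_hits <- data.frame(segment_id = integer(0), name = character(0),
                           strand = character(0), start0 = integer(0),
                           end0 = integer(0), identity = numeric(0),
                           coverage = numeric(0), score = numeric(0))
  n_unassigned <- 0L

  # Evaluate one inter-lox chunk; when a chunk cannot be matched as a
  # single segment (typically because an interior lox site was missed at
  # the primary threshold), retry after splitting it at the best interior
  # lox candidate. Returns a list of hit rows.
  evaluate_chunk <- function(c_start, c_end, depth) {
    len <- c_end - c_start
    if (len < params$min_chunk) return(list())
    chunk <- substr(read, c_start + 1L, c_end)
    votes <- kmer_hit_counts(chunk, bank$seqs, params$kmer)
    best <- which.max(votes)
    if (votes[best] >= params$min_votes) {
      seg_seq <- bank$seqs[best]
      lc <- nchar(chunk); ls <- nchar(seg_seq)
      dist <- if (chunk == seg_seq) 0L else
        banded_edit_distance(chunk, seg_seq,
                             abs(lc - ls) + params$band_slack)
      identity <- 1 - dist / max(lc, ls)
      coverage <- min(1, lc / ls)
      if (identity >= params$min_identity &&
          coverage >= params$min_coverage) {
        return(list(data.frame(
          segment_id = bank$segment_id[best],
          name = design$segments$name[bank$segment_id[best]],
          strand = bank$strand[best],
          start0 = c_start, end0 = c_end,
          identity = identity, coverage = coverage,
          score = identity * lc)))
      }
    }
    # repair pass: split at the best interior lox candidate
    if (depth < 3L && len >= 2L * params$min_chunk + lox_len) {
      d <- myers_end_dists(design$lox_sequence, chunk)
      lo <- params$min_chunk + lox_len
      hi <- len - params$min_chunk
      if (hi >= lo) {
        win <- lo:hi
        j <- win[which.min(d[win])]
        if (d[j] <= ceiling(0.45 * lox_len)) {
          site_start <- max(0L, j - lox_len - d[j])
          left <- evaluate_chunk(c_start, c_start + site_start, depth + 1L)
          right <- evaluate_chunk(c_start + j, c_end, depth + 1L)
          if (length(left) + length(right) > 0L) return(c(left, right))
        }
      }
    }
    n_unassigned <<- n_unassigned + 1L
    list()
  }

  # Fixed boundaries at the flank/array junctions, derived from the
  # anchor positions and the anchors' known offsets inside the flanks;
  # they guarantee the terminal segments are examined even when the
  # first or last lox site itself is missed in a noisy read.
  hL <- best_infix_hit(design$left_anchor, read)
  hR <- best_infix_hit(design$right_anchor, read)
  offL <- regexpr(design$left_anchor, design$left_flank, fixed = TRUE)[1] - 1L
  offR <- regexpr(design$right_anchor, design$right_flank, fixed = TRUE)[1] - 1L
  b_left <- (hL$start - 1L) - offL + nchar(design$left_flank)
  b_right <- (hR$start - 1L) - offR
  bounds <- data.frame(start0 = b_left, end0 = b_left)
  if (!is.null(lox_hits)) {
    inside <- lox_hits$end0 > b_left + params$min_chunk &
      lox_hits$start0 < b_right - params$min_chunk
    bounds <- rbind(bounds, lox_hits[inside, c("start0", "end0")])
  }
  bounds <- rbind(bounds, data.frame(start0 = b_right, end0 = b_right))
  bounds <- bounds[order(bounds$start0), , drop = FALSE]
  rows <- list()
  if (nrow(bounds) >= 2L) {
    for (ci in seq_len(nrow(bounds) - 1L))
      rows <- c(rows, evaluate_chunk(bounds$end0[ci],
                                     bounds$start0[ci + 1L], 0L))
  }
  hits <- if (length(rows)) do.call(rbind, rows) else empty_hits
  hits <- resolve_overlaps(hits)
  hits <- hits[order(hits$start0), , drop = FALSE]
  rownames(hits) <- NULL
  attr(hits, "n_unassigned") <- n_unassigned
  hits
}

# Greedy score-ranked overlap resolution (ties: longer hit, then
# leftmost); accepted hits may overlap an earlier accepted hit by at most
# 20% of the shorter one. Chunk-derived hits are disjoint by
# construction, so this is usually a no-op.
resolve_overlaps <- function(hits, max_overlap_frac = 0.2) {
  if (nrow(hits) <= 1L) return(hits)
  len <- hits$end0 - hits$start0
  ord <- order(-hits$score, -len, hits$start0)
  accepted <- integer(0)
  for (h in ord) {
    ok <- TRUE
    for (a in accepted) {
      ov <- min(hits$end0[h], hits$end0[a]) - max(hits$start0[h], hits$start0[a])
      if (ov > max_overlap_frac * min(len[h], len[a])) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, h)
  }
  hits[sort(accepted), , drop = FALSE]
}

#' Call the genotype of one read
#'
#' Orients the read, annotates its signed segment content and converts
#' the ordered accepted hits into a canonical genotype key. QC flags
#' (comma-joined in `qc_flags`) mark large unannotated interior gaps
#' (`gap`, > `gap_max` bp between consecutive hits or between an anchor
#' and its nearest hit) and chunks that could not be assigned
#' (`unassigned_chunk`). A read with zero accepted hits is called as the
#' empty genotype with flag `no_hits` (unless it genuinely is the empty
#' amplicon).
#'
#' @param read Character scalar, or a single-read `scramble_reads`.
#' @param design A `module_design`.
#' @param params A [caller_params()].
#' @param read_id Optional id for the output row.
#' @return One-row data frame: `read_id`, `key`, `n_hits`,
#'   `mean_identity`, `qc_flags`.
#' @export
call_genotype <- function(read, design, params = caller_params(),
                          read_id = "read") {
  if (inherits(read, "scramble_reads")) {
    stopifnot(length(read) == 1L)
    read_id <- read$id[1]
    read <- read$sequence[1]
  }
  anch <- find_anchors(read, design, params$max_edit_frac)
  flags <- character(0)
  if (!anch$full_length) {
    return(data.frame(read_id = read_id, key = NA_character_, n_hits = 0L,
                      mean_identity = NA_real_, qc_flags = "not_full_length",
                      stringsAsFactors = FALSE))
  }
  oriented <- orient_read(read, anch$strand)
  hits <- annotate_segments(oriented, design, params)
  if (attr(hits, "n_unassigned") > 0L) flags <- c(flags, "unassigned_chunk")
  # gap check over the interior spanned by the lox array
  oa <- find_anchors(oriented, design, params$max_edit_frac)
  interior_start <- oa$hits$end0[oa$hits$anchor == "left"]
  interior_end <- oa$hits$start0[oa$hits$anchor == "right"]
  lox_len <- nchar(design$lox_sequence)
  bounds <- c(interior_start, interior_end)
  if (nrow(hits) > 0L)
    bounds <- c(interior_start, as.vector(rbind(hits$start0, hits$end0)),
                interior_end)
  gaps <- bounds[seq(2, length(bounds), by = 2)] -
    bounds[seq(1, length(bounds) - 1, by = 2)]
  if (length(gaps) && any(gaps - lox_len > params$gap_max))
    flags <- c(flags, "gap")
  key <- canonical_key(hits$segment_id * ifelse(hits$strand == "+", 1L, -1L))
  empty_len <- nchar(design$left_flank) + nchar(design$right_flank) +
    2L * nchar(design$lox_sequence)
  if (nrow(hits) == 0L && nchar(read) > empty_len + params$gap_max)
    flags <- c(flags, "no_hits")
  data.frame(read_id = read_id, key = key, n_hits = nrow(hits),
             mean_identity = if (nrow(hits)) mean(hits$identity) else NA_real_,
             qc_flags = paste(flags, collapse = ","),
             stringsAsFactors = FALSE)
}

#' Filter and genotype a read pool
#'
#' The full pool-genotyping stage: [filter_reads()] then
#' [call_genotype()] on every kept read.
#'
#' @param reads A `scramble_reads`, `DNAStringSet` or named character
#'   vector.
#' @param design A `module_design`.
#' @param params A [caller_params()].
#' @param min_length,max_edit_frac Passed to [filter_reads()].
#' @return A list: `calls` (data frame, one row per kept read), `qc`
#'   (filter report).
#' @export
call_reads <- function(reads, design, params = caller_params(),
                       min_length = NULL, max_edit_frac = NULL) {
  max_edit_frac <- max_edit_frac %||% params$max_edit_frac
  flt <- filter_reads(reads, design, min_length = min_length,
                      max_edit_frac = max_edit_frac)
  kept <- flt$reads
  calls <- vector("list", length(kept))
  for (i in seq_along(calls)) {
    oriented <- orient_read(kept$sequence[i], flt$strand[i])
    row <- call_genotype(oriented, design, params, read_id = kept$id[i])
    calls[[i]] <- row
  }
  calls <- if (length(calls)) do.call(rbind, calls) else
    data.frame(read_id = character(0), key = character(0),
               n_hits = integer(0), mean_identity = numeric(0),
               qc_flags = character(0))
  list(calls = calls, qc = flt$qc)
}

#' Aggregate per-read calls into a genotype table
#'
#' Collapses calls by genotype key into a table of read counts and
#' frequencies, sorted by count (ties by key), and records the totals:
#' annotated read count and distinct genotype count.
#'
#' @param calls Data frame from [call_reads()]/[call_genotype()].
#' @param drop_flagged Drop reads with any QC flag before aggregating
#'   (default `FALSE`: flagged reads keep their best-effort call).
#' @return A `genotype_table` data frame (`key`, `count`, `frequency`)
#'   with attributes `n_reads` and `n_distinct`.
#' @export
aggregate_calls <- function(calls, drop_flagged = FALSE) {
  stopifnot(is.data.frame(calls))
  calls <- calls[!is.na(calls$key), , drop = FALSE]
  if (drop_flagged) calls <- calls[!nzchar(calls$qc_flags), , drop = FALSE]
  if (nrow(calls) == 0L)
    stop(if (drop_flagged) "all calls are QC-flagged" else "no callable reads")
  counts <- table(calls$key)
  tab <- data.frame(key = names(counts), count = as.integer(counts),
                    stringsAsFactors = FALSE)
  tab$frequency <- tab$count / sum(tab$count)
  tab <- tab[order(-tab$count, tab$key), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "n_reads") <- sum(tab$count)
  attr(tab, "n_distinct") <- nrow(tab)
  class(tab) <- c("genotype_table", "data.frame")
  tab
}

#' Copy-number summary statistics of a genotype table
#'
#' The pool-level statistics of a genotyping run, all read-frequency
#' weighted: the transcription-unit (TU) count histogram; per-gene
#' duplication frequency (fraction of reads with copy number >= 2);
#' the per-gene copy-number spectrum (fractions with copy exactly 3,
#' exactly 4, and >= 5); and per-gene deletion frequency (copy 0).
#'
#' @param table A `genotype_table` from [aggregate_calls()].
#' @param design A `module_design`.
#' @return A list with elements `tu_histogram` (data frame `tu`,
#'   `frequency`), `duplication_frequency`, `deletion_frequency` (named
#'   vectors over gene cassettes) and `copy_spectrum` (data frame `gene`,
#'   `copy3`, `copy4`, `copy5plus`).
#' @export
summary_stats <- function(table, design) {
  stopifnot(is.data.frame(table), nrow(table) > 0L)
  genes <- design$segments$name[design$segments$role == "gene_cassette"]
  freq <- table$frequency
  cn <- t(vapply(table$key,
                 function(k) copy_numbers(parse_key(k), design),
                 numeric(nrow(design$segments))))
  colnames(cn) <- design$segments$name
  tu <- as.integer(rowSums(cn[, genes, drop = FALSE]))
  tu_hist <- aggregate(freq, by = list(tu = tu), FUN = sum)
  names(tu_hist)[2] <- "frequency"
  tu_hist <- tu_hist[order(tu_hist$tu), , drop = FALSE]
  rownames(tu_hist) <- NULL
  dup <- vapply(genes, function(g) sum(freq[cn[, g] >= 2]), numeric(1))
  del <- vapply(genes, function(g) sum(freq[cn[, g] == 0]), numeric(1))
  spectrum <- data.frame(
    gene = genes,
    copy3 = vapply(genes, function(g) sum(freq[cn[, g] == 3]), numeric(1)),
    copy4 = vapply(genes, function(g) sum(freq[cn[, g] == 4]), numeric(1)),
    copy5plus = vapply(genes, function(g) sum(freq[cn[, g] >= 5]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(tu_histogram = tu_hist,
       duplication_frequency = dup,
       deletion_frequency = del,
       copy_spectrum = spectrum)
}
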
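#' Explain an observed genotype as structural events
#'
#' Describes an observed genotype relative to the reference design as a
#' set of deletion, duplication and inversion-block calls. The
#' description is *descriptive*, not a minimal event history: a segment
#' with copy number 0 yields one deletion call; copy number >= 2 yields
#' one duplication call with `copy_delta = copy - 1`; inversion blocks
#' are maximal runs of minus-oriented elements whose segment ids are
#' consecutive-descending in reference order (an isolated minus-oriented
#' element is its own block).
#'
#' @param design A `module_design`.
#' @param observed Signed integer vector or canonical key.
#' @return A data frame of event calls: `event_type` (`deletion` /
#'   `duplication` / `inversion_block`), `segments` (comma-joined names),
#'   `first_element`, `last_element` (1-based positions of the block in
#'   the observed genotype; `NA` for copy-number calls), `copy_delta`.
#' @export
#' @examples
#' d <- default_his_design(segment_length = 200, flank_length = 60)
#' diff_genotype(d, parse_key("-3,-2,-1,+4,+5,+6,+7"))
diff_genotype <- function(design, observed) {
  if (is.character(observed)) observed <- parse_key(observed)
  observed <- check_genotype(observed, design)
  counts <- copy_numbers(observed, design)
  rows <- list()
  for (nm in names(counts)[counts == 0L])
    rows[[length(rows) + 1L]] <- data.frame(
      event_type = "deletion", segments = nm,
      first_element = NA_integer_, last_element = NA_integer_,
      copy_delta = NA_integer_, stringsAsFactors = FALSE)
  for (nm in names(counts)[counts >= 2L])
    rows[[length(rows) + 1L]] <- data.frame(
      event_type = "duplication", segments = nm,
      first_element = NA_integer_, last_element = NA_integer_,
      copy_delta = counts[[nm]] - 1L, stringsAsFactors = FALSE)
  m <- length(observed)
  i <- 1L
  while (i <= m) {
    if (observed[i] < 0L) {
      j <- i
      while (j < m && observed[j + 1L] < 0L &&
             abs(observed[j + 1L]) == abs(observed[j]) - 1L) j <- j + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        event_type = "inversion_block",
        segments = paste(design$segments$name[abs(observed[j:i])],
                         collapse = ","),
        first_element = i, last_element = j,
        copy_delta = NA_integer_, stringsAsFactors = FALSE)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (length(rows) == 0L)
    return(data.frame(event_type = character(0), segments = character(0),
                      first_element = integer(0), last_element = integer(0),
                      copy_delta = integer(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# 1-based inclusive intervals of the lox sites in the rendered parental
# reference; site k (0..n) sits left of segment k+1.
reference_lox_sites <- function(design, offset = 0L) {
  lox_len <- nchar(design$lox_sequence)
  starts <- integer(nrow(design$segments) + 1L)
  pos <- nchar(design$left_flank) + 1L
  for (k in seq_along(starts)) {
    starts[k] <- pos
    if (k <= nrow(design$segments))
      pos <- pos + lox_len + design$segments$length[k]
  }
  data.frame(site = seq_along(starts) - 1L,
             start = starts + offset,
             end = starts + lox_len - 1L + offset)
}

#' Gene-level impact of structural events
#'
#' Classifies each annotated gene of the module against a set of event
#' calls from [diff_genotype()]: `deleted` if its segment is deleted,
#' `duplicated` if copy number >= 2, `inverted` if it lies inside an
#' inversion block, and additionally `utr_disrupted` if a deletion or
#' inversion-block boundary (a reference lox-site interval) overlaps the
#' gene's annotated 3' UTR. A gene can carry several impacts (e.g. a
#' duplicated-and-inverted gene reports both, comma-joined); a gene with
#' none is `unaffected`.
#'
#' Genes are matched to segments by their `Name` attribute (equal to the
#' design's segment name). When a gene has no `three_prime_UTR` feature,
#' a fallback window of `utr_fallback` bp immediately downstream of the
#' gene is used and flagged as inferred.
#'
#' @param events Data frame from [diff_genotype()].
#' @param annotation A [GenomicRanges::GRanges] with `type` values
#'   including `gene` (and ideally `three_prime_UTR` with a `Parent` or
#'   `Name` linking to the gene), in module-reference coordinates
#'   (1-based inclusive, as in GFF3); or a path to a GFF3 file.
#' @param design A `module_design`.
#' @param utr_fallback Window (bp) downstream of a gene used when no UTR
#'   feature exists.
#' @return A data frame with one row per annotated gene: `gene`,
#'   `impact` (comma-joined set or `"unaffected"`), `utr_inferred`,
#'   `evidence` (semicolon-joined event descriptions).
#' @export
annotate_gene_impact <- function(events, annotation, design,
                                 utr_fallback = 200L) {
  stopifnot(is.data.frame(events))
  if (is.character(annotation))
    annotation <- rtracklayer::import(annotation, format = "gff3")
  if (!methods::is(annotation, "GRanges"))
    stop("annotation must be a GRanges or a GFF3 path")
  types <- as.character(annotation$type)
  gene_gr <- annotation[types == "gene"]
  if (length(gene_gr) == 0L) stop("annotation contains no gene features")
  gene_names <- as.character(gene_gr$Name %||% gene_gr$ID)
  if (any(is.na(gene_names) | !nzchar(gene_names)))
    stop("every gene feature needs a Name (or ID) attribute")
  utr_gr <- annotation[types == "three_prime_UTR"]
  utr_parent <- if (length(utr_gr)) {
    p <- utr_gr$Parent %||% utr_gr$Name
    vapply(p, function(x) as.character(x)[1], character(1))
  } else character(0)
  utr_parent <- sub("^gene:", "", utr_parent)

  deleted <- events$segments[events$event_type == "deletion"]
  duplicated_ <- events$segments[events$event_type == "duplication"]
  inverted <- unique(unlist(strsplit(
    events$segments[events$event_type == "inversion_block"], ",")))

  # boundary lox intervals (reference coordinates) of deletions and
  # inversion blocks
  sites <- reference_lox_sites(design)
  boundary_sites <- integer(0)
  seg_index <- setNames(design$segments$segment_id, design$segments$name)
  for (r in which(events$event_type == "deletion")) {
    s <- seg_index[[events$segments[r]]]
    boundary_sites <- c(boundary_sites, s - 1L, s)
  }
  for (r in which(events$event_type == "inversion_block")) {
    ids <- seg_index[strsplit(events$segments[r], ",")[[1]]]
    boundary_sites <- c(boundary_sites, min(ids) - 1L, max(ids))
  }
  boundary_sites <- unique(boundary_sites)
  boundary_gr <- if (length(boundary_sites)) {
    GenomicRanges::GRanges(
      seqnames = as.character(GenomicRanges::seqnames(gene_gr))[1],
      IRanges::IRanges(start = sites$start[match(boundary_sites, sites$site)],
                       end = sites$end[match(boundary_sites, sites$site)]))
  } else GenomicRanges::GRanges()

  out <- vector("list", length(gene_gr))
  for (gi in seq_along(gene_gr)) {
    g <- gene_names[gi]
    impacts <- character(0)
    evid <- character(0)
    if (g %in% deleted) { impacts <- c(impacts, "deleted")
      evid <- c(evid, paste0("deletion:", g)) }
    if (g %in% duplicated_) { impacts <- c(impacts, "duplicated")
      evid <- c(evid, paste0("duplication:", g)) }
    if (g %in% inverted) { impacts <- c(impacts, "inverted")
      evid <- c(evid, "inversion_block") }
    utr_i <- which(utr_parent == g)
    inferred <- length(utr_i) == 0L
    utr_range <- if (!inferred) {
      utr_gr[utr_i]
    } else {
      GenomicRanges::GRanges(
        as.character(GenomicRanges::seqnames(gene_gr[gi])),
        IRanges::IRanges(start = GenomicRanges::end(gene_gr[gi]) + 1L,
                         width = utr_fallback))
    }
    if (length(boundary_gr) &&
        any(IRanges::overlapsAny(utr_range, boundary_gr))) {
      impacts <- c(impacts, "utr_disrupted")
      evid <- c(evid, "boundary_in_3utr")
    }
    out[[gi]] <- data.frame(
      gene = g,
      impact = if (length(impacts)) paste(impacts, collapse = ",")
               else "unaffected",
      utr_inferred = inferred,
      evidence = paste(evid, collapse = ";"),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
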
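#' Genotypes as signed segment sequences
#'
#' A genotype is the ordered content of the lox array, represented as a
#' signed integer vector: element `+k` is segment `k` in reference
#' orientation, `-k` its inversion. The empty vector is the fully deleted
#' module. Copy number of a segment is its number of occurrences,
#' irrespective of sign. loxPsym sites are implicit: every adjacency and
#' both array ends carry one, an invariant every recombination event
#' preserves.
#'
#' `parental_genotype()` returns the intact reference arrangement
#' `(+1, ..., +n)`.
#'
#' @param design A `module_design`.
#' @return Integer vector of signed segment ids.
#' @export
#' @examples
#' d <- default_his_design(segment_length = 200, flank_length = 60)
#' parental_genotype(d)
parental_genotype <- function(design) {
  stopifnot(inherits(design, "module_design"))
  seq_len(nrow(design$segments))
}

#' Canonical text key of a genotype
#'
#' Signed segment ids joined left-to-right as read from the left flank,
#' e.g. `"+1,-2"`. Two genotypes are identical iff their keys are equal;
#' whole-molecule mirror images are *not* collapsed because the flanking
#' primer anchors fix the reading orientation. The empty genotype has key
#' `""`.
#'
#' @param genotype Signed integer vector.
#' @return Character scalar.
#' @export
#' @examples
#' canonical_key(c(1L, -2L))
#' parse_key("+1,-2")
canonical_key <- function(genotype) {
  genotype <- as.integer(genotype)
  if (length(genotype) == 0L) return("")
  paste0(ifelse(genotype > 0L, "+", "-"), abs(genotype), collapse = ",")
}

#' @rdname canonical_key
#' @param key Character scalar as produced by `canonical_key()`.
#' @export
parse_key <- function(key) {
  stopifnot(is.character(key), length(key) == 1L)
  if (!nzchar(key)) return(integer(0))
  parts <- strsplit(key, ",", fixed = TRUE)[[1]]
  if (!all(grepl("^[+-][0-9]+$", parts)))
    stop("malformed genotype key: ", key)
  as.integer(parts)
}

check_genotype <- function(genotype, design = NULL) {
  genotype <- as.integer(genotype)
  if (any(genotype == 0L)) stop("genotype elements must be non-zero signed ids")
  if (!is.null(design) && length(genotype) &&
      any(abs(genotype) > nrow(design$segments)))
    stop("unknown segment_id in genotype: ",
         paste(setdiff(abs(genotype), design$segments$segment_id), collapse = ", "))
  genotype
}

#' Construct a recombination event
#'
#' An event is defined by a pair of lox-site indices `0 <= i < j <= m` for
#' a genotype of `m` elements (site `k` sits immediately left of element
#' `k + 1`), and acts on the block of elements strictly between the two
#' sites: deletion excises the block (the two sites collapse into one),
#' inversion reverses the block and flips every orientation, duplication
#' inserts a tandem copy of the block immediately after it.
#'
#' @param event_type One of `"deletion"`, `"inversion"`, `"duplication"`.
#' @param i,j Lox site indices, `0 <= i < j`.
#' @return A list of class `recombination_event`.
#' @export
#' @examples
#' apply_event(1:3, recombination_event("inversion", 0, 3))
recombination_event <- function(event_type, i, j) {
  event_type <- match.arg(event_type, EVENT_TYPES)
  i <- as.integer(i); j <- as.integer(j)
  if (is.na(i) || is.na(j) || i < 0L || i >= j)
    stop("event requires lox-site indices 0 <= i < j")
  structure(list(event_type = event_type, i = i, j = j),
            class = "recombination_event")
}

#' Apply a recombination event to a genotype
#'
#' @param genotype Signed integer vector.
#' @param event A [recombination_event()].
#' @return The rearranged genotype (signed integer vector).
#' @export
apply_event <- function(genotype, event) {
  stopifnot(inherits(event, "recombination_event"))
  genotype <- check_genotype(genotype)
  m <- length(genotype)
  if (event$j > m)
    stop("lox site index ", event$j, " out of range for genotype of length ", m)
  idx <- (event$i + 1L):event$j
  block <- genotype[idx]
  switch(event$event_type,
    deletion = genotype[-idx],
    inversion = { genotype[idx] <- -rev(block); genotype },
    duplication = append(genotype, block, after = event$j)
  )
}

#' Enumerate all applicable events for a genotype
#'
#' All `(type, i, j)` with `0 <= i < j <= m` for each allowed type, where
#' `m` is the current element count. The empty genotype admits no events.
#'
#' @param genotype Signed integer vector (only its length matters).
#' @param allowed_types Subset of `c("deletion", "inversion",
#'   "duplication")`.
#' @return Data frame with columns `event_type`, `i`, `j`.
#' @export
#' @examples
#' nrow(applicable_events(1:2))  # 3 site pairs x 3 types
applicable_events <- function(genotype, allowed_types = EVENT_TYPES) {
  allowed_types <- match.arg(allowed_types, EVENT_TYPES, several.ok = TRUE)
  m <- length(genotype)
  if (m == 0L)
    return(data.frame(event_type = character(0), i = integer(0),
                      j = integer(0), stringsAsFactors = FALSE))
  pairs <- t(utils::combn(0:m, 2L))
  data.frame(
    event_type = rep(allowed_types, each = nrow(pairs)),
    i = rep(pairs[, 1], times = length(allowed_types)),
    j = rep(pairs[, 2], times = length(allowed_types)),
    stringsAsFactors = FALSE
  )
}

#' Per-segment copy numbers and transcription-unit count
#'
#' Copy number is the orientation-insensitive occurrence count of each
#' segment id. The transcription-unit (TU) count of a genotype is the sum
#' of copy numbers over `gene_cassette` segments; `marker` segments are
#' excluded.
#'
#' @param genotype Signed integer vector.
#' @param design A `module_design`.
#' @return `copy_numbers()`: named integer vector (one entry per design
#'   segment); `tu_count()`: integer scalar.
#' @export
#' @examples
#' d <- default_his_design(segment_length = 200, flank_length = 60)
#' copy_numbers(c(1L, 2L, -2L), d)
copy_numbers <- function(genotype, design) {
  genotype <- check_genotype(genotype, design)
  counts <- tabulate(abs(genotype), nbins = nrow(design$segments))
  setNames(as.integer(counts), design$segments$name)
}

#' @rdname copy_numbers
#' @export
tu_count <- function(genotype, design) {
  counts <- copy_numbers(genotype, design)
  sum(counts[design$segments$role == "gene_cassette"])
}

#' Render the amplicon sequence of a genotype
#'
#' Emits `left_flank . lox . (segment . lox)* . right_flank`, with
#' negatively oriented elements rendered as the reverse complement of the
#' whole segment. The empty genotype renders as
#' `left_flank . lox . right_flank`.
#'
#' @param design A `module_design`.
#' @param genotype Signed integer vector.
#' @return Character scalar DNA sequence.
#' @export
render_sequence <- function(design, genotype) {
  genotype <- check_genotype(genotype, design)
  lox <- design$lox_sequence
  if (length(genotype) == 0L)
    return(paste0(design$left_flank, lox, design$right_flank))
  oriented <- ifelse(genotype > 0L,
                     design$segments$sequence[abs(genotype)],
                     design$segments$rc_sequence[abs(genotype)])
  paste0(design$left_flank, lox,
         paste0(oriented, lox, collapse = ""),
         design$right_flank)
}

#' Amplicon length of a genotype without rendering it
#'
#' `|left_flank| + |right_flank| + (k + 1) * |lox| + sum of segment
#' lengths` for a genotype retaining `k` elements.
#'
#' @inheritParams render_sequence
#' @return Integer length in bp.
#' @export
amplicon_length <- function(design, genotype) {
  genotype <- check_genotype(genotype, design)
  k <- length(genotype)
  nchar(design$left_flank) + nchar(design$right_flank) +
    (k + 1L) * nchar(design$lox_sequence) +
    sum(design$segments$length[abs(genotype)])
}
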
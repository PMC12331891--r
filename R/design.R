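#' Build a loxPsym-segmented module design
#'
#' A module design is the reference description of a synthetic construct in
#' which `n` segments (gene cassettes, in reference order and `+`
#' orientation) alternate with `n + 1` loxPsym sites, flanked on either
#' side by fixed sequence carrying the forward/reverse PCR primer anchors:
#'
#' ```
#' left_flank . lox . seg1 . lox . seg2 ... segN . lox . right_flank
#' ```
#'
#' @param layout Data frame describing segments in reference order, with
#'   columns `order`, `segment_id`, `name` and `role`
#'   (`"gene_cassette"` or `"marker"`). `segment_id` must be the integers
#'   `1..n` (in `order`).
#' @param sequences Named character vector of segment sequences (names
#'   matching `layout$name`). If `NULL`, random sequences of length
#'   `segment_length` are generated deterministically from `seed`.
#' @param segment_length Integer length (bp) used when generating segment
#'   sequences; recycled across segments.
#' @param lox_sequence The recombination site sequence; defaults to the
#'   canonical 34 bp [LOXPSYM].
#' @param left_flank,right_flank Flanking sequences containing the primer
#'   anchors. Generated randomly (length `flank_length`) when `NULL`.
#' @param left_anchor,right_anchor Primer-anchor subsequences used for
#'   full-length read detection. Default to the outermost `anchor_length`
#'   bases of the corresponding flank.
#' @param anchor_length,flank_length Integer lengths (bp) for generated
#'   anchors/flanks. Anchors must be 15-64 bp.
#' @param landing_pad_length Length (bp) of the unique landing pad left at
#'   each deleted native locus; default 23.
#' @param marker_inside_lox_array Logical; whether a `marker` segment sits
#'   inside the lox array (default `FALSE`; markers are excluded from
#'   transcription-unit counts either way).
#' @param seed Integer seed controlling generated sequence content.
#' @return An object of class `module_design`.
#' @export
#' @examples
#' d <- build_reference(data.frame(order = 1, segment_id = 1,
#'                                 name = "GENE1", role = "gene_cassette"),
#'                      segment_length = 200, flank_length = 60)
#' nchar(render_sequence(d, parental_genotype(d)))
build_reference <- function(layout, sequences = NULL, segment_length = 2700L,
                            lox_sequence = LOXPSYM,
                            left_flank = NULL, right_flank = NULL,
                            left_anchor = NULL, right_anchor = NULL,
                            anchor_length = 30L, flank_length = 300L,
                            landing_pad_length = 23L,
                            marker_inside_lox_array = FALSE, seed = 1L) {
  stopifnot(is.data.frame(layout),
            all(c("order", "segment_id", "name", "role") %in% names(layout)))
  layout <- layout[order(layout$order), , drop = FALSE]
  n <- nrow(layout)
  if (n < 1L) stop("layout must describe at least one segment")
  if (anyDuplicated(layout$name))
    stop("duplicate segment names in layout: ",
         paste(unique(layout$name[duplicated(layout$name)]), collapse = ", "))
  if (!identical(as.integer(layout$segment_id), seq_len(n)))
    stop("segment_id must be consecutive integers 1..n in layout order")
  if (!all(layout$role %in% c("gene_cassette", "marker")))
    stop("role must be 'gene_cassette' or 'marker'")

  segment_length <- rep_len(as.integer(segment_length), n)
  if (is.null(sequences)) {
    sequences <- with_seed(stage_seed(seed, "segments"), {
      vapply(segment_length, random_dna, character(1))
    })
    names(sequences) <- layout$name
  }
  if (!all(layout$name %in% names(sequences)))
    stop("missing sequences for segments: ",
         paste(setdiff(layout$name, names(sequences)), collapse = ", "))
  sequences <- toupper(unname(sequences[layout$name]))
  if (any(!nzchar(sequences))) stop("segment sequences must be non-empty")
  if (any(grepl("[^ACGT]", sequences)))
    stop("segment sequences must be over the alphabet {A,C,G,T}")

  if (is.null(left_flank) || is.null(right_flank)) {
    fl <- with_seed(stage_seed(seed, "flanks"), {
      c(random_dna(flank_length), random_dna(flank_length))
    })
    left_flank <- left_flank %||% fl[1]
    right_flank <- right_flank %||% fl[2]
  }
  left_flank <- toupper(left_flank)
  right_flank <- toupper(right_flank)
  lox_sequence <- toupper(lox_sequence)
  left_anchor <- toupper(left_anchor %||% substr(left_flank, 1L, anchor_length))
  right_anchor <- toupper(right_anchor %||%
    substr(right_flank, nchar(right_flank) - anchor_length + 1L,
           nchar(right_flank)))
  if (nchar(left_anchor) < 15L || nchar(right_anchor) < 15L)
    stop("primer anchors must be at least 15 bp")
  if (nchar(left_anchor) > 64L || nchar(right_anchor) > 64L)
    stop("primer anchors longer than 64 bp are not supported")

  if (any(grepl(lox_sequence, sequences, fixed = TRUE)))
    stop("a segment sequence contains the lox site sequence")
  for (fl in c(left_flank, right_flank))
    if (grepl(lox_sequence, fl, fixed = TRUE))
      stop("a flank sequence contains the lox site sequence")

  segments <- data.frame(
    segment_id = seq_len(n),
    name = as.character(layout$name),
    role = as.character(layout$role),
    sequence = sequences,
    length = nchar(sequences),
    stringsAsFactors = FALSE
  )
  segments$rc_sequence <- revcomp(segments$sequence)

  design <- structure(
    list(segments = segments,
         lox_sequence = lox_sequence,
         left_flank = left_flank,
         right_flank = right_flank,
         left_anchor = left_anchor,
         right_anchor = right_anchor,
         landing_pad_length = as.integer(landing_pad_length),
         marker_inside_lox_array = isTRUE(marker_inside_lox_array)),
    class = "module_design"
  )
  validate_design(design)
  design
}

validate_design <- function(design) {
  stopifnot(inherits(design, "module_design"))
  ref <- render_sequence(design, parental_genotype(design))
  n_lox <- lengths(regmatches(ref, gregexpr(design$lox_sequence, ref, fixed = TRUE)))
  if (n_lox != nrow(design$segments) + 1L)
    stop("rendered reference must contain exactly segment count + 1 lox sites")
  for (a in c(design$left_anchor, design$right_anchor)) {
    hits <- gregexpr(a, ref, fixed = TRUE)[[1]]
    if (length(hits) != 1L || hits[1] == -1L)
      stop("primer anchor must occur exactly once in the rendered reference")
  }
  invisible(design)
}

#' @export
print.module_design <- function(x, ...) {
  cat("module_design:", nrow(x$segments), "segments,",
      nrow(x$segments) + 1L, "lox sites\n")
  cat("  lox site:", nchar(x$lox_sequence), "bp; flanks:",
      nchar(x$left_flank), "/", nchar(x$right_flank), "bp; anchors:",
      nchar(x$left_anchor), "/", nchar(x$right_anchor), "bp\n")
  cat("  parental amplicon:",
      fmt_int(amplicon_length(x, parental_genotype(x))), "bp\n")
  print(x$segments[, c("segment_id", "name", "role", "length")], row.names = FALSE)
  invisible(x)
}

#' Default seven-gene histidine module design
#'
#' The reference construct emulated throughout the package: seven HIS gene
#' cassettes (`HIS1`..`HIS7`) joined by eight loxPsym-bearing linkers and
#' integrated as a single ~20 kb module, amplified by primers anchored in
#' the flanks. Segment content is random DNA generated deterministically
#' from `seed`; only the layout, lengths and loxPsym chemistry matter for
#' the analyses the package performs.
#'
#' @param segment_length Length of each gene cassette (default 2,700 bp,
#'   giving a ~20 kb parental amplicon).
#' @param flank_length,anchor_length Flank and primer-anchor lengths (bp).
#' @param seed Integer seed fixing the generated sequence content.
#' @return A `module_design` with 7 gene-cassette segments.
#' @export
#' @examples
#' d <- default_his_design(segment_length = 300, flank_length = 60)
#' tu_count(parental_genotype(d), d)
default_his_design <- function(segment_length = 2700L, flank_length = 300L,
                               anchor_length = 30L, seed = 20201L) {
  layout <- data.frame(order = 1:7, segment_id = 1:7,
                       name = paste0("HIS", 1:7),
                       role = "gene_cassette")
  build_reference(layout, segment_length = segment_length,
                  flank_length = flank_length, anchor_length = anchor_length,
                  seed = seed)
}

#' Write / read a module design as FASTA + TSV layout + YAML config
#'
#' `write_design()` stores segment sequences as FASTA, the layout as a TSV
#' (columns `order`, `segment_id`, `name`, `role`) and the lox site,
#' flanks, anchors and scalar options as a YAML key-value file.
#' `read_design()` reverses this.
#'
#' @param design A `module_design`.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return `write_design()` returns the three file paths invisibly;
#'   `read_design()` returns a `module_design`.
#' @export
write_design <- function(design, dir, prefix = "design") {
  stopifnot(inherits(design, "module_design"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(prefix, "_segments.fasta"))
  tsv <- file.path(dir, paste0(prefix, "_layout.tsv"))
  cfg <- file.path(dir, paste0(prefix, "_config.yaml"))
  seqs <- Biostrings::DNAStringSet(design$segments$sequence)
  names(seqs) <- design$segments$name
  Biostrings::writeXStringSet(seqs, fa)
  write.table(design$segments[, c("segment_id", "name", "role")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  yaml::write_yaml(list(
    lox_sequence = design$lox_sequence,
    left_flank = design$left_flank,
    right_flank = design$right_flank,
    left_anchor = design$left_anchor,
    right_anchor = design$right_anchor,
    landing_pad_length = design$landing_pad_length,
    marker_inside_lox_array = design$marker_inside_lox_array
  ), cfg)
  invisible(c(fasta = fa, layout = tsv, config = cfg))
}

#' @rdname write_design
#' @param fasta,layout,config Paths written by `write_design()`.
#' @export
read_design <- function(fasta, layout, config) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  lt <- read.delim(layout, stringsAsFactors = FALSE)
  lt$order <- seq_len(nrow(lt))
  cfg <- yaml::read_yaml(config)
  build_reference(lt, sequences = setNames(as.character(seqs), names(seqs)),
                  lox_sequence = cfg$lox_sequence,
                  left_flank = cfg$left_flank, right_flank = cfg$right_flank,
                  left_anchor = cfg$left_anchor,
                  right_anchor = cfg$right_anchor,
                  landing_pad_length = cfg$landing_pad_length,
                  marker_inside_lox_array = isTRUE(cfg$marker_inside_lox_array))
}
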
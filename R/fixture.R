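#' Gene/UTR annotation of the rendered module reference
#'
#' Builds a [GenomicRanges::GRanges] annotating each gene-cassette
#' segment of the parental rendering with a `gene` feature spanning the
#' segment and a `three_prime_UTR` feature covering its last
#' `utr_length` bases, optionally extended `utr_readthrough` bases past
#' the segment end into the downstream lox linker (terminator
#' read-through; this is what makes a lox-boundary event able to disrupt
#' a UTR).
#'
#' @param design A `module_design`.
#' @param utr_length 3' UTR length (bp) inside the segment.
#' @param utr_readthrough Extension (bp) past the segment end.
#' @param offset Coordinate offset (bp) added to every feature (e.g. an
#'   upstream genomic arm).
#' @param seqname Contig name for the features.
#' @return A `GRanges` with `type`, `Name` and `Parent` metadata columns,
#'   1-based inclusive coordinates as in GFF3.
#' @export
module_annotation <- function(design, utr_length = 200L,
                              utr_readthrough = 0L, offset = 0L,
                              seqname = "module") {
  segs <- design$segments
  lox_len <- nchar(design$lox_sequence)
  pos <- nchar(design$left_flank) + offset
  rows <- list()
  for (k in seq_len(nrow(segs))) {
    seg_start <- pos + lox_len + 1L
    seg_end <- seg_start + segs$length[k] - 1L
    pos <- seg_end
    if (segs$role[k] != "gene_cassette") next
    utr_len_k <- min(utr_length, segs$length[k])
    rows[[length(rows) + 1L]] <- data.frame(
      start = seg_start, end = seg_end, type = "gene",
      Name = segs$name[k], Parent = NA_character_)
    rows[[length(rows) + 1L]] <- data.frame(
      start = seg_end - utr_len_k + 1L,
      end = seg_end + min(utr_readthrough, lox_len), type = "three_prime_UTR",
      Name = paste0(segs$name[k], "_3UTR"), Parent = segs$name[k])
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(seqname,
                               IRanges::IRanges(df$start, df$end),
                               strand = "+")
  gr$type <- df$type
  gr$Name <- df$Name
  gr$Parent <- df$Parent
  gr
}

#' Build a toy host-genome fixture (FASTA + GFF3)
#'
#' Constructs a small multi-contig genome emulating the host of a
#' relocated gene module: (1) `module_locus` — the rendered parental
#' module embedded between two genomic arms; (2) `native_loci` — one
#' region per gene cassette where the native gene has been deleted and
#' replaced by a unique landing pad of `design$landing_pad_length` bp
#' (default 23); (3) `filler_contig` — `n_filler_genes` unrelated genes.
#' The GFF3 annotation covers module genes/UTRs, landing pads and filler
#' genes, consistent with the FASTA coordinates.
#'
#' @param design A `module_design`.
#' @param n_filler_genes Number of unrelated filler genes (>= 0).
#' @param seed Integer seed (changes sequence content, not structure).
#' @param arm_length Length (bp) of the genomic arms around the module.
#' @param utr_readthrough Passed to [module_annotation()].
#' @param out_dir If non-`NULL`, write `genome.fasta` and `genome.gff3`
#'   there.
#' @return A list with `fasta` (named `DNAStringSet`), `gff` (`GRanges`)
#'   and, when written, `paths`.
#' @export
make_genome_fixture <- function(design, n_filler_genes = 3L, seed = 1L,
                                arm_length = 500L, utr_readthrough = 0L,
                                out_dir = NULL) {
  stopifnot(n_filler_genes >= 0L)
  lp_len <- design$landing_pad_length
  genes <- design$segments[design$segments$role == "gene_cassette", ]
  with_seed(stage_seed(seed, "genome_fixture"), {
    arms <- c(random_dna(arm_length), random_dna(arm_length))
    module_seq <- paste0(arms[1],
                         render_sequence(design, parental_genotype(design)),
                         arms[2])
    # native loci: spacer + landing pad per deleted gene
    spacer_len <- 400L
    native_parts <- character(0)
    lp_rows <- list()
    pos <- 0L
    for (k in seq_len(nrow(genes))) {
      sp <- random_dna(spacer_len)
      lp <- random_dna(lp_len)
      native_parts <- c(native_parts, sp, lp)
      lp_rows[[k]] <- data.frame(start = pos + spacer_len + 1L,
                                 end = pos + spacer_len + lp_len,
                                 Name = paste0(genes$name[k], "_landing_pad"))
      pos <- pos + spacer_len + lp_len
    }
    native_seq <- paste0(paste(native_parts, collapse = ""), random_dna(200L))
    # filler genes
    filler_len <- 600L
    filler_gap <- 150L
    filler_rows <- list()
    filler_parts <- character(0)
    pos <- 0L
    for (k in seq_len(n_filler_genes)) {
      filler_parts <- c(filler_parts, random_dna(filler_gap),
                        random_dna(filler_len))
      filler_rows[[k]] <- data.frame(start = pos + filler_gap + 1L,
                                     end = pos + filler_gap + filler_len,
                                     Name = sprintf("FIL%d", k))
      pos <- pos + filler_gap + filler_len
    }
    filler_seq <- if (n_filler_genes > 0L)
      paste0(paste(filler_parts, collapse = ""), random_dna(filler_gap))
    else random_dna(2L * filler_gap)

    fasta <- Biostrings::DNAStringSet(c(
      module_locus = module_seq,
      native_loci = native_seq,
      filler_contig = filler_seq))

    mod_gr <- module_annotation(design, utr_readthrough = utr_readthrough,
                                offset = arm_length, seqname = "module_locus")
    lp_df <- do.call(rbind, lp_rows)
    lp_gr <- GenomicRanges::GRanges("native_loci",
                                    IRanges::IRanges(lp_df$start, lp_df$end),
                                    strand = "+")
    lp_gr$type <- "landing_pad"
    lp_gr$Name <- lp_df$Name
    lp_gr$Parent <- NA_character_
    gff <- suppressWarnings(c(mod_gr, lp_gr))
    if (n_filler_genes > 0L) {
      fl_df <- do.call(rbind, filler_rows)
      fl_gr <- GenomicRanges::GRanges("filler_contig",
                                      IRanges::IRanges(fl_df$start, fl_df$end),
                                      strand = "+")
      fl_gr$type <- "gene"
      fl_gr$Name <- fl_df$Name
      fl_gr$Parent <- NA_character_
      gff <- suppressWarnings(c(gff, fl_gr))
    }
    out <- list(fasta = fasta, gff = gff)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      fa_path <- file.path(out_dir, "genome.fasta")
      gff_path <- file.path(out_dir, "genome.gff3")
      Biostrings::writeXStringSet(fasta, fa_path)
      rtracklayer::export(gff, gff_path, format = "gff3")
      out$paths <- c(fasta = fa_path, gff = gff_path)
    }
    out
  })
}
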
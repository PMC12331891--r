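#' Nanopore-like read error model
#'
#' Independent per-base substitution, insertion and deletion
#' probabilities, an optional whole-read truncation probability (uniform
#' breakpoint; the tail is lost), and a constant placeholder base quality.
#' Defaults follow a generic R9-era nanopore profile; the genotype caller
#' never uses quality values.
#'
#' @param sub_rate,ins_rate,del_rate Per-base probabilities, each in
#'   `[0, 0.25]`.
#' @param p_truncate Probability that a read is truncated.
#' @param quality Constant Phred quality written to FASTQ.
#' @param seed Optional integer seed.
#' @return A list of class `error_model`.
#' @export
error_model <- function(sub_rate = 0.03, ins_rate = 0.02, del_rate = 0.04,
                        p_truncate = 0.02, quality = 12L, seed = NULL) {
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(!is.finite(rates)) || any(rates < 0) || any(rates > 0.25))
    stop("error rates must lie in [0, 0.25]")
  if (p_truncate < 0 || p_truncate > 1) stop("p_truncate must lie in [0, 1]")
  structure(list(sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, p_truncate = p_truncate,
                 quality = as.integer(quality), seed = seed),
            class = "error_model")
}

#' Sample amplicon molecules from a pool (PCR step)
#'
#' Multinomial draw of `n_molecules` genotype keys with weights
#' `abundance * exp(-beta * amplicon_length / 1000)`. `length_bias_beta =
#' 0` (the default) disables length bias, so empirical frequencies
#' converge to pool frequencies; positive values enrich shorter
#' amplicons, emulating PCR bias against long templates.
#'
#' @param pool A `scramble_pool`.
#' @param design A `module_design`.
#' @param n_molecules Number of molecules to draw (>= 1).
#' @param length_bias_beta Length-bias strength (per kb).
#' @param seed Integer seed.
#' @return Character vector of `n_molecules` genotype keys (a multiset).
#' @export
pcr_sample <- function(pool, design, n_molecules, length_bias_beta = 0,
                       seed = NULL) {
  stopifnot(is.data.frame(pool), n_molecules >= 1)
  if (nrow(pool) == 0L) stop("empty pool")
  if (is.null(seed)) stop("a seed is required")
  lens <- vapply(pool$key, function(k) amplicon_length(design, parse_key(k)),
                 numeric(1))
  w <- pool$abundance * exp(-length_bias_beta * lens / 1000)
  with_seed(stage_seed(seed, "pcr"), {
    sample(pool$key, n_molecules, replace = TRUE, prob = w)
  })
}

apply_read_errors <- function(seq_chars, em) {
  n <- length(seq_chars)
  bases <- c("A", "C", "G", "T")
  out <- seq_chars
  # substitutions: replace with one of the three other bases
  sub_idx <- which(runif(n) < em$sub_rate)
  if (length(sub_idx)) {
    shift <- sample.int(3L, length(sub_idx), replace = TRUE)
    cur <- match(out[sub_idx], bases)
    out[sub_idx] <- bases[((cur - 1L + shift) %% 4L) + 1L]
  }
  # deletions
  keep <- runif(length(out)) >= em$del_rate
  out <- out[keep]
  # insertions: a random base after the affected position
  if (length(out)) {
    ins_idx <- which(runif(length(out)) < em$ins_rate)
    if (length(ins_idx)) {
      times <- rep(1L, length(out))
      times[ins_idx] <- 2L
      expanded <- rep(seq_along(out), times)
      res <- out[expanded]
      dup_pos <- cumsum(times)[ins_idx]  # position of the inserted copy
      res[dup_pos] <- sample(bases, length(ins_idx), replace = TRUE)
      out <- res
    }
  }
  out
}

#' Synthesize long reads from genotype molecules
#'
#' Renders each molecule's amplicon with [render_sequence()], picks a
#' sequencing strand uniformly, applies the per-base error model and
#' optional truncation, and attaches a constant-quality string. Read ids
#' encode the ground-truth genotype key (`truth=`) purely as a test
#' affordance; the genotype caller never reads it. Deterministic given
#' `seed`.
#'
#' @param keys Character vector of genotype keys (one read per entry),
#'   e.g. from [pcr_sample()].
#' @param design A `module_design`.
#' @param em An [error_model()].
#' @param seed Integer seed.
#' @return A `scramble_reads` object: list with `id`, `sequence`,
#'   `quality`, `truth`, `strand`.
#' @export
synthesize_reads <- function(keys, design, em = error_model(), seed = NULL) {
  stopifnot(inherits(em, "error_model"), is.character(keys))
  seed <- seed %||% em$seed
  if (is.null(seed)) stop("a seed is required (in the error model or as argument)")
  uniq <- unique(keys)
  rendered <- vapply(uniq, function(k) render_sequence(design, parse_key(k)),
                     character(1))
  rendered_rc <- revcomp(rendered)
  key_idx <- match(keys, uniq)  # index, not name: the empty key "" is legal
  with_seed(stage_seed(seed, "reads"), {
    n <- length(keys)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    seqs <- character(n)
    for (i in seq_len(n)) {
      tmpl <- if (strands[i] == "+") rendered[[key_idx[i]]] else rendered_rc[[key_idx[i]]]
      chars <- strsplit(tmpl, "", fixed = TRUE)[[1]]
      chars <- apply_read_errors(chars, em)
      if (length(chars) > 1L && runif(1) < em$p_truncate) {
        cut <- sample.int(length(chars) - 1L, 1L)
        chars <- chars[seq_len(cut)]
      }
      seqs[i] <- paste(chars, collapse = "")
    }
    ids <- sprintf("sr%06d;strand=%s;truth=%s", seq_len(n), strands, keys)
    structure(list(id = ids, sequence = seqs,
                   quality = strrep(rawToChar(as.raw(em$quality + 33L)),
                                    nchar(seqs)),
                   truth = keys, strand = strands),
              class = "scramble_reads")
    })
}

#' @export
print.scramble_reads <- function(x, ...) {
  cat("scramble_reads:", length(x$id), "reads, mean length",
      round(mean(nchar(x$sequence))), "bp\n")
  invisible(x)
}

#' @export
length.scramble_reads <- function(x) length(x$id)

#' Subset reads
#' @param x A `scramble_reads` object.
#' @param i Index vector.
#' @param ... Ignored.
#' @export
`[.scramble_reads` <- function(x, i, ...) {
  structure(lapply(unclass(x), `[`, i), class = "scramble_reads")
}

#' Coerce to a `scramble_reads` object
#'
#' Accepts a `scramble_reads`, a named [Biostrings::DNAStringSet] or a
#' named character vector of sequences.
#'
#' @param x Object to coerce.
#' @return A `scramble_reads` object (with placeholder qualities).
#' @export
as_reads <- function(x) {
  if (inherits(x, "scramble_reads")) return(x)
  if (methods::is(x, "DNAStringSet")) {
    ids <- names(x) %||% sprintf("read%06d", seq_along(x))
    x <- setNames(as.character(x), ids)
  }
  if (is.character(x)) {
    ids <- names(x) %||% sprintf("read%06d", seq_along(x))
    truth <- rep(NA_character_, length(x))
    m <- regmatches(ids, regexpr("truth=[^;[:space:]]*", ids))
    has <- grepl("truth=", ids, fixed = TRUE)
    truth[has] <- sub("^truth=", "", m)
    return(structure(list(id = unname(ids), sequence = unname(x),
                          quality = strrep("I", nchar(x)),
                          truth = truth,
                          strand = rep(NA_character_, length(x))),
                     class = "scramble_reads"))
  }
  stop("cannot coerce object of class ", paste(class(x), collapse = "/"),
       " to scramble_reads")
}

#' Ground-truth genotype keys encoded in read ids
#'
#' Test affordance: parses the `truth=` tag that [synthesize_reads()]
#' writes into read ids. Analysis code must never rely on it.
#'
#' @param reads A `scramble_reads` object.
#' @return Character vector of keys (`NA` where absent).
#' @export
reads_truth <- function(reads) as_reads(reads)$truth

#' Write / read FASTQ
#'
#' FASTQ I/O through [Biostrings::writeXStringSet()] /
#' [Biostrings::readDNAStringSet()]. Gzipped paths (`.gz`) are handled
#' transparently. Qualities are placeholders and are not preserved on
#' read-in.
#'
#' @param reads A `scramble_reads` object.
#' @param path Output path (`.fastq` or `.fastq.gz`).
#' @export
write_fastq <- function(reads, path) {
  reads <- as_reads(reads)
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  as_reads(x)
}
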
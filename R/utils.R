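`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] that
#' works on plain character vectors.
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGT")
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

#' Derive a stage-specific seed from a global seed
#'
#' A single run-level seed fans out to independent per-stage streams keyed
#' by stage name, so adding or reordering pipeline stages never perturbs
#' the draws of another stage.
#'
#' @param seed Integer global seed.
#' @param stage Character scalar naming the stage (e.g. `"induction"`).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  cp <- utf8ToInt(stage)
  h <- sum(cp * seq_along(cp)) %% 65521
  as.integer((abs(as.double(seed)) * 48271 + h * 9973 + 12345) %% 2147483647)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Deterministic text form of a number for messages.
fmt_int <- function(x) format(x, big.mark = ",", scientific = FALSE)
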
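#' Canonical loxPsym site sequence
#'
#' The 34 bp palindromic Cre recombination site used between segments of a
#' synthetic module: two 13 bp recombinase-binding arms around the
#' palindromic 8 bp spacer `ATGTACAT`. Because the spacer is symmetric,
#' recombination between two loxPsym sites can resolve in either relative
#' orientation, which is what makes deletions, inversions and duplications
#' all accessible from the same substrate.
#'
#' @format A length-one character vector of 34 bases, equal to its own
#'   reverse complement.
#' @export
LOXPSYM <- "ATAACTTCGTATAATGTACATTATACGAAGTTAT"

stopifnot(nchar(LOXPSYM) == 34L)

# Event types a pair of loxPsym sites can resolve to.
EVENT_TYPES <- c("deletion", "inversion", "duplication")
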
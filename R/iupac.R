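#' IUPAC nucleotide ambiguity codes
#'
#' Named list mapping each IUPAC nucleotide code to the set of concrete
#' bases it allows.
#' @keywords internal
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

# complement of every IUPAC code, used by revcomp()
IUPAC_FROM <- "ACGTRYSWKMBDHVN"
IUPAC_TO   <- "TGCAYRSWMKVHDBN"

#' Reverse-complement a nucleotide string (IUPAC-aware)
#'
#' @param x character vector of nucleotide strings (IUPAC codes allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr(paste0(IUPAC_FROM, tolower(IUPAC_FROM)),
                 paste0(IUPAC_TO, tolower(IUPAC_TO)), x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

check_iupac <- function(seq, what = "sequence") {
  ch <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!ch %in% names(IUPAC_SETS))
  if (length(bad) > 0)
    stop(sprintf("illegal IUPAC character '%s' in %s at position %d",
                 ch[bad[1]], what, bad[1]), call. = FALSE)
  ch
}

#' Degeneracy of an IUPAC-encoded oligonucleotide
#'
#' Product over positions of the number of concrete bases each code allows.
#'
#' @param seq IUPAC nucleotide string.
#' @return integer degeneracy (>= 1).
#' @export
degeneracy <- function(seq) {
  ch <- check_iupac(seq)
  prod(vapply(IUPAC_SETS[ch], length, 1L))
}

#' Expand a degenerate IUPAC sequence into all concrete sequences
#'
#' @param seq IUPAC nucleotide string.
#' @return character vector of length `degeneracy(seq)`; every element
#'   matches `seq` position-wise.
#' @export
#' @examples
#' expand_degenerate("ARC")  # "AAC" "AGC"
expand_degenerate <- function(seq) {
  ch <- check_iupac(seq)
  grid <- expand.grid(IUPAC_SETS[ch], stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  do.call(paste0, grid)
}
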
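#' @importFrom Biostrings pairwiseAlignment AAString alignedPattern
#'   alignedSubject pid nucleotideSubstitutionMatrix
NULL

.sqamp_cache <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.sqamp_cache$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .sqamp_cache$B62 <- e$BLOSUM62
  }
  .sqamp_cache$B62
}

#' Default protein aligner configuration
#'
#' Local alignment with affine gaps (open 11, extend 1) and a BLOSUM62
#' matrix, mirroring standard BLASTp settings.
#' @param gap_open,gap_extend positive gap penalties.
#' @param type Biostrings alignment type.
#' @return list used by the verification and taxonomy stages.
#' @export
aligner_config <- function(gap_open = 11, gap_extend = 1, type = "local") {
  list(gap_open = gap_open, gap_extend = gap_extend, type = type)
}

# scores of one peptide against many reference proteins (local, BLOSUM62)
aa_scores <- function(peptide, refs, cfg = aligner_config()) {
  pairwiseAlignment(Biostrings::AAStringSet(refs), AAString(peptide),
                    type = cfg$type, substitutionMatrix = blosum62(),
                    gapOpening = cfg$gap_open, gapExtension = cfg$gap_extend,
                    scoreOnly = TRUE)
}

# full best-hit alignment details: identity over the aligned span, score
# normalized by query length (so short spurious local alignments cannot
# pass), internal stops within the span
aa_best_hit <- function(peptide, refs, cfg = aligner_config()) {
  sc <- aa_scores(peptide, refs, cfg)
  best <- which.max(sc)
  aln <- pairwiseAlignment(AAString(refs[[best]]), AAString(peptide),
                           type = cfg$type, substitutionMatrix = blosum62(),
                           gapOpening = cfg$gap_open, gapExtension = cfg$gap_extend)
  qal <- as.character(alignedSubject(aln))
  list(ref_id = names(refs)[best],
       score = sc[best],
       identity = pid(aln, type = "PID1") / 100,
       norm_score = sc[best] / nchar(peptide),
       span_stops = lengths(regmatches(qal, gregexpr("\\*", qal))),
       columns = nchar(qal))
}

#' Pairwise nucleotide identity (global, terminal gaps excluded)
#'
#' Needleman-Wunsch with affine gaps; identity is matches divided by
#' alignment columns, excluding columns that fall in a terminal gap run of
#' either sequence. Symmetric in its arguments.
#'
#' @param a,b nucleotide strings.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return identity fraction in \[0, 1\].
#' @export
pairwise_identity <- function(a, b, match = 5, mismatch = -4,
                              gap_open = 10, gap_extend = 1) {
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  sub <- nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                      baseOnly = FALSE)
  aln <- pairwiseAlignment(DNAString(a), DNAString(b), type = "global",
                           substitutionMatrix = sub,
                           gapOpening = gap_open, gapExtension = gap_extend)
  p <- strsplit(as.character(alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(alignedSubject(aln)), "")[[1]]
  first <- max(min(which(p != "-")), min(which(s != "-")))
  last <- min(max(which(p != "-")), max(which(s != "-")))
  idx <- first:last
  sum(p[idx] == s[idx]) / length(idx)
}

#' Align a query peptide into reference alignment columns
#'
#' Glocal affine-gap dynamic programming of the peptide against the
#' position-specific profile of the reference alignment (column score =
#' frequency-weighted BLOSUM62 average). Reference columns skipped before
#' and after the aligned region are free; query residues that insert
#' relative to the reference are aligned to no column and discarded from
#' the output row, which therefore has exactly the reference column count.
#'
#' @param peptide amino-acid string.
#' @param resource a `reference_resource` (its `alignment` is the profile).
#' @param gap_open,gap_extend positive affine gap penalties (BLOSUM62 scale).
#' @param min_coverage minimum fraction of query residues that must be
#'   aligned to columns; below it the query is flagged unplaceable.
#' @return list with `row` (gapped string in reference column space),
#'   `score`, `matched_fraction`.
#' @export
align_query <- function(peptide, resource, gap_open = 11, gap_extend = 1,
                        min_coverage = 0.5) {
  aln <- resource$alignment
  m <- nchar(aln[[1]])
  B <- blosum62()
  rows <- do.call(rbind, strsplit(toupper(aln), ""))
  letters20 <- AA20
  # column residue frequencies over the 20 standard amino acids
  F <- vapply(seq_len(m), function(j) {
    col <- rows[, j]
    col <- col[col %in% letters20]
    if (length(col) == 0) return(numeric(20))
    tabulate(match(col, letters20), 20) / length(col)
  }, numeric(20))
  q <- strsplit(toupper(peptide), "")[[1]]
  qkey <- ifelse(q %in% rownames(B), q, "X")
  prof <- B[qkey, letters20, drop = FALSE] %*% F       # n x m
  n <- length(q)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  X[1, ] <- 0                                  # free leading deletions
  Y[, 1] <- -(gap_open + (seq_len(n + 1) - 2) * gap_extend)
  Y[1, 1] <- NEG
  for (i in seq_len(n)) {
    prev <- pmax(M[i, 1:m], X[i, 1:m], Y[i, 1:m])
    M[i + 1, 2:(m + 1)] <- prof[i, ] + prev
    Y[i + 1, ] <- pmax(M[i, ] - gap_open, Y[i, ] - gap_extend)
    ck <- cummax(M[i + 1, 1:m] + gap_extend * (1:m))
    X[i + 1, 2:(m + 1)] <- ck - gap_open - gap_extend * (1:m)
  }
  endvals <- pmax(M[n + 1, ], Y[n + 1, ])
  jj <- which.max(endvals)
  score <- endvals[jj]
  state <- if (M[n + 1, jj] >= Y[n + 1, jj]) "M" else "Y"
  col_of <- rep(NA_integer_, n)
  i <- n
  tol <- 1e-9
  while (i > 0) {
    if (state == "M") {
      col_of[i] <- jj - 1L
      target <- M[i + 1, jj] - prof[i, jj - 1]
      cands <- c(M = M[i, jj - 1], X = X[i, jj - 1], Y = Y[i, jj - 1])
      state <- names(cands)[which(abs(cands - target) < tol)][1]
      i <- i - 1L; jj <- jj - 1L
    } else if (state == "Y") {
      target <- Y[i + 1, jj]
      state <- if (abs(M[i, jj] - gap_open - target) < tol) "M" else "Y"
      i <- i - 1L
    } else { # X: deletion run within current row, chain back to M
      target <- X[i + 1, jj]
      state <- if (abs(M[i + 1, jj - 1] - gap_open - target) < tol) "M" else "X"
      jj <- jj - 1L
    }
    if (state == "X" && i == 0) break
  }
  matched <- mean(!is.na(col_of))
  if (matched < min_coverage)
    stop(structure(list(message = sprintf(
      "query aligns to only %.0f%% of its residues (minimum %.0f%%)",
      100 * matched, 100 * min_coverage), call = NULL),
      class = c("sqamp_unplaceable", "error", "condition")))
  row <- rep("-", m)
  ok <- !is.na(col_of)
  row[col_of[ok]] <- q[ok]
  list(row = paste(row, collapse = ""), score = score,
       matched_fraction = matched)
}
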
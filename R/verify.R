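#' Six-frame translation of an amplicon
#'
#' Translates all three frames on both strands with the bacterial genetic
#' code (NCBI table 11). Start-codon handling is disabled (amplicons are
#' gene-internal), stops are rendered `*`, codons containing `N` become
#' `X`, and trailing partial codons are dropped.
#'
#' @param nt_seq nucleotide string over ACGTN, length >= 3.
#' @return data.frame with columns `strand` (`+`/`-`), `frame` (0-2) and
#'   `peptide`.
#' @export
six_frame_translate <- function(nt_seq) {
  nt_seq <- toupper(nt_seq)
  if (!grepl("^[ACGTN]+$", nt_seq))
    stop("amplicon sequence must be over ACGTN", call. = FALSE)
  if (nchar(nt_seq) < 3) stop("sequence shorter than one codon", call. = FALSE)
  strands <- c("+" = nt_seq, "-" = revcomp(nt_seq))
  out <- expand.grid(strand = c("+", "-"), frame = 0:2,
                     stringsAsFactors = FALSE)
  out$peptide <- vapply(seq_len(nrow(out)), function(k) {
    s <- substring(strands[[out$strand[k]]], out$frame[k] + 1L)
    len <- 3L * (nchar(s) %/% 3L)
    if (len == 0L) return("")
    suppressWarnings(as.character(
      translate(DNAString(substr(s, 1L, len)), genetic.code = GENETIC_CODE_11,
                no.init.codon = TRUE, if.fuzzy.codon = "solve")))
  }, "")
  out[order(out$strand == "-", out$frame), c("strand", "frame", "peptide")]
}

internal_stop_count <- function(peptide) {
  if (nchar(peptide) <= 1) return(0L)
  sum(strsplit(substr(peptide, 1, nchar(peptide) - 1L), "")[[1]] == "*")
}

#' Choose the reading frame of an ASV by reference homology
#'
#' Each of the six translations is locally aligned (affine gaps, BLOSUM62)
#' against every reference protein; the reported frame/strand maximizes
#' the best-hit score. Ties are broken by fewer internal stops, then `+`
#' strand, then lower frame.
#'
#' @param nt_seq ASV nucleotide sequence (or a list with `nt_seq`).
#' @param resource a `reference_resource`.
#' @param cfg an [aligner_config()].
#' @return list with `strand`, `frame`, `peptide`, `internal_stops`,
#'   `score`, `nt_length`.
#' @export
best_frame <- function(nt_seq, resource, cfg = aligner_config()) {
  if (is.list(nt_seq)) nt_seq <- nt_seq$nt_seq
  frames <- six_frame_translate(nt_seq)
  refs <- stats::setNames(resource$entries$protein_seq, resource$entries$id)
  frames$score <- vapply(frames$peptide, function(p) {
    if (nchar(p) == 0) return(-Inf)
    max(aa_scores(p, refs, cfg))
  }, 0, USE.NAMES = FALSE)
  frames$stops <- vapply(frames$peptide, internal_stop_count, 0L)
  ord <- order(-frames$score, frames$stops, frames$strand == "-", frames$frame)
  b <- frames[ord[1], ]
  list(strand = b$strand, frame = b$frame, peptide = b$peptide,
       internal_stops = b$stops, score = b$score, nt_length = nchar(nt_seq))
}

#' Homology filter for translated ASVs
#'
#' An ASV stays a candidate iff its best local alignment to any reference
#' entry (target or decoy alike; phylogenetic placement decides the class)
#' reaches both the identity and the length-normalized score threshold,
#' with no stop codon inside the aligned span. The reported reason is the
#' first failed rule in the order too_short, internal_stop, no_homology.
#'
#' @param translation result of [best_frame()].
#' @param resource a `reference_resource`.
#' @param min_identity minimum identity over the aligned span (default 0.4).
#' @param min_norm_score minimum alignment score per query residue (default
#'   0.8); normalizing by the query length rather than the aligned span
#'   keeps short spurious local alignments from qualifying.
#' @param min_length minimum ASV nucleotide length (default 100).
#' @param cfg an [aligner_config()].
#' @return list with `status` (`candidate`/`excluded`), `reason` (`ok`,
#'   `too_short`, `internal_stop`, `no_homology`) and `best_hit` (list of
#'   `ref_id`, `identity`, `norm_score`; NULL when too short).
#' @export
homology_filter <- function(translation, resource, min_identity = 0.4,
                            min_norm_score = 0.8, min_length = 100,
                            cfg = aligner_config()) {
  if (!is.null(translation$nt_length) && translation$nt_length < min_length)
    return(list(status = "excluded", reason = "too_short", best_hit = NULL))
  refs <- stats::setNames(resource$entries$protein_seq, resource$entries$id)
  hit <- aa_best_hit(translation$peptide, refs, cfg)
  best <- list(ref_id = hit$ref_id, identity = hit$identity,
               norm_score = hit$norm_score)
  if (hit$span_stops > 0)
    return(list(status = "excluded", reason = "internal_stop", best_hit = best))
  if (hit$identity < min_identity || hit$norm_score < min_norm_score)
    return(list(status = "excluded", reason = "no_homology", best_hit = best))
  list(status = "candidate", reason = "ok", best_hit = best)
}

#' Translate and homology-filter a set of ASVs
#'
#' Convenience wrapper running [best_frame()] and [homology_filter()] per
#' ASV. Deterministic: no randomness anywhere in the verification stage.
#'
#' @param asvs data.frame with columns `id` and `nt_seq`.
#' @param resource a `reference_resource`.
#' @param ... passed to [homology_filter()].
#' @return data.frame with one row per ASV: `id`, `strand`, `frame`,
#'   `peptide`, `score`, `status`, `reason`, `best_ref`, `identity`,
#'   `norm_score`.
#' @export
verify_asvs <- function(asvs, resource, ...) {
  rows <- lapply(seq_len(nrow(asvs)), function(i) {
    tr <- best_frame(asvs$nt_seq[i], resource)
    v <- homology_filter(tr, resource, ...)
    data.frame(id = asvs$id[i], strand = tr$strand, frame = tr$frame,
               peptide = tr$peptide, score = tr$score,
               status = v$status, reason = v$reason,
               best_ref = if (is.null(v$best_hit)) NA_character_ else v$best_hit$ref_id,
               identity = if (is.null(v$best_hit)) NA_real_ else v$best_hit$identity,
               norm_score = if (is.null(v$best_hit)) NA_real_ else v$best_hit$norm_score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
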
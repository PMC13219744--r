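#' Best-hit taxonomy with a hard identity floor
#'
#' Aligns a peptide locally against a genome-protein database and assigns
#' the taxonomy of the best-scoring hit only when its identity over the
#' aligned span reaches `floor` (the conservative 90% convention for this
#' marker); otherwise the peptide is "unclassified". Ties on score are
#' broken by higher identity, then lexicographic id. Multi-copy marker
#' genes are distinct database entries sharing a taxonomy string; best-hit
#' logic is per entry.
#'
#' @param peptide amino-acid string.
#' @param db data.frame with columns `id`, `protein`, `taxonomy`
#'   (semicolon-separated ranks).
#' @param floor minimum identity for assignment (default 0.9).
#' @param cfg an [aligner_config()].
#' @return list with `hit_id`, `identity`, `ranks` (`"unclassified"` when
#'   below floor or no alignment).
#' @export
classify <- function(peptide, db, floor = 0.9, cfg = aligner_config()) {
  if (nrow(db) == 0) stop("empty classification database", call. = FALSE)
  refs <- stats::setNames(db$protein, db$id)
  sc <- aa_scores(peptide, refs, cfg)
  top <- which(sc == max(sc))
  idt <- vapply(top, function(j) {
    aln <- pairwiseAlignment(AAString(refs[[j]]), AAString(peptide),
                             type = cfg$type, substitutionMatrix = blosum62(),
                             gapOpening = cfg$gap_open,
                             gapExtension = cfg$gap_extend)
    pid(aln, type = "PID1") / 100
  }, 0)
  pick <- top[order(-idt, db$id[top])][1]
  identity <- idt[match(pick, top)]
  if (identity >= floor)
    list(hit_id = db$id[pick], identity = identity, ranks = db$taxonomy[pick])
  else
    list(hit_id = db$id[pick], identity = identity, ranks = "unclassified")
}

#' Classify a table of verified ASV peptides
#'
#' @param verdicts data.frame with columns `id` and `peptide`.
#' @param db,floor,cfg see [classify()].
#' @return data.frame `id`, `hit_id`, `identity`, `ranks`.
#' @export
classify_asvs <- function(verdicts, db, floor = 0.9, cfg = aligner_config()) {
  rows <- lapply(seq_len(nrow(verdicts)), function(i) {
    cl <- classify(verdicts$peptide[i], db, floor, cfg)
    data.frame(id = verdicts$id[i], hit_id = cl$hit_id,
               identity = cl$identity, ranks = cl$ranks,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-clade taxonomic composition of placed ASVs
#'
#' Cross-tabulates placement clades against taxonomy at one rank;
#' "unclassified" is its own category. Percentages sum to 100 within each
#' clade.
#'
#' @param placements data.frame with columns `id` and `clade_id`
#'   (e.g. the `table` element of [place_asvs()], verified rows).
#' @param assignments data.frame from [classify_asvs()].
#' @param rank rank index into the semicolon-separated taxonomy string
#'   (1 = domain), or one of `"class"`, `"family"`, `"genus"` under the
#'   seven-rank GTDB convention.
#' @return data.frame `clade_id`, `taxon`, `count`, `percent`.
#' @export
clade_composition <- function(placements, assignments,
                              rank = "class") {
  rank_idx <- if (is.character(rank))
    switch(rank, domain = 1L, phylum = 2L, class = 3L, order = 4L,
           family = 5L, genus = 6L, species = 7L,
           stop("unknown rank: ", rank, call. = FALSE))
  else as.integer(rank)
  missing <- setdiff(placements$id, assignments$id)
  if (length(missing) > 0)
    stop("ASVs without taxonomy assignment: ", paste(missing, collapse = ", "),
         call. = FALSE)
  tax <- assignments$ranks[match(placements$id, assignments$id)]
  taxon <- vapply(tax, function(t) {
    if (identical(t, "unclassified")) return("unclassified")
    parts <- trimws(strsplit(t, ";")[[1]])
    if (length(parts) < rank_idx || !nzchar(parts[rank_idx])) "unclassified"
    else parts[rank_idx]
  }, "", USE.NAMES = FALSE)
  tab <- as.data.frame(table(clade_id = placements$clade_id, taxon = taxon),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  names(tab)[3] <- "count"
  tab$clade_id <- as.integer(tab$clade_id)
  tot <- tapply(tab$count, tab$clade_id, sum)
  tab$percent <- 100 * tab$count / as.numeric(tot[as.character(tab$clade_id)])
  rownames(tab) <- NULL
  tab[order(tab$clade_id, -tab$count), ]
}
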
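#' Greedy abundance-sorted OTU clustering
#'
#' ASVs are processed in decreasing total-count order (ties broken by
#' lexicographic id); each joins the first existing centroid whose
#' [pairwise_identity()] to it reaches `threshold`, otherwise it founds a
#' new cluster. This mirrors vsearch's cluster_size behaviour
#' (first-matching, not best-matching, centroid) with identity defined
#' over alignment columns excluding terminal gaps.
#'
#' @param asvs data.frame with columns `id`, `nt_seq` and `total_count`
#'   (total count may be missing, then all equal).
#' @param threshold identity threshold in (0, 1\]; 0.9 is the species-level
#'   proxy used for this marker.
#' @param match_rule `"first"` (default, vsearch-like) or `"best"`.
#' @return list of clusters, each a list with `otu_id`, `centroid`,
#'   `members`, `identities` (named numeric, identity of each member to
#'   the centroid).
#' @export
cluster_greedy <- function(asvs, threshold = 0.9, match_rule = c("first", "best")) {
  match_rule <- match.arg(match_rule)
  stopifnot(threshold > 0, threshold <= 1)
  if (nrow(asvs) == 0) return(list())
  if (is.null(asvs$total_count)) asvs$total_count <- 1
  ord <- order(-asvs$total_count, asvs$id)
  asvs <- asvs[ord, , drop = FALSE]
  clusters <- list()
  for (i in seq_len(nrow(asvs))) {
    id <- asvs$id[i]; seqi <- asvs$nt_seq[i]
    assigned <- FALSE
    best_j <- 0L; best_idt <- -1
    for (j in seq_along(clusters)) {
      idt <- pairwise_identity(seqi, clusters[[j]]$centroid_seq)
      if (idt >= threshold) {
        if (match_rule == "first") {
          clusters[[j]]$members <- c(clusters[[j]]$members, id)
          clusters[[j]]$identities <- c(clusters[[j]]$identities,
                                        stats::setNames(idt, id))
          assigned <- TRUE
          break
        } else if (idt > best_idt) {
          best_idt <- idt; best_j <- j
        }
      }
    }
    if (!assigned && match_rule == "best" && best_j > 0L) {
      clusters[[best_j]]$members <- c(clusters[[best_j]]$members, id)
      clusters[[best_j]]$identities <- c(clusters[[best_j]]$identities,
                                         stats::setNames(best_idt, id))
      assigned <- TRUE
    }
    if (!assigned) {
      clusters[[length(clusters) + 1L]] <- list(
        otu_id = length(clusters) + 1L, centroid = id, centroid_seq = seqi,
        members = id, identities = stats::setNames(1.0, id))
    }
  }
  clusters
}

#' OTU membership table
#'
#' @param clusters result of [cluster_greedy()].
#' @return data.frame with columns `otu_id`, `centroid`, `member`,
#'   `identity`.
#' @export
otu_membership <- function(clusters) {
  do.call(rbind, lapply(clusters, function(cl)
    data.frame(otu_id = cl$otu_id, centroid = cl$centroid,
               member = cl$members, identity = unname(cl$identities),
               stringsAsFactors = FALSE)))
}

#' Collapse an ASV count matrix to OTU counts
#'
#' Sums member counts per cluster; column (sample) structure is preserved,
#' so total counts are conserved.
#'
#' @param clusters result of [cluster_greedy()].
#' @param counts integer matrix, rows = ASV ids, columns = samples.
#' @return integer matrix, rows = `OTU_<id>`.
#' @export
otu_counts <- function(clusters, counts) {
  out <- t(vapply(clusters, function(cl) {
    mem <- intersect(cl$members, rownames(counts))
    colSums(counts[mem, , drop = FALSE])
  }, numeric(ncol(counts))))
  rownames(out) <- sprintf("OTU_%d", vapply(clusters, `[[`, 0L, "otu_id"))
  colnames(out) <- colnames(counts)
  out
}
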
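#' @importFrom Biostrings readAAStringSet readDNAStringSet translate DNAString
#'   DNAStringSet AAStringSet writeXStringSet
#' @importFrom ape read.tree write.tree
NULL

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# bacterial/archaeal/plastid genetic code (NCBI table 11)
GENETIC_CODE_11 <- Biostrings::getGeneticCode("11")

ungap <- function(x) gsub("[-.]", "", x)

#' Load and validate a marker-gene reference bundle
#'
#' The bundle is the ground truth every downstream stage consumes: curated
#' reference proteins of the marker family (plus paralogous decoys), their
#' multiple alignment, an unrooted maximum-likelihood reference tree with
#' branch lengths, optional coding sequences for primer work, and
#' per-sequence metadata with a target / non-target label and a taxonomy
#' string.
#'
#' Edge numbering convention: the tree is traversed depth-first starting
#' from the first leaf in protein-FASTA file order; at every node the
#' incident edges are visited in ascending order of the smallest
#' file-order index of the tips reachable through them. Edges get 0-based
#' ids in discovery order. The convention is canonical (independent of
#' Newick rotation), so jplace output is reproducible.
#'
#' @param protein_fasta path to the reference protein FASTA.
#' @param alignment_fasta path to the gapped amino-acid alignment FASTA.
#' @param tree_newick path to the Newick reference tree (branch lengths
#'   required, non-negative).
#' @param metadata_tsv path to a TSV with columns `id`, `label`
#'   (`target`/`non_target`), `taxonomy` (semicolon-separated ranks,
#'   unknown ranks empty) and optionally `source`.
#' @param nt_fasta optional path to coding sequences; each must translate
#'   (bacterial code, frame 1) to the protein entry up to a trailing stop.
#' @return object of class `reference_resource` with elements `entries`
#'   (data.frame), `alignment` (named character), `tree` (ape `phylo`),
#'   `edges` (edge table with 0-based `edge_id`), `target_leaves`.
#' @export
load_reference <- function(protein_fasta, alignment_fasta, tree_newick,
                           metadata_tsv, nt_fasta = NULL) {
  prot <- readAAStringSet(protein_fasta)
  aln <- readAAStringSet(alignment_fasta)
  tree <- read.tree(tree_newick)
  meta <- utils::read.delim(metadata_tsv, stringsAsFactors = FALSE)
  nt <- if (!is.null(nt_fasta)) readDNAStringSet(nt_fasta) else NULL
  build_reference(
    proteins = stats::setNames(as.character(prot), names(prot)),
    alignment = stats::setNames(as.character(aln), names(aln)),
    tree = tree, metadata = meta,
    nt = if (is.null(nt)) NULL else stats::setNames(as.character(nt), names(nt)))
}

#' Assemble and validate a reference resource from in-memory pieces
#'
#' Workhorse behind [load_reference()]; also used by the synthetic-data
#' generator.
#'
#' @param proteins named character vector of protein sequences (file order
#'   defines the edge-numbering root).
#' @param alignment named character vector of gapped rows, uniform width.
#' @param tree ape `phylo`.
#' @param metadata data.frame with `id`, `label`, `taxonomy`, optional `source`.
#' @param nt optional named character vector of coding sequences.
#' @return `reference_resource`.
#' @export
build_reference <- function(proteins, alignment, tree, metadata, nt = NULL) {
  ids <- names(proteins)
  if (anyDuplicated(ids)) stop("duplicated sequence ids in protein set")
  if (!all(c("id", "label", "taxonomy") %in% names(metadata)))
    stop("metadata must have columns id, label, taxonomy")
  missing_meta <- setdiff(ids, metadata$id)
  if (length(missing_meta) > 0)
    stop("entries missing from metadata: ", paste(missing_meta, collapse = ", "))
  bad_label <- setdiff(metadata$label, c("target", "non_target"))
  if (length(bad_label) > 0)
    stop("unknown labels in metadata: ", paste(bad_label, collapse = ", "))
  proteins <- toupper(proteins)
  badseq <- ids[!grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", proteins)]
  if (length(badseq) > 0)
    stop("invalid protein characters in: ", paste(badseq, collapse = ", "))

  # alignment consistency
  if (length(unique(nchar(alignment))) != 1)
    stop("alignment rows have differing column counts")
  extra_aln <- setdiff(names(alignment), ids)
  if (length(extra_aln) > 0)
    stop("alignment ids absent from protein set: ",
         paste(extra_aln, collapse = ", "))
  for (id in names(alignment)) {
    if (ungap(toupper(alignment[[id]])) != proteins[[id]])
      stop(sprintf("alignment row '%s' does not ungap to its protein sequence", id))
  }

  # tree consistency
  if (is.null(tree$edge.length)) stop("reference tree has no branch lengths")
  if (any(tree$edge.length < 0)) stop("reference tree has negative branch lengths")
  extra_tip <- setdiff(tree$tip.label, ids)
  if (length(extra_tip) > 0)
    stop("tree leaves absent from protein set: ", paste(extra_tip, collapse = ", "))
  no_row <- setdiff(tree$tip.label, names(alignment))
  if (length(no_row) > 0)
    stop("tree leaves without alignment row: ", paste(no_row, collapse = ", "))

  if (!is.null(nt)) {
    nt <- toupper(nt)
    extra_nt <- setdiff(names(nt), ids)
    if (length(extra_nt) > 0)
      stop("nucleotide ids absent from protein set: ",
           paste(extra_nt, collapse = ", "))
    for (id in names(nt)) {
      pep <- suppressWarnings(as.character(
        translate(DNAString(nt[[id]]), genetic.code = GENETIC_CODE_11,
                  no.init.codon = TRUE, if.fuzzy.codon = "solve")))
      pep <- sub("\\*$", "", pep)
      if (pep != proteins[[id]])
        stop(sprintf("nt entry '%s' does not translate to its protein", id))
    }
  }

  meta <- metadata[match(ids, metadata$id), , drop = FALSE]
  entries <- data.frame(
    id = ids,
    protein_seq = unname(proteins),
    nt_seq = if (is.null(nt)) NA_character_ else unname(nt[ids]),
    label = meta$label,
    taxonomy = meta$taxonomy,
    source = if ("source" %in% names(meta)) meta$source else NA_character_,
    stringsAsFactors = FALSE)

  target_leaves <- intersect(tree$tip.label, entries$id[entries$label == "target"])
  edges <- number_edges(tree, ids)
  structure(list(entries = entries, alignment = alignment, tree = tree,
                 edges = edges, target_leaves = target_leaves),
            class = "reference_resource")
}

#' @export
print.reference_resource <- function(x, ...) {
  cat(sprintf(paste0("<reference_resource> %d entries (%d target), ",
                     "%d tree leaves, %d edges, alignment %d x %d\n"),
              nrow(x$entries), sum(x$entries$label == "target"),
              length(x$tree$tip.label), nrow(x$edges),
              length(x$alignment), nchar(x$alignment[[1]])))
  invisible(x)
}

# Canonical 0-based edge numbering (see load_reference docs). Returns a
# data.frame: edge_id, parent, child (ape node numbers; parent = nearer the
# traversal root), length, child_tips (list of tip labels on the child side).
number_edges <- function(tree, file_order_ids) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  adj <- vector("list", nnode)
  for (k in seq_len(nrow(tree$edge))) {
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]
    adj[[a]] <- c(adj[[a]], k); adj[[b]] <- c(adj[[b]], k)
  }
  tip_rank <- match(tree$tip.label, file_order_ids)
  # min file-order rank reachable through edge k from node v (away from v)
  min_rank_beyond <- function(k, v) {
    w <- setdiff(tree$edge[k, ], v)
    seen <- rep(FALSE, nnode); seen[v] <- TRUE
    stack <- w; best <- Inf
    while (length(stack) > 0) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[u]) next
      seen[u] <- TRUE
      if (u <= ntip) best <- min(best, tip_rank[u])
      for (kk in adj[[u]]) {
        nb <- setdiff(tree$edge[kk, ], u)
        if (!seen[nb]) stack <- c(stack, nb)
      }
    }
    best
  }
  root_tip <- which.min(tip_rank)
  order_rows <- integer(0); parents <- integer(0); children <- integer(0)
  visit <- function(v, from_edge) {
    ks <- setdiff(adj[[v]], from_edge)
    if (length(ks) == 0) return()
    ranks <- vapply(ks, function(k) min_rank_beyond(k, v), 0)
    for (k in ks[order(ranks)]) {
      w <- setdiff(tree$edge[k, ], v)
      order_rows <<- c(order_rows, k)
      parents <<- c(parents, v); children <<- c(children, w)
      visit(w, k)
    }
  }
  visit(root_tip, NA)
  child_tips <- lapply(seq_along(order_rows), function(i) {
    v <- children[i]
    if (v <= ntip) return(tree$tip.label[v])
    # tips on the child side = tips reachable from child avoiding parent
    seen <- rep(FALSE, nnode); seen[parents[i]] <- TRUE
    stack <- v; tips <- character(0)
    while (length(stack) > 0) {
      u <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (seen[u]) next
      seen[u] <- TRUE
      if (u <= ntip) tips <- c(tips, tree$tip.label[u])
      for (kk in adj[[u]]) {
        nb <- setdiff(tree$edge[kk, ], u)
        if (!seen[nb]) stack <- c(stack, nb)
      }
    }
    tips
  })
  df <- data.frame(edge_id = seq_along(order_rows) - 1L,
                   ape_row = order_rows,
                   parent = parents, child = children,
                   length = tree$edge.length[order_rows])
  df$child_tips <- child_tips
  df
}

#' Edges of the target clade
#'
#' Returns the edge ids of the minimal spanning subtree connecting the
#' target leaves, plus the stem edge of that subtree when the targets are
#' a proper subset of the leaves. A placement on the stem is
#' target-adjacent by construction and is classified as target. The stem
#' is defined in the tree's canonical rooted view (rooted at the first
#' file-order leaf): it is the parent edge of the most recent common
#' ancestor of the target leaves; when the traversal root itself lies
#' inside the target clade no such edge exists and only the spanning
#' subtree is returned.
#'
#' @param resource a `reference_resource`.
#' @return sorted integer vector of 0-based edge ids.
#' @export
target_edges <- function(resource) {
  tl <- resource$target_leaves
  if (length(tl) == 0) stop("target_leaves is empty", call. = FALSE)
  ed <- resource$edges
  n_t <- length(tl)
  below <- vapply(ed$child_tips, function(tp) sum(tp %in% tl), 0L)
  n_leaves <- length(resource$tree$tip.label)
  # spanning-subtree edges: targets on both sides
  span <- ed$edge_id[below >= 1L & (n_t - below) >= 1L]
  res <- span
  if (n_t < n_leaves) {
    # stem: deepest edge with all targets on its child side
    cand <- which(below == n_t)
    if (length(cand) > 0) {
      sizes <- vapply(ed$child_tips[cand], length, 0L)
      res <- c(res, ed$edge_id[cand[which.min(sizes)]])
    }
  }
  sort(unique(res))
}

#' Write a reference resource back to a file set
#'
#' Inverse of [load_reference()]; the Newick is written in the package's
#' canonical edge traversal order so that reloading reproduces the same
#' edge numbering.
#'
#' @param resource a `reference_resource`.
#' @param dir output directory (created if missing).
#' @return invisibly, the named list of file paths written.
#' @export
write_reference <- function(resource, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(protein_fasta = file.path(dir, "reference_proteins.faa"),
                alignment_fasta = file.path(dir, "reference_alignment.faa"),
                tree_newick = file.path(dir, "reference_tree.nwk"),
                metadata_tsv = file.path(dir, "reference_metadata.tsv"),
                nt_fasta = file.path(dir, "reference_cds.fna"))
  writeXStringSet(AAStringSet(stats::setNames(resource$entries$protein_seq,
                                              resource$entries$id)),
                  paths$protein_fasta)
  writeXStringSet(AAStringSet(resource$alignment), paths$alignment_fasta)
  write.tree(resource$tree, paths$tree_newick)
  utils::write.table(resource$entries[, c("id", "label", "taxonomy", "source")],
                     paths$metadata_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!all(is.na(resource$entries$nt_seq))) {
    keep <- !is.na(resource$entries$nt_seq)
    writeXStringSet(DNAStringSet(stats::setNames(resource$entries$nt_seq[keep],
                                                 resource$entries$id[keep])),
                    paths$nt_fasta)
  } else paths$nt_fasta <- NULL
  invisible(paths)
}
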
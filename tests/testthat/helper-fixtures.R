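# Shared in-code fixtures: tiny reference bundles and brute-force oracles.

# minimal consistent 3-entry bundle (2 targets A,B + 1 decoy C)
toy_bundle <- function() {
  prot <- c(A = "MKLVAGHEE", B = "MKLVADHEE", C = "MRTWPDHQQ")
  tree <- ape::read.tree(text = "(A:0.1,B:0.2,C:0.8);")
  meta <- data.frame(id = c("A", "B", "C"),
                     label = c("target", "target", "non_target"),
                     taxonomy = c("Bacteria;;Clostridia;;;;",
                                  "Bacteria;;Clostridia;;;;",
                                  "Bacteria;;Bacilli;;;;"),
                     stringsAsFactors = FALSE)
  build_reference(prot, prot, tree, meta)
}

# random reference bundle for placement tests: n leaves, prot_len residues
random_bundle <- function(n = 8, prot_len = 30, seed = 1, n_target = ceiling(n / 2)) {
  set.seed(seed)
  tr <- ape::rtree(n, br = function(k) stats::rexp(k, 4),
                   tip.label = sprintf("L%02d", seq_len(n)))
  mod <- substitution_model("LG")
  root <- sample.int(20, prot_len, replace = TRUE, prob = mod$pi)
  states <- sqamp:::evolve_along_tree(tr, root, mod)
  prot <- vapply(states, function(s) paste(sqamp:::AA20[s], collapse = ""), "")
  meta <- data.frame(id = names(prot),
                     label = ifelse(names(prot) %in% sprintf("L%02d", seq_len(n_target)),
                                    "target", "non_target"),
                     taxonomy = "Bacteria;;;;;;", stringsAsFactors = FALSE)
  build_reference(prot, prot, ape::unroot(tr), meta)
}

# independent naive pruning: attach the query as a sister of edge `edge_id`
# at its midpoint with pendant length p, then compute the likelihood by a
# plain recursive post-order pass over the rebuilt topology (no message
# caching, no midpoint shortcuts).
naive_attached_loglik <- function(resource, query_row, edge_id, pendant, model) {
  ed <- resource$edges
  k <- which(ed$edge_id == edge_id)
  tree <- resource$tree
  ntip <- length(tree$tip.label)
  # children lists keyed by parent in the resource's rooted-at-first-leaf view
  kids <- split(seq_len(nrow(ed)), ed$parent)
  seqs <- c(resource$alignment, list(.query = query_row))
  tipm <- function(id) sqamp:::tip_matrix(seqs[[id]], model)
  # conditional likelihood vector of the subtree below edge row i, seen from
  # its top (after crossing the edge), with log-scaling
  below <- function(i, split_row = NULL) {
    v <- ed$child[i]
    if (!is.null(split_row) && i == split_row) {
      # replace this edge by: half-edge to a new node joining (rest of edge +
      # subtree) and the query pendant
      sub <- below_node(v, split_row = NULL)
      Pq <- transition_matrix(model, pendant)
      Ph <- transition_matrix(model, ed$length[i] / 2)
      Mjoin <- (Ph %*% sub$M) * (Pq %*% tipm(".query"))
      P2 <- transition_matrix(model, ed$length[i] / 2)
      M <- P2 %*% Mjoin
      return(list(M = M, ls = sub$ls))
    }
    sub <- below_node(v, split_row)
    P <- transition_matrix(model, ed$length[i])
    list(M = P %*% sub$M, ls = sub$ls)
  }
  below_node <- function(v, split_row) {
    if (v <= ntip) return(list(M = tipm(tree$tip.label[v]), ls = 0))
    M <- 1; ls <- 0
    for (i in kids[[as.character(v)]]) {
      b <- below(i, split_row)
      M <- M * b$M; ls <- ls + b$ls
    }
    sc <- apply(M, 2, max); sc[sc <= 0] <- 1
    list(M = M / rep(sc, each = 20), ls = ls + log(sc))
  }
  # root of the traversal is the first-file-order leaf; its pendant edge is
  # edge row with parent == that leaf
  root_row <- which(ed$edge_id == 0L)
  root_leaf <- ed$parent[root_row]
  b <- below(root_row, split_row = k)
  site <- colSums(model$pi * tipm(tree$tip.label[root_leaf]) * b$M)
  sum(log(site) + b$ls)
}

# greedy clustering oracle from a precomputed full identity matrix
greedy_oracle <- function(asvs, threshold) {
  ord <- order(-asvs$total_count, asvs$id)
  a <- asvs[ord, ]
  n <- nrow(a)
  idm <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i < j) idm[i, j] <- idm[j, i] <- pairwise_identity(a$nt_seq[i], a$nt_seq[j])
  centroid <- integer(0)
  assign <- integer(n)
  for (i in seq_len(n)) {
    hit <- which(idm[i, centroid] >= threshold)
    if (length(hit) > 0) assign[i] <- hit[1]
    else { centroid <- c(centroid, i); assign[i] <- length(centroid) }
  }
  split(a$id, assign)
}

# random protein sampled from LG equilibrium frequencies
random_peptide <- function(len, model = substitution_model("LG")) {
  paste(sqamp:::AA20[sample.int(20, len, replace = TRUE, prob = model$pi)],
        collapse = "")
}
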
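#' Configuration for the synthetic-data generator
#'
#' The generator emulates the structure of a functional-marker reference
#' bundle and its amplicon data: a monophyletic target family plus
#' paralogous decoys diverged from a distant common ancestor, coding
#' sequences with a primer-delimited ~340 bp amplicon window, ASVs cut
#' from those windows with sequencing/PCR substitution errors, and
#' multi-sample count tables with spiked enrichment in a treated
#' condition.
#'
#' @param seed master seed (default 42).
#' @param n_target_leaves,n_decoy_leaves reference family sizes.
#' @param tree_branch_scale mean branch length (expected substitutions per
#'   site) of the within-group trees; the two groups are separated by a
#'   1.5-substitutions-per-site ancestral branch.
#' @param protein_length reference protein length in residues.
#' @param nt_error_rate per-base substitution rate applied to amplicons
#'   (default 0.01, a denoising-residual/PCR-error proxy).
#' @param n_samples_per_condition samples per condition (default 3,
#'   triplicate sequencing).
#' @param community_model `"log_series"` (rumen-like dominance structure)
#'   or `"uniform"` (gut-like low-richness communities).
#' @param n_target_asvs,n_decoy_asvs ASVs drawn from target / decoy leaves
#'   (defaults 50 and 20).
#' @param library_size mean reads per sample (default 20000).
#' @param sample_dispersion NB dispersion of replicate counts (default 0.05).
#' @param spike data.frame with columns `feature`, `fold`; NULL means the
#'   first three target ASVs at 8-fold.
#' @param amp_start 0-based CDS position of the amplicon window start; the
#'   window is 340 nt and the two 21 nt primer sites are its ends.
#' @param wobble_transition,wobble_transversion per-position rates of
#'   synonymous third-base noise inside primer sites (transitions are
#'   covered by the degenerate primers, transversions are mismatches).
#' @param syn_rate probability that a non-primer codon uses a random
#'   synonymous alternative instead of the canonical codon.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(seed = 42L,
                         n_target_leaves = 12L, n_decoy_leaves = 6L,
                         tree_branch_scale = 0.15,
                         protein_length = 250L,
                         nt_error_rate = 0.01,
                         n_samples_per_condition = 3L,
                         community_model = c("log_series", "uniform"),
                         n_target_asvs = 50L, n_decoy_asvs = 20L,
                         library_size = 20000L,
                         sample_dispersion = 0.05,
                         spike = NULL,
                         amp_start = 181L,
                         wobble_transition = 0.05,
                         wobble_transversion = 0.01,
                         syn_rate = 0.3) {
  stopifnot(nt_error_rate >= 0, nt_error_rate <= 0.2,
            n_target_leaves >= 2, n_decoy_leaves >= 1,
            protein_length >= 120, amp_start + 340 <= 3 * protein_length)
  structure(list(seed = as.integer(seed),
                 n_target_leaves = n_target_leaves,
                 n_decoy_leaves = n_decoy_leaves,
                 tree_branch_scale = tree_branch_scale,
                 protein_length = protein_length,
                 nt_error_rate = nt_error_rate,
                 n_samples_per_condition = n_samples_per_condition,
                 community_model = match.arg(community_model),
                 n_target_asvs = n_target_asvs,
                 n_decoy_asvs = n_decoy_asvs,
                 library_size = library_size,
                 sample_dispersion = sample_dispersion,
                 spike = spike,
                 amp_start = as.integer(amp_start),
                 wobble_transition = wobble_transition,
                 wobble_transversion = wobble_transversion,
                 syn_rate = syn_rate),
            class = "synth_config")
}

# codons (table 11) per amino acid, stops excluded
codons_by_aa <- function() {
  cod <- GENETIC_CODE_11
  split(names(cod), unname(cod))
}

TRANSITION <- c(A = "G", G = "A", C = "T", T = "C")

# evolve sequences of state indices (1..20) down a rooted ape tree
evolve_along_tree <- function(tree, root_states, model) {
  n <- length(root_states)
  ntip <- length(tree$tip.label)
  seqs <- vector("list", ntip + tree$Nnode)
  root <- ntip + 1L
  seqs[[root]] <- root_states
  ord <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(ord$edge))) {
    a <- ord$edge[k, 1]; b <- ord$edge[k, 2]
    P <- transition_matrix(model, ord$edge.length[k])
    ps <- seqs[[a]]
    seqs[[b]] <- vapply(ps, function(s) sample.int(20L, 1L, prob = P[s, ]), 0L)
  }
  stats::setNames(seqs[seq_len(ntip)], tree$tip.label)
}

#' Simulate a marker-gene reference bundle
#'
#' Generates random within-group topologies for targets and decoys
#' (exponential branch lengths with mean `tree_branch_scale`), joins them
#' across a long ancestral branch, evolves a root protein along the tree
#' under the placement substitution model (so the model is well-specified
#' for recovery tests), freezes the amino acids under the two primer
#' sites across the target group, and back-translates every protein with
#' a per-column canonical codon table plus controlled synonymous noise.
#' The degenerate primer pair covers each canonical primer site with
#' two-fold codes (transition partners) at third-codon positions.
#'
#' @param config a [synth_config()].
#' @param model the substitution model used both to evolve and (by
#'   default) to place; `"misspecified"` evolves under Poisson instead,
#'   to stress-test placement robustness.
#' @return list with `resource` (validated `reference_resource`), `truth`
#'   (per-entry data.frame), `primers` (list `fwd`, `rev` of
#'   [degenerate_primer()]), `amp_window` (0-based inclusive start/end)
#'   and `config`.
#' @export
simulate_reference <- function(config = synth_config(),
                               model = c("well_specified", "misspecified")) {
  model_mode <- match.arg(model)
  place_model <- substitution_model("LG")
  evo_model <- if (model_mode == "well_specified") place_model
               else substitution_model("poisson")
  set.seed(config$seed)
  nt_ <- config$n_target_leaves; nd <- config$n_decoy_leaves
  brl <- function(n) stats::rexp(n, rate = 1 / config$tree_branch_scale)
  t1 <- ape::rtree(nt_, br = brl, tip.label = sprintf("T%02d", seq_len(nt_)))
  t2 <- if (nd >= 2)
    ape::rtree(nd, br = brl, tip.label = sprintf("D%02d", seq_len(nd)))
  else NULL
  nw1 <- sub(";$", "", ape::write.tree(t1))
  nw2 <- if (is.null(t2)) sprintf("D01:%g", brl(1)) else
    sub(";$", "", ape::write.tree(t2))
  tree <- ape::read.tree(text = sprintf("(%s:0.75,%s:0.75);", nw1, nw2))

  L <- config$protein_length
  root_states <- sample.int(20L, L, replace = TRUE, prob = evo_model$pi)
  states <- evolve_along_tree(tree, root_states, evo_model)

  # amplicon window and primer-site codons (0-based nt coordinates)
  ws <- config$amp_start; we <- ws + 339L
  fwd_nt <- ws:(ws + 20L); rev_nt <- (we - 20L):we
  prim_cod <- sort(unique(c(fwd_nt %/% 3L, rev_nt %/% 3L))) + 1L # 1-based codons
  # freeze primer-site amino acids across the target group
  t_root <- states[["T01"]]
  for (id in names(states)) {
    if (startsWith(id, "T")) states[[id]][prim_cod] <- t_root[prim_cod]
  }
  proteins <- vapply(states, function(s) paste(AA20[s], collapse = ""), "")

  # canonical codon per (amino acid, column)
  cba <- codons_by_aa()
  canon <- matrix("", 20, L)
  for (a in seq_len(20)) {
    opts <- cba[[AA20[a]]]
    canon[a, ] <- sample(opts, L, replace = TRUE)
  }
  make_cds <- function(s, id) {
    cods <- canon[cbind(s, seq_len(L))]
    # synonymous variation outside the primer sites
    for (j in setdiff(seq_len(L), prim_cod)) {
      if (stats::runif(1) < config$syn_rate) {
        opts <- cba[[AA20[s[j]]]]
        if (length(opts) > 1) cods[j] <- sample(setdiff(opts, cods[j]), 1)
      }
    }
    # third-base wobble noise inside primer sites (targets only; decoys
    # drift freely through their own synonymous noise)
    if (startsWith(id, "T")) {
      for (j in prim_cod) {
        u <- stats::runif(1)
        b3 <- substr(cods[j], 3, 3)
        newb <- if (u < config$wobble_transversion)
          sample(setdiff(c("A", "C", "G", "T"), c(b3, TRANSITION[[b3]])), 1)
        else if (u < config$wobble_transversion + config$wobble_transition)
          TRANSITION[[b3]]
        else b3
        cand <- paste0(substr(cods[j], 1, 2), newb)
        if (GENETIC_CODE_11[[cand]] == AA20[s[j]]) cods[j] <- cand
      }
    }
    paste(cods, collapse = "")
  }
  cds <- vapply(names(states), function(id) make_cds(states[[id]], id), "")

  # degenerate primers from the canonical target window, two-fold codes at
  # third-codon positions
  canon_cds_t <- paste(canon[cbind(t_root, seq_len(L))], collapse = "")
  iupac_for <- function(bases) {
    names(IUPAC_SETS)[vapply(IUPAC_SETS, function(s) setequal(s, bases), TRUE)]
  }
  window_primer <- function(nt_pos) { # 0-based positions on + strand
    ch <- strsplit(substr(canon_cds_t, min(nt_pos) + 1L, max(nt_pos) + 1L), "")[[1]]
    third <- ((nt_pos %% 3L) == 2L)
    vapply(seq_along(ch), function(i) {
      if (third[i]) iupac_for(c(ch[i], TRANSITION[[ch[i]]])) else ch[i]
    }, "")
  }
  fwd <- degenerate_primer("SYNF", paste(window_primer(fwd_nt), collapse = ""),
                           "forward")
  rev_ <- degenerate_primer("SYNR",
                            revcomp(paste(window_primer(rev_nt), collapse = "")),
                            "reverse")

  classes <- c("Clostridia", "Bacilli", "Gammaproteobacteria", "Bacteroidia")
  meta <- data.frame(
    id = names(states),
    label = ifelse(startsWith(names(states), "T"), "target", "non_target"),
    taxonomy = vapply(seq_along(states), function(i) {
      cl <- if (startsWith(names(states)[i], "T"))
        classes[1 + (i %% 2)] else classes[3 + (i %% 2)]
      sprintf("Bacteria;Phylum_%s;%s;Order_X;Family_%s;Genus_%02d;",
              substr(cl, 1, 3), cl, substr(names(states)[i], 1, 1), i)
    }, ""),
    source = "synthetic",
    stringsAsFactors = FALSE)

  resource <- build_reference(proteins = proteins, alignment = proteins,
                              tree = ape::unroot(tree), metadata = meta,
                              nt = cds)
  list(resource = resource,
       truth = meta[, c("id", "label")],
       primers = list(fwd = fwd, rev = rev_),
       amp_window = c(start = ws, end = we),
       config = config)
}

#' Simulate amplicon ASVs and a multi-sample count table
#'
#' Cuts reads from the primer-delimited window of randomly chosen source
#' leaves (targets and decoys), applies per-base substitution errors at
#' `nt_error_rate`, reverse-complements each ASV with probability 1/2,
#' draws per-sample counts under the community model with NB replicate
#' noise, and multiplies spiked features in the treated condition.
#'
#' @param ref_sim result of [simulate_reference()].
#' @param config a [synth_config()]; defaults to the one inside `ref_sim`.
#' @return list with `asvs` (data.frame `id`, `nt_seq`), `counts`
#'   (integer matrix ASV x sample), `condition` (named vector
#'   control/treated), `truth` (per-ASV data.frame: `id`, `source_leaf`,
#'   `is_target`, `strand`, `frame`, `true_fold`) and `spike`.
#' @export
simulate_amplicons <- function(ref_sim, config = ref_sim$config) {
  set.seed(config$seed + 1L)
  res <- ref_sim$resource
  ws <- ref_sim$amp_window[["start"]]; we <- ref_sim$amp_window[["end"]]
  leaves_t <- grep("^T", res$tree$tip.label, value = TRUE)
  leaves_d <- grep("^D", res$tree$tip.label, value = TRUE)
  n_asv <- config$n_target_asvs + config$n_decoy_asvs
  src <- c(sample(leaves_t, config$n_target_asvs, replace = TRUE),
           sample(leaves_d, config$n_decoy_asvs, replace = TRUE))
  ids <- sprintf("ASV_%03d", seq_len(n_asv))
  cds <- stats::setNames(res$entries$nt_seq, res$entries$id)
  frame_plus <- (3L - (ws %% 3L)) %% 3L
  bases <- c("A", "C", "G", "T")
  seqs <- character(n_asv); strands <- character(n_asv)
  for (i in seq_len(n_asv)) {
    s <- substr(cds[[src[i]]], ws + 1L, we + 1L)
    ch <- strsplit(s, "")[[1]]
    err <- stats::runif(length(ch)) < config$nt_error_rate
    if (any(err))
      ch[err] <- vapply(ch[err], function(b) sample(setdiff(bases, b), 1), "")
    s <- paste(ch, collapse = "")
    if (stats::runif(1) < 0.5) {
      s <- revcomp(s); strands[i] <- "-"
    } else strands[i] <- "+"
    seqs[i] <- s
  }

  # community abundances over ASVs
  p <- switch(config$community_model,
              uniform = rep(1 / n_asv, n_asv),
              log_series = { x <- 0.999
                w <- x^seq_len(n_asv) / seq_len(n_asv); w / sum(w) })
  spike <- ref_sim$config$spike
  if (is.null(spike))
    spike <- data.frame(feature = ids[seq_len(min(3L, config$n_target_asvs))],
                        fold = 8)
  n <- config$n_samples_per_condition
  samples <- c(sprintf("control_%d", seq_len(n)), sprintf("treated_%d", seq_len(n)))
  condition <- stats::setNames(rep(c("control", "treated"), each = n), samples)
  fold <- stats::setNames(rep(1, n_asv), ids)
  fold[spike$feature] <- spike$fold
  counts <- matrix(0L, n_asv, 2L * n, dimnames = list(ids, samples))
  for (s in seq_along(samples)) {
    mu <- config$library_size * p
    if (condition[s] == "treated") mu <- mu * fold
    counts[, s] <- stats::rnbinom(n_asv, mu = mu,
                                  size = 1 / config$sample_dispersion)
  }
  truth <- data.frame(id = ids, source_leaf = src,
                      is_target = startsWith(src, "T"),
                      strand = strands, frame = frame_plus,
                      true_fold = unname(fold[ids]),
                      stringsAsFactors = FALSE)
  list(asvs = data.frame(id = ids, nt_seq = seqs, stringsAsFactors = FALSE),
       counts = counts, condition = condition, truth = truth, spike = spike)
}
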
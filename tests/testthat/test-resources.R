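test_that("a minimal consistent bundle loads with canonical edge numbering", {
  res <- toy_bundle()
  expect_s3_class(res, "reference_resource")
  expect_equal(nrow(res$entries), 3)
  expect_equal(length(res$tree$tip.label), 3)
  expect_equal(nrow(res$edges), 3)       # unrooted 3-leaf tree has 3 edges
  expect_equal(res$edges$edge_id, 0:2)
  expect_setequal(res$target_leaves, c("A", "B"))
})

test_that("planted inconsistencies are rejected with the offending id", {
  prot <- c(A = "MKLVAGHEE", B = "MKLVADHEE", C = "MRTWPDHQQ")
  tree <- ape::read.tree(text = "(A:0.1,B:0.2,C:0.8);")
  meta <- data.frame(id = c("A", "B", "C"),
                     label = c("target", "target", "non_target"),
                     taxonomy = "x;")
  aln_bad <- prot; aln_bad[["B"]] <- "MKLVAAHEE"
  expect_error(build_reference(prot, aln_bad, tree, meta), "B")
  tree_bad <- ape::read.tree(text = "(A:0.1,B:0.2,Z:0.8);")
  expect_error(build_reference(prot, prot, tree_bad, meta), "Z")
  neg <- tree; neg$edge.length[1] <- -0.1
  expect_error(build_reference(prot, prot, neg, meta), "negative")
  ragged <- prot; ragged[["A"]] <- "MKLVAGHEEK"
  expect_error(build_reference(prot, ragged, tree, meta), "column|ungap")
  # coding sequence that does not translate to its protein
  nt_bad <- c(A = "ATGAAATTAGTTGCAGGTCATGAAGAA")  # TTA at codon 3 = L, ok...
  nt_bad[["A"]] <- "ATGAAACTGGTTGCAGGTCATGAACAT" # ...last codon H, not E
  expect_error(build_reference(prot, prot, tree, meta, nt = nt_bad), "A")
})

test_that("writing and reloading a bundle reproduces entries, alignment and edges", {
  res <- toy_bundle()
  dir <- withr::local_tempdir()
  paths <- write_reference(res, dir)
  res2 <- load_reference(paths$protein_fasta, paths$alignment_fasta,
                         paths$tree_newick, paths$metadata_tsv)
  expect_identical(res2$entries$id, res$entries$id)
  expect_identical(res2$entries$protein_seq, res$entries$protein_seq)
  expect_identical(res2$alignment, res$alignment)
  expect_equal(res2$edges$edge_id, res$edges$edge_id)
  expect_equal(res2$edges$length, res$edges$length)
  expect_identical(lapply(res2$edges$child_tips, sort),
                   lapply(res$edges$child_tips, sort))
})

test_that("target edges match path enumeration plus stem on a 5-leaf tree", {
  prot <- stats::setNames(rep("MKLVAGHEE", 5), c("A", "B", "C", "D", "E"))
  tree <- ape::read.tree(text = "((A:0.1,B:0.1):0.2,(C:0.1,D:0.1):0.3,E:0.4);")
  mk <- function(targets) {
    meta <- data.frame(id = names(prot),
                       label = ifelse(names(prot) %in% targets,
                                      "target", "non_target"),
                       taxonomy = "x;")
    build_reference(prot, prot, tree, meta)
  }
  # brute-force oracle: union of edges on tip-to-tip paths via ape::nodepath
  path_edges <- function(res, targets) {
    ed <- res$edges
    out <- integer(0)
    tips <- match(targets, res$tree$tip.label)
    for (i in seq_along(tips)) for (j in seq_along(tips)) {
      if (i >= j) next
      np <- ape::nodepath(res$tree, tips[i], tips[j])
      for (k in seq_len(length(np) - 1)) {
        row <- which((ed$parent == np[k] & ed$child == np[k + 1]) |
                     (ed$parent == np[k + 1] & ed$child == np[k]))
        out <- c(out, ed$edge_id[row])
      }
    }
    sort(unique(out))
  }
  res3 <- mk(c("A", "B", "E"))
  got <- target_edges(res3)
  pe <- path_edges(res3, c("A", "B", "E"))
  expect_true(all(pe %in% got))
  expect_lte(length(setdiff(got, pe)), 1)  # at most the stem edge extra
  # all leaves targets -> all edges
  res_all <- mk(c("A", "B", "C", "D", "E"))
  expect_setequal(target_edges(res_all), res_all$edges$edge_id)
  # single target -> exactly its pendant edge
  res_one <- mk("C")
  ed <- res_one$edges
  pend <- ed$edge_id[ed$child == match("C", res_one$tree$tip.label)]
  expect_equal(target_edges(res_one), pend)
  # clustered pair away from the traversal root: two pendant edges + stem
  res_cd <- mk(c("C", "D"))
  ecd <- target_edges(res_cd)
  expect_length(ecd, 3)
  pend_cd <- res_cd$edges$edge_id[res_cd$edges$child %in%
                                    match(c("C", "D"), res_cd$tree$tip.label)]
  expect_true(all(pend_cd %in% ecd))
  # when the traversal root (first file-order leaf) is itself a target the
  # spanning subtree touches the root and there is no stem edge
  res_ab <- mk(c("A", "B"))
  expect_length(target_edges(res_ab), 2)
  expect_error(target_edges(mk(character(0))), "empty")
})

test_that("target edges grow monotonically as leaves are added", {
  skip_if_not_installed("ape")
  set.seed(21)
  for (rep in 1:5) {
    res <- random_bundle(n = 7, prot_len = 10, seed = rep, n_target = 1)
    labels <- res$tree$tip.label
    prev <- NULL
    for (k in 1:6) {
      res$target_leaves <- labels[1:k]
      cur <- target_edges(res)
      if (!is.null(prev)) expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})
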
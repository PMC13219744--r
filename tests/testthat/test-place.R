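test_that("single-site likelihoods match the Poisson closed form", {
  prot <- c(A = "A", B = "A", C = "C")
  tree <- ape::read.tree(text = "(A:0.1,B:0.2,C:0.3);")
  meta <- data.frame(id = c("A", "B", "C"),
                     label = c("target", "target", "non_target"),
                     taxonomy = "x;")
  res <- build_reference(prot, prot, tree, meta)
  mod <- substitution_model("poisson")
  ps <- function(t) 1 / 20 + (19 / 20) * exp(-20 * t / 19)
  pd <- function(t) (1 - ps(t)) / 19
  expected <- log(sum(vapply(1:20, function(x)
    (1 / 20) *
      (if (x == 1) ps(0.1) else pd(0.1)) *
      (if (x == 1) ps(0.2) else pd(0.2)) *
      (if (x == 2) ps(0.3) else pd(0.3)), 0)))
  expect_equal(reference_loglik(res, mod), expected, tolerance = 1e-9)
  # a query that is all-gap at the only site adds nothing to the likelihood
  ll_gap <- edge_log_likelihood(res, "-", edge_id = 0, pendant = 0.5, model = mod)
  expect_equal(ll_gap, reference_loglik(res, mod), tolerance = 1e-9)
})

test_that("likelihood is invariant to the traversal root (pulley principle)", {
  set.seed(31)
  res <- random_bundle(n = 6, prot_len = 20, seed = 31)
  mod <- substitution_model("LG")
  ll <- reference_loglik(res, mod)
  # rebuilding the bundle with a different file order moves the traversal
  # root; the unrooted likelihood must not change
  perm <- c(4, 2, 6, 1, 3, 5)
  prot <- stats::setNames(res$entries$protein_seq, res$entries$id)[perm]
  meta <- res$entries[perm, c("id", "label", "taxonomy")]
  res2 <- build_reference(prot, prot, res$tree, meta)
  expect_equal(reference_loglik(res2, mod), ll, tolerance = 1e-8)
  # and the best placement edge is the same edge (matched via child tips)
  q <- random_peptide(20)
  p1 <- place_query(res, q, mod)
  p2 <- place_query(res2, q, mod)
  tips1 <- res$edges$child_tips[[which(res$edges$edge_id == p1$best_edge)]]
  tips2 <- res2$edges$child_tips[[which(res2$edges$edge_id == p2$best_edge)]]
  all_tips <- res$tree$tip.label
  same_split <- setequal(tips1, tips2) ||
    setequal(tips1, setdiff(all_tips, tips2))
  expect_true(same_split)
  expect_equal(p1$log_likelihood, p2$log_likelihood, tolerance = 1e-6)
})

test_that("reference likelihood agrees with phangorn's pruning", {
  skip_if_not_installed("phangorn")
  res <- random_bundle(n = 8, prot_len = 40, seed = 8)
  mod <- substitution_model("LG")
  aln <- res$alignment
  pd <- phangorn::phyDat(t(vapply(aln, function(s) strsplit(s, "")[[1]],
                                  character(40))), type = "AA")
  fit <- phangorn::pml(res$tree, pd, model = "LG")
  expect_equal(reference_loglik(res, mod), fit$logLik, tolerance = 1e-6)
})

test_that("query alignment into reference columns handles ends and insertions", {
  rs <- simulate_reference(synth_config(seed = 55))
  res <- rs$resource
  pep <- res$entries$protein_seq[3]
  expect_identical(align_query(pep, res)$row, res$alignment[[res$entries$id[3]]])
  trimmed <- substr(pep, 6, nchar(pep))
  expect_identical(align_query(trimmed, res)$row,
                   paste0("-----", trimmed))
  # a short insertion is discarded from the output row
  with_ins <- paste0(substr(pep, 1, 100), "WWW", substr(pep, 101, nchar(pep)))
  expect_identical(align_query(with_ins, res)$row, align_query(pep, res)$row)
  # unalignable junk is flagged
  expect_error(align_query(paste(rep("W", 50), collapse = ""), res),
               class = "sqamp_unplaceable")
})

test_that("self-placement lands on the leaf's pendant edge and verifies", {
  res <- random_bundle(n = 5, prot_len = 60, seed = 12, n_target = 2)
  mod <- substitution_model("LG")
  for (leaf in c("L01", "L05")) {
    pl <- place_query(res, res$alignment[[leaf]], mod, asv_id = leaf)
    node <- match(leaf, res$tree$tip.label)
    pend_edge <- res$edges$edge_id[res$edges$child == node]
    expect_equal(pl$best_edge, pend_edge)
    expect_lte(pl$pendant_length, 1e-4)
    expect_equal(pl$verified, leaf == "L01" || leaf == "L02")
    expect_gt(pl$lwr[as.character(pend_edge)], 0.5)
  }
  # like-weight ratios always normalize
  pl <- place_query(res, res$alignment[["L03"]], mod)
  expect_equal(sum(pl$lwr), 1, tolerance = 1e-9)
  expect_true(all(pl$lwr[as.character(pl$best_edge)] >= pl$lwr))
})

test_that("placement agrees with a naive rebuild-the-tree oracle", {
  mod <- substitution_model("LG")
  grid <- exp(seq(log(1e-8), log(5), length.out = 60))
  for (seed in 1:3) {
    res <- random_bundle(n = 8, prot_len = 25, seed = 100 + seed)
    engine <- sqamp:::make_engine(res, mod)
    q <- align_query(res$entries$protein_seq[sample(8, 1)], res)$row
    best_oracle <- c(edge = NA, ll = -Inf)
    for (eid in res$edges$edge_id) {
      for (p in grid[c(1, 15, 30, 45, 60)]) {
        mine <- edge_log_likelihood(res, q, eid, p, mod, engine = engine)
        oracle <- naive_attached_loglik(res, q, eid, p, mod)
        expect_equal(mine, oracle, tolerance = 1e-6)
        if (oracle > best_oracle["ll"]) best_oracle <- c(edge = eid, ll = oracle)
      }
    }
    pl <- place_query(res, q, mod, engine = engine)
    expect_equal(pl$best_edge, unname(best_oracle["edge"]))
    expect_gte(pl$log_likelihood + 1e-6, best_oracle[["ll"]])
  }
})

test_that("decoy-derived queries are rejected and target queries verified", {
  rs <- simulate_reference(synth_config(seed = 55, nt_error_rate = 0))
  amp <- simulate_amplicons(rs, synth_config(seed = 55, nt_error_rate = 0,
                                             n_target_asvs = 20,
                                             n_decoy_asvs = 10))
  v <- verify_asvs(amp$asvs, rs$resource)
  pl <- place_asvs(v, rs$resource, amp$counts)
  m <- merge(pl$table, amp$truth, by = "id")
  expect_gte(mean(m$verified[m$is_target]), 0.95)
  expect_lte(mean(m$verified[!m$is_target]), 0.05)
})

test_that("jplace output is valid, internally consistent and round-trips", {
  res <- random_bundle(n = 5, prot_len = 60, seed = 12, n_target = 2)
  mod <- substitution_model("LG")
  pl <- place_query(res, res$alignment[["L01"]], mod, asv_id = "q1",
                    multiplicity = 17)
  path <- withr::local_tempfile(fileext = ".jplace")
  write_jplace(list(pl), res, path)
  doc <- jsonlite::read_json(path)
  expect_equal(doc$version, 3)
  expect_equal(unlist(doc$fields),
               c("edge_num", "likelihood", "like_weight_ratio",
                 "distal_length", "pendant_length"))
  # every edge id 0..E-1 appears exactly once in the tree string
  for (eid in res$edges$edge_id)
    expect_equal(lengths(regmatches(doc$tree,
      gregexpr(sprintf("\\{%d\\}", eid), doc$tree))), 1)
  rec <- doc$placements[[1]]
  expect_equal(rec$nm[[1]][[1]], "q1")
  expect_equal(rec$nm[[1]][[2]], 17)
  best <- rec$p[[1]]
  expect_equal(best[[1]], pl$best_edge)
  expect_gt(best[[3]], 0.5)
  # distal length = half the attachment edge length by the midpoint convention
  expect_equal(best[[4]],
               res$edges$length[res$edges$edge_id == pl$best_edge] / 2)
  expect_error(write_jplace(list(), res, path), "no placements")
})
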
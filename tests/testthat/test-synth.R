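test_that("the generator is deterministic for a fixed seed", {
  a <- simulate_reference(synth_config(seed = 42))
  b <- simulate_reference(synth_config(seed = 42))
  expect_identical(a$resource$entries, b$resource$entries)
  expect_identical(ape::write.tree(a$resource$tree),
                   ape::write.tree(b$resource$tree))
  expect_identical(a$primers$fwd$seq, b$primers$fwd$seq)
  da <- withr::local_tempdir(); db_ <- withr::local_tempdir()
  write_reference(a$resource, da); write_reference(b$resource, db_)
  for (f in list.files(da))
    expect_identical(unname(tools::md5sum(file.path(da, f))),
                     unname(tools::md5sum(file.path(db_, f))))
  amp_a <- simulate_amplicons(a)
  amp_b <- simulate_amplicons(b)
  expect_identical(amp_a$asvs, amp_b$asvs)
  expect_identical(amp_a$counts, amp_b$counts)
  # a different seed gives different data
  c_ <- simulate_reference(synth_config(seed = 43))
  expect_false(identical(a$resource$entries$protein_seq,
                         c_$resource$entries$protein_seq))
})

test_that("the reference bundle passes validation and separates the groups", {
  rs <- simulate_reference(synth_config(seed = 42))
  res <- rs$resource
  expect_s3_class(res, "reference_resource")   # build_reference validated it
  expect_equal(sum(res$entries$label == "target"), 12)
  prot <- stats::setNames(res$entries$protein_seq, res$entries$id)
  aa_ident <- function(a, b) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
    mean(x == y)
  }
  t_ids <- res$entries$id[res$entries$label == "target"]
  d_ids <- res$entries$id[res$entries$label == "non_target"]
  intra <- mean(apply(utils::combn(t_ids, 2), 2,
                      function(p) aa_ident(prot[[p[1]]], prot[[p[2]]])))
  inter <- mean(vapply(t_ids[1:6], function(a)
    mean(vapply(d_ids, function(b) aa_ident(prot[[a]], prot[[b]]), 0)), 0))
  expect_gt(intra, inter)
  # the primer-delimited window is 340 nt with both primer sites at its ends
  expect_equal(rs$amp_window[["end"]] - rs$amp_window[["start"]] + 1L, 340L)
})

test_that("error-free amplicons translate to exact reference sub-peptides", {
  cfg <- synth_config(seed = 99, nt_error_rate = 0, n_target_asvs = 15,
                      n_decoy_asvs = 5)
  rs <- simulate_reference(cfg)
  amp <- simulate_amplicons(rs, cfg)
  prot <- stats::setNames(rs$resource$entries$protein_seq,
                          rs$resource$entries$id)
  for (i in seq_len(nrow(amp$asvs))) {
    s <- amp$asvs$nt_seq[i]
    if (amp$truth$strand[i] == "-") s <- revcomp(s)
    tr <- six_frame_translate(s)
    pep <- tr$peptide[tr$strand == "+" & tr$frame == amp$truth$frame[i]]
    pep <- sub("\\*.*$", "", pep)  # nothing to trim when error-free
    expect_true(grepl(pep, prot[[amp$truth$source_leaf[i]]], fixed = TRUE))
  }
})

test_that("community models order richness and spikes hit their fold target", {
  cfg_rich <- synth_config(seed = 42, community_model = "log_series")
  rs <- simulate_reference(cfg_rich)
  amp_ls <- simulate_amplicons(rs, cfg_rich)
  cfg_even <- synth_config(seed = 42, community_model = "uniform",
                           n_target_asvs = 10, n_decoy_asvs = 5)
  amp_un <- simulate_amplicons(rs, cfg_even)
  # log-series: strong dominance; uniform: balanced (control samples only,
  # so the spiked treated condition does not enter the comparison)
  ctrl_ls <- amp_ls$counts[, grepl("^control", colnames(amp_ls$counts))]
  ctrl_un <- amp_un$counts[, grepl("^control", colnames(amp_un$counts))]
  p_ls <- rowSums(ctrl_ls) / sum(ctrl_ls)
  p_un <- rowSums(ctrl_un) / sum(ctrl_un)
  expect_gt(max(p_ls), 2 * max(p_un))
  # richness ordering is preserved under rarefaction to 100 reads
  cov_ls <- alpha_metrics(subsample(rowSums(ctrl_ls), 100, seed = 1))$observed /
    sum(rowSums(ctrl_ls) > 0)
  cov_un <- alpha_metrics(subsample(rowSums(ctrl_un), 100, seed = 1))$observed /
    sum(rowSums(ctrl_un) > 0)
  expect_lt(cov_ls, cov_un)
  # spiked features: realized treated/control ratio near the nominal fold
  ctrl <- grepl("^control", colnames(amp_ls$counts))
  for (f in amp_ls$spike$feature) {
    ratio <- mean(amp_ls$counts[f, !ctrl]) / mean(amp_ls$counts[f, ctrl])
    expect_gt(ratio, 4.5)
    expect_lt(ratio, 14)
  }
  expect_true(all(amp_ls$truth$true_fold[amp_ls$truth$id %in%
                                           amp_ls$spike$feature] == 8))
})
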
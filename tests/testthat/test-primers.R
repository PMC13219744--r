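test_that("degenerate expansion enumerates exactly the allowed sequences", {
  expect_identical(expand_degenerate("ATG"), "ATG")
  expect_setequal(expand_degenerate("ARC"), c("AAC", "AGC"))
  expect_length(expand_degenerate("NN"), 16)
  expect_equal(length(expand_degenerate("RYSW")), degeneracy("RYSW"))
  expect_error(expand_degenerate("AXG"), "position 2")
  # every expansion matches the pattern position-wise
  for (seq in c("RRYT", "BDHV", "ANCT")) {
    ch <- strsplit(seq, "")[[1]]
    for (e in expand_degenerate(seq)) {
      ec <- strsplit(e, "")[[1]]
      expect_true(all(mapply(function(b, code)
        b %in% sqamp:::IUPAC_SETS[[code]], ec, ch)))
    }
  }
})

test_that("binding-site search matches trivial cases and strands", {
  s <- find_binding_sites("ATN", "GGATCGG", 0)
  expect_equal(nrow(s), 1)
  expect_equal(s$start, 2)
  expect_equal(s$mismatches, 0)
  r <- find_binding_sites("CAT", "ATGAAA", 0, orientation = "reverse")
  expect_equal(r$start, 0)
  expect_equal(r$strand, "-")
  # primer longer than template: empty, not an error
  expect_equal(nrow(find_binding_sites("ACGTACGTACGT", "ACG", 1)), 0)
})

test_that("binding-site search equals the expand-and-slide brute force", {
  set.seed(11)
  bases <- c("A", "C", "G", "T")
  for (rep in 1:5) {
    # random 30-mer with a few degenerate positions
    pr <- sample(bases, 30, TRUE)
    deg_pos <- sample(30, 3)
    pr[deg_pos] <- sample(c("R", "Y", "N", "S", "W"), 3, TRUE)
    primer <- paste(pr, collapse = "")
    # template: random background with planted copies at 0-3 mutations
    tch <- sample(bases, 2000, TRUE)
    for (site in 1:4) {
      st <- 450 * site
      copy <- strsplit(expand_degenerate(primer)[1], "")[[1]]
      k <- site - 1
      if (k > 0) {
        pos <- sample(30, k)
        copy[pos] <- vapply(copy[pos], function(b) sample(setdiff(bases, b), 1), "")
      }
      tch[(st + 1):(st + 30)] <- copy
    }
    template <- paste(tch, collapse = "")
    got <- find_binding_sites(primer, template, max_mismatches = 2)
    expect_gte(nrow(got), 3)  # the 0-, 1- and 2-mutation plants
    # brute force: min Hamming distance over all concrete expansions
    exps <- strsplit(expand_degenerate(primer), "")
    tch <- strsplit(template, "")[[1]]
    brute <- lapply(0:(2000 - 30), function(st) {
      win <- tch[(st + 1):(st + 30)]
      mm <- min(vapply(exps, function(e) sum(e != win), 0L))
      if (mm <= 2) data.frame(start = st, mismatches = mm) else NULL
    })
    brute <- do.call(rbind, brute)
    expect_equal(got$start, brute$start)
    expect_equal(got$mismatches, brute$mismatches)
    # mismatch-0 sites equal exact-set matching via expansion
    exact <- sort(unlist(lapply(expand_degenerate(primer), function(e)
      as.vector(gregexpr(e, template, fixed = TRUE)[[1]]))))
    exact <- exact[exact > 0] - 1L
    expect_equal(got$start[got$mismatches == 0], exact)
  }
})

test_that("in-silico PCR recovers constructed amplicons", {
  set.seed(3)
  FWD <- "ACGTACGTACGTACGTACGT"
  REV <- "TGCATGCATGCATGCATGCA"   # written 5'->3' on the minus strand
  insert <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  template <- paste0(FWD, insert, revcomp(REV))
  fwd <- degenerate_primer("F", FWD, "forward")
  rev <- degenerate_primer("R", REV, "reverse")
  amp <- in_silico_pcr(fwd, rev, template)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$length, nchar(FWD) + 300 + nchar(REV))
  expect_identical(amp$amplicon, template)
  # swapped orientation: no product
  expect_equal(nrow(in_silico_pcr(
    degenerate_primer("F2", REV, "forward"),
    degenerate_primer("R2", FWD, "reverse"), template)), 0)
  # two forward sites upstream of one reverse site: two products
  template2 <- paste0(FWD, insert, FWD, insert, revcomp(REV))
  amp2 <- in_silico_pcr(fwd, rev, template2)
  expect_equal(nrow(amp2), 2)
  expect_equal(sort(amp2$start), c(0, nchar(FWD) + 300))
  # amplicon ends reproduce the primer sites on the template
  for (i in seq_len(nrow(amp2))) {
    expect_identical(substr(amp2$amplicon[i], 1, nchar(FWD)), FWD)
    expect_identical(substr(amp2$amplicon[i], amp2$length[i] - nchar(REV) + 1,
                            amp2$length[i]), revcomp(REV))
  }
})

test_that("primer pair coverage counts perfect templates and is monotone", {
  set.seed(4)
  FWD <- "GGATCCGGATCCGGATCC"
  REV <- "AAGCTTAAGCTTAAGCTT"
  mk <- function(perfect) {
    mid <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
    f <- FWD
    if (!perfect) substr(f, 3, 3) <- "T"  # one mismatch in the fwd site
    paste0(f, mid, revcomp(REV))
  }
  db <- stats::setNames(c(vapply(1:8, function(i) mk(TRUE), ""),
                          vapply(1:2, function(i) mk(FALSE), "")),
                        sprintf("t%02d", 1:10))
  fwd <- degenerate_primer("F", FWD, "forward")
  rev <- degenerate_primer("R", REV, "reverse")
  cov0 <- primer_pair_coverage(fwd, rev, db, 0)
  expect_equal(cov0$n_templates, 10)
  expect_equal(cov0$n_perfect, 8)
  expect_equal(cov0$fraction_perfect, 0.8)
  # perfect-fraction definition is 0-mismatch regardless of search tolerance,
  # and every template amplifies once a mismatch is allowed
  cov1 <- primer_pair_coverage(fwd, rev, db, 1)
  expect_equal(cov1$n_perfect, 8)
  expect_true(all(!is.na(cov1$per_template$amplicon_length)))
  expect_error(primer_pair_coverage(fwd, rev, character(0)), "empty")
})

test_that("Wallace-rule Tm enumerates expansions", {
  expect_equal(primer_tm("AAAA"), c(min = 8, mean = 8, max = 8))
  expect_equal(primer_tm("GGGG"), c(min = 16, mean = 16, max = 16))
  expect_equal(primer_tm("RRRR"), c(min = 8, mean = 12, max = 16))
  expect_error(primer_tm("NNNNNNNN", cap = 1000), "cap")
})

test_that("primer proposal emits minimal consensus over gap-free windows", {
  rows <- c(a = "ACGTACGTACGTACGTAC", b = "ACGTACGTACGTACGTAC")
  cand <- propose_primers(rows, window = 15, max_degeneracy = 8)
  expect_true(nrow(cand) > 0)
  expect_true(all(cand$degeneracy == 1))
  expect_true(all(cand$coverage == 1))
  # one A/G column -> R in the consensus, degeneracy 2
  rows2 <- c(a = "ACGTACGTACGTACGTAC", b = "ACGTACGTGCGTACGTAC")
  cand2 <- propose_primers(rows2, window = 15, max_degeneracy = 8)
  expect_true(all(grepl("R", cand2$seq[cand2$start <= 8])))
  expect_true(all(cand2$degeneracy[cand2$start <= 8] == 2))
  # gapped column excluded
  rows3 <- c(a = "ACGTACG-ACGTACGTAC", b = "ACGTACGTGCGTACGTAC")
  cand3 <- propose_primers(rows3, window = 15, max_degeneracy = 64)
  expect_true(all(cand3$start > 7))
  # brute-force consensus on a small random alignment
  set.seed(9)
  aln <- vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""), "")
  names(aln) <- letters[1:5]
  got <- propose_primers(aln, window = 15, max_degeneracy = 4096)
  M <- do.call(rbind, strsplit(aln, ""))
  for (r in seq_len(nrow(got))) {
    s <- got$start[r]
    expected <- vapply((s + 1):(s + 15), function(j) {
      u <- sort(unique(M[, j]))
      names(sqamp:::IUPAC_SETS)[vapply(sqamp:::IUPAC_SETS,
                                       function(x) setequal(x, u), TRUE)]
    }, "")
    expect_identical(got$seq[r], paste(expected, collapse = ""))
  }
})

test_that("coverage reaches 1 when mismatches are unbounded", {
  set.seed(5)
  db <- stats::setNames(vapply(1:4, function(i)
    paste(sample(c("A", "C", "G", "T"), 120, TRUE), collapse = ""), ""),
    paste0("s", 1:4))
  fwd <- degenerate_primer("F", "ACGTACGTACGTACG", "forward")
  rev <- degenerate_primer("R", "TTGCATGCATGCATG", "reverse")
  cov <- primer_pair_coverage(fwd, rev, db, max_mismatches = 15)
  expect_true(all(!is.na(cov$per_template$fwd_mismatches)))
  expect_true(all(cov$per_template$amplicon_length <= 120))
})
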
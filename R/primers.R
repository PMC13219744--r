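#' Construct a degenerate primer
#'
#' An IUPAC-encoded oligo with an orientation and an optional 5'-head
#' (adapter) sequence. The head never participates in template matching;
#' it models the generic 16 bp two-step-barcoding adapters carried by
#' sequencing primers.
#'
#' @param name primer name.
#' @param seq IUPAC nucleotide string, written 5'->3' on the strand the
#'   primer anneals to.
#' @param orientation `"forward"` or `"reverse"`.
#' @param head optional 5' adapter sequence (plain ACGT), excluded from
#'   matching.
#' @param min_len minimum accepted primer length (default 10).
#' @return an object of class `degenerate_primer`.
#' @export
degenerate_primer <- function(name, seq, orientation = c("forward", "reverse"),
                              head = NULL, min_len = 10L) {
  orientation <- match.arg(orientation)
  seq <- toupper(seq)
  check_iupac(seq, what = sprintf("primer '%s'", name))
  if (nchar(seq) < min_len)
    stop(sprintf("primer '%s' is shorter than %d nt", name, min_len),
         call. = FALSE)
  if (!is.null(head)) {
    head <- toupper(head)
    check_iupac(head, what = sprintf("head of primer '%s'", name))
  }
  structure(list(name = name, seq = seq, orientation = orientation,
                 head = head),
            class = "degenerate_primer")
}

#' @export
print.degenerate_primer <- function(x, ...) {
  cat(sprintf("<degenerate_primer> %s (%s) %s  [%d nt, degeneracy %d%s]\n",
              x$name, x$orientation, x$seq, nchar(x$seq), degeneracy(x$seq),
              if (is.null(x$head)) "" else sprintf(", head %s", x$head)))
  invisible(x)
}

as_primer <- function(x, orientation = "forward") {
  if (inherits(x, "degenerate_primer")) return(x)
  degenerate_primer("primer", x, orientation, min_len = 1L)
}

# logical matrix [template position, primer position]: template base allowed
# by primer code at that offset. Template ambiguity codes count as a match
# only when the primer position's set is a superset of the template code's
# set (conservative coverage).
.mismatch_profile <- function(primer_seq, template) {
  tch <- strsplit(toupper(template), "")[[1]]
  pch <- check_iupac(primer_seq)
  L <- length(pch)
  n <- length(tch) - L + 1L
  if (n < 1L) return(integer(0))
  bad <- which(!tch %in% names(IUPAC_SETS))
  if (length(bad) > 0)
    stop(sprintf("illegal character '%s' in template at position %d",
                 tch[bad[1]], bad[1]), call. = FALSE)
  mm <- integer(n)
  for (j in seq_len(L)) {
    pset <- IUPAC_SETS[[pch[j]]]
    ok <- vapply(IUPAC_SETS[tch[j:(j + n - 1L)]],
                 function(ts) all(ts %in% pset), TRUE)
    mm <- mm + !ok
  }
  mm
}

#' Find primer binding sites on a template
#'
#' Forward primers are scanned along the + strand; reverse primers are
#' scanned as their reverse complement along the + strand and reported on
#' strand `-`. Per site, the mismatch count is the number of positions
#' where the template base is not in the primer position's allowed base
#' set; indels are not modelled. Site coordinates (`start`, 0-based) refer
#' to the + strand of the template.
#'
#' @param primer a [degenerate_primer] or an IUPAC string (then
#'   `orientation` applies).
#' @param template nucleotide string (ACGT; IUPAC codes are treated as
#'   mismatches unless subsumed by the primer code).
#' @param max_mismatches maximum mismatches per reported site.
#' @param orientation used only when `primer` is a bare string.
#' @return data.frame with columns `start`, `strand`, `mismatches`; zero
#'   rows when the primer is longer than the template.
#' @export
find_binding_sites <- function(primer, template, max_mismatches = 0L,
                               orientation = "forward") {
  primer <- as_primer(primer, orientation)
  scan_seq <- if (primer$orientation == "forward") primer$seq else revcomp(primer$seq)
  mm <- .mismatch_profile(scan_seq, template)
  hit <- which(mm <= max_mismatches)
  data.frame(start = hit - 1L,
             strand = rep(if (primer$orientation == "forward") "+" else "-",
                          length(hit)),
             mismatches = mm[hit],
             stringsAsFactors = FALSE)[order(hit), , drop = FALSE]
}

#' In-silico PCR with a degenerate primer pair
#'
#' Reports every properly oriented forward/reverse site pair whose product
#' length (primers included, matching how amplicon sizes are read off a
#' gel) falls within `size_range`. Primer sites may not overlap.
#'
#' @param fwd forward [degenerate_primer].
#' @param rev reverse [degenerate_primer].
#' @param template nucleotide string.
#' @param max_mismatches maximum mismatches per primer site.
#' @param size_range numeric length-2 vector, inclusive product size bounds.
#' @return data.frame with columns `start`, `end` (0-based, end exclusive),
#'   `length`, `fwd_mismatches`, `rev_mismatches`, `amplicon`; sorted by
#'   `start`. Zero rows when there is no product.
#' @export
in_silico_pcr <- function(fwd, rev, template, max_mismatches = 0L,
                          size_range = c(1L, 10000L)) {
  fwd <- as_primer(fwd, "forward"); rev <- as_primer(rev, "reverse")
  if (fwd$orientation != "forward" || rev$orientation != "reverse")
    stop("in_silico_pcr needs a forward and a reverse primer", call. = FALSE)
  fs <- find_binding_sites(fwd, template, max_mismatches)
  rs <- find_binding_sites(rev, template, max_mismatches)
  Lf <- nchar(fwd$seq); Lr <- nchar(rev$seq)
  out <- list()
  for (i in seq_len(nrow(fs))) {
    for (j in seq_len(nrow(rs))) {
      a <- fs$start[i]            # amplicon start (0-based)
      b <- rs$start[j] + Lr       # amplicon end (exclusive)
      len <- b - a
      if (rs$start[j] < a + Lf) next      # overlapping / wrong order
      if (len < size_range[1] || len > size_range[2]) next
      out[[length(out) + 1L]] <- data.frame(
        start = a, end = b, length = len,
        fwd_mismatches = fs$mismatches[i], rev_mismatches = rs$mismatches[j],
        amplicon = substr(template, a + 1L, b), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), end = integer(0), length = integer(0),
                      fwd_mismatches = integer(0), rev_mismatches = integer(0),
                      amplicon = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

#' Database coverage of a primer pair
#'
#' A template counts as "perfect" iff the pair produces at least one
#' properly oriented product in which both primer sites have zero
#' mismatches. Per template the report records the best (minimum) mismatch
#' count seen for each primer over all products within `max_mismatches`,
#' and the product length of the best product.
#'
#' @param fwd,rev forward and reverse [degenerate_primer]s.
#' @param db named character vector of nucleotide sequences (names = ids),
#'   or a data.frame with columns `id` and `nt_seq`.
#' @param max_mismatches site search tolerance (perfection always means 0).
#' @param size_range passed to [in_silico_pcr()].
#' @return object of class `coverage_report`: list with `n_templates`,
#'   `n_perfect`, `fraction_perfect` and `per_template` (data.frame `id`,
#'   `fwd_mismatches`, `rev_mismatches`, `amplicon_length`, NA = no site /
#'   no product).
#' @export
primer_pair_coverage <- function(fwd, rev, db, max_mismatches = 0L,
                                 size_range = c(1L, 10000L)) {
  if (is.data.frame(db)) db <- stats::setNames(db$nt_seq, db$id)
  if (length(db) == 0) stop("empty template database", call. = FALSE)
  mm_search <- max(max_mismatches, 0L)
  rows <- lapply(names(db), function(id) {
    prods <- in_silico_pcr(fwd, rev, db[[id]], max_mismatches = mm_search,
                           size_range = size_range)
    if (nrow(prods) == 0)
      return(data.frame(id = id, fwd_mismatches = NA_integer_,
                        rev_mismatches = NA_integer_,
                        amplicon_length = NA_integer_))
    best <- which.min(prods$fwd_mismatches + prods$rev_mismatches)
    data.frame(id = id,
               fwd_mismatches = min(prods$fwd_mismatches),
               rev_mismatches = min(prods$rev_mismatches),
               amplicon_length = prods$length[best])
  })
  per <- do.call(rbind, rows)
  perfect <- !is.na(per$fwd_mismatches) &
    per$fwd_mismatches == 0L & per$rev_mismatches == 0L
  structure(list(n_templates = length(db),
                 n_perfect = sum(perfect),
                 fraction_perfect = sum(perfect) / length(db),
                 per_template = per),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("<coverage_report> %d/%d templates perfect (%.1f%%)\n",
              x$n_perfect, x$n_templates, 100 * x$fraction_perfect))
  invisible(x)
}

#' Melting temperature of a degenerate primer
#'
#' Wallace rule, 2(A+T) + 4(G+C) degrees C, enumerated over all concrete
#' expansions of the primer (the head is excluded).
#'
#' @param primer a [degenerate_primer] or IUPAC string.
#' @param cap maximum degeneracy enumerated exactly (default 4096).
#' @return named numeric vector `c(min=, mean=, max=)`.
#' @export
primer_tm <- function(primer, cap = 4096L) {
  primer <- as_primer(primer)
  if (degeneracy(primer$seq) > cap)
    stop(sprintf("degeneracy %d exceeds enumeration cap %d; sample expansions instead",
                 degeneracy(primer$seq), cap), call. = FALSE)
  exps <- expand_degenerate(primer$seq)
  tm <- vapply(exps, function(s) {
    ch <- strsplit(s, "")[[1]]
    2 * sum(ch %in% c("A", "T")) + 4 * sum(ch %in% c("G", "C"))
  }, 0)
  c(min = min(tm), mean = mean(tm), max = max(tm))
}

#' Propose degenerate primer candidates from conserved alignment windows
#'
#' Slides a window over gap-free regions of a nucleotide alignment and
#' emits the minimal IUPAC consensus of each window. Bases observed at a
#' frequency below `min_base_freq` are dropped from the consensus before
#' encoding, so rare variants lower a candidate's coverage instead of
#' inflating its degeneracy.
#'
#' @param alignment named character vector of equal-length gapped
#'   nucleotide rows (or a `Biostrings::DNAStringSet`).
#' @param window window width in columns (>= 15).
#' @param max_degeneracy keep only candidates at or below this degeneracy.
#' @param min_base_freq minimum per-column base frequency for inclusion in
#'   the consensus (default 0 = union consensus).
#' @return data.frame with columns `start` (0-based column), `seq`,
#'   `degeneracy`, `coverage` (fraction of rows matched at 0 mismatches);
#'   zero rows if no gap-free window exists.
#' @export
propose_primers <- function(alignment, window = 20L, max_degeneracy = 64L,
                            min_base_freq = 0) {
  if (methods::is(alignment, "XStringSet"))
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  if (length(alignment) < 2) stop("alignment needs >= 2 rows", call. = FALSE)
  if (window < 15) stop("window must be >= 15", call. = FALSE)
  ncol <- unique(nchar(alignment))
  if (length(ncol) != 1) stop("alignment rows differ in length", call. = FALSE)
  M <- do.call(rbind, strsplit(toupper(alignment), ""))
  out <- list()
  for (s in seq_len(ncol - window + 1L)) {
    W <- M[, s:(s + window - 1L), drop = FALSE]
    if (any(W == "-" | W == ".")) next
    cons <- character(window)
    ok <- TRUE
    for (j in seq_len(window)) {
      bases <- unlist(IUPAC_SETS[W[, j]], use.names = FALSE)
      tab <- table(bases) / length(bases)
      keep <- names(tab)[tab >= min_base_freq]
      if (length(keep) == 0) keep <- names(tab)[which.max(tab)]
      code <- names(IUPAC_SETS)[vapply(IUPAC_SETS, function(set)
        setequal(set, keep), TRUE)]
      if (length(code) == 0) { ok <- FALSE; break }
      cons[j] <- code
    }
    if (!ok) next
    seq <- paste(cons, collapse = "")
    deg <- degeneracy(seq)
    if (deg > max_degeneracy) next
    matched <- vapply(seq_len(nrow(W)), function(r)
      all(mapply(function(tb, pc) all(IUPAC_SETS[[tb]] %in% IUPAC_SETS[[pc]]),
                 W[r, ], cons)), TRUE)
    out[[length(out) + 1L]] <- data.frame(
      start = s - 1L, seq = seq, degeneracy = deg,
      coverage = mean(matched), stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(start = integer(0), seq = character(0),
                      degeneracy = integer(0), coverage = numeric(0)))
  do.call(rbind, out)
}
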
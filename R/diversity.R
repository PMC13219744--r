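#' Rarefy a count vector to a fixed depth
#'
#' Draws `depth` reads without replacement (multivariate hypergeometric),
#' the standard rarefaction model for "subsampled reads". Bit-reproducible
#' for a fixed seed; the caller's random-number state is left untouched
#' when a seed is given.
#'
#' @param counts non-negative integer vector.
#' @param depth number of reads to keep; must not exceed `sum(counts)`.
#' @param seed optional integer seed.
#' @return integer vector of the same length summing to `depth`, or `NULL`
#'   (with a warning) when `depth > sum(counts)`.
#' @export
subsample <- function(counts, depth, seed = NULL) {
  total <- sum(counts)
  if (depth > total) {
    warning(sprintf("depth %d exceeds library size %d; sample skipped",
                    depth, total), call. = FALSE)
    return(NULL)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  if (depth == total) return(as.integer(counts))
  # draw without replacement from the expanded read pool
  pool <- rep.int(seq_along(counts), counts)
  tabulate(sample(pool, depth, replace = FALSE), nbins = length(counts))
}

#' Alpha-diversity metrics of a count vector
#'
#' Observed richness (number of non-zero features), Shannon index in
#' natural log, and the Gini-Simpson index 1 - sum(p^2).
#'
#' @param counts non-negative vector with positive sum.
#' @return list with `observed`, `shannon`, `simpson`.
#' @export
alpha_metrics <- function(counts) {
  if (sum(counts) <= 0) stop("all-zero count vector", call. = FALSE)
  p <- counts[counts > 0] / sum(counts)
  list(observed = length(p),
       shannon = -sum(p * log(p)),
       simpson = 1 - sum(p^2))
}

#' Subsampled alpha-diversity profile of a count matrix
#'
#' For every sample x depth x replicate, rarefies the sample to the depth
#' and computes [alpha_metrics()]. Samples shallower than a depth are
#' skipped with a warning, not an error.
#'
#' @param counts integer matrix, rows = features, columns = samples.
#' @param depths subsampling depths (default 100, 1000, 10000 reads).
#' @param reps replicates per sample x depth (default 10).
#' @param seed integer seed for the whole profile.
#' @return data.frame with columns `sample`, `depth`, `replicate`,
#'   `observed`, `shannon`, `simpson`.
#' @export
rarefaction_profile <- function(counts, depths = c(100, 1000, 10000),
                                reps = 10, seed = 1) {
  stopifnot(reps >= 1)
  out <- list()
  for (s in seq_len(ncol(counts))) {
    for (d in depths) {
      for (r in seq_len(reps)) {
        sub <- subsample(counts[, s], d,
                         seed = seed + 7919L * s + 104729L * match(d, depths) + r)
        if (is.null(sub)) next
        am <- alpha_metrics(sub)
        out[[length(out) + 1L]] <- data.frame(
          sample = colnames(counts)[s], depth = d, replicate = r,
          observed = am$observed, shannon = am$shannon, simpson = am$simpson,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(sample = character(0), depth = numeric(0),
                      replicate = integer(0), observed = integer(0),
                      shannon = numeric(0), simpson = numeric(0)))
  do.call(rbind, out)
}

#' Mean and standard deviation per sample x depth of a rarefaction profile
#'
#' @param profile result of [rarefaction_profile()].
#' @return data.frame with per-cell means and sds of the three metrics.
#' @export
summarize_rarefaction <- function(profile) {
  agg <- stats::aggregate(profile[, c("observed", "shannon", "simpson")],
                          by = profile[, c("sample", "depth")],
                          function(x) c(mean = mean(x), sd = stats::sd(x)))
  data.frame(sample = agg$sample, depth = agg$depth,
             observed_mean = agg$observed[, "mean"], observed_sd = agg$observed[, "sd"],
             shannon_mean = agg$shannon[, "mean"], shannon_sd = agg$shannon[, "sd"],
             simpson_mean = agg$simpson[, "mean"], simpson_sd = agg$simpson[, "sd"])
}
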
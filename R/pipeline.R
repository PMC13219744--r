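PIPELINE_SCHEMA <- list(
  seed = "integer", out_dir = "character",
  synth = "list", inputs = "list",
  verify = c("min_identity", "min_norm_score", "min_length"),
  otu = c("threshold"),
  diversity = c("depths", "reps"),
  taxonomy = c("floor", "rank"),
  enrich = c("alpha"))

#' Validate a pipeline configuration
#'
#' The configuration is a named list (usually parsed from YAML): a `seed`,
#' an `out_dir`, either a `synth` block (passed to [synth_config()]) or an
#' `inputs` block with paths (`protein_fasta`, `alignment_fasta`,
#' `tree_newick`, `metadata_tsv`, `nt_fasta`, `asv_fasta`, `counts_tsv`,
#' `condition_tsv`), and optional per-stage parameter blocks (`verify`,
#' `otu`, `diversity`, `taxonomy`, `enrich`). Unknown keys are rejected.
#'
#' @param config named list or path to a YAML file.
#' @return the validated config list.
#' @export
pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), names(PIPELINE_SCHEMA))
  if (length(unknown) > 0)
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  for (blk in c("verify", "otu", "diversity", "taxonomy", "enrich")) {
    extra <- setdiff(names(config[[blk]]), PIPELINE_SCHEMA[[blk]])
    if (length(extra) > 0)
      stop(sprintf("unknown keys in '%s' block: %s", blk,
                   paste(extra, collapse = ", ")), call. = FALSE)
  }
  if (is.null(config$synth) && is.null(config$inputs))
    stop("config needs a 'synth' or an 'inputs' block", call. = FALSE)
  if (is.null(config$seed)) config$seed <- 42L
  if (is.null(config$out_dir)) stop("config needs out_dir", call. = FALSE)
  config
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the full amplicon-analysis pipeline
#'
#' Orchestrates reference loading (or synthesis), ASV verification
#' (translation + homology filter), phylogenetic placement with jplace
#' export, OTU clustering, subsampled alpha diversity, taxonomy
#' assignment and differential abundance, writing per-stage TSVs, summary
#' tables (per-sample verified/excluded proportions of reads and ASVs;
#' per-clade ASV composition) and a run manifest to `out_dir`.
#' Deterministic given the config.
#'
#' @param config named list or YAML path, see [pipeline_config()].
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config) {
  config <- pipeline_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tool = sprintf("sqamp %s",
                                  as.character(utils::packageVersion("sqamp"))),
                   seed = config$seed, stages = list())

  if (!is.null(config$synth)) {
    sc <- stage("synth", do.call(synth_config,
                                 c(list(seed = config$seed), config$synth)))
    ref_sim <- stage("synth", simulate_reference(sc))
    amp <- stage("synth", simulate_amplicons(ref_sim))
    resource <- ref_sim$resource
    asvs <- amp$asvs; counts <- amp$counts; condition <- amp$condition
    indir <- file.path(out, "inputs")
    write_reference(resource, indir)
    write_asv_fasta(asvs, file.path(indir, "asvs.fasta"))
    write_counts_tsv(counts, file.path(indir, "asv_counts.tsv"), "asv_id")
    utils::write.table(amp$truth, file.path(indir, "synthetic_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    paths <- config$inputs
    resource <- stage("resources", load_reference(
      paths$protein_fasta, paths$alignment_fasta, paths$tree_newick,
      paths$metadata_tsv, nt_fasta = paths$nt_fasta))
    asvs <- stage("resources", read_asv_fasta(paths$asv_fasta))
    counts <- stage("resources", read_counts_tsv(paths$counts_tsv))
    cond <- utils::read.delim(paths$condition_tsv, stringsAsFactors = FALSE)
    condition <- stats::setNames(cond[[2]], cond[[1]])
  }
  manifest$stages$resources <- list(n_entries = nrow(resource$entries),
                                    n_asvs = nrow(asvs),
                                    total_reads = sum(counts))

  vcfg <- config$verify
  verdicts <- stage("verify", do.call(verify_asvs,
                                      c(list(asvs, resource), vcfg)))
  utils::write.table(verdicts[, setdiff(names(verdicts), "peptide")],
                     file.path(out, "verify_verdicts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$verify <- list(candidates = sum(verdicts$status == "candidate"),
                                 excluded = sum(verdicts$status != "candidate"))

  placed <- stage("place", place_asvs(verdicts, resource, counts))
  utils::write.table(placed$table, file.path(out, "placements.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(placed$placements) > 0)
    write_jplace(placed$placements, resource, file.path(out, "placements.jplace"))
  final <- placed$table
  manifest$stages$place <- list(verified = sum(final$verified),
                                excluded = sum(!final$verified))

  # Per-sample verified/excluded proportions of reads and of ASVs
  ver_ids <- final$id[final$verified]
  in_counts <- rownames(counts) %in% final$id
  prop <- data.frame(
    sample = colnames(counts),
    reads_total = colSums(counts),
    reads_verified_pct = 100 * colSums(counts[rownames(counts) %in% ver_ids, ,
                                              drop = FALSE]) / colSums(counts),
    asvs_total = colSums(counts > 0),
    asvs_verified_pct = 100 * colSums(counts[rownames(counts) %in% ver_ids, ,
                                             drop = FALSE] > 0) /
      pmax(colSums(counts > 0), 1))
  utils::write.table(prop, file.path(out, "verified_proportions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ver_asvs <- asvs[asvs$id %in% ver_ids, , drop = FALSE]
  ver_counts <- counts[rownames(counts) %in% ver_ids, , drop = FALSE]
  ver_asvs$total_count <- rowSums(ver_counts)[ver_asvs$id]

  clusters <- stage("otu", cluster_greedy(
    ver_asvs, threshold = config$otu$threshold %||% 0.9))
  if (length(clusters) > 0) {
    utils::write.table(otu_membership(clusters),
                       file.path(out, "otu_membership.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    ocounts <- otu_counts(clusters, ver_counts)
    write_counts_tsv(ocounts, file.path(out, "otu_counts.tsv"), "otu_id")
  }
  manifest$stages$otu <- list(n_otus = length(clusters),
                              n_members = nrow(ver_asvs))

  depths <- config$diversity$depths %||% c(100, 1000, 10000)
  reps <- config$diversity$reps %||% 10
  div <- withCallingHandlers(
    stage("diversity", rarefaction_profile(ver_counts, depths, reps,
                                           seed = config$seed)),
    warning = function(w) { message("diversity: ", conditionMessage(w))
      invokeRestart("muffleWarning") })
  utils::write.table(div, file.path(out, "alpha_diversity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest$stages$diversity <- list(rows = nrow(div))

  # taxonomy against the bundle's own protein set (stand-in genome DB when
  # no external database is configured)
  db <- data.frame(id = resource$entries$id,
                   protein = resource$entries$protein_seq,
                   taxonomy = resource$entries$taxonomy,
                   stringsAsFactors = FALSE)
  ver_pep <- verdicts[verdicts$id %in% ver_ids, c("id", "peptide")]
  if (nrow(ver_pep) > 0) {
    assign_ <- stage("taxonomy", classify_asvs(
      ver_pep, db, floor = config$taxonomy$floor %||% 0.9))
    utils::write.table(assign_, file.path(out, "taxonomy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    comp <- stage("taxonomy", clade_composition(
      final[final$verified, c("id", "clade_id")], assign_,
      rank = config$taxonomy$rank %||% "class"))
    utils::write.table(comp, file.path(out, "clade_composition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$taxonomy <- list(
      classified = sum(assign_$ranks != "unclassified"),
      unclassified = sum(assign_$ranks == "unclassified"))
  }

  if (length(unique(condition[colnames(counts)])) == 2) {
    enr <- stage("enrich", nb_wald_test(ver_counts,
                                        condition[colnames(ver_counts)],
                                        alpha = config$enrich$alpha %||% 0.01))
    utils::write.table(enr, file.path(out, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$stages$enrich <- list(significant = sum(enr$significant))
  }

  # read-count conservation across the verify/place boundary
  stopifnot(sum(counts) == sum(counts[rownames(counts) %in% ver_ids, ]) +
              sum(counts[!rownames(counts) %in% ver_ids, ]))
  manifest$outputs <- sort(list.files(out, recursive = TRUE))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
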
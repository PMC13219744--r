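## Maximum-likelihood evolutionary placement of query peptides on a fixed
## reference tree. For every edge the query is attached at the edge
## midpoint by a pendant branch whose length is optimized; the edge with
## the highest log-likelihood wins and like-weight ratios are reported
## over all edges. Conditional likelihoods of the reference tree are
## query-independent and computed once per (resource, model) by a
## message-passing form of Felsenstein pruning with per-site scaling.

# directed-message engine; returns per-edge site factors S_e = pi * C_parent
# * C_child at the edge midpoint (20 x nsite) plus accumulated log-scalers
make_engine <- function(resource, model) {
  ed <- resource$edges
  tree <- resource$tree
  ntip <- length(tree$tip.label)
  m <- nchar(resource$alignment[[1]])
  tipmats <- lapply(stats::setNames(tree$tip.label, tree$tip.label),
                    function(id) tip_matrix(resource$alignment[[id]], model))
  nb <- list()   # per node: data.frame(edge_row, other)
  for (k in seq_len(nrow(ed))) {
    p <- as.character(ed$parent[k]); c_ <- as.character(ed$child[k])
    nb[[p]] <- rbind(nb[[p]], data.frame(k = k, other = ed$child[k]))
    nb[[c_]] <- rbind(nb[[c_]], data.frame(k = k, other = ed$parent[k]))
  }
  memo <- new.env(parent = emptyenv())
  # belief at node u excluding the edge towards node v (NA = none excluded)
  belief <- function(u, v) {
    if (u <= ntip) {
      lab <- tree$tip.label[u]
      return(list(M = tipmats[[lab]], ls = numeric(m)))
    }
    rows <- nb[[as.character(u)]]
    rows <- rows[is.na(v) | rows$other != v, , drop = FALSE]
    M <- matrix(1, 20, m); ls <- numeric(m)
    for (i in seq_len(nrow(rows))) {
      mm <- msg(rows$other[i], u, rows$k[i])
      M <- M * mm$M; ls <- ls + mm$ls
    }
    sc <- apply(M, 2, max)
    sc[sc <= 0] <- 1
    list(M = M / rep(sc, each = 20), ls = ls + log(sc))
  }
  # message from u into v along edge row k: P(t) %*% belief(u, excl v)
  msg <- function(u, v, k) {
    key <- paste(u, v, sep = ">")
    if (!is.null(memo[[key]])) return(memo[[key]])
    B <- belief(u, v)
    P <- transition_matrix(model, ed$length[k])
    out <- list(M = P %*% B$M, ls = B$ls)
    memo[[key]] <- out
    out
  }
  edge_site_factors <- function(edge_id) {
    k <- which(ed$edge_id == edge_id)
    if (length(k) != 1) stop("unknown edge id: ", edge_id, call. = FALSE)
    Ph <- transition_matrix(model, ed$length[k] / 2)
    Bp <- belief(ed$parent[k], ed$child[k])
    Bc <- belief(ed$child[k], ed$parent[k])
    S <- model$pi * (Ph %*% Bp$M) * (Ph %*% Bc$M)
    list(S = S, ls = Bp$ls + Bc$ls)
  }
  list(edge_site_factors = edge_site_factors, belief = belief,
       edges = ed, nsite = m)
}

#' Log-likelihood of the reference tree with a query attached to one edge
#'
#' The query is attached by a pendant branch at the midpoint of `edge_id`
#' under a reversible amino-acid model; computed by pruning in log space
#' with per-node scaling (never returns -Inf for finite input). Gap and X
#' states contribute ones (missing data).
#'
#' @param resource a `reference_resource`.
#' @param query result of [align_query()] (list with `row`), or a gapped
#'   row string in reference column space.
#' @param edge_id 0-based edge id (see `resource$edges`).
#' @param pendant pendant branch length, >= 0.
#' @param model an [substitution_model()]; default LG.
#' @param engine optional precomputed engine (internal reuse).
#' @return log-likelihood (natural log).
#' @export
edge_log_likelihood <- function(resource, query, edge_id, pendant,
                                model = substitution_model("LG"),
                                engine = NULL) {
  if (is.list(query)) query <- query$row
  if (is.null(engine)) engine <- make_engine(resource, model)
  ef <- engine$edge_site_factors(edge_id)
  Tq <- tip_matrix(query, model)
  Cq <- transition_matrix(model, pendant) %*% Tq
  site <- colSums(ef$S * Cq)
  site[site < 1e-300] <- 1e-300
  sum(log(site) + ef$ls)
}

#' Log-likelihood of the reference tree alone
#'
#' @param resource a `reference_resource`.
#' @param model an [substitution_model()].
#' @return log-likelihood (natural log).
#' @export
reference_loglik <- function(resource, model = substitution_model("LG")) {
  engine <- make_engine(resource, model)
  ed <- resource$edges
  k <- 1L
  Bp <- engine$belief(ed$parent[k], ed$child[k])
  Bc <- engine$belief(ed$child[k], ed$parent[k])
  P <- transition_matrix(model, ed$length[k])
  site <- colSums((model$pi * Bp$M) * (P %*% Bc$M))
  sum(log(site) + Bp$ls + Bc$ls)
}

# per-edge clade ids: contiguous runs of edges sharing target/non-target
# status (components of the edge-adjacency graph restricted to one
# status), numbered 1.. in order of each run's smallest edge id
edge_clades <- function(resource) {
  ed <- resource$edges
  tset <- target_edges(resource)
  status <- ed$edge_id %in% tset
  n <- nrow(ed)
  comp <- rep(NA_integer_, n)
  nodes_of <- function(i) c(ed$parent[i], ed$child[i])
  cur <- 0L
  for (i in order(ed$edge_id)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    stack <- i
    while (length(stack) > 0) {
      a <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (!is.na(comp[a])) next
      comp[a] <- cur
      for (b in seq_len(n)) {
        if (is.na(comp[b]) && status[b] == status[a] &&
            length(intersect(nodes_of(a), nodes_of(b))) > 0)
          stack <- c(stack, b)
      }
    }
  }
  data.frame(edge_id = ed$edge_id, target = status, clade_id = comp)
}

#' Place a query peptide on the reference tree
#'
#' Evaluates every edge of the reference tree, optimizing the pendant
#' branch length on `pendant_bounds` (Brent / golden-section, tolerance
#' `tol`); reports the maximum-likelihood edge, like-weight ratios over
#' all edges, the clade id of the best edge, and the verification verdict
#' (best edge inside the target clade, stem included).
#'
#' @param resource a `reference_resource`.
#' @param query result of [align_query()] or a gapped row string.
#' @param model an [substitution_model()]; default LG.
#' @param pendant_bounds search interval for the pendant length.
#' @param tol optimizer tolerance.
#' @param asv_id optional query name carried into the result.
#' @param multiplicity read count carried into jplace output.
#' @param engine optional precomputed engine (reused across queries).
#' @return object of class `sq_placement`: list with `asv_id`,
#'   `best_edge`, `log_likelihood`, `pendant_length`, `distal_length`,
#'   `lwr` (named by edge id), `clade_id`, `verified`, `multiplicity`.
#' @export
place_query <- function(resource, query, model = substitution_model("LG"),
                        pendant_bounds = c(1e-8, 5), tol = 1e-5,
                        asv_id = "query", multiplicity = 1,
                        engine = NULL) {
  if (is.list(query)) query <- query$row
  if (is.null(engine)) engine <- make_engine(resource, model)
  Tq <- tip_matrix(query, model)
  ed <- engine$edges
  n <- nrow(ed)
  ll <- numeric(n); pend <- numeric(n)
  for (i in seq_len(n)) {
    ef <- engine$edge_site_factors(ed$edge_id[i])
    f <- function(p) {
      Cq <- transition_matrix(model, p) %*% Tq
      site <- colSums(ef$S * Cq)
      site[site < 1e-300] <- 1e-300
      sum(log(site) + ef$ls)
    }
    opt <- stats::optimize(f, interval = pendant_bounds, maximum = TRUE,
                           tol = tol)
    # optimize() never evaluates the boundary: check the lower bound too
    lo <- f(pendant_bounds[1])
    if (lo >= opt$objective) {
      ll[i] <- lo; pend[i] <- pendant_bounds[1]
    } else {
      ll[i] <- opt$objective; pend[i] <- opt$maximum
    }
  }
  lwr <- exp(ll - max(ll)); lwr <- lwr / sum(lwr)
  names(lwr) <- ed$edge_id
  best <- which(ll == max(ll))[1]
  clades <- edge_clades(resource)
  best_id <- ed$edge_id[best]
  structure(list(
    asv_id = asv_id,
    best_edge = best_id,
    log_likelihood = ll[best],
    pendant_length = pend[best],
    distal_length = ed$length[best] / 2,
    lwr = lwr,
    pendant_all = stats::setNames(pend, ed$edge_id),
    clade_id = clades$clade_id[clades$edge_id == best_id],
    verified = best_id %in% target_edges(resource),
    multiplicity = multiplicity), class = "sq_placement")
}

#' @export
print.sq_placement <- function(x, ...) {
  cat(sprintf("<sq_placement> %s -> edge %d (lwr %.3f, logL %.3f, pendant %.2g), %s, clade %d\n",
              x$asv_id, x$best_edge, max(x$lwr), x$log_likelihood,
              x$pendant_length,
              if (x$verified) "verified" else "not verified", x$clade_id))
  invisible(x)
}

#' Align and place all candidate ASVs
#'
#' Runs [align_query()] and [place_query()] for every candidate row of a
#' [verify_asvs()] table; queries whose profile alignment covers less than
#' half of their residues are excluded with reason `unplaceable`.
#'
#' @param verdicts data.frame from [verify_asvs()].
#' @param resource a `reference_resource`.
#' @param counts optional count matrix (rows = ASV ids) supplying jplace
#'   multiplicities (total count per ASV).
#' @param model an [substitution_model()].
#' @return list with `placements` (list of `sq_placement`) and `table`
#'   (data.frame: `id`, `status`, `reason`, `best_edge`, `log_likelihood`,
#'   `lwr_best`, `clade_id`, `verified`).
#' @export
place_asvs <- function(verdicts, resource, counts = NULL,
                       model = substitution_model("LG")) {
  engine <- make_engine(resource, model)
  placements <- list()
  rows <- lapply(seq_len(nrow(verdicts)), function(i) {
    id <- verdicts$id[i]
    if (verdicts$status[i] != "candidate")
      return(data.frame(id = id, status = "excluded",
                        reason = verdicts$reason[i], best_edge = NA_integer_,
                        log_likelihood = NA_real_, lwr_best = NA_real_,
                        clade_id = NA_integer_, verified = FALSE))
    q <- tryCatch(align_query(verdicts$peptide[i], resource),
                  sqamp_unplaceable = function(e) NULL)
    if (is.null(q))
      return(data.frame(id = id, status = "excluded", reason = "unplaceable",
                        best_edge = NA_integer_, log_likelihood = NA_real_,
                        lwr_best = NA_real_, clade_id = NA_integer_,
                        verified = FALSE))
    mult <- if (!is.null(counts) && id %in% rownames(counts))
      sum(counts[id, ]) else 1
    pl <- place_query(resource, q, model = model, asv_id = id,
                      multiplicity = mult, engine = engine)
    placements[[id]] <<- pl
    data.frame(id = id,
               status = if (pl$verified) "verified" else "excluded",
               reason = if (pl$verified) "ok" else "off_target_placement",
               best_edge = pl$best_edge, log_likelihood = pl$log_likelihood,
               lwr_best = max(pl$lwr), clade_id = pl$clade_id,
               verified = pl$verified)
  })
  list(placements = placements, table = do.call(rbind, rows))
}

# newick string of the reference tree with {edge_id} annotations in the
# package's canonical numbering; rooted at the first-file-order leaf
jplace_tree_string <- function(resource) {
  ed <- resource$edges
  tree <- resource$tree
  ntip <- length(tree$tip.label)
  children_of <- split(seq_len(nrow(ed)), ed$parent)
  sub <- function(i) {  # newick for the subtree hanging below edge row i
    v <- ed$child[i]
    kids <- children_of[[as.character(v)]]
    core <- if (v <= ntip) tree$tip.label[v] else
      paste0("(", paste(vapply(kids, sub, ""), collapse = ","), ")")
    sprintf("%s:%g{%d}", core, ed$length[i], ed$edge_id[i])
  }
  root_row <- which(ed$edge_id == 0L)
  root_tip <- ed$parent[root_row]
  paste0("(", tree$tip.label[root_tip], ":0,", sub(root_row), ");")
}

#' Write placements to a jplace (version 3) file
#'
#' @param placements list of `sq_placement` objects.
#' @param resource the `reference_resource` they were placed on.
#' @param path output file.
#' @param min_lwr edges below this like-weight ratio are omitted from a
#'   record (the best edge is always kept).
#' @return invisibly, `path`.
#' @export
write_jplace <- function(placements, resource, path, min_lwr = 0.01) {
  if (length(placements) == 0) stop("no placements to write", call. = FALSE)
  ed <- resource$edges
  recs <- lapply(placements, function(p) {
    keep <- which(p$lwr >= min_lwr | names(p$lwr) == as.character(p$best_edge))
    keep <- keep[order(-p$lwr[keep])]
    rows <- lapply(keep, function(k) {
      eid <- as.integer(names(p$lwr)[k])
      pendant_k <- if (!is.null(p$pendant_all)) p$pendant_all[[as.character(eid)]]
        else p$pendant_length
      list(eid,
           unname(p$log_likelihood + log(p$lwr[k]) - log(max(p$lwr))),
           unname(p$lwr[k]),
           ed$length[ed$edge_id == eid] / 2,
           unname(pendant_k))
    })
    list(p = rows, nm = list(list(p$asv_id, p$multiplicity)))
  })
  doc <- list(version = 3,
              tree = jplace_tree_string(resource),
              placements = unname(recs),
              fields = list("edge_num", "likelihood", "like_weight_ratio",
                            "distal_length", "pendant_length"),
              metadata = list(invocation = "sqamp::write_jplace"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
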
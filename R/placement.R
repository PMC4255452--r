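# Evolutionary placement: score a query against every edge of the fixed
# reference tree. The reference partial likelihoods on both sides of
# every edge are computed once (per tree/alignment/model) and reused for
# every edge and query; per edge only the attachment position, the
# pendant branch and the query's own partial enter the computation, so
# the reference tree is never re-estimated.

.PENDANT_MIN <- 1e-8
.PENDANT_MAX <- 10
.PENDANT_INIT <- 0.1

# log-likelihood of the query attached to edge `row` at distal position x
# (distance from the proximal node) with pendant length qlen
.place_loglik <- function(cache, row, x, qlen, qenc) {
  tree <- cache$tree
  len <- tree$edge.length[row]
  ch <- tree$edge[row, 2]
  site_logs <- lapply(cache$cats, function(cat) {
    r <- cat$rate
    A <- transition_probs(cache$model, (len - x) * r) %*% cat$down[[ch]]
    B <- transition_probs(cache$model, x * r) %*% cat$U[[row]]
    Cq <- transition_probs(cache$model, qlen * r) %*% qenc
    v <- colSums(cache$pi * A * B * Cq)
    log(v) + cat$dsc[[ch]] + cat$Usc[[row]]
  })
  .combine_cats(site_logs)
}

.optimize_placement <- function(cache, row, qenc, tol = 1e-6,
                                max_iter = 32L) {
  len <- cache$tree$edge.length[row]
  x <- len / 2
  qlen <- .PENDANT_INIT
  ll <- .place_loglik(cache, row, x, qlen, qenc)
  for (it in seq_len(max_iter)) {
    prev <- ll
    op <- stats::optimize(function(p) .place_loglik(cache, row, x, p, qenc),
                          interval = c(.PENDANT_MIN, .PENDANT_MAX),
                          maximum = TRUE, tol = 1e-4)
    if (op$objective > ll) { qlen <- op$maximum; ll <- op$objective }
    if (len > 1e-9) {
      ox <- stats::optimize(function(d) .place_loglik(cache, row, d, qlen, qenc),
                            interval = c(0, len), maximum = TRUE, tol = 1e-4)
      if (ox$objective > ll) { x <- ox$maximum; ll <- ox$objective }
    }
    if (ll - prev < tol) break
  }
  list(loglik = ll, distal = x, pendant = qlen)
}

#' Score one candidate attachment edge for a query
#'
#' Attaches the query by a new node splitting the given edge, optimizing
#' the pendant branch length and the attachment position coordinate-wise
#' while all reference branch lengths and the topology stay untouched.
#'
#' @param refpkg a `pia_refpkg` (tree, reference alignment, model), or a
#'   prepared placement cache from [placement_cache()].
#' @param masked_query_row query expressed on reference columns (see
#'   [mask_query_to_ref()]).
#' @param edge_id the edge to evaluate.
#' @return list with `loglik`, `pendant_length` and `distal_length`.
#' @export
place_on_edge <- function(refpkg, masked_query_row, edge_id) {
  cache <- placement_cache(refpkg)
  if (nchar(masked_query_row) != cache$S) {
    stop("query row length ", nchar(masked_query_row),
         " does not match reference width ", cache$S)
  }
  row <- .edge_row(cache$tree, edge_id)
  qenc <- .encode_partial(masked_query_row)
  opt <- .optimize_placement(cache, row, qenc)
  list(loglik = opt$loglik, pendant_length = opt$pendant,
       distal_length = opt$distal)
}

#' Prepare (or pass through) a placement cache
#'
#' Computes the bidirectional reference partials once so that many
#' queries/edges can be placed without recomputation.
#'
#' @param refpkg a `pia_refpkg`, or an existing cache (returned as is).
#' @return placement cache.
#' @export
placement_cache <- function(refpkg) {
  if (!is.null(refpkg$cats)) return(refpkg)  # already a cache
  .partials_cache(refpkg$tree, refpkg$ref_alignment, refpkg$model)
}

#' Evolutionary placement of a query on all edges
#'
#' Evaluates every edge of the reference tree, ranks the candidate
#' placements by log-likelihood, and reports likelihood weight ratios
#' `lwr_i = exp(logL_i - logL_max) / sum_j exp(logL_j - logL_max)`.
#' Near-ties in log-likelihood (< 1e-9) are broken by the smaller edge id.
#'
#' @param refpkg a `pia_refpkg` or placement cache.
#' @param masked_query_row query on reference columns.
#' @param query_id id recorded on the placements.
#' @param keep number of top placements to report (default: all edges).
#' @return data.frame of class `pia_placements`: query_id, edge_id,
#'   log_likelihood, lwr, distal_length, pendant_length, best flag;
#'   sorted by descending log-likelihood.
#' @export
epa_place <- function(refpkg, masked_query_row, query_id = "query",
                      keep = Inf) {
  cache <- placement_cache(refpkg)
  tree <- cache$tree
  if (length(tree$tip.label) < 3L) {
    stop("degenerate reference tree: need >= 3 tips")
  }
  if (nchar(masked_query_row) != cache$S) {
    stop("query row length ", nchar(masked_query_row),
         " does not match reference width ", cache$S)
  }
  qenc <- .encode_partial(masked_query_row)
  E <- n_edges(tree)
  res <- lapply(seq_len(E), function(row) {
    opt <- .optimize_placement(cache, row, qenc)
    data.frame(query_id = query_id, edge_id = tree$edge_id[row],
               log_likelihood = opt$loglik, distal_length = opt$distal,
               pendant_length = opt$pendant, stringsAsFactors = FALSE)
  })
  pl <- do.call(rbind, res)
  # lwr over all evaluated edges
  w <- exp(pl$log_likelihood - max(pl$log_likelihood))
  pl$lwr <- w / sum(w)
  # sort: descending logL, ties (< 1e-9) by smaller edge_id
  ord <- order(-round(pl$log_likelihood / 1e-9) * 1e-9, pl$edge_id)
  pl <- pl[ord, , drop = FALSE]
  if (is.finite(keep)) pl <- utils::head(pl, as.integer(keep))
  pl$best <- seq_len(nrow(pl)) == 1L
  rownames(pl) <- NULL
  pl <- pl[, c("query_id", "edge_id", "log_likelihood", "lwr",
               "distal_length", "pendant_length", "best")]
  class(pl) <- c("pia_placements", "data.frame")
  pl
}

# ---- jplace ------------------------------------------------------------

.JPLACE_FIELDS <- c("edge_num", "likelihood", "like_weight_ratio",
                    "distal_length", "pendant_length")

#' Write placements to a jplace (version 3) file
#'
#' @param placements a `pia_placements` data.frame (possibly several
#'   queries concatenated); may have zero rows.
#' @param tree the reference `pia_tree` whose edge ids the placements use.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_jplace <- function(placements, tree, path) {
  tree <- as_pia_tree(tree)
  if (nrow(placements) > 0 &&
      !all(placements$edge_id %in% tree$edge_id)) {
    stop("placement edge_num not present in tree")
  }
  by_query <- split(placements, placements$query_id)
  entries <- lapply(names(by_query), function(qid) {
    p <- by_query[[qid]]
    mat <- lapply(seq_len(nrow(p)), function(i) {
      list(p$edge_id[i], p$log_likelihood[i], p$lwr[i],
           p$distal_length[i], p$pendant_length[i])
    })
    list(p = mat, n = list(qid))
  })
  doc <- list(version = 3L,
              tree = newick_string(tree, tags = TRUE, digits = 12),
              placements = entries,
              fields = as.list(.JPLACE_FIELDS),
              metadata = list(invocation = "pia"))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a jplace (version 3) file
#'
#' @param path jplace file written by [write_jplace()] (or compatible).
#' @return list with `tree` (a `pia_tree`) and `placements` (a
#'   `pia_placements` data.frame; `best` flags the top placement per
#'   query).
#' @export
read_jplace <- function(path) {
  doc <- jsonlite::read_json(path)
  fields <- unlist(doc$fields)
  if (!all(.JPLACE_FIELDS %in% fields)) {
    stop("jplace file missing required fields")
  }
  tree <- read_newick(doc$tree)
  rows <- list()
  for (entry in doc$placements) {
    qid <- unlist(entry$n)[1]
    for (p in entry$p) {
      v <- stats::setNames(unlist(p), fields)
      rows[[length(rows) + 1L]] <- data.frame(
        query_id = qid, edge_id = as.integer(v[["edge_num"]]),
        log_likelihood = as.numeric(v[["likelihood"]]),
        lwr = as.numeric(v[["like_weight_ratio"]]),
        distal_length = as.numeric(v[["distal_length"]]),
        pendant_length = as.numeric(v[["pendant_length"]]),
        stringsAsFactors = FALSE)
    }
  }
  pl <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(query_id = character(0), edge_id = integer(0),
               log_likelihood = numeric(0), lwr = numeric(0),
               distal_length = numeric(0), pendant_length = numeric(0),
               stringsAsFactors = FALSE)
  if (nrow(pl) > 0 && !all(pl$edge_id %in% tree$edge_id)) {
    stop("jplace edge_num not present in tree")
  }
  if (nrow(pl) > 0) {
    pl$best <- stats::ave(pl$log_likelihood, pl$query_id,
                          FUN = function(x) seq_along(x) == 1L) == 1
  } else {
    pl$best <- logical(0)
  }
  class(pl) <- c("pia_placements", "data.frame")
  list(tree = tree, placements = pl)
}
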
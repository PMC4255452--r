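# Felsenstein pruning over edge-numbered trees, with cached partial
# likelihood vectors on both sides of every edge. The caches make branch
# optimization and per-edge query placement a 1-D problem that never
# recomputes the whole tree: for a reversible model, rooting the tree at
# any point v on an edge gives
#   L(site) = sum_a pi_a * down_v(a) * up_v(a)
# where down/up are conditional likelihoods of the data on either side.

# residue string -> 20 x S indicator matrix; gaps / X / ? are missing
# data (columns of ones), stops and other letters are an error
.encode_partial <- function(residues) {
  chars <- strsplit(toupper(residues), "")[[1]]
  S <- length(chars)
  M <- matrix(0, 20L, S)
  idx <- match(chars, .aa_order)
  missing <- chars %in% c("-", "X", "?")
  if (any(is.na(idx) & !missing)) {
    stop("illegal residue '", chars[is.na(idx) & !missing][1],
         "' in sequence data")
  }
  M[cbind(idx[!missing], which(!missing))] <- 1
  M[, missing] <- 1
  M
}

.encode_tips <- function(tree, aln) {
  rows <- match(tree$tip.label, names(aln))
  if (anyNA(rows)) {
    stop("alignment has no row for tip '",
         tree$tip.label[is.na(rows)][1], "'")
  }
  lapply(unclass(aln)[rows], .encode_partial)
}

.col_rescale <- function(M, sc) {
  mx <- apply(M, 2, max)
  pos <- mx > 0
  if (!all(pos)) stop("zero likelihood column (conflicting data)")
  list(M = M / rep(mx, each = nrow(M)), sc = sc + log(mx))
}

.logsumexp <- function(M) {
  # rows = categories, columns = sites
  mx <- apply(M, 2, max)
  mx + log(colSums(exp(M - rep(mx, each = nrow(M)))))
}

# Full bidirectional partials cache for (tree, alignment, model).
# For every edge row: D = down partial at the child (subtree below),
# U = partial at the parent of everything outside the child's subtree,
# each with per-site log scaling; one set per gamma category.
.partials_cache <- function(tree, aln, model) {
  tree <- as_pia_tree(tree)
  enc <- .encode_tips(tree, aln)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- tree$edge[1, 1]
  E <- nrow(tree$edge)
  S <- ncol(enc[[1]])
  pi <- as.numeric(model$freqs)
  kids <- split(seq_len(E), tree$edge[, 1])

  cats <- lapply(model$rates, function(rate) {
    P <- lapply(seq_len(E), function(r) {
      transition_probs(model, tree$edge.length[r] * rate)
    })
    down <- vector("list", nnode)
    dsc <- vector("list", nnode)
    for (i in seq_len(ntip)) { down[[i]] <- enc[[i]]; dsc[[i]] <- numeric(S) }
    for (r in rev(seq_len(E))) {   # reverse cladewise = postorder
      p <- tree$edge[r, 1]; ch <- tree$edge[r, 2]
      contrib <- P[[r]] %*% down[[ch]]
      if (is.null(down[[p]])) {
        down[[p]] <- contrib; dsc[[p]] <- dsc[[ch]]
      } else {
        down[[p]] <- down[[p]] * contrib
        dsc[[p]] <- dsc[[p]] + dsc[[ch]]
      }
    }
    for (nd in (ntip + 1L):nnode) {
      rs <- .col_rescale(down[[nd]], dsc[[nd]])
      down[[nd]] <- rs$M; dsc[[nd]] <- rs$sc
    }
    # up partials, preorder (cladewise order guarantees parent before child)
    U <- vector("list", E); Usc <- vector("list", E)
    upnode <- vector("list", nnode); upsc <- vector("list", nnode)
    upnode[[root]] <- matrix(1, 20L, S); upsc[[root]] <- numeric(S)
    for (r in seq_len(E)) {
      p <- tree$edge[r, 1]; ch <- tree$edge[r, 2]
      u <- upnode[[p]]; sc <- upsc[[p]]
      for (s in kids[[as.character(p)]]) {
        if (s == r) next
        u <- u * (P[[s]] %*% down[[tree$edge[s, 2]]])
        sc <- sc + dsc[[tree$edge[s, 2]]]
      }
      rs <- .col_rescale(u, sc)
      U[[r]] <- rs$M; Usc[[r]] <- rs$sc
      if (ch > ntip) {
        rs <- .col_rescale(P[[r]] %*% U[[r]], Usc[[r]])
        upnode[[ch]] <- rs$M; upsc[[ch]] <- rs$sc
      }
    }
    list(P = P, down = down, dsc = dsc, U = U, Usc = Usc,
         root_site_log = log(colSums(pi * down[[root]])) + dsc[[root]],
         rate = rate)
  })
  list(tree = tree, model = model, pi = pi, ncat = length(cats),
       S = S, cats = cats, root = root)
}

.combine_cats <- function(site_logs) {
  if (length(site_logs) == 1L) return(sum(site_logs[[1]]))
  M <- do.call(rbind, site_logs)   # categories x sites
  sum(.logsumexp(M) - log(nrow(M)))
}

#' Felsenstein pruning log-likelihood
#'
#' Log-likelihood of a gapped protein alignment on a tree under a
#' reversible substitution model, summing over all ancestral states by
#' the pruning algorithm with per-site scaling. Gaps and X are treated as
#' missing data. With several gamma categories the site likelihood is the
#' mean over categories.
#'
#' @param tree a `pia_tree` whose tip labels index rows of `aln`.
#' @param aln a `pia_alignment` containing one row per tip.
#' @param model a `pia_model`.
#' @return scalar log-likelihood.
#' @export
pruning_loglik <- function(tree, aln, model) {
  cache <- .partials_cache(tree, aln, model)
  .combine_cats(lapply(cache$cats, `[[`, "root_site_log"))
}

# log-likelihood as a function of one edge's length, from the cache
.loglik_edge_t <- function(cache, row, t) {
  site_logs <- lapply(cache$cats, function(cat) {
    P <- transition_probs(cache$model, t * cat$rate)
    ch <- cache$tree$edge[row, 2]
    v <- colSums(cache$pi * cat$U[[row]] * (P %*% cat$down[[ch]]))
    log(v) + cat$Usc[[row]] + cat$dsc[[ch]]
  })
  .combine_cats(site_logs)
}

#' Optimize a single branch length
#'
#' One-dimensional derivative-free maximization of the pruning
#' log-likelihood over one edge's length, holding everything else fixed.
#' The returned log-likelihood never falls below the starting value.
#'
#' @param tree a `pia_tree`.
#' @param edge_id edge to optimize.
#' @param aln tip alignment.
#' @param model a `pia_model`.
#' @param bounds length-2 numeric search interval (substitutions/site).
#' @param tol convergence tolerance on the length.
#' @return list with `length` (optimized), `loglik`, and `tree` (updated).
#' @export
optimize_branch <- function(tree, edge_id, aln, model,
                            bounds = c(1e-8, 10), tol = 1e-6) {
  if (length(bounds) != 2L || bounds[1] <= 0 || bounds[2] <= bounds[1]) {
    stop("invalid bounds")
  }
  tree <- as_pia_tree(tree)
  row <- .edge_row(tree, edge_id)
  cache <- .partials_cache(tree, aln, model)
  f <- function(t) .loglik_edge_t(cache, row, t)
  start_len <- tree$edge.length[row]
  start_ll <- f(max(start_len, bounds[1]))
  opt <- stats::optimize(f, interval = bounds, maximum = TRUE, tol = tol)
  # endpoints: optimize() never samples the boundary exactly
  cand_len <- c(opt$maximum, bounds[1])
  cand_ll <- c(opt$objective, f(bounds[1]))
  best <- which.max(cand_ll)
  if (cand_ll[best] >= start_ll) {
    new_len <- cand_len[best]; new_ll <- cand_ll[best]
  } else {
    new_len <- start_len; new_ll <- start_ll
  }
  tree$edge.length[row] <- new_len
  list(length = new_len, loglik = new_ll, tree = tree)
}
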
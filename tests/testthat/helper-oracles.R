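# Independent oracles used across the suite. These deliberately avoid the
# code paths they check: likelihoods by explicit enumeration of ancestral
# states, local alignment by top-down recursion, placement by grafting a
# new tip and re-running full pruning.

test_model <- substitution_model()

# log-likelihood by explicit summation over all internal-node state
# assignments (feasible for <= 4 tips / <= 3 internal nodes)
brute_force_loglik <- function(tree, aln, model) {
  tree <- as_pia_tree(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- tree$edge[1, 1]
  internals <- (ntip + 1L):nnode
  pi <- as.numeric(model$freqs)
  P <- lapply(seq_len(nrow(tree$edge)), function(r) {
    transition_probs(model, tree$edge.length[r])
  })
  aln_m <- aln_matrix(aln)[tree$tip.label, , drop = FALSE]
  aa <- rownames(model$Q)
  total <- 0
  for (site in seq_len(ncol(aln_m))) {
    tip_state <- match(aln_m[, site], aa)
    grid <- as.matrix(expand.grid(rep(list(1:20), length(internals))))
    site_lik <- 0
    for (g in seq_len(nrow(grid))) {
      state <- integer(nnode)
      state[seq_len(ntip)] <- tip_state
      state[internals] <- grid[g, ]
      p <- pi[state[root]]
      for (r in seq_len(nrow(tree$edge))) {
        p <- p * P[[r]][state[tree$edge[r, 1]], state[tree$edge[r, 2]]]
      }
      site_lik <- site_lik + p
    }
    total <- total + log(site_lik)
  }
  total
}

# optimal local alignment score by top-down recursion over (position,
# gap-state), independent of the package's alignment engine
sw_score_oracle <- function(q, t, s) {
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  go <- s$gap_open; ge <- s$gap_extend
  memo <- new.env()
  # best score of an alignment extending to exactly (i, j) in state st
  best_at <- function(i, j, st) {
    key <- paste(i, j, st)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (st == "M") {
      sub <- s$matrix[qc[i], tc[j]]
      prev <- if (i == 1 || j == 1) 0 else {
        max(0, best_at(i - 1, j - 1, "M"), best_at(i - 1, j - 1, "X"),
            best_at(i - 1, j - 1, "Y"))
      }
      sub + prev
    } else if (st == "X") {  # gap in target (q residue i unmatched)
      if (i == 1) -Inf else {
        max(best_at(i - 1, j, "M") + go + ge, best_at(i - 1, j, "X") + ge)
      }
    } else {                 # gap in query
      if (j == 1) -Inf else {
        max(best_at(i, j - 1, "M") + go + ge, best_at(i, j - 1, "Y") + ge)
      }
    }
    memo[[key]] <- val
    val
  }
  best <- 0
  for (i in seq_along(qc)) for (j in seq_along(tc)) {
    best <- max(best, best_at(i, j, "M"))
  }
  best
}

# exhaustive placement oracle: per edge, re-optimize the attachment on a
# freshly grafted tree with full-tree pruning (no caches)
naive_place_edge <- function(tree, aln_plus_query, model, edge_id, qid,
                             n_rounds = 3L) {
  te <- tree_edges(tree)
  len <- te$length[te$edge_id == edge_id]
  x <- len / 2; q <- 0.1
  f <- function(x, q) {
    pruning_loglik(graft_at(tree, edge_id, x, q, qid), aln_plus_query, model)
  }
  ll <- f(x, q)
  for (i in seq_len(n_rounds)) {
    op <- stats::optimize(function(p) f(x, p), c(1e-8, 10), maximum = TRUE,
                          tol = 1e-4)
    if (op$objective > ll) { q <- op$maximum; ll <- op$objective }
    if (len > 1e-9) {
      ox <- stats::optimize(function(d) f(d, q), c(0, len), maximum = TRUE,
                            tol = 1e-4)
      if (ox$objective > ll) { x <- ox$maximum; ll <- ox$objective }
    }
  }
  ll
}

# edges sharing at least one node
edges_adjacent <- function(tree, e1, e2) {
  te <- tree_edges(tree)
  a <- te[te$edge_id == e1, ]; b <- te[te$edge_id == e2, ]
  length(intersect(c(a$parent, a$child), c(b$parent, b$child))) > 0
}

random_protein <- function(n) {
  paste(sample(rownames(test_model$Q), n, replace = TRUE), collapse = "")
}
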
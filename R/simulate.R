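# Fixture generation: random unrooted trees, protein sequence evolution
# along them under the package model, fabricated queries with known true
# placements, and whole simulated reference packages. A single integer
# seed fixes all randomness; the caller's RNG state is left untouched.

.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Random unrooted bifurcating tree
#'
#' Uniform random topology (via `ape::rtopology`) with independent
#' exponential branch lengths; deterministic per seed.
#'
#' @param n_tips number of tips (>= 3).
#' @param seed integer seed.
#' @param mean_branch mean branch length in substitutions/site
#'   (default 0.1).
#' @return a `pia_tree` with `2 * n_tips - 3` edges.
#' @export
random_tree <- function(n_tips, seed = 1L, mean_branch = 0.1) {
  if (n_tips < 3L) stop("n_tips must be >= 3")
  .with_seed(seed, {
    phy <- ape::rtopology(n_tips, rooted = FALSE)
    phy$edge.length <- stats::rexp(nrow(phy$edge), rate = 1 / mean_branch)
    as_pia_tree(phy)
  })
}

#' Evolve a protein alignment along a tree
#'
#' Root states are drawn from the model's stationary frequencies and
#' propagated along each edge with the model's transition probabilities.
#' With several gamma categories each site is assigned a category first.
#' The returned alignment carries the simulated states of every internal
#' node in attribute `node_states` (needed by [make_query()]).
#'
#' @param tree a `pia_tree`.
#' @param model a `pia_model`.
#' @param n_sites number of alignment columns.
#' @param seed integer seed.
#' @return gap-free `pia_alignment` over the tree's tips.
#' @export
evolve <- function(tree, model, n_sites, seed = 1L) {
  tree <- as_pia_tree(tree)
  if (n_sites < 1L) stop("n_sites must be >= 1")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- tree$edge[1, 1]
  pi <- as.numeric(model$freqs)
  .with_seed(seed, {
    rates <- if (model$n_gamma_cats > 1L) {
      model$rates[sample.int(model$n_gamma_cats, n_sites, replace = TRUE)]
    } else rep(1, n_sites)
    states <- matrix(NA_integer_, nnode, n_sites)
    states[root, ] <- sample.int(20L, n_sites, replace = TRUE, prob = pi)
    for (r in seq_len(nrow(tree$edge))) {   # cladewise: parent before child
      p <- tree$edge[r, 1]; ch <- tree$edge[r, 2]
      len <- tree$edge.length[r]
      for (rate in unique(rates)) {
        cols <- which(rates == rate)
        P <- transition_probs(model, len * rate)
        cum <- t(apply(P, 1, cumsum))
        u <- stats::runif(length(cols))
        par_states <- states[p, cols]
        states[ch, cols] <- vapply(seq_along(cols), function(k) {
          sum(cum[par_states[k], ] < u[k]) + 1L
        }, integer(1))
      }
    }
    rows <- vapply(seq_len(ntip), function(i) {
      paste(.aa_order[states[i, ]], collapse = "")
    }, character(1))
    aln <- alignment(stats::setNames(rows, tree$tip.label))
    attr(aln, "node_states") <- states
    attr(aln, "site_rates") <- rates
    aln
  })
}

#' Fabricate a query with a known true placement
#'
#' Attaches a new lineage at the midpoint of a chosen edge and evolves it
#' for the pendant length, starting from the simulated state at the
#' attachment point. Requires the alignment to carry the `node_states`
#' attribute written by [evolve()].
#'
#' @param tree the `pia_tree` used for [evolve()].
#' @param aln the alignment returned by [evolve()].
#' @param model the `pia_model`.
#' @param edge_id edge from which the query truly descends.
#' @param pendant pendant branch length (>= 0).
#' @param seed integer seed.
#' @return list with `seq` (gap-free protein string) and `truth`
#'   (list of `edge_id` and `pendant`).
#' @export
make_query <- function(tree, aln, model, edge_id, pendant, seed = 1L) {
  tree <- as_pia_tree(tree)
  if (pendant < 0) stop("pendant must be >= 0")
  states <- attr(aln, "node_states")
  if (is.null(states)) {
    stop("alignment carries no node_states; use an alignment from evolve()")
  }
  rates <- attr(aln, "site_rates")
  row <- .edge_row(tree, edge_id)
  p <- tree$edge[row, 1]
  ch <- tree$edge[row, 2]
  len <- tree$edge.length[row]
  n_sites <- ncol(states)
  .with_seed(seed, {
    # state at the edge midpoint, conditional on BOTH endpoint states
    # (the true lineage passes through the midpoint):
    # P(mid = s | p = a, c = b) proportional to P_as(l/2) * P_sb(l/2)
    a <- states[p, ]; b <- states[ch, ]
    cur <- integer(n_sites)
    for (rate in unique(rates)) {
      cols <- which(rates == rate)
      Ph <- transition_probs(model, (len / 2) * rate)
      for (k in cols) {
        w <- Ph[a[k], ] * Ph[, b[k]]
        cur[k] <- sample.int(20L, 1L, prob = w)
      }
    }
    # then evolve independently along the pendant branch
    if (pendant > 0) {
      for (rate in unique(rates)) {
        cols <- which(rates == rate)
        P <- transition_probs(model, pendant * rate)
        cum <- t(apply(P, 1, cumsum))
        u <- stats::runif(length(cols))
        cur[cols] <- vapply(seq_along(cols), function(k) {
          sum(cum[cur[cols][k], ] < u[k]) + 1L
        }, integer(1))
      }
    }
    list(seq = paste(.aa_order[cur], collapse = ""),
         truth = list(edge_id = edge_id, pendant = pendant))
  })
}

#' Simulate a complete reference package
#'
#' Random tree, evolved reference alignment, baits taken as the ungapped
#' reference sequences, and a landmark map assigning the first two tips
#' tier LANDMARK1 and the last tip tier LANDMARK2 (by label order).
#'
#' @param family family name.
#' @param n_tips tips in the reference tree.
#' @param n_sites alignment columns.
#' @param seed integer seed.
#' @param model a `pia_model`.
#' @param mean_branch mean branch length for the random tree.
#' @return a validated `pia_refpkg` (alignment rows carry `node_states`).
#' @export
simulate_refpkg <- function(family, n_tips = 8L, n_sites = 200L, seed = 1L,
                            model = substitution_model(),
                            mean_branch = 0.1) {
  tree <- random_tree(n_tips, seed = seed, mean_branch = mean_branch)
  aln <- evolve(tree, model, n_sites, seed = seed + 1L)
  labs <- sort(tree$tip.label)
  lm <- landmark_map(
    tip_id = c(labs[1:2], labs[length(labs)]),
    tier = c("LANDMARK1", "LANDMARK1", "LANDMARK2"))
  pkg <- reference_package(
    family = family,
    baits = stats::setNames(ungap(as.character(aln)), names(aln)),
    ref_alignment = aln, tree = tree, landmarks = lm, model = model,
    manifest = list(created_by = "pia simulate_refpkg", seed = seed,
                    n_tips = n_tips, n_sites = n_sites))
  pkg
}

#' Simulate a transcriptome containing planted family members
#'
#' Back-translates simulated query proteins into transcripts (random
#' synonymous codons, standard genetic code) and pads the collection
#' with unrelated random transcripts, producing a nucleotide FASTA-ready
#' set with known truth.
#'
#' @param refpkg a simulated `pia_refpkg` whose alignment has
#'   `node_states`.
#' @param n_queries number of planted family members.
#' @param n_decoys number of unrelated random transcripts.
#' @param pendant pendant length used for the planted queries.
#' @param edge_ids optional true edges for the planted queries (recycled);
#'   default: sampled uniformly.
#' @param seed integer seed.
#' @return list with `transcripts` (named nucleotide vector) and `truth`
#'   (data.frame transcript_id, edge_id, pendant).
#' @export
simulate_transcriptome <- function(refpkg, n_queries = 1L, n_decoys = 3L,
                                   pendant = 0.1, edge_ids = NULL,
                                   seed = 1L) {
  tree <- refpkg$tree
  aln <- refpkg$ref_alignment
  E <- n_edges(tree)
  .with_seed(seed, {
    edge_ids <- if (is.null(edge_ids)) {
      sample(tree$edge_id, n_queries, replace = n_queries > E)
    } else rep_len(edge_ids, n_queries)
    codons <- .codons_by_aa()
    transcripts <- character(0)
    truth <- data.frame(transcript_id = character(0), edge_id = integer(0),
                        pendant = numeric(0), stringsAsFactors = FALSE)
    for (i in seq_len(n_queries)) {
      q <- make_query(tree, aln, refpkg$model, edge_ids[i], pendant,
                      seed = sample.int(1e6, 1))
      id <- sprintf("UN%04d", i)
      aa <- strsplit(q$seq, "")[[1]]
      nt <- vapply(aa, function(a) {
        opts <- codons[[a]]
        opts[sample.int(length(opts), 1)]
      }, character(1))
      transcripts[id] <- paste(nt, collapse = "")
      truth[nrow(truth) + 1L, ] <- list(id, edge_ids[i], pendant)
    }
    for (i in seq_len(n_decoys)) {
      id <- sprintf("UN%04d", n_queries + i)
      transcripts[id] <- paste(sample(c("A", "C", "G", "T"),
                                      90 + 3 * sample.int(40, 1),
                                      replace = TRUE), collapse = "")
    }
    list(transcripts = transcripts, truth = truth)
  })
}

.codons_by_aa <- function() {
  tab <- .codon_table()
  split(names(tab), tab)[.aa_order] |>
    stats::setNames(.aa_order)
}
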
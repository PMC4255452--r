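# Reference packages: the bundled unit of annotation for one gene
# family (baits, reference alignment, edge-numbered tree, landmark map,
# substitution model, manifest). Construction utilities cover
# dereplication of captured sequences, pruning of long-branch tips, and
# branch-length re-optimization on a fixed topology; full topology
# search is deliberately out of scope (topologies come from any external
# tree builder).

#' Construct a reference package
#'
#' @param family gene-family name.
#' @param baits named character vector of bait protein sequences.
#' @param ref_alignment a `pia_alignment` whose row ids equal the tree's
#'   tip set.
#' @param tree a `pia_tree`.
#' @param landmarks a `pia_landmarks` map (may be empty).
#' @param model a `pia_model` (default WAG).
#' @param manifest optional provenance metadata list.
#' @return validated object of class `pia_refpkg`.
#' @export
reference_package <- function(family, baits, ref_alignment, tree,
                              landmarks = landmark_map(character(0), character(0)),
                              model = substitution_model(),
                              manifest = list()) {
  pkg <- structure(
    list(family = family, baits = baits, ref_alignment = ref_alignment,
         tree = as_pia_tree(tree), landmarks = landmarks, model = model,
         manifest = manifest),
    class = "pia_refpkg")
  validate_refpkg(pkg)
  pkg
}

#' Validate a reference package
#'
#' Checks the tree tip set equals the alignment row set, landmark ids
#' resolve to tips, the model is internally consistent, and baits are
#' named.
#'
#' @param pkg a `pia_refpkg`.
#' @return the package, invisibly; stops naming the offending field.
#' @export
validate_refpkg <- function(pkg) {
  if (!nzchar(pkg$family)) stop("refpkg validation: empty family name")
  if (length(pkg$baits) == 0L || is.null(names(pkg$baits))) {
    stop("refpkg validation: baits must be a non-empty named collection")
  }
  tips <- sort(pkg$tree$tip.label)
  rows <- sort(names(pkg$ref_alignment))
  if (!identical(tips, rows)) {
    stop("refpkg validation: tree tip set does not match alignment rows ",
         "(field tree/ref_alignment)")
  }
  suppressWarnings(.check_landmarks(pkg$landmarks, pkg$tree))
  if (!inherits(pkg$model, "pia_model")) {
    stop("refpkg validation: model is not a pia_model")
  }
  invisible(pkg)
}

#' @export
print.pia_refpkg <- function(x, ...) {
  cat("pia_refpkg '", x$family, "': ", length(x$baits), " baits, ",
      length(x$ref_alignment), " reference rows x ",
      aln_ncol(x$ref_alignment), " columns, ",
      length(x$tree$tip.label), " tips\n", sep = "")
  invisible(x)
}

# ---- dereplication ----------------------------------------------------

.pair_identity <- function(a, b, s) {
  short <- min(nchar(a), nchar(b))
  al <- local_align(a, b, s)
  if (al$raw_score == 0) return(0)
  x <- strsplit(al$aligned[1], "")[[1]]
  y <- strsplit(al$aligned[2], "")[[1]]
  sum(x == y & x != "-") / short
}

#' Remove duplicate and near-duplicate sequences
#'
#' At the default threshold 1.0, exact duplicates and exact substrings
#' are removed, keeping the longest representative (ties broken by
#' lexicographic id). At lower thresholds, greedy longest-first
#' clustering removes any sequence whose identity to an already-retained
#' representative (matches over the shorter sequence's length) reaches
#' the threshold.
#'
#' @param seqs named character vector of protein sequences.
#' @param identity_threshold in (0, 1]; default 1.0.
#' @param s scoring scheme used for identity alignment below 1.0.
#' @return list with `retained` (named vector) and `removed` (data.frame
#'   logging every removal and its retained representative).
#' @export
dereplicate <- function(seqs, identity_threshold = 1.0,
                        s = scoring_scheme()) {
  if (length(seqs) == 0L) stop("empty input")
  if (identity_threshold <= 0 || identity_threshold > 1) {
    stop("identity_threshold must be in (0, 1]")
  }
  ord <- order(-nchar(seqs), names(seqs))  # longest first, ties by id
  ids <- names(seqs)[ord]
  kept <- character(0)
  removed <- data.frame(removed_id = character(0),
                        representative = character(0),
                        identity = numeric(0), stringsAsFactors = FALSE)
  for (id in ids) {
    dup_of <- NA_character_; ident <- NA_real_
    for (rep_id in kept) {
      if (identity_threshold >= 1) {
        hit <- identical(seqs[[id]], seqs[[rep_id]]) ||
          grepl(seqs[[id]], seqs[[rep_id]], fixed = TRUE)
        if (hit) { dup_of <- rep_id; ident <- 1; break }
      } else {
        pid <- .pair_identity(seqs[[id]], seqs[[rep_id]], s)
        if (pid >= identity_threshold) { dup_of <- rep_id; ident <- pid; break }
      }
    }
    if (is.na(dup_of)) {
      kept <- c(kept, id)
    } else {
      removed[nrow(removed) + 1L, ] <- list(id, dup_of, ident)
    }
  }
  list(retained = seqs[names(seqs) %in% kept], removed = removed)
}

# ---- long-branch pruning ----------------------------------------------

#' Iteratively remove tips on long terminal branches
#'
#' Removes the tip whose terminal branch exceeds `factor` times the
#' median of all current terminal branch lengths (longest first),
#' recomputing the median after every removal, until no tip exceeds the
#' rule or only 3 tips remain. Alignment rows are dropped in sync when an
#' alignment is supplied.
#'
#' @param tree a `pia_tree` with >= 4 tips.
#' @param aln optional `pia_alignment` to subset alongside.
#' @param factor multiple of the median terminal length (default 10).
#' @return list with `tree`, `aln` (or NULL) and `removed` (data.frame of
#'   tip, branch length and the median at removal time).
#' @export
prune_long_branches <- function(tree, aln = NULL, factor = 10) {
  if (factor <= 1) stop("factor must be > 1")
  tree <- as_pia_tree(tree)
  if (length(tree$tip.label) < 4L) stop("tree too small to prune (< 4 tips)")
  removed <- data.frame(tip = character(0), length = numeric(0),
                        median_at_removal = numeric(0),
                        stringsAsFactors = FALSE)
  repeat {
    ntip <- length(tree$tip.label)
    if (ntip <= 3L) break
    term_rows <- which(tree$edge[, 2] <= ntip)
    lens <- tree$edge.length[term_rows]
    med <- stats::median(lens)
    over <- lens > factor * med
    if (!any(over)) break
    worst <- term_rows[order(-lens, tree$tip.label[tree$edge[term_rows, 2]])][1]
    tip <- tree$tip.label[tree$edge[worst, 2]]
    removed[nrow(removed) + 1L, ] <- list(tip, tree$edge.length[worst], med)
    phy <- ape::drop.tip(tree, tip)
    tree <- as_pia_tree(structure(phy[c("edge", "edge.length", "tip.label",
                                        "Nnode")], class = "phylo"))
  }
  if (!is.null(aln)) {
    aln <- alignment(unclass(aln)[tree$tip.label])
  }
  list(tree = tree, aln = aln, removed = removed)
}

# ---- branch-length re-optimization ------------------------------------

#' Re-optimize all branch lengths on a fixed topology
#'
#' Repeated per-edge one-dimensional optimization sweeps (see
#' [optimize_branch()]); the log-likelihood trace is monotone
#' non-decreasing, and sweeping stops when a full sweep improves the
#' log-likelihood by less than `tol` or after `sweeps` sweeps.
#'
#' @param tree a `pia_tree` whose tips index `aln` rows.
#' @param aln a `pia_alignment`.
#' @param model a `pia_model`.
#' @param sweeps maximum number of full sweeps (default 3).
#' @param tol convergence threshold on per-sweep improvement (default 1e-4).
#' @return list with `tree` (updated lengths), `loglik`, and the
#'   per-update `loglik_trace`.
#' @export
reoptimize_branch_lengths <- function(tree, aln, model, sweeps = 3L,
                                      tol = 1e-4) {
  tree <- as_pia_tree(tree)
  trace <- pruning_loglik(tree, aln, model)
  ll <- trace
  for (sw in seq_len(sweeps)) {
    before <- ll
    for (eid in tree$edge_id) {
      res <- optimize_branch(tree, eid, aln, model)
      tree <- res$tree
      ll <- res$loglik
      trace <- c(trace, ll)
    }
    if (ll - before < tol) break
  }
  list(tree = tree, loglik = ll, loglik_trace = trace)
}

# ---- serialization ----------------------------------------------------

.REFPKG_FILES <- c(baits = "baits.faa", alignment = "ref.aln.faa",
                   tree = "ref.nwk", landmarks = "landmarks.tsv")

#' Write a reference package directory
#'
#' Layout: `manifest.json`, `baits.faa`, `ref.aln.faa`, `ref.nwk` (Newick
#' with `{N}` edge tags), `landmarks.tsv`. The manifest records the
#' family, model settings, creation parameters and per-file md5
#' checksums.
#'
#' @param pkg a `pia_refpkg`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_refpkg <- function(pkg, dir) {
  validate_refpkg(pkg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(pkg$baits, file.path(dir, "baits.faa"))
  write_fasta(unclass(pkg$ref_alignment), file.path(dir, "ref.aln.faa"))
  write_newick(pkg$tree, file.path(dir, "ref.nwk"), tags = TRUE, digits = 12)
  utils::write.table(as.data.frame(pkg$landmarks),
                     file.path(dir, "landmarks.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  sums <- tools::md5sum(file.path(dir, .REFPKG_FILES))
  names(sums) <- .REFPKG_FILES
  model <- pkg$model
  manifest <- c(pkg$manifest, list(
    format_version = "1.0",
    family = pkg$family,
    files = as.list(.REFPKG_FILES),
    md5 = as.list(sums),
    model = list(name = model$name, n_gamma_cats = model$n_gamma_cats,
                 alpha = model$alpha,
                 freqs = if (identical(as.numeric(model$freqs),
                                       .wag_freqs)) "WAG" else
                   as.numeric(model$freqs))))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read and validate a reference package directory
#'
#' @param dir directory written by [write_refpkg()].
#' @return a validated `pia_refpkg`. Missing files, checksum mismatches
#'   and tip/row mismatches raise validation errors naming the field.
#' @export
read_refpkg <- function(dir) {
  man_path <- file.path(dir, "manifest.json")
  if (!file.exists(man_path)) stop("refpkg validation: missing manifest.json")
  manifest <- jsonlite::read_json(man_path)
  files <- unlist(manifest$files)
  for (f in files) {
    if (!file.exists(file.path(dir, f))) {
      stop("refpkg validation: manifest references missing file '", f, "'")
    }
  }
  sums <- tools::md5sum(file.path(dir, files))
  stored <- unlist(manifest$md5)
  bad <- which(unname(sums) != unname(stored[files]))
  if (length(bad) > 0) {
    stop("refpkg validation: checksum mismatch for '", files[bad][1], "'")
  }
  mod <- manifest$model
  freqs <- if (identical(mod$freqs, "WAG")) NULL else unlist(mod$freqs)
  model <- substitution_model(name = if (is.null(mod$name)) "WAG" else mod$name,
                              freqs = freqs,
                              n_gamma_cats = mod$n_gamma_cats,
                              alpha = mod$alpha)
  lm_df <- utils::read.table(file.path(dir, "landmarks.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE,
                             colClasses = "character")
  lm <- if (nrow(lm_df) > 0) {
    landmark_map(lm_df$tip_id, lm_df$tier, lm_df$display_name, lm_df$note)
  } else landmark_map(character(0), character(0))
  keep_meta <- setdiff(names(manifest),
                       c("format_version", "family", "files", "md5", "model"))
  reference_package(
    family = manifest$family,
    baits = read_fasta(file.path(dir, "baits.faa"), "prot"),
    ref_alignment = alignment(read_fasta(file.path(dir, "ref.aln.faa"),
                                         "prot_gapped")),
    tree = read_newick(file.path(dir, "ref.nwk")),
    landmarks = lm, model = model,
    manifest = manifest[keep_meta])
}
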
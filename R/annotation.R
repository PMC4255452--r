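# Interpreting placements against landmark taxa. Landmarks are
# functionally characterized reference genes: tier LANDMARK1 marks genes
# with the sought function, tier LANDMARK2 marks well-characterized but
# functionally distinct relatives (e.g. non-opsin GPCRs on an opsin
# tree). The classification emitted here is advisory context for the
# user's own inspection of the tree, not an orthology assertion.

.TIERS <- c("LANDMARK1", "LANDMARK2", "NONE")

#' Construct a landmark map
#'
#' @param tip_id reference tree tip ids.
#' @param tier one of `"LANDMARK1"`, `"LANDMARK2"`, `"NONE"` per tip.
#' @param display_name optional display names (default: the tip ids).
#' @param note optional free-text source notes.
#' @return data.frame of class `pia_landmarks`.
#' @export
landmark_map <- function(tip_id, tier, display_name = tip_id, note = "") {
  if (length(tip_id) == 0L) {
    lm <- data.frame(tip_id = character(0), tier = character(0),
                     display_name = character(0), note = character(0),
                     stringsAsFactors = FALSE)
    class(lm) <- c("pia_landmarks", "data.frame")
    return(lm)
  }
  if (!all(tier %in% .TIERS)) stop("tier must be one of ", paste(.TIERS, collapse = ", "))
  lm <- data.frame(tip_id = tip_id, tier = tier,
                   display_name = display_name, note = note,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(lm$tip_id)) stop("duplicate landmark tip ids")
  class(lm) <- c("pia_landmarks", "data.frame")
  lm
}

.check_landmarks <- function(lm, tree) {
  missing <- setdiff(lm$tip_id[lm$tier != "NONE"], tree$tip.label)
  if (length(missing) > 0) {
    stop("landmark id '", missing[1], "' is not a tip of the reference tree")
  }
  if (!any(lm$tier == "LANDMARK1")) {
    warning("no LANDMARK1 tip in the landmark map")
  }
  invisible(lm)
}

#' Tag a tree's tips with landmark and query roles
#'
#' Suffixes tip labels with `_LANDMARK1`, `_LANDMARK2` or `_QUERY`
#' according to the landmark map and the supplied query tips; all other
#' tips are unchanged. The output parses back to the same topology and
#' branch lengths.
#'
#' @param tree a `pia_tree` (typically with query tips already grafted).
#' @param lm a `pia_landmarks` map (may be empty).
#' @param query_tips character vector of query tip labels.
#' @return Newick string with tagged labels (no edge-number tags).
#' @export
tag_tree <- function(tree, lm, query_tips = character(0)) {
  tree <- as_pia_tree(tree)
  labs <- tree$tip.label
  if (any(grepl("_(LANDMARK[12]|QUERY)$", labs))) {
    stop("tip labels already carry a role suffix")
  }
  for (tier in c("LANDMARK1", "LANDMARK2")) {
    ids <- lm$tip_id[lm$tier == tier]
    labs[labs %in% ids] <- paste0(labs[labs %in% ids], "_", tier)
  }
  labs[tree$tip.label %in% query_tips] <-
    paste0(labs[tree$tip.label %in% query_tips], "_QUERY")
  tree$tip.label <- labs
  newick_string(tree, tags = FALSE, digits = 12)
}

#' Patristic distance from a point on an edge to a tip
#'
#' The point is given by (edge id, distal length from the edge's proximal
#' node). The distance is the sum of branch lengths along the unique path.
#'
#' @param tree a `pia_tree`.
#' @param edge_id edge carrying the point.
#' @param distal distance of the point from the proximal node of the edge.
#' @param tip tip label.
#' @return non-negative distance.
#' @export
patristic_distance <- function(tree, edge_id, distal, tip) {
  tree <- as_pia_tree(tree)
  row <- .edge_row(tree, edge_id)
  len <- tree$edge.length[row]
  if (distal < -1e-12 || distal > len + 1e-9) stop("invalid point on edge")
  distal <- min(max(distal, 0), len)
  tipn <- match(tip, tree$tip.label)
  if (is.na(tipn)) stop("unknown tip '", tip, "'")
  D <- ape::dist.nodes(tree)
  p <- tree$edge[row, 1]; ch <- tree$edge[row, 2]
  # the path leaves through whichever endpoint is nearer via the tree
  min(distal + D[p, tipn], (len - distal) + D[ch, tipn])
}

#' Classify a placed query against the landmark map
#'
#' From the query's best placement, computes patristic distances from the
#' attachment point to the nearest LANDMARK1 and LANDMARK2 tips. The flag
#' is `candidate_ortholog_context` when the nearest landmark is tier 1
#' and the pendant branch is short (`pendant_length <= pendant_max`),
#' `distant_relative_context` when the nearest landmark is tier 2, and
#' `ambiguous` otherwise (including equidistant ties within 1e-9 and
#' trees with no landmarks). Both distances are always reported so users
#' can inspect the placement themselves.
#'
#' @param placement one-row best placement (from [epa_place()]).
#' @param lm a `pia_landmarks` map.
#' @param tree the reference `pia_tree`.
#' @param family family name recorded on the result.
#' @param pendant_max pendant-length threshold; default 2x the median
#'   terminal branch length of the reference tree.
#' @return one-row data.frame (an annotation record): query_id, family,
#'   best_edge_id, best_lwr, pendant_length, nearest landmark ids and
#'   distances per tier, flag.
#' @export
classify_query <- function(placement, lm, tree, family = NA_character_,
                           pendant_max = NULL) {
  tree <- as_pia_tree(tree)
  stopifnot(nrow(placement) >= 1)
  placement <- placement[which(placement$best)[1], , drop = FALSE]
  if (is.null(pendant_max)) pendant_max <- 2 * median_terminal_branch(tree)

  nearest <- function(tier) {
    ids <- lm$tip_id[lm$tier == tier]
    ids <- intersect(ids, tree$tip.label)
    if (length(ids) == 0L) return(list(id = NA_character_, dist = Inf))
    d <- vapply(ids, function(tp) {
      patristic_distance(tree, placement$edge_id, placement$distal_length, tp)
    }, numeric(1))
    best <- order(d, ids)[1]   # deterministic on exact distance ties
    list(id = ids[best], dist = d[best])
  }
  l1 <- nearest("LANDMARK1")
  l2 <- nearest("LANDMARK2")

  if (!is.finite(l1$dist) && !is.finite(l2$dist)) {
    warning("no landmarks in map; flagging as ambiguous")
    flag <- "ambiguous"
  } else if (abs(l1$dist - l2$dist) < 1e-9) {
    flag <- "ambiguous"
  } else if (l1$dist < l2$dist) {
    flag <- if (placement$pendant_length <= pendant_max)
      "candidate_ortholog_context" else "ambiguous"
  } else {
    flag <- "distant_relative_context"
  }
  data.frame(query_id = placement$query_id, family = family,
             best_edge_id = placement$edge_id, best_lwr = placement$lwr,
             pendant_length = placement$pendant_length,
             nearest_L1 = l1$id,
             nearest_L1_dist = ifelse(is.finite(l1$dist), l1$dist, NA_real_),
             nearest_L2 = l2$id,
             nearest_L2_dist = ifelse(is.finite(l2$dist), l2$dist, NA_real_),
             flag = flag, stringsAsFactors = FALSE)
}

#' Median terminal branch length of a tree
#' @param tree a `pia_tree`.
#' @export
median_terminal_branch <- function(tree) {
  tree <- as_pia_tree(tree)
  ntip <- length(tree$tip.label)
  stats::median(tree$edge.length[tree$edge[, 2] <= ntip])
}

#' Family-by-sample presence matrix
#'
#' A cell is 1 when the sample has at least one
#' `candidate_ortholog_context` record for the family, else 0. Optional
#' user-supplied contamination calls are passed through as an attribute
#' (they are annotations, not computed).
#'
#' @param records annotation records (rows from [classify_query()]) with
#'   an additional `sample` column.
#' @param families,samples optional row/column universes (default: those
#'   present in `records`).
#' @param contamination optional data.frame with `family` and `sample`
#'   columns marking user-flagged contaminated cells.
#' @return integer matrix families x samples, with attribute
#'   `contaminated` (logical matrix) when contamination calls are given.
#' @export
presence_matrix <- function(records, families = NULL, samples = NULL,
                            contamination = NULL) {
  if (is.null(samples)) samples <- sort(unique(records$sample))
  if (is.null(families)) families <- sort(unique(records$family))
  if (length(samples) == 0L) stop("need at least one sample")
  M <- matrix(0L, length(families), length(samples),
              dimnames = list(families, samples))
  hit <- records[records$flag == "candidate_ortholog_context", , drop = FALSE]
  for (i in seq_len(nrow(hit))) {
    M[hit$family[i], hit$sample[i]] <- 1L
  }
  if (!is.null(contamination) && nrow(contamination) > 0) {
    Cm <- matrix(FALSE, length(families), length(samples),
                 dimnames = dimnames(M))
    for (i in seq_len(nrow(contamination))) {
      Cm[contamination$family[i], contamination$sample[i]] <- TRUE
    }
    attr(M, "contaminated") <- Cm
  }
  M
}
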
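# Trees are ape "phylo" objects carrying one extra component, edge_id: a
# dense 0-based integer id per edge row, stable under serialization via
# jplace-style {N} tags. ape::read.tree drops such tags, so Newick
# round-tripping is done by a small reader/writer here; ape remains the
# in-memory container and supplies drop.tip, dist.nodes, rooting etc.

#' Promote an ape phylo to an edge-numbered tree
#'
#' Reorders cladewise and assigns dense edge ids 0..E-1 in edge-row order
#' (unless the tree already carries a valid `edge_id`).
#'
#' @param phy an `ape::phylo`.
#' @return the tree with class `pia_tree` and an `edge_id` component.
#' @export
as_pia_tree <- function(phy) {
  if (inherits(phy, "pia_tree") && !is.null(phy$edge_id) &&
      length(phy$edge_id) == nrow(phy$edge)) {
    return(phy)
  }
  if (!inherits(phy, "phylo")) stop("not a phylo object")
  phy$edge_id <- NULL
  phy <- ape::reorder.phylo(phy, "cladewise")
  if (anyDuplicated(phy$tip.label)) stop("tip labels must be unique")
  phy$edge_id <- seq_len(nrow(phy$edge)) - 1L
  class(phy) <- c("pia_tree", "phylo")
  phy
}

n_edges <- function(tree) nrow(tree$edge)

#' Edge table of a tree
#'
#' @param tree a `pia_tree`.
#' @return data.frame with edge_id, parent, child node numbers, length,
#'   whether the edge is terminal, and the tip label for terminal edges.
#' @export
tree_edges <- function(tree) {
  tree <- as_pia_tree(tree)
  ntip <- length(tree$tip.label)
  child <- tree$edge[, 2]
  data.frame(
    edge_id = tree$edge_id,
    parent = tree$edge[, 1],
    child = child,
    length = tree$edge.length,
    is_terminal = child <= ntip,
    tip_label = ifelse(child <= ntip, tree$tip.label[pmin(child, ntip)], NA),
    stringsAsFactors = FALSE)
}

.edge_row <- function(tree, edge_id) {
  row <- match(edge_id, tree$edge_id)
  if (is.na(row)) stop("unknown edge_id ", edge_id)
  row
}

# ---- Newick parsing ---------------------------------------------------

#' Read a Newick tree, preserving {N} edge numbers
#'
#' Accepts plain Newick or jplace-style edge-numbered Newick in which each
#' branch length may be followed by `{N}`. When tags are present they must
#' form a dense 0..E-1 set and become the tree's edge ids; otherwise ids
#' are assigned in cladewise edge order.
#'
#' @param x a file path or a Newick string (must contain `;`).
#' @return a `pia_tree`.
#' @export
read_newick <- function(x) {
  s <- if (grepl(";", x, fixed = TRUE)) {
    x
  } else if (file.exists(x)) {
    paste(readLines(x, warn = FALSE), collapse = "")
  } else {
    stop("not a Newick string (no ';' found) and not an existing file")
  }
  s <- gsub("[[:space:]]", "", s)
  if (!nzchar(s) || !grepl(";", s, fixed = TRUE)) {
    stop("not a Newick string (no ';' found)")
  }
  s <- sub(";.*$", "", s)
  env <- new.env()
  env$pos <- 1L
  env$chars <- strsplit(s, "")[[1]]
  env$n <- length(env$chars)

  peek <- function() if (env$pos <= env$n) env$chars[env$pos] else ""
  advance <- function() env$pos <- env$pos + 1L
  read_token <- function() {
    out <- character(0)
    while (env$pos <= env$n && !(env$chars[env$pos] %in%
                                 c("(", ")", ",", ":", ";", "{", "}"))) {
      out <- c(out, env$chars[env$pos]); advance()
    }
    paste(out, collapse = "")
  }

  parse_clade <- function() {
    node <- list(children = list(), label = "", length = NA_real_,
                 tag = NA_integer_)
    if (peek() == "(") {
      advance()
      node$children <- list(parse_clade())
      while (peek() == ",") { advance(); node$children <- c(node$children, list(parse_clade())) }
      if (peek() != ")") stop("malformed Newick: expected ')' at position ", env$pos)
      advance()
      node$label <- read_token()
    } else {
      node$label <- read_token()
      if (!nzchar(node$label)) stop("malformed Newick: empty tip label at position ", env$pos)
    }
    if (peek() == ":") {
      advance()
      len <- read_token()
      node$length <- suppressWarnings(as.numeric(len))
      if (is.na(node$length)) stop("malformed branch length '", len, "'")
    }
    if (peek() == "{") {
      advance()
      tag <- read_token()
      node$tag <- suppressWarnings(as.integer(tag))
      if (is.na(node$tag)) stop("malformed edge tag '{", tag, "}'")
      if (peek() != "}") stop("malformed edge tag: missing '}'")
      advance()
    }
    node
  }

  root <- parse_clade()
  if (env$pos <= env$n) stop("trailing characters after Newick tree")

  # flatten to phylo: tips numbered in encounter order, internals in preorder
  tip_labels <- character(0)
  count_tips <- function(nd) {
    if (length(nd$children) == 0L) 1L
    else sum(vapply(nd$children, count_tips, integer(1)))
  }
  ntip <- count_tips(root)
  state <- new.env()
  state$next_tip <- 1L
  state$next_int <- ntip + 1L
  state$parent <- integer(0); state$child <- integer(0)
  state$len <- numeric(0); state$tag <- integer(0)
  state$tips <- character(ntip)

  # preorder: parent numbers assigned before descending
  assign_preorder <- function(nd) {
    if (length(nd$children) == 0L) {
      num <- state$next_tip; state$next_tip <- state$next_tip + 1L
      state$tips[num] <- nd$label
      return(num)
    }
    num <- state$next_int; state$next_int <- state$next_int + 1L
    for (ch in nd$children) {
      idx <- length(state$parent) + 1L
      state$parent[idx] <- num
      state$child[idx] <- NA_integer_
      state$len[idx] <- ch$length
      state$tag[idx] <- ch$tag
      state$child[idx] <- assign_preorder(ch)
    }
    num
  }
  invisible(assign_preorder(root))

  lens <- state$len
  if (anyNA(lens)) lens[is.na(lens)] <- 0
  phy <- list(edge = cbind(state$parent, state$child),
              edge.length = lens,
              tip.label = state$tips,
              Nnode = state$next_int - ntip - 1L)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy <- ape::reorder.phylo(phy, "cladewise")
  if (anyDuplicated(phy$tip.label)) stop("tip labels must be unique")

  tags <- state$tag
  if (all(!is.na(tags))) {
    if (!setequal(tags, seq_along(tags) - 1L)) {
      stop("edge tags must be a dense 0..E-1 set")
    }
    # map tags through the reorder: rows identified by (parent,child) pairs
    key0 <- paste(state$parent, state$child)
    key1 <- paste(phy$edge[, 1], phy$edge[, 2])
    phy$edge_id <- tags[match(key1, key0)]
  } else if (any(!is.na(tags))) {
    stop("either all or no edges may carry {N} tags")
  } else {
    phy$edge_id <- seq_len(nrow(phy$edge)) - 1L
  }
  class(phy) <- c("pia_tree", "phylo")
  phy
}

# ---- Newick writing ---------------------------------------------------

.fmt_len <- function(x, digits) sprintf("%.*g", digits, x)

#' Serialize a tree to Newick
#'
#' Optionally writes jplace-style `{N}` edge-number tags after each branch
#' length, and can graft pendant query branches onto edges while writing
#' (used to build query-attached display trees without renumbering).
#'
#' @param tree a `pia_tree`.
#' @param tags write `{edge_id}` tags (default TRUE).
#' @param digits significant digits for branch lengths.
#' @param grafts optional data.frame with columns `edge_id`, `distal`
#'   (distance from the proximal node), `pendant`, `label`; each row
#'   attaches a new pendant tip at that point. Tags are not written when
#'   grafting (edge numbering changes).
#' @return a single Newick string ending in ";".
#' @export
newick_string <- function(tree, tags = TRUE, digits = 10, grafts = NULL) {
  tree <- as_pia_tree(tree)
  if (!is.null(grafts) && nrow(grafts) > 0) tags <- FALSE
  ntip <- length(tree$tip.label)
  edges <- tree$edge
  kids <- split(seq_len(nrow(edges)), edges[, 1])
  root <- edges[1, 1]

  emit_node <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    rows <- kids[[as.character(node)]]
    parts <- vapply(rows, emit_edge, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  emit_edge <- function(row) {
    child <- edges[row, 2]
    len <- tree$edge.length[row]
    eid <- tree$edge_id[row]
    core <- emit_node(child)
    g <- if (is.null(grafts)) NULL else grafts[grafts$edge_id == eid, , drop = FALSE]
    if (!is.null(g) && nrow(g) > 0) {
      g <- g[order(-g$distal), , drop = FALSE]  # innermost (closest to child) first
      prev <- len
      for (i in seq_len(nrow(g))) {
        seg <- prev - g$distal[i]
        core <- paste0("(", core, ":", .fmt_len(seg, digits), ",",
                       g$label[i], ":", .fmt_len(g$pendant[i], digits), ")")
        prev <- g$distal[i]
      }
      len <- prev
    }
    out <- paste0(core, ":", .fmt_len(len, digits))
    if (tags) out <- paste0(out, "{", eid, "}")
    out
  }
  paste0(emit_node(root), ";")
}

#' Write a tree to a Newick file
#'
#' @inheritParams newick_string
#' @param path output file path.
#' @export
write_newick <- function(tree, path, tags = TRUE, digits = 10) {
  writeLines(newick_string(tree, tags = tags, digits = digits), path)
  invisible(path)
}

#' Attach a pendant tip to a tree edge
#'
#' Splits the edge at `distal` (distance from its proximal node) with a new
#' internal node and hangs a pendant branch of length `pendant` carrying
#' `label`. Edge ids are reassigned densely on the returned tree.
#'
#' @param tree a `pia_tree`.
#' @param edge_id edge to split.
#' @param distal attachment position, in `[0, edge length]`.
#' @param pendant pendant branch length (>= 0).
#' @param label new tip label.
#' @return a new `pia_tree` with one more tip.
#' @export
graft_at <- function(tree, edge_id, distal, pendant, label) {
  tree <- as_pia_tree(tree)
  row <- .edge_row(tree, edge_id)
  len <- tree$edge.length[row]
  if (distal < 0 || distal > len + 1e-12) {
    stop("distal must lie within [0, edge length]")
  }
  if (pendant < 0) stop("pendant must be >= 0")
  if (label %in% tree$tip.label) stop("label already present in tree")
  g <- data.frame(edge_id = edge_id, distal = min(distal, len),
                  pendant = pendant, label = label,
                  stringsAsFactors = FALSE)
  read_newick(newick_string(tree, grafts = g, digits = 15))
}
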
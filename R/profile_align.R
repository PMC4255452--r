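# Adding a query sequence to a fixed reference alignment. Reference
# columns are immutable: the query is threaded through them by a
# profile-to-sequence affine-gap DP; query residues that fit between
# reference columns create new all-gap "insert" columns. Terminal gaps in
# the query are unpenalized (semi-global), since transcript ORFs are
# often fragments of the full protein.

#' Per-column residue frequencies of an alignment
#'
#' @param aln a `pia_alignment`.
#' @return list with `freq` (20 x n_cols matrix; each column sums to 1
#'   when it has at least one non-gap residue), `nongap_frac` (fraction of
#'   rows that are non-gap, X counted as non-gap but uninformative), and
#'   `all_gap` (logical flag per column).
#' @export
column_profile <- function(aln) {
  if (length(aln) == 0L) stop("empty alignment")
  M <- aln_matrix(aln)
  C <- ncol(M)
  freq <- matrix(0, 20L, C, dimnames = list(.aa_order, NULL))
  nongap <- colSums(M != "-") / nrow(M)
  for (j in seq_len(C)) {
    col <- M[, j]
    col <- col[col %in% .aa_order]
    if (length(col) > 0L) {
      tab <- table(factor(col, levels = .aa_order))
      freq[, j] <- as.numeric(tab) / length(col)
    }
  }
  list(freq = freq, nongap_frac = nongap, all_gap = colSums(M != "-") == 0)
}

#' Align a query sequence onto a fixed reference alignment
#'
#' Global-in-query, semi-global-in-profile affine-gap dynamic programming.
#' The match score of query residue q against column i is the
#' frequency-weighted mean substitution score,
#' `nongap_frac_i * sum_a freq_i(a) S(a, q)`. Reference rows are never
#' edited: removing the query row and any columns that became all-gap
#' reproduces the input alignment exactly.
#'
#' @param aln reference `pia_alignment`.
#' @param query protein string (no gaps).
#' @param s a `pia_scoring` scheme (substitution matrix + gap scores).
#' @param query_id row name for the query (default `"query"`).
#' @return extended `pia_alignment` with attributes `insert_cols`
#'   (positions, in extended coordinates, of new all-gap columns) and
#'   `query_id`.
#' @export
add_to_alignment <- function(aln, query, s = scoring_scheme(),
                             query_id = "query") {
  if (length(aln) == 0L) stop("empty profile")
  query <- toupper(query)
  if (!nzchar(query)) stop("query must be non-empty")
  if (grepl(sprintf("[^X%s]", paste(.PROT_LETTERS, collapse = "")), query)) {
    stop("query contains illegal residues")
  }
  if (query_id %in% names(aln)) stop("query id collides with a reference row")
  prof <- column_profile(aln)
  C <- aln_ncol(aln)
  q <- strsplit(query, "")[[1]]
  Lq <- length(q)
  Smat <- .align_matrix(s)[.aa_order, , drop = FALSE]
  # match score matrix: rows = profile columns, cols = query positions
  wF <- prof$freq * rep(prof$nongap_frac, each = 20L)
  SC <- t(wF) %*% Smat[, q, drop = FALSE]

  go <- s$gap_open; ge <- s$gap_extend
  NEG <- -1e18
  M <- matrix(NEG, C + 1L, Lq + 1L)
  D <- matrix(NEG, C + 1L, Lq + 1L)  # query gap (profile column unmatched)
  I <- matrix(NEG, C + 1L, Lq + 1L)  # insert column (query residue unmatched)
  M[1, 1] <- 0
  D[, 1] <- 0                        # free leading deletions
  if (Lq >= 1L) I[1, 2:(Lq + 1L)] <- go + ge * seq_len(Lq)
  for (i in seq_len(C)) {
    # deletion column j = 0 handled by init; j = Lq free trailing deletions
    for (j in seq_len(Lq)) {
      M[i + 1L, j + 1L] <- SC[i, j] +
        max(M[i, j], D[i, j], I[i, j])
      dopen <- if (j == Lq) 0 else go + ge
      dext <- if (j == Lq) 0 else ge
      D[i + 1L, j + 1L] <- max(M[i, j + 1L] + dopen,
                               D[i, j + 1L] + dext,
                               I[i, j + 1L] + dopen)
      I[i + 1L, j + 1L] <- max(M[i + 1L, j] + go + ge,
                               I[i + 1L, j] + ge,
                               D[i + 1L, j] + go + ge)
    }
    # j = 0 column: leading deletions stay free (D already 0); M, I stay NEG
  }
  # traceback from the best terminal state
  states <- c(M = M[C + 1L, Lq + 1L], D = D[C + 1L, Lq + 1L],
              I = I[C + 1L, Lq + 1L])
  st <- names(which.max(states))
  i <- C; j <- Lq
  path <- character(0)  # per step: "M", "D" (consume column), "I" (consume query)
  while (i > 0L || j > 0L) {
    if (i == 0L) { path <- c("I", path); j <- j - 1L; next }
    if (j == 0L) { path <- c("D", path); i <- i - 1L; next }
    if (st == "M") {
      prev <- c(M = M[i, j], D = D[i, j], I = I[i, j])
      path <- c("M", path); i <- i - 1L; j <- j - 1L
      st <- names(which.max(prev))
    } else if (st == "D") {
      dopen <- if (j == Lq) 0 else go + ge
      dext <- if (j == Lq) 0 else ge
      prev <- c(M = M[i, j + 1L] + dopen, D = D[i, j + 1L] + dext,
                I = I[i, j + 1L] + dopen)
      path <- c("D", path); i <- i - 1L
      st <- names(which.max(prev))
    } else {
      prev <- c(M = M[i + 1L, j] + go + ge, I = I[i + 1L, j] + ge,
                D = D[i + 1L, j] + go + ge)
      path <- c("I", path); j <- j - 1L
      st <- names(which.max(prev))
    }
  }
  # build extended rows
  refM <- aln_matrix(aln)
  ext_ref <- vector("list", length(path))
  qrow <- character(length(path))
  insert_cols <- integer(0)
  ci <- 0L; qi <- 0L
  for (k in seq_along(path)) {
    step <- path[k]
    if (step == "M") {
      ci <- ci + 1L; qi <- qi + 1L
      ext_ref[[k]] <- refM[, ci]; qrow[k] <- q[qi]
    } else if (step == "D") {
      ci <- ci + 1L
      ext_ref[[k]] <- refM[, ci]; qrow[k] <- "-"
    } else {
      qi <- qi + 1L
      ext_ref[[k]] <- rep("-", nrow(refM)); qrow[k] <- q[qi]
      insert_cols <- c(insert_cols, k)
    }
  }
  extM <- do.call(cbind, ext_ref)
  rows <- apply(extM, 1, paste, collapse = "")
  out <- alignment(c(stats::setNames(rows, names(aln)),
                     stats::setNames(paste(qrow, collapse = ""), query_id)))
  attr(out, "insert_cols") <- insert_cols
  attr(out, "query_id") <- query_id
  out
}

#' Restrict an aligned query row to the reference columns
#'
#' Drops the query residues that fall in insert (all-gap reference)
#' columns, returning the query expressed on the reference coordinate
#' system, as required for placement.
#'
#' @param extended alignment from [add_to_alignment()] (or any alignment;
#'   insert columns are identified as all-gap-in-reference columns when
#'   the attribute is absent).
#' @param query_id row to mask.
#' @return single gapped string of exactly the reference width.
#' @export
mask_query_to_ref <- function(extended, query_id) {
  if (!query_id %in% names(extended)) stop("unknown id '", query_id, "'")
  ins <- attr(extended, "insert_cols")
  if (is.null(ins)) {
    refM <- aln_matrix(extended)[setdiff(names(extended), query_id), ,
                                 drop = FALSE]
    ins <- which(colSums(refM != "-") == 0L)
  }
  chars <- strsplit(extended[[query_id]], "")[[1]]
  if (length(ins) > 0L) chars <- chars[-ins]
  paste(chars, collapse = "")
}

#' A2m-style rendering of an extended alignment
#'
#' Residues of the query row falling in insert columns are lower-cased so
#' the reference coordinate system stays readable in the output FASTA.
#'
#' @param extended alignment from [add_to_alignment()].
#' @return named character vector of rows.
#' @export
aln_to_a2m <- function(extended) {
  ins <- attr(extended, "insert_cols")
  qid <- attr(extended, "query_id")
  rows <- stats::setNames(as.character(extended), names(extended))
  if (!is.null(ins) && length(ins) > 0L && !is.null(qid)) {
    chars <- strsplit(rows[[qid]], "")[[1]]
    chars[ins] <- tolower(chars[ins])
    rows[[qid]] <- paste(chars, collapse = "")
  }
  rows
}
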
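# Candidate identification by optimal local protein alignment of ORFs
# against a family's bait sequences, with Karlin-Altschul E-value gating
# and top-k retention. The alignment engine is Smith-Waterman with affine
# gaps (Biostrings::pairwiseAlignment); defaults mirror gapped blastp:
# BLOSUM62, gap open -11 / extend -1, lambda = 0.267, K = 0.041.

#' Construct a protein scoring scheme
#'
#' @param matrix symmetric integer substitution matrix over the 20
#'   standard residues (default: BLOSUM62).
#' @param gap_open gap opening score (negative; default -11).
#' @param gap_extend gap extension score per position (negative; default -1).
#' @param lambda Karlin-Altschul scale parameter (nats per score unit).
#' @param K Karlin-Altschul search-space constant.
#' @return object of class `pia_scoring`.
#' @export
scoring_scheme <- function(matrix = NULL, gap_open = -11L, gap_extend = -1L,
                           lambda = 0.267, K = 0.041) {
  if (is.null(matrix)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    matrix <- e$BLOSUM62[.PROT_LETTERS, .PROT_LETTERS]
  }
  if (!isTRUE(all.equal(matrix, t(matrix)))) {
    stop("substitution matrix must be symmetric")
  }
  if (gap_open >= 0 || gap_extend >= 0) stop("gap scores must be negative")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K),
            class = "pia_scoring")
}

# substitution matrix extended with an X row/column (score -1 vs all),
# so queries containing ambiguous residues can be aligned
.align_matrix <- function(s) {
  m <- s$matrix
  if (!"X" %in% rownames(m)) {
    m <- rbind(cbind(m, X = -1L), X = c(rep(-1L, ncol(m)), -1L))
    rownames(m)[nrow(m)] <- "X"
  }
  m
}

#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman alignment with affine gap costs. Gap of length L costs
#' `|gap_open| + L * |gap_extend|`. Scores at or below zero are reported
#' as an empty alignment with raw score 0.
#'
#' @param query,target non-empty protein strings.
#' @param s a `pia_scoring` scheme.
#' @return list with `raw_score`, 0-based half-open spans `q_start`,
#'   `q_end`, `t_start`, `t_end`, and the `aligned` pair of gapped strings.
#' @export
local_align <- function(query, target, s = scoring_scheme()) {
  if (!nzchar(query) || !nzchar(target)) stop("sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(target),
    type = "local", substitutionMatrix = .align_matrix(s),
    gapOpening = abs(s$gap_open), gapExtension = abs(s$gap_extend))
  sc <- Biostrings::score(pa)
  if (sc <= 0) {
    return(list(raw_score = 0, q_start = 0L, q_end = 0L,
                t_start = 0L, t_end = 0L, aligned = c("", "")))
  }
  list(raw_score = sc,
       q_start = Biostrings::start(Biostrings::pattern(pa)) - 1L,
       q_end = Biostrings::end(Biostrings::pattern(pa)),
       t_start = Biostrings::start(Biostrings::subject(pa)) - 1L,
       t_end = Biostrings::end(Biostrings::subject(pa)),
       aligned = c(as.character(Biostrings::alignedPattern(pa)),
                   as.character(Biostrings::alignedSubject(pa))))
}

#' Karlin-Altschul expect value
#'
#' `E = K * m * n * exp(-lambda * S)`: the expected number of local
#' alignments of score >= S between random sequences of the given sizes.
#'
#' @param raw_score alignment raw score S.
#' @param m query length (>= 1).
#' @param n total database letters (>= 1).
#' @param s a `pia_scoring` scheme supplying lambda and K.
#' @return positive expect value, strictly decreasing in `raw_score` and
#'   linear in `m` and `n`.
#' @export
evalue <- function(raw_score, m, n, s = scoring_scheme()) {
  if (m < 1 || n < 1) stop("m and n must be >= 1")
  s$K * m * n * exp(-s$lambda * raw_score)
}

#' Bit score of a raw alignment score
#' @inheritParams evalue
#' @export
bitscore <- function(raw_score, s = scoring_scheme()) {
  (s$lambda * raw_score - log(s$K)) / log(2)
}

#' Search one family's baits with a set of ORFs
#'
#' Every ORF is aligned against every bait of the reference package; an
#' ORF's family-level E-value is its best (smallest) bait E-value, with
#' the search space n = total bait letters of the family. ORFs above the
#' E-value cutoff are discarded and at most `top_k` survivors with the
#' smallest E-values are retained, ties broken by higher raw score then
#' lexicographic query id.
#'
#' @param orfs named character vector of ORF protein sequences (names are
#'   query ids), or an ORF data.frame from [transcriptome_orfs()] (ids are
#'   then built with [query_label()]).
#' @param refpkg a `pia_refpkg` (or any list with `family` and `baits`).
#' @param s scoring scheme.
#' @param evalue_cutoff maximum family E-value (default 1e-20).
#' @param top_k ORFs retained per family (default 3; `Inf` keeps all).
#' @return data.frame of retained hits: query_id, family_id, bait_id,
#'   raw_score, bitscore, evalue and 0-based half-open aligned spans,
#'   ranked by increasing E-value.
#' @export
search_family <- function(orfs, refpkg, s = scoring_scheme(),
                          evalue_cutoff = 1e-20, top_k = 3) {
  baits <- refpkg$baits
  if (length(baits) == 0L) stop("reference package has no baits")
  family <- refpkg$family
  if (is.data.frame(orfs)) {
    ids <- query_label(family, orfs$transcript_id, orfs$orf_index)
    orfs <- stats::setNames(orfs$aa_seq, ids)
  }
  if (length(orfs) == 0L) {
    return(.empty_hits())
  }
  n_db <- sum(nchar(baits))
  rows <- lapply(names(orfs), function(qid) {
    per_bait <- lapply(names(baits), function(bid) {
      al <- local_align(orfs[[qid]], baits[[bid]], s)
      data.frame(query_id = qid, family_id = family, bait_id = bid,
                 raw_score = al$raw_score,
                 bitscore = bitscore(al$raw_score, s),
                 evalue = evalue(al$raw_score, nchar(orfs[[qid]]), n_db, s),
                 q_start = al$q_start, q_end = al$q_end,
                 b_start = al$t_start, b_end = al$t_end,
                 stringsAsFactors = FALSE)
    })
    per_bait <- do.call(rbind, per_bait)
    # family-level hit for this ORF: its best bait
    best <- order(per_bait$evalue, -per_bait$raw_score, per_bait$bait_id)[1]
    per_bait[best, , drop = FALSE]
  })
  hits <- do.call(rbind, rows)
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(hits) == 0L) return(.empty_hits())
  ord <- order(hits$evalue, -hits$raw_score, hits$query_id)
  hits <- hits[ord, , drop = FALSE]
  if (is.finite(top_k)) hits <- utils::head(hits, as.integer(top_k))
  rownames(hits) <- NULL
  hits
}

.empty_hits <- function() {
  data.frame(query_id = character(0), family_id = character(0),
             bait_id = character(0), raw_score = numeric(0),
             bitscore = numeric(0), evalue = numeric(0),
             q_start = integer(0), q_end = integer(0),
             b_start = integer(0), b_end = integer(0),
             stringsAsFactors = FALSE)
}

#' Import hits from BLAST tabular output (outfmt 6)
#'
#' Lets an external search engine substitute for [search_family()]. The
#' standard 12 columns are expected; 1-based inclusive coordinates are
#' converted to 0-based half-open.
#'
#' @param path tab-separated file.
#' @param family_id family to record on the hits (outfmt 6 has no family
#'   column); default `NA`.
#' @return hits data.frame as from [search_family()] (raw_score `NA`).
#' @export
import_tabular_hits <- function(path, family_id = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(.empty_hits())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 12L)) {
    stop("tabular format error at line ", which(nc != 12L)[1],
         ": expected 12 columns, found ", nc[nc != 12L][1])
  }
  m <- do.call(rbind, parts)
  data.frame(query_id = m[, 1], family_id = family_id, bait_id = m[, 2],
             raw_score = NA_real_, bitscore = as.numeric(m[, 12]),
             evalue = as.numeric(m[, 11]),
             q_start = as.integer(m[, 7]) - 1L, q_end = as.integer(m[, 8]),
             b_start = as.integer(m[, 9]) - 1L, b_end = as.integer(m[, 10]),
             stringsAsFactors = FALSE)
}
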
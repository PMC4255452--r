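# Alignment container: a named character vector of equal-width gapped
# protein strings, class "pia_alignment".

.PROT_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a protein alignment
#'
#' @param rows named character vector of gapped rows (gap character `-`),
#'   all the same width, unique non-empty names.
#' @return object of class `pia_alignment`.
#' @export
alignment <- function(rows) {
  if (length(rows) == 0L) stop("alignment must have at least one row")
  if (is.null(names(rows)) || any(!nzchar(names(rows)))) {
    stop("all alignment rows must be named")
  }
  if (anyDuplicated(names(rows))) stop("alignment row ids must be unique")
  rows <- toupper(rows)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L) stop("alignment rows must have equal length")
  bad <- grepl(sprintf("[^-X%s]", paste(.PROT_LETTERS, collapse = "")), rows)
  if (any(bad)) {
    stop("illegal residue in alignment row '", names(rows)[bad][1], "'")
  }
  structure(rows, class = "pia_alignment")
}

#' @export
print.pia_alignment <- function(x, ...) {
  cat("pia_alignment:", length(x), "rows x", aln_ncol(x), "columns\n")
  invisible(x)
}

#' Number of columns of an alignment
#' @param aln a `pia_alignment`.
#' @export
aln_ncol <- function(aln) nchar(aln[[1]])

#' Alignment as a character matrix (rows x columns)
#' @param aln a `pia_alignment`.
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(m) <- names(aln)
  m
}

#' Remove gap characters from a sequence string
#' @param x character vector of (possibly gapped) sequences.
#' @export
ungap <- function(x) gsub("-", "", x, fixed = TRUE)
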
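# FASTA reading/writing with line-numbered format diagnostics. A small
# hand-written reader is used (rather than Biostrings::readAAStringSet)
# because the contract here is strict validation: malformed headers,
# illegal residues and duplicate ids must be reported with the offending
# line number.

#' Read a FASTA file with validation
#'
#' @param path file path.
#' @param alphabet one of `"nuc"` (A/C/G/T/N), `"prot"` (20 amino acids
#'   plus X; a single terminal `*` stop marker is stripped), or
#'   `"prot_gapped"` (protein plus the gap character `-`, for aligned
#'   FASTA). Input case is folded to upper.
#' @return named character vector of sequences, in file order.
#' @export
read_fasta <- function(path, alphabet = c("nuc", "prot", "prot_gapped")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  ids <- character(0)
  seqs <- character(0)
  cur <- NULL
  cur_parts <- character(0)
  flush <- function() {
    if (!is.null(cur)) {
      seqs[length(seqs) + 1L] <<- paste(cur_parts, collapse = "")
      ids[length(ids) + 1L] <<- cur
    }
  }
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      header <- trimws(sub("^>", "", line))
      if (!nzchar(header)) stop("FASTA format error at line ", i, ": empty header")
      id <- strsplit(header, "[[:space:]]+")[[1]][1]
      if (id %in% ids || identical(id, cur)) {
        stop("FASTA format error at line ", i, ": duplicate id '", id, "'")
      }
      flush()
      cur <- id
      cur_parts <- character(0)
    } else {
      if (is.null(cur)) {
        stop("FASTA format error at line ", i, ": sequence before first header")
      }
      res <- toupper(gsub("[[:space:]]", "", line))
      ok <- switch(alphabet,
        nuc = grepl("^[ACGTN]*$", res),
        prot = grepl(sprintf("^[X%s*]*$", paste(.PROT_LETTERS, collapse = "")), res),
        prot_gapped = grepl(sprintf("^[-X%s*]*$", paste(.PROT_LETTERS, collapse = "")), res))
      if (!ok) {
        bad <- regmatches(res, regexpr(switch(alphabet,
          nuc = "[^ACGTN]",
          prot = sprintf("[^X%s*]", paste(.PROT_LETTERS, collapse = "")),
          prot_gapped = sprintf("[^-X%s*]", paste(.PROT_LETTERS, collapse = ""))), res))
        stop("FASTA format error at line ", i, ": illegal residue '", bad, "'")
      }
      cur_parts <- c(cur_parts, res)
    }
  }
  flush()
  if (length(ids) == 0L) stop("FASTA format error: no records in ", path)
  if (alphabet %in% c("prot", "prot_gapped")) {
    seqs <- sub("\\*$", "", seqs)  # terminal stop marker stripped on storage
    if (any(grepl("*", seqs, fixed = TRUE))) {
      stop("FASTA format error: internal stop codon marker '*' in record '",
           ids[grepl("*", seqs, fixed = TRUE)][1], "'")
    }
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (or `pia_alignment`).
#' @param path output path.
#' @param line_width wrap width for sequence lines (default 60).
#' @return the path, invisibly. `read_fasta(write_fasta(x))` is the
#'   identity on records.
#' @export
write_fasta <- function(seqs, path, line_width = 60) {
  if (length(seqs) == 0L) stop("cannot write an empty sequence collection")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
    stop("all sequences must be named")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    cat(">", names(seqs)[i], "\n", sep = "", file = con)
    s <- seqs[[i]]
    if (nchar(s) == 0L) next
    starts <- seq(1L, nchar(s), by = line_width)
    writeLines(substring(s, starts, pmin(starts + line_width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}
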
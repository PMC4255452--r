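# Six-frame ORF extraction from transcript nucleotide sequences.
# ORFs are maximal stop-to-stop (or sequence-edge-to-stop) open readings:
# no start codon is required and edge-truncated readings are kept, since
# assembled transcript fragments commonly truncate coding regions.

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

.translate_frame <- function(chars, offset) {
  n <- length(chars)
  usable <- n - offset
  naa <- usable %/% 3L
  if (naa == 0L) return(character(0))
  tab <- .codon_table()
  idx <- offset + seq_len(naa * 3L)
  codons <- paste0(chars[idx[c(TRUE, FALSE, FALSE)]],
                   chars[idx[c(FALSE, TRUE, FALSE)]],
                   chars[idx[c(FALSE, FALSE, TRUE)]])
  aa <- tab[codons]
  aa[is.na(aa)] <- "X"  # codons containing N are ambiguous
  unname(aa)
}

.revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Extract ORFs from all six reading frames
#'
#' Scans the three forward and three reverse-complement frames of a
#' transcript for maximal stop-free stretches of at least `min_aa`
#' translated residues. Coordinates are 0-based half-open on the forward
#' strand of the transcript; stop codons are excluded from the ORF and its
#' length. `orf_index` ranks ORFs by descending amino-acid length, ties by
#' strand (`+` first) then forward-strand start.
#'
#' @param seq nucleotide string over A/C/G/T/N, or a length-1 named
#'   character vector.
#' @param min_aa minimum translated length in amino acids (default 30).
#' @param transcript_id id recorded on each ORF; defaults to the name of
#'   `seq` (or `"transcript"`).
#' @return data.frame with columns transcript_id, orf_index, frame,
#'   strand, nuc_start, nuc_end, aa_seq.
#' @export
six_frame_orfs <- function(seq, min_aa = 30L, transcript_id = NULL) {
  if (min_aa < 1L) stop("min_aa must be >= 1")
  if (is.null(transcript_id)) {
    transcript_id <- if (!is.null(names(seq))) names(seq)[1] else "transcript"
  }
  s <- toupper(as.character(seq)[1])
  if (grepl("[^ACGTN]", s)) {
    stop("format error: transcript contains letters outside {A,C,G,T,N}")
  }
  L <- nchar(s)
  out <- list()
  for (strand in c("+", "-")) {
    str_seq <- if (strand == "+") s else .revcomp(s)
    chars <- strsplit(str_seq, "")[[1]]
    for (frame in 1:3) {
      offset <- frame - 1L
      aa <- .translate_frame(chars, offset)
      if (length(aa) == 0L) next
      # split into maximal stop-free runs
      is_stop <- aa == "*"
      run_id <- cumsum(is_stop)
      for (rid in unique(run_id)) {
        pos <- which(run_id == rid & !is_stop)
        if (length(pos) < min_aa) next
        aa_start <- pos[1]; aa_end <- pos[length(pos)]
        # coordinates on the scanned strand, 0-based half-open
        st <- offset + (aa_start - 1L) * 3L
        en <- offset + aa_end * 3L
        if (strand == "-") { tmp <- st; st <- L - en; en <- L - tmp }
        out[[length(out) + 1L]] <- data.frame(
          transcript_id = transcript_id, frame = frame, strand = strand,
          nuc_start = st, nuc_end = en,
          aa_seq = paste(aa[aa_start:aa_end], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(transcript_id = character(0), orf_index = integer(0),
                      frame = integer(0), strand = character(0),
                      nuc_start = integer(0), nuc_end = integer(0),
                      aa_seq = character(0), stringsAsFactors = FALSE))
  }
  orfs <- do.call(rbind, out)
  ord <- order(-nchar(orfs$aa_seq), orfs$strand, orfs$nuc_start)
  orfs <- orfs[ord, , drop = FALSE]
  orfs$orf_index <- seq_len(nrow(orfs))
  rownames(orfs) <- NULL
  orfs[, c("transcript_id", "orf_index", "frame", "strand",
           "nuc_start", "nuc_end", "aa_seq")]
}

#' Extract ORFs from every transcript of a nucleotide collection
#'
#' @param seqs named character vector of transcripts.
#' @param min_aa minimum ORF length in amino acids.
#' @return combined ORF data.frame (see [six_frame_orfs()]).
#' @export
transcriptome_orfs <- function(seqs, min_aa = 30L) {
  res <- lapply(names(seqs), function(id) {
    six_frame_orfs(seqs[[id]], min_aa = min_aa, transcript_id = id)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Deterministic query label for a placed ORF
#'
#' Renders the family / transcript / ORF provenance of a query as a
#' whitespace-free label, e.g. `Gprk1_hit_UN0029_ORF1`.
#'
#' @param family gene-family name (non-empty).
#' @param transcript_id transcript id (non-empty).
#' @param orf_index 1-based ORF ordinal.
#' @return character label, unique per (family, transcript, orf).
#' @export
query_label <- function(family, transcript_id, orf_index) {
  if (any(!nzchar(family))) stop("family must be non-empty")
  if (any(!nzchar(transcript_id))) stop("transcript_id must be non-empty")
  sprintf("%s_hit_%s_ORF%d", family, transcript_id, as.integer(orf_index))
}
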
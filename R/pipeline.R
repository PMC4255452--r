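# End-to-end orchestration: transcriptome -> ORFs -> homolog search ->
# profile alignment -> placement -> annotation -> reports. Processing is
# per (sample, family), deterministic, and every stage's counts are
# logged; outputs are keyed by family and sample name, never iteration
# order.

#' Build a pipeline run configuration
#'
#' @param transcriptomes named character vector of FASTA paths (names are
#'   sample ids; unnamed paths use the file base name).
#' @param refpkg_dirs character vector of reference package directories.
#' @param out_dir output directory.
#' @param input_type `"nuc"` (ORFs are extracted) or `"prot"`
#'   (pre-translated; used as single-frame "ORFs" as given).
#' @param min_orf_aa minimum ORF length in amino acids (default 30).
#' @param evalue_cutoff family E-value gate (default 1e-20).
#' @param top_k ORFs retained per family (default 3).
#' @param keep placements reported per query in jplace output
#'   (default all edges).
#' @param pendant_max optional explicit pendant threshold for
#'   classification (default: 2x median terminal branch per family).
#' @param seed integer seed recorded in the manifest (the pipeline itself
#'   draws no random numbers).
#' @return list of class `pia_config`.
#' @export
pia_config <- function(transcriptomes, refpkg_dirs, out_dir,
                       input_type = c("nuc", "prot"),
                       min_orf_aa = 30L, evalue_cutoff = 1e-20,
                       top_k = 3, keep = Inf, pendant_max = NULL,
                       seed = 1L) {
  input_type <- match.arg(input_type)
  if (is.null(names(transcriptomes))) {
    names(transcriptomes) <- tools::file_path_sans_ext(basename(transcriptomes))
  }
  structure(list(transcriptomes = transcriptomes,
                 refpkg_dirs = refpkg_dirs, out_dir = out_dir,
                 input_type = input_type, min_orf_aa = min_orf_aa,
                 evalue_cutoff = evalue_cutoff, top_k = top_k,
                 keep = keep, pendant_max = pendant_max, seed = seed),
            class = "pia_config")
}

#' Validate a pipeline configuration
#'
#' Checks inputs exist, packages validate, and thresholds are sane.
#' Reports issues instead of stopping; a run is blocked when any blocking
#' issue is present (unless forced).
#'
#' @param config a `pia_config`.
#' @return data.frame with columns `level` (`"error"`/`"warning"`) and
#'   `message`; zero rows means all good.
#' @export
validate_inputs <- function(config) {
  issues <- data.frame(level = character(0), message = character(0),
                       stringsAsFactors = FALSE)
  add <- function(level, msg) {
    issues[nrow(issues) + 1L, ] <<- list(level, msg)
  }
  for (i in seq_along(config$transcriptomes)) {
    p <- config$transcriptomes[i]
    if (!file.exists(p)) add("error", paste0("transcriptome not found: ", p))
  }
  if (length(config$refpkg_dirs) == 0L) add("error", "no reference packages")
  for (d in config$refpkg_dirs) {
    if (!dir.exists(d)) {
      add("error", paste0("package directory not found: ", d))
    } else {
      ok <- tryCatch({ read_refpkg(d); TRUE },
                     error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) add("error", paste0("package '", d, "': ", ok))
    }
  }
  if (config$min_orf_aa < 1) add("error", "min_orf_aa must be >= 1")
  if (config$evalue_cutoff <= 0) add("error", "evalue_cutoff must be > 0")
  if (config$top_k < 1) add("error", "top_k must be >= 1")
  issues
}

.fmt_num <- function(x) sprintf("%.6g", x)

#' Run the annotation pipeline
#'
#' Executes ORF extraction, homolog search, profile alignment, placement
#' and landmark classification for every (sample, family) pair, writing
#' per-family jplace files, tagged Newick gene trees with query tips
#' attached at their best placements, an annotation TSV, a family-by-
#' sample presence matrix, a structured run log and a run manifest under
#' `config$out_dir`. Rerunning with identical inputs reproduces
#' byte-identical outputs.
#'
#' @param config a `pia_config`.
#' @param force run even when [validate_inputs()] reports blocking issues.
#' @return the output directory, invisibly.
#' @export
run_pia <- function(config, force = FALSE) {
  issues <- validate_inputs(config)
  if (any(issues$level == "error") && !force) {
    stop("blocked by input validation: ", issues$message[issues$level == "error"][1])
  }
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  logmsg <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  pkgs <- lapply(config$refpkg_dirs, read_refpkg)
  names(pkgs) <- vapply(pkgs, `[[`, character(1), "family")
  pkgs <- pkgs[order(names(pkgs))]
  caches <- lapply(pkgs, placement_cache)
  s <- scoring_scheme()
  records <- list()
  stage_counts <- list()

  samples <- sort(names(config$transcriptomes))
  for (sample in samples) {
    path <- config$transcriptomes[[sample]]
    if (config$input_type == "nuc") {
      txs <- read_fasta(path, "nuc")
      orfs <- transcriptome_orfs(txs, min_aa = config$min_orf_aa)
      logmsg("[", sample, "] transcripts=", length(txs),
             " orfs=", nrow(orfs), " (min_aa=", config$min_orf_aa, ")")
    } else {
      prots <- read_fasta(path, "prot")
      orfs <- data.frame(transcript_id = names(prots), orf_index = 1L,
                         frame = 1L, strand = "+", nuc_start = 0L,
                         nuc_end = 3L * nchar(prots), aa_seq = unname(prots),
                         stringsAsFactors = FALSE)
      logmsg("[", sample, "] proteins=", nrow(orfs))
    }
    for (family in names(pkgs)) {
      pkg <- pkgs[[family]]
      hits <- search_family(orfs, pkg, s,
                            evalue_cutoff = config$evalue_cutoff,
                            top_k = config$top_k)
      orf_seqs <- stats::setNames(
        orfs$aa_seq, query_label(family, orfs$transcript_id, orfs$orf_index))
      placements <- list()
      grafts <- data.frame(edge_id = integer(0), distal = numeric(0),
                           pendant = numeric(0), label = character(0),
                           stringsAsFactors = FALSE)
      fam_records <- list()
      for (qid in hits$query_id) {
        ext <- add_to_alignment(pkg$ref_alignment, orf_seqs[[qid]], s,
                                query_id = qid)
        masked <- mask_query_to_ref(ext, qid)
        pl <- epa_place(caches[[family]], masked, query_id = qid,
                        keep = config$keep)
        placements[[qid]] <- pl
        best <- pl[pl$best, , drop = FALSE]
        grafts[nrow(grafts) + 1L, ] <-
          list(best$edge_id, best$distal_length, best$pendant_length, qid)
        rec <- classify_query(pl, pkg$landmarks, pkg$tree, family = family,
                              pendant_max = config$pendant_max)
        rec$sample <- sample
        fam_records[[qid]] <- rec
      }
      all_pl <- if (length(placements) > 0) do.call(rbind, placements) else
        epa_empty_placements()
      write_jplace(all_pl, pkg$tree,
                   file.path(out, paste0(sample, ".", family, ".jplace")))
      display <- read_newick(newick_string(pkg$tree, grafts = grafts,
                                           digits = 12))
      tagged <- tag_tree(display, pkg$landmarks, query_tips = grafts$label)
      writeLines(tagged, file.path(out, paste0(sample, ".", family,
                                               ".tagged.nwk")))
      records <- c(records, fam_records)
      stage_counts[[paste0(sample, ".", family)]] <- list(
        sample = sample, family = family, orfs = nrow(orfs),
        hits_retained = nrow(hits), placed = length(placements),
        records = length(fam_records))
      logmsg("[", sample, "/", family, "] hits=", nrow(hits),
             " placed=", length(placements))
    }
  }

  rec_df <- if (length(records) > 0) do.call(rbind, records) else
    data.frame(query_id = character(0), family = character(0),
               best_edge_id = integer(0), best_lwr = numeric(0),
               pendant_length = numeric(0), nearest_L1 = character(0),
               nearest_L1_dist = numeric(0), nearest_L2 = character(0),
               nearest_L2_dist = numeric(0), flag = character(0),
               sample = character(0), stringsAsFactors = FALSE)
  rec_df <- rec_df[order(rec_df$sample, rec_df$family, rec_df$query_id), ,
                   drop = FALSE]
  num_cols <- c("best_lwr", "pendant_length", "nearest_L1_dist",
                "nearest_L2_dist")
  rec_out <- rec_df
  for (cn in num_cols) rec_out[[cn]] <- .fmt_num(rec_out[[cn]])
  utils::write.table(rec_out, file.path(out, "annotation.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  M <- presence_matrix(rec_df, families = names(pkgs), samples = samples)
  utils::write.table(cbind(family = rownames(M), as.data.frame(M)),
                     file.path(out, "presence_matrix.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(log_lines, file.path(out, "run_log.txt"))
  manifest <- list(
    tool = "pia", version = as.character(utils::packageVersion("pia")),
    config = list(min_orf_aa = config$min_orf_aa,
                  evalue_cutoff = config$evalue_cutoff,
                  top_k = config$top_k, input_type = config$input_type,
                  seed = config$seed),
    samples = samples, families = names(pkgs),
    stage_counts = stage_counts)
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

epa_empty_placements <- function() {
  pl <- data.frame(query_id = character(0), edge_id = integer(0),
                   log_likelihood = numeric(0), lwr = numeric(0),
                   distal_length = numeric(0), pendant_length = numeric(0),
                   best = logical(0), stringsAsFactors = FALSE)
  class(pl) <- c("pia_placements", "data.frame")
  pl
}
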
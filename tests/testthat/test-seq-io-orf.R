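test_that("read_fasta parses records, joins wrapped lines, validates", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT"), f)
  expect_equal(read_fasta(f, "nuc"), c(a = "ACGT"))

  writeLines(c(">a", "AC", "GT"), f)
  expect_equal(read_fasta(f, "nuc"), c(a = "ACGT"))

  writeLines(c(">a", "ACGT", ">a", "GG"), f)
  expect_error(read_fasta(f, "nuc"), "line 3.*duplicate")

  writeLines(c(">a", "ACGU"), f)
  expect_error(read_fasta(f, "nuc"), "line 2.*illegal residue")

  writeLines(c(">", "ACGT"), f)
  expect_error(read_fasta(f, "nuc"), "line 1.*empty header")

  # terminal stop marker stripped on protein storage, internal rejected
  writeLines(c(">p", "MKV*"), f)
  expect_equal(read_fasta(f, "prot"), c(p = "MKV"))
  writeLines(c(">p", "MK*V"), f)
  expect_error(read_fasta(f, "prot"), "internal stop")
})

test_that("write_fasta round-trips and wraps at the line width", {
  withr::local_seed(42)
  seqs <- stats::setNames(vapply(1:5, function(i) random_protein(10 + 13 * i),
                                 character(1)), paste0("s", 1:5))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  expect_identical(read_fasta(f, "prot"), seqs)

  write_fasta(c(long = random_protein(61)), f)
  lines <- readLines(f)
  expect_length(lines, 3L)  # header + two wrapped sequence lines
  expect_equal(nchar(lines[2]), 60L)
  expect_equal(nchar(lines[3]), 1L)

  expect_error(write_fasta(character(0), f), "empty")
})

test_that("ORF length threshold is a strict boundary at min_aa", {
  # 29 codons between stops -> excluded at min_aa = 30
  s29 <- paste0("TAA", strrep("GCT", 29), "TAA")
  expect_equal(nrow(six_frame_orfs(s29, min_aa = 30)[
    six_frame_orfs(s29, min_aa = 30)$frame == 1 &
      six_frame_orfs(s29, min_aa = 30)$strand == "+", ]), 0L)
  # 30 codons -> exactly one forward frame-1 ORF of length 30
  s30 <- paste0("TAA", strrep("GCT", 30), "TAA")
  orfs <- six_frame_orfs(s30, min_aa = 30)
  fwd1 <- orfs[orfs$frame == 1 & orfs$strand == "+", ]
  expect_equal(nrow(fwd1), 1L)
  expect_equal(nchar(fwd1$aa_seq), 30L)
  expect_equal(fwd1$aa_seq, strrep("A", 30))
  expect_equal(c(fwd1$nuc_start, fwd1$nuc_end), c(3, 93))
})

test_that("reverse-complement ORFs mirror forward ORFs with mapped coordinates", {
  withr::local_seed(7)
  s <- paste(sample(c("A", "C", "G", "T"), 210, replace = TRUE), collapse = "")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  o1 <- six_frame_orfs(s, min_aa = 10)
  o2 <- six_frame_orfs(rc, min_aa = 10)
  flip <- function(o, L) {
    data.frame(strand = ifelse(o$strand == "+", "-", "+"),
               nuc_start = L - o$nuc_end, nuc_end = L - o$nuc_start,
               aa_seq = o$aa_seq)
  }
  key <- function(d) {
    d <- d[order(d$strand, d$nuc_start, d$aa_seq), ]
    paste(d$strand, d$nuc_start, d$nuc_end, d$aa_seq, collapse = "|")
  }
  expect_equal(key(flip(o2, nchar(s))),
               key(o1[, c("strand", "nuc_start", "nuc_end", "aa_seq")]))
})

test_that("every reported ORF re-translates from its coordinates", {
  withr::local_seed(11)
  gc <- Biostrings::GENETIC_CODE
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 150,
                      replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
               collapse = "")
    orfs <- six_frame_orfs(s, min_aa = 5)
    for (i in seq_len(nrow(orfs))) {
      sub <- substr(s, orfs$nuc_start[i] + 1, orfs$nuc_end[i])
      if (orfs$strand[i] == "-") {
        sub <- chartr("ACGTN", "TGCAN",
                      paste(rev(strsplit(sub, "")[[1]]), collapse = ""))
      }
      codons <- substring(sub, seq(1, nchar(sub), 3), seq(3, nchar(sub), 3))
      aa <- unname(gc[codons]); aa[is.na(aa)] <- "X"
      expect_equal(paste(aa, collapse = ""), orfs$aa_seq[i])
    }
  }
})

test_that("raising min_aa only ever removes ORFs", {
  withr::local_seed(3)
  s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  prev <- six_frame_orfs(s, min_aa = 5)
  for (m in c(10, 20, 40)) {
    cur <- six_frame_orfs(s, min_aa = m)
    expect_true(all(paste(cur$strand, cur$nuc_start, cur$nuc_end) %in%
                    paste(prev$strand, prev$nuc_start, prev$nuc_end)))
    prev <- cur
  }
})

test_that("query labels render family/transcript/ORF without whitespace", {
  expect_equal(query_label("Gprk1", "UN0029", 1), "Gprk1_hit_UN0029_ORF1")
  expect_equal(query_label("ninaE", "c12", 3), "ninaE_hit_c12_ORF3")
  expect_error(query_label("", "x", 1), "non-empty")
  expect_error(query_label("f", "", 1), "non-empty")
})
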
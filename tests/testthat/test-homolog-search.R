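test_that("local alignment recovers self-alignment score and symmetry", {
  s <- scoring_scheme()
  seq <- "HEAGAWGHEE"
  al <- local_align(seq, seq, s)
  chars <- strsplit(seq, "")[[1]]
  expect_equal(al$raw_score, sum(diag(s$matrix[chars, chars])))
  expect_equal(al$q_start, 0L)
  expect_equal(al$q_end, nchar(seq))

  # no positive-scoring residue pair -> empty alignment, score 0
  al0 <- local_align("AAAA", "WWWW", s)
  expect_equal(al0$raw_score, 0)
  expect_equal(al0$aligned, c("", ""))

  # symmetry of the optimal score
  for (pair in list(c("MKVLWHE", "MKLWHE"), c("ARNDC", "DCARN"))) {
    expect_equal(local_align(pair[1], pair[2], s)$raw_score,
                 local_align(pair[2], pair[1], s)$raw_score)
  }
  expect_error(local_align("", "MKV", s), "non-empty")
})

test_that("local alignment matches recursion oracle on short sequences", {
  s <- scoring_scheme()
  withr::local_seed(19)
  for (i in 1:12) {
    q <- paste(sample(c("A", "C", "D", "E"), sample(3:6, 1), replace = TRUE),
               collapse = "")
    t <- paste(sample(c("A", "C", "D", "E"), sample(3:6, 1), replace = TRUE),
               collapse = "")
    expect_equal(local_align(q, t, s)$raw_score, sw_score_oracle(q, t, s),
                 info = paste(q, t))
  }
})

test_that("E-value follows the Karlin-Altschul formula", {
  s <- scoring_scheme(lambda = 0.267, K = 0.041)
  expect_equal(evalue(50, 100, 100, s), 0.041 * 1e4 * exp(-13.35))
  # linear in n, strictly decreasing in S
  expect_equal(evalue(50, 100, 200, s), 2 * evalue(50, 100, 100, s))
  expect_lt(evalue(51, 100, 100, s), evalue(50, 100, 100, s))
  expect_error(evalue(50, 0, 100, s), ">= 1")
})

test_that("family search gates on E-value and keeps the top-k ORFs", {
  s <- scoring_scheme()
  withr::local_seed(23)
  bait <- random_protein(120)
  # prefixes of the bait give a ladder of scores / E-values
  lens <- c(120, 80, 60, 45, 36, 25)
  orfs <- stats::setNames(substr(rep(bait, length(lens)), 1, lens),
                          sprintf("orf%02d", seq_along(lens)))
  pkg <- list(family = "fam", baits = c(b1 = bait))
  ev <- vapply(orfs, function(o) {
    evalue(local_align(o, bait, s)$raw_score, nchar(o), nchar(bait), s)
  }, numeric(1))
  passing <- names(ev)[ev <= 1e-20]
  expect_gte(length(passing), 4L)        # fixture sanity: top-k must bind
  expect_lt(length(passing), length(ev)) # and the gate must bind

  hits <- search_family(orfs, pkg, s)
  expect_equal(nrow(hits), 3L)
  expect_true(all(hits$evalue <= 1e-20))
  expect_equal(hits$query_id, names(sort(ev))[1:3])

  # disabling both filters ranks everything
  all_hits <- search_family(orfs, pkg, s, evalue_cutoff = Inf, top_k = Inf)
  expect_equal(nrow(all_hits), length(orfs))
  expect_equal(all_hits$evalue, sort(all_hits$evalue))

  # nothing passes a tiny cutoff: empty result, no error
  none <- search_family(orfs, pkg, s, evalue_cutoff = 1e-300)
  expect_equal(nrow(none), 0L)
})

test_that("search retention is invariant to ORF input order", {
  s <- scoring_scheme()
  withr::local_seed(31)
  bait <- random_protein(100)
  orfs <- stats::setNames(substr(rep(bait, 5), 1, c(100, 70, 55, 48, 40)),
                          paste0("q", 1:5))
  pkg <- list(family = "fam", baits = c(b1 = bait))
  h1 <- search_family(orfs, pkg, s)
  h2 <- search_family(rev(orfs), pkg, s)
  expect_identical(h1, h2)
  expect_error(search_family(orfs, list(family = "f", baits = character(0)), s),
               "no baits")
})

test_that("tabular hit import converts coordinates and validates columns", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("q1", "b1", "98.5", "50", "1", "0",
                     "1", "10", "5", "54", "1e-30", "120"), collapse = "\t"), f)
  hits <- import_tabular_hits(f, family_id = "fam")
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$q_start, 0L)
  expect_equal(hits$q_end, 10L)
  expect_equal(hits$b_start, 4L)
  expect_equal(hits$evalue, 1e-30)

  writeLines(paste(rep("x", 11), collapse = "\t"), f)
  expect_error(import_tabular_hits(f), "line 1.*12 columns")
})
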
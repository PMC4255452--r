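test_that("dereplication removes duplicates and substrings, keeps longest", {
  res <- dereplicate(c(A = "MKV", B = "MKV"))
  expect_equal(names(res$retained), "A")
  expect_equal(res$removed$removed_id, "B")
  expect_equal(res$removed$representative, "A")

  res2 <- dereplicate(c(A = "MKVLW", B = "KVL"))
  expect_equal(names(res2$retained), "A")  # exact substring removed

  withr::local_seed(14)
  rnd <- stats::setNames(vapply(1:10, function(i) random_protein(25),
                                character(1)), paste0("s", 1:10))
  res3 <- dereplicate(rnd)
  expect_equal(length(res3$retained), 10L)  # unrelated sequences all kept
  # oracle: no pair is identical or substring-related
  for (i in 1:9) for (j in (i + 1):10) {
    expect_false(grepl(rnd[i], rnd[j], fixed = TRUE) ||
                 grepl(rnd[j], rnd[i], fixed = TRUE))
  }
  # idempotence
  res4 <- dereplicate(res3$retained)
  expect_identical(res4$retained, res3$retained)
  expect_equal(nrow(res4$removed), 0L)
  expect_error(dereplicate(character(0)), "empty")
  expect_error(dereplicate(c(A = "MK"), identity_threshold = 0), "in \\(0, 1\\]")
})

test_that("long-branch pruning applies the factor-x-median rule iteratively", {
  # all terminal lengths equal: nothing removed
  tr <- read_newick("((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  res <- prune_long_branches(tr, factor = 10)
  expect_equal(length(res$tree$tip.label), 4L)
  expect_equal(nrow(res$removed), 0L)

  # one extreme outlier among 10 tips: exactly that tip goes
  tips <- paste0("(t", 1:9, ":0.1", collapse = ",")
  tr10 <- read_newick(paste0("(", paste0("t", 1:9, ":0.1", collapse = ","),
                             ",bad:10);"))
  res10 <- prune_long_branches(tr10, factor = 10)
  expect_identical(res10$removed$tip, "bad")
  expect_equal(length(res10$tree$tip.label), 9L)

  # ladder of lengths: match a direct simulation of the stated rule
  lens <- c(0.1, 0.1, 0.1, 0.1, 0.5, 1.2, 3.0, 9.0)
  nwk <- paste0("(", paste0("t", 1:8, ":", lens, collapse = ","), ");")
  sim_lens <- lens; names(sim_lens) <- paste0("t", 1:8)
  repeat {
    if (length(sim_lens) <= 3) break
    med <- stats::median(sim_lens)
    over <- sim_lens > 3 * med
    if (!any(over)) break
    worst <- names(sort(sim_lens[over], decreasing = TRUE))[1]
    sim_lens <- sim_lens[names(sim_lens) != worst]
  }
  res8 <- prune_long_branches(read_newick(nwk), factor = 3)
  expect_setequal(res8$tree$tip.label, names(sim_lens))
  # never goes below 3 tips
  expect_gte(length(res8$tree$tip.label), 3L)
  expect_error(prune_long_branches(read_newick("(a:1,b:1,c:1);")), "too small")
})

test_that("branch re-optimization recovers simulated lengths monotonically", {
  m <- test_model
  tr <- random_tree(5, seed = 31, mean_branch = 0.15)
  aln <- evolve(tr, m, 1200, seed = 32)
  start <- tr
  start$edge.length <- rep(0.3, length(start$edge.length))
  res <- reoptimize_branch_lengths(start, aln, m, sweeps = 4)
  expect_true(all(diff(res$loglik_trace) > -1e-9))
  rel_err <- abs(res$tree$edge.length - tr$edge.length) / tr$edge.length
  expect_lt(stats::median(rel_err), 0.3)
  # restart at the optimum changes little
  res2 <- reoptimize_branch_lengths(res$tree, aln, m, sweeps = 1)
  expect_lt(res2$loglik - res$loglik, 0.1)
})

test_that("reference packages round-trip through their directory layout", {
  pkg <- simulate_refpkg("rhod", n_tips = 6, n_sites = 80, seed = 41)
  d <- withr::local_tempdir()
  write_refpkg(pkg, d)
  expect_setequal(dir(d), c("manifest.json", "baits.faa", "ref.aln.faa",
                            "ref.nwk", "landmarks.tsv"))
  pkg2 <- read_refpkg(d)
  expect_identical(pkg2$family, pkg$family)
  expect_identical(as.character(pkg2$ref_alignment)[order(names(pkg2$ref_alignment))],
                   as.character(pkg$ref_alignment)[order(names(pkg$ref_alignment))])
  expect_identical(unname(pkg2$baits[names(pkg$baits)]), unname(pkg$baits))
  expect_identical(newick_string(pkg2$tree, digits = 12),
                   newick_string(pkg$tree, digits = 12))
  expect_identical(as.data.frame(pkg2$landmarks)[order(pkg2$landmarks$tip_id), ],
                   as.data.frame(pkg$landmarks)[order(pkg$landmarks$tip_id), ],
                   ignore_attr = TRUE)
  expect_identical(pkg2$model$name, pkg$model$name)
  expect_silent(validate_refpkg(pkg2))

  # tampering is caught
  writeLines("corrupted", file.path(d, "ref.nwk"))
  expect_error(read_refpkg(d), "checksum.*ref.nwk")
  file.remove(file.path(d, "ref.nwk"))
  expect_error(read_refpkg(d), "missing file")
})

test_that("tip/row mismatches fail package validation", {
  pkg <- simulate_refpkg("fam", n_tips = 5, n_sites = 40, seed = 51)
  d <- withr::local_tempdir()
  write_refpkg(pkg, d)
  # append an extra alignment row and refresh the checksum via manifest edit
  rows <- read_fasta(file.path(d, "ref.aln.faa"), "prot_gapped")
  rows <- c(rows, extra = rows[[1]])
  write_fasta(rows, file.path(d, "ref.aln.faa"))
  man <- jsonlite::read_json(file.path(d, "manifest.json"))
  man$md5[["ref.aln.faa"]] <-
    unname(tools::md5sum(file.path(d, "ref.aln.faa")))
  jsonlite::write_json(man, file.path(d, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  expect_error(read_refpkg(d), "tip set does not match")
})
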
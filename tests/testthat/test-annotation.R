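test_that("tag_tree suffixes exactly the mapped tips and round-trips", {
  tr <- read_newick("((a:0.1,b:0.2):0.05,(c:0.1,q1:0.2):0.1,d:0.4);")
  lm <- landmark_map(c("a", "b", "c"),
                     c("LANDMARK1", "LANDMARK1", "LANDMARK2"))
  s <- tag_tree(tr, lm, query_tips = "q1")
  tagged <- read_newick(s)
  expect_setequal(tagged$tip.label,
                  c("a_LANDMARK1", "b_LANDMARK1", "c_LANDMARK2", "q1_QUERY", "d"))
  # stripping suffixes recovers the input tree byte-identically
  stripped <- gsub("_(LANDMARK[12]|QUERY)", "", s)
  expect_identical(stripped, newick_string(tr, tags = FALSE, digits = 12))

  # empty landmark map: only QUERY suffixes
  s2 <- tag_tree(tr, landmark_map(character(0), character(0)),
                 query_tips = "q1")
  expect_setequal(read_newick(s2)$tip.label, c("a", "b", "c", "q1_QUERY", "d"))

  # collision with an existing suffix is refused
  tr2 <- read_newick("(x_QUERY:0.1,y:0.1,z:0.1);")
  expect_error(tag_tree(tr2, lm), "suffix")
})

test_that("classification follows the nearest-landmark / pendant rule", {
  # a, b are tier-1 landmarks; d is tier-2; c unlabeled
  tr <- read_newick("((a:0.1,b:0.1):0.1,(c:0.1,d:0.1):0.1);")
  lm <- landmark_map(c("a", "b", "d"),
                     c("LANDMARK1", "LANDMARK1", "LANDMARK2"))
  te <- tree_edges(tr)
  ea <- te$edge_id[!is.na(te$tip_label) & te$tip_label == "a"]
  ed <- te$edge_id[!is.na(te$tip_label) & te$tip_label == "d"]
  mk_pl <- function(eid, pend) {
    structure(data.frame(query_id = "q", edge_id = eid, log_likelihood = -1,
                         lwr = 0.9, distal_length = 0.05,
                         pendant_length = pend, best = TRUE),
              class = c("pia_placements", "data.frame"))
  }
  # next to a LANDMARK1 tip, short pendant -> candidate ortholog context
  rec <- classify_query(mk_pl(ea, 0.01), lm, tr, family = "f")
  expect_equal(rec$flag, "candidate_ortholog_context")
  expect_equal(rec$nearest_L1, "a")
  # same attachment, very long pendant -> ambiguous
  rec_long <- classify_query(mk_pl(ea, 5), lm, tr, family = "f")
  expect_equal(rec_long$flag, "ambiguous")
  # deep among tier-2 -> distant relative context
  rec2 <- classify_query(mk_pl(ed, 0.01), lm, tr, family = "f")
  expect_equal(rec2$flag, "distant_relative_context")
  expect_equal(rec2$nearest_L2, "d")
  # exactly equidistant tiers -> ambiguous (symmetric quartet midpoint)
  mid <- te$edge_id[!te$is_terminal][1]
  rec3 <- classify_query(mk_pl(mid, 0.01), lm, tr, family = "f")
  rec3b <- classify_query(mk_pl(mid, 0.01), lm, tr, family = "f")
  expect_identical(rec3, rec3b)  # pure function of its inputs
  # distances are always reported
  expect_true(is.finite(rec$nearest_L1_dist) && is.finite(rec$nearest_L2_dist))
  # no landmarks at all -> ambiguous with warning
  expect_warning(
    rec0 <- classify_query(mk_pl(ea, 0.01),
                           landmark_map(character(0), character(0)), tr, "f"),
    "no landmarks")
  expect_equal(rec0$flag, "ambiguous")
})

test_that("equidistant tier-1 and tier-2 landmarks yield an ambiguous flag", {
  tr <- read_newick("((a:0.1,b:0.3):0.1,(c:0.1,d:0.3):0.1);")
  lm <- landmark_map(c("a", "c"), c("LANDMARK1", "LANDMARK2"))
  te <- tree_edges(tr)
  mid <- te$edge_id[!te$is_terminal][1]
  pl <- structure(data.frame(query_id = "q", edge_id = mid,
                             log_likelihood = -1, lwr = 1,
                             distal_length = 0, pendant_length = 0.01,
                             best = TRUE),
                  class = c("pia_placements", "data.frame"))
  rec <- classify_query(pl, lm, tr, family = "f")
  expect_equal(rec$nearest_L1_dist, rec$nearest_L2_dist, tolerance = 1e-12)
  expect_equal(rec$flag, "ambiguous")
})

test_that("presence matrix marks candidate-ortholog families per sample", {
  recs <- data.frame(
    query_id = c("q1", "q2", "q3"),
    family = c("f1", "f1", "f2"),
    flag = c("candidate_ortholog_context", "distant_relative_context",
             "distant_relative_context"),
    sample = c("A", "B", "B"), stringsAsFactors = FALSE)
  M <- presence_matrix(recs)
  expect_equal(M["f1", "A"], 1L)
  expect_equal(M["f1", "B"], 0L)
  expect_equal(sum(M), 1L)  # column/row sums match candidate tallies
  # sample with only distant-relative records stays all-zero
  expect_equal(unname(M[, "B"]), c(0L, 0L))
  # contamination calls pass through as an annotation
  M2 <- presence_matrix(recs, contamination = data.frame(
    family = "f2", sample = "A", stringsAsFactors = FALSE))
  expect_true(attr(M2, "contaminated")["f2", "A"])
})
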
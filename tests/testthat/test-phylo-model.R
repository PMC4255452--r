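test_that("rate matrix satisfies reversibility, zero row sums, unit mean rate", {
  m <- test_model
  Q <- m$Q
  pi <- as.numeric(m$freqs)
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  expect_lt(max(abs(diag(pi) %*% Q - t(diag(pi) %*% Q))), 1e-12)
  expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
  expect_error(substitution_model(freqs = rep(0.05, 19)), "20")
  bad <- wag_exchangeabilities(); bad[1, 2] <- bad[1, 2] + 1
  expect_error(substitution_model(exchangeabilities = bad), "symmetric")
})

test_that("transition probabilities behave like a CTMC", {
  m <- test_model
  pi <- as.numeric(m$freqs)
  expect_equal(transition_probs(m, 0), diag(20), ignore_attr = TRUE)
  # ergodic limit: long branches forget the starting state
  Pinf <- transition_probs(m, 50)
  expect_lt(max(abs(sweep(Pinf, 2, pi))), 1e-6)
  # Chapman-Kolmogorov on random time splits
  withr::local_seed(4)
  for (i in 1:5) {
    s <- stats::runif(1, 0, 2); t <- stats::runif(1, 0, 2)
    expect_lt(max(abs(transition_probs(m, s) %*% transition_probs(m, t) -
                        transition_probs(m, s + t))), 1e-8)
  }
  expect_lt(max(abs(rowSums(transition_probs(m, 0.37)) - 1)), 1e-10)
  expect_error(transition_probs(m, -0.1), ">= 0")
})

test_that("discrete gamma rates have unit mean and correct limits", {
  expect_equal(gamma_category_rates(0.7, 1), 1.0)
  expect_equal(gamma_category_rates(123, 1), 1.0)
  expect_lt(max(abs(gamma_category_rates(1e6, 4) - 1)), 1e-2)
  r <- gamma_category_rates(0.5, 4)
  expect_equal(mean(r), 1, tolerance = 1e-10)
  # oracle: numerical quadrature of the quantile construction
  alpha <- 0.5; k <- 4
  breaks <- stats::qgamma(seq(0, 1, length.out = k + 1), alpha, rate = alpha)
  oracle <- vapply(seq_len(k), function(i) {
    stats::integrate(function(x) x * stats::dgamma(x, alpha, rate = alpha),
                     breaks[i], breaks[i + 1], rel.tol = 1e-10)$value * k
  }, numeric(1))
  expect_equal(r, oracle / mean(oracle), tolerance = 1e-6)
  expect_error(gamma_category_rates(-1, 4), "positive")
})

test_that("pruning equals the stationary log-density on a zero-length cherry", {
  m <- test_model
  tr <- read_newick("(a:0,b:0);")
  seq <- "ARNDV"
  aln <- alignment(c(a = seq, b = seq))
  expected <- sum(log(m$freqs[strsplit(seq, "")[[1]]]))
  expect_equal(pruning_loglik(tr, aln, m), expected, tolerance = 1e-10)
})

test_that("pruning matches explicit ancestral-state enumeration", {
  m <- test_model
  withr::local_seed(101)
  for (i in 1:5) {
    n_tips <- sample(3:4, 1)
    tr <- random_tree(n_tips, seed = sample.int(1e6, 1))
    aln <- evolve(tr, m, n_sites = sample(2:4, 1), seed = sample.int(1e6, 1))
    expect_equal(pruning_loglik(tr, aln, m),
                 brute_force_loglik(tr, aln, m), tolerance = 1e-8)
  }
})

test_that("pruning agrees with an independent likelihood implementation", {
  skip_if_not_installed("phangorn")
  m <- test_model
  tr <- random_tree(7, seed = 77)
  aln <- evolve(tr, m, 60, seed = 78)
  pd <- phangorn::phyDat(aln_matrix(aln), type = "AA")
  fit <- phangorn::pml(tr, pd, model = "WAG")
  expect_equal(pruning_loglik(tr, aln, m), as.numeric(fit$logLik),
               tolerance = 1e-6)
})

test_that("log-likelihood is invariant to the choice of root", {
  m <- test_model
  tr <- random_tree(6, seed = 55)
  aln <- evolve(tr, m, 30, seed = 56)
  ref <- pruning_loglik(tr, aln, m)
  for (tip in tr$tip.label[1:3]) {
    re <- ape::root(tr, outgroup = tip, resolve.root = TRUE)
    expect_equal(pruning_loglik(as_pia_tree(re), aln, m), ref,
                 tolerance = 1e-9)
  }
})

test_that("gamma-rate likelihood averages categories (2-category check)", {
  mg <- substitution_model(n_gamma_cats = 2, alpha = 0.6)
  tr <- random_tree(4, seed = 9)
  aln <- evolve(tr, test_model, 5, seed = 10)
  # oracle: mean of per-category likelihoods with scaled branch lengths
  per_cat <- vapply(mg$rates, function(r) {
    tr2 <- tr; tr2$edge.length <- tr$edge.length * r
    exp_site <- exp(vapply(seq_len(5), function(s) {
      sub <- alignment(vapply(unclass(aln), substr, character(1), s, s))
      pruning_loglik(tr2, sub, test_model)
    }, numeric(1)))
    exp_site
  }, numeric(5))
  expect_equal(pruning_loglik(tr, aln, mg), sum(log(rowMeans(per_cat))),
               tolerance = 1e-8)
})

test_that("branch optimization recovers a simulated length and is monotone", {
  m <- test_model
  tr <- read_newick("(a:0.15,b:0.15);")  # path length 0.3 between tips
  aln <- evolve(tr, m, 5000, seed = 123)
  start <- tr; start$edge.length <- c(0.5, 0.5)
  ll0 <- pruning_loglik(start, aln, m)
  res <- optimize_branch(start, 0L, aln, m)
  expect_gte(res$loglik, ll0 - 1e-9)
  res2 <- optimize_branch(res$tree, 1L, aln, m)
  expect_gte(res2$loglik, res$loglik - 1e-9)
  total <- sum(res2$tree$edge.length)
  expect_lt(abs(total - 0.3), 0.05)

  # idempotence at the optimum
  res3 <- optimize_branch(res2$tree, 1L, aln, m)
  expect_lt(abs(res3$length - res2$tree$edge.length[2]), 1e-4)
  expect_lt(abs(res3$loglik - res2$loglik), 1e-6)
})

test_that("identical tip sequences drive a branch to the lower bound", {
  m <- test_model
  tr <- read_newick("((a:0.2,b:0.2):0.1,c:0.3,d:0.3);")
  seqs <- random_protein(40)
  aln <- alignment(c(a = seqs, b = seqs, c = random_protein(40),
                     d = random_protein(40)))
  te <- tree_edges(tr)
  eid <- te$edge_id[!is.na(te$tip_label) & te$tip_label == "a"]
  res <- optimize_branch(tr, eid, aln, m)
  res <- optimize_branch(res$tree,
                         te$edge_id[!is.na(te$tip_label) & te$tip_label == "b"],
                         aln, m)
  expect_lt(res$tree$edge.length[te$tip_label %in% "a" & !is.na(te$tip_label)],
            1e-6)
})
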
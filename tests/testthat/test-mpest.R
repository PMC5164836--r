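# Pseudo-likelihood species-tree estimation: triple probabilities and
# counts, the objective, branch-length optimization, and the NNI search.

test_that("coalescent triple probabilities obey the closed form", {
  expect_equal(unname(triple_probabilities(0)[1, ]), rep(1 / 3, 3))
  expect_equal(unname(triple_probabilities(50)[1, ]), c(1, 0, 0),
               tolerance = 1e-12)
  expect_equal(triple_probabilities(1)[1, "concordant"],
               c(concordant = 1 - (2 / 3) * exp(-1)))  # 0.7547471...
  Ts <- seq(0, 8, by = 0.25)
  P <- triple_probabilities(Ts)
  expect_equal(rowSums(P), rep(1, length(Ts)))
  expect_true(all(diff(P[, "concordant"]) > 0))
  expect_error(triple_probabilities(-0.1), ">= 0")
})

test_that("triple counting matches per-tree brute-force extraction", {
  t1 <- read_newick(text = "((A,B),C);")
  ct <- count_triples(rep(list(t1), 10))
  expect_equal(unname(ct$counts[1, ]), c(10, 0, 0))

  # missing taxa change per-triple totals
  trees <- list(read_newick(text = "(((A,B),C),D);"),
                read_newick(text = "((A,B),C);"),
                read_newick(text = "((A,B),D);"))
  ct <- count_triples(trees)
  tot <- rowSums(ct$counts)
  trip_lab <- apply(ct$triples, 1, function(ix)
    paste(ct$species[ix], collapse = ""))
  expect_equal(tot[trip_lab == "ABC"], 2)
  expect_equal(tot[trip_lab == "ABD"], 2)
  expect_equal(tot[trip_lab == "ACD"], 1)
  expect_equal(tot[trip_lab == "BCD"], 1)

  expect_error(count_triples(list(read_newick(text = "((A,A),B);"))),
               "duplicate species")

  # random gene-tree sets against the prune-and-count oracle
  set.seed(21)
  labs <- paste0("s", 1:8)
  trees <- lapply(1:6, function(i) {
    keep <- sort(sample(labs, sample(5:8, 1)))
    tr <- ape::rtree(length(keep), tip.label = sample(keep))
    tr
  })
  ct <- count_triples(trees, species = labs)
  for (r in seq_len(nrow(ct$triples))) {
    trio <- ct$species[ct$triples[r, ]]
    want <- c("ab|c" = 0, "ac|b" = 0, "bc|a" = 0)
    for (tr in trees) {
      if (!all(trio %in% tr$tip.label)) next
      res <- oracle_triple(tr, trio)
      want[res] <- want[res] + 1
    }
    expect_equal(unname(ct$counts[r, ]), unname(want))
  }
})

test_that("pseudo-log-likelihood equals an independent re-summation", {
  sp3 <- read_newick(text = "((A,B),C);")
  zero <- triple_counts(c("A", "B", "C"), matrix(0, 1, 3), n_trees = 0)
  expect_equal(pseudo_loglik(sp3, zero, tau = 2), 0)

  # one concordant triple, large T: approaches 0 from below
  ct <- triple_counts(c("A", "B", "C"), matrix(c(10, 0, 0), 1), n_trees = 10)
  ll_big <- pseudo_loglik(sp3, ct, tau = 15)
  expect_lt(ll_big, 0)
  expect_gt(ll_big, -1e-5)
  expect_lt(pseudo_loglik(sp3, ct, tau = 1), ll_big)

  # caterpillar with hand-enumerated paths as the oracle
  set.seed(17)
  cat5 <- read_newick(text = "((((A,B),C),D),E);")
  taus <- c(0.7, 1.3, 0.4)  # above {A,B}, {A,B,C}, {A,B,C,D}
  counts <- matrix(rpois(30, 40), 10, 3)
  ct <- triple_counts(c("A", "B", "C", "D", "E"), counts)
  tau_named <- stats::setNames(
    taus, vapply(list(c("A", "B"), c("A", "B", "C"), c("A", "B", "C", "D")),
                 paste, "", collapse = "\r"))
  got <- pseudo_loglik(cat5, ct, tau = tau_named)
  # oracle: reuse the hand-enumerated caterpillar paths to get each T
  exp_ct <- caterpillar5_expected_counts(taus[1], taus[2], taus[3], N = 1)
  ll <- 0
  for (r in 1:10) {
    pr <- exp_ct$counts[r, ]  # N=1 gives the probabilities themselves
    ll <- ll + sum(counts[r, ] * log(pr))
  }
  expect_equal(got, ll, tolerance = 1e-10)

  expect_error(pseudo_loglik(read_newick(text = "((A,B),(C,E));"), ct),
               "absent from tree")
})

test_that("single-branch optimum matches the closed-form inversion and grid search", {
  sp3 <- read_newick(text = "((A,B),C);")
  n <- c(70, 20, 10)
  ct <- triple_counts(c("A", "B", "C"), matrix(n, 1), n_trees = sum(n))
  fit <- optimize_branch_lengths(sp3, ct)
  t_closed <- -log((3 / 2) * (1 - n[1] / sum(n)))
  expect_equal(unname(fit$tau), t_closed, tolerance = 1e-5)
  # grid search + golden-section refinement as an independent check
  f <- function(x) pseudo_loglik(sp3, ct, tau = x)
  grid <- seq(1e-8, 5, length.out = 2001)
  x0 <- grid[which.max(vapply(grid, f, numeric(1)))]
  opt <- stats::optimize(f, c(max(1e-8, x0 - 0.01), x0 + 0.01),
                         maximum = TRUE, tol = 1e-9)
  expect_equal(t_closed, opt$maximum, tolerance = 1e-4)

  # uniform counts: star-tree signal drives tau to the lower bound
  ctu <- triple_counts(c("A", "B", "C"), matrix(c(5, 5, 5), 1), n_trees = 15)
  fitu <- optimize_branch_lengths(sp3, ctu)
  expect_lt(unname(fitu$tau), 1e-6)
})

test_that("branch lengths are recovered from counts generated at known tau", {
  set.seed(2024)
  p <- triple_probabilities(1.0)[1, ]
  n <- as.vector(stats::rmultinom(1, 1e4, p))
  ct <- triple_counts(c("A", "B", "C"), matrix(n, 1), n_trees = 1e4)
  fit <- optimize_branch_lengths(read_newick(text = "((A,B),C);"), ct)
  expect_equal(unname(fit$tau), 1.0, tolerance = 0.05)
  # the optimum is a local maximum against +-10% perturbations
  for (f in c(0.9, 1.1))
    expect_lte(pseudo_loglik(fit$tree, ct, tau = unname(fit$tau) * f),
               fit$logLik)
})

test_that("the expectation-matching 5-taxon tree is the global optimum", {
  truth <- read_newick(text = "((((A,B),C),D),E);")
  ct <- caterpillar5_expected_counts(0.8, 0.8, 0.8, N = 1000)
  lls <- vapply(all_rooted_topologies(c("A", "B", "C", "D", "E")),
                function(tp) optimize_branch_lengths(tp, ct)$logLik,
                numeric(1))
  best <- max(lls)
  truth_ll <- optimize_branch_lengths(truth, ct)$logLik
  expect_equal(truth_ll, best, tolerance = 1e-9)
  # strictly better than any different topology (no NNI neighbour improves)
  expect_lt(sort(lls, decreasing = TRUE)[2], best - 1e-3)

  # starting at the truth, the search stays there
  fit <- mpest(ct, start = truth, n_restarts = 1)
  expect_equal(rf_dist(fit$tree, truth), 0)
})

test_that("the search never scores below its start tree", {
  set.seed(64)
  labs <- sort(paste0("s", 1:6))
  m <- choose(6, 3)
  for (i in 1:3) {
    counts <- matrix(rpois(3 * m, 8), m, 3)
    ct <- triple_counts(labs, counts)
    start <- ape::rtree(6, tip.label = sample(labs))
    fit <- mpest(ct, start = start, n_restarts = 1)
    expect_gte(fit$logLik, optimize_branch_lengths(start, ct)$logLik - 1e-9)
  }
  expect_error(mpest(triple_counts(c("A", "B", "C"),
                                   matrix(c(3, 1, 1), 1))), ">= 4 species")
})

test_that("mpest methods expose the fit consistently", {
  sp <- rhodophyta_tree()
  gts <- sim_msc_gene_trees(sp, 60, seed = 3)
  fit <- mpest(gts, n_restarts = 1, seed = 3)
  expect_s3_class(fit, "mpest")
  expect_equal(length(coef(fit)), 13L)  # 15-taxon rooted binary: 13 internal edges
  expect_true(all(coef(fit) >= 1e-8 & coef(fit) <= 20))
  ll <- logLik(fit)
  expect_s3_class(ll, "logLik")
  expect_lte(as.numeric(ll), 0)
  expect_output(print(fit), "pseudo-logLik")
  expect_output(print(summary(fit)), "coalescent units")
  sims <- simulate(fit, nsim = 5, seed = 1)
  expect_length(sims, 5L)
  expect_setequal(sims[[1]]$tip.label, sp$tip.label)
})
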
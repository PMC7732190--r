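test_that("candidate sets validate names and leaf sets", {
  pair <- test_backbone_pair()
  expect_s3_class(candidate_set(pair), "candidate_set")
  expect_error(candidate_set(pair[1]), "at least 2")
  bad <- pair
  bad$farris <- ape::drop.tip(bad$farris, "out1")
  expect_error(candidate_set(bad), "differ")
})

test_that("ties break deterministically by candidate order", {
  tr <- strong_tree6()
  aln <- random_alignment(tr$tip.label, 30, seed = 1)
  m <- site_model("LG", lg_frequencies(), NULL)
  ev <- evaluate_candidates(aln, m, list(first = tr, second = tr),
                            optimize = FALSE)
  expect_equal(ev$winner, "first")
  expect_equal(unname(diff(ev$loglik)), 0)
})

test_that("candidate log-likelihoods equal independent evaluations", {
  pair <- test_backbone_pair()
  aln <- simulate_alignment(pair$farris, synth_model(make_profile_set(3,
    seed = 2)), 200, seed = 3)$alignment
  m <- site_model("LG", "empirical", 0.8)
  ev <- evaluate_candidates(aln, m, pair, optimize = FALSE)
  direct <- log_likelihood(pair$felsenstein, aln,
                           lbazone:::resolve_model(m, aln))$loglik
  expect_equal(unname(ev$loglik["felsenstein"]), direct, tolerance = 1e-8)
})

test_that("self-simulation selects the generating candidate", {
  tr <- strong_tree6()
  alt <- parse_newick(paste0("((A:0.2,C:0.2):0.15,(B:0.2,D:0.2):0.15,",
                             "(E:0.2,F:0.2):0.15);"))
  m <- site_model("LG", lg_frequencies(), 1)
  for (r in 1:5) {
    aln <- simulate_alignment(tr, m, 3000, seed = 10 + r)$alignment
    ev <- evaluate_candidates(aln, m, list(alt = alt, true = tr), tol = 1e-2)
    expect_equal(ev$winner, "true")
  }
})

test_that("NNI search improves monotonically and recovers the truth", {
  tr <- strong_tree6()
  wrong <- parse_newick(paste0("((A:0.2,C:0.2):0.15,(B:0.2,D:0.2):0.15,",
                               "(E:0.2,F:0.2):0.15);"))
  m <- site_model("LG", lg_frequencies(), 1)
  aln <- simulate_alignment(tr, m, 3000, seed = 21)$alignment
  res <- nni_search(wrong, aln, m)
  expect_true(all(diff(res$path) > 0))
  expect_true(lbazone:::identical_topology(res$tree, tr))
  # a local optimum is returned unchanged
  res2 <- nni_search(res$tree, aln, m, max_rounds = 3)
  expect_true(lbazone:::identical_topology(res2$tree, res$tree))
})

test_that("bootstrap support is reproducible and complementary", {
  pair <- test_backbone_pair()
  mix <- make_profile_set(5, seed = 31)
  aln <- simulate_alignment(pair$farris, synth_model(mix), 800,
                            seed = 32)$alignment
  m <- site_model("LG", "empirical", 0.8)
  taxa <- alignment_taxa(aln)
  focal <- tree_clades(pair$farris)$focal
  outg <- tree_clades(pair$farris)$outgroup
  sp <- list(
    farris_split = taxon_split(c(outg, focal), setdiff(taxa, c(outg, focal))),
    fel_split = taxon_split(c(focal, tree_clades(pair$farris)$ingroup2),
                            setdiff(taxa, c(focal,
                                            tree_clades(pair$farris)$ingroup2))))
  bs1 <- bootstrap_support(aln, m, pair, sp, n_reps = 150, seed = 5)
  bs2 <- bootstrap_support(aln, m, pair, sp, n_reps = 150, seed = 5)
  expect_identical(bs1$frequency, bs2$frequency)
  # the two candidates differ exactly in these incompatible splits
  expect_equal(sum(bs1$frequency), 1)
  expect_gte(bs1$frequency[1], 0.9)   # strong Farris-zone signal
})

test_that("overwhelming signal yields unanimous bootstrap support", {
  tr <- parse_newick("((A:0.3,B:0.3):0.5,(C:0.3,D:0.3):0.5);")
  alt <- parse_newick("((A:0.3,C:0.3):0.5,(B:0.3,D:0.3):0.5);")
  m <- site_model("LG", lg_frequencies(), NULL)
  aln <- simulate_alignment(tr, m, 10000, seed = 51)$alignment
  sp <- list(AB = taxon_split(c("A", "B"), c("C", "D")))
  bs <- bootstrap_support(aln, m, list(t1 = tr, t2 = alt), sp,
                          n_reps = 200, seed = 52)
  expect_equal(bs$frequency[1], 1)
})

test_that("a zero-length internal branch gives ~50/50 support", {
  tr <- parse_newick("((A:0.3,B:0.3):1e-9,(C:0.3,D:0.3):1e-9);")
  alt <- parse_newick("((A:0.3,C:0.3):1e-9,(B:0.3,D:0.3):1e-9);")
  m <- site_model("LG", lg_frequencies(), NULL)
  aln <- simulate_alignment(tr, m, 1500, seed = 41)$alignment
  sp <- list(AB = taxon_split(c("A", "B"), c("C", "D")),
             AC = taxon_split(c("A", "C"), c("B", "D")))
  bs <- bootstrap_support(aln, m, list(t1 = tr, t2 = alt), sp,
                          n_reps = 200, seed = 42)
  expect_lt(abs(bs$frequency[1] - 0.5), 0.15)
})

test_that("length transfer carries shared splits to NNI neighbors", {
  tr <- strong_tree6()
  nb <- phangorn::nni(tr)[[1]]
  moved <- lbazone:::transfer_lengths(nb, tr, default = 0.123)
  expect_equal(sum(moved$edge.length %in% c(tr$edge.length, 0.123)),
               nrow(moved$edge))
})
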
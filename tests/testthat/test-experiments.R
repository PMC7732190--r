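# Experiment-driver mechanics at small scale; the full-scale scientific
# reproductions live in test-acceptance.R.

test_that("branch-length tables pair every branch with its truth", {
  pair <- test_backbone_pair()
  mix <- make_profile_set(4, seed = 1)
  tab <- branch_length_experiment(pair$felsenstein, synth_model(mix),
                                  list(hom = site_model("LG", "empirical", 0.8)),
                                  n_sites = 1000, seed = 2, tol = 1e-2)
  ntip <- length(pair$felsenstein$tip.label)
  expect_equal(sum(tab$type == "terminal"), ntip)
  expect_equal(sum(tab$type == "internal"),
               nrow(pair$felsenstein$edge) - ntip)
  expect_equal(sum(tab$type == "clade_depth"), 4L)
  expect_true(all(is.finite(tab$estimate)))
  expect_error(branch_length_experiment(ape::rtree(5), synth_model(mix),
                                        list(), 100), "named clades")
})

test_that("recovery tables tally winners that sum to the replicate count", {
  pair <- test_backbone_pair()
  mix <- make_profile_set(4, seed = 3)
  rec <- recovery_experiment(pair, "farris", synth_model(mix),
                             list(homogeneous = site_model("LG", "empirical", 0.8)),
                             n_replicates = 4, n_sites = 600, seed = 5)
  expect_s3_class(rec, "recovery_table")
  expect_equal(sum(rec$count), 4L)
  det <- attr(rec, "replicates")
  expect_equal(nrow(det), 4L)
  expect_equal(recovery_rate(rec, "homogeneous"),
               mean(det$winner == "farris"))
  expect_error(recovery_experiment(pair, "nope", synth_model(mix), list(),
                                   2, 100), "must be one of")
})

test_that("homogeneous generation is recovered by both model classes", {
  pair <- test_backbone_pair()
  hom_gen <- site_model("LG", lg_frequencies(), discrete_gamma(0.8, 4))
  mix <- make_profile_set(20, 0.2, seed = 7)
  rec <- recovery_experiment(pair, "felsenstein", hom_gen,
                             inference_models(mix),
                             n_replicates = 4, n_sites = 1500, seed = 8,
                             tol = 0.3)
  expect_equal(recovery_rate(rec, "homogeneous"), 1)
  expect_equal(recovery_rate(rec, "heterogeneous"), 1)
})

test_that("mixing limits and monotonicity hold with strong signal", {
  treeA <- strong_tree6()
  treeB <- parse_newick(paste0("((A:0.2,C:0.2):0.15,(B:0.2,D:0.2):0.15,",
                               "(E:0.2,F:0.2):0.15);"))
  m <- site_model("LG", lg_frequencies(), 1)
  res <- mixing_experiment(list(tree = treeA, model = m),
                           list(tree = treeB, model = m),
                           list(A = treeA, B = treeB),
                           proportions = c(0, 0.5, 1),
                           n_pairs = 3, n_sites = 1200,
                           infer_model = m, seed = 9, tol = 1e-2)
  expect_equal(res$wins_A[res$proportion == 0], 0L)
  expect_equal(res$wins_A[res$proportion == 1], 3L)
  expect_true(all(diff(res$wins_A) >= 0))
  expect_error(mixing_experiment(list(tree = treeA, model = m),
                                 list(tree = treeB, model = m),
                                 list(A = treeA, B = treeB),
                                 proportions = c(-0.1),
                                 n_pairs = 1, n_sites = 100,
                                 infer_model = m), "0, 1")
})

test_that("monophyly ranking scores genes and pools quarter site sets", {
  bb <- make_backbone()
  ref <- backbone_reference_clades(bb)
  mix <- make_profile_set(4, seed = 11)
  genes <- make_gene_set(bb, gene_set_config(n_genes = 8,
                                             sites_per_gene = 120),
                         synth_model(mix), seed = 12)
  mr <- monophyly_rank(genes, ref, site_model("LG", "empirical", 0.8),
                       seed = 13, tol = 0.5)
  expect_equal(nrow(mr$scores), 8L)
  expect_true(all(mr$scores$score <= mr$scores$n_clades))
  expect_length(mr$best_genes, 2L)      # 8 genes -> quarter = 2 genes
  expect_equal(ncol(mr$best), 2L * 120L)
  expect_equal(ncol(mr$worst), 2L * 120L)
  expect_error(monophyly_rank(genes[1:3], ref,
                              site_model("LG", "empirical", 0.8)), ">= 4")
})

test_that("a strong-signal gene recovers every reference clade", {
  bb <- make_backbone(backbone_config(outgroup_terminal = 0.3,
                                      focal_terminal = 0.3,
                                      ingroup_terminal = 0.2,
                                      internal_length = 0.15))
  m <- site_model("LG", lg_frequencies(), 1)
  aln <- simulate_alignment(bb, m, 3000, seed = 14)$alignment
  start <- random_addition_tree(aln, m, seed = 15, tol = 0.5)
  fit <- nni_search(start, aln, m, tol = 0.5)
  ref <- backbone_reference_clades(bb)
  score <- sum(vapply(ref, function(cl) is_monophyletic(fit$tree, cl),
                      logical(1)))
  expect_equal(score, length(ref))
})

test_that("cross-validation of a model against itself is a coin flip", {
  pair <- test_backbone_pair()
  mix <- make_profile_set(3, seed = 21)
  aln <- simulate_alignment(pair$farris, synth_model(mix), 2000,
                            seed = 22)$alignment
  m <- site_model("LG", "empirical", 0.8)
  cv <- cross_validation(aln, pair$farris, m, m, train_sites = 1200,
                         test_sites = 400, n_reps = 3, seed = 23, tol = 0.5)
  expect_equal(cv$mean, 0, tolerance = 1e-6)
  expect_error(cross_validation(aln, pair$farris, m, m, train_sites = 1900,
                                test_sites = 200), "exceeds")
})

test_that("taxon removal prunes candidates and simulation together", {
  pair <- test_backbone_pair()
  drop <- attr(pair$felsenstein, "long_focal")
  mix <- make_profile_set(4, seed = 31)
  rec <- recovery_experiment(pair, "felsenstein", synth_model(mix),
                             list(homogeneous = site_model("LG", "empirical",
                                                           0.8)),
                             n_replicates = 2, n_sites = 500, seed = 32,
                             drop_taxa = drop)
  det <- attr(rec, "replicates")
  expect_equal(nrow(det), 2L)
  expect_equal(sum(rec$count), 2L)
})
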
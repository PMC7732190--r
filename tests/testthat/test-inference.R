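test_that("two-leaf Poisson likelihood matches the closed form", {
  for (t in c(0.05, 0.7, 3)) {
    tr <- parse_newick(sprintf("(A:%g,B:%g);", t / 2, t / 2))
    aln <- aa_alignment(matrix(c(0L, 0L), 2, 1,
                               dimnames = list(c("A", "B"), NULL)))
    m <- site_model("Poisson", frequency_profile(rep(1 / 20, 20)), NULL)
    expect_equal(log_likelihood(tr, aln, m)$loglik,
                 log((1 / 20) * (1 / 20 + (19 / 20) * exp(-(20 / 19) * t))),
                 tolerance = 1e-10)
  }
})

test_that("all-gap columns contribute zero log-likelihood", {
  tr <- strong_tree6()
  codes <- matrix(20L, 6, 3, dimnames = list(tr$tip.label, NULL))
  codes[, 1] <- c(0L, 1L, 2L, 3L, 4L, 5L)
  res <- log_likelihood(tr, aa_alignment(codes),
                        site_model("LG", lg_frequencies(), 0.8))
  expect_equal(res$persite[2:3], c(0, 0))
  expect_equal(res$loglik, sum(res$persite), tolerance = 1e-6)
})

test_that("taxon mismatch raises an error", {
  tr <- strong_tree6()
  aln <- random_alignment(c("A", "B", "C", "D", "E", "Z"), 5, seed = 1)
  expect_error(log_likelihood(tr, aln, site_model()), "differ")
})

test_that("likelihood is invariant to re-rooting (pulley principle)", {
  set.seed(21)
  tr <- ape::rtree(7)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.6)
  aln <- random_alignment(tr$tip.label, 40, gap_prob = 0.05, seed = 22)
  m <- site_model("LG", make_profile_set(3, seed = 2), 0.7)
  base <- log_likelihood(tr, aln, m)$loglik
  for (og in c("t1", "t4")) {
    rr <- ape::root(ape::unroot(tr), outgroup = og, resolve.root = TRUE)
    expect_equal(log_likelihood(rr, aln, m)$loglik, base, tolerance = 1e-8)
  }
})

test_that("pruning agrees with an independent phangorn LG+G fit", {
  set.seed(31)
  tr <- ape::rtree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.8)
  chars <- lbazone:::alignment_chars(random_alignment(tr$tip.label, 80,
                                                      gap_prob = 0.1,
                                                      seed = 32))
  aln <- aa_alignment(chars)
  m <- site_model("LG", lg_frequencies(), discrete_gamma(0.6, 4))
  ours <- log_likelihood(tr, aln, m)$loglik
  fit <- phangorn::pml(tr, phangorn::phyDat(chars, type = "AA"),
                       model = "LG", bf = as.numeric(lg_frequencies()),
                       k = 4, shape = 0.6)
  expect_equal(ours, fit$logLik, tolerance = 1e-6)
})

test_that("pruning equals brute-force enumeration on small trees", {
  set.seed(41)
  cases <- list(
    list(nwk = "((A:0.3,B:0.5):0.2,(C:0.4,D:0.1):0.3);",
         ex = "LG", ncomp = 2, k = 2),
    list(nwk = "((A:0.2,B:0.2):0.1,C:0.5,(D:0.3,E:0.6):0.2);",
         ex = "Poisson", ncomp = 3, k = 1),
    list(nwk = "(A:0.8,B:0.1,(C:0.4,(D:0.2,E:0.9):0.15):0.05);",
         ex = "LG", ncomp = 1, k = 2))
  for (cs in cases) {
    tr <- parse_newick(cs$nwk)
    mix <- make_profile_set(cs$ncomp, 0.5, seed = 50 + cs$ncomp)
    m <- site_model(cs$ex, mix, discrete_gamma(0.8, cs$k))
    aln <- random_alignment(tr$tip.label, 3, gap_prob = 0.15,
                            seed = 60 + cs$ncomp)
    got <- log_likelihood(tr, aln, m)$persite
    for (s in 1:3) {
      codes <- setNames(unclass(aln)[, s], rownames(aln))
      expect_equal(got[s], enum_site_loglik(tr, codes, m), tolerance = 1e-8)
    }
  }
})

test_that("branch-length optimization is monotone and flags convergence", {
  tr <- strong_tree6()
  aln <- simulate_alignment(tr, site_model("LG", lg_frequencies(), 1),
                            800, seed = 71)$alignment
  start <- tr; start$edge.length[] <- 0.5
  m <- site_model("LG", lg_frequencies(), 1)
  before <- log_likelihood(start, aln, m)$loglik
  fit <- optimize_branch_lengths(start, aln, m)
  expect_gte(fit$result$loglik, before)
  expect_true(fit$converged)
  one <- optimize_branch_lengths(start, aln, m, max_cycles = 1L)
  expect_false(one$converged)
  expect_gte(one$result$loglik, before)
})

test_that("identical sequences drive the branch to the lower bound", {
  set.seed(61)
  tr <- parse_newick("(A:0.3,B:0.3);")
  codes <- matrix(rep(sample.int(20, 50, TRUE) - 1L, 2), 2, byrow = TRUE,
                  dimnames = list(c("A", "B"), NULL))
  fit <- optimize_branch_lengths(tr, aa_alignment(codes),
                                 site_model("LG", lg_frequencies(), NULL))
  expect_lt(sum(fit$tree$edge.length), 1e-5)
})

test_that("branch lengths are recovered within 10% on matched simulations", {
  set.seed(81)
  tr <- strong_tree6()
  m <- site_model("LG", lg_frequencies(), discrete_gamma(0.8, 4))
  sim <- simulate_alignment(tr, m, 20000, seed = 82)
  start <- tr; start$edge.length[] <- 0.1
  fit <- optimize_branch_lengths(start, sim$alignment, m, tol = 1e-4)
  key <- function(t) vapply(lbazone:::edge_descendant_tips(t), function(x)
    paste(sort(x), collapse = ","), character(1))
  est <- setNames(fit$tree$edge.length, key(fit$tree))
  truth <- setNames(tr$edge.length, key(tr))
  rel <- abs(est[names(truth)] - truth) / truth
  expect_true(all(rel < 0.10))
})

test_that("gamma shape is recovered and pushes to the bound when absent", {
  set.seed(91)
  tr <- ape::rtree(8)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 0.5)
  m <- site_model("LG", lg_frequencies(), discrete_gamma(0.8, 4))
  sim <- simulate_alignment(tr, m, 10000, seed = 92)
  est <- estimate_alpha(tr, sim$alignment, m)
  expect_gt(est$alpha, 0.6)
  expect_lt(est$alpha, 1.0)
  expect_gte(est$loglik, log_likelihood(tr, sim$alignment, m)$loglik - 1e-6)

  flat <- simulate_alignment(tr, site_model("LG", lg_frequencies(), NULL),
                             5000, seed = 93)
  est2 <- estimate_alpha(tr, flat$alignment,
                         site_model("LG", lg_frequencies(),
                                    discrete_gamma(1, 4)))
  expect_gt(est2$alpha, 9)
})

test_that("PMSF profiles equal direct Bayes posteriors", {
  tr <- test_backbone_pair()$farris
  mix <- make_profile_set(4, 0.3, seed = 101)
  g <- discrete_gamma(0.8, 4)
  aln <- simulate_alignment(tr, site_model("LG", mix, g), 60,
                            seed = 102)$alignment
  prof <- pmsf_profiles(aln, tr, mix, gamma = g)
  expect_true(all(abs(rowSums(prof) - 1) < 1e-9))

  # direct Bayes oracle from single-component likelihoods
  compll <- vapply(1:4, function(p) {
    m1 <- site_model("LG", mix$profiles[[p]], g)
    log_likelihood(tr, aln, m1)$persite
  }, numeric(60))
  post <- exp(sweep(compll, 1, apply(compll, 1, max)))
  post <- post * rep(mix$weights, each = 60)
  post <- post / rowSums(post)
  expect_equal(unname(attr(prof, "posteriors")), unname(post),
               tolerance = 1e-10)
  got_prof <- prof
  attr(got_prof, "posteriors") <- NULL
  dimnames(got_prof) <- NULL
  expect_equal(got_prof, unname(post %*% lbazone:::mixture_matrix(mix)),
               tolerance = 1e-10)
})

test_that("a site possible under only one component gets its profile", {
  tr <- parse_newick("((A:0.01,B:0.01):0.01,(C:0.01,D:0.01):0.01);")
  p1 <- frequency_profile(c(rep(1e-10, 19), 1 - 19e-10))  # all V
  p2 <- frequency_profile(c(1 - 19e-10, rep(1e-10, 19)))  # all A
  mix <- profile_mixture(list(p1, p2))
  aln <- aa_alignment(matrix(0L, 4, 1, dimnames = list(tr$tip.label, NULL)))
  prof <- pmsf_profiles(aln, tr, mix, gamma = NULL)
  expect_gt(attr(prof, "posteriors")[1, 2], 0.9999)
})

test_that("a 1-component mixture and single profile give equal likelihoods", {
  tr <- strong_tree6()
  aln <- random_alignment(tr$tip.label, 30, seed = 111)
  g <- discrete_gamma(0.7, 4)
  a <- log_likelihood(tr, aln, site_model("LG", lg_frequencies(), g))$loglik
  b <- log_likelihood(tr, aln,
                      site_model("LG", profile_mixture(list(lg_frequencies())),
                                 g))$loglik
  expect_equal(a, b, tolerance = 1e-10)
})
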
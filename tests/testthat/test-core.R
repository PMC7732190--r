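test_that("newick parsing validates structure and round-trips", {
  tr <- parse_newick("((A:1,B:1):0.1,(C:1,D:1):0.1);")
  expect_s3_class(tr, "phylo")
  expect_equal(length(tr$tip.label), 4L)
  internal <- tr$edge.length[tr$edge[, 2] > 4]
  expect_equal(sort(internal), c(0.1, 0.1))

  tr2 <- parse_newick("(A:1,B:2);")
  expect_equal(sum(tr2$edge.length), 3)

  expect_error(parse_newick("((A,B),(C,D);"), "position")
  expect_error(parse_newick("((A,B),(A,C));"), "duplicate")
  expect_error(parse_newick("(A:1,B:1,C:1,D:1);"), "multifurcation")
  res <- parse_newick("(A:1,B:1,C:1,D:1);", resolve = TRUE)
  expect_true(lbazone:::is_binary_tree(res))
})

test_that("newick write -> parse preserves random trees", {
  set.seed(42)
  for (i in 1:20) {
    tr <- ape::rtree(10)
    tr$edge.length <- round(runif(nrow(tr$edge), 0.01, 2), 6)
    back <- parse_newick(write_newick(tr))
    expect_true(lbazone:::identical_topology(tr, back))
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-9)
  }
})

test_that("extract_splits yields n-3 nontrivial canonical splits", {
  sp <- extract_splits(parse_newick("((A,B),(C,D));"))
  expect_length(sp, 1L)
  expect_equal(sp[[1]]$side_a, c("A", "B"))

  cat5 <- parse_newick("(A,(B,(C,(D,E))));")
  expect_length(extract_splits(cat5), 2L)

  set.seed(7)
  for (i in 1:5) {
    tr <- ape::rtree(12)
    expect_length(extract_splits(tr), 9L)
  }
})

test_that("split canonical orientation makes equality well defined", {
  a <- taxon_split(c("B", "A"), c("D", "C"))
  b <- taxon_split(c("C", "D"), c("A", "B"))
  expect_identical(lbazone:::split_key(a), lbazone:::split_key(b))
  expect_error(taxon_split(c("A"), c("A", "B")), "disjoint")
})

test_that("unrooted monophyly follows split membership", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_true(is_monophyletic(tr, c("A", "B", "C", "D")))
  expect_true(is_monophyletic(tr, "A"))
  expect_error(is_monophyletic(tr, c("A", "Z")), "unknown")
})

test_that("prune_taxa sums through removed nodes and preserves paths", {
  tr <- parse_newick("((A:1,B:1):0.2,((C:1,D:1):0.2,E:1):0.2);")
  pr <- prune_taxa(tr, drop = "D")
  cterm <- pr$edge.length[pr$edge[, 2] == match("C", pr$tip.label)]
  expect_equal(cterm, 1.2)

  expect_error(prune_taxa(tr, drop = c("A", "B")), "at least 4")

  set.seed(11)
  tr2 <- ape::rtree(12)
  drop <- sample(tr2$tip.label, 6)
  pr2 <- prune_taxa(tr2, drop = drop)
  keep <- setdiff(tr2$tip.label, drop)
  expect_equal(ape::cophenetic.phylo(pr2)[keep, keep],
               ape::cophenetic.phylo(tr2)[keep, keep], tolerance = 1e-10)
})

test_that("prune_taxa with an alignment drops matching rows", {
  tr <- parse_newick("((A:1,B:1):0.2,(C:1,D:1):0.2);")
  aln <- random_alignment(c("A", "B", "C", "D"), 10, seed = 1)
  # empty drop is the identity
  idem <- prune_taxa(tr, aln, character(0))
  expect_identical(unclass(idem$alignment), unclass(aln))
})

test_that("subsample_sites draws uniformly without replacement", {
  aln <- random_alignment(letters[1:4], 100, seed = 2)
  full <- subsample_sites(aln, 100, seed = 5)
  expect_equal(sort(attr(full, "sites")), 1:100)

  s1 <- subsample_sites(aln, 1, seed = 9)
  s2 <- subsample_sites(aln, 1, seed = 9)
  expect_identical(unclass(s1), unclass(s2))
  expect_error(subsample_sites(aln, 101), "cannot draw")

  hits <- integer(100)
  for (i in 1:300) {
    idx <- attr(subsample_sites(aln, 50, seed = 1000 + i), "sites")
    hits[idx] <- hits[idx] + 1L
  }
  expect_true(all(abs(hits / 300 - 0.5) < 0.15))
  expect_lt(abs(mean(hits / 300) - 0.5), 0.02)
})

test_that("FASTA and relaxed PHYLIP round-trip alignments", {
  aln <- random_alignment(c("tax_one", "tax_two", "tax3", "t4"), 37,
                          gap_prob = 0.1, seed = 3)
  fa <- tempfile(fileext = ".fasta")
  write_fasta_aa(aln, fa, width = 10)
  expect_identical(unclass(read_fasta_aa(fa)), unclass(aln))

  ph <- tempfile(fileext = ".phy")
  write_phylip_aa(aln, ph)
  expect_identical(unclass(read_phylip_aa(ph)), unclass(aln))
})

test_that("splits serialize to TSV and back", {
  sp <- extract_splits(test_backbone_pair()$farris)
  f <- tempfile(fileext = ".tsv")
  write_splits_tsv(sp, f)
  back <- read_splits_tsv(f)
  expect_identical(vapply(back, lbazone:::split_key, character(1)),
                   vapply(sp, lbazone:::split_key, character(1)))
})

test_that("clade_mean_depth averages root-to-tip distances in the clade", {
  tr <- parse_newick("(((A:1,B:3):0.5,C:0.2):0.1,(D:1,E:1):0.1);")
  expect_equal(clade_mean_depth(tr, c("A", "B")), 2)
  expect_equal(clade_mean_depth(tr, c("D", "E")), 1)
})

test_that("bundled preset fixtures load through the package readers", {
  far <- parse_newick(paste(readLines(system.file(
    "extdata", "farris-default.nwk", package = "lbazone")), collapse = ""))
  fel <- parse_newick(paste(readLines(system.file(
    "extdata", "felsenstein-default.nwk", package = "lbazone")), collapse = ""))
  expect_true(lbazone:::identical_topology(far, make_backbone_pair()$farris))
  expect_equal(sort(far$edge.length), sort(fel$edge.length))
  mx <- read_profile_mixture_tsv(system.file(
    "extdata", "profiles-c20-default.tsv", package = "lbazone"))
  expect_length(mx$profiles, 20L)
  expect_equal(lbazone:::mixture_matrix(mx),
               lbazone:::mixture_matrix(make_profile_set(20, 0.2, seed = 7)),
               tolerance = 1e-9)
})
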
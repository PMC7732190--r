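# Shared fixtures and independent oracles.
#
# The enumeration oracle computes mixture likelihoods by summing over all
# internal-node state assignments — independent of the pruning recursion
# it is used to check. Transition matrices come from transition_matrix(),
# which is itself tested against closed forms, Chapman-Kolmogorov, and
# phangorn.

aa_codes <- function(x) {
  ab <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  m <- match(toupper(x), ab) - 1L
  m[is.na(m)] <- 20L
  m
}

# Random alignment of integer codes (optionally with gaps).
random_alignment <- function(taxa, n_sites, gap_prob = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  codes <- matrix(sample.int(20L, length(taxa) * n_sites, replace = TRUE) - 1L,
                  nrow = length(taxa), dimnames = list(taxa, NULL))
  if (gap_prob > 0) {
    gaps <- matrix(runif(length(codes)) < gap_prob, nrow = nrow(codes))
    codes[gaps] <- 20L
  }
  aa_alignment(codes)
}

# Enumeration likelihood for one site-pattern column under a mixture
# model. tree: phylo; codes: named integer vector (tip -> 0..20).
enum_site_loglik <- function(tree, codes, model) {
  mix <- lbazone:::model_mixture(model)
  rates <- model$gamma$rates
  k <- length(rates)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  total <- 0
  for (p in seq_along(mix$profiles)) {
    Q <- build_rate_matrix(model$exchangeabilities, mix$profiles[[p]])
    pi <- attr(Q, "freqs")
    for (r in seq_len(k)) {
      P <- lapply(seq_len(nrow(tree$edge)), function(e)
        transition_matrix(Q, tree$edge.length[e] * rates[r]))
      grid <- as.matrix(expand.grid(rep(list(1:20), nnode)))
      lik <- 0
      root <- ntip + 1L
      for (g in seq_len(nrow(grid))) {
        state <- function(node) {
          if (node <= ntip) codes[tree$tip.label[node]] + 1L
          else grid[g, node - ntip]
        }
        pr <- pi[grid[g, 1L]]   # root = first internal node (ape convention)
        for (e in seq_len(nrow(tree$edge))) {
          sp <- state(tree$edge[e, 1L]); sc <- state(tree$edge[e, 2L])
          pr <- pr * (if (sc == 21L) 1 else P[[e]][sp, sc])
          if (pr == 0) break
        }
        lik <- lik + pr
      }
      total <- total + mix$weights[p] * (1 / k) * lik
    }
  }
  log(total)
}

# Small clade-annotated backbone pair shared by experiment tests.
test_backbone_pair <- function() make_backbone_pair()

# Strong-signal 6-leaf tree where every method should succeed.
strong_tree6 <- function() {
  parse_newick(paste0("((A:0.2,B:0.2):0.15,(C:0.2,D:0.2):0.15,",
                      "(E:0.2,F:0.2):0.15);"))
}
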
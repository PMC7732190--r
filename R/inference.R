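# Likelihood computation and optimization on a fixed topology. The
# numerical core (pruning with per-node scaling, coordinate-wise
# branch-length optimization) lives in src/pruning.cpp; this file
# prepares eigendecompositions and marshals trees/alignments.

# Convert (tree, alignment, model) into the argument set the C++ core
# expects. The model must be resolved (no "empirical" mode).
likelihood_args <- function(tree, alignment, model) {
  if (model$mode == "empirical") model <- resolve_model(model, alignment)
  taxa <- alignment_taxa(alignment)
  if (!setequal(tree$tip.label, taxa))
    stop2("tree leaves and alignment taxa differ")
  tr <- ape::reorder.phylo(tree, "postorder")
  tips <- unclass(alignment)[tr$tip.label, , drop = FALSE]
  gamma <- model$gamma
  k <- gamma$k
  if (model$mode %in% c("single", "mixture")) {
    mix <- model_mixture(model)
    ncomp <- length(mix$profiles)
    V <- W <- array(0, c(20, 20, ncomp))
    lam <- pimat <- matrix(0, 20, ncomp)
    for (p in seq_len(ncomp)) {
      Q <- build_rate_matrix(model$exchangeabilities, mix$profiles[[p]])
      eg <- rate_matrix_eigen(Q)
      V[, , p] <- eg$V; W[, , p] <- eg$W
      lam[, p] <- eg$lambda; pimat[, p] <- eg$pi
    }
    grid <- expand.grid(rate = seq_len(k), comp = seq_len(ncomp))
    ml <- list(persite = FALSE, V = V, W = W, lam = lam, pimat = pimat,
               comp = grid$comp - 1L,
               tmult = gamma$rates[grid$rate],
               logw = log(mix$weights[grid$comp]) - log(k))
  } else {
    prof <- model$frequencies
    S <- ncol(tips)
    if (nrow(prof) != S)
      stop2("per-site profile count (", nrow(prof),
            ") does not match alignment sites (", S, ")")
    V <- W <- array(0, c(20, 20, S))
    lam <- pimat <- matrix(0, 20, S)
    for (s in seq_len(S)) {
      Q <- build_rate_matrix(model$exchangeabilities, prof[s, ])
      eg <- rate_matrix_eigen(Q)
      V[, , s] <- eg$V; W[, , s] <- eg$W
      lam[, s] <- eg$lambda; pimat[, s] <- eg$pi
    }
    ml <- list(persite = TRUE, V = V, W = W, lam = lam, pimat = pimat,
               comp = rep(0L, k),
               tmult = gamma$rates,
               logw = rep(-log(k), k))
  }
  list(edge = tr$edge, edge_length = tr$edge.length, tips = tips,
       model = ml, tree = tr)
}

#' Log-likelihood of an alignment on a tree under a site model
#'
#' Felsenstein pruning with per-node, per-site rescaling. Mixture models
#' sum component and gamma-rate class likelihoods per site; per-site
#' profile models (PMSF) use each column's own stationary profile. Gap
#' and unknown states contribute a conditional vector of ones (fully
#' missing), so an all-gap column has log-likelihood 0.
#'
#' @param tree A \code{phylo} whose leaves match the alignment taxa.
#' @param alignment An \code{aa_alignment}.
#' @param model A \code{site_model}.
#' @return An object of class \code{lba_loglik}: list with \code{loglik},
#'   \code{persite}, \code{model}, \code{tree}.
#' @export
log_likelihood <- function(tree, alignment, model) {
  args <- likelihood_args(tree, alignment, model)
  res <- cpp_loglik(args$edge, args$edge_length, args$tips, args$model)
  structure(list(loglik = res$loglik, persite = as.numeric(res$persite),
                 model = model, tree = tree),
            class = "lba_loglik")
}

#' @export
print.lba_loglik <- function(x, ...) {
  cat("log-likelihood:", format(x$loglik, digits = 12),
      "over", length(x$persite), "sites\n")
  invisible(x)
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate-wise optimization of each branch on [1e-8, 20] (Brent),
#' cycling over branches until the total log-likelihood improves by less
#' than \code{tol}; the log-likelihood is non-decreasing across cycles.
#' Non-convergence after \code{max_cycles} is flagged, not an error.
#'
#' @inheritParams log_likelihood
#' @param tol Convergence tolerance on the log-likelihood (default 1e-6).
#' @param max_cycles Maximum optimization cycles (default 100).
#' @param bounds Branch-length search interval.
#' @param ttol Relative tolerance of the per-branch line search.
#' @return List with \code{tree} (optimized lengths), \code{result} (an
#'   \code{lba_loglik}), \code{converged}, \code{cycles}.
#' @export
optimize_branch_lengths <- function(tree, alignment, model, tol = 1e-6,
                                    max_cycles = 100L,
                                    bounds = c(1e-8, 20), ttol = 1e-5) {
  args <- likelihood_args(tree, alignment, model)
  res <- cpp_optimize_bl(args$edge, args$edge_length, args$tips, args$model,
                         lower = bounds[1], upper = bounds[2],
                         tol = tol, max_cycles = as.integer(max_cycles),
                         ttol = ttol)
  out_tree <- args$tree
  out_tree$edge.length <- as.numeric(res$edge_length)
  attr(out_tree, "clades") <- attr(tree, "clades")
  structure(list(
    tree = out_tree,
    result = structure(list(loglik = res$loglik,
                            persite = as.numeric(res$persite),
                            model = model, tree = out_tree),
                       class = "lba_loglik"),
    converged = isTRUE(res$converged),
    cycles = res$cycles), class = "lba_blfit")
}

#' Estimate the gamma shape parameter at fixed branch lengths
#'
#' One-dimensional likelihood optimization of the discrete-gamma shape;
#' optionally interleaved with branch-length cycles.
#'
#' @inheritParams log_likelihood
#' @param bounds Search interval for alpha.
#' @param interleave Number of alternations of (alpha fit, branch-length
#'   fit); 0 fits alpha only at the given lengths.
#' @param bl_tol Branch-length tolerance used when interleaving.
#' @return List with \code{alpha}, \code{loglik}, \code{tree}.
#' @export
estimate_alpha <- function(tree, alignment, model, bounds = c(0.05, 10),
                           interleave = 0L, bl_tol = 1e-4) {
  fit_alpha <- function(tr) {
    args <- likelihood_args(tr, alignment, model)
    f <- function(la) {
      g <- discrete_gamma(exp(la), model$gamma$k)
      ncomp_classes <- length(args$model$tmult) / model$gamma$k
      args$model$tmult <- rep(g$rates, times = ncomp_classes)
      cpp_loglik(args$edge, args$edge_length, args$tips, args$model)$loglik
    }
    opt <- optimize(f, log(bounds), maximum = TRUE, tol = 1e-4)
    list(alpha = exp(opt$maximum), loglik = opt$objective)
  }
  cur_tree <- tree
  est <- fit_alpha(cur_tree)
  if (interleave > 0L) {
    for (i in seq_len(interleave)) {
      model$gamma <- discrete_gamma(est$alpha, model$gamma$k)
      fit <- optimize_branch_lengths(cur_tree, alignment, model, tol = bl_tol)
      cur_tree <- fit$tree
      est <- fit_alpha(cur_tree)
    }
  }
  list(alpha = est$alpha, loglik = est$loglik, tree = cur_tree)
}

#' Posterior mean site frequency (PMSF) profiles
#'
#' For each alignment column, the posterior probability of each mixture
#' component is computed on a guide tree (component prior weight times
#' the column's likelihood under that component, normalized), and the
#' returned profile is the posterior-weighted average of the component
#' profiles. These per-site profiles can then stand in for the full
#' mixture at much lower cost, following the two-pass protocol: fit a
#' homogeneous model, use its tree as guide, compute PMSF profiles, and
#' analyse under the per-site-profile model.
#'
#' @param alignment An \code{aa_alignment}.
#' @param guide_tree Tree (with branch lengths) used to evaluate
#'   component likelihoods.
#' @param mixture A \code{profile_mixture}.
#' @param ex Exchangeability matrix shared by all components.
#' @param gamma A \code{gamma_rates} object (or shape value).
#' @return An n_sites x 20 matrix of simplex-valid per-site profiles,
#'   with the posterior component weights attached as attribute
#'   \code{"posteriors"}.
#' @export
pmsf_profiles <- function(alignment, guide_tree, mixture,
                          ex = exchangeability_matrix("LG"), gamma = NULL) {
  model <- site_model(ex, mixture, gamma)
  args <- likelihood_args(guide_tree, alignment, model)
  res <- cpp_loglik(args$edge, args$edge_length, args$tips, args$model,
                    want_classmat = TRUE)
  clsll <- res$classmat                    # nclass x S, class = comp x rate
  k <- model$gamma$k
  ncomp <- length(mixture$profiles)
  S <- ncol(clsll)
  # collapse gamma classes within components: log sum_r (1/k) exp(ll);
  # classes are laid out rate-fastest within component
  compll <- matrix(0, ncomp, S)
  for (p in seq_len(ncomp)) {
    idx <- ((p - 1L) * k + 1L):(p * k)
    block <- clsll[idx, , drop = FALSE]
    m <- apply(block, 2L, max)
    compll[p, ] <- m + log(colMeans(exp(sweep(block, 2L, m))))
  }
  logpost <- sweep(compll, 1L, log(mixture$weights), "+")
  m <- apply(logpost, 2L, max)
  post <- exp(sweep(logpost, 2L, m))
  post <- sweep(post, 2L, colSums(post), "/")
  prof <- t(post) %*% mixture_matrix(mixture)     # S x 20
  prof <- prof / rowSums(prof)
  attr(prof, "posteriors") <- t(post)
  prof
}

#' Build a PMSF site model via the two-pass protocol
#'
#' Fits branch lengths under the homogeneous model, uses the fitted tree
#' as PMSF guide, and returns the per-site-profile model plus the guide.
#'
#' @inheritParams pmsf_profiles
#' @param tree Topology to fit the guide on.
#' @param homogeneous_model The first-pass \code{site_model} (defaults to
#'   LG with empirical frequencies and the mixture's gamma).
#' @export
pmsf_model <- function(alignment, tree, mixture,
                       ex = exchangeability_matrix("LG"), gamma = NULL,
                       homogeneous_model = NULL) {
  if (is.null(homogeneous_model))
    homogeneous_model <- site_model(ex, "empirical", gamma)
  guide <- optimize_branch_lengths(tree, alignment,
                                   resolve_model(homogeneous_model, alignment),
                                   tol = 1e-4)$tree
  prof <- pmsf_profiles(alignment, guide, mixture, ex, gamma)
  list(model = site_model(ex, prof, gamma), guide_tree = guide)
}

#' EM re-optimization of mixture weights
#'
#' With component likelihoods fixed (branch lengths, profiles, gamma),
#' mixture weights have a closed EM update: the new weight of a
#' component is the mean over sites of its posterior probability. The
#' update is iterated to convergence, and components whose weight falls
#' below \code{prune} are removed (with renormalization) so that, e.g.,
#' on compositionally homogeneous data a "+F"-augmented mixture
#' collapses to its empirical-frequency class — the weight-level
#' analogue of an estimated site-heterogeneous model adapting to
#' homogeneous data.
#'
#' @inheritParams log_likelihood
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the log-likelihood.
#' @param prune Drop components with converged weight below this value
#'   (0 disables pruning).
#' @return List with \code{model} (the re-weighted, possibly pruned
#'   \code{site_model}), \code{weights} (over the original components),
#'   \code{loglik}.
#' @export
optimize_mixture_weights <- function(tree, alignment, model,
                                     max_iter = 200L, tol = 1e-6,
                                     prune = 1e-4) {
  model <- resolve_model(model, alignment)
  if (model$mode != "mixture")
    stop2("weight optimization applies to mixture models")
  mix <- model$frequencies
  k <- model$gamma$k
  ncomp <- length(mix$profiles)
  args <- likelihood_args(tree, alignment, model)
  clsll <- cpp_loglik(args$edge, args$edge_length, args$tips, args$model,
                      want_classmat = TRUE)$classmat   # (ncomp*k) x S
  S <- ncol(clsll)
  # collapse rate classes (uniform 1/k) within components
  compll <- matrix(0, ncomp, S)
  for (p in seq_len(ncomp)) {
    block <- clsll[((p - 1L) * k + 1L):(p * k), , drop = FALSE]
    m <- apply(block, 2L, max)
    compll[p, ] <- m + log(colMeans(exp(sweep(block, 2L, m))))
  }
  w <- mix$weights
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    lw <- compll + log(w)
    m <- apply(lw, 2L, max)
    lik <- exp(sweep(lw, 2L, m))
    ll <- sum(m + log(colSums(lik)))
    post <- sweep(lik, 2L, colSums(lik), "/")
    w <- rowMeans(post)
    if (ll - ll_old < tol) break
    ll_old <- ll
  }
  keep <- if (prune > 0) which(w >= prune) else seq_len(ncomp)
  if (length(keep) == 0L) keep <- which.max(w)
  new_mix <- profile_mixture(mix$profiles[keep], weights = w[keep])
  list(model = site_model(model$exchangeabilities, new_mix, model$gamma),
       weights = w, loglik = ll)
}
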
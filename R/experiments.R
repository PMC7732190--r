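# Experiment drivers: branch-length bias, topology recovery, composite
# mixing, monophyly-based gene ranking, and cross-validation model
# comparison. Each returns a plain data.frame ready to write as TSV.

# Standard inference models used across experiments: the misspecified
# site-homogeneous model (LG with empirical "+F" frequencies and gamma)
# and the matched site-heterogeneous mixture.
#' Default inference models for the recovery experiments
#'
#' @param mixture The profile mixture used for heterogeneous inference
#'   (typically the generating set, mirroring the use of a fixed
#'   C-series profile library as a stand-in for the full CAT model).
#' @param alpha,k Discrete-gamma shape and category count.
#' @return Named list of two \code{site_model}s:
#'   \code{homogeneous} (LG+F+G) and \code{heterogeneous} (mixture+G+F,
#'   the mixture gaining an empirical-frequency class at fit time as in
#'   C-series "+F" models).
#' @export
inference_models <- function(mixture, alpha = 0.8, k = 4L) {
  list(homogeneous = site_model("LG", "empirical", discrete_gamma(alpha, k)),
       heterogeneous = site_model("LG", mixture, discrete_gamma(alpha, k),
                                  plus_f = TRUE))
}

#' Branch-length estimation under matched and misspecified models
#'
#' Simulates one alignment on the (clade-annotated) tree under
#' \code{gen_model}, fits branch lengths on the true topology under each
#' inference model, and tabulates per-branch estimates plus per-clade
#' mean root-to-tip depths against the generating truth.
#'
#' @param tree Clade-annotated tree (see \code{tree_clades}).
#' @param gen_model Generating \code{site_model}.
#' @param infer_models Named list of \code{site_model}s.
#' @param n_sites Sites to simulate.
#' @param seed Integer seed.
#' @param tol Branch-length optimization tolerance.
#' @return A \code{data.frame} with columns \code{item} (branch id or
#'   clade name), \code{type} ("internal", "terminal" or "clade_depth"),
#'   \code{model}, \code{estimate}, \code{truth}.
#' @export
branch_length_experiment <- function(tree, gen_model, infer_models,
                                     n_sites = 20000L, seed = 1L,
                                     tol = 1e-4) {
  clades <- tree_clades(tree)
  if (length(clades) == 0L) stop2("tree has no named clades")
  sim <- simulate_alignment(tree, gen_model, n_sites, seed = seed)
  ntip <- length(tree$tip.label)
  rows <- list()
  for (mn in names(infer_models)) {
    model <- resolve_model(infer_models[[mn]], sim$alignment)
    fit <- optimize_branch_lengths(tree, sim$alignment, model, tol = tol)
    est_tree <- fit$tree
    # per-branch comparison: match edges by the taxon set below them
    key_t <- vapply(edge_descendant_tips(tree), function(x)
      paste(sort(x), collapse = ","), character(1))
    key_e <- vapply(edge_descendant_tips(est_tree), function(x)
      paste(sort(x), collapse = ","), character(1))
    est_len <- setNames(est_tree$edge.length, key_e)
    for (i in seq_len(nrow(tree$edge))) {
      rows[[length(rows) + 1L]] <- data.frame(
        item = key_t[i],
        type = if (tree$edge[i, 2L] <= ntip) "terminal" else "internal",
        model = mn,
        estimate = unname(est_len[key_t[i]]),
        truth = tree$edge.length[i])
    }
    for (cn in names(clades)) {
      if (length(clades[[cn]]) < 2L) next
      rows[[length(rows) + 1L]] <- data.frame(
        item = cn, type = "clade_depth", model = mn,
        estimate = clade_mean_depth(est_tree, clades[[cn]]),
        truth = clade_mean_depth(tree, clades[[cn]]))
    }
  }
  do.call(rbind, rows)
}

#' Topology recovery under matched and misspecified inference
#'
#' Per replicate: simulate an alignment on the generating topology via
#' the jittered parameter ensemble, evaluate all candidate topologies
#' under each inference model (branch lengths optimized; the expensive
#' mixture fits are warm-started from the homogeneous fits), and tally
#' winners.
#'
#' @param candidates Named list / \code{candidate_set} of topologies.
#' @param generating Name of the generating candidate.
#' @param gen_model Generating \code{site_model}.
#' @param infer_models Named list of \code{site_model}s.
#' @param n_replicates,n_sites Replicate count and sites per replicate.
#' @param seed Integer seed.
#' @param jitter_sd Lognormal branch-length jitter across the parameter
#'   ensemble (one set per replicate).
#' @param drop_taxa Taxa removed (from the generating tree before
#'   simulation, and from all candidates) — the taxon-removal variant.
#' @param nni_refine Also run NNI refinement from each candidate and
#'   count a replicate as "other" when the refined tree beats all
#'   candidates by more than \code{nni_margin} log-likelihood units.
#' @param nni_margin See \code{nni_refine}.
#' @param tol,max_cycles Optimization controls.
#' @param stratum Label recorded in the output (e.g. gene-quality pool).
#' @return A \code{data.frame} of class \code{recovery_table}: one row
#'   per (generating, inference model, winner) with counts, plus
#'   attribute \code{"replicates"} holding the per-replicate detail.
#' @export
recovery_experiment <- function(candidates, generating, gen_model,
                                infer_models, n_replicates = 50L,
                                n_sites = 2000L, seed = 1L,
                                jitter_sd = 0.05, drop_taxa = character(0),
                                nni_refine = FALSE, nni_margin = 0.1,
                                tol = 1e-2, max_cycles = 100L,
                                stratum = "all") {
  if (!inherits(candidates, "candidate_set"))
    candidates <- candidate_set(candidates)
  if (!generating %in% names(candidates))
    stop2("generating topology must be one of the candidates")
  gen_tree <- candidates[[generating]]
  cands <- candidates
  if (length(drop_taxa) > 0L) {
    gen_tree <- prune_taxa(gen_tree, drop = drop_taxa)
    cands <- candidate_set(lapply(candidates, prune_taxa, drop = drop_taxa))
  }
  ens <- make_parameter_ensemble(gen_tree, gen_model, n_replicates,
                                 jitter_sd = jitter_sd,
                                 seed = derive_seed(seed, 0L))
  sims <- simulate_ensemble(ens, n_sites, n_replicates, seed = seed)

  det <- list()
  for (r in seq_len(n_replicates)) {
    aln <- sims[[r]]$alignment
    hom_first <- "homogeneous" %in% names(infer_models)
    order_models <- c(intersect("homogeneous", names(infer_models)),
                      setdiff(names(infer_models), "homogeneous"))
    hom_trees <- NULL
    for (mn in order_models) {
      ev <- evaluate_candidates(aln, infer_models[[mn]], cands,
                                optimize = TRUE, tol = tol,
                                max_cycles = max_cycles,
                                start_lengths = if (mn != "homogeneous")
                                  hom_trees else NULL)
      if (mn == "homogeneous") hom_trees <- ev$trees
      winner <- ev$winner
      margin <- ev$loglik[winner] - max(ev$loglik[names(ev$loglik) != winner])
      if (nni_refine) {
        ref <- nni_search(ev$trees[[winner]], aln, infer_models[[mn]],
                          tol = tol)
        same <- any(vapply(cands, function(tr)
          identical_topology(ref$tree, tr), logical(1)))
        if (!same && ref$loglik > ev$loglik[winner] + nni_margin)
          winner <- "other"
      }
      det[[length(det) + 1L]] <- data.frame(
        replicate = r, generating = generating, infer_model = mn,
        stratum = stratum, winner = winner, logl_margin = margin)
    }
  }
  det <- do.call(rbind, det)
  tab <- as.data.frame(table(infer_model = det$infer_model,
                             winner = det$winner))
  tab <- tab[tab$Freq > 0L, ]
  gen_label <- if (gen_model$mode == "mixture" &&
                   length(gen_model$frequencies$profiles) > 1L)
    "heterogeneous" else "homogeneous"
  out <- data.frame(generating = generating, gen_label = gen_label,
                    infer_model = as.character(tab$infer_model),
                    stratum = stratum,
                    winner = as.character(tab$winner), count = tab$Freq,
                    n_replicates = n_replicates, row.names = NULL)
  attr(out, "replicates") <- det
  class(out) <- c("recovery_table", "data.frame")
  out
}

# Unrooted topology identity via split sets.
identical_topology <- function(a, b) {
  if (!setequal(a$tip.label, b$tip.label)) return(FALSE)
  ka <- sort(vapply(extract_splits(a), split_key, character(1)))
  kb <- sort(vapply(extract_splits(b), split_key, character(1)))
  identical(ka, kb)
}

#' Correct-recovery rate from a recovery table
#'
#' @param recovery A \code{recovery_table}.
#' @param model Inference model name.
#' @return Fraction of replicates whose winner is the generating
#'   topology under \code{model}.
#' @export
recovery_rate <- function(recovery, model) {
  sub <- recovery[recovery$infer_model == model, ]
  if (nrow(sub) == 0L) stop2("no rows for model ", model)
  sum(sub$count[sub$winner == sub$generating]) / sub$n_replicates[1L]
}

#' Composite-data titration between two generating topologies
#'
#' For each of \code{n_pairs} pairs of alignments — one simulated under
#' topology A's parameters, one under topology B's — and each mixing
#' proportion p, a composite alignment of round(p * n_sites) sites drawn
#' without replacement from the A-simulation and the remainder from the
#' B-simulation is analysed, and the winning topology recorded.
#'
#' @param params_A,params_B \code{list(tree, model)} generating
#'   parameter sets for the two topologies.
#' @param candidates Candidate set to evaluate composites against.
#' @param proportions Proportions of A-derived sites, in [0, 1].
#' @param n_pairs Number of alignment pairs.
#' @param n_sites Sites per parent alignment (and per composite).
#' @param infer_model Inference \code{site_model}.
#' @param seed Integer seed.
#' @param tol Optimization tolerance.
#' @return A \code{data.frame}: proportion, wins_A, wins_B, n_pairs.
#'   Per-pair winners are attached as attribute \code{"detail"}.
#' @export
mixing_experiment <- function(params_A, params_B, candidates,
                              proportions = seq(0.1, 0.9, by = 0.1),
                              n_pairs = 20L, n_sites = 2000L,
                              infer_model = NULL, seed = 1L, tol = 1e-2,
                              max_cycles = 100L) {
  if (any(proportions < 0 | proportions > 1))
    stop2("proportions must lie in [0, 1]")
  if (!inherits(candidates, "candidate_set"))
    candidates <- candidate_set(candidates)
  stopifnot(length(names(candidates)) >= 2L)
  nmA <- names(candidates)[1L]; nmB <- names(candidates)[2L]
  det <- list()
  for (i in seq_len(n_pairs)) {
    simA <- simulate_alignment(params_A$tree, params_A$model, n_sites,
                               seed = derive_seed(seed, 2L * i))
    simB <- simulate_alignment(params_B$tree, params_B$model, n_sites,
                               seed = derive_seed(seed, 2L * i + 1L))
    for (p in proportions) {
      nA <- round(p * n_sites)
      pick <- with_seed(derive_seed(seed, 1000L + 2L * i), {
        list(a = sample.int(n_sites, nA),
             b = sample.int(n_sites, n_sites - nA))
      })
      comp <- aa_alignment(cbind(
        unclass(simA$alignment)[, pick$a, drop = FALSE],
        unclass(simB$alignment)[alignment_taxa(simA$alignment),
                                pick$b, drop = FALSE]))
      ev <- evaluate_candidates(comp, infer_model, candidates,
                                optimize = TRUE, tol = tol,
                                max_cycles = max_cycles)
      det[[length(det) + 1L]] <- data.frame(pair = i, proportion = p,
                                            winner = ev$winner)
    }
  }
  det <- do.call(rbind, det)
  agg <- do.call(rbind, lapply(sort(unique(det$proportion)), function(p) {
    w <- det$winner[det$proportion == p]
    data.frame(proportion = p, wins_A = sum(w == nmA),
               wins_B = sum(w == nmB), n_pairs = n_pairs)
  }))
  attr(agg, "detail") <- det
  agg
}

#' Rank genes by monophyly score and pool best/worst quarters
#'
#' Per gene: a gene tree is inferred (NNI from a parsimony
#' random-addition start under \code{infer_model}) and scored by the
#' number of reference clades recovered monophyletic; clades whose taxa
#' are incomplete in a gene are skipped and the score normalized by the
#' scoreable count. Genes are sorted by descending normalized score
#' (ties by input order) and the top and bottom quarters (by gene count)
#' are pooled into concatenated site sets.
#'
#' @param genes List of \code{aa_alignment}s (or \code{make_gene_set}
#'   output).
#' @param reference_clades Named list of taxon vectors.
#' @param infer_model A \code{site_model} for gene-tree inference.
#' @param seed Integer seed.
#' @param tol Optimization tolerance for gene-tree fits.
#' @return List: \code{scores} (data.frame gene, score, n_clades,
#'   normalized, rank), \code{best} and \code{worst} (pooled
#'   \code{aa_alignment}s), \code{best_genes}, \code{worst_genes}.
#' @export
monophyly_rank <- function(genes, reference_clades, infer_model,
                           seed = 1L, tol = 1e-2) {
  if (length(genes) < 4L) stop2("need >= 4 genes")
  alns <- lapply(genes, function(g)
    if (inherits(g, "aa_alignment")) g else g$alignment)
  n <- length(alns)
  rows <- list()
  for (g in seq_len(n)) {
    aln <- alns[[g]]
    start <- random_addition_tree(aln, infer_model,
                                  seed = derive_seed(seed, g), tol = tol)
    fit <- nni_search(start, aln, infer_model, tol = tol)
    score <- 0L; scoreable <- 0L
    for (cl in reference_clades) {
      if (!all(cl %in% alignment_taxa(aln))) next
      scoreable <- scoreable + 1L
      if (is_monophyletic(fit$tree, cl)) score <- score + 1L
    }
    rows[[g]] <- data.frame(gene = g, score = score, n_clades = scoreable,
                            normalized = if (scoreable > 0L)
                              score / scoreable else NA_real_)
  }
  sc <- do.call(rbind, rows)
  ord <- order(-sc$normalized, sc$gene)
  sc$rank <- match(seq_len(n), ord)
  q <- max(1L, floor(n / 4))
  best_genes <- ord[seq_len(q)]
  worst_genes <- ord[(n - q + 1L):n]
  list(scores = sc,
       best = concat_alignments(alns[best_genes]),
       worst = concat_alignments(alns[worst_genes]),
       best_genes = best_genes, worst_genes = worst_genes)
}

#' Cross-validation comparison of two site models
#'
#' Per repetition: disjoint training and test site sets are drawn,
#' each model's continuous parameters (branch lengths, and optionally
#' the gamma shape) are fitted on the training data against the fixed
#' topology, and the difference in test-set log-likelihood
#' (model A minus model B) is recorded. The winner is the model with
#' the higher mean test log-likelihood.
#'
#' @param alignment An \code{aa_alignment}.
#' @param tree Fixed topology used for both models.
#' @param model_A,model_B \code{site_model}s to compare.
#' @param train_sites,test_sites Sizes of the disjoint draws.
#' @param n_reps Repetitions.
#' @param seed Integer seed.
#' @param estimate_shape Also fit the gamma shape on the training data.
#' @param tol Optimization tolerance.
#' @return List of class \code{cross_validation_result}: \code{delta}
#'   (per-rep test logL_A - logL_B), \code{mean}, \code{sd},
#'   \code{n_reps}, \code{winner}.
#' @export
cross_validation <- function(alignment, tree, model_A, model_B,
                             train_sites = 10000L, test_sites = 2000L,
                             n_reps = 10L, seed = 1L,
                             estimate_shape = FALSE, tol = 1e-3,
                             max_cycles = 100L) {
  S <- n_sites(alignment)
  if (train_sites + test_sites > S)
    stop2("train + test (", train_sites + test_sites,
          ") exceeds available sites (", S, ")")
  delta <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    idx <- with_seed(derive_seed(seed, r),
                     sample.int(S, train_sites + test_sites))
    train <- aa_alignment(unclass(alignment)[, idx[seq_len(train_sites)],
                                             drop = FALSE])
    test <- aa_alignment(unclass(alignment)[, idx[(train_sites + 1L):
                                                  (train_sites + test_sites)],
                                            drop = FALSE])
    test_ll <- function(model) {
      model <- resolve_model(model, train)
      fit <- optimize_branch_lengths(tree, train, model, tol = tol,
                                     max_cycles = max_cycles)
      if (estimate_shape) {
        est <- estimate_alpha(fit$tree, train, model)
        model$gamma <- discrete_gamma(est$alpha, model$gamma$k)
        fit <- optimize_branch_lengths(fit$tree, train, model, tol = tol)
      }
      log_likelihood(fit$tree, test, model)$loglik
    }
    delta[r] <- test_ll(model_A) - test_ll(model_B)
  }
  structure(list(delta = delta, mean = mean(delta), sd = sd(delta),
                 n_reps = n_reps,
                 winner = if (mean(delta) >= 0) "A" else "B"),
            class = "cross_validation_result")
}

#' @export
print.cross_validation_result <- function(x, ...) {
  cat(sprintf("cross-validation: mean dlogL = %.2f +/- %.2f (%d reps), winner: model %s\n",
              x$mean, x$sd, x$n_reps, x$winner))
  invisible(x)
}
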
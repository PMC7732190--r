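# Synthetic study system: paired Farris/Felsenstein backbone trees with
# long terminal branches on a focal clade and the outgroup, short
# internals, Dirichlet profile sets emulating across-site compositional
# heterogeneity, and gene sets with a built-in quality gradient.

#' Configuration of the synthetic backbone tree
#'
#' Four clades hang off a central backbone: an outgroup and a focal
#' clade with long terminal branches, and two short-branch ingroup
#' clades. The two arrangements differ only in where the focal clade
#' attaches: \code{"farris"} places it sister to the outgroup (the two
#' long branches are adjacent, so long-branch attraction reinforces the
#' true tree); \code{"felsenstein"} places it sister to the second
#' ingroup clade, separated from the outgroup by short internal
#' branches (the classic zone where misspecified models join the long
#' branches in error). Both arrangements share an identical multiset of
#' branch lengths, so recovery asymmetry between them cannot be a
#' tree-length artifact.
#'
#' Terminal-length defaults (long terminals ~1.0-1.2, short terminals
#' 0.25, internals 0.04 substitutions/site) are package defaults chosen
#' to land in the LBA-sensitive regime; they are calibration knobs, not
#' empirical estimates. The focal clade's terminals are graded — two
#' long tips (the fast "acoelomorph analog", listed in the tree's
#' \code{"long_focal"} attribute) and one short tip (the slow
#' "xenoturbellid analog") — so taxon-removal experiments can drop the
#' long subclade.
#'
#' @param outgroup_size,focal_size Number of taxa in the outgroup and
#'   focal clades.
#' @param ingroup_sizes Sizes of the two short-branch ingroup clades.
#' @param outgroup_terminal,focal_terminal,ingroup_terminal Terminal
#'   branch lengths (substitutions/site); \code{focal_terminal} may be a
#'   vector of per-taxon lengths (longest listed first).
#' @param internal_length Length of every internal branch.
#' @param arrangement \code{"farris"} or \code{"felsenstein"}.
#' @return A list of class \code{backbone_config}.
#' @export
backbone_config <- function(outgroup_size = 3L, focal_size = 3L,
                            ingroup_sizes = c(3L, 3L),
                            outgroup_terminal = 2.0,
                            focal_terminal = c(1.7, 1.7, 0.55),
                            ingroup_terminal = 0.2,
                            internal_length = 0.07,
                            arrangement = c("felsenstein", "farris")) {
  arrangement <- match.arg(arrangement)
  if (outgroup_size < 1L || focal_size < 1L || any(ingroup_sizes < 1L) ||
      length(ingroup_sizes) < 2L)
    stop2("need >= 4 clades with >= 1 taxon each")
  if (any(outgroup_terminal <= 0) || any(focal_terminal <= 0) ||
      any(ingroup_terminal <= 0) || internal_length <= 0)
    stop2("branch lengths must be > 0")
  focal_terminal <- rep_len(focal_terminal, focal_size)
  outgroup_terminal <- rep_len(outgroup_terminal, outgroup_size)
  structure(list(outgroup_size = outgroup_size, focal_size = focal_size,
                 ingroup_sizes = ingroup_sizes,
                 outgroup_terminal = outgroup_terminal,
                 focal_terminal = focal_terminal,
                 ingroup_terminal = ingroup_terminal,
                 internal_length = internal_length,
                 arrangement = arrangement),
            class = "backbone_config")
}

# Ladderized newick for one clade, cherry first: ((l1,l2),l3,...), so
# the first two taxa always form a two-taxon subclade.
clade_newick <- function(labels, terminals, internal) {
  n <- length(labels)
  s <- sprintf("%s:%.10g", labels[1L], terminals[1L])
  if (n == 1L) return(s)
  s <- sprintf("(%s,%s:%.10g)", s, labels[2L], terminals[2L])
  if (n > 2L) for (i in 3L:n)
    s <- sprintf("(%s:%.10g,%s:%.10g)", s, internal, labels[i], terminals[i])
  s
}

#' Build the synthetic backbone tree
#'
#' @param config A \code{backbone_config}.
#' @param seed Unused (the generator is deterministic); accepted so all
#'   generators share a calling convention.
#' @return A binary unrooted \code{phylo} with named-clade annotations
#'   (\code{tree_clades}: outgroup, focal, ingroup1, ingroup2) and the
#'   long focal tips in attribute \code{"long_focal"}.
#' @export
make_backbone <- function(config = backbone_config(), seed = NULL) {
  stopifnot(inherits(config, "backbone_config"))
  il <- config$internal_length
  out_l <- paste0("out", seq_len(config$outgroup_size))
  foc_l <- paste0("foc", seq_len(config$focal_size))
  inA_l <- paste0("inA", seq_len(config$ingroup_sizes[1L]))
  inB_l <- paste0("inB", seq_len(config$ingroup_sizes[2L]))
  cl <- function(labels, terms)
    clade_newick(labels, rep_len(terms, length(labels)), il)
  out_s <- cl(out_l, config$outgroup_terminal)
  foc_s <- cl(foc_l, config$focal_terminal)
  inA_s <- cl(inA_l, config$ingroup_terminal)
  inB_s <- cl(inB_l, config$ingroup_terminal)
  stem <- sprintf(":%.10g", il)
  nwk <- if (config$arrangement == "farris") {
    sprintf("(%s%s,%s%s,(%s%s,%s%s):%.10g);",
            inA_s, stem, inB_s, stem, out_s, stem, foc_s, stem, il)
  } else {
    sprintf("(%s%s,%s%s,(%s%s,%s%s):%.10g);",
            out_s, stem, inA_s, stem, inB_s, stem, foc_s, stem, il)
  }
  tr <- parse_newick(nwk)
  tree_clades(tr) <- list(outgroup = out_l, focal = foc_l,
                          ingroup1 = inA_l, ingroup2 = inB_l)
  long <- foc_l[config$focal_terminal > min(config$focal_terminal)]
  attr(tr, "long_focal") <- if (length(long)) long else character(0)
  attr(tr, "arrangement") <- config$arrangement
  tr
}

#' Paired Farris/Felsenstein backbones
#'
#' @param config A \code{backbone_config}; its \code{arrangement} field
#'   is ignored.
#' @return Named list of trees \code{farris} and \code{felsenstein}
#'   sharing one leaf set and branch-length multiset.
#' @export
make_backbone_pair <- function(config = backbone_config()) {
  cfg_far <- config; cfg_far$arrangement <- "farris"
  cfg_fel <- config; cfg_fel$arrangement <- "felsenstein"
  list(farris = make_backbone(cfg_far),
       felsenstein = make_backbone(cfg_fel))
}

#' Draw a synthetic profile mixture from a Dirichlet distribution
#'
#' Components are i.i.d. Dirichlet(concentration * 1_20) with uniform
#' weights. Low concentration (default 0.2) yields sparse, strongly
#' heterogeneous profiles — the qualitative feature of empirical
#' site-frequency profiles that drives convergent substitutions.
#'
#' @param n_components Number of profiles (>= 1).
#' @param concentration Dirichlet concentration parameter (> 0).
#' @param seed Optional integer seed.
#' @return A \code{profile_mixture}.
#' @export
make_profile_set <- function(n_components = 20L, concentration = 0.2,
                             seed = NULL) {
  if (n_components < 1L) stop2("need >= 1 component")
  if (concentration <= 0) stop2("concentration must be > 0")
  with_seed(seed, {
    m <- matrix(rgamma(n_components * 20L, shape = concentration),
                nrow = n_components)
    m <- pmax(m, 1e-12)
    profile_mixture(m / rowSums(m))
  })
}

#' Default site-heterogeneous generating model for the backbone
#'
#' LG exchangeabilities, a Dirichlet profile mixture, and 4-category
#' discrete-gamma rates with shape 0.8.
#'
#' @param mixture A \code{profile_mixture} (default: 20 components drawn
#'   with \code{seed}).
#' @param alpha Gamma shape.
#' @param k Gamma categories.
#' @param exchangeabilities Matrix name or object.
#' @param seed Seed for the default mixture draw.
#' @export
synth_model <- function(mixture = NULL, alpha = 0.8, k = 4L,
                        exchangeabilities = "LG", seed = 1L) {
  if (is.null(mixture)) mixture <- make_profile_set(seed = seed)
  site_model(exchangeabilities, mixture, discrete_gamma(alpha, k))
}

#' Configuration of the graded-quality gene set
#'
#' Gene quality is controlled by per-gene scale factors applied to the
#' backbone's terminal and internal branches: best-end genes have short
#' terminals and long internals (the regime that resists long-branch
#' attraction), worst-end genes the reverse. Scales interpolate linearly
#' across genes.
#'
#' @param n_genes Number of genes.
#' @param sites_per_gene Sites simulated per gene.
#' @param terminal_scale_range Terminal scale at the best and worst end.
#' @param internal_scale_range Internal scale at the best and worst end.
#' @export
gene_set_config <- function(n_genes = 20L, sites_per_gene = 500L,
                            terminal_scale_range = c(0.5, 2.0),
                            internal_scale_range = c(1.5, 0.5)) {
  if (n_genes < 1L) stop2("need >= 1 gene")
  if (terminal_scale_range[1L] > terminal_scale_range[2L] &&
      internal_scale_range[1L] > internal_scale_range[2L])
    stop2("best-end genes must not have both longer terminals and ",
          "shorter internals than worst-end genes")
  structure(list(n_genes = n_genes, sites_per_gene = sites_per_gene,
                 terminal_scale_range = terminal_scale_range,
                 internal_scale_range = internal_scale_range),
            class = "gene_set_config")
}

# Scale a tree's terminal and internal branches separately.
scale_tree_edges <- function(tree, terminal_scale, internal_scale) {
  ntip <- length(tree$tip.label)
  is_term <- tree$edge[, 2L] <= ntip
  tree$edge.length[is_term] <- tree$edge.length[is_term] * terminal_scale
  tree$edge.length[!is_term] <- tree$edge.length[!is_term] * internal_scale
  tree
}

#' Simulate a gene set with a known quality gradient
#'
#' Gene g is simulated on the backbone with terminal branches scaled by
#' \code{terminal_scale(g)} and internal branches by
#' \code{internal_scale(g)}; gene 1 is the best (short terminals, long
#' internals). The true rank accompanies each gene so rank-recovery by
#' monophyly scoring can be validated against ground truth.
#'
#' @param backbone Tree from \code{make_backbone}.
#' @param config A \code{gene_set_config}.
#' @param gen_model Generating \code{site_model}.
#' @param seed Integer seed.
#' @return List of genes, each \code{list(alignment, true_rank,
#'   terminal_scale, internal_scale, tree)}.
#' @export
make_gene_set <- function(backbone, config = gene_set_config(),
                          gen_model = synth_model(), seed = 1L) {
  n <- config$n_genes
  ts <- seq(config$terminal_scale_range[1L], config$terminal_scale_range[2L],
            length.out = n)
  is <- seq(config$internal_scale_range[1L], config$internal_scale_range[2L],
            length.out = n)
  lapply(seq_len(n), function(g) {
    tr <- scale_tree_edges(backbone, ts[g], is[g])
    sim <- simulate_alignment(tr, gen_model, config$sites_per_gene,
                              seed = derive_seed(seed, g))
    list(alignment = sim$alignment, true_rank = g,
         terminal_scale = ts[g], internal_scale = is[g], tree = tr)
  })
}

#' Reference clades for monophyly scoring on the backbone
#'
#' The four named clades plus each clade's two-taxon crown pair (for
#' clades of three or more taxa), giving a finer-grained score.
#'
#' @param backbone Tree from \code{make_backbone}.
#' @return Named list of character vectors.
#' @export
backbone_reference_clades <- function(backbone) {
  cl <- tree_clades(backbone)
  out <- cl
  for (nm in names(cl)) {
    taxa <- cl[[nm]]
    if (length(taxa) >= 3L) {
      # the crown pair is the cherry of the ladderized clade subtree
      pair <- taxa[seq_len(2L)]
      if (is_monophyletic(backbone, pair))
        out[[paste0(nm, "_crown")]] <- pair
    }
  }
  out
}
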
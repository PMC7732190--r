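# Trees are plain ape "phylo" objects with unrooted likelihood semantics:
# the stored root is presentational only (reversible models make root
# placement non-identifiable). All branch lengths are substitutions/site.

#' Parse a newick string into a tree
#'
#' Wraps \code{ape} newick parsing with the validation this package
#' relies on everywhere: unique leaf labels, non-negative branch lengths
#' (missing lengths default to 0), and binary internal nodes.
#' Multifurcating inputs are rejected unless \code{resolve = TRUE}, in
#' which case they are resolved arbitrarily with zero-length branches.
#' A basal trifurcation (the standard unrooted representation) is always
#' accepted.
#'
#' @param text A newick string (terminating semicolon optional).
#' @param resolve Resolve multifurcations with zero-length branches
#'   instead of rejecting them.
#' @return An object of class \code{phylo}.
#' @export
parse_newick <- function(text, resolve = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  tr <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop2("newick parse error: ", conditionMessage(e))
  )
  if (is.null(tr)) stop2("newick parse error: unparseable string")
  if (anyDuplicated(tr$tip.label))
    stop2("duplicate leaf label: ",
          paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0, nrow(tr$edge))
  tr$edge.length[is.na(tr$edge.length)] <- 0
  if (any(tr$edge.length < 0))
    stop2("negative branch length in newick input")
  if (!is_binary_tree(tr)) {
    if (!resolve)
      stop2("tree contains multifurcations; pass resolve = TRUE to resolve ",
            "them arbitrarily with zero-length branches")
    tr <- ape::multi2di(tr, random = FALSE)
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  tr
}

# Cheap structural check with error positions; ape's messages lack them.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop2("newick parse error at position ", i, ": unbalanced ')'")
    }
  }
  if (depth != 0L)
    stop2("newick parse error at position ", nchar(text),
          ": ", depth, " unclosed '('")
  invisible(TRUE)
}

# Binary in the unrooted sense: every internal node has degree 3, except
# that the stored root may have degree 2 (rooted representation) or 3.
is_binary_tree <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  deg <- tabulate(c(tree$edge[, 1L], tree$edge[, 2L]),
                  nbins = ntip + tree$Nnode)
  internal <- setdiff(seq_len(ntip + tree$Nnode), seq_len(ntip))
  all(deg[setdiff(internal, root)] == 3L) && deg[root] %in% c(2L, 3L)
}

#' Serialize a tree to newick
#'
#' @param tree A \code{phylo} object.
#' @param digits Significant digits for branch lengths (default 10, which
#'   round-trips through \code{parse_newick} to working precision).
#' @return A newick string.
#' @export
write_newick <- function(tree, digits = 10) {
  ape::write.tree(tree, digits = digits)
}

#' Construct a canonical bipartition of a taxon set
#'
#' The side containing the lexicographically smallest taxon is stored as
#' \code{side_a}, so equal splits compare equal regardless of input
#' orientation.
#'
#' @param side_a,side_b Character vectors partitioning the taxon set.
#' @return An object of class \code{taxon_split}.
#' @export
taxon_split <- function(side_a, side_b) {
  side_a <- sort(unique(as.character(side_a)))
  side_b <- sort(unique(as.character(side_b)))
  if (length(intersect(side_a, side_b)) > 0L)
    stop2("split sides must be disjoint")
  if (length(side_a) == 0L || length(side_b) == 0L)
    stop2("split sides must be non-empty")
  if (side_b[1L] < side_a[1L]) { tmp <- side_a; side_a <- side_b; side_b <- tmp }
  structure(list(side_a = side_a, side_b = side_b), class = "taxon_split")
}

#' @export
print.taxon_split <- function(x, ...) {
  cat(paste(x$side_a, collapse = ","), "|",
      paste(x$side_b, collapse = ","), "\n")
  invisible(x)
}

# Stable string key for set operations over splits.
split_key <- function(split) {
  paste(paste(split$side_a, collapse = ","),
        paste(split$side_b, collapse = ","), sep = "|")
}

#' Extract the nontrivial splits of a tree
#'
#' One split per internal branch; trivial splits (one taxon on a side) are
#' excluded. A binary unrooted tree with n leaves yields n - 3 splits.
#'
#' @param tree A \code{phylo} object with at least 4 leaves.
#' @return A list of \code{taxon_split} objects.
#' @export
extract_splits <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 4L) stop2("split extraction requires >= 4 leaves")
  desc <- edge_descendant_tips(tree)
  keys <- character(0)
  out <- list()
  for (i in seq_len(nrow(tree$edge))) {
    side <- desc[[i]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    sp <- taxon_split(side, setdiff(tree$tip.label, side))
    k <- split_key(sp)
    if (!k %in% keys) { keys <- c(keys, k); out[[length(out) + 1L]] <- sp }
  }
  out
}

# For each edge (row of tree$edge), the tip labels below its child end.
edge_descendant_tips <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  sets <- vector("list", ntip + tr$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tr$tip.label[i]
  for (i in seq_len(nrow(tr$edge))) {
    p <- tr$edge[i, 1L]; v <- tr$edge[i, 2L]
    sets[[p]] <- c(sets[[p]], sets[[v]])
  }
  # map back to the input edge order
  res <- vector("list", nrow(tree$edge))
  post_child <- tr$edge[, 2L]
  for (i in seq_len(nrow(tree$edge))) {
    v <- tree$edge[i, 2L]
    res[[i]] <- sets[[v]]
  }
  res
}

#' Test unrooted monophyly of a taxon set
#'
#' True iff some branch of the tree has exactly \code{taxa} on one side.
#' Singletons, the full leaf set, and its complement are monophyletic by
#' convention (they correspond to terminal branches or the whole tree).
#'
#' @param tree A \code{phylo} object.
#' @param taxa Character vector of tip labels.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown) > 0L)
    stop2("unknown taxa: ", paste(unknown, collapse = ", "))
  n <- length(tree$tip.label)
  if (length(taxa) <= 1L || length(taxa) >= n - 1L) return(TRUE)
  target <- split_key(taxon_split(taxa, setdiff(tree$tip.label, taxa)))
  any(vapply(extract_splits(tree), split_key, character(1)) == target)
}

#' Drop taxa from a tree (and optionally a matched alignment)
#'
#' Degree-2 nodes left by the removal are suppressed with their adjacent
#' branch lengths summed, so pairwise path lengths among the surviving
#' taxa are unchanged.
#'
#' @param tree A \code{phylo} object.
#' @param alignment Optional \code{aa_alignment} whose rows are dropped in
#'   step with the tree.
#' @param drop Character vector of tip labels to remove.
#' @return If \code{alignment} is NULL, the pruned tree; otherwise a list
#'   with elements \code{tree} and \code{alignment}.
#' @export
prune_taxa <- function(tree, alignment = NULL, drop = character(0)) {
  drop <- unique(as.character(drop))
  unknown <- setdiff(drop, tree$tip.label)
  if (length(unknown) > 0L)
    stop2("unknown taxa: ", paste(unknown, collapse = ", "))
  keep_n <- length(tree$tip.label) - length(drop)
  if (keep_n < 4L)
    stop2("pruning would leave ", keep_n, " taxa; at least 4 are required")
  out_tree <- if (length(drop) == 0L) tree else
    ape::drop.tip(tree, drop, collapse.singles = TRUE)
  if (is.null(alignment)) return(out_tree)
  list(tree = out_tree,
       alignment = alignment_subset_taxa(alignment,
                                         setdiff(alignment_taxa(alignment), drop)))
}

# Named-clade annotations carried by synthetic backbones -----------------

#' Named clade annotations of a tree
#'
#' @param tree A \code{phylo} object.
#' @return A named list of character vectors (possibly empty).
#' @export
tree_clades <- function(tree) attr(tree, "clades") %||% list()

#' @rdname tree_clades
#' @param value Named list of character vectors of tip labels.
#' @export
`tree_clades<-` <- function(tree, value) {
  stopifnot(is.list(value))
  for (cl in value) {
    if (!all(cl %in% tree$tip.label)) stop2("clade contains unknown taxa")
  }
  attr(tree, "clades") <- value
  tree
}

#' Mean root-to-tip depth within a named clade
#'
#' The average distance from each clade member to the clade's common
#' ancestor (the clade-side endpoint of the branch subtending it). Used to
#' summarise terminal-path lengths of major clades.
#'
#' @param tree A \code{phylo} object in which \code{taxa} is monophyletic.
#' @param taxa Character vector of clade members.
#' @return Numeric scalar.
#' @export
clade_mean_depth <- function(tree, taxa) {
  taxa <- as.character(taxa)
  if (!all(taxa %in% tree$tip.label)) stop2("clade contains unknown taxa")
  if (length(taxa) == 1L) return(0)
  if (!is_monophyletic(tree, taxa)) stop2("taxa are not monophyletic")
  # root outside the clade so its MRCA is the attachment node regardless
  # of where the stored (presentational) root happens to sit
  out_tip <- setdiff(tree$tip.label, taxa)[1L]
  rt <- ape::root(ape::unroot(tree), outgroup = out_tip, resolve.root = TRUE)
  anc <- ape::getMRCA(rt, taxa)
  depths <- ape::node.depth.edgelength(rt)
  tips <- match(taxa, rt$tip.label)
  mean(depths[tips] - depths[anc])
}

#' Serialize splits as tab-separated sides
#'
#' One line per split: comma-joined \code{side_a}, a tab, comma-joined
#' \code{side_b}.
#'
#' @param splits List of \code{taxon_split} objects.
#' @param path Output file path.
#' @export
write_splits_tsv <- function(splits, path) {
  lines <- vapply(splits, function(s)
    paste(paste(s$side_a, collapse = ","),
          paste(s$side_b, collapse = ","), sep = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_splits_tsv
#' @return \code{read_splits_tsv} returns a list of \code{taxon_split}.
#' @export
read_splits_tsv <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop2("malformed split line: ", l)
    taxon_split(strsplit(parts[1], ",", fixed = TRUE)[[1]],
                strsplit(parts[2], ",", fixed = TRUE)[[1]])
  })
}
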
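# Amino-acid alignments are integer matrices (taxa x sites) over the
# fixed alphabet ARNDCQEGHILKMFPSTWYV coded 0..19; code 20 is gap/unknown
# and is treated as fully missing in all likelihoods.

#' Construct an amino-acid alignment
#'
#' @param codes Integer matrix, taxa in rows, sites in columns, values in
#'   0..20 (20 = gap/unknown). Row names are the taxon labels. A character
#'   matrix of one-letter codes is also accepted.
#' @param taxa Optional taxon labels overriding row names.
#' @return An object of class \code{aa_alignment}.
#' @export
aa_alignment <- function(codes, taxa = NULL) {
  if (is.character(codes)) {
    m <- matrix(match(toupper(codes), .aa_alphabet) - 1L,
                nrow = nrow(codes), dimnames = dimnames(codes))
    m[is.na(m)] <- 20L
    codes <- m
  }
  storage.mode(codes) <- "integer"
  if (!is.null(taxa)) rownames(codes) <- taxa
  if (is.null(rownames(codes))) stop2("alignment requires taxon labels")
  if (anyDuplicated(rownames(codes))) stop2("duplicate taxon labels")
  if (any(is.na(codes)) || any(codes < 0L) || any(codes > 20L))
    stop2("alignment codes must be integers in 0..20")
  structure(codes, class = c("aa_alignment", "matrix"))
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat("aa_alignment:", nrow(x), "taxa x", ncol(x), "sites\n")
  invisible(x)
}

#' @rdname aa_alignment
#' @param alignment An \code{aa_alignment}.
#' @export
alignment_taxa <- function(alignment) rownames(alignment)

#' @rdname aa_alignment
#' @export
n_sites <- function(alignment) ncol(alignment)

# Character-matrix view (one-letter codes, "-" for missing).
alignment_chars <- function(alignment) {
  lv <- c(.aa_alphabet, "-")
  matrix(lv[unclass(alignment) + 1L], nrow = nrow(alignment),
         dimnames = dimnames(alignment))
}

#' Subset an alignment to the given taxa (in the given order)
#'
#' @param alignment An \code{aa_alignment}.
#' @param taxa Character vector of taxon labels to keep.
#' @export
alignment_subset_taxa <- function(alignment, taxa) {
  missing <- setdiff(taxa, rownames(alignment))
  if (length(missing) > 0L)
    stop2("unknown taxa: ", paste(missing, collapse = ", "))
  aa_alignment(unclass(alignment)[taxa, , drop = FALSE])
}

#' Subsample alignment columns without replacement
#'
#' Draws \code{n} distinct columns uniformly at random, emulating the
#' random site subsets used to reduce phylogenomic alignments to a
#' tractable size.
#'
#' @param alignment An \code{aa_alignment}.
#' @param n Number of columns to draw (must not exceed the site count).
#' @param seed Optional integer seed for reproducibility.
#' @return An \code{aa_alignment} of \code{n} sites. The drawn column
#'   indices are attached as attribute \code{"sites"}.
#' @export
subsample_sites <- function(alignment, n, seed = NULL) {
  S <- ncol(alignment)
  if (n > S) stop2("cannot draw ", n, " sites from ", S)
  idx <- with_seed(seed, sample.int(S, n, replace = FALSE))
  out <- aa_alignment(unclass(alignment)[, idx, drop = FALSE])
  attr(out, "sites") <- idx
  out
}

#' Concatenate alignments over a shared taxon set
#'
#' @param alignments List of \code{aa_alignment} objects with identical
#'   taxon sets (rows are reordered to the first alignment's order).
#' @export
concat_alignments <- function(alignments) {
  stopifnot(length(alignments) >= 1L)
  taxa <- rownames(alignments[[1L]])
  mats <- lapply(alignments, function(a) {
    if (!setequal(rownames(a), taxa)) stop2("taxon sets differ")
    unclass(a)[taxa, , drop = FALSE]
  })
  aa_alignment(do.call(cbind, mats))
}

#' Observed amino-acid frequencies of an alignment
#'
#' Counts over the 20 amino acids (gaps ignored), normalized to sum to 1.
#' Zero counts are clamped to a small positive value before normalization
#' so the result is usable as a stationary profile ("+F" models).
#'
#' @param alignment An \code{aa_alignment}.
#' @return A \code{frequency_profile}.
#' @export
empirical_frequencies <- function(alignment) {
  tab <- tabulate(unclass(alignment)[unclass(alignment) < 20L] + 1L, nbins = 20L)
  frequency_profile(pmax(tab, 0.5) / sum(pmax(tab, 0.5)))
}

# FASTA ------------------------------------------------------------------

#' Read / write amino-acid FASTA
#'
#' Reading goes through \code{ape::read.FASTA}; any character outside the
#' 20-letter alphabet becomes the missing code.
#'
#' @param path File path.
#' @return \code{read_fasta_aa} returns an \code{aa_alignment}.
#' @export
read_fasta_aa <- function(path) {
  bin <- ape::read.FASTA(path, type = "AA")
  chr <- as.character(bin)
  lens <- lengths(chr)
  if (length(unique(lens)) != 1L) stop2("unequal sequence lengths in FASTA")
  m <- do.call(rbind, chr)
  rownames(m) <- names(chr)
  aa_alignment(m)
}

#' @rdname read_fasta_aa
#' @param alignment An \code{aa_alignment}.
#' @param width Line-wrap width for sequence lines.
#' @export
write_fasta_aa <- function(alignment, path, width = 70L) {
  chars <- alignment_chars(alignment)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(chars))) {
    writeLines(paste0(">", rownames(chars)[i]), con)
    s <- paste(chars[i, ], collapse = "")
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# Relaxed sequential PHYLIP ----------------------------------------------

#' Read / write relaxed sequential PHYLIP amino-acid alignments
#'
#' Relaxed format: header "ntaxa nsites", then one record per taxon of a
#' whitespace-delimited name followed by the sequence (possibly wrapped
#' over subsequent lines).
#'
#' @param path File path.
#' @return \code{read_phylip_aa} returns an \code{aa_alignment}.
#' @export
read_phylip_aa <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- scan(text = lines[1L], what = integer(), n = 2L, quiet = TRUE)
  if (length(hdr) != 2L) stop2("malformed PHYLIP header")
  ntax <- hdr[1L]; nsite <- hdr[2L]
  body <- paste(lines[-1L], collapse = "\n")
  toks <- strsplit(body, "\\s+")[[1L]]
  toks <- toks[nzchar(toks)]
  names_out <- character(ntax)
  seqs <- character(ntax)
  i <- 1L
  for (t in seq_len(ntax)) {
    if (i > length(toks)) stop2("truncated PHYLIP file")
    names_out[t] <- toks[i]; i <- i + 1L
    acc <- ""
    while (nchar(acc) < nsite) {
      if (i > length(toks)) stop2("sequence for ", names_out[t], " is short")
      acc <- paste0(acc, toks[i]); i <- i + 1L
    }
    if (nchar(acc) != nsite)
      stop2("sequence for ", names_out[t], " has ", nchar(acc),
            " sites, expected ", nsite)
    seqs[t] <- acc
  }
  m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  rownames(m) <- names_out
  aa_alignment(m)
}

#' @rdname read_phylip_aa
#' @param alignment An \code{aa_alignment}.
#' @export
write_phylip_aa <- function(alignment, path) {
  chars <- alignment_chars(alignment)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(nrow(chars), ncol(chars)), con)
  for (i in seq_len(nrow(chars)))
    writeLines(paste(rownames(chars)[i],
                     paste(chars[i, ], collapse = "")), con)
  invisible(path)
}

# phangorn interop (used for parsimony starts and test oracles) ----------
as_phyDat_aa <- function(alignment) {
  phangorn::phyDat(alignment_chars(alignment), type = "AA")
}
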
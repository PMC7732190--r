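# Substitution-model building blocks: exchangeabilities, frequency
# profiles, finite profile mixtures, discrete-gamma rates, rate matrices
# and transition probabilities. All matrices use the fixed state order
# ARNDCQEGHILKMFPSTWYV.

#' Exchangeability matrices
#'
#' Symmetric 20x20 non-negative relative substitution propensities with a
#' zero diagonal. \code{"LG"} gives the published Le & Gascuel (2008)
#' values bundled with the package; \code{"Poisson"} gives equal
#' off-diagonal entries (the F81-style assumption underlying CAT-F81).
#'
#' @param name \code{"LG"} or \code{"Poisson"}.
#' @return A 20x20 matrix with attribute \code{name}.
#' @export
exchangeability_matrix <- function(name = c("LG", "Poisson")) {
  name <- match.arg(name)
  m <- matrix(0, 20, 20, dimnames = list(.aa_alphabet, .aa_alphabet))
  if (name == "LG") {
    m[lower.tri(m)] <- .lg_lower
    m <- m + t(m)
  } else {
    m[] <- 1
    diag(m) <- 0
  }
  structure(m, name = name)
}

#' The LG stationary amino-acid frequencies
#'
#' @return A \code{frequency_profile} with the published LG frequencies.
#' @export
lg_frequencies <- function() frequency_profile(.lg_freqs)

#' A stationary frequency profile over the 20 amino acids
#'
#' @param p Numeric vector of length 20; non-negative, summing to 1
#'   (renormalized if within 1e-6 of 1, rejected otherwise).
#' @export
frequency_profile <- function(p) {
  p <- as.numeric(p)
  if (length(p) != 20L) stop2("a profile has 20 entries")
  if (any(p < 0)) stop2("profile entries must be >= 0")
  s <- sum(p)
  if (abs(s - 1) > 1e-6) stop2("profile entries must sum to 1 (got ", s, ")")
  structure(p / s, names = .aa_alphabet, class = "frequency_profile")
}

#' A finite mixture of frequency profiles
#'
#' A single-component mixture is exactly the corresponding homogeneous
#' model; the simulation and likelihood code treats them identically.
#'
#' @param profiles A list of \code{frequency_profile}s or a numeric matrix
#'   with one profile per row.
#' @param weights Mixture weights (default uniform); renormalized.
#' @export
profile_mixture <- function(profiles, weights = NULL) {
  if (is.matrix(profiles))
    profiles <- lapply(seq_len(nrow(profiles)), function(i)
      frequency_profile(profiles[i, ]))
  profiles <- lapply(profiles, function(p)
    if (inherits(p, "frequency_profile")) p else frequency_profile(p))
  k <- length(profiles)
  if (k < 1L) stop2("a mixture needs at least one component")
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(weights) != k || any(weights < 0) || sum(weights) <= 0)
    stop2("invalid mixture weights")
  structure(list(profiles = profiles, weights = weights / sum(weights)),
            class = "profile_mixture")
}

#' @export
print.profile_mixture <- function(x, ...) {
  cat("profile_mixture:", length(x$profiles), "components\n")
  invisible(x)
}

# Components as a k x 20 matrix.
mixture_matrix <- function(mixture) {
  do.call(rbind, lapply(mixture$profiles, as.numeric))
}

#' Read / write a profile mixture as TSV
#'
#' One row per component: the weight followed by the 20 frequencies.
#'
#' @param path File path.
#' @export
read_profile_mixture_tsv <- function(path) {
  m <- as.matrix(read.table(path, sep = "\t", header = FALSE))
  if (ncol(m) != 21L) stop2("expected 21 columns (weight + 20 frequencies)")
  profile_mixture(m[, -1L, drop = FALSE], weights = m[, 1L])
}

#' @rdname read_profile_mixture_tsv
#' @param mixture A \code{profile_mixture}.
#' @export
write_profile_mixture_tsv <- function(mixture, path) {
  m <- cbind(mixture$weights, mixture_matrix(mixture))
  write.table(format(m, digits = 12, scientific = FALSE, trim = TRUE),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Discrete-gamma rate heterogeneity
#'
#' The standard equal-probability discretization of a Gamma(alpha, alpha)
#' distribution into k categories, each represented by its category mean;
#' the mean rate is exactly 1.
#'
#' @param alpha Shape parameter (> 0).
#' @param k Number of categories (default 4).
#' @return An object of class \code{gamma_rates} with fields
#'   \code{alpha}, \code{k}, \code{rates}.
#' @export
discrete_gamma <- function(alpha, k = 4L) {
  if (!is.numeric(alpha) || alpha <= 0) stop2("alpha must be > 0")
  k <- as.integer(k)
  if (k < 1L) stop2("k must be >= 1")
  if (k == 1L) {
    rates <- 1
  } else {
    bounds <- qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
    # E[X | a < X < b] * k for X ~ Gamma(alpha, alpha), via the
    # incomplete-gamma identity with shape alpha + 1
    upper <- pgamma(bounds[-1L], shape = alpha + 1, rate = alpha)
    lower <- pgamma(bounds[-(k + 1L)], shape = alpha + 1, rate = alpha)
    rates <- (upper - lower) * k
    rates <- rates / (sum(rates) / k)  # exact unit mean against roundoff
  }
  structure(list(alpha = alpha, k = k, rates = rates), class = "gamma_rates")
}

#' A site model: exchangeabilities + frequency description + gamma rates
#'
#' The frequency description takes one of four modes: a single profile, a
#' finite \code{profile_mixture}, the string \code{"empirical"} (resolve
#' to the observed alignment frequencies at fit time; the "+F" option),
#' or a per-site profile matrix (one row per alignment column, the PMSF
#' representation).
#'
#' @param exchangeabilities An \code{exchangeability_matrix} or its name.
#' @param frequencies A \code{frequency_profile}, \code{profile_mixture},
#'   \code{"empirical"}, or an n_sites x 20 matrix of per-site profiles.
#' @param gamma A \code{gamma_rates} object, or a shape value from which
#'   a default 4-category discretization is built. \code{NULL} disables
#'   rate heterogeneity (a single unit-rate category).
#' @param plus_f For mixture mode: append the alignment's observed
#'   frequencies as an extra component at fit time (the "+F" class of
#'   C-series mixture models), resolved when the model meets data.
#' @return An object of class \code{site_model}.
#' @export
site_model <- function(exchangeabilities = exchangeability_matrix("LG"),
                       frequencies = lg_frequencies(),
                       gamma = NULL, plus_f = FALSE) {
  if (is.character(exchangeabilities))
    exchangeabilities <- exchangeability_matrix(exchangeabilities)
  if (is.null(gamma)) gamma <- discrete_gamma(1, k = 1L)
  if (is.numeric(gamma) && length(gamma) == 1L) gamma <- discrete_gamma(gamma)
  stopifnot(inherits(gamma, "gamma_rates"))
  mode <- if (inherits(frequencies, "profile_mixture")) "mixture"
          else if (identical(frequencies, "empirical")) "empirical"
          else if (is.matrix(frequencies)) "persite"
          else "single"
  if (mode == "single") frequencies <- frequency_profile(frequencies)
  if (mode == "persite") {
    if (ncol(frequencies) != 20L) stop2("per-site profiles need 20 columns")
    frequencies <- frequencies / rowSums(frequencies)
  }
  if (plus_f && mode != "mixture")
    stop2("plus_f applies to mixture models only")
  structure(list(exchangeabilities = exchangeabilities,
                 frequencies = frequencies,
                 gamma = gamma,
                 mode = mode,
                 plus_f = isTRUE(plus_f)),
            class = "site_model")
}

#' @export
print.site_model <- function(x, ...) {
  ex <- attr(x$exchangeabilities, "name")
  desc <- switch(x$mode,
    single = "single profile",
    mixture = paste0(length(x$frequencies$profiles), "-component mixture",
                     if (isTRUE(x$plus_f)) " (+F class at fit time)" else ""),
    empirical = "empirical (+F) frequencies",
    persite = paste0("per-site profiles (", nrow(x$frequencies), " sites)"))
  cat("site_model:", ex, "+", desc,
      if (x$gamma$k > 1L)
        paste0("+ G(alpha=", signif(x$gamma$alpha, 4), ", k=", x$gamma$k, ")")
      else "(rate-homogeneous)", "\n")
  invisible(x)
}

# Resolve data-dependent frequency components against an alignment:
# "empirical" single-profile mode, and the "+F" extra mixture class.
resolve_model <- function(model, alignment = NULL) {
  if (model$mode == "empirical") {
    if (is.null(alignment)) stop2("empirical frequencies need an alignment")
    return(site_model(model$exchangeabilities,
                      empirical_frequencies(alignment), model$gamma))
  }
  if (model$mode == "mixture" && isTRUE(model$plus_f)) {
    if (is.null(alignment)) stop2("plus_f mixtures need an alignment")
    mx <- model$frequencies
    k <- length(mx$profiles)
    mx2 <- profile_mixture(c(mx$profiles,
                             list(empirical_frequencies(alignment))),
                           weights = c(mx$weights * k / (k + 1), 1 / (k + 1)))
    return(site_model(model$exchangeabilities, mx2, model$gamma))
  }
  model
}

# Mixture view of any resolved model (single -> 1-component mixture).
model_mixture <- function(model) {
  switch(model$mode,
    single = profile_mixture(list(model$frequencies)),
    mixture = model$frequencies,
    stop2("model mode '", model$mode, "' has no mixture view"))
}

#' Build a normalized reversible rate matrix from exchangeabilities and a
#' profile
#'
#' Q_ij = ex_ij * pi_j for i != j, diagonal set so rows sum to zero, then
#' scaled so the expected substitution rate at stationarity is 1 (branch
#' lengths are expected substitutions per site). Zero profile entries are
#' clamped to 1e-10 and renormalized.
#'
#' @param ex An \code{exchangeability_matrix}.
#' @param profile A \code{frequency_profile} (or numeric vector).
#' @return A 20x20 rate matrix with the stationary profile attached as
#'   attribute \code{"freqs"}.
#' @export
build_rate_matrix <- function(ex, profile) {
  pi <- pmax(as.numeric(profile), 1e-10)
  pi <- pi / sum(pi)
  Q <- unclass(ex) * rep(pi, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  beta <- -sum(pi * diag(Q))
  Q <- Q / beta
  attr(Q, "freqs") <- pi
  Q
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed from the symmetric eigendecomposition available for
#' reversible rate matrices.
#'
#' @param Q A rate matrix from \code{build_rate_matrix}.
#' @param t Branch length times rate multiplier (>= 0).
#' @return A 20x20 row-stochastic matrix.
#' @export
transition_matrix <- function(Q, t) {
  if (t < 0) stop2("t must be >= 0")
  eg <- rate_matrix_eigen(Q)
  P <- eg$V %*% (exp(eg$lambda * t) * eg$W)
  P[P < 0] <- 0
  P / rowSums(P)
}

# Eigendecomposition of a reversible Q via the similar symmetric matrix
# diag(sqrt(pi)) Q diag(1/sqrt(pi)). Returns V, lambda, W such that
# P(t) = V diag(exp(lambda t)) W.
rate_matrix_eigen <- function(Q) {
  pi <- attr(Q, "freqs")
  if (is.null(pi)) stop2("Q lacks stationary frequencies")
  sq <- sqrt(pi)
  A <- Q * (sq %o% (1 / sq))
  A <- (A + t(A)) / 2
  eg <- eigen(A, symmetric = TRUE)
  list(V = eg$vectors / sq, lambda = eg$values,
       W = sweep(t(eg$vectors), 2L, sq, "*"), pi = pi)
}
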
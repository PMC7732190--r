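test_that("exchangeability matrices are symmetric and named", {
  lg <- exchangeability_matrix("LG")
  expect_true(isSymmetric(unclass(lg)))
  expect_true(all(diag(lg) == 0))
  expect_true(all(lg >= 0))
  # published values, state order ARNDCQEGHILKMFPSTWYV
  expect_equal(lg["A", "R"], 0.425093, tolerance = 1e-6)
  expect_equal(lg["A", "C"], 2.489084, tolerance = 1e-6)

  po <- exchangeability_matrix("Poisson")
  expect_true(all(po[upper.tri(po)] == 1))
})

test_that("profiles and mixtures enforce simplex validity", {
  expect_error(frequency_profile(rep(0.1, 20)), "sum to 1")
  expect_error(frequency_profile(c(-0.05, rep(1.05 / 19, 19))), ">= 0")
  p <- frequency_profile(rep(0.05, 20))
  expect_equal(sum(p), 1)

  mx <- profile_mixture(list(p, lg_frequencies()), weights = c(2, 2))
  expect_equal(mx$weights, c(0.5, 0.5))
  expect_error(profile_mixture(list()), "at least one")
})

test_that("profile mixtures round-trip through TSV", {
  mx <- make_profile_set(5, 0.3, seed = 4)
  f <- tempfile(fileext = ".tsv")
  write_profile_mixture_tsv(mx, f)
  back <- read_profile_mixture_tsv(f)
  expect_equal(lbazone:::mixture_matrix(back), lbazone:::mixture_matrix(mx),
               tolerance = 1e-9)
  expect_equal(back$weights, mx$weights, tolerance = 1e-9)
})

test_that("rate matrices satisfy normalization and detailed balance", {
  for (nm in c("LG", "Poisson")) {
    ex <- exchangeability_matrix(nm)
    prof <- if (nm == "LG") lg_frequencies() else
      frequency_profile(rep(1 / 20, 20))
    Q <- build_rate_matrix(ex, prof)
    pi <- attr(Q, "freqs")
    expect_equal(unname(rowSums(Q)), rep(0, 20), tolerance = 1e-12)
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12)
    flux <- Q * pi                       # pi_i Q_ij
    expect_lt(max(abs(flux - t(flux))), 1e-12)
    # stationarity: pi Q = 0
    expect_equal(as.numeric(pi %*% Q), rep(0, 20), tolerance = 1e-12)
  }

  # Poisson + uniform: off-diagonal rates all 1/19 after normalization
  Qp <- build_rate_matrix(exchangeability_matrix("Poisson"),
                          frequency_profile(rep(1 / 20, 20)))
  expect_equal(unique(round(Qp[row(Qp) != col(Qp)], 12)), 1 / 19)
})

test_that("LG stationary distribution equals the LG profile (eigen oracle)", {
  Q <- build_rate_matrix(exchangeability_matrix("LG"), lg_frequencies())
  eg <- eigen(t(Q))
  i0 <- which.min(abs(eg$values))
  stat <- Re(eg$vectors[, i0]); stat <- stat / sum(stat)
  expect_equal(stat, as.numeric(lg_frequencies()), tolerance = 1e-9)
})

test_that("transition matrices are stochastic and consistent", {
  Q <- build_rate_matrix(exchangeability_matrix("LG"), lg_frequencies())
  expect_equal(transition_matrix(Q, 0), diag(20), tolerance = 1e-9)
  expect_error(transition_matrix(Q, -0.1), ">= 0")

  P1 <- transition_matrix(Q, 0.3)
  expect_equal(rowSums(P1), rep(1, 20), tolerance = 1e-10)
  # Chapman-Kolmogorov
  expect_lt(max(abs(P1 %*% transition_matrix(Q, 0.7) -
                    transition_matrix(Q, 1.0))), 1e-8)

  # equal-frequency Poisson closed form for the diagonal
  Qp <- build_rate_matrix(exchangeability_matrix("Poisson"),
                          frequency_profile(rep(1 / 20, 20)))
  for (t in c(0.1, 0.5, 2)) {
    P <- transition_matrix(Qp, t)
    expect_equal(diag(P), rep(1 / 20 + (19 / 20) * exp(-(20 / 19) * t), 20),
                 tolerance = 1e-10)
  }
})

test_that("discrete gamma matches quadrature and limits", {
  expect_equal(discrete_gamma(0.7, 1)$rates, 1)
  expect_true(all(abs(discrete_gamma(1e6, 4)$rates - 1) < 1e-2))
  expect_error(discrete_gamma(-1), "> 0")

  g <- discrete_gamma(0.5, 4)
  expect_equal(mean(g$rates), 1, tolerance = 1e-10)
  expect_true(all(diff(g$rates) > 0))

  # quadrature oracle: mean of Gamma(0.5, 0.5) within each probability
  # quartile, computed by numeric integration
  bounds <- qgamma(seq(0, 1, 0.25), 0.5, 0.5)
  quad <- vapply(1:4, function(i) {
    integrate(function(x) x * dgamma(x, 0.5, 0.5), bounds[i], bounds[i + 1],
              rel.tol = 1e-10)$value * 4
  }, numeric(1))
  expect_equal(g$rates, quad / mean(quad), tolerance = 1e-6)
})

test_that("site models expose the four frequency modes", {
  m1 <- site_model("LG", lg_frequencies(), 0.8)
  expect_equal(m1$mode, "single")
  m2 <- site_model("Poisson", make_profile_set(3, seed = 1), 0.8)
  expect_equal(m2$mode, "mixture")
  m3 <- site_model("LG", "empirical", 0.8)
  expect_equal(m3$mode, "empirical")
  aln <- random_alignment(letters[1:3], 50, seed = 6)
  r3 <- lbazone:::resolve_model(m3, aln)
  expect_equal(r3$mode, "single")
  expect_equal(as.numeric(r3$frequencies),
               as.numeric(empirical_frequencies(aln)))
  m4 <- site_model("LG", matrix(1 / 20, 5, 20), 0.8)
  expect_equal(m4$mode, "persite")
})

test_that("empirical frequencies count residues and ignore gaps", {
  codes <- matrix(c(0L, 0L, 1L, 20L), 2, 2, dimnames = list(c("a", "b"), NULL))
  f <- empirical_frequencies(aa_alignment(codes))
  expect_gt(f[1], f[2])
  expect_equal(sum(f), 1)
})
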
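test_that("latent bounds partition the Gaussian scale consistently with the cdf", {
  mP <- count_marginal("poisson", mu = 2.5)
  b0 <- latent_bounds(0L, mP)
  expect_identical(unname(b0[1, "lower"]), -Inf)
  # bounds for y = 3 are the probit images of F(2), F(3), computed by
  # brute-force pmf summation
  b3 <- latent_bounds(3L, mP)
  F2 <- brute_cdf(function(y) marginal_pmf(mP, y), 2)
  F3 <- brute_cdf(function(y) marginal_pmf(mP, y), 3)
  expect_equal(unname(b3[1, ]), qnorm(c(F2, F3)))
  # consecutive intervals tile the real line
  bb <- latent_bounds(0:40, mP)
  expect_equal(bb[-1, "lower"], bb[-41, "upper"])
  expect_identical(latent_bounds(0L, count_marginal("zero"))[1, ],
                   c(lower = -Inf, upper = Inf))
})

test_that("MCEM recovers independence and a planted bivariate correlation", {
  marg <- list(fish_nb(), fish_zinb())
  gm_ind <- group_copula_model(marg, diag(2))
  set.seed(61)
  Y <- simulate_counts(gm_ind, 500)
  f <- mcem_fit(Y, marg, mcem_settings(n_mc = 40, max_iter = 30, seed = 1))
  expect_lt(abs(f$sigma[1, 2]), 0.1)
  expect_equal(diag(f$sigma), c(1, 1))
  # planted rho = 0.574 (the worked bivariate reef-fish example)
  gm <- group_copula_model(marg, matrix(c(1, 0.574, 0.574, 1), 2))
  rhos <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    Ys <- simulate_counts(gm, 500)
    mcem_fit(Ys, marg, mcem_settings(n_mc = 40, max_iter = 30,
                                     seed = 2000 + s))$sigma[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(rhos) - 0.574), 0.08)
  # every returned matrix is a valid correlation matrix
  expect_true(all(abs(rhos) <= 1))
})

test_that("MCEM is invariant to species order and rejects degenerate input", {
  marg <- list(count_marginal("nb", mu = 4, theta = 1.5),
               count_marginal("zinb", mu = 9, theta = 2, pi = 0.15),
               count_marginal("poisson", mu = 2))
  lam <- sqrt(c(0.6, 0.5, 0.4))
  S <- tcrossprod(lam); diag(S) <- 1
  gm <- group_copula_model(marg, S)
  set.seed(77)
  Y <- simulate_counts(gm, 800)
  f1 <- mcem_fit(Y, marg, mcem_settings(n_mc = 40, max_iter = 30, seed = 3))
  ord <- c(3, 1, 2)
  f2 <- mcem_fit(Y[, ord], marg[ord],
                 mcem_settings(n_mc = 40, max_iter = 30, seed = 3))
  expect_equal(unname(f1$sigma[ord, ord]), unname(f2$sigma), tolerance = 0.08)
  Yz <- cbind(Y[, 1], 0L)
  expect_error(mcem_fit(Yz, list(marg[[1]], count_marginal("zero"))),
               "degenerate")
  expect_error(mcem_fit(Y[, 1, drop = FALSE], marg[1]), "at least 2")
  expect_error(mcem_settings(n_mc = 5), "n_mc")
})

test_that("expand_correlation embeds the block and leaves independence elsewhere", {
  expect_identical(expand_correlation(matrix(numeric(0), 0, 0), integer(0), 4),
                   diag(4))
  S <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_identical(expand_correlation(S, 1:2, 2), S)
  E <- expand_correlation(matrix(c(1, 0.574, 0.574, 1), 2), c(3, 7), 10)
  expect_equal(E[3, 7], 0.574)
  expect_equal(E[1, 2], 0)
  expect_equal(diag(E), rep(1, 10))
  expect_error(expand_correlation(S, c(2, 2), 5), "distinct")
  expect_error(expand_correlation(S, c(1, 9), 5), "distinct|1..p")
})

test_that("simulation preserves each marginal distribution (round trip)", {
  marg <- list(count_marginal("nb", mu = 3, theta = 1.2),
               count_marginal("zinb", mu = 10, theta = 2, pi = 0.25),
               count_marginal("zip", mu = 4, pi = 0.3))
  sigma <- expand_correlation(matrix(c(1, 0.6, 0.6, 1), 2), c(1, 2), 3)
  gm <- group_copula_model(marg, sigma)
  Y <- simulate_counts(gm, 10000, seed = 8)
  for (j in 1:3) {
    m <- marg[[j]]
    mu_th <- sum((0:500) * marginal_pmf(m, 0:500))
    se <- sqrt((sum((0:500)^2 * marginal_pmf(m, 0:500)) - mu_th^2) / 10000)
    expect_lt(abs(mean(Y[, j]) - mu_th), 3 * se)
    # chi-square of simulated vs theoretical pmf over pooled-tail bins
    ymax <- marginal_quantile(m, 0.999)
    obs <- tabulate(pmin(Y[, j], ymax + 1) + 1, nbins = ymax + 2)
    pr <- c(marginal_pmf(m, 0:ymax), 1 - marginal_cdf(m, ymax))
    keep <- pr * 10000 >= 5
    chi <- suppressWarnings(chisq.test(obs[keep], p = pr[keep] / sum(pr[keep])))
    expect_gt(chi$p.value, 0.001)
  }
  # degenerate species simulate as constant zero
  gm2 <- group_copula_model(c(marg, list(count_marginal("zero"))), diag(4))
  expect_true(all(simulate_counts(gm2, 50, seed = 1)[, 4] == 0L))
})

test_that("rho-to-I curve is monotone and pins the comonotone endpoint", {
  m <- count_marginal("nb", mu = 4, theta = 1.5)
  cv <- rho_to_I_curve(m, m, rho_grid = c(-0.9, -0.4, 0, 0.4, 0.9, 1),
                       n_per_dataset = 1000, n_reps = 20, seed = 12)
  expect_true(all(diff(cv$mean_I) > -0.01))   # monotone up to MC noise
  expect_equal(cv$mean_I[cv$rho == 1], 1)     # identical marginals, rho = 1
  expect_true(all(cv$q025 <= cv$mean_I & cv$mean_I <= cv$q975))
  # inverse lookup returns an interpolated rho inside the grid
  r <- rho_for_index(cv, 0.8)
  expect_true(r > -1 && r < 1)
  expect_error(rho_for_index(cv, 2), "outside")
})

test_that("model containers validate their invariants", {
  m2 <- list(count_marginal("poisson", mu = 1), count_marginal("poisson", mu = 2))
  bad <- matrix(c(1, 0.9, 0.2, 1), 2)
  expect_error(group_copula_model(m2, bad), "symmetric")
  expect_error(group_copula_model(m2, matrix(c(2, 0, 0, 2), 2)), "diagonal")
  expect_error(group_copula_model(m2, matrix(c(1, 1.2, 1.2, 1), 2)),
               "semi-definite")
  gm <- group_copula_model(m2, diag(2))
  expect_error(community_model(list(gm, list(marginals = m2[1])), c(5, 5)),
               "species dimension")
})
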
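test_that("cdf matches brute-force pmf summation and the mixture definition", {
  mP <- count_marginal("poisson", mu = 2.5)
  expect_identical(marginal_cdf(mP, -1), 0)
  # frozen from the brute-force sum e^{-2.5} (1 + 2.5 + 2.5^2/2)
  expect_equal(marginal_cdf(mP, 2), 0.5438131, tolerance = 1e-6)
  mz <- fish_zinb()
  p0_nb <- dnbinom(0, mu = 15.375, size = 1.857)
  expect_equal(marginal_cdf(mz, 0), 0.095 + (1 - 0.095) * p0_nb)
  # pmf sums to 1 over a generous truncation for all families
  fams <- list(count_marginal("poisson", mu = 3),
               count_marginal("zip", mu = 3, pi = 0.3),
               count_marginal("nb", mu = 3, theta = 1.2),
               count_marginal("zinb", mu = 3, theta = 1.2, pi = 0.3))
  for (m in fams) {
    expect_equal(sum(marginal_pmf(m, 0:500)), 1, tolerance = 1e-10)
    cdf <- marginal_cdf(m, -1:500)
    expect_true(all(diff(cdf) >= 0))
    expect_equal(cdf[1], 0)
    expect_equal(cdf[length(cdf)], 1, tolerance = 1e-10)
    expect_equal(cdf[-1], cumsum(marginal_pmf(m, 0:500)), tolerance = 1e-12)
  }
  expect_error(count_marginal("nb", mu = -1, theta = 1), "mu")
  expect_error(count_marginal("zinb", mu = 1, theta = 1, pi = 1), "pi")
})

test_that("quantile is the generalized inverse of the cdf", {
  mP <- count_marginal("poisson", mu = 2.5)
  expect_identical(marginal_quantile(mP, 0.70), 3L)
  # cross-checked against brute-force cumulative summation
  expect_identical(marginal_quantile(fish_zinb(), 0.90),
                   brute_quantile(function(y) marginal_pmf(fish_zinb(), y), 0.90))
  expect_identical(marginal_quantile(fish_zinb(), 0.90), 30L)
  expect_identical(marginal_quantile(fish_nb(), 0.75), 4L)
  fams <- list(mP, count_marginal("zip", mu = 4, pi = 0.25),
               count_marginal("nb", mu = 2.714, theta = 1.635),
               count_marginal("zinb", mu = 15.375, theta = 1.857, pi = 0.095))
  for (m in fams) {
    expect_identical(marginal_quantile(m, 0), 0L)
    # adjunction on the support (outside the documented q = 1 clamp region)
    for (y in 0:25) {
      if (marginal_pmf(m, y) < 1e-14 || marginal_cdf(m, y) > 1 - 1e-12) next
      expect_identical(marginal_quantile(m, marginal_cdf(m, y)), as.integer(y))
    }
    for (q in c(0.05, 0.3, 0.62, 0.9, 0.999))
      expect_gte(marginal_cdf(m, marginal_quantile(m, q)), q)
    # q = 1 returns a finite clamp deep in the upper tail
    y1 <- marginal_quantile(m, 1)
    expect_true(is.finite(y1))
    expect_lt(1 - marginal_cdf(m, y1), 1e-11)
  }
  expect_error(marginal_quantile(mP, 1.2), "0, 1")
})

test_that("family limits: ZINB(pi = 0) equals NB, NB(theta -> Inf) approaches Poisson", {
  y <- 0:60
  nb <- count_marginal("nb", mu = 5, theta = 2)
  zinb0 <- count_marginal("zinb", mu = 5, theta = 2, pi = 0)
  expect_equal(marginal_pmf(zinb0, y), marginal_pmf(nb, y), tolerance = 1e-14)
  big <- count_marginal("nb", mu = 5, theta = 1e6)
  pois <- count_marginal("poisson", mu = 5)
  expect_equal(marginal_pmf(big, y), marginal_pmf(pois, y), tolerance = 1e-4)
})

test_that("maximum likelihood fitting recovers parameters; NB dominates Poisson in likelihood", {
  set.seed(31)
  counts <- rpois(200, 3.7)
  fp <- fit_marginal(counts, "poisson")
  expect_equal(fp$marginal$mu, mean(counts))
  # over-dispersed data: NB log-likelihood >= Poisson log-likelihood (nesting)
  over <- rnbinom(300, mu = 4, size = 0.8)
  expect_gte(fit_marginal(over, "nb")$loglik, fit_marginal(over, "poisson")$loglik)
  # simulation recovery at n = 2000
  z <- ifelse(runif(2000) < 0.2, 0L, rnbinom(2000, mu = 10, size = 2))
  fz <- fit_marginal(z, "zinb")
  expect_true(fz$converged)
  expect_equal(fz$marginal$mu, 10, tolerance = 0.1)
  expect_equal(fz$marginal$theta, 2, tolerance = 0.25)
  expect_equal(fz$marginal$pi, 0.2, tolerance = 0.25)
})

test_that("mean recovery holds across all four families over seeded replicates", {
  set.seed(99)
  gen <- list(
    poisson = function(n) rpois(n, 6),
    zip = function(n) ifelse(runif(n) < 0.25, 0L, rpois(n, 6)),
    nb = function(n) rnbinom(n, mu = 6, size = 1.5),
    zinb = function(n) ifelse(runif(n) < 0.25, 0L, rnbinom(n, mu = 6, size = 1.5)))
  for (fam in names(gen)) {
    err <- replicate(50, {
      f <- fit_marginal(gen[[fam]](2000), fam)
      abs(f$marginal$mu - 6) / 6
    })
    expect_lt(median(err), 0.05)
  }
})

test_that("all-zero counts yield the degenerate point-mass sentinel", {
  for (fam in c("poisson", "zip", "nb", "zinb")) {
    f <- fit_marginal(integer(5), fam)
    expect_true(f$degenerate)
    expect_identical(f$marginal$family, "zero")
  }
  z <- count_marginal("zero")
  expect_identical(marginal_quantile(z, 0.99), 0L)
  expect_identical(marginal_cdf(z, 0), 1)
})

test_that("AICc selection prefers the generating family and honors n > k + 1", {
  set.seed(7)
  eq <- rpois(3000, 5)
  expect_identical(select_marginal(eq)$family, "poisson")
  zi <- ifelse(runif(1500) < 0.4, 0L, rnbinom(1500, mu = 12, size = 1.5))
  expect_identical(select_marginal(zi)$family, "zinb")
  # AICc formula
  f <- fit_marginal(rpois(50, 2), "nb")
  expect_equal(f$aicc, -2 * f$loglik + 2 * 2 + 2 * 2 * 3 / (50 - 2 - 1))
  # n = 4 excludes the ZINB candidate (k = 3, n <= k + 1) with a warning
  expect_warning(sel <- select_marginal(c(0L, 1L, 3L, 2L)), "n <= k \\+ 1")
  expect_false(identical(sel$family, "zinb"))
})

test_that("rare-species flagging follows the singleton and strict-prevalence rules", {
  Y <- cbind(single = c(5L, rep(0L, 39)),          # singleton -> flagged
             everywhere = rep(2L, 40),             # full prevalence -> not
             attwo = c(1L, 1L, rep(0L, 38)),       # 2/40 = 0.05 exactly -> not
             scarce = c(1L, 1L, 1L, rep(0L, 37)))  # 3/40 = 0.075
  fl <- flag_rare(Y, min_prevalence = 0.05)
  expect_identical(unname(fl), c(TRUE, FALSE, FALSE, FALSE))
  expect_true(flag_rare(Y, min_prevalence = 0.10)[["scarce"]])
  expect_error(flag_rare(Y, min_prevalence = 0), "0, 1")
})

test_that("per-group fitting covers every species and reports a tidy table", {
  dat <- generate_community(tiny_spec())
  fits <- fit_marginals(dat$Y, dat$groups)
  rep <- marginals_report(fits)
  expect_identical(nrow(rep), ncol(dat$Y) * nlevels(dat$groups))
  expect_true(all(c("species", "group", "family", "mu", "aicc") %in% names(rep)))
  pooled <- fit_marginals(dat$Y, dat$groups, aicc_scope = "pooled")
  fam_by_group <- sapply(pooled, function(g) sapply(g, `[[`, "family"))
  # pooled scope: a species keeps one family across groups unless absent there
  present <- sapply(levels(dat$groups), function(g)
    colSums(dat$Y[dat$groups == g, ]) > 0)
  for (j in seq_len(ncol(dat$Y))) {
    fams <- fam_by_group[j, present[j, ]]
    expect_lte(length(unique(fams)), 1L)
  }
})
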
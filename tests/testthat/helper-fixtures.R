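# Shared fixtures and tiny brute-force oracles, all built in code.

# brute-force cdf by cumulative pmf summation (independent of marginal_cdf)
brute_cdf <- function(pmf, y) sum(pmf(0:y))

# brute-force generalized-inverse quantile from a pmf closure
brute_quantile <- function(pmf, q, y_max = 5000) {
  cs <- cumsum(pmf(0:y_max))
  which(cs >= q)[1] - 1L
}

# the two marginals of the worked bivariate reef-fish example
fish_nb <- function() count_marginal("nb", mu = 2.714, theta = 1.635)
fish_zinb <- function() count_marginal("zinb", mu = 15.375, theta = 1.857,
                                       pi = 0.095)

# small three-group community with one planted correlated block per group
tiny_spec <- function(seed = 42, ...) {
  synthetic_spec(p = 10, g = 3, sizes = c(10, 10, 10), rare_fraction = 0.2,
                 block_range = c(3, 4), rho_range = c(0.5, 0.8),
                 effect_size = 0.5, seed = seed, ...)
}

# exchangeable null count matrix: iid NB columns, no group structure
null_counts <- function(n, p, mu = 4, theta = 1.5) {
  matrix(stats::rnbinom(n * p, mu = mu, size = theta), n, p,
         dimnames = list(NULL, paste0("sp", seq_len(p))))
}

# is point x (length 2) inside (or on) the convex hull of 2-d rows of P?
in_hull_2d <- function(x, P) {
  all_pts <- rbind(P, x)
  hull <- grDevices::chull(all_pts)
  !(nrow(all_pts) %in% hull)
}
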
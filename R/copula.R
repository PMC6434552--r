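#' Latent Gaussian bounds for an observed count
#'
#' A discrete observation `y` does not pin down a single point on the
#' latent Gaussian scale: it corresponds to the whole interval
#' `(qnorm(F(y - 1)), qnorm(F(y))]` (a side of the observation's
#' hyper-rectangle), with `qnorm(0) = -Inf` and `qnorm(1) = +Inf`.
#'
#' @param y Integer vector of counts.
#' @param m A [count_marginal()].
#' @return Two-column matrix `lower`, `upper`.
#' @export
latent_bounds <- function(y, m) {
  cbind(lower = stats::qnorm(marginal_cdf(m, y - 1)),
        upper = stats::qnorm(marginal_cdf(m, y)))
}

#' Settings for the Monte Carlo EM copula fit
#'
#' @param n_mc Monte Carlo latent draws per observation in the E-step
#'   (>= 10); grows geometrically by `growth` per iteration (capped at
#'   `n_mc_cap`) to damp Monte Carlo noise near convergence.
#' @param max_iter Maximum EM iterations.
#' @param tol Convergence tolerance on the maximum absolute entrywise
#'   change of the Polyak-averaged correlation iterate (> 0).
#' @param seed Optional integer seed.
#' @param burnin Gibbs sweeps before the first E-step average.
#' @param sweeps Gibbs sweeps per subsequent E-step (warm-started).
#' @param growth Geometric growth factor for `n_mc`.
#' @param n_mc_cap Upper cap on `n_mc`.
#' @return A list of class `mcem_settings`.
#' @export
mcem_settings <- function(n_mc = 50, max_iter = 50, tol = 0.005, seed = NULL,
                          burnin = 10, sweeps = 2, growth = 1.2,
                          n_mc_cap = 200) {
  if (n_mc < 10) stop("'n_mc' must be >= 10", call. = FALSE)
  if (tol <= 0) stop("'tol' must be > 0", call. = FALSE)
  structure(list(n_mc = n_mc, max_iter = max_iter, tol = tol, seed = seed,
                 burnin = burnin, sweeps = sweeps, growth = growth,
                 n_mc_cap = n_mc_cap), class = "mcem_settings")
}

## Project a symmetric matrix to a valid correlation matrix:
## unit-diagonal normalization, then eigenvalue clipping if needed.
project_correlation <- function(S, eps = 1e-8) {
  d <- sqrt(diag(S))
  R <- S / tcrossprod(d)
  e <- eigen(R, symmetric = TRUE)
  if (min(e$values) < 0) {
    v <- pmax(e$values, eps)
    R <- e$vectors %*% (v * t(e$vectors))
    d <- sqrt(diag(R))
    R <- R / tcrossprod(d)
  }
  R <- (R + t(R)) / 2
  diag(R) <- 1
  R
}

## Normal-scores rank correlation start, shrunk 10% toward identity.
normal_scores_init <- function(Y) {
  n <- nrow(Y)
  Z <- apply(Y, 2, function(y)
    stats::qnorm((rank(y, ties.method = "average") - 0.5) / n))
  S <- stats::cor(Z)
  project_correlation(0.9 * S + 0.1 * diag(ncol(Y)))
}

## One vectorized Gibbs sweep over all coordinates of the stacked latent
## matrix Z (M x p), each row truncated to its own interval (L, U].
.gibbs_sweep <- function(Z, L, U, beta, s) {
  p <- ncol(Z)
  for (j in seq_len(p)) {
    mu_j <- Z[, -j, drop = FALSE] %*% beta[[j]]
    pa <- stats::pnorm((L[, j] - mu_j) / s[j])
    pb <- stats::pnorm((U[, j] - mu_j) / s[j])
    u <- stats::runif(nrow(Z))
    pu <- pmin(pmax(pa + u * (pb - pa), 1e-12), 1 - 1e-12)
    z <- mu_j + s[j] * stats::qnorm(pu)
    ## numerically degenerate interval: fall back to nearest finite bound
    bad <- !is.finite(z)
    if (any(bad))
      z[bad] <- pmin(pmax(mu_j[bad], L[bad, j]), U[bad, j])
    Z[, j] <- z
  }
  Z
}

#' Estimate a Gaussian copula correlation matrix by Monte Carlo EM
#'
#' Marginal distributions are held fixed (the estimation is conditioned
#' on them). Each observed count vector constrains the latent Gaussian
#' vector to a hyper-rectangle; the E-step draws latent vectors from the
#' current multivariate normal truncated to each observation's rectangle
#' by coordinate-wise Gibbs sampling, and the M-step replaces the
#' correlation matrix with the correlation-normalized average of the
#' sampled outer products, projected back to a valid correlation matrix.
#' Iterates until the Polyak-averaged matrix moves less than `tol` or
#' `max_iter` is reached.
#'
#' @param Y n-by-m matrix of counts for the m jointly modeled species.
#' @param marginals List of m [count_marginal()] objects, none degenerate.
#' @param settings An [mcem_settings()] list.
#' @return List of class `mcem_fit`: `sigma` (the estimated correlation
#'   matrix), `converged`, `iterations`, `delta_path`, `settings`.
#' @export
mcem_fit <- function(Y, marginals, settings = mcem_settings()) {
  Y <- as.matrix(Y)
  p <- ncol(Y)
  n <- nrow(Y)
  if (p < 2) stop("need at least 2 species to estimate a copula", call. = FALSE)
  if (length(marginals) != p) stop("one marginal per column required", call. = FALSE)
  if (any(vapply(marginals, is_degenerate, logical(1))) || any(colSums(Y) == 0))
    stop("degenerate (all-zero) species must be excluded before MCEM",
         call. = FALSE)
  if (!is.null(settings$seed)) set.seed(settings$seed)

  L1 <- U1 <- Zmid <- matrix(0, n, p)
  for (j in seq_len(p)) {
    b <- latent_bounds(Y[, j], marginals[[j]])
    L1[, j] <- b[, 1]; U1[, j] <- b[, 2]
    Fmid <- pmin(pmax((marginal_cdf(marginals[[j]], Y[, j] - 1) +
                       marginal_cdf(marginals[[j]], Y[, j])) / 2,
                      1e-12), 1 - 1e-12)
    Zmid[, j] <- stats::qnorm(Fmid)
  }

  sigma <- normal_scores_init(Y)
  n_mc <- settings$n_mc
  rep_block <- function(M, k) M[rep(seq_len(n), k), , drop = FALSE]
  Z <- rep_block(Zmid, n_mc)
  L <- rep_block(L1, n_mc); U <- rep_block(U1, n_mc)

  avg_win <- vector("list", 5)
  prev_avg <- NULL
  delta_path <- numeric(0)
  converged <- FALSE
  it <- 0
  while (it < settings$max_iter) {
    it <- it + 1
    ## conditional regression coefficients under current sigma
    beta <- vector("list", p); s <- numeric(p)
    for (j in seq_len(p)) {
      bj <- solve(sigma[-j, -j, drop = FALSE], sigma[-j, j])
      beta[[j]] <- bj
      s[j] <- sqrt(max(1 - sum(sigma[j, -j] * bj), 1e-8))
    }
    n_sweep <- if (it == 1) settings$burnin else settings$sweeps
    for (sw in seq_len(n_sweep)) Z <- .gibbs_sweep(Z, L, U, beta, s)
    S <- crossprod(Z) / nrow(Z)
    sigma <- project_correlation(S)

    avg_win[[(it - 1) %% 5 + 1]] <- sigma
    got <- Filter(Negate(is.null), avg_win)
    avg <- Reduce(`+`, got) / length(got)
    if (!is.null(prev_avg)) {
      delta <- max(abs(avg - prev_avg))
      delta_path <- c(delta_path, delta)
      if (it >= 5 && delta < settings$tol) { converged <- TRUE }
    }
    prev_avg <- avg
    if (converged) break

    new_mc <- min(ceiling(settings$growth * n_mc), settings$n_mc_cap)
    if (new_mc > n_mc) {
      add <- new_mc - n_mc
      Z <- rbind(Z, rep_block(Zmid, add))
      L <- rbind(L, rep_block(L1, add))
      U <- rbind(U, rep_block(U1, add))
      n_mc <- new_mc
    }
  }
  sigma_hat <- project_correlation(prev_avg)
  dimnames(sigma_hat) <- list(colnames(Y), colnames(Y))
  if (!converged)
    warning("MCEM did not reach tol = ", settings$tol, " within ",
            settings$max_iter, " iterations (last delta = ",
            signif(utils::tail(delta_path, 1), 3), ")", call. = FALSE)
  structure(list(sigma = sigma_hat, converged = converged, iterations = it,
                 delta_path = delta_path, settings = settings),
            class = "mcem_fit")
}

#' @export
print.mcem_fit <- function(x, ...) {
  cat("<mcem_fit> ", nrow(x$sigma), "x", ncol(x$sigma),
      " copula correlation matrix; ", x$iterations, " iterations; ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  invisible(x)
}

#' Expand a block correlation matrix to full species dimension
#'
#' Embeds the m-by-m correlation matrix of the jointly modeled species at
#' the given indices of a p-by-p identity matrix: all other species are
#' modeled as independent (zero off-diagonals, unit diagonal).
#'
#' @param sigma_m m-by-m correlation matrix.
#' @param idx Distinct species indices in `1..p`.
#' @param p Total number of species.
#' @return p-by-p correlation matrix.
#' @export
expand_correlation <- function(sigma_m, idx, p) {
  idx <- as.integer(idx)
  if (anyDuplicated(idx) || any(idx < 1) || any(idx > p))
    stop("'idx' must be distinct indices within 1..p", call. = FALSE)
  if (length(idx) != NROW(sigma_m))
    stop("'idx' length must match dim(sigma_m)", call. = FALSE)
  S <- diag(p)
  if (length(idx)) S[idx, idx] <- as.matrix(sigma_m)
  S
}

#' Per-group copula model
#'
#' Bundles one group's p marginal distributions with its p-by-p copula
#' correlation matrix (typically built with [expand_correlation()] from
#' the jointly estimated block).
#'
#' @param marginals List of p [count_marginal()] objects.
#' @param sigma p-by-p correlation matrix (symmetric, unit diagonal,
#'   positive semi-definite).
#' @param assoc_index Indices of the species whose correlations were
#'   estimated jointly (optional bookkeeping).
#' @param group Group label.
#' @param n Group sample size.
#' @return Object of class `group_copula_model`.
#' @export
group_copula_model <- function(marginals, sigma, assoc_index = integer(0),
                               group = NA_character_, n = NA_integer_) {
  p <- length(marginals)
  sigma <- as.matrix(sigma)
  stopifnot(nrow(sigma) == p, ncol(sigma) == p)
  if (max(abs(sigma - t(sigma))) > 1e-8) stop("'sigma' must be symmetric", call. = FALSE)
  if (max(abs(diag(sigma) - 1)) > 1e-8) stop("'sigma' must have unit diagonal", call. = FALSE)
  if (min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    stop("'sigma' must be positive semi-definite", call. = FALSE)
  structure(list(marginals = marginals, sigma = sigma,
                 assoc_index = as.integer(assoc_index), group = group, n = n),
            class = "group_copula_model")
}

#' Community model: one copula model per group
#'
#' @param groups Named list of [group_copula_model()] objects sharing the
#'   same species dimension and ordering.
#' @param sizes Integer vector of group sample sizes (n_1..n_g).
#' @param species Character vector of species names.
#' @return Object of class `community_model`.
#' @export
community_model <- function(groups, sizes, species = NULL) {
  ps <- vapply(groups, function(g) length(g$marginals), integer(1))
  if (length(unique(ps)) != 1)
    stop("all groups must share the same species dimension", call. = FALSE)
  if (length(sizes) != length(groups))
    stop("one size per group required", call. = FALSE)
  if (is.null(species)) species <- paste0("sp", seq_len(ps[1]))
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  structure(list(groups = groups, sizes = as.integer(sizes), species = species),
            class = "community_model")
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> ", length(x$species), " species, ",
      length(x$groups), " group(s), sizes ",
      paste(x$sizes, collapse = "/"), "\n", sep = "")
  invisible(x)
}

#' Simulate a community count matrix from a copula model
#'
#' Each sampling unit draws a latent vector `z ~ MVN(0, sigma)`, maps it
#' through the standard normal cdf to copula space, and inverts each
#' species' marginal cdf: `y_j = marginal_quantile(m_j, pnorm(z_j))`.
#' Degenerate (point-mass-at-zero) species are emitted as constant 0.
#'
#' @param model A [group_copula_model()].
#' @param n Number of sampling units to draw.
#' @param seed Optional integer seed.
#' @return n-by-p integer matrix.
#' @export
simulate_counts <- function(model, n, seed = NULL) {
  stopifnot(inherits(model, "group_copula_model"))
  if (!is.null(seed)) set.seed(seed)
  p <- length(model$marginals)
  R <- tryCatch(chol(model$sigma),
                error = function(e) chol(model$sigma + 1e-10 * diag(p)))
  Z <- matrix(stats::rnorm(n * p), n, p) %*% R
  U <- stats::pnorm(Z)
  Y <- matrix(0L, n, p)
  for (j in seq_len(p))
    Y[, j] <- marginal_quantile(model$marginals[[j]], U[, j])
  colnames(Y) <- names(model$marginals)
  Y
}

## Bivariate copula simulation for the rho -> I curve; |rho| = 1 allowed.
.sim_bivariate <- function(mk, ml, rho, n) {
  z1 <- stats::rnorm(n)
  z2 <- if (abs(rho) >= 1) sign(rho) * z1
        else rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  cbind(marginal_quantile(mk, stats::pnorm(z1)),
        marginal_quantile(ml, stats::pnorm(z2)))
}

#' Map copula correlation to the index of association by simulation
#'
#' For each value of `rho`, `n_reps` datasets of `n_per_dataset`
#' bivariate counts are simulated from the Gaussian copula with the two
#' given marginals; the index of association is computed per dataset and
#' its mean and empirical 0.025/0.975 quantiles are returned. The curve
#' is smooth and monotone in `rho`, which makes it usable (with
#' [rho_for_index()]) to choose a `rho` that targets a desired index.
#'
#' Replicates in which a simulated species is entirely absent (possible
#' for small `n_per_dataset`) are resampled; the count is recorded in the
#' `resampled` column.
#'
#' @param mk,ml [count_marginal()] objects for the two species.
#' @param rho_grid Values in `[-1, 1]`.
#' @param n_per_dataset Observations per simulated dataset.
#' @param n_reps Replicate datasets per `rho` (>= 2).
#' @param seed Optional integer seed.
#' @return Data frame: `rho`, `mean_I`, `q025`, `q975`, `resampled`.
#' @export
rho_to_I_curve <- function(mk, ml, rho_grid = seq(-1, 1, by = 0.02),
                           n_per_dataset = 5000, n_reps = 100, seed = NULL) {
  if (n_reps < 2) stop("'n_reps' must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(rho_grid, function(rho) {
    I <- numeric(n_reps)
    resampled <- 0L
    for (r in seq_len(n_reps)) {
      repeat {
        Y <- .sim_bivariate(mk, ml, rho, n_per_dataset)
        if (all(colSums(Y) > 0)) break
        resampled <- resampled + 1L
      }
      I[r] <- index_of_association(Y[, 1], Y[, 2])
    }
    data.frame(rho = rho, mean_I = mean(I),
               q025 = unname(stats::quantile(I, 0.025)),
               q975 = unname(stats::quantile(I, 0.975)),
               resampled = resampled)
  })
  do.call(rbind, res)
}

#' Invert the rho-to-I curve for a target index value
#'
#' Linear interpolation on the precomputed monotone mean curve.
#'
#' @param curve Output of [rho_to_I_curve()].
#' @param target Desired index of association.
#' @return The interpolated `rho`.
#' @export
rho_for_index <- function(curve, target) {
  if (target < min(curve$mean_I) || target > max(curve$mean_I))
    stop("target index outside the range of the curve", call. = FALSE)
  stats::approx(curve$mean_I, curve$rho, xout = target, ties = mean)$y
}

#' Fit marginals, screen associations and estimate the copula per group
#'
#' Convenience wrapper running the model-building pathway: (i) select a
#' marginal family per species and group by AICc, (ii) screen species
#' pairs for significant associations, (iii) estimate the copula
#' correlation block for the associated species by MCEM and expand it to
#' the full species set (independence elsewhere). Rare and degenerate
#' species are never dropped from the model: they are carried as
#' independent marginals.
#'
#' @param Y Sample-by-species count matrix.
#' @param groups Factor of group labels (one per row); `NULL` fits a
#'   single pooled model.
#' @param families Candidate marginal families.
#' @param screen Run the association screen (step ii)? If `FALSE`, all
#'   non-degenerate species enter the copula jointly.
#' @param error_rate,method,n_perm,exclude_rare,min_prevalence Screening
#'   settings, see [screen_associations()].
#' @param settings [mcem_settings()] for the copula fit.
#' @param aicc_scope See [fit_marginals()].
#' @param seed Optional master seed.
#' @return A [community_model()]; each group model carries its
#'   `association_screen` (attribute `screen`) and `mcem_fit`
#'   (attribute `fit`).
#' @export
fit_community_model <- function(Y, groups = NULL, families = .family_order,
                                screen = TRUE, error_rate = 0.01,
                                method = "PCER", n_perm = 999,
                                exclude_rare = FALSE, min_prevalence = 0.05,
                                settings = mcem_settings(),
                                aicc_scope = "group", seed = NULL) {
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("sp", seq_len(ncol(Y)))
  if (is.null(groups)) groups <- factor(rep("all", nrow(Y)))
  groups <- as.factor(groups)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 2)
  fits <- fit_marginals(Y, groups, families, aicc_scope)
  screens <- if (screen)
    screen_associations(Y, groups, error_rate, method, n_perm, seed = seeds[1],
                        exclude_rare = exclude_rare,
                        min_prevalence = min_prevalence)
  set.seed(seeds[2])
  mcem_seeds <- sample.int(.Machine$integer.max, nlevels(groups))
  p <- ncol(Y)
  gms <- lapply(seq_along(levels(groups)), function(gi) {
    g <- levels(groups)[gi]
    Yg <- Y[groups == g, , drop = FALSE]
    marg <- lapply(fits[[g]], `[[`, "marginal")
    nondeg <- which(!vapply(marg, is_degenerate, logical(1)) & colSums(Yg) > 0)
    idx <- if (screen) intersect(associated_species(screens[[g]]), nondeg)
           else nondeg
    fit <- NULL
    sigma <- diag(p)
    if (length(idx) >= 2) {
      st <- settings; st$seed <- mcem_seeds[gi]
      fit <- mcem_fit(Yg[, idx, drop = FALSE], marg[idx], st)
      sigma <- expand_correlation(fit$sigma, idx, p)
    }
    gm <- group_copula_model(marg, sigma, assoc_index = idx, group = g,
                             n = nrow(Yg))
    attr(gm, "screen") <- if (screen) screens[[g]]
    attr(gm, "fit") <- fit
    gm
  })
  names(gms) <- levels(groups)
  community_model(gms, sizes = as.integer(table(groups)),
                  species = colnames(Y))
}
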
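#' Discrete marginal distributions for species counts
#'
#' A `count_marginal` describes the univariate distribution of one species'
#' counts. Four families are supported: Poisson, zero-inflated Poisson
#' (ZIP), negative binomial (NB) and zero-inflated negative binomial
#' (ZINB), plus a degenerate `"zero"` family (point mass at 0) used as a
#' sentinel for species never observed in a group.
#'
#' The NB is parameterized by its mean `mu` and dispersion `theta`
#' (variance `mu + mu^2/theta`); `pi` is the structural-zero mixture
#' weight of the zero-inflated families, so e.g. the ZINB pmf is
#' `pi * 1(y == 0) + (1 - pi) * dnbinom(y, mu, theta)`.
#'
#' @param family One of `"poisson"`, `"zip"`, `"nb"`, `"zinb"`, `"zero"`.
#' @param mu Mean of the count component (> 0; ignored for `"zero"`).
#' @param theta NB dispersion (> 0; required for `"nb"`/`"zinb"`).
#' @param pi Structural-zero probability in `[0, 1)` (required for
#'   `"zip"`/`"zinb"`).
#' @return An object of class `count_marginal`.
#' @examples
#' m <- count_marginal("nb", mu = 2.714, theta = 1.635)
#' marginal_quantile(m, 0.75)
#' @export
count_marginal <- function(family = c("poisson", "zip", "nb", "zinb", "zero"),
                           mu = NULL, theta = NULL, pi = NULL) {
  family <- match.arg(family)
  if (family == "zero") {
    m <- structure(list(family = "zero", mu = 0, theta = NULL, pi = NULL),
                   class = "count_marginal")
    return(m)
  }
  if (is.null(mu) || !is.finite(mu) || mu <= 0)
    stop("'mu' must be a positive finite number", call. = FALSE)
  if (family %in% c("nb", "zinb")) {
    if (is.null(theta) || !is.finite(theta) || theta <= 0)
      stop("'theta' must be a positive finite number for NB-type families",
           call. = FALSE)
  } else theta <- NULL
  if (family %in% c("zip", "zinb")) {
    if (is.null(pi) || !is.finite(pi) || pi < 0 || pi >= 1)
      stop("'pi' must lie in [0, 1)", call. = FALSE)
  } else pi <- NULL
  structure(list(family = family, mu = mu, theta = theta, pi = pi),
            class = "count_marginal")
}

#' @export
print.count_marginal <- function(x, ...) {
  pars <- c(mu = x$mu, theta = x$theta, pi = x$pi)
  cat("<count_marginal> ", x$family,
      if (length(pars)) paste0(" (", paste(names(pars), signif(pars, 4),
                                           sep = " = ", collapse = ", "), ")"),
      "\n", sep = "")
  invisible(x)
}

is_degenerate <- function(m) m$family == "zero"

## pmf of the count component (no zero inflation)
base_pmf <- function(m, y, log = FALSE) {
  switch(m$family,
         poisson = , zip = stats::dpois(y, m$mu, log = log),
         nb = , zinb = stats::dnbinom(y, mu = m$mu, size = m$theta, log = log),
         zero = stop("degenerate marginal has no count component"))
}

base_cdf <- function(m, y) {
  switch(m$family,
         poisson = , zip = stats::ppois(y, m$mu),
         nb = , zinb = stats::pnbinom(y, mu = m$mu, size = m$theta),
         zero = stop("degenerate marginal has no count component"))
}

base_quantile <- function(m, q) {
  switch(m$family,
         poisson = , zip = stats::qpois(q, m$mu),
         nb = , zinb = stats::qnbinom(q, mu = m$mu, size = m$theta),
         zero = stop("degenerate marginal has no count component"))
}

#' Probability mass function of a count marginal
#'
#' @param m A [count_marginal()].
#' @param y Integer vector of counts.
#' @param log Return log-probabilities?
#' @return Numeric vector of probabilities.
#' @export
marginal_pmf <- function(m, y, log = FALSE) {
  stopifnot(inherits(m, "count_marginal"))
  if (is_degenerate(m)) {
    p <- as.numeric(y == 0)
    return(if (log) base::log(p) else p)
  }
  p <- base_pmf(m, y)
  if (!is.null(m$pi)) p <- m$pi * (y == 0) + (1 - m$pi) * p
  p[y < 0 | y != floor(y)] <- 0
  if (log) base::log(p) else p
}

#' Cumulative distribution function of a count marginal
#'
#' `F(-1)` is defined as 0 (the empty lower tail), which the latent-bound
#' construction of the Gaussian copula relies on. For zero-inflated
#' families `F(y) = pi + (1 - pi) * F_base(y)` for `y >= 0`.
#'
#' @inheritParams marginal_pmf
#' @param y Integer vector, each `>= -1`.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
marginal_cdf <- function(m, y) {
  stopifnot(inherits(m, "count_marginal"))
  if (any(y < -1)) stop("'y' must be >= -1", call. = FALSE)
  if (is_degenerate(m)) return(as.numeric(y >= 0))
  p <- numeric(length(y))
  pos <- y >= 0
  if (any(pos)) {
    pb <- base_cdf(m, floor(y[pos]))
    p[pos] <- if (is.null(m$pi)) pb else m$pi + (1 - m$pi) * pb
  }
  p
}

#' Quantile function of a count marginal
#'
#' Returns the smallest integer `y >= 0` with `F(y) >= q`. To keep the
#' copula inverse map finite, `q` is clamped so that `q = 1` (or any `q`
#' within 1e-12 of 1) returns the smallest `y` with `1 - F(y) < 1e-12`.
#'
#' @inheritParams marginal_pmf
#' @param q Probabilities in `[0, 1]`.
#' @return Integer vector of counts.
#' @export
marginal_quantile <- function(m, q) {
  stopifnot(inherits(m, "count_marginal"))
  if (any(q < 0 | q > 1)) stop("'q' must lie in [0, 1]", call. = FALSE)
  if (is_degenerate(m)) return(rep(0L, length(q)))
  q <- pmin(q, 1 - 1e-12)
  if (is.null(m$pi)) qb <- q
  else qb <- pmax(0, (q - m$pi) / (1 - m$pi))
  as.integer(base_quantile(m, qb))
}

n_par <- function(family) {
  switch(family, poisson = 1L, zip = 2L, nb = 2L, zinb = 3L, zero = 0L)
}

aicc <- function(loglik, k, n) {
  if (n <= k + 1) return(NA_real_)
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))

zi_negll <- function(counts, nb = TRUE) {
  is0 <- counts == 0
  function(par) {
    mu <- exp(par[1])
    if (nb) { theta <- exp(par[2]); pi <- inv_logit(par[3]) }
    else pi <- inv_logit(par[2])
    if (!is.finite(mu) || mu > 1e8) return(1e10)
    lp <- if (nb) stats::dnbinom(counts, mu = mu, size = theta, log = TRUE)
          else stats::dpois(counts, mu, log = TRUE)
    ll <- sum(ifelse(is0, log(pi + (1 - pi) * exp(lp)), log1p(-pi) + lp))
    if (!is.finite(ll)) 1e10 else -ll
  }
}

#' Fit a count marginal by maximum likelihood
#'
#' The Poisson MLE is closed form; NB uses quasi-Newton optimization on
#' the log scale; the zero-inflated families maximize the mixture
#' log-likelihood numerically with multiple starting values of `pi`
#' (0.01, 0.25, 0.5) to avoid boundary local optima. A vector of all
#' zeros yields the degenerate point-mass-at-zero sentinel (flagged via
#' `degenerate = TRUE`) rather than an MLE.
#'
#' @param counts Non-negative integer vector, length >= 2.
#' @param family One of `"poisson"`, `"zip"`, `"nb"`, `"zinb"`.
#' @return A `fitted_marginal`: list with elements `marginal`
#'   ([count_marginal()]), `loglik`, `aicc`, `n`, `k`, `converged`,
#'   `degenerate`.
#' @export
fit_marginal <- function(counts, family = c("poisson", "zip", "nb", "zinb")) {
  family <- match.arg(family)
  if (length(counts) < 2) stop("need at least 2 observations", call. = FALSE)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("'counts' must be non-negative integers", call. = FALSE)
  n <- length(counts)
  if (all(counts == 0)) {
    return(structure(list(marginal = count_marginal("zero"), loglik = 0,
                          aicc = NA_real_, n = n, k = 0L, converged = TRUE,
                          degenerate = TRUE, family = "zero"),
                     class = "fitted_marginal"))
  }
  ybar <- mean(counts)
  v <- stats::var(counts)
  theta0 <- ybar^2 / max(v - ybar, ybar / 10)
  fit <- switch(family,
    poisson = {
      ll <- sum(stats::dpois(counts, ybar, log = TRUE))
      list(m = count_marginal("poisson", mu = ybar), ll = ll, conv = TRUE)
    },
    nb = {
      negll <- function(par) {
        ll <- sum(stats::dnbinom(counts, mu = exp(par[1]),
                                 size = exp(par[2]), log = TRUE))
        if (!is.finite(ll)) 1e10 else -ll
      }
      o <- stats::optim(c(log(ybar), log(theta0)), negll, method = "BFGS")
      list(m = count_marginal("nb", mu = exp(o$par[1]), theta = exp(o$par[2])),
           ll = -o$value, conv = o$convergence == 0)
    },
    zip = {
      f <- zi_negll(counts, nb = FALSE)
      best <- NULL
      for (pi0 in c(0.01, 0.25, 0.5)) {
        o <- try(stats::optim(c(log(ybar / (1 - pi0)), logit(pi0)), f,
                              method = "BFGS"), silent = TRUE)
        if (!inherits(o, "try-error") &&
            (is.null(best) || o$value < best$value)) best <- o
      }
      list(m = count_marginal("zip", mu = exp(best$par[1]),
                              pi = inv_logit(best$par[2])),
           ll = -best$value, conv = best$convergence == 0)
    },
    zinb = {
      f <- zi_negll(counts, nb = TRUE)
      best <- NULL
      for (pi0 in c(0.01, 0.25, 0.5)) {
        o <- try(stats::optim(c(log(ybar / (1 - pi0)), log(theta0), logit(pi0)),
                              f, method = "BFGS"), silent = TRUE)
        if (!inherits(o, "try-error") &&
            (is.null(best) || o$value < best$value)) best <- o
      }
      list(m = count_marginal("zinb", mu = exp(best$par[1]),
                              theta = exp(best$par[2]),
                              pi = inv_logit(best$par[3])),
           ll = -best$value, conv = best$convergence == 0)
    })
  k <- n_par(family)
  structure(list(marginal = fit$m, loglik = fit$ll, aicc = aicc(fit$ll, k, n),
                 n = n, k = k, converged = fit$conv, degenerate = FALSE,
                 family = family),
            class = "fitted_marginal")
}

#' @export
print.fitted_marginal <- function(x, ...) {
  cat("<fitted_marginal> ", x$family, ": loglik = ", signif(x$loglik, 6),
      ", AICc = ", signif(x$aicc, 6), ", n = ", x$n, "\n", sep = "")
  print(x$marginal)
  invisible(x)
}

.family_order <- c("poisson", "zip", "nb", "zinb")

#' Select a marginal family by AICc
#'
#' Fits every candidate family and returns the one with minimal corrected
#' AIC. Candidates with `n <= k + 1` (non-positive AICc denominator) are
#' excluded with a warning. Ties are broken by fewest parameters, then by
#' the fixed order Poisson < ZIP < NB < ZINB.
#'
#' @inheritParams fit_marginal
#' @param families Character vector of candidate families.
#' @return The winning `fitted_marginal`; its `candidates` attribute holds
#'   all fits.
#' @export
select_marginal <- function(counts, families = .family_order) {
  families <- match.arg(families, .family_order, several.ok = TRUE)
  if (all(counts == 0)) return(fit_marginal(counts, families[1]))
  n <- length(counts)
  keep <- vapply(families, function(f) n > n_par(f) + 1, logical(1))
  if (any(!keep))
    warning("excluding candidate(s) with n <= k + 1: ",
            paste(families[!keep], collapse = ", "), call. = FALSE)
  families <- families[keep]
  if (!length(families)) stop("no admissible candidate families", call. = FALSE)
  fits <- lapply(families, function(f)
    tryCatch(fit_marginal(counts, f), error = function(e) NULL))
  ok <- !vapply(fits, is.null, logical(1))
  ok[ok] <- vapply(fits[ok], function(f) is.finite(f$aicc), logical(1))
  if (!any(ok))
    stop("no candidate family converged for these counts (tried: ",
         paste(families, collapse = ", "), ")", call. = FALSE)
  fits <- fits[ok]
  a <- vapply(fits, `[[`, numeric(1), "aicc")
  k <- vapply(fits, `[[`, integer(1), "k")
  fam <- vapply(fits, `[[`, character(1), "family")
  best <- order(a, k, match(fam, .family_order))[1]
  out <- fits[[best]]
  attr(out, "candidates") <- fits
  out
}

#' Flag rare species
#'
#' A species is rare if it occurs in at most one sampling unit (a
#' singleton) or in strictly fewer than `min_prevalence` of the units.
#' Rare species are typically excluded from association screening but are
#' retained (as independent) in the community model.
#'
#' @param Y Sample-by-species count matrix or data frame.
#' @param min_prevalence Prevalence threshold in (0, 1); default 0.05.
#' @return Named logical vector, one entry per species.
#' @export
flag_rare <- function(Y, min_prevalence = 0.05) {
  if (min_prevalence <= 0 || min_prevalence >= 1)
    stop("'min_prevalence' must lie in (0, 1)", call. = FALSE)
  Y <- as.matrix(Y)
  occ <- colSums(Y > 0)
  stats::setNames(occ <= 1 | occ / nrow(Y) < min_prevalence, colnames(Y))
}

#' Fit marginals for every species, optionally per group
#'
#' @param Y Sample-by-species count matrix.
#' @param groups Factor of group labels (one per row), or `NULL` for a
#'   single pooled fit.
#' @param families Candidate families passed to [select_marginal()].
#' @param aicc_scope `"group"` selects the family on each group's own
#'   counts; `"pooled"` selects the family once on the pooled counts, then
#'   refits its parameters per group.
#' @return A data-frame-like list of `fitted_marginal` objects indexed
#'   `[[group]][[species]]`.
#' @export
fit_marginals <- function(Y, groups = NULL, families = .family_order,
                          aicc_scope = c("group", "pooled")) {
  aicc_scope <- match.arg(aicc_scope)
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("sp", seq_len(ncol(Y)))
  if (is.null(groups)) groups <- factor(rep("all", nrow(Y)))
  groups <- as.factor(groups)
  pooled_fam <- if (aicc_scope == "pooled")
    vapply(seq_len(ncol(Y)), function(j) select_marginal(Y[, j], families)$family,
           character(1))
  out <- lapply(levels(groups), function(g) {
    Yg <- Y[groups == g, , drop = FALSE]
    fits <- lapply(seq_len(ncol(Y)), function(j) {
      if (aicc_scope == "pooled" && pooled_fam[j] != "zero" &&
          any(Yg[, j] > 0))
        fit_marginal(Yg[, j], pooled_fam[j])
      else select_marginal(Yg[, j], families)
    })
    names(fits) <- colnames(Y)
    fits
  })
  names(out) <- levels(groups)
  out
}

#' Tabulate fitted marginals as a data frame
#'
#' @param fits Output of [fit_marginals()].
#' @return Data frame with columns species, group, family, mu, theta, pi,
#'   loglik, aicc.
#' @export
marginals_report <- function(fits) {
  do.call(rbind, lapply(names(fits), function(g) {
    do.call(rbind, lapply(names(fits[[g]]), function(sp) {
      f <- fits[[g]][[sp]]
      m <- f$marginal
      data.frame(species = sp, group = g, family = f$family,
                 mu = m$mu, theta = if (is.null(m$theta)) NA_real_ else m$theta,
                 pi = if (is.null(m$pi)) NA_real_ else m$pi,
                 loglik = f$loglik, aicc = f$aicc,
                 converged = f$converged, stringsAsFactors = FALSE)
    }))
  }))
}
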
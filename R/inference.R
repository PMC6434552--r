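## one-way PERMANOVA pseudo-F from a matrix of squared dissimilarities.
## SS_total = (1/N) sum_{i<j} d2_ij ; SS_within = sum_g (1/n_g) sum_{i<j in g} d2
pseudo_F_stat <- function(D2, gidx, g, N) {
  ssw <- 0
  for (idx in gidx) ssw <- ssw + sum(D2[idx, idx]) / (2 * length(idx))
  sst <- sum(D2) / (2 * N)
  ssa <- sst - ssw
  if (sst <= 0) return(0)
  if (ssw <= 0) return(Inf)
  (ssa / (g - 1)) / (ssw / (N - g))
}

new_test_result <- function(statistic, p_permutation = NA_real_,
                            p_model_based = NA_real_, n_perm = NA_integer_,
                            n_sim = NA_integer_, null_distribution = NULL,
                            method = "test", extra = list()) {
  structure(c(list(statistic = statistic, p_permutation = p_permutation,
                   p_model_based = p_model_based, n_perm = n_perm,
                   n_sim = n_sim, null_distribution = null_distribution,
                   method = method), extra),
            class = "cc_test_result")
}

#' @export
print.cc_test_result <- function(x, ...) {
  cat("<", x$method, "> statistic = ", signif(x$statistic, 6), sep = "")
  if (is.finite(x$p_permutation))
    cat(", permutation p = ", format(x$p_permutation), " (", x$n_perm,
        " permutations)", sep = "")
  if (is.finite(x$p_model_based))
    cat(", model-based p = ", format(x$p_model_based), " (", x$n_sim,
        " simulations)", sep = "")
  cat("\n")
  invisible(x)
}

#' PERMANOVA: one-way pseudo-F test on a dissimilarity matrix
#'
#' The pseudo-F ratio is computed from sums of squared inter-point
#' dissimilarities, `F = (SS_among / (g - 1)) / (SS_within / (N - g))`,
#' and tested by random permutation of the group labels. For univariate
#' data under Euclidean distance it coincides exactly with the classical
#' one-way ANOVA F. The p-value follows the `(b + 1)/(B + 1)` convention.
#'
#' @param D A [dissimilarity_matrix()], `dist` or square matrix.
#' @param groups Factor of group labels (>= 2 levels, `N > g`).
#' @param n_perm Number of label permutations.
#' @param seed Optional integer seed.
#' @return A `cc_test_result` with the permutation null distribution.
#' @export
permanova <- function(D, groups, n_perm = 999, seed = NULL) {
  D2 <- as.matrix(D)^2
  groups <- as.factor(groups)
  N <- nrow(D2)
  g <- nlevels(groups)
  if (g < 2) stop("need at least 2 groups", call. = FALSE)
  if (N <= g) stop("need N > g", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  gi <- as.integer(groups)
  F_obs <- pseudo_F_stat(D2, split(seq_len(N), gi), g, N)
  F_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pg <- sample(gi)
    F_perm[b] <- pseudo_F_stat(D2, split(seq_len(N), pg), g, N)
  }
  p <- (sum(F_perm >= F_obs) + 1) / (n_perm + 1)
  new_test_result(F_obs, p_permutation = p, n_perm = n_perm,
                  null_distribution = F_perm, method = "PERMANOVA")
}

#' Model-based null distribution of the pseudo-F statistic
#'
#' Simulates datasets under the null hypothesis that every sampling unit
#' has an equal probability `1/g` of arising from any group's fitted
#' copula model (or probability `n_i / N` with `prob = "size"`), keeping
#' the nominal group sizes fixed. The pseudo-F statistic is recomputed
#' for each simulated dataset on the same dissimilarity recipe; the
#' model-based p-value is the `(b + 1)/(n_sim + 1)` proportion of null
#' statistics that equal or exceed the observed one.
#'
#' @param Y Observed count matrix.
#' @param groups Factor of group labels.
#' @param model A [community_model()] with one fitted model per group.
#' @param n_sim Number of simulated null datasets.
#' @param measure,transform Dissimilarity recipe, see [dissim()].
#' @param prob `"equal"` (1/g) or `"size"` (n_i/N) multinomial draw
#'   probabilities.
#' @param seed Optional integer seed.
#' @return A `cc_test_result` with the model-based null distribution.
#' @export
model_based_null <- function(Y, groups, model, n_sim = 999, measure = "bray",
                             transform = "sqrt", prob = c("equal", "size"),
                             seed = NULL) {
  prob <- match.arg(prob)
  Y <- as.matrix(Y)
  groups <- as.factor(groups)
  stopifnot(inherits(model, "community_model"))
  if (!is.null(seed)) set.seed(seed)
  g <- nlevels(groups)
  N <- nrow(Y)
  pr <- if (prob == "equal") rep(1 / g, g) else as.numeric(table(groups)) / N
  D <- dissim(Y, measure, transform)
  gidx <- split(seq_len(N), groups)
  F_obs <- pseudo_F_stat(unclass(D)^2, gidx, g, N)
  F_null <- numeric(n_sim)
  for (b in seq_len(n_sim)) {
    gen <- sample.int(g, N, replace = TRUE, prob = pr)
    Ys <- matrix(0L, N, ncol(Y))
    for (gi in unique(gen)) {
      rows <- which(gen == gi)
      Ys[rows, ] <- simulate_counts(model$groups[[gi]], length(rows))
    }
    Ds2 <- unclass(dissim(Ys, measure, transform))^2
    F_null[b] <- pseudo_F_stat(Ds2, gidx, g, N)
  }
  p <- (sum(F_null >= F_obs) + 1) / (n_sim + 1)
  new_test_result(F_obs, p_model_based = p, n_sim = n_sim,
                  null_distribution = F_null, method = "PERMANOVA (model-based null)")
}

## canonical correlations between m PCoA axes and the group indicator
.cap_stat <- function(Q, groups) {
  G <- stats::model.matrix(~groups)[, -1, drop = FALSE]
  cc <- stats::cancor(Q, G)
  list(trace = sum(cc$cor^2), first = cc$cor[1]^2)
}

## trace statistic plus its permutation distribution. The trace of squared
## canonical correlations equals ||Ux' Ug||_F^2 for orthonormal bases of the
## centered column spaces, and permuting group labels permutes Ug's rows, so
## the bases are computed once.
.cap_null_stats <- function(Q, groups, n_perm) {
  N <- nrow(Q)
  Ux <- qr.Q(qr(scale(Q, center = TRUE, scale = FALSE)))
  G <- stats::model.matrix(~groups)[, -1, drop = FALSE]
  Ug <- qr.Q(qr(scale(G, center = TRUE, scale = FALSE)))
  obs <- sum(crossprod(Ux, Ug)^2)
  perm <- vapply(seq_len(n_perm), function(b)
    sum(crossprod(Ux, Ug[sample.int(N), , drop = FALSE])^2), numeric(1))
  list(obs = obs, perm = perm)
}

.cap_loo <- function(Q, groups) {
  N <- nrow(Q)
  correct <- 0L
  for (i in seq_len(N)) {
    fit <- try(suppressWarnings(
      MASS::lda(Q[-i, , drop = FALSE], grouping = droplevels(groups[-i]))),
      silent = TRUE)
    if (inherits(fit, "try-error")) next
    pred <- stats::predict(fit, Q[i, , drop = FALSE])$class
    if (as.character(pred) == as.character(groups[i])) correct <- correct + 1L
  }
  correct / N
}

#' Canonical analysis of principal coordinates (CAP)
#'
#' PCoA of the dissimilarity matrix (positive-eigenvalue axes only),
#' followed by canonical discriminant analysis of the first `m_axes`
#' coordinates against the group labels. The test statistic is the trace
#' of squared canonical correlations (the squared first canonical
#' correlation is also reported), tested by permutation of the labels.
#' Leave-one-out allocation success refits the discriminant without each
#' unit (on the fixed PCoA axes) and classifies it to the nearest group
#' centroid in the canonical space. When `m_axes` is `NULL` it is chosen
#' to maximize leave-one-out allocation success.
#'
#' @param D A [dissimilarity_matrix()] or square matrix.
#' @param groups Factor of group labels.
#' @param m_axes Number of principal coordinate axes, `1 <= m_axes < N`
#'   and at most the number of positive eigenvalues; `NULL` to choose
#'   automatically.
#' @param n_perm Number of label permutations.
#' @param seed Optional integer seed.
#' @return A `cc_test_result` with extras `allocation_success`, `m_axes`,
#'   `first_sq_canonical`.
#' @export
cap <- function(D, groups, m_axes = NULL, n_perm = 999, seed = NULL) {
  groups <- as.factor(groups)
  Dm <- as.matrix(D)
  N <- nrow(Dm)
  if (!is.null(seed)) set.seed(seed)
  pc <- pcoa(Dm)
  K <- ncol(pc$points)
  K_max <- min(K, N - nlevels(groups) - 1)
  if (!is.null(m_axes)) {
    if (m_axes < 1 || m_axes >= N || m_axes > K)
      stop("'m_axes' must satisfy 1 <= m_axes <= number of positive axes (",
           K, ") and < N", call. = FALSE)
  } else {
    succ <- vapply(seq_len(K_max), function(m)
      .cap_loo(pc$points[, seq_len(m), drop = FALSE], groups), numeric(1))
    m_axes <- which.max(succ)           # ties -> fewest axes
  }
  Q <- pc$points[, seq_len(m_axes), drop = FALSE]
  st <- .cap_stat(Q, groups)
  loo <- .cap_loo(Q, groups)
  ns <- .cap_null_stats(Q, groups, n_perm)
  p <- (sum(ns$perm >= ns$obs) + 1) / (n_perm + 1)
  new_test_result(st$trace, p_permutation = p, n_perm = n_perm,
                  null_distribution = ns$perm, method = "CAP",
                  extra = list(allocation_success = loo, m_axes = m_axes,
                               first_sq_canonical = st$first))
}

#' Multinomial mixture schedule between null and alternative
#'
#' The continuum between the null and alternative hypotheses is modeled
#' as a sliding scale of mixture probabilities
#' `P_k = (1 - f_k) P0 + f_k PA`, where `P0[i, j]` is the probability
#' that a unit in nominal group `i` is generated from group `j`'s model
#' under the null (default: `1/g` everywhere) and `PA` under the
#' alternative (default: identity). `f` runs from 0 (null) to 1
#' (alternative) in `n_steps` equal steps.
#'
#' @param g Number of groups.
#' @param n_steps Number of steps (>= 2).
#' @param P0,PA g-by-g row-stochastic matrices (defaults as above).
#' @return Object of class `mixture_schedule` with elements `P0`, `PA`,
#'   `f`.
#' @export
mixture_schedule <- function(g, n_steps = 20, P0 = NULL, PA = NULL) {
  if (is.null(P0)) P0 <- matrix(1 / g, g, g)
  if (is.null(PA)) PA <- diag(g)
  stopifnot(nrow(P0) == g, ncol(P0) == g, nrow(PA) == g, ncol(PA) == g)
  if (max(abs(rowSums(P0) - 1)) > 1e-8 || max(abs(rowSums(PA) - 1)) > 1e-8)
    stop("rows of P0 and PA must sum to 1", call. = FALSE)
  if (n_steps < 2) stop("'n_steps' must be >= 2", call. = FALSE)
  structure(list(P0 = P0, PA = PA, f = seq(0, 1, length.out = n_steps)),
            class = "mixture_schedule")
}

#' Empirical power along a null-to-alternative mixture continuum
#'
#' At each step `k`, `n_sims_per_step` datasets are generated: every
#' sampling unit in nominal group `i` draws its generating group `j` with
#' probability `P_k[i, j]` and its count vector from group `j`'s copula
#' model (the group sizes follow the nominal design). Each dataset is
#' tested (PERMANOVA pseudo-F or the CAP trace statistic, with `n_perm`
#' permutations), and power is the fraction of p-values at or below
#' `alpha`. At `f = 0` this recovers the test's size.
#'
#' @param model A [community_model()].
#' @param schedule A [mixture_schedule()].
#' @param test `"permanova"` or `"cap"`.
#' @param n_sims_per_step Simulated datasets per step.
#' @param alpha Significance level.
#' @param n_perm Permutations per simulated test.
#' @param measure,transform Dissimilarity recipe.
#' @param m_axes PCoA axes for CAP (capped at availability per dataset).
#' @param species Optional species subset (indices or names) used in the
#'   simulated analysis.
#' @param seed Optional integer seed.
#' @return Data frame: `f`, `power`, `n_sims`, `se` (binomial standard
#'   error).
#' @export
power_curve <- function(model, schedule, test = c("permanova", "cap"),
                        n_sims_per_step = 1000, alpha = 0.05, n_perm = 999,
                        measure = "bray", transform = "sqrt", m_axes = 7,
                        species = NULL, seed = NULL) {
  test <- match.arg(test)
  stopifnot(inherits(model, "community_model"),
            inherits(schedule, "mixture_schedule"))
  if (n_sims_per_step < 1) stop("'n_sims_per_step' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- length(model$groups)
  sizes <- model$sizes
  nominal <- factor(rep(seq_len(g), sizes))
  N <- sum(sizes)
  if (is.character(species)) species <- match(species, model$species)
  out <- lapply(seq_along(schedule$f), function(k) {
    Pk <- (1 - schedule$f[k]) * schedule$P0 + schedule$f[k] * schedule$PA
    rej <- 0L
    for (s in seq_len(n_sims_per_step)) {
      gen <- integer(N)
      for (i in seq_len(g)) {
        rows <- which(as.integer(nominal) == i)
        gen[rows] <- sample.int(g, length(rows), replace = TRUE, prob = Pk[i, ])
      }
      Ys <- matrix(0L, N, length(model$species))
      for (j in unique(gen)) {
        rows <- which(gen == j)
        Ys[rows, ] <- simulate_counts(model$groups[[j]], length(rows))
      }
      if (!is.null(species)) Ys <- Ys[, species, drop = FALSE]
      D <- dissim(Ys, measure, transform)
      pval <- if (test == "permanova") {
        permanova(D, nominal, n_perm = n_perm)$p_permutation
      } else {
        pc <- pcoa(D)
        m <- min(m_axes, ncol(pc$points))
        Q <- pc$points[, seq_len(m), drop = FALSE]
        ns <- .cap_null_stats(Q, nominal, n_perm)
        (sum(ns$perm >= ns$obs) + 1) / (n_perm + 1)
      }
      if (pval <= alpha) rej <- rej + 1L
    }
    pw <- rej / n_sims_per_step
    data.frame(f = schedule$f[k], power = pw, n_sims = n_sims_per_step,
               se = sqrt(pw * (1 - pw) / n_sims_per_step))
  })
  do.call(rbind, out)
}
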
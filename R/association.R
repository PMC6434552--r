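#' Index of association between two species
#'
#' Similarity of the relative-abundance profiles of two species across
#' sampling units:
#' `I = 1 - 0.5 * sum_i | y_ik / sum(y_k) - y_il / sum(y_l) |`,
#' which lies in `[0, 1]` and excludes joint absences (a unit where both
#' species are absent contributes nothing to the sum). `I = 1` for
#' proportional profiles, `I = 0` for disjoint ones.
#'
#' @param yk,yl Count vectors of equal length (one entry per sampling
#'   unit); each must have a positive total.
#' @return The index value.
#' @examples
#' index_of_association(c(1, 1, 0), c(0, 2, 2))  # 0.5
#' @export
index_of_association <- function(yk, yl) {
  if (length(yk) != length(yl)) stop("vectors must have equal length", call. = FALSE)
  sk <- sum(yk); sl <- sum(yl)
  if (sk <= 0 || sl <= 0)
    stop("index of association is undefined for a species with zero total; ",
         "exclude it before screening", call. = FALSE)
  1 - 0.5 * sum(abs(yk / sk - yl / sl))
}

## I for one fixed normalized profile against many permuted profiles.
## pk: normalized vector; pl_perm: n x B matrix of permuted normalized values.
.index_perm <- function(pk, pl_perm) {
  1 - 0.5 * colSums(abs(pk - pl_perm))
}

#' Permutation test for the index of association
#'
#' One species' counts are randomly permuted across sampling units in
#' each iteration, which breaks any association while preserving both
#' marginal profiles. The two-tailed p-value uses the `(b + 1)/(B + 1)`
#' convention on each tail: `p = min(1, 2 * min(p_lower, p_upper))`.
#' Also returned are the empirical lower/upper bounds of the permutation
#' distribution at the requested two-tailed rate.
#'
#' If either column is constant across units the index is invariant under
#' permutation; `p = 1` is returned with a warning.
#'
#' @inheritParams index_of_association
#' @param n_perm Number of permutations (>= 1).
#' @param error_rate Two-tailed rate defining the reported bounds.
#' @param seed Optional integer seed.
#' @return List with `I`, `p_value`, `p_lower`, `p_upper`, `lower`,
#'   `upper`, `n_perm`.
#' @export
pair_permutation_test <- function(yk, yl, n_perm = 999, error_rate = 0.05,
                                  seed = NULL) {
  if (n_perm < 1) stop("'n_perm' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  I_obs <- index_of_association(yk, yl)
  n <- length(yk)
  if (length(unique(yk)) == 1L || length(unique(yl)) == 1L) {
    warning("constant column: index is invariant under permutation; p = 1",
            call. = FALSE)
    return(list(I = I_obs, p_value = 1, p_lower = 1, p_upper = 1,
                lower = I_obs, upper = I_obs, n_perm = n_perm))
  }
  pk <- yk / sum(yk)
  pl <- yl / sum(yl)
  perm_idx <- matrix(0L, n, n_perm)
  for (b in seq_len(n_perm)) perm_idx[, b] <- sample.int(n)
  I_perm <- .index_perm(pk, matrix(pl[perm_idx], n))
  p_lower <- (sum(I_perm <= I_obs) + 1) / (n_perm + 1)
  p_upper <- (sum(I_perm >= I_obs) + 1) / (n_perm + 1)
  srt <- sort(I_perm)
  k <- max(1L, ceiling(error_rate / 2 * (n_perm + 1)))
  list(I = I_obs, p_value = min(1, 2 * min(p_lower, p_upper)),
       p_lower = p_lower, p_upper = p_upper,
       lower = srt[k], upper = srt[n_perm + 1L - k], n_perm = n_perm)
}

## within-permutation two-tailed tail probabilities for one pair's
## permutation values (length B); used by the FWER max-statistic.
.perm_tailprob <- function(v) {
  B <- length(v)
  r_le <- rank(v, ties.method = "max") / B
  r_ge <- (B - rank(v, ties.method = "min") + 1) / B
  pmin(r_le, r_ge)
}

#' Screen species pairs for significant associations
#'
#' For each a priori group, every pair among the retained species is
#' tested by permutation of the index of association. Two multiplicity
#' regimes are available: `"PCER"` (per-comparison error rate) declares a
#' pair significant when its observed index falls outside its own
#' pair-specific two-tailed empirical permutation bounds at `error_rate`;
#' `"FWER"` controls the family-wise rate with a max-statistic (min-p)
#' construction: per permutation the most extreme two-tailed tail
#' probability across all pairs is recorded, and a pair is declared when
#' its observed tail probability beats the `error_rate` quantile of that
#' extreme-value distribution. The same row permutations are shared
#' across pairs.
#'
#' Species with an all-zero column in a group are always excluded there
#' (the index is undefined); rare species can additionally be excluded
#' via `exclude_rare`.
#'
#' @param Y Sample-by-species count matrix.
#' @param groups Factor of group labels, one per row.
#' @param error_rate Nominal two-tailed rate (default 0.01).
#' @param method `"PCER"` or `"FWER"`.
#' @param n_perm Number of permutations; must satisfy
#'   `error_rate * (n_perm + 1) >= 1`.
#' @param seed Optional master seed; group streams are derived from it.
#' @param exclude_rare Exclude species flagged by [flag_rare()]?
#' @param min_prevalence Prevalence threshold for [flag_rare()].
#' @return A list of `association_screen` objects, one per group, each
#'   with matrices `I`, `pvals`, `lower`, `upper`, `significant` over the
#'   full species set (`NA` rows/columns for excluded species).
#' @export
screen_associations <- function(Y, groups, error_rate = 0.01,
                                method = c("PCER", "FWER"), n_perm = 999,
                                seed = NULL, exclude_rare = FALSE,
                                min_prevalence = 0.05) {
  method <- match.arg(method)
  if (error_rate * (n_perm + 1) < 1)
    stop("not enough permutations to resolve error_rate = ", error_rate,
         ": need n_perm >= ", ceiling(1 / error_rate) - 1, call. = FALSE)
  Y <- as.matrix(Y)
  if (is.null(colnames(Y))) colnames(Y) <- paste0("sp", seq_len(ncol(Y)))
  groups <- as.factor(groups)
  if (any(table(groups) < 3)) stop("each group needs >= 3 sampling units", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  group_seeds <- sample.int(.Machine$integer.max, nlevels(groups))
  out <- lapply(seq_along(levels(groups)), function(gi) {
    g <- levels(groups)[gi]
    set.seed(group_seeds[gi])
    Yg <- Y[groups == g, , drop = FALSE]
    keep <- colSums(Yg) > 0
    if (exclude_rare) keep <- keep & !flag_rare(Yg, min_prevalence)
    .screen_group(Yg, keep, error_rate, method, n_perm, g)
  })
  names(out) <- levels(groups)
  out
}

.screen_group <- function(Yg, keep, error_rate, method, n_perm, group) {
  p <- ncol(Yg)
  n <- nrow(Yg)
  sp <- colnames(Yg)
  I_mat <- p_mat <- lo_mat <- hi_mat <- matrix(NA_real_, p, p,
                                               dimnames = list(sp, sp))
  sig <- matrix(FALSE, p, p, dimnames = list(sp, sp))
  ki <- which(keep)
  if (length(ki) >= 2) {
    P <- sweep(Yg[, ki, drop = FALSE], 2, colSums(Yg[, ki, drop = FALSE]), "/")
    perm_idx <- matrix(0L, n, n_perm)
    for (b in seq_len(n_perm)) perm_idx[, b] <- sample.int(n)
    pairs <- utils::combn(seq_along(ki), 2)
    n_pairs <- ncol(pairs)
    I_obs <- numeric(n_pairs)
    p_two <- numeric(n_pairs)
    lo <- hi <- numeric(n_pairs)
    u_obs <- numeric(n_pairs)
    U <- if (method == "FWER") matrix(0, n_pairs, n_perm)
    kq <- max(1L, ceiling(error_rate / 2 * (n_perm + 1)))
    for (q in seq_len(n_pairs)) {
      a <- pairs[1, q]; b <- pairs[2, q]
      ## permute the member whose species name sorts later, so results are
      ## invariant to the column order of Y
      if (sp[ki[a]] > sp[ki[b]]) { tmp <- a; a <- b; b <- tmp }
      pk <- P[, a]; pl <- P[, b]
      I_obs[q] <- 1 - 0.5 * sum(abs(pk - pl))
      I_perm <- .index_perm(pk, matrix(pl[perm_idx], n))
      p_l <- (sum(I_perm <= I_obs[q]) + 1) / (n_perm + 1)
      p_u <- (sum(I_perm >= I_obs[q]) + 1) / (n_perm + 1)
      p_two[q] <- min(1, 2 * min(p_l, p_u))
      u_obs[q] <- min(p_l, p_u)
      srt <- sort(I_perm)
      lo[q] <- srt[kq]; hi[q] <- srt[n_perm + 1L - kq]
      if (method == "FWER") U[q, ] <- .perm_tailprob(I_perm)
    }
    sig_pair <- if (method == "PCER") {
      p_two <= error_rate
    } else {
      M <- apply(U, 2, min)                  # most extreme pair per permutation
      crit <- sort(M)[max(1L, floor(error_rate * (n_perm + 1)))]
      u_obs <= crit
    }
    for (q in seq_len(n_pairs)) {
      a <- ki[pairs[1, q]]; b <- ki[pairs[2, q]]
      I_mat[a, b] <- I_mat[b, a] <- I_obs[q]
      p_mat[a, b] <- p_mat[b, a] <- p_two[q]
      lo_mat[a, b] <- lo_mat[b, a] <- lo[q]
      hi_mat[a, b] <- hi_mat[b, a] <- hi[q]
      sig[a, b] <- sig[b, a] <- sig_pair[q]
    }
  }
  diag(I_mat)[keep] <- 1
  structure(list(I = I_mat, pvals = p_mat, lower = lo_mat, upper = hi_mat,
                 significant = sig, error_rate = error_rate, method = method,
                 n_perm = n_perm, group = group, retained = sp[keep]),
            class = "association_screen")
}

#' @export
print.association_screen <- function(x, ...) {
  ns <- sum(x$significant[upper.tri(x$significant)])
  nsp <- sum(rowSums(x$significant) > 0)
  cat("<association_screen> group ", x$group, ": ", ns,
      " significant pair(s) involving ", nsp, " species (",
      x$method, " ", x$error_rate, ", ", x$n_perm, " permutations)\n",
      sep = "")
  invisible(x)
}

#' Significant pairs of a screen as a data frame
#'
#' @param screens List of `association_screen` objects from
#'   [screen_associations()].
#' @param all Include non-significant pairs too?
#' @return Data frame: group, species_a, species_b, I, p_value,
#'   lower_bound, upper_bound, significant.
#' @export
screen_report <- function(screens, all = FALSE) {
  do.call(rbind, lapply(screens, function(s) {
    ut <- which(upper.tri(s$I) & !is.na(s$I), arr.ind = TRUE)
    if (!nrow(ut)) return(NULL)
    d <- data.frame(group = s$group,
                    species_a = rownames(s$I)[ut[, 1]],
                    species_b = colnames(s$I)[ut[, 2]],
                    I = s$I[ut], p_value = s$pvals[ut],
                    lower_bound = s$lower[ut], upper_bound = s$upper[ut],
                    significant = s$significant[ut],
                    stringsAsFactors = FALSE)
    if (all) d else d[d$significant, , drop = FALSE]
  }))
}

#' Species involved in at least one significant association
#'
#' @param screen An `association_screen`.
#' @return Integer indices of associated species (columns of `Y`).
#' @export
associated_species <- function(screen) {
  which(rowSums(screen$significant) > 0)
}
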
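#' Dissimilarity matrix container
#'
#' A symmetric non-negative matrix with zero diagonal plus bookkeeping
#' (measure, transform, unit labels). Bray-Curtis entries lie in
#' `[0, 1]`.
#'
#' @param values Symmetric numeric matrix.
#' @param labels Unit identifiers (default: rownames).
#' @param measure,transform Names recorded for provenance.
#' @return Object of class `dissimilarity_matrix` (a matrix).
#' @export
dissimilarity_matrix <- function(values, labels = NULL, measure = "unknown",
                                 transform = "none") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values) || max(abs(values - t(values))) > 1e-8)
    stop("'values' must be a symmetric square matrix", call. = FALSE)
  if (any(values < -1e-12)) stop("dissimilarities must be non-negative", call. = FALSE)
  if (max(abs(diag(values))) > 1e-8) stop("diagonal must be zero", call. = FALSE)
  values[values < 0] <- 0
  diag(values) <- 0
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(values)))
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("dissimilarity_matrix", "matrix"),
            measure = measure, transform = transform)
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat("<dissimilarity_matrix> ", nrow(x), " units, measure = ",
      attr(x, "measure"), ", transform = ", attr(x, "transform"), "\n",
      sep = "")
  invisible(x)
}

apply_transform <- function(Y, transform = c("sqrt", "none", "fourth_root")) {
  transform <- match.arg(transform)
  switch(transform, none = Y, sqrt = sqrt(Y), fourth_root = Y^0.25)
}

#' Bray-Curtis dissimilarities between sampling units
#'
#' `d_ij = sum_k |t(y_ik) - t(y_jk)| / sum_k (t(y_ik) + t(y_jk))` for a
#' pre-transform `t`. A pair of all-zero rows is undefined by the
#' formula; it is set to 0 by convention and counted in the
#' `zero_pairs` attribute. The square-root pre-transform is the default
#' used throughout the centroid and inference pipelines.
#'
#' @param Y Sample-by-species matrix of non-negative values.
#' @param transform `"sqrt"` (default), `"none"` or `"fourth_root"`.
#' @return A [dissimilarity_matrix()].
#' @export
bray_curtis <- function(Y, transform = "sqrt") {
  Y <- as.matrix(Y)
  if (any(Y < 0)) stop("'Y' must be non-negative", call. = FALSE)
  ty <- apply_transform(Y, transform)
  ## empty-row warnings are handled deliberately below
  D <- as.matrix(suppressWarnings(vegan::vegdist(ty, method = "bray")))
  zero_rows <- rowSums(ty) == 0
  n_zero_pairs <- 0L
  if (any(zero_rows)) {
    zp <- outer(zero_rows, zero_rows, "&")
    diag(zp) <- FALSE
    n_zero_pairs <- as.integer(sum(zp) / 2)
    D[zp] <- 0
  }
  out <- dissimilarity_matrix(D, labels = rownames(Y), measure = "bray_curtis",
                              transform = transform)
  attr(out, "zero_pairs") <- n_zero_pairs
  out
}

#' Compute a dissimilarity matrix by name
#'
#' Pluggable front end used by the pipelines: `"bray"` (reference
#' implementation) or `"euclidean"` (mostly for oracle checks, computed
#' on the transformed values).
#'
#' @inheritParams bray_curtis
#' @param measure `"bray"` or `"euclidean"`.
#' @return A [dissimilarity_matrix()].
#' @export
dissim <- function(Y, measure = c("bray", "euclidean"), transform = "sqrt") {
  measure <- match.arg(measure)
  if (measure == "bray") return(bray_curtis(Y, transform))
  ty <- apply_transform(as.matrix(Y), transform)
  dissimilarity_matrix(as.matrix(stats::dist(ty)), labels = rownames(Y),
                       measure = "euclidean", transform = transform)
}

## Squared distances among centroids of arbitrary row subsets of D,
## computed directly from the dissimilarity matrix (no coordinates):
##   d2(A,B) = mean_{i in A, j in B} d2_ij
##             - mean_{i,i' in A} d2/2 - mean_{j,j' in B} d2/2
## 'sets' is a list of row-index vectors. Negative squared distances
## (possible for semi-metric D) are clamped to 0 and counted.
centroid_dist_sets <- function(D, sets) {
  D2 <- unclass(D)^2
  n <- nrow(D2)
  M <- length(sets)
  W <- matrix(0, n, M)
  for (s in seq_len(M)) W[sets[[s]], s] <- 1 / length(sets[[s]])
  G <- crossprod(W, D2) %*% W           # mean cross squared distances
  self <- diag(G) / 2
  Dc2 <- G - outer(self, rep(1, M)) - outer(rep(1, M), self)
  clamped <- sum(Dc2[upper.tri(Dc2)] < -1e-12)
  Dc2[Dc2 < 0] <- 0
  diag(Dc2) <- 0
  list(D = sqrt(Dc2), clamped = clamped)
}

#' Distances among group centroids, directly from a dissimilarity matrix
#'
#' Centroids in the (possibly non-Euclidean) space implied by `D` are
#' never constructed explicitly; their squared inter-centroid distances
#' follow from averages of squared dissimilarities within and between
#' groups. For a Euclidean `D` this reproduces distances between
#' arithmetic-mean centroids exactly. For semi-metric measures (e.g.
#' Bray-Curtis) a squared centroid distance can come out negative; such
#' values are clamped to 0 and counted in the `clamped` attribute.
#'
#' @param D A [dissimilarity_matrix()] (or square matrix).
#' @param groups Factor of group labels, one per row of `D`.
#' @return A [dissimilarity_matrix()] over group centroids with attribute
#'   `clamped`.
#' @export
centroid_distances <- function(D, groups) {
  D <- as.matrix(D)
  groups <- as.factor(groups)
  if (length(groups) != nrow(D))
    stop("'groups' must have one label per row of 'D'", call. = FALSE)
  sets <- split(seq_len(nrow(D)), groups)
  if (any(lengths(sets) == 0)) stop("every group must be non-empty", call. = FALSE)
  cd <- centroid_dist_sets(D, sets)
  out <- dissimilarity_matrix(cd$D, labels = names(sets),
                              measure = paste0("centroid_",
                                               attr(D, "measure") %||% "unknown"),
                              transform = attr(D, "transform") %||% "none")
  attr(out, "clamped") <- cd$clamped
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Principal coordinates analysis (classical scaling)
#'
#' Eigen-decomposition of the Gower-centered matrix `-0.5 * J D^2 J`.
#' Axes are ordered by descending eigenvalue; negative eigenvalues
#' (typical for semi-metric measures like Bray-Curtis) are retained and
#' reported, not dropped or corrected.
#'
#' @param D A [dissimilarity_matrix()] or square symmetric matrix.
#' @return List of class `pcoa`: `values` (all eigenvalues), `vectors`,
#'   `points` (units by positive axes, scaled by `sqrt(lambda)`).
#' @export
pcoa <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  G <- J %*% A %*% J
  G <- (G + t(G)) / 2
  e <- eigen(G, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-9
  pts <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(pts) <- rownames(D)
  structure(list(values = e$values, vectors = e$vectors, points = pts),
            class = "pcoa")
}

#' Metric or non-metric multidimensional scaling
#'
#' Thin multi-start wrapper around [vegan::monoMDS()]: metric mode
#' minimizes stress under a linear regression of configuration distances
#' on dissimilarities; non-metric mode minimizes Kruskal stress-1 with
#' monotone regression. The best of `n_starts` random starts plus a
#' principal-coordinates start is returned; the achieved stress is always
#' reported (a high stress, e.g. > 0.24, is itself informative and is
#' never hidden).
#'
#' @param D A [dissimilarity_matrix()] or `dist`.
#' @param n_dim Embedding dimension (>= 1).
#' @param mode `"metric"` or `"nonmetric"`.
#' @param seed Optional integer seed for the random starts.
#' @param n_starts Number of random starts in addition to the PCoA start.
#' @return List of class `mds_fit`: `points`, `stress`, `mode`,
#'   `converged`.
#' @export
mds <- function(D, n_dim = 2, mode = c("metric", "nonmetric"), seed = NULL,
                n_starts = 8) {
  mode <- match.arg(mode)
  if (n_dim < 1) stop("'n_dim' must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Dm <- as.matrix(D)
  d <- stats::as.dist(Dm)
  n <- nrow(Dm)
  model <- if (mode == "metric") "linear" else "global"
  pc <- pcoa(Dm)
  k_avail <- ncol(pc$points)
  ## exact PCoA start; tiny noise only pads axes PCoA cannot supply
  start0 <- matrix(stats::rnorm(n * n_dim, sd = 1e-6), n, n_dim)
  if (k_avail) {
    kk <- min(n_dim, k_avail)
    start0[, seq_len(kk)] <- pc$points[, seq_len(kk)]
  }
  starts <- c(list(start0),
              replicate(n_starts, matrix(stats::rnorm(n * n_dim), n, n_dim),
                        simplify = FALSE))
  best <- NULL
  for (y0 in starts) {
    f <- vegan::monoMDS(d, y = y0, k = n_dim, model = model,
                        maxit = 1000, smin = 1e-10, sratmax = 1 - 1e-9)
    if (is.null(best) || f$stress < best$stress) best <- f
  }
  pts <- best$points
  rownames(pts) <- rownames(Dm)
  colnames(pts) <- paste0("axis", seq_len(n_dim))
  structure(list(points = pts, stress = best$stress, mode = mode,
                 converged = best$maxits == FALSE || best$iters < best$maxits),
            class = "mds_fit")
}

#' @export
print.mds_fit <- function(x, ...) {
  cat("<mds_fit> ", x$mode, " MDS in ", ncol(x$points),
      " dimensions; stress = ", signif(x$stress, 4), "\n", sep = "")
  invisible(x)
}

#' Ordinate observed and simulated group centroids
#'
#' The centroid-cloud diagnostic: simulate `N_sim` full datasets from the
#' fitted community model (the alternative hypothesis, each group from
#' its own copula model at the observed group sizes), optionally generate
#' `N_sim` null relabelings of the observed units (random permutation of
#' group labels, asserting exchangeability), stack everything into a
#' super-matrix, compute dissimilarities, reduce to distances among all
#' `(N_sim + 1) * g` (plus null) centroids directly from the
#' super-matrix, and ordinate the centroids by metric MDS. A 2-D kernel
#' density estimate per (source, group) summarizes each centroid cloud.
#'
#' @param Y Observed sample-by-species count matrix.
#' @param groups Factor of group labels.
#' @param model A [community_model()] fitted to `Y` (or any model of the
#'   same dimension).
#' @param N_sim Number of simulated datasets (0 = observed centroids
#'   only).
#' @param measure,transform Passed to [dissim()].
#' @param include_null Also generate permutation (null-hypothesis)
#'   centroid clouds?
#' @param n_dim Ordination dimension.
#' @param seed Optional integer seed.
#' @return Object of class `centroid_cloud`: data frame `coordinates`
#'   (id, source, group, axis1..axisK), `stress`, `densities` (list of
#'   [MASS::kde2d()] grids when `n_dim == 2`), `clamped`.
#' @export
centroid_cloud_pipeline <- function(Y, groups, model, N_sim = 100,
                                    measure = "bray", transform = "sqrt",
                                    include_null = TRUE, n_dim = 2,
                                    seed = NULL) {
  Y <- as.matrix(Y)
  groups <- as.factor(groups)
  stopifnot(inherits(model, "community_model"))
  if (length(model$species) != ncol(Y))
    stop("model and data disagree on species dimension", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  g <- nlevels(groups)
  sizes <- table(groups)
  blocks <- list(Y)
  if (N_sim > 0) {
    for (r in seq_len(N_sim)) {
      Ys <- do.call(rbind, lapply(levels(groups), function(lev)
        simulate_counts(model$groups[[lev]], sizes[[lev]])))
      blocks[[r + 1]] <- Ys
    }
  }
  Ysuper <- do.call(rbind, blocks)
  Dsuper <- dissim(Ysuper, measure, transform)

  n <- nrow(Y)
  obs_rows <- split(seq_len(n), groups)
  sets <- obs_rows
  meta <- data.frame(source = "observed", group = levels(groups),
                     replicate = 0L, stringsAsFactors = FALSE)
  if (N_sim > 0) {
    sim_group <- rep(levels(groups), sizes)   # row layout of each sim block
    for (r in seq_len(N_sim)) {
      off <- n * r
      for (lev in levels(groups)) {
        sets <- c(sets, list(off + which(sim_group == lev)))
        meta <- rbind(meta, data.frame(source = "simulated_HA", group = lev,
                                       replicate = r))
      }
    }
    if (include_null) {
      for (r in seq_len(N_sim)) {
        perm <- sample(as.integer(groups))
        for (gi in seq_len(g)) {
          sets <- c(sets, list(which(perm == gi)))
          meta <- rbind(meta, data.frame(source = "simulated_H0",
                                         group = levels(groups)[gi],
                                         replicate = r))
        }
      }
    }
  }
  cd <- centroid_dist_sets(Dsuper, sets)
  ord <- mds(cd$D, n_dim = n_dim, mode = "metric")
  coords <- data.frame(id = paste(meta$source, meta$group, meta$replicate,
                                  sep = "_"),
                       source = meta$source, group = meta$group,
                       ord$points, stringsAsFactors = FALSE)
  densities <- NULL
  if (n_dim == 2) {
    densities <- list()
    for (src in setdiff(unique(coords$source), "observed"))
      for (lev in levels(groups)) {
        xy <- coords[coords$source == src & coords$group == lev, c("axis1", "axis2")]
        if (nrow(xy) >= 10 && stats::sd(xy$axis1) > 0 && stats::sd(xy$axis2) > 0)
          densities[[paste(src, lev, sep = "_")]] <-
            MASS::kde2d(xy$axis1, xy$axis2, n = 50)
      }
  }
  structure(list(coordinates = coords, stress = ord$stress,
                 densities = densities, clamped = cd$clamped,
                 measure = measure, transform = transform),
            class = "centroid_cloud")
}

#' @export
print.centroid_cloud <- function(x, ...) {
  tab <- table(x$coordinates$source)
  cat("<centroid_cloud> ", nrow(x$coordinates), " centroids (",
      paste(names(tab), tab, sep = ": ", collapse = ", "),
      "); stress = ", signif(x$stress, 4), "\n", sep = "")
  invisible(x)
}

#' Plot a centroid cloud with kernel density contours
#'
#' @param x A `centroid_cloud`.
#' @param levels Contour probability mass levels.
#' @param ... Passed to [plot()].
#' @export
plot.centroid_cloud <- function(x, levels = c(0.5, 0.75, 0.95), ...) {
  co <- x$coordinates
  grp <- factor(co$group)
  cols <- grDevices::hcl.colors(nlevels(grp), "Dark 3")
  pch <- c(observed = 17, simulated_HA = 1, simulated_H0 = 3)
  plot(co$axis1, co$axis2, col = cols[as.integer(grp)],
       pch = pch[co$source], xlab = "axis 1", ylab = "axis 2",
       main = sprintf("centroid cloud (stress = %.3f)", x$stress), ...)
  for (nm in names(x$densities)) {
    k <- x$densities[[nm]]
    z <- k$z / sum(k$z)
    zs <- sort(z, decreasing = TRUE)
    cl <- vapply(levels, function(l) zs[which(cumsum(zs) >= l)[1]], numeric(1))
    graphics::contour(k$x, k$y, z, levels = cl, drawlabels = FALSE,
                      add = TRUE, col = "grey60")
  }
  invisible(x)
}
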
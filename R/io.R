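#' Read a sample-by-species count table
#'
#' CSV or TSV (sniffed from the first line unless `sep` is given), first
#' column the sample identifier, one column per species, integer cells.
#' Group labels may live in a designated column of the same file or in a
#' two-column companion file (sample, group).
#'
#' @param path Count table path.
#' @param group_col Name of a group column inside the table, if any.
#' @param group_file Optional companion file with columns sample, group.
#' @param sep Field separator; `NULL` to sniff `,` vs tab.
#' @return List: `Y` (integer matrix, rownames = sample ids), `groups`
#'   (factor or `NULL`).
#' @export
read_count_table <- function(path, group_col = NULL, group_file = NULL,
                             sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    l1 <- readLines(path, n = 1)
    sep <- if (grepl("\t", l1)) "\t" else ","
  }
  d <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                         stringsAsFactors = FALSE)
  ids <- as.character(d[[1]])
  d <- d[, -1, drop = FALSE]
  groups <- NULL
  if (!is.null(group_col)) {
    if (!group_col %in% names(d))
      stop("group column '", group_col, "' not found", call. = FALSE)
    groups <- factor(d[[group_col]])
    d <- d[, setdiff(names(d), group_col), drop = FALSE]
  }
  Y <- as.matrix(d)
  if (any(is.na(Y)) || any(Y < 0) || any(Y != floor(Y)))
    stop("count cells must be non-negative integers", call. = FALSE)
  storage.mode(Y) <- "integer"
  rownames(Y) <- ids
  if (!is.null(group_file)) {
    gd <- utils::read.table(group_file, header = TRUE, sep = sep,
                            stringsAsFactors = FALSE)
    groups <- factor(gd[[2]][match(ids, as.character(gd[[1]]))])
    if (any(is.na(groups)))
      stop("group file is missing labels for some samples", call. = FALSE)
  }
  list(Y = Y, groups = groups)
}

#' Write a count table in the dialect [read_count_table()] reads
#'
#' @param Y Count matrix.
#' @param path Output CSV path.
#' @param groups Optional factor written as a `group` column.
#' @export
write_count_table <- function(Y, path, groups = NULL) {
  d <- data.frame(sample = rownames(Y) %||% paste0("s", seq_len(nrow(Y))),
                  as.data.frame(Y), check.names = FALSE)
  if (!is.null(groups)) d$group <- as.character(groups)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

marginal_to_list <- function(m) {
  Filter(Negate(is.null),
         list(family = m$family, mu = m$mu, theta = m$theta, pi = m$pi))
}

list_to_marginal <- function(l) {
  count_marginal(l$family, mu = l$mu, theta = l$theta, pi = l$pi)
}

#' Serialize a community model to JSON
#'
#' One versioned document holding, per group, the marginal family and
#' parameters of every species plus the dense (row-major) copula
#' correlation matrix.
#'
#' @param model A [community_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "community_model"))
  doc <- list(
    schema = "copulacomm-model", version = 1L,
    species = model$species, sizes = model$sizes,
    groups = lapply(names(model$groups), function(g) {
      gm <- model$groups[[g]]
      list(group = g, n = gm$n,
           assoc_index = gm$assoc_index,
           marginals = lapply(seq_along(gm$marginals), function(j)
             c(list(species = model$species[j]),
               marginal_to_list(gm$marginals[[j]]))),
           sigma = as.vector(t(gm$sigma)))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a community model written by [write_model_json()]
#'
#' @param path Path to the model JSON.
#' @return A [community_model()].
#' @export
read_model_json <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$schema, "copulacomm-model"))
    stop("not a copulacomm model document", call. = FALSE)
  species <- unlist(doc$species)
  p <- length(species)
  gms <- lapply(doc$groups, function(gd) {
    marg <- lapply(gd$marginals, list_to_marginal)
    names(marg) <- vapply(gd$marginals, `[[`, character(1), "species")
    sigma <- matrix(unlist(gd$sigma), p, p, byrow = TRUE)
    group_copula_model(marg, sigma,
                       assoc_index = unlist(gd$assoc_index) %||% integer(0),
                       group = gd$group, n = gd$n %||% NA_integer_)
  })
  names(gms) <- vapply(doc$groups, `[[`, character(1), "group")
  community_model(gms, sizes = unlist(doc$sizes), species = species)
}

#' Write a square dissimilarity matrix as labeled CSV
#'
#' @param D A [dissimilarity_matrix()].
#' @param path Output path.
#' @export
write_dissimilarity_csv <- function(D, path) {
  utils::write.csv(as.data.frame(as.matrix(D)), path, quote = FALSE)
  invisible(path)
}

#' Read a square dissimilarity CSV back
#'
#' @param path Path written by [write_dissimilarity_csv()].
#' @return A [dissimilarity_matrix()].
#' @export
read_dissimilarity_csv <- function(path) {
  d <- utils::read.csv(path, row.names = 1, check.names = FALSE)
  dissimilarity_matrix(as.matrix(d))
}
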
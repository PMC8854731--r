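# Comparing joint-importance profiles (and self-reported preference
# ratings): Spearman correlation, Ward-linkage agglomerative clustering,
# and classical 3-D multidimensional scaling.
#
# The Ward agglomeration is implemented directly (Lance-Williams
# recursion on squared Euclidean distances with a deterministic
# lowest-index tie-break) so that merge order is reproducible; heights
# are on the distance scale, i.e. two singletons merge at their Euclidean
# distance.

#' Build a profile set
#'
#' @param profiles list of `joint_importance_profile`s sharing joint
#'   labels and granularity, or a numeric matrix (rows = profiles).
#' @param row_labels optional row names; defaults to
#'   `<target>_<dataset_tag>` for profile lists.
#' @return An object of class `profile_set` holding a P x J matrix.
#' @export
profile_set <- function(profiles, row_labels = NULL) {
  if (is.matrix(profiles) || is.data.frame(profiles)) {
    mat <- as.matrix(profiles)
    if (is.null(row_labels)) row_labels <- rownames(mat) %||%
        paste0("profile", seq_len(nrow(mat)))
  } else {
    stopifnot(is.list(profiles), length(profiles) >= 1)
    labs <- profiles[[1]]$joint_labels
    for (p in profiles)
      if (!identical(p$joint_labels, labs) ||
          !identical(p$granularity, profiles[[1]]$granularity))
        stop("profiles must share joint labels and granularity", call. = FALSE)
    mat <- do.call(rbind, lapply(profiles, `[[`, "values"))
    colnames(mat) <- labs
    if (is.null(row_labels))
      row_labels <- vapply(profiles, function(p)
        paste0(p$target_name, "_", p$dataset_tag), character(1))
  }
  if (nrow(mat) < 2) stop("need at least 2 profiles", call. = FALSE)
  if (anyNA(mat)) stop("profile set has missing entries", call. = FALSE)
  rownames(mat) <- row_labels
  structure(list(profiles = mat, row_labels = row_labels),
            class = "profile_set")
}

#' Spearman correlation between two profiles
#'
#' Rank correlation with average ranks for ties and a two-sided p-value
#' (asymptotic t approximation, appropriate with ties).
#'
#' @param p,q numeric vectors of equal length >= 3.
#' @return A list with `r`, `p_value` and `n`.
#' @export
profile_spearman <- function(p, q) {
  stopifnot(length(p) == length(q), length(p) >= 3)
  if (stats::sd(p) == 0 || stats::sd(q) == 0)
    stop("constant profile: ranks are degenerate", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(p, q, method = "spearman",
                                         exact = FALSE))
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(p))
}

# Ward merge cost between clusters (sizes na, nb; centroids ca, cb) on the
# squared-distance scale: 2 * na*nb/(na+nb) * ||ca - cb||^2. Equivalently
# maintained by the Lance-Williams recursion below; the reported height is
# the square root (so singleton pairs merge at their Euclidean distance).
#' Ward's-linkage agglomerative clustering
#'
#' Agglomerates the rows of a profile set under Ward's criterion on
#' Euclidean distances, with ties broken deterministically towards the
#' lowest cluster indices. The merge table follows the `hclust`
#' convention: negative entries are singleton rows, positive entries
#' earlier merges.
#'
#' @param set a [profile_set()] (or matrix accepted by it).
#' @return An object of class `dendrogram_result` with `merges` (data
#'   frame: cluster_a, cluster_b, height, size), `linkage`, `distance`,
#'   and `labels`; convert via [as_hclust()].
#' @export
ward_dendrogram <- function(set) {
  if (!inherits(set, "profile_set")) set <- profile_set(set)
  X <- set$profiles
  P <- nrow(X)
  d2 <- as.matrix(stats::dist(X))^2
  size <- rep(1L, P)
  id <- -(1:P)                 # hclust-style identifiers of active clusters
  active <- rep(TRUE, P)
  merges <- data.frame(cluster_a = integer(P - 1), cluster_b = integer(P - 1),
                       height = numeric(P - 1), size = integer(P - 1))
  for (step in seq_len(P - 1)) {
    best <- c(NA_integer_, NA_integer_); bd <- Inf
    act <- which(active)
    for (jj in seq_along(act)[-1]) for (ii in seq_len(jj - 1)) {
      i <- act[ii]; j <- act[jj]
      if (d2[i, j] < bd - 1e-12) { bd <- d2[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    # Lance-Williams update for Ward on squared distances
    for (k in act) {
      if (k == i || k == j) next
      d2[i, k] <- d2[k, i] <-
        ((size[i] + size[k]) * d2[i, k] + (size[j] + size[k]) * d2[j, k] -
           size[k] * d2[i, j]) / (size[i] + size[j] + size[k])
    }
    pair <- sort(c(id[i], id[j]))
    merges$cluster_a[step] <- pair[1]
    merges$cluster_b[step] <- pair[2]
    merges$height[step] <- sqrt(max(bd, 0))
    merges$size[step] <- size[i] + size[j]
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    id[i] <- step
  }
  structure(list(merges = merges, linkage = "ward", distance = "euclidean",
                 labels = set$row_labels), class = "dendrogram_result")
}

#' @export
print.dendrogram_result <- function(x, ...) {
  cat(sprintf("<dendrogram_result> %d leaves, %s linkage on %s distance\n",
              length(x$labels), x$linkage, x$distance))
  print(x$merges)
  invisible(x)
}

#' Convert a dendrogram result to an `hclust` object
#'
#' @param x a `dendrogram_result`.
#' @return An object of class `hclust` (plottable with `plot()`).
#' @export
as_hclust <- function(x) {
  stopifnot(inherits(x, "dendrogram_result"))
  m <- cbind(x$merges$cluster_a, x$merges$cluster_b)
  structure(list(merge = m, height = x$merges$height,
                 order = hclust_leaf_order(m), labels = x$labels,
                 method = "ward.D2", dist.method = x$distance),
            class = "hclust")
}

hclust_leaf_order <- function(merge) {
  expand <- function(i)
    if (i < 0) -i else c(expand(merge[i, 1]), expand(merge[i, 2]))
  expand(nrow(merge))
}

#' Classical metric MDS embedding of a profile set
#'
#' Torgerson scaling: double-centred eigendecomposition of the squared
#' Euclidean dissimilarity matrix, keeping `ndim` dimensions. The
#' embedding is centred and deterministic up to reflection.
#'
#' @param set a [profile_set()] (or matrix).
#' @param ndim embedding dimension (default 3); requires `P > ndim` rows.
#' @return An object of class `embedding_result` with `coordinates`
#'   (P x ndim, centred) and `stress` (normalised residual of pairwise
#'   distances).
#' @export
mds_embed <- function(set, ndim = 3) {
  if (!inherits(set, "profile_set")) set <- profile_set(set)
  X <- set$profiles
  P <- nrow(X)
  if (P <= ndim) stop("need more profiles than embedding dimensions",
                      call. = FALSE)
  d <- stats::dist(X)
  fit <- stats::cmdscale(d, k = ndim, eig = TRUE)
  co <- fit$points
  if (ncol(co) < ndim)   # degenerate spectra yield fewer columns
    co <- cbind(co, matrix(0, P, ndim - ncol(co)))
  co <- sweep(co, 2, colMeans(co))
  rownames(co) <- set$row_labels
  dd <- as.numeric(d)
  de <- as.numeric(stats::dist(co))
  stress <- sqrt(sum((dd - de)^2) / sum(dd^2))
  structure(list(coordinates = co, stress = stress,
                 eigenvalues = fit$eig), class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> %d points in %d dimensions, stress = %.4f\n",
              nrow(x$coordinates), ncol(x$coordinates), x$stress))
  invisible(x)
}

#' Ward dendrogram of self-reported genre ratings
#'
#' Clusters genres (columns) over participants' rating vectors with the
#' same Ward/Euclidean engine as [ward_dendrogram()], for comparison with
#' the importance-profile dendrogram.
#'
#' @param ratings participants x genres numeric table with entries in
#'   \[1, 7\] and no missing values.
#' @return A `dendrogram_result` over genres.
#' @export
rating_dendrogram <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("missing ratings", call. = FALSE)
  if (any(ratings < 1 | ratings > 7))
    stop("ratings must lie in [1, 7]", call. = FALSE)
  ward_dendrogram(profile_set(t(ratings)))
}

#' Pairwise Spearman matrix of a profile set
#'
#' @param set a [profile_set()] (or matrix).
#' @return A list with `r` (P x P correlation matrix) and `p_value`.
#' @export
profile_spearman_matrix <- function(set) {
  if (!inherits(set, "profile_set")) set <- profile_set(set)
  X <- set$profiles
  P <- nrow(X)
  r <- diag(1, P); pv <- matrix(0, P, P)
  dimnames(r) <- dimnames(pv) <- list(set$row_labels, set$row_labels)
  for (i in seq_len(P - 1)) for (j in (i + 1):P) {
    s <- profile_spearman(X[i, ], X[j, ])
    r[i, j] <- r[j, i] <- s$r
    pv[i, j] <- pv[j, i] <- s$p_value
  }
  list(r = r, p_value = pv)
}
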
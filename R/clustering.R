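#' Default number of k-means seeds for a data set
#'
#' Seeding exists to shrink the dissimilarity matrix: 20 000 seeds is the
#' reference setting for national-scale inventories (~10^5 plots); smaller data
#' sets use roughly one seed per six plots.
#'
#' @param n_plots number of plots.
#' @return Integer seed count, `min(20000, ceiling(n_plots / 6))`.
#' @export
default_seed_k <- function(n_plots) as.integer(min(20000L, ceiling(n_plots / 6)))

#' k-means cluster seeding of the importance-value matrix
#'
#' Runs Euclidean Lloyd k-means with `n_start` random restarts to collapse
#' plots with identical or near-identical species importance values into `k`
#' seeds. Initial centers of each restart are drawn from the distinct IV rows,
#' so `k` equal to the number of distinct rows reproduces them exactly. A
#' cluster emptied during iteration is re-seeded with the point farthest from
#' its assigned centroid. The restart with the lowest within-cluster sum of
#' squares wins; ties go to the earliest restart.
#'
#' @param ivm plots x species importance-value matrix (see [compute_iv()]).
#' @param k number of seeds; must not exceed the number of distinct rows.
#' @param n_start number of random restarts.
#' @param max_iter maximum Lloyd iterations per restart.
#' @param rng_seed integer seed.
#' @return A list of class `seed_set`: `centroids` (k x species matrix of mean
#'   IVs), `sizes` (plots per seed), `plot_to_seed` (named integer vector),
#'   `wss` (within-cluster sum of squares of the winning restart).
#' @export
kmeans_seed <- function(ivm, k, n_start = 5L, max_iter = 100L, rng_seed = 1L) {
  x <- as.matrix(ivm)
  ux <- unique(x)
  if (k > nrow(ux))
    stop("k = ", k, " exceeds the ", nrow(ux),
         " distinct IV rows; choose a smaller k")
  set.seed(as.integer(rng_seed))
  xsq <- rowSums(x^2)

  assign_pts <- function(centers) {
    # squared distances via ||x||^2 - 2 x.c + ||c||^2; ||x||^2 constant per row
    d2 <- -2 * tcrossprod(x, centers)
    d2 <- sweep(d2, 2, rowSums(centers^2), "+")
    max.col(-d2, ties.method = "first")
  }

  best <- NULL
  for (r in seq_len(n_start)) {
    centers <- ux[sample(nrow(ux), k), , drop = FALSE]
    cl <- assign_pts(centers)
    for (it in seq_len(max_iter)) {
      cnt <- tabulate(cl, k)
      while (any(cnt == 0L)) {
        # re-seed each empty cluster from the point farthest from its centroid
        resid <- rowSums((x - centers[cl, , drop = FALSE])^2)
        far <- which.max(resid)
        cl[far] <- which(cnt == 0L)[1L]
        cnt <- tabulate(cl, k)
      }
      centers <- rowsum(x, cl) / cnt
      new_cl <- assign_pts(centers)
      if (identical(new_cl, cl)) break
      cl <- new_cl
    }
    wss <- sum((x - centers[cl, , drop = FALSE])^2)
    if (is.null(best) || wss < best$wss - 1e-12)
      best <- list(cl = cl, centers = centers, wss = wss)
  }

  cnt <- tabulate(best$cl, k)
  centroids <- rowsum(x, best$cl) / cnt
  rownames(centroids) <- sprintf("S%05d", seq_len(k))
  structure(list(centroids = centroids,
                 sizes = cnt,
                 plot_to_seed = stats::setNames(best$cl, rownames(x)),
                 wss = best$wss),
            class = "seed_set")
}

#' Bray-Curtis dissimilarity between composition rows
#'
#' `d(u, v) = sum|u_i - v_i| / sum(u_i + v_i)`, in `[0, 1]` for nonnegative
#' rows. Computed with [vegan::vegdist()].
#'
#' @param x nonnegative matrix (plots or seed centroids x species); all-zero
#'   rows are rejected.
#' @return A `dist` object with `rownames(x)` as labels.
#' @export
bray_curtis <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("Bray-Curtis requires nonnegative entries")
  if (any(rowSums(x) == 0)) stop("all-zero rows have undefined Bray-Curtis dissimilarity")
  vegan::vegdist(x, method = "bray")
}

#' Size-weighted average-linkage (UPGMA) agglomeration
#'
#' Hierarchical clustering of seed centroids where each leaf stands for
#' `sizes[i]` plots: the Lance-Williams update
#' `d(i+j, m) = (n_i d(i, m) + n_j d(j, m)) / (n_i + n_j)` is seeded with the
#' leaf weights, which makes merge heights identical to plain UPGMA on the
#' fully expanded plot-level dissimilarity matrix. Implemented with
#' [stats::hclust()] (`method = "average"`, `members = sizes`).
#'
#' @param d dissimilarity (`dist`) between seed centroids.
#' @param sizes plot counts per seed, aligned with the labels of `d`; all >= 1.
#' @return An `hclust` object with a `leaf_sizes` attribute.
#' @export
weighted_average_linkage <- function(d, sizes = NULL) {
  n <- attr(d, "Size")
  if (n > 30000L)
    stop("refusing a dissimilarity matrix with ", n,
         " leaves; seed the data first (see kmeans_seed)")
  if (is.null(sizes)) sizes <- rep(1L, n)
  if (length(sizes) != n) stop("sizes must match the dissimilarity labels")
  if (any(sizes < 1)) stop("sizes must be >= 1")
  hc <- stats::hclust(d, method = "average", members = sizes)
  attr(hc, "leaf_sizes") <- sizes
  hc
}

#' Cut the seed dendrogram into a k-cluster typology of plots
#'
#' Cuts the hierarchy at `k` clusters and propagates seed memberships to plots
#' through the seed assignment map. Cluster ids follow [stats::cutree()]'s
#' stable numbering (order of first appearance among the leaves).
#'
#' @param dend `hclust` from [weighted_average_linkage()].
#' @param seedset `seed_set` from [kmeans_seed()]; pass `NULL` when `dend` was
#'   built directly on plots.
#' @param k number of clusters, `1 <= k <=` number of leaves.
#' @return Named integer vector: plot id -> cluster id in `1..k`.
#' @export
cut_typology <- function(dend, seedset = NULL, k) {
  n_leaves <- length(dend$order)
  if (k < 1L || k > n_leaves)
    stop("k must lie in [1, ", n_leaves, "]")
  seed_cl <- stats::cutree(dend, k = k)
  if (is.null(seedset)) return(seed_cl)
  stopifnot(inherits(seedset, "seed_set"))
  stats::setNames(unname(seed_cl[seedset$plot_to_seed]),
                  names(seedset$plot_to_seed))
}

#' Export a dendrogram as a Newick string
#'
#' Converts the merge history to a rooted binary tree (via
#' [ape::as.phylo()], branch lengths derived from merge heights) and serialises
#' it in Newick format, the standard interchange format for dendrograms.
#'
#' @param dend `hclust` object; leaves must be labelled.
#' @return Newick string (single element character vector, ends in `;`).
#' @export
export_newick <- function(dend) {
  if (is.null(dend$labels))
    dend$labels <- sprintf("S%05d", seq_along(dend$order))
  ape::write.tree(ape::as.phylo(dend))
}
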
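# Core Dufrene-Legendre statistics for one labelling.
# iv: plots x species matrix; cl: integer memberships 1..k (all clusters
# non-empty). Returns per-species specificity A (k x S), fidelity B (k x S),
# their product, and the max statistic with its cluster.
indval_core <- function(iv, cl, k = max(cl), pres = NULL) {
  n_by <- tabulate(cl, k)
  if (any(n_by == 0L)) stop("every cluster must contain at least one plot")
  mean_by <- rowsum(iv, cl, reorder = TRUE) / n_by
  tot <- colSums(mean_by)
  A <- sweep(mean_by, 2, ifelse(tot > 0, tot, 1), "/")
  if (is.null(pres)) pres <- (iv > 0) + 0
  B <- rowsum(pres, cl, reorder = TRUE) / n_by
  ivmat <- A * B
  best <- max.col(t(ivmat), ties.method = "first")
  stat <- ivmat[cbind(best, seq_len(ncol(iv)))]
  list(A = A, B = B, indval_matrix = ivmat, stat = stat, best = best)
}

#' Indicator value (IndVal) of every species for a typology
#'
#' Dufrene-Legendre indicator species analysis. For species `s` and cluster
#' `j`, specificity `A_sj` is the mean importance value of `s` in `j` divided
#' by the sum of its cluster means, and fidelity `B_sj` is the fraction of
#' `j`'s plots where the species occurs. The indicator value of the species is
#' `max_j A_sj * B_sj`, on the 0-1 scale; a species scores 1 when it occurs in
#' every plot of exactly one cluster and nowhere else.
#'
#' @param ivm plots x species importance-value matrix.
#' @param membership named integer vector, plot id -> cluster in `1..k`; must
#'   cover every row of `ivm` and leave no cluster empty.
#' @return Data frame `species, indval, best_cluster` plus attribute
#'   `indval_matrix` (clusters x species `A * B`).
#' @export
indval <- function(ivm, membership) {
  cl <- align_membership(ivm, membership)
  res <- indval_core(ivm, cl)
  out <- data.frame(species = colnames(ivm),
                    indval = res$stat,
                    best_cluster = res$best,
                    stringsAsFactors = FALSE)
  attr(out, "indval_matrix") <- res$indval_matrix
  out
}

align_membership <- function(ivm, membership) {
  if (!is.null(names(membership))) {
    idx <- match(rownames(ivm), names(membership))
    if (anyNA(idx)) stop("membership must cover every plot in the matrix")
    membership <- membership[idx]
  } else if (length(membership) != nrow(ivm)) {
    stop("membership length must match the number of plots")
  }
  as.integer(membership)
}

#' IndVal with permutation p-values
#'
#' Significance of each species' indicator value is assessed by permuting plot
#' labels: `p = (1 + #{permutations with indval* >= observed}) / (n_perm + 1)`,
#' so the smallest attainable p is `1 / (n_perm + 1)`. Plot (not seed) labels
#' are permuted so inference is at the plot level.
#'
#' @inheritParams indval
#' @param n_perm number of label permutations (>= 99).
#' @param rng_seed integer seed, or `NULL` to draw from the current RNG state
#'   (used by [scan_hierarchy()] to keep one stream per scan).
#' @return Data frame `species, indval, best_cluster, p_value`.
#' @export
indval_pvalues <- function(ivm, membership, n_perm = 999L, rng_seed = 1L) {
  if (n_perm < 99L) stop("n_perm must be >= 99")
  cl <- align_membership(ivm, membership)
  k <- max(cl)
  pres <- (ivm > 0) + 0
  obs <- indval_core(ivm, cl, k, pres)
  if (!is.null(rng_seed)) set.seed(as.integer(rng_seed))
  exceed <- integer(ncol(ivm))
  thr <- obs$stat - 1e-12          # tolerate permutation round-off on ties
  for (b in seq_len(n_perm)) {
    perm <- sample(cl)
    stat_b <- indval_core(ivm, perm, k, pres)$stat
    exceed <- exceed + (stat_b >= thr)
  }
  data.frame(species = colnames(ivm),
             indval = obs$stat,
             best_cluster = obs$best,
             p_value = (1 + exceed) / (n_perm + 1),
             stringsAsFactors = FALSE)
}

#' Size-weighted mean silhouette width at the seed level
#'
#' Classical silhouette `s(i) = (b - a) / max(a, b)` evaluated on the seed
#' dissimilarity matrix, with each seed standing for `sizes[i]` plots: the
#' plots collapsed into one seed sit at dissimilarity zero from each other, so
#' `a(i) = sum_{j in C, j != i} n_j d_ij / (N_C - 1)` (with `N_C` the cluster's
#' plot count) and `b(i) = min_{D != C} sum_{j in D} n_j d_ij / N_D`. This
#' equals the plot-level silhouette exactly when seeds are pure duplicates, and
#' reduces to the classical unweighted silhouette when all sizes are 1. Seeds
#' whose cluster holds a single plot score 0.
#'
#' @param d `dist` between seeds (or plots).
#' @param sizes plot count per seed; `NULL` for all-ones.
#' @param membership integer cluster per seed, `>= 2` non-empty clusters.
#' @return Size-weighted mean silhouette width, in `[-1, 1]`.
#' @export
silhouette_mean <- function(d, sizes = NULL, membership) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (is.null(sizes)) sizes <- rep(1, n)
  stopifnot(length(sizes) == n, length(membership) == n)
  cl <- as.integer(membership)
  k <- max(cl)
  if (k < 2L || any(tabulate(cl, k) == 0L))
    stop("silhouettes need >= 2 non-empty clusters")

  G <- matrix(0, n, k)
  G[cbind(seq_len(n), cl)] <- sizes
  M <- dm %*% G                         # M[i, g] = sum_j in g  n_j d_ij
  N <- colSums(G)                       # plots per cluster
  a <- M[cbind(seq_len(n), cl)] / (N[cl] - 1)
  Mb <- sweep(M, 2, N, "/")
  Mb[cbind(seq_len(n), cl)] <- Inf
  b <- apply(Mb, 1, min)
  s <- ifelse(N[cl] == 1, 0,
              ifelse(pmax(a, b) > 0, (b - a) / pmax(a, b), 0))
  sum(s * sizes) / sum(sizes)
}

#' Scan typology cut levels and compute selection diagnostics
#'
#' For every cut level `k` in `k_range` the seed dendrogram is cut, memberships
#' are propagated to plots, indicator species analysis is run with permutation
#' p-values, and the four selection indices are recorded: the sum of
#' significant indicator values, the number of significant indicator species,
#' the mean of significant p-values, and the (size-weighted, seed-level) mean
#' silhouette width, together with whether every cluster has at least one
#' significant indicator species.
#'
#' @param ivm plots x species importance-value matrix.
#' @param dend seed dendrogram ([weighted_average_linkage()]).
#' @param seedset `seed_set` from [kmeans_seed()] (`NULL` if `dend` is on
#'   plots).
#' @param k_range integer vector of length 2, smallest and largest cut level.
#' @param alpha significance level for "significant" species (default 0.05).
#' @param n_perm permutations per level (default 999).
#' @param rng_seed integer seed for the whole scan (one RNG stream).
#' @param d_seed optional precomputed seed dissimilarity (else Bray-Curtis of
#'   the seed centroids).
#' @return Data frame with one row per `k`: `k, sum_sig_indval, n_sig_species,
#'   mean_sig_p, mean_silhouette, all_clusters_covered`.
#' @export
scan_hierarchy <- function(ivm, dend, seedset = NULL,
                           k_range = c(2L, 200L), alpha = 0.05,
                           n_perm = 999L, rng_seed = 1L, d_seed = NULL) {
  n_leaves <- length(dend$order)
  ks <- seq(max(2L, k_range[1]), min(k_range[2], n_leaves))
  if (length(ks) == 0L) stop("k_range contains no feasible level")
  if (is.null(d_seed)) {
    d_seed <- if (is.null(seedset)) bray_curtis(ivm)
              else bray_curtis(seedset$centroids)
  }
  sizes <- if (is.null(seedset)) rep(1, n_leaves) else seedset$sizes
  set.seed(as.integer(rng_seed))
  rows <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    k <- ks[i]
    seed_cl <- stats::cutree(dend, k = k)
    memb <- if (is.null(seedset)) seed_cl else
      stats::setNames(unname(seed_cl[seedset$plot_to_seed]),
                      names(seedset$plot_to_seed))
    res <- indval_pvalues(ivm, memb, n_perm = n_perm, rng_seed = NULL)
    sig <- res$p_value <= alpha
    covered <- all(seq_len(k) %in% res$best_cluster[sig])
    rows[[i]] <- data.frame(
      k = k,
      sum_sig_indval = sum(res$indval[sig]),
      n_sig_species = sum(sig),
      mean_sig_p = if (any(sig)) mean(res$p_value[sig]) else NA_real_,
      mean_silhouette = silhouette_mean(d_seed, sizes, seed_cl),
      all_clusters_covered = covered)
  }
  do.call(rbind, rows)
}

#' Select optimal typologies from scan diagnostics
#'
#' A cut level is eligible only if every cluster has at least one significant
#' indicator species. Within the eligible set each of the four indices is
#' inspected separately -- maximise the sum of significant indicator values,
#' the number of indicator species and the mean silhouette width, minimise the
#' mean significant p-value -- flagging the global best and the local optima
#' (strictly better than both eligible neighbours; boundary rows need only
#' beat their one neighbour) per index. The indices are deliberately not
#' combined into one score; candidates are ranked by how many indices flag
#' them.
#'
#' @param diag diagnostics table from [scan_hierarchy()].
#' @return A list: `table` (diagnostics with per-index `opt_*` flags and
#'   `n_indices_opt`), `candidates` (eligible rows ranked by `n_indices_opt`,
#'   then sum of significant indicator values). Warns and returns empty
#'   candidates when no level is eligible.
#' @export
select_optima <- function(diag) {
  stopifnot(nrow(diag) > 0)
  idx_cols <- c(sum_sig_indval = 1, n_sig_species = 1,
                mean_sig_p = -1, mean_silhouette = 1)
  elig <- which(diag$all_clusters_covered)
  flags <- matrix(FALSE, nrow(diag), length(idx_cols),
                  dimnames = list(NULL, paste0("opt_", names(idx_cols))))
  if (length(elig) == 0L) {
    warning("no cut level has an indicator species in every cluster")
  } else {
    for (j in seq_along(idx_cols)) {
      v <- diag[[names(idx_cols)[j]]][elig] * idx_cols[j]  # maximise v
      v[is.na(v)] <- -Inf                                  # missing never optimal
      if (all(!is.finite(v))) next
      glob <- elig[v == max(v)]
      better_left <- c(TRUE, diff(v) > 0)
      better_right <- c(-diff(v) > 0, TRUE)
      loc <- elig[better_left & better_right & is.finite(v)]
      flags[union(glob, loc), j] <- TRUE
    }
  }
  out <- cbind(diag, flags)
  out$eligible <- diag$all_clusters_covered
  out$n_indices_opt <- rowSums(flags)
  cand <- out[out$eligible & out$n_indices_opt > 0, , drop = FALSE]
  cand <- cand[order(-cand$n_indices_opt, -cand$sum_sig_indval, cand$k), ,
               drop = FALSE]
  list(table = out, candidates = cand)
}
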
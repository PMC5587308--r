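#' Species dominance index per (species, cluster)
#'
#' Within each cluster, the dominance of a species is
#' `SDI = (MC + MSS + THC) / 3` where, with importance values rescaled to the
#' 0-1 range:
#' * `MC` -- mean cover: the species' mean relative IV over all plots of the
#'   cluster (zeros included);
#' * `MSS` -- mean species suppression: the mean inverse plot richness over the
#'   plots where the species occurs;
#' * `THC` -- tendency toward high cover: the fraction of occurrence plots where
#'   the species both exceeds 0.25 relative IV (strictly) and has the most
#'   cover of any species in the plot (ties count as most).
#'
#' The three routes to dominance are thus high cover in many plots, occurrence
#' with few companions, and high cover in the plots it does occupy. Species
#' absent from a cluster get no record.
#'
#' @param ivm plots x species importance-value matrix (0-100 scale).
#' @param membership named integer vector, plot id -> cluster.
#' @param cover_threshold relative-IV threshold of the first THC criterion
#'   (default 0.25, exceeded strictly).
#' @param mc_all_plots if `TRUE`, average `MC` over all plots of the data set
#'   rather than the cluster's plots (non-default reading of "across all
#'   plots").
#' @return Data frame `species, cluster, MC, MSS, THC, SDI, n_occurrence`.
#' @export
compute_sdi <- function(ivm, membership, cover_threshold = 0.25,
                        mc_all_plots = FALSE) {
  cl <- align_membership(ivm, membership)
  v <- ivm / 100
  rich <- rowSums(v > 0)
  rowmax <- apply(v, 1, max)
  k <- max(cl)
  out <- vector("list", k)
  for (j in seq_len(k)) {
    sub <- v[cl == j, , drop = FALSE]
    if (nrow(sub) == 0L) next
    occ <- sub > 0
    n_occ <- colSums(occ)
    keep <- n_occ > 0
    if (!any(keep)) next
    mc <- if (mc_all_plots) colMeans(v) else colMeans(sub)
    mss <- colSums(occ / rich[cl == j]) / pmax(n_occ, 1)
    high <- (sub > cover_threshold) & (sub >= rowmax[cl == j] - 1e-12)
    thc <- colSums(high) / pmax(n_occ, 1)
    sdi <- (mc + mss + thc) / 3
    out[[j]] <- data.frame(species = colnames(v)[keep],
                           cluster = j,
                           MC = unname(mc[keep]),
                           MSS = unname(mss[keep]),
                           THC = unname(thc[keep]),
                           SDI = unname(sdi[keep]),
                           n_occurrence = unname(n_occ[keep]),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Designate dominant species by a pooled SDI percentile cutoff
#'
#' One global cutoff is taken as the given percentile (linear interpolation
#' between order statistics) of the SDI values pooled over all (species,
#' cluster) records; a species is dominant in a cluster when its SDI there is
#' greater than or equal to the cutoff, so records tied at the cutoff all
#' qualify. Raising the percentile can only shrink the dominant sets.
#'
#' @param sdi SDI table from [compute_sdi()].
#' @param percentile percentile of the pooled SDI distribution (default 90;
#'   85 and 95 are the usual alternatives).
#' @return A list: `cutoff`, `percentile`, `table` (the SDI table with a
#'   `dominant` flag), and `dominant` (per-cluster data frames sorted by SDI
#'   descending).
#' @export
dominant_species <- function(sdi, percentile = 90) {
  stopifnot(nrow(sdi) > 0)
  if (percentile < 0 || percentile >= 100)
    stop("percentile must lie in [0, 100); 0 makes every record dominant")
  cutoff <- unname(stats::quantile(sdi$SDI, percentile / 100, type = 7))
  sdi$dominant <- sdi$SDI >= cutoff
  dom <- sdi[sdi$dominant, , drop = FALSE]
  dom <- dom[order(dom$cluster, -dom$SDI), , drop = FALSE]
  rownames(dom) <- NULL
  list(cutoff = cutoff,
       percentile = percentile,
       table = sdi,
       dominant = split(dom, dom$cluster))
}
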
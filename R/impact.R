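#' Screen clusters for the climate-impact case study
#'
#' A cluster enters the impact assessment only when (1) it contains at least
#' `min_plots` plots, (2) every one of its dominant species has a projection
#' under the scenario, and (3) more than half of its dominant species carry at
#' least medium projection reliability. Excluded clusters are reported with the
#' first criterion they fail.
#'
#' @param membership named integer vector, plot id -> cluster.
#' @param dominant result of [dominant_species()].
#' @param delta projection table: `plot_id, species, scenario, delta_iv,
#'   reliability` (and optionally `current_iv`).
#' @param scenario scenario label to screen against.
#' @param min_plots minimum cluster size (default 100).
#' @param min_majority_reliability grade the majority of dominant species must
#'   reach (default `"medium"`).
#' @param require_all_dominant_projected drop clusters with any unprojected
#'   dominant species (default `TRUE`).
#' @return Data frame `cluster, n_plots, n_dominant, eligible, reason`.
#' @export
eligible_clusters <- function(membership, dominant, delta, scenario,
                              min_plots = 100L,
                              min_majority_reliability = c("medium", "high", "low"),
                              require_all_dominant_projected = TRUE) {
  if (min_plots < 1L) stop("min_plots must be >= 1")
  min_majority_reliability <- match.arg(min_majority_reliability)
  grade <- c(low = 1L, medium = 2L, high = 3L)
  need <- grade[min_majority_reliability]
  del <- delta[delta$scenario == scenario, , drop = FALSE]
  proj_sp <- unique(del$species)
  rel_of <- tapply(grade[del$reliability], del$species, function(g) g[1])

  clusters <- sort(unique(as.integer(membership)))
  rows <- lapply(clusters, function(j) {
    dom <- dominant$dominant[[as.character(j)]]
    dom_sp <- if (is.null(dom)) character(0) else dom$species
    n_p <- sum(membership == j)
    reason <- ""
    if (n_p < min_plots) {
      reason <- "min_plots"
    } else if (length(dom_sp) == 0L) {
      reason <- "no dominant species"
    } else if (require_all_dominant_projected && !all(dom_sp %in% proj_sp)) {
      reason <- "missing projection"
    } else if (mean(rel_of[dom_sp] >= need, na.rm = FALSE) <= 0.5) {
      reason <- "reliability"
    }
    data.frame(cluster = j, n_plots = n_p, n_dominant = length(dom_sp),
               eligible = reason == "", reason = reason,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# delta values of the dominant species at the cluster's plots, as a
# plots x species matrix (error on any missing projection)
delta_matrix <- function(plot_ids, dom_sp, delta, scenario, value = "delta_iv") {
  del <- delta[delta$scenario == scenario & delta$species %in% dom_sp &
                 delta$plot_id %in% plot_ids, , drop = FALSE]
  m <- matrix(NA_real_, length(plot_ids), length(dom_sp),
              dimnames = list(plot_ids, dom_sp))
  m[cbind(match(del$plot_id, plot_ids), match(del$species, dom_sp))] <-
    del[[value]]
  if (anyNA(m))
    stop("missing ", value, " projection for a dominant species at some plot",
         " (scenario ", scenario, ")")
  m
}

#' SDI-weighted assemblage impact of a scenario on one cluster
#'
#' The impact statistic is the mean projected change in importance value of the
#' cluster's dominant species over all its plots, each species weighted by its
#' SDI: `sum_p sum_s SDI_s * delta_{p,s} / (n_plots * sum_s SDI_s)`. When the
#' projection table carries `current_iv`, a percent change is also reported,
#' relative to the SDI-weighted mean current IV of the dominant species over
#' the same plots (the raw weighted mean change is always reported alongside,
#' since the percentage baseline is a convention).
#'
#' @param membership named integer vector, plot id -> cluster.
#' @param cluster cluster id to summarise (must be eligible).
#' @param dominant result of [dominant_species()] (per-species SDI weights).
#' @param delta projection table (see [eligible_clusters()]).
#' @param scenario scenario label.
#' @return One-row data frame `cluster, scenario, weighted_mean_delta,
#'   percent_change, n_plots, n_dominant`.
#' @export
assemblage_impact <- function(membership, cluster, dominant, delta, scenario) {
  plots <- names(membership)[membership == cluster]
  dom <- dominant$dominant[[as.character(cluster)]]
  if (is.null(dom) || nrow(dom) == 0L)
    stop("cluster ", cluster, " has no dominant species")
  w <- dom$SDI
  D <- delta_matrix(plots, dom$species, delta, scenario)
  wmd <- sum(colMeans(D) * w) / sum(w)
  pct <- NA_real_
  if ("current_iv" %in% names(delta) && !anyNA(delta$current_iv)) {
    Cur <- delta_matrix(plots, dom$species, delta, scenario, "current_iv")
    base <- sum(colMeans(Cur) * w) / sum(w)
    if (base != 0) pct <- wmd / base * 100
  }
  data.frame(cluster = cluster, scenario = scenario,
             weighted_mean_delta = wmd, percent_change = pct,
             n_plots = length(plots), n_dominant = nrow(dom),
             stringsAsFactors = FALSE)
}

#' Per-plot mean projected change across an assemblage's dominant species
#'
#' The spatial companion of [assemblage_impact()]: at each plot of the cluster,
#' the unweighted mean of the projected IV changes of the cluster's dominant
#' species, suitable for mapping once joined to plot coordinates.
#'
#' @inheritParams assemblage_impact
#' @param coords optional data frame `plot_id, x, y` to join.
#' @return Data frame `plot_id, cluster, scenario, mean_delta` (+ `x`, `y`).
#' @export
plot_impact <- function(membership, cluster, dominant, delta, scenario,
                        coords = NULL) {
  plots <- names(membership)[membership == cluster]
  dom <- dominant$dominant[[as.character(cluster)]]
  if (is.null(dom) || nrow(dom) == 0L)
    stop("cluster ", cluster, " has no dominant species")
  D <- delta_matrix(plots, dom$species, delta, scenario)
  out <- data.frame(plot_id = plots, cluster = cluster, scenario = scenario,
                    mean_delta = rowMeans(D), stringsAsFactors = FALSE)
  if (!is.null(coords))
    out <- merge(out, unique(coords[, c("plot_id", "x", "y")]),
                 by = "plot_id", all.x = TRUE, sort = TRUE)
  rownames(out) <- NULL
  out
}

#' Impact summaries for every eligible cluster under one or more scenarios
#'
#' Convenience wrapper running [eligible_clusters()], [assemblage_impact()] and
#' [plot_impact()] over all clusters and scenarios.
#'
#' @inheritParams eligible_clusters
#' @param scenarios scenario labels (default: all in `delta`).
#' @param coords optional plot coordinates for the per-plot table.
#' @return List with `eligibility`, `summary` (one row per eligible cluster x
#'   scenario) and `plots` (per-plot mean changes).
#' @export
impact_assessment <- function(membership, dominant, delta,
                              scenarios = unique(delta$scenario),
                              min_plots = 100L, coords = NULL, ...) {
  elig_all <- list(); summ <- list(); per_plot <- list()
  for (sc in scenarios) {
    el <- eligible_clusters(membership, dominant, delta, sc,
                            min_plots = min_plots, ...)
    el$scenario <- sc
    elig_all[[sc]] <- el
    for (j in el$cluster[el$eligible]) {
      summ[[paste(sc, j)]] <-
        assemblage_impact(membership, j, dominant, delta, sc)
      per_plot[[paste(sc, j)]] <-
        plot_impact(membership, j, dominant, delta, sc, coords)
    }
  }
  list(eligibility = rbind_list(elig_all),
       summary = rbind_list(summ),
       plots = rbind_list(per_plot))
}

rbind_list <- function(l) {
  if (length(l) == 0L) return(NULL)
  out <- do.call(rbind, c(l, list(make.row.names = FALSE)))
  rownames(out) <- NULL
  out
}
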
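#' Run the full typology pipeline on a synthetic inventory
#'
#' End-to-end driver used for validation studies and by the command-line
#' interface: simulate an inventory from planted assemblage templates,
#' preprocess it into the importance-value matrix, seed with k-means, build the
#' size-weighted UPGMA hierarchy on Bray-Curtis dissimilarities between seed
#' centroids, scan cut levels with indicator-species diagnostics, pick the
#' typology, compute species dominance indices and dominant species, simulate
#' projected importance-value changes, and aggregate them to assemblage impact
#' summaries. Every random step derives its seed from `config$rng_seed`, so a
#' repeated run writes byte-identical tables.
#'
#' @param config a [synthetic_config()] describing the study.
#' @param out_dir directory for the output tables (created if needed); `NULL`
#'   skips writing.
#' @param min_plots_frac rare-species threshold as a fraction of the plot count
#'   (default 0.002, i.e. 0.2 percent of plots, floored at 2).
#' @param k_seeds number of k-means seeds (default [default_seed_k()]).
#' @param k_range cut levels to scan (default 2 up to `min(200, seeds - 1)`).
#' @param choose_k cut level for the reported typology; `NULL` picks the
#'   top-ranked candidate of [select_optima()].
#' @param alpha,n_perm indicator-significance settings (defaults 0.05, 999).
#' @param percentile pooled SDI percentile for dominance (default 90).
#' @param min_impact_plots cluster-size floor of the impact stage (default
#'   100).
#' @param surface optional [delta_iv_config()]; by default one is drawn from
#'   `config$rng_seed` over all retained species.
#' @return Invisibly, a list with every intermediate object (`records`,
#'   `labels`, `ivm`, `seeds`, `dend`, `diagnostics`, `optima`, `chosen_k`,
#'   `membership`, `indicators`, `sdi`, `dominant`, `delta`, `impact`).
#' @export
run_pipeline <- function(config = synthetic_config(),
                         out_dir = NULL,
                         min_plots_frac = 0.002,
                         k_seeds = NULL,
                         k_range = NULL,
                         choose_k = NULL,
                         alpha = 0.05,
                         n_perm = 999L,
                         percentile = 90,
                         min_impact_plots = 100L,
                         surface = NULL) {
  templates <- make_templates(config)
  sim <- simulate_inventory(templates, config)
  records <- filter_plots(sim$records)
  min_plots <- max(2L, round(min_plots_frac * config$n_plots))
  records <- filter_rare_species(records, min_plots = min_plots)
  ivm <- compute_iv(records)

  if (is.null(k_seeds)) k_seeds <- default_seed_k(nrow(ivm))
  k_seeds <- min(k_seeds, nrow(unique(ivm)))
  seeds <- kmeans_seed(ivm, k_seeds, rng_seed = config$rng_seed + 2L)
  d_seed <- bray_curtis(seeds$centroids)
  dend <- weighted_average_linkage(d_seed, seeds$sizes)

  if (is.null(k_range)) k_range <- c(2L, min(200L, k_seeds - 1L))
  diagnostics <- scan_hierarchy(ivm, dend, seeds, k_range = k_range,
                                alpha = alpha, n_perm = n_perm,
                                rng_seed = config$rng_seed + 3L,
                                d_seed = d_seed)
  optima <- select_optima(diagnostics)
  chosen_k <- if (!is.null(choose_k)) choose_k
              else if (nrow(optima$candidates) > 0) optima$candidates$k[1]
              else diagnostics$k[which.max(diagnostics$sum_sig_indval)]
  membership <- cut_typology(dend, seeds, chosen_k)
  indicators <- indval_pvalues(ivm, membership, n_perm = n_perm,
                               rng_seed = config$rng_seed + 4L)
  sdi <- compute_sdi(ivm, membership)
  dominant <- dominant_species(sdi, percentile = percentile)

  if (is.null(surface))
    surface <- delta_iv_config(colnames(ivm), rng_seed = config$rng_seed + 5L)
  delta <- simulate_delta_iv(records, surface, ivm = ivm)
  coords <- unique(records[, c("plot_id", "x", "y")])
  impact <- impact_assessment(membership, dominant, delta,
                              min_plots = min_impact_plots, coords = coords)

  result <- list(templates = templates, records = records, labels = sim$labels,
                 ivm = ivm, seeds = seeds, dend = dend,
                 diagnostics = diagnostics, optima = optima,
                 chosen_k = chosen_k, membership = membership,
                 indicators = indicators, sdi = sdi, dominant = dominant,
                 delta = delta, impact = impact)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  invisible(result)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write every pipeline table to a directory
#'
#' Tab-separated text throughout: tree records, true template labels, the IV
#' matrix, seed assignments, the dendrogram (Newick), the diagnostics scan,
#' plot memberships at the chosen level, the indicator table, the SDI table
#' with dominance flags, the projection table, and the impact summaries.
#'
#' @param result list returned by [run_pipeline()].
#' @param out_dir target directory.
#' @return Invisibly, the directory.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_records(result$records, p("records.tsv"))
  write_tsv(result$labels, p("true_labels.tsv"))
  write_iv_matrix(result$ivm, p("iv_matrix.tsv"))
  write_tsv(data.frame(plot_id = names(result$seeds$plot_to_seed),
                       seed = unname(result$seeds$plot_to_seed)),
            p("seed_assignment.tsv"))
  writeLines(export_newick(result$dend), p("dendrogram.nwk"))
  write_tsv(result$diagnostics, p("diagnostics.tsv"))
  write_tsv(result$optima$table, p("selection.tsv"))
  write_tsv(data.frame(plot_id = names(result$membership),
                       cluster = unname(result$membership)),
            p("membership.tsv"))
  write_tsv(result$indicators, p("indicators.tsv"))
  sdi <- result$dominant$table
  sdi$cutoff <- result$dominant$cutoff
  write_tsv(sdi, p("sdi.tsv"))
  write_tsv(result$delta, p("delta_iv.tsv"))
  if (!is.null(result$impact$summary))
    write_tsv(result$impact$summary, p("impact_summary.tsv"))
  if (!is.null(result$impact$plots))
    write_tsv(result$impact$plots, p("impact_plots.tsv"))
  write_tsv(result$impact$eligibility, p("impact_eligibility.tsv"))
  invisible(out_dir)
}
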
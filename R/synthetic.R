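#' Configuration for the synthetic forest-inventory generator
#'
#' Bundles the parameters of the planted-assemblage simulator. Plots are drawn
#' from a set of assemblage templates, each with its own species pool, a pair
#' of (near-)exclusive indicator species, and skewed expected importance-value
#' shares. The defaults describe the standard validation study used throughout
#' the package: 4 assemblages, 800 plots, 32 species, plot richness between 1
#' and 12 species.
#'
#' @param n_templates number of planted assemblage templates.
#' @param n_plots number of inventory plots to simulate.
#' @param n_species total size of the species pool (codes `SP001`, ...).
#' @param richness_range integer vector of length 2, minimum and maximum
#'   species per plot.
#' @param noise_sd standard deviation of the Gaussian noise added to the log
#'   basal-area shares of a plot. `0` reproduces the template shares exactly.
#' @param mixing_prob probability that a plot borrows one species from a
#'   foreign template.
#' @param indicators_per_template number of exclusive indicator species per
#'   template (occupancy probability 0.9).
#' @param mean_stems expected number of tree stems per plot.
#' @param rng_seed integer seed; all randomness in the generator derives from
#'   it, so equal configurations give byte-identical output tables.
#'
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_templates = 4L,
                             n_plots = 800L,
                             n_species = 32L,
                             richness_range = c(1L, 12L),
                             noise_sd = 0.35,
                             mixing_prob = 0.05,
                             indicators_per_template = 2L,
                             mean_stems = 18,
                             rng_seed = 1L) {
  cfg <- list(
    n_templates = as.integer(n_templates),
    n_plots = as.integer(n_plots),
    n_species = as.integer(n_species),
    richness_range = as.integer(richness_range),
    noise_sd = noise_sd,
    mixing_prob = mixing_prob,
    indicators_per_template = as.integer(indicators_per_template),
    mean_stems = mean_stems,
    rng_seed = as.integer(rng_seed)
  )
  if (cfg$n_templates < 1L || cfg$n_plots < 1L || cfg$n_species < 1L)
    stop("n_templates, n_plots and n_species must be positive")
  if (length(cfg$richness_range) != 2L ||
      cfg$richness_range[1] < 1L ||
      cfg$richness_range[2] < cfg$richness_range[1] ||
      cfg$richness_range[2] > cfg$n_species)
    stop("richness_range must satisfy 1 <= min <= max <= n_species")
  if (cfg$mixing_prob < 0 || cfg$mixing_prob > 1)
    stop("mixing_prob must lie in [0, 1]")
  if (cfg$noise_sd < 0) stop("noise_sd must be nonnegative")
  class(cfg) <- "synthetic_config"
  cfg
}

species_codes <- function(n) sprintf("SP%03d", seq_len(n))

#' Build planted assemblage templates
#'
#' Splits the species pool into per-template assemblages. Each template
#' receives `indicators_per_template` exclusive indicator species (occupancy
#' probability 0.9) plus a random draw of shared species; indicator species of
#' distinct templates are disjoint. Expected importance-value shares are skewed
#' exponentials with indicator species up-weighted, normalised to sum to 1.
#'
#' @param config a [synthetic_config()].
#' @return A list of `assemblage_template` objects, each with fields
#'   `template_id`, `species_pool`, `occupancy_prob`, `mean_iv_share` and
#'   `indicator_species`.
#' @export
make_templates <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n_t <- config$n_templates
  ipt <- config$indicators_per_template
  if (config$n_species < 2L * n_t)
    stop("infeasible config: need n_species >= 2 * n_templates (",
         2L * n_t, " species for ", n_t, " templates)")
  if (config$n_species < n_t * ipt)
    stop("infeasible config: ", n_t, " templates with ", ipt,
         " disjoint indicator species each need >= ", n_t * ipt, " species")

  set.seed(config$rng_seed)
  sp <- species_codes(config$n_species)
  ind_idx <- matrix(seq_len(n_t * ipt), nrow = n_t, byrow = TRUE)
  shared <- sp[-seq_len(n_t * ipt)]
  n_extra <- min(length(shared), max(2L, config$richness_range[2]))

  templates <- vector("list", n_t)
  for (t in seq_len(n_t)) {
    indicators <- sp[ind_idx[t, ]]
    extra <- if (n_extra > 0L) sample(shared, n_extra) else character(0)
    pool <- c(indicators, extra)
    occ <- stats::setNames(stats::runif(length(pool), 0.15, 0.6), pool)
    occ[indicators] <- 0.9
    w <- stats::rexp(length(pool))
    w[seq_along(indicators)] <- 2.5 + stats::rexp(length(indicators))
    share <- stats::setNames(w / sum(w), pool)
    templates[[t]] <- structure(
      list(template_id = sprintf("T%d", t),
           species_pool = pool,
           occupancy_prob = occ,
           mean_iv_share = share,
           indicator_species = indicators),
      class = "assemblage_template")
  }
  templates
}

validate_templates <- function(templates) {
  ind <- unlist(lapply(templates, `[[`, "indicator_species"))
  if (anyDuplicated(ind)) stop("indicator species of templates must be disjoint")
  for (tp in templates) {
    if (abs(sum(tp$mean_iv_share) - 1) > 1e-9)
      stop("mean_iv_share of template ", tp$template_id, " does not sum to 1")
    if (any(tp$occupancy_prob[tp$indicator_species] < 0.8))
      stop("indicator occupancy below 0.8 in template ", tp$template_id)
  }
  invisible(templates)
}

#' Simulate a per-stem forest inventory from assemblage templates
#'
#' Draws each plot from one template: species are included independently with
#' their occupancy probabilities (richness clamped to `richness_range`, keeping
#' indicator species preferentially), every plot is guaranteed at least one of
#' its template's indicator species so that the planted labels remain
#' recoverable, basal-area shares are normalised
#' exponentials of Gaussian-perturbed log template shares, stem counts are
#' proportional to shares with a floor of one stem, and with probability
#' `mixing_prob` the plot borrows one species from a foreign template. Plot
#' coordinates are uniform on the unit square and `region_code` is `west`
#' (x < 0.5) or `east`.
#'
#' @param templates output of [make_templates()].
#' @param config the same [synthetic_config()].
#' @return A list with `records` (a per-stem tree record table: `plot_id`,
#'   `species_code`, `dbh_cm`, `basal_area_m2`, `region_code`, `plot_flags`,
#'   `x`, `y`) and `labels` (true `plot_id` -> `template_id` assignments).
#' @export
simulate_inventory <- function(templates, config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_templates(templates)
  set.seed(config$rng_seed + 1L)

  n_p <- config$n_plots
  rmin <- config$richness_range[1]
  rmax <- config$richness_range[2]
  plot_ids <- sprintf("P%05d", seq_len(n_p))
  tpl_of <- sample(length(templates), n_p, replace = TRUE)
  x <- stats::runif(n_p)
  y <- stats::runif(n_p)
  all_sp <- species_codes(config$n_species)

  recs <- vector("list", n_p)
  for (i in seq_len(n_p)) {
    tp <- templates[[tpl_of[i]]]
    pool <- tp$species_pool
    keep <- stats::runif(length(pool)) < tp$occupancy_prob
    sel <- pool[keep]
    # planted-structure guarantee: every plot carries at least one of its
    # template's indicator species, so truth labels stay recoverable
    if (!any(tp$indicator_species %in% sel))
      sel <- c(tp$indicator_species[1], sel)
    # clamp richness into range; indicators are the last to be dropped
    lo <- min(rmin, length(pool))
    if (length(sel) < lo) {
      add <- setdiff(pool[order(tp$occupancy_prob, decreasing = TRUE)], sel)
      sel <- c(sel, add[seq_len(lo - length(sel))])
    }
    if (length(sel) > rmax) {
      extras <- setdiff(sel, tp$indicator_species)
      n_drop <- length(sel) - rmax
      drop <- if (length(extras) >= n_drop) sample(extras, n_drop) else
        c(extras, sample(intersect(sel, tp$indicator_species),
                         n_drop - length(extras)))
      sel <- setdiff(sel, drop)
    }
    if (stats::runif(1) < config$mixing_prob) {
      foreign <- setdiff(all_sp, pool)
      if (length(foreign) > 0L) {
        borrow <- sample(foreign, 1L)
        if (length(sel) >= rmax) sel[length(sel)] <- borrow
        else sel <- c(sel, borrow)
      }
    }
    base_share <- tp$mean_iv_share[match(sel, pool)]
    base_share[is.na(base_share)] <- mean(tp$mean_iv_share)  # borrowed species
    logw <- log(base_share) + stats::rnorm(length(sel), 0, config$noise_sd)
    share <- exp(logw - max(logw))
    share <- share / sum(share)

    n_tot <- max(length(sel), stats::rpois(1L, config$mean_stems))
    stems <- pmax(1L, round(share * n_tot))
    ba_tot <- stats::rlnorm(1L, meanlog = log(1.5), sdlog = 0.4)
    ba_sp <- share * ba_tot

    sp_col <- rep(sel, stems)
    u <- stats::rexp(sum(stems))
    ba_stem <- unlist(lapply(seq_along(sel), function(s) {
      idx <- sum(stems[seq_len(s - 1L)]) + seq_len(stems[s])
      ba_sp[s] * u[idx] / sum(u[idx])
    }), use.names = FALSE)
    recs[[i]] <- data.frame(
      plot_id = plot_ids[i],
      species_code = sp_col,
      basal_area_m2 = ba_stem,
      stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, recs)
  records$dbh_cm <- 200 * sqrt(records$basal_area_m2 / pi)
  idx <- match(records$plot_id, plot_ids)
  records$region_code <- ifelse(x[idx] < 0.5, "west", "east")
  records$plot_flags <- ""
  records$x <- x[idx]
  records$y <- y[idx]
  records <- records[, c("plot_id", "species_code", "dbh_cm", "basal_area_m2",
                         "region_code", "plot_flags", "x", "y")]
  rownames(records) <- NULL
  labels <- data.frame(plot_id = plot_ids,
                       template_id = vapply(templates, `[[`, "",
                                            "template_id")[tpl_of],
                       stringsAsFactors = FALSE)
  list(records = records, labels = labels)
}

#' Configuration of projected importance-value change surfaces
#'
#' Describes, per species and climate scenario, a smooth linear trend surface
#' `delta_iv(x, y) = b0 + bx * x + by * y` together with a projection
#' reliability grade. When `coefficients` or `reliability` are not supplied
#' they are drawn at random from the given seed: intercepts N(0, 4) scaled by
#' `scenario_scale`, slopes N(0, 6), grades sampled with weights 0.15 / 0.35 /
#' 0.50 for low / medium / high.
#'
#' @param species character vector of species codes to project.
#' @param scenarios scenario labels (default a mild and a severe scenario).
#' @param coefficients optional data frame `species, scenario, b0, bx, by`.
#' @param reliability optional data frame `species, scenario, reliability` with
#'   grades in `low`, `medium`, `high`.
#' @param scenario_scale named multiplier on the random trend magnitudes per
#'   scenario; ignored when `coefficients` is supplied.
#' @param rng_seed integer seed for the random draws.
#' @return A list of class `delta_iv_config`.
#' @export
delta_iv_config <- function(species,
                            scenarios = c("PCM_Low", "Hadley_High"),
                            coefficients = NULL,
                            reliability = NULL,
                            scenario_scale = NULL,
                            rng_seed = 1L) {
  set.seed(as.integer(rng_seed))
  grid <- expand.grid(species = species, scenario = scenarios,
                      stringsAsFactors = FALSE)
  if (is.null(scenario_scale))
    scenario_scale <- stats::setNames(seq(1, 2.5, length.out = length(scenarios)),
                                      scenarios)
  if (is.null(coefficients)) {
    sc <- scenario_scale[grid$scenario]
    coefficients <- data.frame(
      grid,
      b0 = stats::rnorm(nrow(grid), 0, 4) * sc,
      bx = stats::rnorm(nrow(grid), 0, 6) * sc,
      by = stats::rnorm(nrow(grid), 0, 6) * sc,
      stringsAsFactors = FALSE)
  }
  if (is.null(reliability)) {
    reliability <- data.frame(
      grid,
      reliability = sample(c("low", "medium", "high"), nrow(grid),
                           replace = TRUE, prob = c(0.15, 0.35, 0.5)),
      stringsAsFactors = FALSE)
  }
  need <- merge(grid, coefficients, all.x = TRUE)
  if (anyNA(need$b0)) stop("coefficients missing for some (species, scenario)")
  need_r <- merge(grid, reliability, all.x = TRUE)
  if (anyNA(need_r$reliability) ||
      !all(need_r$reliability %in% c("low", "medium", "high")))
    stop("every species needs a reliability grade in {low, medium, high} for every scenario")
  structure(list(species = species, scenarios = scenarios,
                 coefficients = coefficients, reliability = reliability),
            class = "delta_iv_config")
}

#' Simulate projected importance-value changes over plot locations
#'
#' Evaluates each species x scenario trend surface of a [delta_iv_config()] at
#' the plot coordinates of an inventory, producing one row per (plot, species,
#' scenario). When an importance-value matrix is supplied, the plot's current
#' IV for the species is attached as the `current_iv` baseline (0 where the
#' species is absent).
#'
#' @param records tree record table carrying `plot_id`, `x`, `y` (one
#'   coordinate pair per plot), e.g. from [simulate_inventory()].
#' @param surface a [delta_iv_config()].
#' @param ivm optional importance-value matrix (see [compute_iv()]) used to
#'   fill `current_iv`.
#' @return A data frame `plot_id, species, scenario, delta_iv, current_iv,
#'   reliability` with finite `delta_iv` everywhere.
#' @export
simulate_delta_iv <- function(records, surface, ivm = NULL) {
  stopifnot(inherits(surface, "delta_iv_config"))
  if (!all(c("x", "y") %in% names(records)) ||
      anyNA(records$x) || anyNA(records$y))
    stop("records must carry complete x, y plot coordinates")
  coords <- unique(records[, c("plot_id", "x", "y")])
  if (anyDuplicated(coords$plot_id))
    stop("plots must have a single coordinate pair")

  co <- surface$coefficients
  out <- merge(expand.grid(plot_id = coords$plot_id,
                           key = seq_len(nrow(co)),
                           stringsAsFactors = FALSE),
               cbind(key = seq_len(nrow(co)), co))
  out <- merge(out, coords, by = "plot_id")
  out$delta_iv <- out$b0 + out$bx * out$x + out$by * out$y
  out <- merge(out, surface$reliability, by = c("species", "scenario"))
  out$current_iv <- 0
  if (!is.null(ivm)) {
    pi_ <- match(out$plot_id, rownames(ivm))
    si <- match(out$species, colnames(ivm))
    ok <- !is.na(pi_) & !is.na(si)
    out$current_iv[ok] <- ivm[cbind(pi_[ok], si[ok])]
  }
  out <- out[order(out$scenario, out$plot_id, out$species),
             c("plot_id", "species", "scenario", "delta_iv", "current_iv",
               "reliability")]
  rownames(out) <- NULL
  out
}
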
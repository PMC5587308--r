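# Hand-built dominance objects and projection tables for the impact stage.

make_dominant <- function(clusters, species, sdis) {
  tabs <- Map(function(cl, sp, w) {
    data.frame(species = sp, cluster = cl, SDI = w, dominant = TRUE,
               stringsAsFactors = FALSE)
  }, clusters, species, sdis)
  names(tabs) <- as.character(clusters)
  list(cutoff = NA_real_, table = do.call(rbind, tabs), dominant = tabs)
}

make_delta <- function(plot_ids, species, scenario, delta,
                       reliability = "high", current_iv = NULL) {
  g <- expand.grid(plot_id = plot_ids, species = species,
                   stringsAsFactors = FALSE)
  g$scenario <- scenario
  g$delta_iv <- delta
  g$reliability <- reliability
  if (!is.null(current_iv)) g$current_iv <- current_iv
  g
}

test_that("eligibility applies the three screening criteria in order", {
  memb <- setNames(c(rep(1L, 99), rep(2L, 120), rep(3L, 150), rep(4L, 150)),
                   sprintf("p%03d", 1:519))
  dom <- make_dominant(1:4,
                       list("A", c("A", "B", "C"), c("A", "Z"), c("A", "B")),
                       list(0.5, c(0.4, 0.3, 0.2), c(0.4, 0.3), c(0.4, 0.3)))
  delta <- make_delta(names(memb), c("A", "B", "C"), "S1", 1)
  delta$reliability[delta$species == "A"] <- "high"
  delta$reliability[delta$species == "B"] <- "medium"
  delta$reliability[delta$species == "C"] <- "low"

  el <- eligible_clusters(memb, dom, delta, "S1", min_plots = 100)
  expect_equal(el$reason[el$cluster == 1], "min_plots")       # 99 < 100
  expect_true(el$eligible[el$cluster == 2])                   # 2/3 >= medium
  expect_equal(el$reason[el$cluster == 3], "missing projection")
  expect_true(el$eligible[el$cluster == 4])

  # flip the majority below half: one of two dominants at low reliability
  delta$reliability[delta$species == "B"] <- "low"
  el2 <- eligible_clusters(memb, dom, delta, "S1", min_plots = 100)
  expect_equal(el2$reason[el2$cluster == 4], "reliability")
})

test_that("assemblage impact is the SDI-weighted mean of projected changes", {
  memb <- setNames(rep(1L, 10), sprintf("p%02d", 1:10))
  # one dominant species with a constant field: impact = c
  dom1 <- make_dominant(1, list("A"), list(0.37))
  d1 <- make_delta(names(memb), "A", "S1", -4.2)
  expect_equal(assemblage_impact(memb, 1, dom1, d1, "S1")$weighted_mean_delta,
               -4.2, tolerance = 1e-12)

  # two dominants, SDIs (0.6, 0.2), plot-constant deltas (-10, +30) -> 0
  dom2 <- make_dominant(1, list(c("A", "B")), list(c(0.6, 0.2)))
  d2 <- rbind(make_delta(names(memb), "A", "S1", -10),
              make_delta(names(memb), "B", "S1", 30))
  expect_equal(assemblage_impact(memb, 1, dom2, d2, "S1")$weighted_mean_delta,
               0, tolerance = 1e-12)

  # null projection
  d0 <- rbind(make_delta(names(memb), "A", "S1", 0),
              make_delta(names(memb), "B", "S1", 0))
  expect_equal(assemblage_impact(memb, 1, dom2, d0, "S1")$weighted_mean_delta,
               0)

  # missing projections error out
  expect_error(assemblage_impact(memb, 1, dom2, d2[-1, ], "S1"), "missing")
})

test_that("impact is a convex combination and scales with the field", {
  set.seed(51)
  memb <- setNames(rep(1L, 25), sprintf("p%02d", 1:25))
  dom <- make_dominant(1, list(c("A", "B", "C")), list(c(0.5, 0.3, 0.1)))
  d <- rbind(make_delta(names(memb), "A", "S1", rnorm(25, 2, 5)),
             make_delta(names(memb), "B", "S1", rnorm(25, -3, 5)),
             make_delta(names(memb), "C", "S1", rnorm(25, 0, 5)))
  imp <- assemblage_impact(memb, 1, dom, d, "S1")$weighted_mean_delta
  expect_gte(imp, min(d$delta_iv) - 1e-9)
  expect_lte(imp, max(d$delta_iv) + 1e-9)

  d7 <- d
  d7$delta_iv <- 7 * d7$delta_iv
  expect_equal(assemblage_impact(memb, 1, dom, d7, "S1")$weighted_mean_delta,
               7 * imp, tolerance = 1e-9)
  pl <- plot_impact(memb, 1, dom, d, "S1")
  pl7 <- plot_impact(memb, 1, dom, d7, "S1")
  expect_equal(pl7$mean_delta, 7 * pl$mean_delta, tolerance = 1e-9)
})

test_that("per-plot impacts are plain means and agree with equal-SDI aggregation", {
  memb <- setNames(rep(1L, 8), sprintf("p%02d", 1:8))
  dom1 <- make_dominant(1, list("A"), list(0.4))
  d <- make_delta(names(memb), "A", "S1", seq(-4, 3))
  pl <- plot_impact(memb, 1, dom1, d, "S1")
  expect_equal(pl$mean_delta[order(pl$plot_id)], seq(-4, 3))

  # symmetric pair of dominants cancels
  dom2 <- make_dominant(1, list(c("A", "B")), list(c(0.3, 0.3)))
  ds <- rbind(make_delta(names(memb), "A", "S1", 5),
              make_delta(names(memb), "B", "S1", -5))
  expect_true(all(plot_impact(memb, 1, dom2, ds, "S1")$mean_delta == 0))

  # with equal SDIs the mean of per-plot impacts equals the assemblage impact
  set.seed(52)
  de <- rbind(make_delta(names(memb), "A", "S1", rnorm(8)),
              make_delta(names(memb), "B", "S1", rnorm(8)))
  pl2 <- plot_impact(memb, 1, dom2, de, "S1")
  agg <- assemblage_impact(memb, 1, dom2, de, "S1")$weighted_mean_delta
  expect_equal(mean(pl2$mean_delta), agg, tolerance = 1e-9)
})

test_that("percent change uses the SDI-weighted current-IV baseline", {
  memb <- setNames(rep(1L, 4), paste0("p", 1:4))
  dom <- make_dominant(1, list("A"), list(0.5))
  d <- make_delta(names(memb), "A", "S1", -5, current_iv = 20)
  out <- assemblage_impact(memb, 1, dom, d, "S1")
  expect_equal(out$percent_change, -25)
  expect_equal(out$weighted_mean_delta, -5)
})

test_that("the assessment wrapper summarises every eligible cluster and scenario", {
  memb <- setNames(rep(1:2, each = 60), sprintf("p%03d", 1:120))
  dom <- make_dominant(1:2, list("A", "B"), list(0.5, 0.4))
  delta <- rbind(make_delta(names(memb), "A", "S1", 2),
                 make_delta(names(memb), "B", "S1", -1),
                 make_delta(names(memb), "A", "S2", 4),
                 make_delta(names(memb), "B", "S2", -2))
  res <- impact_assessment(memb, dom, delta, min_plots = 50)
  expect_equal(nrow(res$summary), 4)
  expect_equal(sort(res$summary$weighted_mean_delta), c(-2, -1, 2, 4))
  expect_equal(nrow(res$plots), 4 * 60)
  expect_true(all(res$eligibility$eligible))
})
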
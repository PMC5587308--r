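test_that("indicator values follow the specificity-by-fidelity definition", {
  # species IVs (10, 10 | 0, 30): A1 = 10/25 = 0.4, B1 = 1 -> indval 0.4
  ivm <- cbind(s = c(10, 10, 0, 30), other = c(90, 90, 100, 70))
  rownames(ivm) <- paste0("p", 1:4)
  memb <- setNames(c(1L, 1L, 2L, 2L), rownames(ivm))
  res <- indval(ivm, memb)
  expect_equal(res$indval[res$species == "s"], 0.4, tolerance = 1e-12)
  expect_equal(res$best_cluster[res$species == "s"], 1L)

  # perfect specificity and fidelity
  perfect <- cbind(a = c(100, 100, 0, 0), b = c(0, 0, 100, 100))
  rownames(perfect) <- paste0("p", 1:4)
  res2 <- indval(perfect, setNames(c(1L, 1L, 2L, 2L), rownames(perfect)))
  expect_equal(res2$indval, c(1, 1))

  # identical means and full presence -> indval 1/k
  flat <- matrix(50, 6, 2, dimnames = list(paste0("p", 1:6), c("a", "b")))
  res3 <- indval(flat, setNames(rep(1:3, each = 2), rownames(flat)))
  expect_equal(res3$indval, c(1 / 3, 1 / 3), tolerance = 1e-12)

  # indicator values always land in [0, 1]
  res4 <- indval(toy_iv(), setNames(rep(1:2, each = 3), rownames(toy_iv())))
  expect_true(all(res4$indval >= 0 & res4$indval <= 1))
})

test_that("indval matches the brute-force oracle on random matrices", {
  set.seed(31)
  for (rep in 1:5) {
    n <- sample(6:12, 1)
    k <- sample(2:3, 1)
    m <- matrix(rexp(n * 5) * rbinom(n * 5, 1, 0.7), n, 5)
    m[rowSums(m) == 0, 1] <- 1
    m <- 100 * m / rowSums(m)
    rownames(m) <- paste0("p", seq_len(n))
    colnames(m) <- paste0("s", 1:5)
    cl <- setNames(sample(rep(seq_len(k), length.out = n)), rownames(m))
    got <- indval(m, cl)
    ora <- indval_stat_oracle(m, unname(cl[rownames(m)]))
    expect_equal(got$indval, ora$stat, tolerance = 1e-12)
    expect_equal(got$best_cluster, ora$best)
  }
})

test_that("permutation p-values hit the attainable extremes", {
  set.seed(6)
  # strong indicator in well-mixed groups: minimal attainable p
  n <- 20
  pres <- c(rep(100, 10), rep(0, 10))
  m <- cbind(ind = pres, bg = 100 - pres + 1e-9)
  m <- 100 * m / rowSums(m)
  rownames(m) <- paste0("p", 1:n)
  memb <- setNames(rep(1:2, each = 10), rownames(m))
  res <- indval_pvalues(m, memb, n_perm = 999, rng_seed = 12)
  expect_equal(res$p_value[res$species == "ind"], 0.001)

  # constant species: statistic invariant under permutation -> p = 1
  flat <- cbind(const = rep(40, 8), rest = rep(60, 8))
  rownames(flat) <- paste0("p", 1:8)
  resf <- indval_pvalues(flat, setNames(rep(1:2, each = 4), rownames(flat)),
                         n_perm = 99, rng_seed = 1)
  expect_equal(resf$p_value, c(1, 1))
})

test_that("permutation p-values agree with exhaustive enumeration", {
  set.seed(91)
  cases <- list(list(n = 6, sizes = c(3, 3)),
                list(n = 8, sizes = c(4, 4)),
                list(n = 8, sizes = c(3, 3, 2)))
  n_perm <- 999
  for (cs in cases) {
    m <- matrix(rexp(cs$n * 4) * rbinom(cs$n * 4, 1, 0.6), cs$n, 4)
    m[rowSums(m) == 0, 1] <- 1
    m <- 100 * m / rowSums(m)
    rownames(m) <- paste0("p", seq_len(cs$n))
    colnames(m) <- paste0("s", 1:4)
    cl <- rep(seq_along(cs$sizes), cs$sizes)
    ora <- indval_p_oracle(m, cl)
    got <- indval_pvalues(m, setNames(cl, rownames(m)),
                          n_perm = n_perm, rng_seed = 77)
    tol <- 3 * sqrt(ora$p_exact * (1 - ora$p_exact) / n_perm) + 2 / (n_perm + 1)
    expect_true(all(abs(got$p_value - ora$p_exact) <= tol),
                info = paste("sizes", paste(cs$sizes, collapse = "/")))
    expect_equal(got$indval, ora$obs, tolerance = 1e-12)
  }
})

test_that("weighted silhouettes behave at the extremes", {
  # two tight, far-apart clusters: within 0, between 1
  d <- as.dist(rbind(c(0, 0, 1, 1), c(0, 0, 1, 1),
                     c(1, 1, 0, 0), c(1, 1, 0, 0)))
  expect_equal(silhouette_mean(d, NULL, c(1, 1, 2, 2)), 1)

  # every point equidistant to own and neighbouring cluster
  deq <- as.dist(matrix(0.4, 4, 4) - diag(0.4, 4))
  expect_equal(silhouette_mean(deq, NULL, c(1, 1, 2, 2)), 0)

  expect_error(silhouette_mean(deq, NULL, rep(1, 4)), "clusters")
})

test_that("unit sizes reproduce the classical silhouette", {
  skip_if_not_installed("cluster")
  set.seed(14)
  x <- matrix(rexp(30 * 4), 30, 4)
  d <- bray_curtis(x)
  cl <- sample(rep(1:3, each = 10))
  ref <- mean(cluster::silhouette(cl, d)[, "sil_width"])
  expect_equal(silhouette_mean(d, NULL, cl), ref, tolerance = 1e-12)
})

test_that("size-weighted seed silhouette equals plot-level silhouette on duplicates", {
  skip_if_not_installed("cluster")
  set.seed(15)
  base <- matrix(rexp(10 * 4), 10, 4)
  base <- 100 * base / rowSums(base)
  reps <- sample(1:5, 10, replace = TRUE)
  reps[1] <- 1  # include a singleton seed
  x <- base[rep(1:10, reps), ]
  seed_cl <- rep(1:2, each = 5)
  plot_cl <- rep(seed_cl, reps)

  got <- silhouette_mean(bray_curtis(base), reps, seed_cl)
  ref <- mean(cluster::silhouette(plot_cl, bray_curtis(x))[, "sil_width"])
  expect_equal(got, ref, tolerance = 1e-9)
})

test_that("hierarchy scans are deterministic and sized by k_range", {
  cfg <- synthetic_config(n_plots = 150, rng_seed = 23)
  ivm <- compute_iv(simulate_inventory(make_templates(cfg), cfg)$records)
  ss <- kmeans_seed(ivm, k = 25, rng_seed = 2)
  dend <- weighted_average_linkage(bray_curtis(ss$centroids), ss$sizes)

  one <- scan_hierarchy(ivm, dend, ss, k_range = c(2, 2), n_perm = 99,
                        rng_seed = 5)
  expect_equal(nrow(one), 1)
  expect_equal(one$k, 2)

  a <- scan_hierarchy(ivm, dend, ss, k_range = c(2, 6), n_perm = 99,
                      rng_seed = 5)
  b <- scan_hierarchy(ivm, dend, ss, k_range = c(2, 6), n_perm = 99,
                      rng_seed = 5)
  expect_identical(a, b)
  expect_true(all(a$mean_silhouette >= -1 & a$mean_silhouette <= 1))
  expect_true(all(a$n_sig_species <= ncol(ivm)))
})

test_that("optimum selection flags global and local optima per index", {
  # monotone increasing index: global best is the largest eligible k
  mono <- data.frame(
    k = 2:6,
    sum_sig_indval = 1:5,
    n_sig_species = rep(4L, 5),
    mean_sig_p = rep(0.02, 5),
    mean_silhouette = rep(0.3, 5),
    all_clusters_covered = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  tmono <- select_optima(mono)$table
  expect_true(tmono$opt_sum_sig_indval[tmono$k == 5])
  expect_false(any(tmono$opt_sum_sig_indval[tmono$k < 5]))
  expect_false(tmono$opt_sum_sig_indval[tmono$k == 6])  # ineligible

  # a row strictly dominating both neighbours is flagged in all four indices
  diag <- data.frame(
    k = 2:6,
    sum_sig_indval = c(1, 9, 3, 4, 5),
    n_sig_species = c(5, 8, 6, 7, 6),
    mean_sig_p = c(0.04, 0.01, 0.03, 0.02, 0.03),
    mean_silhouette = c(0.2, 0.6, 0.3, 0.4, 0.3),
    all_clusters_covered = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  sel <- select_optima(diag)
  tab <- sel$table
  expect_equal(unname(tab$n_indices_opt[tab$k == 3]), 4)
  expect_equal(sel$candidates$k[1], 3)

  none <- diag
  none$all_clusters_covered <- FALSE
  expect_warning(out <- select_optima(none), "no cut level")
  expect_equal(nrow(out$candidates), 0)
})

test_that("p-values are super-uniform under shuffled labels", {
  cfg <- synthetic_config(n_plots = 200, n_species = 30, rng_seed = 33)
  ivm <- compute_iv(simulate_inventory(make_templates(cfg), cfg)$records)
  set.seed(44)
  memb <- setNames(sample(rep(1:4, length.out = nrow(ivm))), rownames(ivm))
  res <- indval_pvalues(ivm, memb, n_perm = 199, rng_seed = 45)
  expect_lte(mean(res$p_value <= 0.05), 0.12)
  expect_true(all(res$p_value >= 1 / 200))
})
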
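# Independent oracles and tiny fixture builders, deliberately written without
# reusing the package's own code paths.

# A minimal per-stem record table: one row per (plot, species) with the given
# basal area replicated `stems` times.
make_records <- function(plot_id, species_code, ba, stems = 1L,
                         region_code = NA_character_, plot_flags = "") {
  df <- data.frame(plot_id = plot_id, species_code = species_code,
                   basal_area_m2 = ba, stringsAsFactors = FALSE)
  df <- df[rep(seq_len(nrow(df)), stems), , drop = FALSE]
  df$basal_area_m2 <- df$basal_area_m2 / rep(stems, stems)
  df$region_code <- rep(region_code, length.out = nrow(df))
  df$plot_flags <- rep(plot_flags, length.out = nrow(df))
  rownames(df) <- NULL
  df
}

# Brute-force Bray-Curtis between two vectors.
bc_pair <- function(u, v) sum(abs(u - v)) / sum(u + v)

# All distinct arrangements of the multiset `x` (used to enumerate plot-label
# permutations exhaustively on tiny instances).
multiset_perms <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (v in unique(x)) {
    rest <- x[-match(v, x)]
    for (p in multiset_perms(rest)) out[[length(out) + 1L]] <- c(v, p)
  }
  out
}

# Exhaustive Dufrene-Legendre oracle: the max A*B statistic per species,
# written from the definition with plain loops.
indval_stat_oracle <- function(iv, cl) {
  k <- max(cl)
  S <- ncol(iv)
  stat <- numeric(S)
  best <- integer(S)
  for (s in seq_len(S)) {
    means <- sapply(seq_len(k), function(j) mean(iv[cl == j, s]))
    A <- if (sum(means) > 0) means / sum(means) else rep(0, k)
    B <- sapply(seq_len(k), function(j) mean(iv[cl == j, s] > 0))
    ab <- A * B
    best[s] <- which.max(ab)
    stat[s] <- max(ab)
  }
  list(stat = stat, best = best)
}

# Exact permutation p-values by enumerating every distinct relabelling.
indval_p_oracle <- function(iv, cl) {
  obs <- indval_stat_oracle(iv, cl)$stat
  perms <- multiset_perms(cl)
  stats_mat <- sapply(perms, function(p) indval_stat_oracle(iv, p)$stat)
  if (is.null(dim(stats_mat))) stats_mat <- matrix(stats_mat, nrow = 1)
  p <- rowMeans(stats_mat >= obs - 1e-12)
  list(obs = obs, p_exact = p, n_arrangements = length(perms))
}

# Small well-separated two-group IV matrix (rows sum to 100).
toy_iv <- function() {
  m <- rbind(c(70, 30, 0, 0),
             c(60, 40, 0, 0),
             c(80, 20, 0, 0),
             c(0, 0, 50, 50),
             c(0, 0, 40, 60),
             c(0, 10, 45, 45))
  dimnames(m) <- list(paste0("p", 1:6), paste0("sp", 1:4))
  m
}

true_label_vector <- function(sim) {
  stats::setNames(sim$labels$template_id, sim$labels$plot_id)
}
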
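# Independent oracles used to cross-check package implementations.

# Naive trimmed-mean-of-M-values factors, written directly from the
# published algorithm: reference sample by upper-quartile/library ratio
# closest to the mean, doubly trimmed (30% on M, 5% on A) precision-
# weighted mean of log2 ratios, factors scaled to geometric mean 1.
naive_tmm <- function(counts) {
  libs <- colSums(counts)
  f75 <- apply(counts, 2L, function(col) stats::quantile(col, 0.75)) / libs
  ref <- which.min(abs(f75 - mean(f75)))
  one_factor <- function(obs, ref_col, n_obs, n_ref) {
    m <- log2((obs / n_obs) / (ref_col / n_ref))
    a <- (log2(obs / n_obs) + log2(ref_col / n_ref)) / 2
    w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref_col) / (n_ref * ref_col)
    ok <- is.finite(m) & is.finite(a) & a > -1e10
    m <- m[ok]; a <- a[ok]; w <- w[ok]
    if (max(abs(m)) < 1e-6) return(1)
    n <- length(m)
    lo_m <- floor(n * 0.3) + 1; hi_m <- n + 1 - lo_m
    lo_a <- floor(n * 0.05) + 1; hi_a <- n + 1 - lo_a
    keep <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    one_factor(counts[, j], counts[, ref], libs[j], libs[ref])
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Distance-free PERMANOVA R^2 for Euclidean distances: the classical
# coordinate-space one-way ANOVA partition summed over dimensions.
coordinate_r_squared <- function(coords, groups) {
  groups <- as.factor(groups)
  sst <- sum(scale(coords, scale = FALSE)^2)
  ssw <- 0
  for (lev in levels(groups)) {
    sub <- coords[groups == lev, , drop = FALSE]
    ssw <- ssw + sum(scale(sub, scale = FALSE)^2)
  }
  1 - ssw / sst
}

# Small simulated dataset shared by several tests.
tiny_dataset <- function(seed = 42, effect = 1, proportion = 0.25,
                         direction = "unidirectional", n_taxa = 40) {
  set.seed(seed)
  cfg <- default_config(n_taxa = n_taxa)
  sim <- simulate_abundances(scenario_spec(direction, effect, proportion), cfg)
  counts <- simulate_sequencing(sim$abundance, cfg$depth_mean, cfg$depth_sd)
  list(sim = sim, counts = counts, config = cfg)
}
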
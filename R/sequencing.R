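#' Simulate amplicon sequencing of an abundance matrix
#'
#' Converts absolute abundances into compositional read counts.  For each
#' sample a library size is drawn from Normal(`depth_mean`, `depth_sd`),
#' rounded, and redrawn while below `min_depth`; reads are then allocated
#' across taxa by a multinomial draw with probabilities proportional to the
#' sample's absolute abundances.  The multinomial conserves the fixed read
#' budget, which is exactly the compositional constraint under study, and
#' makes the counts invariant to any global rescaling of the input
#' abundances.
#'
#' @param abundance Taxa x samples matrix of non-negative abundances; every
#'   column must have a positive sum.
#' @param depth_mean,depth_sd Mean and standard deviation of the per-sample
#'   library size (defaults 50000 and 10000).
#' @param min_depth Smallest admissible library size (default 1); normal
#'   draws below it are rejected and redrawn.
#' @return An integer matrix of the same shape with a `"library_sizes"`
#'   attribute; column sums equal the drawn library sizes exactly.
#' @examples
#' set.seed(7)
#' sim <- simulate_abundances(scenario_spec("unidirectional", 1, 0.1))
#' counts <- simulate_sequencing(sim$abundance)
#' all(colSums(counts) == attr(counts, "library_sizes"))
#' @export
simulate_sequencing <- function(abundance, depth_mean = 50000,
                                depth_sd = 10000, min_depth = 1) {
  if (!is.matrix(abundance) || !is.numeric(abundance)) {
    stop("'abundance' must be a numeric matrix", call. = FALSE)
  }
  if (any(abundance < 0)) {
    stop("'abundance' must be non-negative", call. = FALSE)
  }
  if (depth_mean <= 0 || depth_sd < 0) {
    stop("'depth_mean' must be > 0 and 'depth_sd' >= 0", call. = FALSE)
  }
  totals <- colSums(abundance)
  if (any(totals <= 0)) {
    stop("every sample must contain at least one taxon with positive ",
         "abundance", call. = FALSE)
  }
  n_samples <- ncol(abundance)
  sizes <- integer(n_samples)
  for (j in seq_len(n_samples)) {
    repeat {
      s <- round(stats::rnorm(1, depth_mean, depth_sd))
      if (s >= min_depth) break
    }
    sizes[j] <- as.integer(s)
  }
  counts <- matrix(0L, nrow = nrow(abundance), ncol = n_samples,
                   dimnames = dimnames(abundance))
  for (j in seq_len(n_samples)) {
    counts[, j] <- stats::rmultinom(1, size = sizes[j],
                                    prob = abundance[, j])[, 1]
  }
  storage.mode(counts) <- "integer"
  attr(counts, "library_sizes") <- sizes
  counts
}
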
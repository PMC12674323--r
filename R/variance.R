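#' Log-Pearson distance between samples
#'
#' `1 -` the Pearson correlation between log-transformed sample profiles.
#' Matrices already on a log scale (CLR output) are correlated as-is; for
#' other scales the values are log-transformed first, carrying the
#' pseudocount convention through each sample's divisor when zeros are
#' present.
#'
#' @param values Taxa x samples matrix (a `"norm_matrix"` or a positive
#'   abundance matrix).
#' @param pseudocount Pseudocount applied via per-sample divisors when the
#'   matrix contains zeros (default 0.5).
#' @return A [stats::dist] over samples with attribute `metric =
#'   "log_pearson"`.
#' @export
log_pearson_distance <- function(values, pseudocount = 0.5) {
  log_scale <- isTRUE(attr(values, "log_scale"))
  vals <- unclass(values)
  if (!log_scale) {
    offset <- if (any(vals == 0)) {
      if (pseudocount <= 0) {
        stop("zeros present: a positive pseudocount is required", call. = FALSE)
      }
      pseudocount / (attr(values, "divisors") %||% rep(1, ncol(vals)))
    } else {
      rep(0, ncol(vals))
    }
    vals <- log(sweep(vals, 2L, offset, "+"))
  }
  if (any(apply(vals, 2L, stats::sd) == 0)) {
    stop("log-Pearson distance undefined for zero-variance samples",
         call. = FALSE)
  }
  d <- stats::as.dist(1 - stats::cor(vals))
  attr(d, "metric") <- "log_pearson"
  d
}

#' Bray-Curtis dissimilarity between samples
#'
#' `sum |x - y| / sum (x + y)` over taxa, computed with
#' [vegan::vegdist()].
#'
#' @param values Taxa x samples matrix of non-negative values.
#' @return A [stats::dist] over samples with attribute `metric =
#'   "bray_curtis"`.
#' @examples
#' bray_curtis_distance(cbind(a = c(1, 2, 3), b = c(3, 2, 1)))  # 1/3
#' @export
bray_curtis_distance <- function(values) {
  vals <- unclass(values)
  if (any(vals < 0)) {
    stop("Bray-Curtis requires non-negative values", call. = FALSE)
  }
  if (any(colSums(vals) == 0)) {
    stop("Bray-Curtis undefined for all-zero samples", call. = FALSE)
  }
  d <- vegan::vegdist(t(vals), method = "bray")
  attr(d, "metric") <- "bray_curtis"
  d
}

#' Aitchison distance between samples
#'
#' Euclidean distance between CLR-transformed sample profiles.  Accepts
#' either a raw count matrix (CLR is applied with the usual pseudocount
#' convention) or an already CLR-transformed `"norm_matrix"`.
#'
#' @param counts Taxa x samples count matrix, or a CLR `"norm_matrix"`.
#' @param pseudocount Passed to [clr_transform()] when counts are given.
#' @return A [stats::dist] over samples with attribute `metric =
#'   "aitchison"`.
#' @export
aitchison_distance <- function(counts, pseudocount = 0.5) {
  clr <- if (identical(attr(counts, "method"), "clr")) {
    counts
  } else {
    clr_transform(counts, pseudocount = pseudocount)
  }
  d <- stats::dist(t(unclass(clr)))
  attr(d, "metric") <- "aitchison"
  d
}

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix
#' with a single grouping factor, using the standard distance-based
#' partition: total sum of squares `sum_{i<j} d_ij^2 / n`, within-group
#' sum of squares accumulated per group, `R^2 = 1 - SSW / SST`, and the
#' pseudo-F ratio `(SSB / (k - 1)) / (SSW / (n - k))`.  The permutation
#' p-value shuffles group labels; `R^2` itself requires no permutations, so
#' `n_permutations = 0` skips the test (p is `NA`).  Semantics match
#' `vegan::adonis2` for a one-factor model.
#'
#' @param d A [stats::dist] or symmetric distance matrix over samples.
#' @param groups Group labels, one per sample; at least two non-empty
#'   groups.
#' @param n_permutations Number of label permutations for the p-value
#'   (default 999; 0 to skip).
#' @return List of class `"permanova"`: `r_squared`, `pseudo_f`,
#'   `p_value`, `n_permutations`, `ss` (SSB/SSW/SST) and `df`.
#' @examples
#' x <- cbind(matrix(rnorm(10), 2), matrix(rnorm(10, 5), 2))
#' permanova(dist(t(x)), rep(c("a", "b"), each = 5), n_permutations = 99)
#' @export
permanova <- function(d, groups, n_permutations = 999) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  groups <- as.factor(groups)
  if (length(groups) != n) {
    stop("need one group label per sample", call. = FALSE)
  }
  groups <- droplevels(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need at least two groups", call. = FALSE)
  d2 <- dm^2
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw_for <- function(g) {
    ssw <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1L) {
        sub <- d2[idx, idx, drop = FALSE]
        ssw <- ssw + sum(sub[upper.tri(sub)]) / length(idx)
      }
    }
    ssw
  }
  ssw <- ssw_for(groups)
  ssb <- sst - ssw
  r2 <- if (sst > 0) ssb / sst else 0
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  p <- NA_real_
  if (n_permutations > 0) {
    f_perm <- replicate(n_permutations, {
      gp <- groups[sample.int(n)]
      ssw_p <- ssw_for(gp)
      ((sst - ssw_p) / (k - 1)) / (ssw_p / (n - k))
    })
    p <- (1 + sum(f_perm >= f)) / (n_permutations + 1)
  }
  structure(
    list(r_squared = r2, pseudo_f = f, p_value = p,
         n_permutations = n_permutations,
         ss = c(between = ssb, within = ssw, total = sst),
         df = c(between = k - 1, within = n - k)),
    class = "permanova"
  )
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: R2 = %.4f, pseudo-F(%d, %d) = %.3f",
              x$r_squared, x$df[["between"]], x$df[["within"]], x$pseudo_f))
  if (!is.na(x$p_value)) {
    cat(sprintf(", p = %.4g (%d permutations)", x$p_value, x$n_permutations))
  }
  cat("\n")
  invisible(x)
}
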
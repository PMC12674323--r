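#' @title Normalizations under comparison
#' @name normalizations
#' @description
#' The four transformations whose downstream behaviour the package
#' benchmarks: per-sample relative abundance, the centered log-ratio (CLR),
#' TMM effective-library scaling (edgeR), and median-of-ratios size factors
#' (DESeq2-style).  Each returns a taxa x samples matrix of class
#' `"norm_matrix"` carrying the method tag, the per-sample divisors that
#' were applied (used downstream to carry the pseudocount convention onto
#' the normalized scale) and, for CLR, the pseudocount used.
NULL

norm_matrix <- function(values, method, divisors = NULL, log_scale = FALSE,
                        pseudocount = 0, factors = NULL) {
  structure(values, class = c("norm_matrix", class(values)),
            method = method, divisors = divisors, log_scale = log_scale,
            pseudocount = pseudocount, factors = factors)
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat(sprintf("<norm_matrix> %s, %d taxa x %d samples\n",
              attr(x, "method"), nrow(x), ncol(x)))
  utils::str(unclass(x)[seq_len(min(3L, nrow(x))), seq_len(min(4L, ncol(x)))])
  invisible(x)
}

#' Relative abundance (total-sum scaling)
#'
#' Divides each sample's counts by its library size, so each column sums
#' to one.
#'
#' @param counts Taxa x samples count matrix with positive column sums.
#' @return A `"norm_matrix"` of proportions (method `"relative"`); the
#'   library sizes are stored as the per-sample divisors.
#' @examples
#' m <- matrix(c(10, 30, 60), ncol = 1)
#' relative_abundance(m)[, 1]
#' @export
relative_abundance <- function(counts) {
  libs <- colSums(counts)
  if (any(libs <= 0)) {
    stop("every sample needs a positive total count", call. = FALSE)
  }
  norm_matrix(sweep(counts, 2L, libs, "/"), method = "relative",
              divisors = libs)
}

#' Centered log-ratio (CLR) transform
#'
#' Per sample, the log of each count divided by the geometric mean of the
#' sample's counts: `log(x) - mean(log(x))`, so every column sums to zero.
#' When the matrix contains zeros a pseudocount (default 0.5) is first
#' added to every count; with no zeros present the counts are transformed
#' as-is.
#'
#' @param counts Taxa x samples count matrix.
#' @param pseudocount Value added to every count when any zero is present
#'   (default 0.5).  Must be positive if zeros occur.
#' @return A `"norm_matrix"` on the log scale (method `"clr"`); the
#'   `"pseudocount"` attribute records the value actually added (0 when
#'   none was needed).
#' @examples
#' clr_transform(matrix(c(1, 10, 100), ncol = 1))[, 1]  # -log(10), 0, log(10)
#' @export
clr_transform <- function(counts, pseudocount = 0.5) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  used <- if (any(counts == 0)) pseudocount else 0
  if (used <= 0 && any(counts == 0)) {
    stop("matrix contains zero counts: a positive pseudocount is required",
         call. = FALSE)
  }
  lg <- log(counts + used)
  vals <- sweep(lg, 2L, colMeans(lg), "-")
  norm_matrix(vals, method = "clr", log_scale = TRUE, pseudocount = used)
}

#' TMM scaling factors
#'
#' Trimmed-mean-of-M-values normalization factors as implemented in edgeR:
#' a reference sample is chosen as the one whose upper-quartile/library-size
#' ratio is closest to the mean of that ratio, and each sample's factor is
#' the precision-weighted trimmed mean (30% trim on M, 5% on A) of its
#' per-taxon log-ratios against the reference.  Factors are normalized to
#' have geometric mean one.
#'
#' @param counts Taxa x samples count matrix (at least two samples).
#' @return Positive numeric vector of one scaling factor per sample.
#' @seealso [normalize_counts()] to apply the factors.
#' @export
tmm_factors <- function(counts) {
  if (ncol(counts) < 2L) {
    stop("TMM needs at least two samples", call. = FALSE)
  }
  if (any(colSums(counts) <= 0)) {
    stop("every sample needs a positive total count", call. = FALSE)
  }
  f <- edgeR::calcNormFactors(as.matrix(counts), method = "TMM")
  names(f) <- colnames(counts)
  f
}

#' Median-of-ratios size factors
#'
#' The DESeq2-style size factor: per taxon, the geometric mean across
#' samples is computed over the taxa that are positive in every sample;
#' each sample's factor is the median over those taxa of count divided by
#' geometric mean.  If no taxon is positive in all samples, the geometric
#' mean of each taxon is instead taken over the samples where it is
#' positive, and each sample's median runs over its own positive taxa.
#'
#' @param counts Taxa x samples count matrix.
#' @return Positive numeric vector of one size factor per sample.
#' @examples
#' m <- cbind(a = c(2, 4, 8), b = c(6, 12, 24))   # proportional columns
#' deseq_size_factors(m)                           # 1/sqrt(3), sqrt(3)
#' @export
deseq_size_factors <- function(counts) {
  counts <- as.matrix(counts)
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (any(all_pos)) {
    log_geo <- rowMeans(log(counts[all_pos, , drop = FALSE]))
    sf <- apply(counts[all_pos, , drop = FALSE], 2L, function(col) {
      exp(stats::median(log(col) - log_geo))
    })
  } else {
    if (all(counts == 0)) {
      stop("no taxon with a positive count in any sample", call. = FALSE)
    }
    log_geo <- apply(counts, 1L, function(row) mean(log(row[row > 0])))
    sf <- apply(counts, 2L, function(col) {
      ok <- col > 0 & is.finite(log_geo)
      if (!any(ok)) {
        stop("a sample shares no positive taxon with the rest of the data",
             call. = FALSE)
      }
      exp(stats::median(log(col[ok]) - log_geo[ok]))
    })
  }
  names(sf) <- colnames(counts)
  sf
}

#' Apply scaling factors to a count matrix
#'
#' Produces the normalized abundance values used in testing: for TMM,
#' counts divided by the effective library size (library size times TMM
#' factor); for the median-of-ratios method, counts divided by the size
#' factor.
#'
#' @param counts Taxa x samples count matrix.
#' @param factors Per-sample positive factors from [tmm_factors()] or
#'   [deseq_size_factors()].
#' @param method `"tmm"` or `"deseq"`.
#' @return A `"norm_matrix"` tagged with the method; the per-sample
#'   divisors actually applied are stored in the `"divisors"` attribute.
#' @export
normalize_counts <- function(counts, factors, method = c("tmm", "deseq")) {
  method <- match.arg(method)
  if (length(factors) != ncol(counts)) {
    stop("need exactly one factor per sample", call. = FALSE)
  }
  if (any(factors <= 0)) stop("factors must be positive", call. = FALSE)
  divisors <- switch(method,
    tmm = colSums(counts) * factors,
    deseq = factors
  )
  norm_matrix(sweep(counts, 2L, divisors, "/"), method = method,
              divisors = divisors, factors = factors)
}
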
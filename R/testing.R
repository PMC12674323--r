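#' Parse `<subject>_<group>_<timepoint>` sample names
#'
#' The package's sample naming convention encodes the design in the column
#' names of every matrix written to or read from disk.
#'
#' @param x Character vector of sample names.
#' @return Data frame with columns `sample`, `subject`, `group`,
#'   `timepoint`.
#' @export
parse_sample_names <- function(x) {
  parts <- strsplit(x, "_", fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop("sample names must follow <subject>_<group>_<timepoint>: ",
         paste(x[bad], collapse = ", "), call. = FALSE)
  }
  parts <- do.call(rbind, parts)
  data.frame(sample = x, subject = parts[, 1], group = parts[, 2],
             timepoint = parts[, 3], stringsAsFactors = FALSE)
}

#' Per-subject response on a transformed scale
#'
#' Builds the subject-level quantity the group test compares.  In the
#' default `"post_only"` mode each subject contributes its
#' post-intervention value per taxon (log-transformed on non-log scales).
#' In `"change"` mode it is the between-timepoint change of each taxon
#' within each subject: for log-scale data (CLR) the plain difference post
#' minus baseline, and for all other scales the log-ratio of post to
#' baseline values.  On scales where sampling zeros occur, the CLR
#' pseudocount convention is carried through the normalization: the
#' pseudocount divided by each sample's divisor is added before taking
#' logs.
#'
#' @param values Taxa x samples matrix covering both timepoints, columns
#'   named `<subject>_<group>_<timepoint>`; typically a `"norm_matrix"`.
#' @param mode `"post_only"` (default) or `"change"`.
#' @param pseudocount Pseudocount applied (via the per-sample divisors)
#'   when the matrix contains zeros; default 0.5.
#' @return Taxa x subjects matrix with a `"groups"` attribute giving each
#'   subject's group label.
#' @export
per_subject_response <- function(values, mode = c("post_only", "change"),
                                 pseudocount = 0.5) {
  mode <- match.arg(mode)
  log_scale <- isTRUE(attr(values, "log_scale"))
  divisors <- attr(values, "divisors")
  info <- parse_sample_names(colnames(values))
  subjects <- unique(info$subject)
  base_idx <- match(paste0(subjects, "_",
                           info$group[match(subjects, info$subject)], "_base"),
                    info$sample)
  post_idx <- match(paste0(subjects, "_",
                           info$group[match(subjects, info$subject)], "_post"),
                    info$sample)
  if (anyNA(base_idx) || anyNA(post_idx)) {
    stop("every subject must appear at both timepoints", call. = FALSE)
  }
  vals <- unclass(values)
  if (!log_scale) {
    offset <- if (any(vals == 0)) {
      if (pseudocount <= 0) {
        stop("zeros present: a positive pseudocount is required", call. = FALSE)
      }
      pseudocount / (divisors %||% rep(1, ncol(vals)))
    } else {
      rep(0, ncol(vals))
    }
    vals <- log(sweep(vals, 2L, offset, "+"))
    if (any(!is.finite(vals))) {
      stop("non-finite values after log transform", call. = FALSE)
    }
  }
  resp <- switch(mode,
    change = vals[, post_idx, drop = FALSE] - vals[, base_idx, drop = FALSE],
    post_only = vals[, post_idx, drop = FALSE]
  )
  colnames(resp) <- subjects
  attr(resp, "groups") <- info$group[match(subjects, info$subject)]
  resp
}

#' Row-wise Kruskal-Wallis rank sum tests
#'
#' Tie-corrected Kruskal-Wallis H statistic for every row of a matrix
#' against one grouping, computed via the rank-based sum-of-squares
#' identity `H = (n - 1) * SSB / SST` (which equals the classical
#' tie-corrected statistic).  Rows where all observations are tied are
#' assigned H = 0 and p = 1.  P-values come from the chi-squared
#' distribution with `k - 1` degrees of freedom.
#'
#' @param x Numeric matrix, one test per row.
#' @param groups Group labels, one per column; every group must be
#'   non-empty.
#' @return List with numeric vectors `statistic` and `p.value` (one entry
#'   per row) and the scalar `df`.
#' @export
row_kruskal_wallis <- function(x, groups) {
  x <- as.matrix(x)
  groups <- as.factor(groups)
  if (length(groups) != ncol(x)) {
    stop("need one group label per column", call. = FALSE)
  }
  if (nlevels(droplevels(groups)) < 2L) {
    stop("need at least two non-empty groups", call. = FALSE)
  }
  groups <- droplevels(groups)
  n <- ncol(x)
  k <- nlevels(groups)
  ranks <- t(apply(x, 1L, rank))
  if (nrow(x) == 1L) ranks <- matrix(ranks, nrow = 1L)
  rbar <- (n + 1) / 2
  ind <- stats::model.matrix(~ groups - 1)        # n x k indicator
  group_sums <- ranks %*% ind
  group_n <- as.vector(table(groups))
  ssb <- sweep(sweep(group_sums, 2L, group_n, "/"), 2L, rbar, "-")^2 %*% group_n
  sst <- rowSums((ranks - rbar)^2)
  h <- (n - 1) * as.vector(ssb) / sst
  h[sst == 0] <- 0
  p <- stats::pchisq(h, df = k - 1, lower.tail = FALSE)
  p[sst == 0] <- 1
  list(statistic = h, p.value = p, df = k - 1)
}

#' Kruskal-Wallis rank sum test
#'
#' Scalar interface to [row_kruskal_wallis()] for a single response
#' vector.
#'
#' @param x Numeric vector of observations.
#' @param groups Group labels, one per observation.
#' @return List with `statistic`, `p.value` and `df`.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
kruskal_wallis <- function(x, groups) {
  res <- row_kruskal_wallis(matrix(x, nrow = 1L), groups)
  list(statistic = res$statistic[1], p.value = res$p.value[1], df = res$df)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' False-discovery-rate adjusted p-values (step-up rule, clipped at 1).
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) ||
      any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must be numbers in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Detect significantly responding taxa
#'
#' The full per-dataset detection step: compute the per-subject response on
#' the matrix's scale, run one Kruskal-Wallis test per taxon between the
#' control and treatment groups, adjust the p-values across the taxa of the
#' dataset with Benjamini-Hochberg, and flag taxa with adjusted p below
#' `alpha`.
#'
#' @param values Taxa x samples matrix over both timepoints (columns named
#'   `<subject>_<group>_<timepoint>`), typically a `"norm_matrix"` or the
#'   raw absolute-abundance matrix.
#' @param alpha Significance cutoff on the adjusted p-value (default 0.1).
#' @param mode,pseudocount Passed to [per_subject_response()].
#' @return Data frame of class `"dda_result"`: `taxon`, `statistic`, `p`,
#'   `p_adj`, `flagged`.
#' @export
detect_responders <- function(values, alpha = 0.1,
                              mode = c("post_only", "change"),
                              pseudocount = 0.5) {
  if (alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be in (0, 1)", call. = FALSE)
  }
  resp <- per_subject_response(values, mode = mode, pseudocount = pseudocount)
  kw <- row_kruskal_wallis(resp, attr(resp, "groups"))
  p_adj <- bh_adjust(kw$p.value)
  out <- data.frame(
    taxon = rownames(values) %||% taxon_ids(nrow(values)),
    statistic = kw$statistic, p = kw$p.value, p_adj = p_adj,
    flagged = p_adj < alpha, stringsAsFactors = FALSE
  )
  class(out) <- c("dda_result", "data.frame")
  out
}

#' Score detections against the ground truth
#'
#' Counts false positives (flagged non-responders) and false negatives
#' (unflagged responders).  Both rates are normalized by the total taxon
#' count, so a scenario in which half of all taxa are misclassified yields
#' a rate of 0.5.
#'
#' @param flags Logical vector of per-taxon significance flags, or a
#'   `"dda_result"`.
#' @param truth A `"truth_table"` from [select_responders()], or a logical
#'   responder vector.
#' @return List of class `"error_rates"`: counts `tp`, `fp`, `tn`, `fn`
#'   and rates `fp_rate`, `fn_rate`.
#' @export
error_rates <- function(flags, truth) {
  if (inherits(flags, "dda_result")) flags <- flags$flagged
  responder <- if (is.data.frame(truth)) truth$responder else truth
  if (length(flags) != length(responder)) {
    stop("flags and truth must cover the same taxa", call. = FALSE)
  }
  n <- length(flags)
  tp <- sum(flags & responder)
  fp <- sum(flags & !responder)
  fn <- sum(!flags & responder)
  tn <- sum(!flags & !responder)
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         fp_rate = fp / n, fn_rate = fn / n, n_taxa = n),
    class = "error_rates"
  )
}

#' @export
print.error_rates <- function(x, ...) {
  cat(sprintf(
    "Error rates over %d taxa: FP %.3f (%d), FN %.3f (%d), TP %d, TN %d\n",
    x$n_taxa, x$fp_rate, x$fp, x$fn_rate, x$fn, x$tp, x$tn))
  invisible(x)
}
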
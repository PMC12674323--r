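rep_methods <- c("absolute", "relative", "clr", "tmm", "deseq")

# Subset samples of a (possibly normalized) matrix, keeping the per-sample
# metadata attributes aligned with the retained columns.
subset_samples <- function(values, idx) {
  out <- unclass(values)[, idx, drop = FALSE]
  div <- attr(values, "divisors")
  norm_matrix(out, method = attr(values, "method") %||% "absolute",
              divisors = if (!is.null(div)) div[idx],
              log_scale = isTRUE(attr(values, "log_scale")),
              pseudocount = attr(values, "pseudocount") %||% 0)
}

# Deterministic per-iteration child seed: distinct for every
# (direction, scenario, iteration) triple of a run, always below 2^31.
scenario_seed <- function(master_seed, direction, scenario, iteration) {
  base <- (abs(as.integer(master_seed)) * 1009) %% 2147483647
  dir_off <- if (direction == "bidirectional") 536870912 else 0
  (base + dir_off + scenario * 1000003 + iteration) %% 2147483647
}

#' Build the five data representations for one simulated dataset
#'
#' Ground-truth absolute abundances plus the four normalizations of the
#' sequenced counts: relative abundance, CLR, TMM and median-of-ratios.
#'
#' @param abundance Taxa x samples absolute-abundance matrix.
#' @param counts Matching count matrix from [simulate_sequencing()].
#' @param pseudocount CLR pseudocount (default 0.5).
#' @return Named list of matrices, one per representation.
#' @export
build_representations <- function(abundance, counts, pseudocount = 0.5) {
  list(
    absolute = abundance,
    relative = relative_abundance(counts),
    clr = clr_transform(counts, pseudocount = pseudocount),
    tmm = normalize_counts(counts, tmm_factors(counts), method = "tmm"),
    deseq = normalize_counts(counts, deseq_size_factors(counts),
                             method = "deseq")
  )
}

#' Run one scenario iteration end to end
#'
#' One full simulate - sequence - normalize - test - evaluate pass: the
#' ground-truth dataset is generated, sequenced, transformed into the five
#' representations, each representation is tested for responding taxa and
#' scored against the truth table, and (optionally) the PERMANOVA variance
#' explained by treatment is computed on the post-intervention samples
#' under each representation's distance metrics (log-Pearson for all;
#' Bray-Curtis for non-log scales, Aitchison for CLR).
#'
#' @param spec A [scenario_spec()].
#' @param config A [default_config()].
#' @param seed Optional integer seed for this iteration.
#' @param permanova Compute the variance partition as well (default TRUE)?
#' @return List of class `"scenario_result"`: `spec`, `truth`, `errors`
#'   (data frame, one row per representation) and `variance` (data frame,
#'   one row per representation x metric, or NULL).
#' @examples
#' res <- run_scenario(scenario_spec("unidirectional", 10, 0.25), seed = 1)
#' res$errors
#' @export
run_scenario <- function(spec, config = default_config(), seed = NULL,
                         permanova = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  sim <- simulate_abundances(spec, config)
  counts <- simulate_sequencing(sim$abundance, config$depth_mean,
                                config$depth_sd, config$min_depth)
  reps <- build_representations(sim$abundance, counts, config$pseudocount)

  errors <- do.call(rbind, lapply(names(reps), function(m) {
    det <- detect_responders(reps[[m]], alpha = config$alpha,
                             mode = config$response_mode,
                             pseudocount = config$pseudocount)
    er <- error_rates(det, sim$truth)
    data.frame(method = m, tp = er$tp, fp = er$fp, tn = er$tn, fn = er$fn,
               fp_rate = er$fp_rate, fn_rate = er$fn_rate,
               stringsAsFactors = FALSE)
  }))

  variance <- NULL
  if (permanova) {
    post_idx <- grep("_post$", colnames(sim$abundance))
    groups <- parse_sample_names(colnames(sim$abundance))$group[post_idx]
    variance <- do.call(rbind, lapply(names(reps), function(m) {
      sub <- subset_samples(reps[[m]], post_idx)
      dists <- list(log_pearson = log_pearson_distance(
        sub, pseudocount = config$pseudocount))
      dists[[if (m == "clr") "aitchison" else "bray_curtis"]] <-
        if (m == "clr") aitchison_distance(sub) else bray_curtis_distance(sub)
      do.call(rbind, lapply(names(dists), function(metric) {
        pm <- permanova(dists[[metric]], groups,
                        n_permutations = config$n_permutations)
        data.frame(method = m, metric = metric, r_squared = pm$r_squared,
                   pseudo_f = pm$pseudo_f, p_value = pm$p_value,
                   stringsAsFactors = FALSE)
      }))
    }))
  }

  structure(list(spec = spec, truth = sim$truth, errors = errors,
                 variance = variance),
            class = "scenario_result")
}

#' @export
print.scenario_result <- function(x, ...) {
  print(x$spec)
  print(x$errors, row.names = FALSE)
  if (!is.null(x$variance)) print(x$variance, row.names = FALSE)
  invisible(x)
}

#' Run a full experiment over the scenario grid
#'
#' Iterates [run_scenario()] over every grid point, with a deterministic
#' per-iteration seed derived from the master seed so any iteration is
#' independently reproducible and the full run is byte-identical under the
#' same master seed.
#'
#' @param direction `"unidirectional"` (experiment 1) or `"bidirectional"`
#'   (experiment 2).
#' @param grid Data frame with columns `effect_size` and `proportion`
#'   (default [default_grid()], 30 scenarios).
#' @param n_iterations Iterations per scenario (default 100).
#' @param seed Master seed.
#' @param config A [default_config()].
#' @param permanova Compute PERMANOVA variance per iteration (default
#'   TRUE)?
#' @param verbose Print per-scenario progress?
#' @return List of class `"compo_experiment"` with long-format data frames
#'   `errors` and `variance` (columns `effect_size`, `proportion`,
#'   `iteration` plus the per-representation results), the `direction`,
#'   `grid`, `n_iterations`, `seed` and `config`.
#' @examples
#' ex <- run_experiment("unidirectional",
#'                      grid = data.frame(effect_size = 10, proportion = 0.5),
#'                      n_iterations = 2, seed = 1, permanova = FALSE)
#' summary(ex)
#' @export
run_experiment <- function(direction = c("unidirectional", "bidirectional"),
                           grid = default_grid(), n_iterations = 100,
                           seed = 1, config = default_config(),
                           permanova = TRUE, verbose = FALSE) {
  direction <- match.arg(direction)
  if (!all(c("effect_size", "proportion") %in% names(grid)) || !nrow(grid)) {
    stop("'grid' needs columns effect_size and proportion and >= 1 row",
         call. = FALSE)
  }
  if (n_iterations < 1) stop("'n_iterations' must be >= 1", call. = FALSE)

  err_list <- vector("list", nrow(grid) * n_iterations)
  var_list <- if (permanova) err_list else NULL
  idx <- 0L
  for (s in seq_len(nrow(grid))) {
    spec <- scenario_spec(direction, grid$effect_size[s], grid$proportion[s])
    if (verbose) {
      message(sprintf("scenario %d/%d: effect %gx, proportion %g%%",
                      s, nrow(grid), spec$effect_size, 100 * spec$proportion))
    }
    for (i in seq_len(n_iterations)) {
      idx <- idx + 1L
      res <- run_scenario(spec, config = config,
                          seed = scenario_seed(seed, direction, s, i),
                          permanova = permanova)
      err <- res$errors
      err$effect_size <- spec$effect_size
      err$proportion <- spec$proportion
      err$iteration <- i
      err_list[[idx]] <- err
      if (permanova) {
        v <- res$variance
        v$effect_size <- spec$effect_size
        v$proportion <- spec$proportion
        v$iteration <- i
        var_list[[idx]] <- v
      }
    }
  }
  structure(
    list(direction = direction,
         errors = do.call(rbind, err_list),
         variance = if (permanova) do.call(rbind, var_list),
         grid = grid, n_iterations = n_iterations, seed = seed,
         config = config),
    class = "compo_experiment"
  )
}

#' @export
print.compo_experiment <- function(x, ...) {
  cat(sprintf(
    "<compo_experiment> %s: %d scenarios x %d iterations (seed %s)\n",
    x$direction, nrow(x$grid), x$n_iterations, format(x$seed)))
  cat("  use summary() for the aggregated error/variance tables\n")
  invisible(x)
}

#' Aggregate an experiment into summary tables
#'
#' Scenario-level means are taken first (each scenario averaged over its
#' iterations, weighting scenarios equally), then summarized per
#' representation: the mean and maximum of the scenario-mean FP and FN
#' rates, with each transformation's fold change relative to the
#' absolute-abundance data.  Also returns per-scenario delta tables
#' (transformation minus relative abundance, with the absolute-data rate
#' removed from both) and, when PERMANOVA was run, the scenario-mean
#' R-squared per representation and metric together with the
#' Bray-Curtis/Aitchison minus log-Pearson differences.
#'
#' @param object A `"compo_experiment"`.
#' @param ... Unused.
#' @return List of class `"compo_summary"`: `table1`, `scenario_means`,
#'   `delta_vs_relative`, `r2_means`, `delta_r2`, `direction`,
#'   `n_iterations`.
#' @export
summary.compo_experiment <- function(object, ...) {
  errors <- object$errors
  scen <- stats::aggregate(
    cbind(fp_rate, fn_rate) ~ effect_size + proportion + method,
    data = errors, FUN = mean)

  methods <- intersect(rep_methods, unique(scen$method))
  table1 <- do.call(rbind, lapply(methods, function(m) {
    sub <- scen[scen$method == m, ]
    data.frame(method = m,
               max_fp = max(sub$fp_rate), mean_fp = mean(sub$fp_rate),
               max_fn = max(sub$fn_rate), mean_fn = mean(sub$fn_rate),
               stringsAsFactors = FALSE)
  }))
  abs_row <- table1[table1$method == "absolute", ]
  table1$fp_fold <- table1$mean_fp / abs_row$mean_fp
  table1$fn_fold <- table1$mean_fn / abs_row$mean_fn

  # per-scenario differences vs relative abundance, absolute-data rate
  # removed from both sides (it cancels in the difference)
  wide <- function(col) {
    stats::reshape(scen[, c("effect_size", "proportion", "method", col)],
                   idvar = c("effect_size", "proportion"),
                   timevar = "method", direction = "wide")
  }
  delta <- NULL
  if (all(c("relative", "absolute") %in% methods)) {
    wfp <- wide("fp_rate")
    wfn <- wide("fn_rate")
    delta <- wfp[, c("effect_size", "proportion")]
    for (m in setdiff(methods, c("absolute", "relative"))) {
      delta[[paste0("dfp_", m)]] <-
        (wfp[[paste0("fp_rate.", m)]] - wfp[["fp_rate.absolute"]]) -
        (wfp[["fp_rate.relative"]] - wfp[["fp_rate.absolute"]])
      delta[[paste0("dfn_", m)]] <-
        (wfn[[paste0("fn_rate.", m)]] - wfn[["fn_rate.absolute"]]) -
        (wfn[["fn_rate.relative"]] - wfn[["fn_rate.absolute"]])
    }
  }

  r2_means <- delta_r2 <- NULL
  if (!is.null(object$variance)) {
    r2_means <- stats::aggregate(
      r_squared ~ effect_size + proportion + method + metric,
      data = object$variance, FUN = mean)
    lp <- r2_means[r2_means$metric == "log_pearson", ]
    other <- r2_means[r2_means$metric != "log_pearson", ]
    key <- c("effect_size", "proportion", "method")
    mm <- merge(other, lp[, c(key, "r_squared")], by = key,
                suffixes = c("", "_log_pearson"))
    mm$delta_r2 <- mm$r_squared - mm$r_squared_log_pearson
    delta_r2 <- mm[order(mm$method, mm$proportion, mm$effect_size),
                   c(key, "metric", "delta_r2")]
  }

  structure(
    list(table1 = table1, scenario_means = scen, delta_vs_relative = delta,
         r2_means = r2_means, delta_r2 = delta_r2,
         direction = object$direction, n_iterations = object$n_iterations),
    class = "compo_summary"
  )
}

#' @export
print.compo_summary <- function(x, digits = 3, ...) {
  cat(sprintf("Experiment summary (%s, %d iterations/scenario)\n",
              x$direction, x$n_iterations))
  t1 <- x$table1
  t1$fp_fold <- ifelse(t1$method == "absolute", NA, t1$fp_fold)
  t1$fn_fold <- ifelse(t1$method == "absolute", NA, t1$fn_fold)
  out <- data.frame(
    Method = t1$method,
    `Max FP` = round(t1$max_fp, digits),
    `Mean FP` = round(t1$mean_fp, digits),
    `FP fold` = ifelse(is.na(t1$fp_fold), "-", round(t1$fp_fold, digits)),
    `Max FN` = round(t1$max_fn, digits),
    `Mean FN` = round(t1$mean_fn, digits),
    `FN fold` = ifelse(is.na(t1$fn_fold), "-", round(t1$fn_fold, digits)),
    check.names = FALSE
  )
  print(out, row.names = FALSE)
  if (!is.null(x$r2_means)) {
    cat("\nMean PERMANOVA R2 by representation and metric (grid average):\n")
    agg <- stats::aggregate(r_squared ~ method + metric, data = x$r2_means,
                            FUN = mean)
    print(agg, row.names = FALSE, digits = digits)
  }
  invisible(x)
}

#' Heatmap of scenario-level summaries
#'
#' Draws an effect-size by response-proportion heatmap (the scenario grid)
#' of a chosen quantity: scenario-mean FP rate, FN rate, or PERMANOVA
#' R-squared for one representation.
#'
#' @param x A `"compo_summary"`.
#' @param what `"fp"`, `"fn"` or `"r2"`.
#' @param method Representation to plot (default `"absolute"`).
#' @param metric Distance metric when `what = "r2"` (default
#'   `"log_pearson"`).
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, the plotted matrix (effect sizes x proportions).
#' @export
plot.compo_summary <- function(x, what = c("fp", "fn", "r2"),
                               method = "absolute", metric = "log_pearson",
                               ...) {
  what <- match.arg(what)
  if (what == "r2") {
    if (is.null(x$r2_means)) stop("no PERMANOVA results in this summary",
                                  call. = FALSE)
    df <- x$r2_means[x$r2_means$method == method &
                       x$r2_means$metric == metric, ]
    df$value <- df$r_squared
    lab <- sprintf("mean R2 (%s, %s)", method, metric)
  } else {
    df <- x$scenario_means[x$scenario_means$method == method, ]
    df$value <- if (what == "fp") df$fp_rate else df$fn_rate
    lab <- sprintf("mean %s rate (%s)", toupper(what), method)
  }
  if (!nrow(df)) stop("no rows for that method/metric", call. = FALSE)
  eff <- sort(unique(df$effect_size))
  prop <- sort(unique(df$proportion))
  z <- matrix(NA_real_, length(eff), length(prop))
  z[cbind(match(df$effect_size, eff), match(df$proportion, prop))] <- df$value
  graphics::image(seq_along(eff), seq_along(prop), z, axes = FALSE,
                  xlab = "effect size", ylab = "proportion responding",
                  main = lab, ...)
  graphics::axis(1, at = seq_along(eff), labels = eff)
  graphics::axis(2, at = seq_along(prop), labels = prop)
  graphics::box()
  invisible(z)
}
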
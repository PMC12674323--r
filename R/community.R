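#' Cohort design for a two-arm, two-timepoint intervention
#'
#' Builds the subject-level design used throughout the package: two groups
#' (control `"c"` and treatment `"t"`), each subject sampled at a baseline
#' and a post-intervention timepoint.
#'
#' @param n_per_group Number of subjects per group (default 10, i.e. a
#'   20-subject cohort).
#' @return A data frame of class `"cohort_design"` with columns `subject`
#'   and `group`, plus a `"timepoints"` attribute `c("base", "post")`.
#' @examples
#' cohort_design()
#' @export
cohort_design <- function(n_per_group = 10) {
  if (!is.numeric(n_per_group) || length(n_per_group) != 1L ||
      n_per_group < 1 || n_per_group != round(n_per_group)) {
    stop("'n_per_group' must be a single positive integer", call. = FALSE)
  }
  n_per_group <- as.integer(n_per_group)
  design <- data.frame(
    subject = c(sprintf("c%02d", seq_len(n_per_group)),
                sprintf("t%02d", seq_len(n_per_group))),
    group = rep(c("c", "t"), each = n_per_group),
    stringsAsFactors = FALSE
  )
  attr(design, "timepoints") <- c("base", "post")
  class(design) <- c("cohort_design", "data.frame")
  design
}

#' Specify one simulation scenario
#'
#' A scenario is one point of the experimental grid: the directionality
#' regime of the treatment effect, the per-taxon effect magnitude, and the
#' fraction of taxa that respond.
#'
#' @param direction `"unidirectional"` (all responders increase) or
#'   `"bidirectional"` (responders increase/decrease at a 1:1 ratio).
#' @param effect_size Non-negative effect magnitude `e`; a responding taxon
#'   is multiplied by `(1 + e)` (increase) or divided by `(1 + e)`
#'   (decrease) in the treatment group.
#' @param proportion Fraction of taxa responding, in `[0, 1]`.
#' @return A list of class `"scenario_spec"`.
#' @examples
#' scenario_spec("unidirectional", effect_size = 1, proportion = 0.25)
#' @export
scenario_spec <- function(direction = c("unidirectional", "bidirectional"),
                          effect_size, proportion) {
  direction <- match.arg(direction)
  if (!is.numeric(effect_size) || length(effect_size) != 1L || effect_size < 0) {
    stop("'effect_size' must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(proportion) || length(proportion) != 1L ||
      proportion < 0 || proportion > 1) {
    stop("'proportion' must be a single number in [0, 1]", call. = FALSE)
  }
  structure(
    list(direction = direction, effect_size = as.numeric(effect_size),
         proportion = as.numeric(proportion)),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario: %s, effect size %gx, %g%% of taxa responding\n",
              x$direction, x$effect_size, 100 * x$proportion))
  invisible(x)
}

#' Default scenario grid
#'
#' The 5 x 6 grid of effect sizes and response proportions over which each
#' experiment is run: effect sizes 0.1, 0.5, 1, 5, 10 crossed with response
#' proportions 1, 5, 10, 25, 50 and 75 percent (30 scenarios).
#'
#' @return A data frame with columns `effect_size` and `proportion`.
#' @export
default_grid <- function() {
  grid <- expand.grid(
    effect_size = c(0.1, 0.5, 1, 5, 10),
    proportion = c(0.01, 0.05, 0.10, 0.25, 0.50, 0.75),
    KEEP.OUT.ATTRS = FALSE
  )
  grid[order(grid$proportion, grid$effect_size), , drop = FALSE]
}

taxon_ids <- function(n_taxa) sprintf("taxon_%03d", seq_len(n_taxa))

#' Generate a baseline log-normal taxon abundance profile
#'
#' Draws the absolute abundance of each taxon as the exponential of a
#' normal deviate.  The defaults (100 taxa, log-mean 12.5, log-sd 2.5)
#' produce a community with a few dominant and many rare taxa, resembling a
#' gut bacteriome profile at genus/family level.
#'
#' @param n_taxa Number of taxa (default 100).
#' @param log_mean,log_sd Mean and standard deviation of the natural-log
#'   abundances (defaults 12.5 and 2.5).
#' @return A named positive numeric vector of length `n_taxa`.
#' @examples
#' set.seed(1)
#' prof <- generate_baseline_profile()
#' summary(log(prof))
#' @export
generate_baseline_profile <- function(n_taxa = 100, log_mean = 12.5,
                                      log_sd = 2.5) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1L || n_taxa < 1) {
    stop("'n_taxa' must be a positive count", call. = FALSE)
  }
  if (log_sd < 0) stop("'log_sd' must be non-negative", call. = FALSE)
  n_taxa <- as.integer(n_taxa)
  ab <- exp(stats::rnorm(n_taxa, mean = log_mean, sd = log_sd))
  names(ab) <- taxon_ids(n_taxa)
  ab
}

#' Derive a correlated cohort from one baseline profile
#'
#' Every subject's baseline abundance is the shared profile multiplied by
#' an independent per-taxon log-normal deviation `exp(Normal(0,
#' subject_log_sd))`.  Sharing the profile makes taxon abundances
#' positively correlated across subjects, as in real microbiota data; with
#' the defaults (profile log-sd 2.5, subject log-sd 0.5) the expected
#' between-subject correlation of log-abundances is
#' 2.5^2 / (2.5^2 + 0.5^2), about 0.96.
#'
#' @param baseline Positive numeric vector from
#'   [generate_baseline_profile()].
#' @param design A [cohort_design()] (its rows define the subjects), or a
#'   single subject count.
#' @param subject_log_sd Standard deviation of the per-subject log-scale
#'   deviation (default 0.5).
#' @return A taxa x subjects matrix of positive baseline abundances,
#'   columns named by subject.
#' @export
generate_cohort <- function(baseline, design = cohort_design(),
                            subject_log_sd = 0.5) {
  if (!is.numeric(baseline) || any(baseline <= 0)) {
    stop("'baseline' must be a strictly positive numeric vector", call. = FALSE)
  }
  if (subject_log_sd < 0) stop("'subject_log_sd' must be >= 0", call. = FALSE)
  if (is.numeric(design) && length(design) == 1L) {
    subjects <- sprintf("s%02d", seq_len(design))
  } else {
    subjects <- design$subject
  }
  n_taxa <- length(baseline)
  n_sub <- length(subjects)
  dev <- matrix(exp(stats::rnorm(n_taxa * n_sub, 0, subject_log_sd)),
                nrow = n_taxa, ncol = n_sub)
  mat <- baseline * dev
  dimnames(mat) <- list(names(baseline) %||% taxon_ids(n_taxa), subjects)
  mat
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Draw the ground-truth responder set for one scenario
#'
#' Selects `round(proportion * n_taxa)` taxa uniformly at random as
#' responders (rounding half away from zero, so 1% of 100 taxa is exactly
#' one responder).  In the unidirectional regime all responders increase;
#' in the bidirectional regime increases and decreases are assigned at a
#' 1:1 ratio (counts differing by at most one when odd).
#'
#' @param n_taxa Number of taxa in the community.
#' @param spec A [scenario_spec()].
#' @return A data frame of class `"truth_table"` with columns `taxon`,
#'   `responder` (logical) and `direction` (+1, -1, or 0 for
#'   non-responders).
#' @export
select_responders <- function(n_taxa, spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  n_taxa <- as.integer(n_taxa)
  n_resp <- floor(spec$proportion * n_taxa + 0.5)  # round half away from zero
  responder <- rep(FALSE, n_taxa)
  direction <- rep(0L, n_taxa)
  if (n_resp > 0) {
    idx <- sample.int(n_taxa, n_resp)
    responder[idx] <- TRUE
    if (spec$direction == "unidirectional") {
      direction[idx] <- 1L
    } else {
      n_up <- ceiling(n_resp / 2)
      direction[idx] <- rep(c(1L, -1L), c(n_up, n_resp - n_up))
    }
  }
  out <- data.frame(taxon = taxon_ids(n_taxa), responder = responder,
                    direction = direction, stringsAsFactors = FALSE)
  class(out) <- c("truth_table", "data.frame")
  out
}

#' Apply the treatment effect to responder taxa
#'
#' For subjects in the treatment group only, each responding taxon is
#' multiplied by `(1 + effect_size)` if it responds positively, or divided
#' by `(1 + effect_size)` if it responds negatively.  Control subjects and
#' non-responding taxa are returned unchanged.
#'
#' @param mat Taxa x subjects matrix of baseline abundances (columns in
#'   `design` order).
#' @param truth A `"truth_table"` from [select_responders()].
#' @param effect_size Non-negative effect magnitude.
#' @param design The [cohort_design()] matching the columns of `mat`.
#' @return A matrix of the same shape: the post-intervention abundances
#'   before temporal noise.
#' @export
apply_treatment <- function(mat, truth, effect_size, design) {
  if (nrow(mat) != nrow(truth)) {
    stop("truth table and abundance matrix disagree on taxon count",
         call. = FALSE)
  }
  if (effect_size < 0) stop("'effect_size' must be >= 0", call. = FALSE)
  if (ncol(mat) != nrow(design)) {
    stop("design and abundance matrix disagree on subject count", call. = FALSE)
  }
  treated <- design$group == "t"
  fold <- rep(1, nrow(mat))
  fold[truth$direction == 1L] <- 1 + effect_size
  fold[truth$direction == -1L] <- 1 / (1 + effect_size)
  mat[, treated] <- mat[, treated, drop = FALSE] * fold
  mat
}

#' Apply random temporal noise to a between-timepoint transition
#'
#' Multiplies every taxon in every subject by an independent random factor
#' representing unexplained change between the two sampling timepoints.
#' The default model draws the factor from Uniform(1 - f, 1 + f) with
#' f = 0.25 (a random change of up to 25% either way); a log-symmetric
#' alternative draws `exp(Uniform(-log(1 + f), log(1 + f)))`.
#'
#' @param mat Taxa x subjects abundance matrix.
#' @param noise_fraction Maximum fractional change `f`, in `[0, 1)`.
#' @param model `"uniform"` (default) or `"log_uniform"`.
#' @return Matrix of the same shape with noise applied.
#' @export
apply_temporal_noise <- function(mat, noise_fraction = 0.25,
                                 model = c("uniform", "log_uniform")) {
  model <- match.arg(model)
  if (noise_fraction < 0 || noise_fraction >= 1) {
    stop("'noise_fraction' must be in [0, 1): larger values would allow ",
         "non-positive abundances", call. = FALSE)
  }
  n <- length(mat)
  mult <- switch(model,
    uniform = stats::runif(n, 1 - noise_fraction, 1 + noise_fraction),
    log_uniform = exp(stats::runif(n, -log1p(noise_fraction),
                                   log1p(noise_fraction)))
  )
  mat * mult
}

#' Simulate the full ground-truth abundance dataset for one scenario
#'
#' Composes the generator steps: a shared baseline profile, a correlated
#' cohort of subjects, responder selection, the treatment effect on the
#' treatment arm, and temporal noise on the baseline-to-post transition of
#' every subject.  The result is the 2n-sample absolute-abundance matrix
#' (both timepoints) that downstream sequencing and testing consume.
#'
#' @param spec A [scenario_spec()].
#' @param config Simulation parameters, see [default_config()].
#' @return A list of class `"abundance_set"`: `abundance` (taxa x 2n
#'   matrix, columns `<subject>_<group>_<timepoint>`), `truth`
#'   (truth table) and `design` (cohort design).
#' @examples
#' set.seed(42)
#' sim <- simulate_abundances(scenario_spec("unidirectional", 1, 0.25))
#' dim(sim$abundance)
#' @export
simulate_abundances <- function(spec, config = default_config()) {
  design <- cohort_design(config$n_per_group)
  baseline_profile <- generate_baseline_profile(config$n_taxa,
                                                config$log_mean, config$log_sd)
  base_mat <- generate_cohort(baseline_profile, design, config$subject_log_sd)
  truth <- select_responders(config$n_taxa, spec)
  post_mat <- apply_treatment(base_mat, truth, spec$effect_size, design)
  post_mat <- apply_temporal_noise(post_mat, config$noise_fraction,
                                   config$noise_model)
  abundance <- cbind(base_mat, post_mat)
  colnames(abundance) <- c(
    paste(design$subject, design$group, "base", sep = "_"),
    paste(design$subject, design$group, "post", sep = "_")
  )
  structure(list(abundance = abundance, truth = truth, design = design,
                 spec = spec),
            class = "abundance_set")
}

#' Default simulation configuration
#'
#' All tunable parameters of the generator and analysis pipeline with their
#' default values: 100 taxa with log-normal abundances (log-mean 12.5,
#' log-sd 2.5), 10 subjects per group with subject log-sd 0.5, 25% uniform
#' temporal noise, sequencing depth Normal(50000, 10000), CLR/log
#' pseudocount 0.5, Kruskal-Wallis + BH significance cutoff 0.1 comparing
#' the groups' post-intervention values (`response_mode = "post_only"`; the
#' paired between-timepoint change is available as `"change"`), and
#' PERMANOVA on post-intervention samples with R-squared read from the
#' unpermuted partition.
#'
#' @param ... Named overrides of any default.
#' @return A list of class `"compo_config"`.
#' @examples
#' default_config(n_taxa = 50, alpha = 0.05)
#' @export
default_config <- function(...) {
  config <- list(
    n_taxa = 100L,
    log_mean = 12.5,
    log_sd = 2.5,
    n_per_group = 10L,
    subject_log_sd = 0.5,
    noise_fraction = 0.25,
    noise_model = "uniform",
    depth_mean = 50000,
    depth_sd = 10000,
    min_depth = 1,
    pseudocount = 0.5,
    alpha = 0.1,
    response_mode = "post_only",
    permanova_samples = "post",
    n_permutations = 0L
  )
  overrides <- list(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(config))
    if (length(bad)) {
      stop("unknown config parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    config[names(overrides)] <- overrides
  }
  class(config) <- "compo_config"
  config
}

#' @export
print.compo_config <- function(x, ...) {
  cat("Simulation configuration:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
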
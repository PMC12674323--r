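test_that("baseline profile follows the configured log-normal law", {
  expect_equal(generate_baseline_profile(5, log_mean = 3, log_sd = 0),
               stats::setNames(rep(exp(3), 5), sprintf("taxon_%03d", 1:5)))

  set.seed(101)
  prof <- generate_baseline_profile(10000, log_mean = 12.5, log_sd = 2.5)
  expect_true(all(prof > 0))
  # law-of-large-numbers check against the stated distribution
  expect_lt(abs(mean(log(prof)) - 12.5), 4 * 2.5 / sqrt(10000))
  expect_lt(abs(stats::sd(log(prof)) - 2.5), 0.1)

  expect_error(generate_baseline_profile(0), "positive count")
  expect_error(generate_baseline_profile(10, log_sd = -1), "non-negative")
})

test_that("cohort subjects are correlated log-normal variants of the baseline", {
  prof <- stats::setNames(rep(100, 5), sprintf("taxon_%03d", 1:5))
  identical_cohort <- generate_cohort(prof, cohort_design(2), subject_log_sd = 0)
  expect_true(all(identical_cohort == 100))
  expect_equal(ncol(identical_cohort), 4L)

  set.seed(202)
  big <- generate_baseline_profile(20000, 12.5, 2.5)
  mat <- generate_cohort(big, 2, subject_log_sd = 0.5)
  expect_true(all(mat > 0))
  # variance-components identity: cor = 2.5^2 / (2.5^2 + 0.5^2) ~ 0.962
  expect_equal(stats::cor(log(mat[, 1]), log(mat[, 2])),
               2.5^2 / (2.5^2 + 0.5^2), tolerance = 0.01)

  full <- generate_cohort(big[1:50], cohort_design(10), 0.5)
  expect_identical(dim(full), c(50L, 20L))
})

test_that("responder selection honours proportion, rounding and regime", {
  for (p in c(0.01, 0.05, 0.10, 0.25, 0.50, 0.75)) {
    truth <- select_responders(100, scenario_spec("unidirectional", 1, p))
    expect_identical(sum(truth$responder), as.integer(round(100 * p)))
    expect_true(all(truth$direction[truth$responder] == 1L))
    expect_true(all(truth$direction[!truth$responder] == 0L))
  }
  none <- select_responders(100, scenario_spec("unidirectional", 1, 0))
  expect_false(any(none$responder))

  bi <- select_responders(100, scenario_spec("bidirectional", 1, 0.10))
  expect_identical(sum(bi$direction == 1L), 5L)
  expect_identical(sum(bi$direction == -1L), 5L)
  # odd responder counts split 1:1 up to one taxon
  odd <- select_responders(100, scenario_spec("bidirectional", 1, 0.25))
  expect_lte(abs(sum(odd$direction == 1L) - sum(odd$direction == -1L)), 1L)
})

test_that("treatment multiplies responders in the treatment arm only", {
  design <- cohort_design(2)
  mat <- matrix(10, nrow = 4, ncol = 4,
                dimnames = list(sprintf("taxon_%03d", 1:4), design$subject))
  truth <- data.frame(taxon = rownames(mat),
                      responder = c(TRUE, TRUE, FALSE, FALSE),
                      direction = c(1L, -1L, 0L, 0L))
  out <- apply_treatment(mat, truth, effect_size = 1, design = design)
  treated <- design$group == "t"
  expect_equal(out[1, treated], mat[1, treated] * 2)      # up: x(1+e)
  expect_equal(out[2, treated], mat[2, treated] / 2)      # down: /(1+e)
  expect_equal(out[3:4, ], mat[3:4, ])                    # non-responders
  expect_equal(out[, !treated], mat[, !treated])          # control untouched

  expect_equal(apply_treatment(mat, truth, 0, design), mat)  # null effect
  expect_error(apply_treatment(mat[1:3, ], truth, 1, design), "taxon count")
})

test_that("temporal noise is a bounded multiplicative perturbation", {
  mat <- matrix(runif(200, 1, 10), 20, 10)
  expect_equal(apply_temporal_noise(mat, 0), mat)

  set.seed(7)
  noisy <- apply_temporal_noise(mat, 0.25)
  mult <- noisy / mat
  expect_true(all(mult >= 0.75 & mult <= 1.25))

  set.seed(8)
  big <- apply_temporal_noise(matrix(1, 1000, 100), 0.25)
  expect_equal(mean(big), 1, tolerance = 4 * 0.25 / sqrt(3) / sqrt(1e5))

  set.seed(9)
  lg <- apply_temporal_noise(mat, 0.25, model = "log_uniform") / mat
  expect_true(all(lg >= 1 / 1.25 & lg <= 1.25))

  expect_error(apply_temporal_noise(mat, 1), "non-positive")
})

test_that("simulated datasets stay strictly positive with a coherent design", {
  for (seed in 1:3) {
    set.seed(seed)
    spec <- scenario_spec(if (seed %% 2) "unidirectional" else "bidirectional",
                          effect_size = c(0.1, 1, 10)[seed],
                          proportion = c(0.01, 0.25, 0.75)[seed])
    sim <- simulate_abundances(spec, default_config(n_taxa = 50))
    expect_true(all(sim$abundance > 0))
    expect_identical(dim(sim$abundance), c(50L, 40L))
    info <- parse_sample_names(colnames(sim$abundance))
    expect_setequal(unique(info$timepoint), c("base", "post"))
    expect_identical(sum(info$group == "c"), 20L)
    expect_identical(sum(sim$truth$responder),
                     as.integer(floor(50 * spec$proportion + 0.5)))
  }
})

test_that("post/baseline ratio of treated up-responders has median 1 + effect", {
  set.seed(11)
  cfg <- default_config(n_taxa = 400)
  sim <- simulate_abundances(scenario_spec("unidirectional", 1, 0.5), cfg)
  info <- parse_sample_names(colnames(sim$abundance))
  treated_post <- info$group == "t" & info$timepoint == "post"
  treated_base <- info$group == "t" & info$timepoint == "base"
  up <- sim$truth$direction == 1L
  ratios <- sim$abundance[up, treated_post] / sim$abundance[up, treated_base]
  # noise multiplier has median 1, so the ratio has median (1 + e) = 2
  expect_equal(stats::median(ratios), 2, tolerance = 0.02)
})
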
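test_that("sample-name parsing recovers the design", {
  info <- parse_sample_names(c("c01_c_base", "t03_t_post"))
  expect_identical(info$subject, c("c01", "t03"))
  expect_identical(info$group, c("c", "t"))
  expect_identical(info$timepoint, c("base", "post"))
  expect_error(parse_sample_names("sample1"), "subject")
})

test_that("per-subject responses follow the documented scale conventions", {
  mat <- matrix(c(2, 4, 2, 4, 4, 8, 6, 4), nrow = 2,
                dimnames = list(c("taxon_001", "taxon_002"),
                                c("a_c_base", "b_t_base", "a_c_post",
                                  "b_t_post")))
  # identical baseline and post gives an all-zero change matrix
  same <- mat
  same[, 3:4] <- same[, 1:2]
  expect_true(all(per_subject_response(same, mode = "change") == 0))

  ch <- per_subject_response(mat, mode = "change")
  expect_equal(ch["taxon_001", "a"], log(4 / 2))          # log-ratio scale
  expect_identical(attr(ch, "groups"), c("c", "t"))

  po <- per_subject_response(mat, mode = "post_only")
  expect_equal(unname(po[, "b"]), log(c(6, 4)))

  # CLR mode: change equals CLR(post) - CLR(base)
  d <- tiny_dataset(seed = 5)
  clr <- clr_transform(d$counts)
  resp <- per_subject_response(clr, mode = "change")
  info <- parse_sample_names(colnames(clr))
  s1_base <- which(info$subject == "c01" & info$timepoint == "base")
  s1_post <- which(info$subject == "c01" & info$timepoint == "post")
  expect_equal(unname(resp[, "c01"]),
               unname(unclass(clr)[, s1_post] - unclass(clr)[, s1_base]))

  expect_error(per_subject_response(mat[, 1:3]), "both timepoints")
})

test_that("a treated up-responder at effect 1 with zero noise changes by log 2", {
  set.seed(21)
  cfg <- default_config(n_taxa = 20, noise_fraction = 0)
  sim <- simulate_abundances(scenario_spec("unidirectional", 1, 0.5), cfg)
  resp <- per_subject_response(sim$abundance, mode = "change")
  up <- sim$truth$direction == 1L
  treated <- attr(resp, "groups") == "t"
  expect_equal(unname(resp[up, treated]),
               matrix(log(2), sum(up), sum(treated)), tolerance = 1e-12)
  expect_true(all(abs(resp[, !treated]) < 1e-12))
})

test_that("Kruskal-Wallis statistic matches the rank-sum formula and oracle", {
  res <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-12)   # 3.857142...
  expect_equal(res$p.value, stats::pchisq(27 / 7, 1, lower.tail = FALSE))

  tie <- kruskal_wallis(rep(2, 8), rep(c("a", "b"), 4))
  expect_identical(c(tie$statistic, tie$p.value), c(0, 1))

  set.seed(31)
  for (i in 1:20) {
    g <- rep(c("a", "b"), each = 10)
    x <- if (i %% 2) rnorm(20) else round(rnorm(20))   # with and without ties
    ours <- kruskal_wallis(x, g)
    ref <- stats::kruskal.test(x, factor(g))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p.value, unname(ref$p.value), tolerance = 1e-10)
  }
  # three-group case
  set.seed(32)
  x <- rnorm(15)
  g3 <- rep(letters[1:3], each = 5)
  expect_equal(kruskal_wallis(x, g3)$statistic,
               unname(stats::kruskal.test(x, factor(g3))$statistic),
               tolerance = 1e-10)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "two non-empty groups")
})

test_that("KW flags are invariant to strictly monotone transforms", {
  set.seed(41)
  x <- matrix(rnorm(200), 10, 20)
  g <- rep(c("a", "b"), each = 10)
  expect_equal(row_kruskal_wallis(x, g)$statistic,
               row_kruskal_wallis(exp(x), g)$statistic, tolerance = 1e-12)
})

test_that("BH adjustment implements the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(0.07, 9)), rep(0.07, 9))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.27, 0.6)
  expect_true(all(bh_adjust(p) >= p))
  expect_true(all(bh_adjust(p) <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("detection matches an end-to-end reference pipeline", {
  d <- tiny_dataset(seed = 6, effect = 5, proportion = 0.25)
  rel <- relative_abundance(d$counts)
  det <- detect_responders(rel, alpha = 0.1, mode = "post_only")

  # reference route: stats::kruskal.test + stats::p.adjust on the same input
  info <- parse_sample_names(colnames(rel))
  post <- info$timepoint == "post"
  vals <- log(unclass(rel) + 0.5 / attr(rel, "divisors")[col(rel)])
  pref <- apply(vals[, post], 1L, function(v) {
    stats::kruskal.test(v, factor(info$group[post]))$p.value
  })
  expect_equal(det$p, unname(pref), tolerance = 1e-10)
  expect_identical(det$flagged,
                   unname(stats::p.adjust(pref, "BH") < 0.1))

  # constant taxa are never flagged
  flat <- matrix(3, 4, ncol(rel), dimnames = list(NULL, colnames(rel)))
  expect_false(any(detect_responders(flat)$flagged))
  expect_error(detect_responders(rel, alpha = 1.2), "alpha")
})

test_that("error rates use the total-taxon-count denominator", {
  truth <- c(rep(TRUE, 25), rep(FALSE, 75))
  perfect <- error_rates(truth, truth)
  expect_identical(c(perfect$fp_rate, perfect$fn_rate), c(0, 0))

  none <- error_rates(rep(FALSE, 100), truth)
  expect_equal(none$fn_rate, 0.25)
  expect_equal(none$fp_rate, 0)

  all_flagged <- error_rates(rep(TRUE, 100), c(rep(TRUE, 50), rep(FALSE, 50)))
  expect_equal(all_flagged$fp_rate, 0.50)
  expect_equal(all_flagged$fn_rate, 0)
  expect_identical(with(all_flagged, tp + fp + tn + fn), 100L)

  expect_error(error_rates(rep(TRUE, 3), truth), "same taxa")
})

test_that("null scenarios keep the absolute-data FP rate at the BH level", {
  cfg <- default_config()
  fps <- vapply(1:30, function(i) {
    res <- run_scenario(scenario_spec("unidirectional", 0, 0), cfg,
                        seed = 5000 + i, permanova = FALSE)
    res$errors$fp_rate[res$errors$method == "absolute"]
  }, numeric(1))
  expect_lte(mean(fps), 0.1)
})

test_that("false negatives decrease with effect size in expectation", {
  cfg <- default_config()
  mean_fn <- vapply(c(0.1, 1, 10), function(e) {
    mean(vapply(1:15, function(i) {
      res <- run_scenario(scenario_spec("unidirectional", e, 0.25), cfg,
                          seed = 7000 + i, permanova = FALSE)
      res$errors$fn_rate[res$errors$method == "absolute"]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_fn) <= 0))
  expect_lt(mean_fn[3], 0.02)    # 11-fold effects are essentially always seen
})
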
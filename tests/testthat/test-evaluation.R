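# Peak detection, analysis windows and performance-metric aggregation.

test_that("the peak is the earliest day of maximum onset incidence", {
  expect_equal(detect_peak(c(1, 0, 3, 2, 3)), 2)
  expect_equal(detect_peak(5), 0)
  expect_equal(detect_peak(c(0, 0, 2, 7, 1)), 3)
  # a pre-first-case zero run does not shift the day labels
  expect_equal(detect_peak(c(0, 4, 1), days = 10:12), 11)
  expect_true(is.na(detect_peak(numeric(0))))
  expect_true(is.na(detect_peak(c(0, 0))))
  expect_validation_error(detect_peak(c(1, -1)))
})

test_that("window ends scale first-case-to-peak time by the peak coefficient", {
  expect_equal(window_end(10, 20, 0.5), 15)
  # epsilon = 1 analyses exactly up to the peak
  for (first in c(0, 4, 11)) expect_equal(window_end(first, first + 13, 1), first + 13)
  # degenerate window: peak on the first case day
  expect_equal(window_end(7, 7, 0.5), 7)
  expect_equal(window_end(7, 7, 3), 7)
  # half-up rounding to whole days
  expect_equal(window_end(0, 5, 0.5), 3)
  expect_equal(window_end(0, 5, 0.9), 5)
  expect_validation_error(window_end(0, 5, -1))
  expect_validation_error(window_end(5, 3, 1))
})

test_that("peak asynchronicity is the sample sd of defined peak days", {
  expect_equal(peak_asynchronicity(c(5, 5, 5)), 0)
  expect_equal(peak_asynchronicity(c(0, 10)), 7.071068, tolerance = 1e-6)
  expect_equal(peak_asynchronicity(c(2, 4, 9)), 3.605551, tolerance = 1e-6)
  expect_true(is.na(peak_asynchronicity(c(3, NA))))
})

test_that("metric aggregation follows the CI-containment definitions", {
  # one scenario cell with known CIs, truth delta = 0.4
  reps <- tibble::tibble(
    scenario = 1L, replicate = 1:3, group = "g1", epsilon = 1, alpha = 0.05,
    delta_true = 0.4, status = "ok",
    delta_hat = c(0.35, 0.2, 0.45),
    ci_low = c(0.1, -0.1, 0.2), ci_high = c(0.6, 0.5, 0.7),
    n_cases = 50L, first_case_day = 0, peak_day = 10,
    peak_asynchronicity = 2, fraction = 0.5, size = 100, r0 = 2
  )
  rep0 <- dplyr::mutate(reps, delta_true = 0, scenario = 2L)  # homogeneous cell
  report <- summarise_study(dplyr::bind_rows(reps, rep0))

  cell <- report[report$scenario == 1, ]
  expect_equal(cell$coverage, 1)              # all three CIs contain 0.4
  expect_equal(cell$sensitivity, 2 / 3)       # two CIs exclude 0
  expect_true(is.na(cell$specificity))        # not a homogeneous cell
  expect_equal(cell$bias, mean(0.4 - c(0.35, 0.2, 0.45)))
  expect_equal(cell$coverage_error, 0.95 - 1)

  cell0 <- report[report$scenario == 2, ]
  expect_equal(cell0$specificity, 1 / 3)      # one CI contains 0
  expect_true(is.na(cell0$sensitivity))
  expect_equal(cell0$coverage, 1 / 3)         # truth 0 inside the CI: only rep 2
})

test_that("undefined replicates leave denominators but stay accounted", {
  reps <- tibble::tibble(
    scenario = 1L, replicate = 1:3, group = "g1", epsilon = 1, alpha = 0.05,
    delta_true = 0.4,
    status = c("ok", "no_emissions", "ok"),
    delta_hat = c(0.4, NA, 0.4),
    ci_low = c(0.1, NA, 0.1), ci_high = c(0.6, NA, 0.6),
    n_cases = c(50L, 0L, 50L), first_case_day = 0, peak_day = c(10, NA, 12),
    peak_asynchronicity = NA_real_, fraction = 0.5, size = 100, r0 = 2
  )
  cell <- summarise_study(reps)
  expect_equal(cell$n_valid, 2L)
  expect_equal(cell$n_undefined, 1L)
  expect_equal(cell$bias, 0)
  expect_equal(cell$coverage, 1)
  # a cell with no valid replicate is flagged, not dropped
  allbad <- dplyr::mutate(reps, status = "no_emissions", delta_hat = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_)
  cell2 <- summarise_study(allbad)
  expect_equal(cell2$n_valid, 0L)
  expect_true(is.na(cell2$bias))
})

test_that("evaluate_replicates recovers a perfect estimator as bias 0 coverage 1", {
  sc <- small_scenario(delta = c(0, 0), sizes = c(100, 100), imports = c(1, 1))
  lls <- lapply(1:5, function(s) simulate_outbreak(sc, seed = s))
  out <- evaluate_replicates(lls, sc, epsilons = 100, alphas = 0.5)
  expect_true(all(c("bias", "coverage", "sensitivity", "specificity") %in% names(out)))
  expect_equal(nrow(out), 2)  # one row per group
  expect_true(all(is.na(out$sensitivity)))  # truth is 0 everywhere
  expect_true(all(out$specificity >= 0 & out$specificity <= 1, na.rm = TRUE))
})

test_that("pairs entering the counts are non-decreasing in the peak coefficient", {
  sc <- small_scenario(sizes = c(150, 150), imports = c(1, 1))
  ll <- simulate_outbreak(sc, seed = 21)
  gt <- scenario_group_table(sc)
  eps_grid <- c(0.25, 0.5, 0.75, 1, 1.5, 2, 5)
  n_emitted <- sapply(eps_grid, function(e) {
    estimate_assortativity_peak(ll, gt, epsilon = e)$n_emitted
  })
  for (g in 1:2) expect_true(all(diff(n_emitted[g, ]) >= 0))
})

test_that("evaluation of fixed trees is deterministic", {
  sc <- small_scenario()
  lls <- lapply(1:3, function(s) simulate_outbreak(sc, seed = s))
  expect_identical(evaluate_replicates(lls, sc), evaluate_replicates(lls, sc))
})

test_that("a study report has one cell per scenario-group-epsilon-alpha", {
  spec <- ensemble_spec(2, 2, base_seed = 77)
  report <- run_study(spec, epsilons = c(0.5, 1), alphas = c(0.05, 0.25))
  n_groups <- vapply(sample_scenarios(spec), function(s) length(s$labels), 0L)
  expect_equal(nrow(report), sum(n_groups) * 2 * 2)
  expect_s3_class(report, "transmix_study")
  # reproducible end to end
  expect_equal(as.data.frame(report),
               as.data.frame(run_study(spec, epsilons = c(0.5, 1),
                                       alphas = c(0.05, 0.25))))
  # glance aggregates per (epsilon, alpha)
  g <- glance(report)
  expect_equal(nrow(g), 4)
})

test_that("minimal study: one scenario, one replicate, one cell per group", {
  spec <- ensemble_spec(1, 1, base_seed = 2)
  report <- run_study(spec, epsilons = 1, alphas = 0.05)
  G <- length(sample_scenarios(spec)[[1]]$labels)
  expect_equal(nrow(report), G)
})
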
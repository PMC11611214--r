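# Branching-process simulator: kernels, structural invariants, calibration.

test_that("delay pmfs are proper and the generation time has no lag-0 mass", {
  w <- generation_pmf(5, 2)
  expect_equal(sum(w), 1)
  expect_equal(w[1], 0)
  expect_true(all(w >= 0))
  inc <- incubation_pmf(4, 2)
  expect_equal(sum(inc), 1)
  expect_gt(inc[1], 0)  # same-day onset allowed
  # moments survive discretisation approximately
  d <- seq_along(w) - 1
  expect_equal(sum(d * w), 5, tolerance = 0.15)
  expect_validation_error(discretise_gamma(-1, 2))
})

test_that("individual force of infection follows the generation-time kernel", {
  # all mass at lag 3
  w <- c(0, 0, 0, 1)
  expect_equal(individual_foi(0, r0 = 2, pi_col = c(0.5, 0.5), w = w, t = 3),
               c(1, 1))
  expect_equal(individual_foi(0, 2, c(0.5, 0.5), w, t = 7), c(0, 0))
  expect_equal(individual_foi(5, 2, c(0.5, 0.5), w, t = 5), c(0, 0))  # lag 0
  # summed over all days and recipient groups the kernel integrates to R0
  w2 <- generation_pmf(5, 2)
  tot <- Reduce(`+`, lapply(1:(length(w2) + 2), function(t) {
    individual_foi(0, 2, c(0.3, 0.7), w2, t)
  }))
  expect_equal(sum(tot), 2)
})

test_that("scenario validation enforces the model's structural constraints", {
  expect_validation_error(scenario(c(10, 20), c(0.5), c(1, 1), c(1, 0)))
  expect_validation_error(scenario(c(10, 20), c(2, 0), c(1, 1), c(1, 0)))
  expect_validation_error(scenario(c(10, 20), c(0, 0), c(-1, 1), c(1, 0)))
  expect_validation_error(scenario(c(10, 20), c(0, 0), c(1, 1), c(0, 0)))
  expect_validation_error(scenario(c(10, 20), c(0, 0), c(1, 1), c(11, 0)))
  bad_w <- c(0.5, 0.5)  # mass at lag 0
  expect_validation_error(scenario(c(10, 20), c(0, 0), c(1, 1), c(1, 0),
                                   generation = bad_w))
})

test_that("simulated trees satisfy their structural invariants", {
  sc <- small_scenario(imports = c(2, 1))
  ll <- simulate_outbreak(sc, seed = 5)
  expect_gt(nrow(ll), 3)
  expect_false(anyDuplicated(ll$case_id) > 0)  # permanent immunity
  # per-group counts never exceed the census
  expect_true(all(table(factor(ll$group, levels = sc$labels)) <= sc$group_sizes))
  # infector infected strictly before infectee; onset after infection
  j <- match(ll$infector_id, ll$case_id)
  has <- !is.na(j)
  expect_true(all(ll$infection_day[j[has]] < ll$infection_day[has]))
  expect_true(all(ll$onset_day >= ll$infection_day))
  # imports are exactly the day-0 seeds
  expect_equal(sum(is.na(ll$infector_id)), 3)
  expect_true(all(ll$infection_day[is.na(ll$infector_id)] == 0))
})

test_that("the same scenario and seed reproduce the identical tree", {
  sc <- small_scenario()
  expect_identical(simulate_outbreak(sc, seed = 99), simulate_outbreak(sc, seed = 99))
  expect_false(identical(simulate_outbreak(sc, seed = 1), simulate_outbreak(sc, seed = 2)))
})

test_that("no transmission occurs without reproduction", {
  sc <- small_scenario(r0 = c(0, 0), imports = c(2, 1))
  ll <- simulate_outbreak(sc, seed = 1)
  expect_equal(nrow(ll), 3)
  expect_true(all(is.na(ll$infector_id)))
})

test_that("a fully assortative seeded group keeps every case within itself", {
  sc <- small_scenario(delta = c(1, 0), r0 = c(2.5, 2.5),
                       sizes = c(200, 200), imports = c(1, 0))
  ll <- simulate_outbreak(sc, seed = 7)
  expect_gt(nrow(ll), 10)
  expect_true(all(ll$group == "g1"))
})

test_that("nosocomial-scale outbreaks terminate long before the horizon", {
  spec <- ensemble_spec(10, 1, base_seed = 123)
  scenarios <- sample_scenarios(spec)
  last_day <- vapply(seq_along(scenarios), function(i) {
    ll <- simulate_outbreak(scenarios[[i]], seed = scenario_seed(123, i, 1))
    max(ll$infection_day)
  }, 0)
  expect_true(all(last_day < 300))
})

test_that("index-case offspring calibrates to R0 in a large susceptible pool", {
  w <- generation_pmf(5, 2)
  sc <- scenario(1e5, delta = 0, r0 = 2, imports = 1, horizon = length(w))
  off <- vapply(1:2000, function(s) {
    ll <- simulate_outbreak(sc, seed = s)
    sum(ll$infector_id == "1", na.rm = TRUE)
  }, 0)
  se <- sd(off) / sqrt(length(off))
  expect_lt(abs(mean(off) - 2), 3 * se)
})

test_that("realised within-group mixing matches the expected matrix diagonal", {
  # two large half-and-half groups far from saturation, gamma = 2 (delta = 1/3)
  sc <- scenario(c(5e4, 5e4), delta = c(1 / 3, 1 / 3), r0 = c(2, 2),
                 imports = c(1, 1), horizon = 25)
  frac <- rep(NA_real_, 60)
  for (s in seq_along(frac)) {
    ll <- simulate_outbreak(sc, seed = 1000 + s)
    cnt <- count_transmissions(ll)
    if (cnt$n_emitted[1] >= 5) frac[s] <- cnt$tau_within[1] / cnt$n_emitted[1]
  }
  frac <- frac[!is.na(frac)]
  target <- pi_from_gamma(2, 0.5)  # 2/3
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - target), 4 * se)
})
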
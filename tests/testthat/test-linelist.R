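# Transmission counting on line lists and the end-to-end estimator surface.

test_that("transmission pairs are counted per emitting group", {
  ll <- toy_linelist()
  cnt <- count_transmissions(ll)
  expect_equal(cnt$tau_within[cnt$group == "g1"], 2L)  # A->B, B->D
  expect_equal(cnt$n_emitted[cnt$group == "g1"], 3L)   # + A->C
  expect_equal(cnt$tau_within[cnt$group == "g2"], 0L)
  expect_equal(cnt$n_emitted[cnt$group == "g2"], 0L)
})

test_that("a pair needs both onsets inside the analysis window", {
  cnt <- count_transmissions(toy_linelist(), window_end = 4)
  # B->D dropped: D's onset (6) falls outside, though B's (3) is inside
  expect_equal(cnt$tau_within[cnt$group == "g1"], 1L)
  expect_equal(cnt$n_emitted[cnt$group == "g1"], 2L)
  # per-group windows, named by emitting group
  cnt2 <- count_transmissions(toy_linelist(), window_end = c(g1 = 4, g2 = 100))
  expect_equal(cnt2$n_emitted, c(2L, 0L))
})

test_that("unknown groups and malformed line lists are rejected", {
  expect_validation_error(count_transmissions(toy_linelist(), groups = "g9"))
  bad <- toy_linelist()
  bad$infector_id[2] <- "ZZ"
  expect_validation_error(count_transmissions(bad))
  dup <- toy_linelist()
  dup$case_id[2] <- "A"
  expect_validation_error(count_transmissions(dup))
})

test_that("estimate_assortativity composes counting, fractions and the interval", {
  est <- estimate_assortativity(toy_linelist(), toy_groups())
  g1 <- est[est$group == "g1", ]
  # tau = (2, 3), f = 0.5: pi = 2/3, delta = (2/3 - 1/2)/(2/3 + 1/2 * (1 - 4/3))
  expect_equal(g1$delta_hat, 1 / 3)
  expect_equal(g1$status, "ok")
  g2 <- est[est$group == "g2", ]
  expect_equal(g2$status, "no_emissions")
  expect_true(is.na(g2$delta_hat))

  expect_validation_error(
    estimate_assortativity(toy_linelist()[0, ], toy_groups()))
  expect_validation_error(  # group g2 absent from the census table
    estimate_assortativity(toy_linelist(), data.frame(group = "g1", size = 50)))
})

test_that("peak-relative estimation windows each group at its own peak", {
  sc <- small_scenario(imports = c(1, 1))
  ll <- simulate_outbreak(sc, seed = 2)   # sizeable epidemic in both groups
  est <- estimate_assortativity_peak(ll, scenario_group_table(sc), epsilon = 1)
  summ <- summarise_outbreak(ll, groups = sc$labels)
  expect_equal(est$window_end, summ$peak_day)   # epsilon = 1: window ends at T
  # a window far past the end of the outbreak recovers the unwindowed counts
  est_all <- estimate_assortativity_peak(ll, scenario_group_table(sc), epsilon = 100)
  full <- estimate_assortativity(ll, scenario_group_table(sc))
  expect_equal(est_all$n_emitted, full$n_emitted)
  expect_validation_error(
    estimate_assortativity_peak(ll, scenario_group_table(sc), epsilon = -1))
})

test_that("pooling over trees averages per-tree estimates and tracks spread", {
  ll <- toy_linelist()
  gt <- toy_groups()
  # degenerate posterior: identical trees pool to the single-tree estimate
  pooled <- estimate_assortativity_trees(list(ll, ll), gt)
  single <- estimate_assortativity(ll, gt)
  expect_equal(pooled$delta_hat[pooled$group == "g1"],
               single$delta_hat[single$group == "g1"])
  expect_equal(pooled$spread_high - pooled$spread_low,
               c(0, NA))  # zero width for g1; g2 never emits
  expect_equal(pooled$status, c("ok", "undefined"))
  expect_equal(pooled$n_undefined, c(0L, 2L))

  # two trees disagreeing on one link: pooled estimate is the mean
  ll2 <- ll
  ll2$infector_id[4] <- "C"  # D infected from g2 instead of g1
  p2 <- estimate_assortativity_trees(list(ll, ll2), gt)
  d1 <- estimate_assortativity(ll, gt)$delta_hat[1]
  d2 <- estimate_assortativity(ll2, gt)$delta_hat[1]
  expect_equal(p2$delta_hat[p2$group == "g1"], mean(c(d1, d2)))

  # count pooling runs the estimator once on summed counts
  pc <- estimate_assortativity_trees(list(ll, ll2), gt, pool = "counts")
  expect_equal(pc$n_emitted[pc$group == "g1"], 5L)

  expect_validation_error(estimate_assortativity_trees(list(), gt))
})

test_that("pooled estimate over perturbed trees stays inside the true-tree CI", {
  sc <- small_scenario(delta = c(0.6, 0), sizes = c(150, 150), imports = c(1, 1))
  ll <- simulate_outbreak(sc, seed = 3)
  gt <- scenario_group_table(sc)
  base <- estimate_assortativity(ll, gt)
  # perturb: re-draw a random 10% of infector links among earlier-onset cases
  # (infection days dropped: onset order does not constrain infection order)
  ll$infection_day <- NULL
  set.seed(42)
  trees <- lapply(1:100, function(i) {
    l2 <- ll
    movable <- which(!is.na(l2$infector_id))
    for (k in sample(movable, ceiling(length(movable) * 0.1))) {
      earlier <- which(l2$onset_day < l2$onset_day[k] & l2$case_id != l2$case_id[k])
      if (length(earlier) > 0) {
        l2$infector_id[k] <- l2$case_id[earlier[sample.int(length(earlier), 1)]]
      }
    }
    l2
  })
  pooled <- estimate_assortativity_trees(trees, gt)
  g1p <- pooled$delta_hat[pooled$group == "g1"]
  expect_gte(g1p, base$ci_low[base$group == "g1"])
  expect_lte(g1p, base$ci_high[base$group == "g1"])
})
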
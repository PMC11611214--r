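#' Specify a scenario ensemble
#'
#' Describes the distributions from which whole outbreak scenarios are drawn.
#' The defaults emulate nosocomial settings — person-to-person transmission of
#' healthcare-acquired pathogens in small, fully susceptible populations: 2-4
#' groups, total census 50-500, per-group R0 between 1 and 4, per-group
#' assortativity uniform on \[-1, 1\] with a point mass at exactly 0 (so that
#' specificity is measurable on truly homogeneous groups), 1-5 introductions,
#' and a discretised-gamma generation time with mean 5 and sd 2 days.
#'
#' @param n_scenarios Number of scenarios to draw.
#' @param n_replicates Simulations per scenario.
#' @param n_groups Integer range (min, max) for the number of groups.
#' @param total_size Integer range for the total census across groups.
#' @param r0 Range for the per-group basic reproduction number.
#' @param delta Range for the per-group assortativity.
#' @param prob_delta_zero Probability that a group's delta is exactly 0.
#' @param imports Integer range for the total number of introductions; each
#'   is assigned to a uniformly chosen group with remaining census capacity.
#' @param gt_mean,gt_sd Generation-time mean and sd, days.
#' @param inc_mean,inc_sd Incubation-period mean and sd, days.
#' @param horizon Simulation length in days.
#' @param min_group_size Smallest census a sampled group may have.
#' @param base_seed Integer seed from which every scenario and replicate seed
#'   is derived (see [scenario_seed()]).
#' @return An object of class `transmix_ensemble_spec`.
#' @export
ensemble_spec <- function(n_scenarios, n_replicates,
                          n_groups = c(2, 4), total_size = c(50, 500),
                          r0 = c(1, 4), delta = c(-1, 1),
                          prob_delta_zero = 0.2, imports = c(1, 5),
                          gt_mean = 5, gt_sd = 2,
                          inc_mean = 4, inc_sd = 2,
                          horizon = 365, min_group_size = 2,
                          base_seed = 1L) {
  spec <- structure(
    list(n_scenarios = as.integer(n_scenarios),
         n_replicates = as.integer(n_replicates),
         n_groups = as.integer(n_groups), total_size = as.integer(total_size),
         r0 = as.numeric(r0), delta = as.numeric(delta),
         prob_delta_zero = as.numeric(prob_delta_zero),
         imports = as.integer(imports),
         gt_mean = gt_mean, gt_sd = gt_sd,
         inc_mean = inc_mean, inc_sd = inc_sd,
         horizon = as.integer(horizon),
         min_group_size = as.integer(min_group_size),
         base_seed = as.integer(base_seed)),
    class = "transmix_ensemble_spec"
  )
  validate_ensemble_spec(spec)
}

#' @rdname ensemble_spec
#' @param spec A `transmix_ensemble_spec`.
#' @export
validate_ensemble_spec <- function(spec) {
  if (!inherits(spec, "transmix_ensemble_spec")) {
    abort_validation("not a `transmix_ensemble_spec` object.")
  }
  if (is.na(spec$n_scenarios) || spec$n_scenarios < 1) {
    abort_validation("`n_scenarios` must be at least 1.")
  }
  if (is.na(spec$n_replicates) || spec$n_replicates < 1) {
    abort_validation("`n_replicates` must be at least 1.")
  }
  rng2 <- function(x, nm, lo = -Inf) {
    if (length(x) != 2 || any(is.na(x)) || x[1] > x[2] || x[1] < lo) {
      abort_validation("range `", nm, "` must be (min, max) with min <= max",
                       if (is.finite(lo)) paste0(" and min >= ", lo), ".")
    }
  }
  rng2(spec$n_groups, "n_groups", lo = 2)
  rng2(spec$total_size, "total_size", lo = 1)
  rng2(spec$r0, "r0", lo = 0)
  rng2(spec$delta, "delta", lo = -1)
  if (spec$delta[2] > 1) abort_validation("range `delta` must stay within [-1, 1].")
  rng2(spec$imports, "imports", lo = 1)
  if (is.na(spec$prob_delta_zero) || spec$prob_delta_zero < 0 || spec$prob_delta_zero > 1) {
    abort_validation("`prob_delta_zero` must lie in [0, 1].")
  }
  if (spec$min_group_size < 1) abort_validation("`min_group_size` must be >= 1.")
  if (spec$total_size[1] < spec$n_groups[1] * spec$min_group_size) {
    abort_validation("`total_size` too small for `n_groups` groups of ",
                     "`min_group_size`.")
  }
  invisible(spec)
}

#' Deterministic seed for one scenario or replicate
#'
#' Derives a 31-bit seed from `(base_seed, scenario, replicate)` so any single
#' simulation of an ensemble can be re-run in isolation; `replicate = 0` is
#' reserved for the scenario's own parameter draw.
#'
#' @param base_seed Ensemble base seed.
#' @param i Scenario index (1-based).
#' @param j Replicate index (1-based; 0 for parameter sampling).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
scenario_seed <- function(base_seed, i, j = 0) {
  as.integer((as.double(base_seed) + 100003 * as.double(i) + 1009 * as.double(j)) %%
               2147483647)
}

## draw one scenario's parameters (seeded by the caller)
sample_one_scenario <- function(spec, seed) {
  set.seed(seed)
  lo <- spec$n_groups[1]; hi <- spec$n_groups[2]
  G <- if (lo == hi) lo else sample(lo:hi, 1)
  lo <- spec$total_size[1]; hi <- spec$total_size[2]
  total <- if (lo == hi) lo else sample(lo:hi, 1)

  # symmetric Dirichlet(1) split of the census, floored at min_group_size
  prop <- stats::rexp(G)
  prop <- prop / sum(prop)
  sizes <- pmax(spec$min_group_size, round(prop * total))

  dz <- stats::runif(G) < spec$prob_delta_zero
  delta <- ifelse(dz, 0, stats::runif(G, spec$delta[1], spec$delta[2]))
  r0 <- stats::runif(G, spec$r0[1], spec$r0[2])

  lo <- spec$imports[1]; hi <- spec$imports[2]
  m <- if (lo == hi) lo else sample(lo:hi, 1)
  imports <- integer(G)
  for (k in seq_len(m)) {
    open <- which(imports < sizes)      # never seed beyond a group's census
    pick <- open[sample.int(length(open), 1)]
    imports[pick] <- imports[pick] + 1L
  }

  scenario(group_sizes = sizes, delta = delta, r0 = r0, imports = imports,
           generation = generation_pmf(spec$gt_mean, spec$gt_sd),
           incubation = incubation_pmf(spec$inc_mean, spec$inc_sd),
           horizon = spec$horizon)
}

#' Draw an ensemble of scenarios
#'
#' Samples `n_scenarios` full scenario parameterisations from the
#' distributions in the spec. Every scenario is drawn under its own seed
#' derived from the spec's `base_seed`, so the ensemble is reproducible as a
#' whole and any single scenario can be regenerated in isolation.
#'
#' @param spec An [ensemble_spec()].
#' @return A list of [scenario()] objects, with the manifest tibble (one row
#'   per scenario-group, including every seed) attached as attribute
#'   `"manifest"` — see [ensemble_manifest()].
#' @export
sample_scenarios <- function(spec) {
  validate_ensemble_spec(spec)
  scenarios <- purrr::map(seq_len(spec$n_scenarios), function(i) {
    sample_one_scenario(spec, scenario_seed(spec$base_seed, i, 0))
  })
  attr(scenarios, "manifest") <- build_manifest(scenarios, spec)
  scenarios
}

build_manifest <- function(scenarios, spec) {
  purrr::imap(scenarios, function(sc, i) {
    tibble::tibble(
      scenario = i,
      scenario_seed = scenario_seed(spec$base_seed, i, 0),
      group = sc$labels,
      size = sc$group_sizes,
      delta_true = sc$delta,
      r0 = sc$r0,
      imports = sc$imports,
      n_groups = length(sc$labels),
      total_size = sum(sc$group_sizes),
      n_replicates = spec$n_replicates,
      base_seed = spec$base_seed,
      gt_mean = spec$gt_mean, gt_sd = spec$gt_sd,
      inc_mean = spec$inc_mean, inc_sd = spec$inc_sd,
      horizon = spec$horizon
    )
  }) |> dplyr::bind_rows()
}

#' @rdname sample_scenarios
#' @param scenarios The list returned by [sample_scenarios()].
#' @return For `ensemble_manifest()`: the manifest tibble.
#' @export
ensemble_manifest <- function(scenarios) {
  m <- attr(scenarios, "manifest")
  if (is.null(m)) abort_validation("no manifest attached; use sample_scenarios().")
  m
}
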
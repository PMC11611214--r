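#' Discretised gamma probability mass functions for epidemiological delays
#'
#' Places the mass of a gamma distribution with the given mean and standard
#' deviation on integer days: day `d` receives `F(d + 0.5) - F(d - 0.5)`
#' (day 0 receives `F(0.5)`), truncated where the upper tail drops below
#' `tol` and renormalised to sum to 1. `generation_pmf()` additionally zeroes
#' the mass at lag 0 and renormalises — a case cannot infect others on its own
#' infection day — which is the form the simulator's daily force-of-infection
#' kernel expects. `incubation_pmf()` keeps the mass at delay 0 (same-day
#' onset is possible).
#'
#' @param mean,sd Mean and standard deviation of the underlying gamma
#'   distribution, in days (both positive).
#' @param tol Upper-tail probability at which the support is truncated.
#' @return A numeric vector `p` where `p[i]` is the mass at day `i - 1`,
#'   summing to 1.
#' @examples
#' w <- generation_pmf(mean = 5, sd = 2)
#' sum(w)
#' w[1]  # no same-day transmission
#' @export
discretise_gamma <- function(mean, sd, tol = 1e-8) {
  if (length(mean) != 1 || length(sd) != 1 || is.na(mean) || is.na(sd) ||
      mean <= 0 || sd <= 0) {
    abort_validation("`mean` and `sd` must be single positive numbers.")
  }
  shape <- (mean / sd)^2
  rate <- mean / sd^2
  kmax <- max(1L, ceiling(stats::qgamma(1 - tol, shape, rate) + 0.5))
  d <- 0:kmax
  p <- stats::pgamma(d + 0.5, shape, rate) - stats::pgamma(pmax(d - 0.5, 0), shape, rate)
  p / sum(p)
}

#' @rdname discretise_gamma
#' @export
generation_pmf <- function(mean = 5, sd = 2, tol = 1e-8) {
  p <- discretise_gamma(mean, sd, tol)
  p[1] <- 0
  p / sum(p)
}

#' @rdname discretise_gamma
#' @export
incubation_pmf <- function(mean = 4, sd = 2, tol = 1e-8) {
  discretise_gamma(mean, sd, tol)
}

#' Specify one outbreak scenario
#'
#' Bundles and validates everything the branching-process simulator needs:
#' per-group census sizes, true assortativity `delta`, basic reproduction
#' numbers `r0` and initial imports, plus the epidemic-level generation-time
#' and incubation probability mass functions and the simulation horizon.
#'
#' @param group_sizes Census size per group (positive integers).
#' @param delta True rescaled assortativity per group, in \[-1, 1\].
#' @param r0 Basic reproduction number per group (non-negative).
#' @param imports Number of cases seeded at day 0 per group; at least one
#'   import overall, and no more imports than a group's census.
#' @param generation Generation-time pmf over integer lags (mass at lag 0
#'   must be 0); see [generation_pmf()].
#' @param incubation Incubation-period pmf over integer delays from
#'   infection to symptom onset; see [incubation_pmf()].
#' @param horizon Number of daily steps to simulate (default 365).
#' @param labels Optional group labels (default `g1 ... gG`).
#' @return A validated object of class `transmix_scenario`.
#' @examples
#' sc <- scenario(group_sizes = c(80, 120), delta = c(0.5, 0),
#'                r0 = c(2, 1.5), imports = c(1, 0))
#' @export
scenario <- function(group_sizes, delta, r0, imports,
                     generation = generation_pmf(),
                     incubation = incubation_pmf(),
                     horizon = 365, labels = NULL) {
  G <- length(group_sizes)
  if (is.null(labels)) labels <- paste0("g", seq_len(G))
  x <- structure(
    list(group_sizes = as.numeric(group_sizes), delta = as.numeric(delta),
         r0 = as.numeric(r0), imports = as.numeric(imports),
         generation = as.numeric(generation), incubation = as.numeric(incubation),
         horizon = as.integer(horizon), labels = as.character(labels)),
    class = "transmix_scenario"
  )
  validate_scenario(x)
}

#' @rdname scenario
#' @param x A `transmix_scenario` object.
#' @export
validate_scenario <- function(x) {
  if (!inherits(x, "transmix_scenario")) {
    abort_validation("not a `transmix_scenario` object.")
  }
  G <- length(x$group_sizes)
  if (G < 1) abort_validation("at least one group is required.")
  lens <- lengths(x[c("delta", "r0", "imports", "labels")])
  if (any(lens != G)) {
    abort_validation("`delta`, `r0`, `imports` and `labels` must all have ",
                     "one entry per group (", G, ").")
  }
  if (any(x$group_sizes < 1) || any(x$group_sizes != round(x$group_sizes))) {
    abort_validation("`group_sizes` must be positive integers.")
  }
  if (any(x$delta < -1) || any(x$delta > 1)) {
    abort_validation("`delta` must lie in [-1, 1].")
  }
  if (any(x$r0 < 0)) abort_validation("`r0` must be non-negative.")
  if (any(x$imports < 0) || any(x$imports != round(x$imports))) {
    abort_validation("`imports` must be non-negative integers.")
  }
  if (sum(x$imports) < 1) {
    abort_validation("at least one group needs an initial import.")
  }
  if (any(x$imports > x$group_sizes)) {
    abort_validation("`imports` cannot exceed the group census.")
  }
  for (nm in c("generation", "incubation")) {
    p <- x[[nm]]
    if (length(p) < 1 || any(p < 0) || abs(sum(p) - 1) > 1e-6) {
      abort_validation("`", nm, "` must be a non-negative pmf summing to 1.")
    }
  }
  if (x$generation[1] != 0) {
    abort_validation("the generation-time pmf must place no mass at lag 0.")
  }
  if (is.na(x$horizon) || x$horizon < 1) {
    abort_validation("`horizon` must be a positive integer number of days.")
  }
  if (anyDuplicated(x$labels)) abort_validation("group labels must be unique.")
  invisible(x)
}

#' @export
print.transmix_scenario <- function(x, ...) {
  cat("<transmix_scenario> ", length(x$group_sizes), " groups, total census ",
      sum(x$group_sizes), ", horizon ", x$horizon, " days\n", sep = "")
  print(tibble::tibble(group = x$labels, size = x$group_sizes,
                       delta = x$delta, r0 = x$r0, imports = x$imports))
  invisible(x)
}

#' Group census table of a scenario
#'
#' @param x A `transmix_scenario`.
#' @return A tibble with columns `group` and `size`, ready for
#'   [estimate_assortativity()].
#' @export
scenario_group_table <- function(x) {
  validate_scenario(x)
  tibble::tibble(group = x$labels, size = x$group_sizes)
}

#' Per-infector force of infection towards each group
#'
#' The daily kernel of the branching process: an individual from group `a`
#' infected on day `s` exerts, on day `t`, a force of infection
#' `w(t - s) * r0[a] * P[b, a]` towards each group `b`, where `w` is the
#' generation-time pmf and `P` the expected mixing matrix. Summed over all
#' days and recipient groups this equals `r0[a]`, so `r0` is the expected
#' number of secondary cases in a fully susceptible population.
#'
#' @param infection_day Day the infector was infected.
#' @param r0 The infector's group reproduction number.
#' @param pi_col Mixing-matrix column for the infector's group (a probability
#'   vector over recipient groups).
#' @param w Generation-time pmf (`w[i]` = mass at lag `i - 1`; `w[1] = 0`).
#' @param t Current day.
#' @return Numeric vector of per-recipient-group force of infection; zero
#'   outside the generation-time support.
#' @export
individual_foi <- function(infection_day, r0, pi_col, w, t) {
  lag <- t - infection_day
  if (lag < 1 || lag > length(w) - 1) return(numeric(length(pi_col)))
  w[lag + 1] * r0 * pi_col
}

## Branching-process core on plain vectors; `simulate_outbreak()` wraps it.
## Draw order per day is fixed for reproducibility: binomial case counts in
## group order, then per group (in order) the infector draws for its new
## cases, then their incubation delays.
sim_core <- function(sc, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  G <- length(sc$group_sizes)
  N <- sc$group_sizes
  if (G == 1) {
    P <- matrix(1, 1, 1)
  } else {
    f <- N / sum(N)
    P <- mixing_matrix(gamma_from_delta(sc$delta), f)
  }
  w <- sc$generation
  max_lag <- length(w) - 1L          # w[1] is lag 0 (zero mass)
  inc <- sc$incubation
  ninc <- length(inc)

  cap <- sum(N)
  grp <- integer(cap); inf_day <- integer(cap)
  onset <- integer(cap); infector <- integer(cap)   # 0 = import
  n <- 0L

  # imports at day 0, group order; incubation draws in case order
  for (a in seq_len(G)) {
    k <- sc$imports[a]
    if (k > 0) {
      ix <- n + seq_len(k)
      grp[ix] <- a; inf_day[ix] <- 0L; infector[ix] <- 0L
      onset[ix] <- sample.int(ninc, k, replace = TRUE, prob = inc) - 1L
      n <- n + k
    }
  }
  S <- N - sc$imports

  for (t in 0:(sc$horizon - 1L)) {
    if (n == 0L || all(S == 0)) break
    max_s <- max(inf_day[seq_len(n)])
    if (t > max_s + max_lag) break   # no present or future infectious pressure

    act <- which(inf_day[seq_len(n)] >= t - max_lag & inf_day[seq_len(n)] <= t - 1L)
    if (length(act) == 0L) next
    base <- w[t - inf_day[act] + 1L] * sc$r0[grp[act]]
    pos <- base > 0
    if (!any(pos)) next
    act <- act[pos]; base <- base[pos]
    ga <- grp[act]

    lambda <- as.vector(P[, ga, drop = FALSE] %*% base)
    p <- 1 - exp(-lambda / N)
    X <- stats::rbinom(G, S, p)
    if (all(X == 0L)) next
    S <- S - X
    for (b in which(X > 0L)) {
      wv <- base * P[b, ga]
      who <- act[sample.int(length(act), X[b], replace = TRUE, prob = wv)]
      delay <- sample.int(ninc, X[b], replace = TRUE, prob = inc) - 1L
      ix <- n + seq_len(X[b])
      grp[ix] <- b
      inf_day[ix] <- t + 1L
      onset[ix] <- t + 1L + delay
      infector[ix] <- who
      n <- n + X[b]
    }
  }

  idx <- seq_len(n)
  list(group = grp[idx], infection_day = inf_day[idx], onset_day = onset[idx],
       infector = infector[idx])
}

#' Simulate one outbreak as a discrete-time branching process
#'
#' Runs a stochastic, group-structured branching process in daily steps. Each
#' infected individual `j` from group `a`, infected on day `s`, exerts a force
#' of infection `w(t - s) * r0[a] * P[b, a]` on group `b` at day `t`
#' ([individual_foi()]). Groups receive total force `lambda_b(t)`, each of the
#' `S_b(t)` remaining susceptibles is infected with probability
#' `1 - exp(-lambda_b(t) / N_b)`, and the number of new cases in group `b` is
#' a binomial draw; new cases are allocated at random among susceptibles and
#' become permanently immune. Each new case's infector is drawn from all
#' currently infectious individuals with probability proportional to their
#' individual contribution to the group's force of infection, and its symptom
#' onset is its infection day plus an independent incubation draw. The run
#' stops early once no infectious pressure can ever arise again (all
#' susceptibles depleted, or every case is past the generation-time support).
#'
#' @param sc A [scenario()].
#' @param seed Integer seed; the same scenario and seed reproduce the
#'   identical tree.
#' @return A line-list tibble with one row per infected case: `case_id`,
#'   `group`, `infection_day`, `onset_day`, `infector_id` (`NA` for the
#'   imported index cases).
#' @examples
#' sc <- scenario(group_sizes = c(80, 120), delta = c(0.5, 0),
#'                r0 = c(2, 1.5), imports = c(1, 0))
#' ll <- simulate_outbreak(sc, seed = 1)
#' @export
simulate_outbreak <- function(sc, seed = NULL) {
  validate_scenario(sc)
  res <- sim_core(sc, seed)
  tibble::tibble(
    case_id = as.character(seq_along(res$group)),
    group = sc$labels[res$group],
    onset_day = res$onset_day,
    infection_day = res$infection_day,
    infector_id = ifelse(res$infector == 0L, NA_character_,
                         as.character(res$infector))
  )
}
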
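#' Group census fractions
#'
#' Computes the relative size \eqn{f_a = N_a / \sum_g N_g} of each group from
#' a group table. At least two groups are required: with a single group every
#' transmission is trivially within-group and the assortativity coefficient is
#' undefined (the fraction must lie strictly inside (0, 1)).
#'
#' @param groups A data frame with columns `group` (label) and `size`
#'   (census count, positive integer).
#' @return A tibble with columns `group`, `size` and `fraction`, in the input
#'   order. Fractions sum to 1.
#' @examples
#' group_fractions(data.frame(group = c("hcw", "patient"), size = c(30, 70)))
#' @export
group_fractions <- function(groups) {
  groups <- as_group_table(groups)
  if (nrow(groups) < 2) {
    abort_validation("`groups` must contain at least 2 groups; got ", nrow(groups), ".")
  }
  tibble::tibble(
    group = groups$group,
    size = groups$size,
    fraction = groups$size / sum(groups$size)
  )
}

## coerce and validate a group table (group, size)
as_group_table <- function(groups) {
  if (!is.data.frame(groups) || !all(c("group", "size") %in% names(groups))) {
    abort_validation("`groups` must be a data frame with columns `group` and `size`.")
  }
  size <- groups$size
  if (any(is.na(size)) || any(size < 1) || any(size != round(size))) {
    abort_validation("every group `size` must be a positive integer.")
  }
  if (anyDuplicated(groups$group)) {
    abort_validation("group labels must be unique.")
  }
  tibble::tibble(group = as.character(groups$group), size = as.numeric(size))
}

#' Assortativity coefficient from a within-group transmission proportion
#'
#' Inverts the within-group mixing proportion: given the proportion
#' \eqn{\pi_{a \leftarrow a}} of transmissions from group *a* that stay in
#' group *a*, and the group's relative size \eqn{f_a}, returns
#' \eqn{\gamma_a = \pi (1 - f) / (f (1 - \pi))}. \eqn{\gamma = 1} is
#' homogeneous mixing; \eqn{\pi = 1} maps to `Inf` (fully assortative) and
#' \eqn{\pi = 0} to 0 (fully disassortative).
#'
#' @param pi Within-group transmission proportion(s) in \[0, 1\].
#' @param f Relative group size(s), strictly in (0, 1).
#' @return Numeric vector of gamma values in \[0, Inf\].
#' @seealso [delta_from_gamma()], [pi_from_gamma()]
#' @export
gamma_from_pi <- function(pi, f) {
  check_proportion(pi, "pi")
  check_fraction(f)
  out <- pi * (1 - f) / (f * (1 - pi))
  out[pi == 1] <- Inf
  out[pi == 0] <- 0
  out
}

#' Expected within-group proportion for a given assortativity
#'
#' The forward map of [gamma_from_pi()]: the diagonal entry of the mixing
#' matrix, \eqn{\pi_{a \leftarrow a} = \gamma f / ((1 - f) + \gamma f)}.
#' `gamma = Inf` gives 1.
#'
#' @inheritParams gamma_from_pi
#' @param gamma Assortativity coefficient(s), non-negative or `Inf`.
#' @return Numeric vector of proportions in \[0, 1\].
#' @export
pi_from_gamma <- function(gamma, f) {
  check_gamma(gamma)
  check_fraction(f)
  out <- gamma * f / ((1 - f) + gamma * f)
  out[is.infinite(gamma)] <- 1
  out
}

#' Rescaled assortativity delta from gamma
#'
#' Maps the multiplicative assortativity coefficient onto \[-1, 1\]:
#' \eqn{\delta = (\gamma - 1)/(\gamma + 1)}, with \eqn{\gamma = \infty}
#' mapping to 1. 0 is homogeneous mixing, -1 fully disassortative, 1 fully
#' assortative. The map is strictly increasing.
#'
#' @inheritParams pi_from_gamma
#' @return Numeric vector of delta values in \[-1, 1\].
#' @export
delta_from_gamma <- function(gamma) {
  check_gamma(gamma)
  out <- (gamma - 1) / (gamma + 1)
  out[is.infinite(gamma)] <- 1
  out
}

#' @rdname delta_from_gamma
#' @param delta Rescaled assortativity in \[-1, 1\]; `delta = 1` maps to `Inf`.
#' @export
gamma_from_delta <- function(delta) {
  if (any(is.na(delta)) || any(delta < -1) || any(delta > 1)) {
    abort_validation("`delta` must lie in [-1, 1].")
  }
  out <- (1 + delta) / (1 - delta)
  out[delta == 1] <- Inf
  out
}

#' Rescaled assortativity directly from the within-group proportion
#'
#' Closed form for \eqn{\delta_a} in terms of the observed proportion and the
#' group fraction: \eqn{\delta = (\pi - f) / (\pi + f(1 - 2\pi))}. Identical to
#' `delta_from_gamma(gamma_from_pi(pi, f))` and strictly increasing in `pi`,
#' which is what licenses transforming interval endpoints for `pi` into
#' interval endpoints for `delta`.
#'
#' @inheritParams gamma_from_pi
#' @return Numeric vector of delta values in \[-1, 1\].
#' @export
delta_from_pi <- function(pi, f) {
  check_proportion(pi, "pi")
  check_fraction(f)
  (pi - f) / (pi + f * (1 - 2 * pi))
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval on a binomial proportion from beta-distribution
#' quantiles: lower bound `qbeta(alpha/2, x, n - x + 1)` (0 when `x = 0`),
#' upper bound `qbeta(1 - alpha/2, x + 1, n - x)` (1 when `x = n`). The
#' interval is conservative: coverage is at least `1 - alpha`.
#'
#' @param x Number of successes (vectorised).
#' @param n Number of trials, at least 1.
#' @param alpha Significance level in (0, 1); the interval has nominal
#'   coverage `1 - alpha`.
#' @return A tibble with columns `low` and `high`.
#' @examples
#' clopper_pearson(6, 10, 0.05)
#' @export
clopper_pearson <- function(x, n, alpha = 0.05) {
  if (length(alpha) != 1 || is.na(alpha) || alpha <= 0 || alpha >= 1) {
    abort_validation("`alpha` must be a single value in (0, 1).")
  }
  if (any(is.na(x)) || any(is.na(n)) || any(x < 0) || any(x > n)) {
    abort_validation("need 0 <= x <= n.")
  }
  if (any(n < 1)) {
    abort_undefined("Clopper-Pearson interval is undefined for 0 trials.")
  }
  k <- pmax(length(x), length(n))
  b <- cp_bounds(rep_len(x, k), rep_len(n, k), alpha)
  tibble::tibble(low = b$low, high = b$high)
}

## beta-quantile kernel shared by the estimator and the study harness
cp_bounds <- function(x, n, alpha) {
  list(
    low = ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1)),
    high = ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x))
  )
}

#' Expected mixing matrix for given assortativities and group fractions
#'
#' Builds the G x G column-stochastic matrix whose column *a* gives the
#' expected distribution over recipient groups of transmissions emitted by an
#' infector in group *a*: diagonal \eqn{\gamma_a f_a / ((1-f_a) + \gamma_a f_a)}
#' and off-diagonal \eqn{f_b / ((1-f_a) + \gamma_a f_a)}. An infinite
#' \eqn{\gamma_a} yields the unit column on *a* (all transmissions stay
#' within the group).
#'
#' @param gamma Per-group assortativity coefficients (non-negative or `Inf`).
#' @param fraction Per-group relative sizes, summing to 1.
#' @param labels Optional dimnames.
#' @return A G x G numeric matrix; every column sums to 1.
#' @examples
#' mixing_matrix(gamma = c(2, 1), fraction = c(0.3, 0.7))
#' @export
mixing_matrix <- function(gamma, fraction, labels = NULL) {
  if (length(gamma) != length(fraction)) {
    abort_validation("`gamma` and `fraction` must have the same length.")
  }
  check_gamma(gamma)
  check_fraction(fraction)
  if (abs(sum(fraction) - 1) > 1e-8) {
    abort_validation("`fraction` must sum to 1.")
  }
  G <- length(fraction)
  P <- matrix(0, G, G)
  for (a in seq_len(G)) {
    if (is.infinite(gamma[a])) {
      P[a, a] <- 1
    } else {
      denom <- (1 - fraction[a]) + gamma[a] * fraction[a]
      P[, a] <- fraction / denom
      P[a, a] <- gamma[a] * fraction[a] / denom
    }
  }
  if (!is.null(labels)) dimnames(P) <- list(labels, labels)
  P
}

#' Point estimate and confidence interval for delta from transmission counts
#'
#' The core estimator: given the number of within-group transmission pairs
#' `tau_within` and the total number of transmissions emitted by the group
#' `n_emitted`, the within-group proportion is
#' \eqn{\hat\pi = \tau_{a\leftarrow a} / \tau_{\cdot\leftarrow a}} and
#' \eqn{\hat\delta = (\hat\pi - f)/(\hat\pi + f(1 - 2\hat\pi))}. The
#' confidence interval maps the exact Clopper-Pearson bounds on \eqn{\pi}
#' through the same strictly increasing transform, so interval ordering is
#' preserved. Groups that emitted no transmissions get `status =
#' "no_emissions"` and `NA` estimates rather than an error, so batch
#' evaluation over many simulations never aborts.
#'
#' @param tau_within Within-group transmission count(s).
#' @param n_emitted Total transmissions emitted by the group(s).
#' @param fraction Relative group size(s) in (0, 1).
#' @param alpha Significance level for the interval.
#' @param group Optional group labels carried into the output.
#' @return A tibble with columns `group`, `n_emitted`, `tau_within`, `pi_hat`,
#'   `gamma_hat`, `delta_hat`, `ci_low`, `ci_high`, `alpha`, `status`.
#' @examples
#' estimate_delta(tau_within = 6, n_emitted = 10, fraction = 0.5)
#' @export
estimate_delta <- function(tau_within, n_emitted, fraction, alpha = 0.05,
                           group = NULL) {
  if (any(is.na(tau_within)) || any(is.na(n_emitted)) ||
      any(tau_within < 0) || any(n_emitted < 0) || any(tau_within > n_emitted)) {
    abort_validation("need 0 <= tau_within <= n_emitted, no missing values.")
  }
  check_fraction(fraction)
  k <- max(length(tau_within), length(n_emitted), length(fraction))
  tau_within <- rep_len(tau_within, k)
  n_emitted <- rep_len(n_emitted, k)
  fraction <- rep_len(fraction, k)
  if (is.null(group)) group <- as.character(seq_len(k))

  ok <- n_emitted > 0
  pi_hat <- ifelse(ok, tau_within / n_emitted, NA_real_)
  delta_hat <- gamma_hat <- ci_low <- ci_high <- rep(NA_real_, k)
  if (any(ok)) {
    gamma_hat[ok] <- gamma_from_pi(pi_hat[ok], fraction[ok])
    delta_hat[ok] <- delta_from_pi(pi_hat[ok], fraction[ok])
    ci <- clopper_pearson(tau_within[ok], n_emitted[ok], alpha)
    ci_low[ok] <- delta_from_pi(ci$low, fraction[ok])
    ci_high[ok] <- delta_from_pi(ci$high, fraction[ok])
  }
  out <- tibble::tibble(
    group = rep_len(as.character(group), k),
    n_emitted = as.integer(n_emitted),
    tau_within = as.integer(tau_within),
    fraction = fraction,
    pi_hat = pi_hat,
    gamma_hat = gamma_hat,
    delta_hat = delta_hat,
    ci_low = ci_low,
    ci_high = ci_high,
    alpha = alpha,
    status = ifelse(ok, "ok", "no_emissions")
  )
  new_estimates_tbl(out)
}

new_estimates_tbl <- function(x) {
  class(x) <- c("transmix_estimates", class(tibble::as_tibble(x)))
  x
}

## ---- input checks and classed conditions --------------------------------

abort_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("transmix_validation_error", "error")))
}

abort_undefined <- function(...) {
  stop(errorCondition(paste0(...), class = c("transmix_undefined_error", "error")))
}

check_proportion <- function(p, name) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort_validation("`", name, "` must lie in [0, 1].")
  }
}

check_fraction <- function(f) {
  if (any(is.na(f)) || any(f <= 0) || any(f >= 1)) {
    abort_validation("group fractions must lie strictly in (0, 1); ",
                     "a single-group population has no assortativity.")
  }
}

check_gamma <- function(gamma) {
  if (any(is.na(gamma)) || any(gamma < 0)) {
    abort_validation("`gamma` must be non-negative (Inf allowed).")
  }
}
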
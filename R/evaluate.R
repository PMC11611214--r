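#' Epidemic peak of a daily onset-incidence series
#'
#' The peak day is the day with the highest symptom-onset incidence at or
#' after the first case; ties are broken towards the earliest such day, so an
#' early plateau is treated as the peak rather than a later recurrence.
#'
#' @param incidence Daily case counts (non-negative).
#' @param days Day labels for the series (default `0, 1, ...`).
#' @return The peak day, on the scale of `days`; `NA` for an all-zero series.
#' @examples
#' detect_peak(c(1, 0, 3, 2, 3))  # day 2: earliest maximum
#' @export
detect_peak <- function(incidence, days = seq_along(incidence) - 1) {
  if (length(incidence) == 0 || all(incidence == 0)) return(NA_real_)
  if (any(incidence < 0)) abort_validation("`incidence` must be non-negative.")
  first <- which(incidence > 0)[1]
  after <- seq(first, length(incidence))
  days[after[which.max(incidence[after])]]
}

#' End day of the peak-relative analysis window
#'
#' The analysis window for a group runs from its first case to
#' `first + round(epsilon * (T - first))`, where `T` is the group's peak day
#' and `epsilon` the peak coefficient. The peak coefficient scales the time
#' elapsed between the group's first case and its peak, so `epsilon = 1`
#' analyses exactly up to the peak and the window does not depend on when the
#' group's outbreak started in calendar time. Rounding is half-up to whole
#' days.
#'
#' @param first_case_day Day of the group's first symptom onset.
#' @param peak_day The group's epidemic peak day `T` (from [detect_peak()]).
#' @param epsilon Peak coefficient, non-negative.
#' @return Integer day; `NA` where first or peak day is `NA`.
#' @examples
#' window_end(10, 20, 0.5)  # 15
#' @export
window_end <- function(first_case_day, peak_day, epsilon) {
  if (any(epsilon < 0, na.rm = TRUE)) {
    abort_validation("`epsilon` must be non-negative.")
  }
  if (any(peak_day < first_case_day, na.rm = TRUE)) {
    abort_validation("`peak_day` cannot precede `first_case_day`.")
  }
  # round-half-up: base round() would take .5 to the nearest even day
  first_case_day + floor(epsilon * (peak_day - first_case_day) + 0.5)
}

#' Peak asynchronicity across groups
#'
#' The sample standard deviation (n - 1 denominator) of per-group peak days —
#' a summary of how staggered the groups' epidemics are. Groups without a
#' defined peak are dropped; fewer than two defined peaks give `NA`.
#'
#' @param peak_days Per-group peak days.
#' @return Standard deviation in days, or `NA`.
#' @export
peak_asynchronicity <- function(peak_days) {
  p <- peak_days[!is.na(peak_days)]
  if (length(p) < 2) return(NA_real_)
  stats::sd(p)
}

#' Per-group epidemic summary of a line list
#'
#' @param linelist A transmission-chain line list.
#' @param groups Optional group labels to report (zero-case groups included).
#' @return A tibble with columns `group`, `n_cases`, `first_case_day`,
#'   `peak_day`.
#' @export
summarise_outbreak <- function(linelist, groups = NULL) {
  ll <- validate_linelist(linelist)
  if (is.null(groups)) groups <- unique(ll$group)
  out <- tibble::tibble(group = as.character(groups),
                        n_cases = 0L,
                        first_case_day = NA_real_, peak_day = NA_real_)
  for (i in seq_along(groups)) {
    o <- ll$onset_day[ll$group == groups[i]]
    if (length(o) == 0) next
    out$n_cases[i] <- length(o)
    out$first_case_day[i] <- min(o)
    inc <- tabulate(o - min(o) + 1L)
    out$peak_day[i] <- detect_peak(inc, days = min(o) + seq_along(inc) - 1)
  }
  out
}

## ---- fast replicate-level machinery (plain vectors, integer group codes) --

core_from_linelist <- function(ll, labels) {
  grp <- match(ll$group, labels)
  if (any(is.na(grp))) {
    abort_validation("line-list group(s) not among scenario groups: ",
                     paste(unique(ll$group[is.na(grp)]), collapse = ", "))
  }
  inf <- match(ll$infector_id, ll$case_id)
  inf[is.na(ll$infector_id)] <- 0L
  list(group = grp, infection_day = ll$infection_day %||% rep(NA_real_, nrow(ll)),
       onset_day = ll$onset_day, infector = inf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## One replicate -> one row per (group, epsilon, alpha), as plain vectors.
replicate_rows <- function(res, sc, epsilons, alphas) {
  G <- length(sc$group_sizes)
  frac <- sc$group_sizes / sum(sc$group_sizes)
  grp <- res$group; onset <- res$onset_day
  ncase <- tabulate(grp, G)
  first <- peak <- rep(NA_real_, G)
  for (a in which(ncase > 0)) {
    o <- onset[grp == a]
    m <- min(o)
    inc <- tabulate(o - m + 1L)
    first[a] <- m
    peak[a] <- m + which.max(inc) - 1L   # earliest max; series starts at first case
  }
  asyn <- peak_asynchronicity(peak)
  last_inf <- if (length(res$infection_day) > 0) suppressWarnings(max(res$infection_day)) else NA_real_

  has <- res$infector > 0L
  j <- res$infector[has]
  e <- grp[j]
  oj <- onset[j]; ok <- onset[has]
  within <- e == grp[has]

  ncell <- length(epsilons) * length(alphas)
  out <- vector("list", ncell)
  k <- 0L
  for (eps in epsilons) {
    wend <- window_end(first, peak, eps)
    wv <- wend[e]
    keep <- !is.na(wv) & oj <= wv & ok <= wv
    tauT <- tabulate(e[keep], G)
    tauW <- tabulate(e[keep & within], G)
    okg <- tauT > 0 & is.finite(frac) & frac > 0 & frac < 1
    dh <- rep(NA_real_, G)
    if (any(okg)) dh[okg] <- delta_from_pi(tauW[okg] / tauT[okg], frac[okg])
    for (al in alphas) {
      cl <- ch <- rep(NA_real_, G)
      if (any(okg)) {
        b <- cp_bounds(tauW[okg], tauT[okg], al)
        cl[okg] <- delta_from_pi(b$low, frac[okg])
        ch[okg] <- delta_from_pi(b$high, frac[okg])
      }
      k <- k + 1L
      out[[k]] <- list(
        group = sc$labels, epsilon = rep(eps, G), alpha = rep(al, G),
        delta_true = sc$delta, fraction = frac, size = sc$group_sizes,
        r0 = sc$r0, n_cases = ncase,
        first_case_day = first, peak_day = peak, window_end = wend,
        tau_within = tauW, n_emitted = tauT,
        delta_hat = dh, ci_low = cl, ci_high = ch,
        status = ifelse(okg, "ok", "no_emissions"),
        peak_asynchronicity = rep(asyn, G),
        last_infection_day = rep(last_inf, G)
      )
    }
  }
  fields <- names(out[[1]])
  stats::setNames(lapply(fields, function(f) {
    do.call(c, lapply(out, `[[`, f))
  }), fields)
}

bind_row_lists <- function(rows) {
  fields <- names(rows[[1]])
  tibble::as_tibble(stats::setNames(lapply(fields, function(f) {
    do.call(c, lapply(rows, `[[`, f))
  }), fields))
}

## shared cell aggregator for evaluate_replicates() and summarise_study()
summarise_cells <- function(reps, by) {
  reps |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      # summaries may not reuse names of columns still needed below:
      # summarise() masks a column as soon as a summary takes its name
      n_replicates = dplyr::n(),
      n_valid = sum(.data$status == "ok"),
      n_undefined = dplyr::n() - sum(.data$status == "ok"),
      bias = mean_or_na(.data$delta_true[.data$status == "ok"] -
                          .data$delta_hat[.data$status == "ok"]),
      coverage = mean_or_na(
        (.data$ci_low <= .data$delta_true &
           .data$delta_true <= .data$ci_high)[.data$status == "ok"]),
      sensitivity = if (.data$delta_true[1] != 0) {
        mean_or_na((.data$ci_low > 0 | .data$ci_high < 0)[.data$status == "ok"])
      } else NA_real_,
      specificity = if (.data$delta_true[1] == 0) {
        mean_or_na((.data$ci_low <= 0 & .data$ci_high >= 0)[.data$status == "ok"])
      } else NA_real_,
      mean_cases = mean(.data$n_cases),
      mean_peak_day = mean_or_na(.data$peak_day[!is.na(.data$peak_day)]),
      peak_asynchronicity = mean_or_na(
        .data$peak_asynchronicity[!is.na(.data$peak_asynchronicity)]),
      delta_true = .data$delta_true[1],
      .groups = "drop"
    ) |>
    dplyr::mutate(coverage_error = (1 - .data$alpha) - .data$coverage)
}

mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)

#' Estimator performance over replicate outbreaks of one scenario
#'
#' Computes the four performance metrics for each (group, epsilon, alpha)
#' cell over a set of replicate transmission trees simulated from one known
#' scenario: **bias**, the mean of (true delta - estimate); **coverage**, the
#' fraction of replicates whose confidence interval contains the true delta
#' (with `coverage_error = (1 - alpha) - coverage`, positive when uncertainty
#' is understated); **sensitivity**, for groups with nonzero true delta, the
#' fraction of replicates whose CI excludes 0; and **specificity**, for
#' truly homogeneous groups, the fraction whose CI contains 0. Replicates in
#' which a group emitted no transmissions inside the window are excluded from
#' every denominator and reported in `n_undefined`; a cell with no valid
#' replicate keeps `NA` metrics rather than being dropped.
#'
#' @param linelists A list of line lists, e.g. repeated [simulate_outbreak()]
#'   runs of `sc`.
#' @param sc The [scenario()] that generated them (supplies the true deltas).
#' @param epsilons Peak coefficients to evaluate.
#' @param alphas Significance levels to evaluate.
#' @return A tibble with one row per (group, epsilon, alpha).
#' @export
evaluate_replicates <- function(linelists, sc,
                                epsilons = 1,
                                alphas = c(0.05, 0.1, 0.25, 0.5)) {
  validate_scenario(sc)
  if (!is.list(linelists) || length(linelists) == 0 || is.data.frame(linelists)) {
    abort_validation("`linelists` must be a non-empty list of line lists.")
  }
  rows <- purrr::imap(linelists, function(ll, i) {
    r <- replicate_rows(core_from_linelist(validate_linelist(ll), sc$labels),
                        sc, epsilons, alphas)
    r$replicate <- rep(as.integer(i), length(r$group))
    r
  })
  summarise_cells(bind_row_lists(rows), by = c("group", "epsilon", "alpha"))
}

#' Replicate-level estimates for a whole scenario ensemble
#'
#' The workhorse of the simulation study: samples the ensemble, simulates
#' every scenario x replicate outbreak under its derived seed, analyses each
#' group inside its peak-relative window for every requested peak coefficient,
#' and returns one row per (scenario, replicate, group, epsilon, alpha) with
#' the truth, the estimate, its confidence interval, case counts, peak
#' timings and the replicate's last infection day.
#'
#' @param spec An [ensemble_spec()].
#' @param epsilons Peak coefficients to evaluate.
#' @param alphas Significance levels to evaluate.
#' @param verbose Log progress every 10% of scenarios.
#' @return A tibble of replicate-level results, with the ensemble manifest
#'   attached as attribute `"manifest"`.
#' @export
run_study_replicates <- function(spec, epsilons = 1, alphas = 0.05,
                                 verbose = FALSE) {
  validate_ensemble_spec(spec)
  scenarios <- sample_scenarios(spec)
  tick <- max(1L, spec$n_scenarios %/% 10L)
  per_scenario <- purrr::imap(scenarios, function(sc, i) {
    if (verbose && i %% tick == 0) {
      message("scenario ", i, "/", spec$n_scenarios)
    }
    rows <- lapply(seq_len(spec$n_replicates), function(j) {
      res <- sim_core(sc, seed = scenario_seed(spec$base_seed, i, j))
      r <- replicate_rows(res, sc, epsilons, alphas)
      r$replicate <- rep(as.integer(j), length(r$group))
      r
    })
    out <- bind_row_lists(rows)
    out$scenario <- i
    out
  })
  reps <- dplyr::bind_rows(per_scenario)
  attr(reps, "manifest") <- attr(scenarios, "manifest")
  reps
}

#' Aggregate replicate-level study rows into the performance report
#'
#' @param reps Output of [run_study_replicates()].
#' @return A `transmix_study` tibble, one row per
#'   (scenario, group, epsilon, alpha) cell with bias, coverage,
#'   coverage_error, sensitivity, specificity, replicate accounting, mean case
#'   counts, mean peak day and peak asynchronicity.
#' @export
summarise_study <- function(reps) {
  need <- c("scenario", "group", "epsilon", "alpha", "delta_true", "status")
  if (!all(need %in% names(reps))) {
    abort_validation("`reps` must come from run_study_replicates().")
  }
  cells <- summarise_cells(reps, by = c("scenario", "group", "epsilon", "alpha"))
  extra <- reps |>
    dplyr::distinct(.data$scenario, .data$group,
                    .data$fraction, .data$size, .data$r0)
  out <- dplyr::left_join(cells, extra, by = c("scenario", "group"))
  class(out) <- c("transmix_study", class(tibble::tibble()))
  out
}

#' Run a full estimator-performance study
#'
#' Convenience wrapper: [run_study_replicates()] followed by
#' [summarise_study()].
#'
#' @inheritParams run_study_replicates
#' @param alphas Significance levels (default the four evaluated levels
#'   0.05, 0.1, 0.25, 0.5).
#' @param keep_replicates Attach the replicate-level tibble as attribute
#'   `"replicates"`.
#' @return A `transmix_study` performance report (see [summarise_study()]).
#' @examples
#' \donttest{
#' spec <- ensemble_spec(n_scenarios = 4, n_replicates = 5, base_seed = 42)
#' report <- run_study(spec, epsilons = 1, alphas = 0.05)
#' }
#' @export
run_study <- function(spec, epsilons = 1, alphas = c(0.05, 0.1, 0.25, 0.5),
                      keep_replicates = FALSE, verbose = FALSE) {
  reps <- run_study_replicates(spec, epsilons = epsilons, alphas = alphas,
                               verbose = verbose)
  out <- summarise_study(reps)
  attr(out, "manifest") <- attr(reps, "manifest")
  if (keep_replicates) attr(out, "replicates") <- reps
  out
}
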
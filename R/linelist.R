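#' Validate a transmission-chain line list
#'
#' A line list records one case per row: `case_id`, `group`, `onset_day`
#' (integer day of symptom onset, 0-based from outbreak start), optionally
#' `infection_day`, and `infector_id` (`NA` or empty for imported cases).
#' Checks id uniqueness, resolvable infector links, and — when infection days
#' are present — that every infector was infected strictly before each of
#' their infectees.
#'
#' @param linelist A data frame as described above.
#' @return The line list as a tibble, invisibly validated; columns coerced to
#'   canonical types (`case_id`/`infector_id` character, days integer).
#' @export
validate_linelist <- function(linelist) {
  need <- c("case_id", "group", "onset_day", "infector_id")
  if (!is.data.frame(linelist) || !all(need %in% names(linelist))) {
    abort_validation("`linelist` must have columns ",
                     paste(need, collapse = ", "), ".")
  }
  ll <- tibble::tibble(
    case_id = as.character(linelist$case_id),
    group = as.character(linelist$group),
    onset_day = as.integer(linelist$onset_day),
    infector_id = as.character(linelist$infector_id)
  )
  ll$infector_id[!is.na(ll$infector_id) & ll$infector_id == ""] <- NA_character_
  if ("infection_day" %in% names(linelist)) {
    ll$infection_day <- as.integer(linelist$infection_day)
    ll <- ll[, c("case_id", "group", "onset_day", "infection_day", "infector_id")]
  }
  if (nrow(ll) == 0) return(ll)
  if (anyDuplicated(ll$case_id)) {
    abort_validation("`case_id` values must be unique.")
  }
  if (any(is.na(ll$onset_day))) {
    abort_validation("`onset_day` must be an integer day for every case.")
  }
  has_inf <- !is.na(ll$infector_id)
  idx <- match(ll$infector_id[has_inf], ll$case_id)
  if (any(is.na(idx))) {
    bad <- unique(ll$infector_id[has_inf][is.na(idx)])
    abort_validation("infector_id not found among case_id: ",
                     paste(utils::head(bad, 5), collapse = ", "))
  }
  if ("infection_day" %in% names(ll) && !any(is.na(ll$infection_day))) {
    if (any(ll$infection_day[has_inf] <= ll$infection_day[idx])) {
      abort_validation("every infector must be infected strictly before its infectee.")
    }
    if (any(ll$onset_day < ll$infection_day)) {
      abort_validation("`onset_day` cannot precede `infection_day`.")
    }
  }
  ll
}

#' Count within-group and total emitted transmissions per group
#'
#' Reads the transmission counts the delta estimator needs off a line list:
#' for each group *a*, `tau_within` is the number of infector-infectee pairs
#' with both cases in *a*, and `n_emitted` the number of pairs whose infector
#' is in *a*. A pair contributes only when **both** the infector's and the
#' infectee's symptom onsets fall on or before `window_end`, so the emitting
#' case is itself observable within the analysis window. Imported cases have
#' no infector and never contribute on the infectee side, but do count as
#' emitters of their own secondary cases.
#'
#' @param linelist A transmission-chain line list (see [validate_linelist()]).
#' @param groups Optional character vector of group labels to report
#'   (defaults to the groups present in the line list, in order of first
#'   appearance). May be a superset of the observed groups — census groups
#'   with no cases report zero counts — but a request sharing no label with a
#'   non-empty line list is rejected as unknown.
#' @param window_end Last symptom-onset day included in the analysis window
#'   (default `Inf`, the whole outbreak). May be a single day applied to all
#'   pairs, or a named vector giving a per-emitting-group window end.
#' @return A tibble with columns `group`, `tau_within`, `n_emitted`.
#' @examples
#' ll <- data.frame(
#'   case_id = c("A", "B", "C", "D"),
#'   group = c("g1", "g1", "g2", "g1"),
#'   onset_day = c(0, 3, 4, 6),
#'   infector_id = c(NA, "A", "A", "B")
#' )
#' count_transmissions(ll)
#' count_transmissions(ll, window_end = 4)
#' @export
count_transmissions <- function(linelist, groups = NULL, window_end = Inf) {
  ll <- validate_linelist(linelist)
  seen <- unique(ll$group)
  if (is.null(groups)) {
    groups <- seen
  } else {
    groups <- as.character(groups)
    # groups with no cases report zero counts, but a request sharing no label
    # with a non-empty line list is a typo, not a quiet zero
    if (nrow(ll) > 0 && !any(groups %in% seen)) {
      abort_validation("unknown group(s): ",
                       paste(setdiff(groups, seen), collapse = ", "),
                       "; known: ", paste(seen, collapse = ", "))
    }
  }
  has_inf <- !is.na(ll$infector_id)
  j <- match(ll$infector_id[has_inf], ll$case_id)  # infector row per pair
  emitter <- ll$group[j]
  onset_j <- ll$onset_day[j]
  onset_k <- ll$onset_day[has_inf]
  within <- emitter == ll$group[has_inf]

  if (length(window_end) > 1 || !is.null(names(window_end))) {
    if (is.null(names(window_end))) {
      abort_validation("a vector `window_end` must be named by group.")
    }
    wend <- window_end[emitter]
    wend[is.na(wend)] <- Inf
  } else {
    wend <- rep_len(window_end, length(emitter))
  }
  keep <- onset_j <= wend & onset_k <= wend

  fg <- factor(emitter[keep], levels = groups)
  tibble::tibble(
    group = groups,
    tau_within = as.integer(tabulate(fg[within[keep]], nbins = length(groups))),
    n_emitted = as.integer(tabulate(fg, nbins = length(groups)))
  )
}

#' Estimate per-group transmission assortativity from a line list
#'
#' The end-to-end estimator: counts within-group and emitted transmissions in
#' the analysis window ([count_transmissions()]), derives group fractions from
#' the census table, and returns the rescaled assortativity
#' \eqn{\hat\delta_a} per group with an exact Clopper-Pearson confidence
#' interval mapped onto the delta scale ([estimate_delta()]).
#'
#' @inheritParams count_transmissions
#' @param groups A data frame with columns `group` and `size` covering every
#'   group that appears in the line list.
#' @param alpha Significance level; the interval has nominal coverage
#'   `1 - alpha`.
#' @return A `transmix_estimates` tibble, one row per group in the census
#'   table, with `delta_hat`, `ci_low`, `ci_high` and a `status` column
#'   (`"no_emissions"` where the group emitted nothing in the window).
#' @examples
#' ll <- data.frame(
#'   case_id = c("A", "B", "C", "D"),
#'   group = c("g1", "g1", "g2", "g1"),
#'   onset_day = c(0, 3, 4, 6),
#'   infector_id = c(NA, "A", "A", "B")
#' )
#' estimate_assortativity(ll, data.frame(group = c("g1", "g2"), size = c(50, 50)))
#' @export
estimate_assortativity <- function(linelist, groups, alpha = 0.05,
                                   window_end = Inf) {
  gt <- group_fractions(groups)
  ll <- validate_linelist(linelist)
  if (nrow(ll) == 0) {
    abort_validation("the line list contains no cases.")
  }
  unknown <- setdiff(unique(ll$group), gt$group)
  if (length(unknown) > 0) {
    abort_validation("line-list group(s) missing from the group table: ",
                     paste(unknown, collapse = ", "),
                     "; known: ", paste(gt$group, collapse = ", "))
  }
  counts <- count_transmissions(ll, groups = gt$group, window_end = window_end)
  est <- estimate_delta(counts$tau_within, counts$n_emitted,
                        fraction = gt$fraction, alpha = alpha,
                        group = gt$group)
  attr(est, "window_end") <- window_end
  est
}

#' Estimate assortativity inside each group's peak-relative analysis window
#'
#' Applies the peak-coefficient analysis window before estimating: for each
#' group the window runs from its first symptom onset to
#' `first + round(epsilon * (T - first))`, where `T` is the group's epidemic
#' peak day ([detect_peak()]). `epsilon = 1` analyses transmission pairs up to
#' the group's peak; values below/above 1 truncate earlier/extend later.
#'
#' @inheritParams estimate_assortativity
#' @param epsilon Peak coefficient, a non-negative scalar.
#' @return A `transmix_estimates` tibble as for [estimate_assortativity()],
#'   with additional columns `first_case_day`, `peak_day` and `window_end`.
#' @export
estimate_assortativity_peak <- function(linelist, groups, epsilon = 1,
                                        alpha = 0.05) {
  if (length(epsilon) != 1 || is.na(epsilon) || epsilon < 0) {
    abort_validation("`epsilon` must be a single non-negative number.")
  }
  gt <- group_fractions(groups)
  ll <- validate_linelist(linelist)
  summ <- summarise_outbreak(ll, groups = gt$group)
  wend <- window_end(summ$first_case_day, summ$peak_day, epsilon)
  names(wend) <- summ$group
  est <- estimate_assortativity(ll, groups, alpha = alpha, window_end = wend)
  est$first_case_day <- summ$first_case_day[match(est$group, summ$group)]
  est$peak_day <- summ$peak_day[match(est$group, summ$group)]
  est$window_end <- unname(wend[match(est$group, summ$group)])
  est
}

#' Pool assortativity estimates over a set of plausible transmission trees
#'
#' When the true tree is uncertain (e.g. a posterior sample of reconstructed
#' transmission trees), the estimator can be applied to each tree and pooled.
#' The default pooling is the across-tree mean of the per-tree point
#' estimates, with an across-tree percentile interval as the reported spread;
#' trees in which a group emitted nothing are excluded from that group's pool
#' and counted. `pool = "counts"` instead sums the transmission counts across
#' trees and runs the estimator once on the pooled counts — simple, but it
#' lets trees that disagree on who emits dominate, so it is not the default.
#'
#' @param linelists A list of transmission-chain line lists (ideally over the
#'   same case set).
#' @inheritParams estimate_assortativity
#' @param pool `"mean"` (default) or `"counts"`.
#' @param probs Two probabilities for the across-tree percentile spread.
#' @return A tibble with one row per group: pooled `delta_hat`, the spread
#'   (`spread_low`, `spread_high`), `n_trees`, `n_undefined` and `status`
#'   (`"undefined"` when no tree yields an estimate for the group).
#' @export
estimate_assortativity_trees <- function(linelists, groups, alpha = 0.05,
                                         window_end = Inf,
                                         pool = c("mean", "counts"),
                                         probs = c(0.025, 0.975)) {
  pool <- match.arg(pool)
  if (!is.list(linelists) || length(linelists) == 0 || is.data.frame(linelists)) {
    abort_validation("`linelists` must be a non-empty list of line lists.")
  }
  gt <- group_fractions(groups)
  per_tree <- purrr::map(linelists, function(ll) {
    estimate_assortativity(ll, groups, alpha = alpha, window_end = window_end)
  })

  if (pool == "counts") {
    counts <- purrr::map(per_tree, ~ .x[, c("tau_within", "n_emitted")])
    tw <- Reduce(`+`, purrr::map(counts, "tau_within"))
    ne <- Reduce(`+`, purrr::map(counts, "n_emitted"))
    est <- estimate_delta(tw, ne, fraction = gt$fraction, alpha = alpha,
                          group = gt$group)
    est$n_trees <- length(linelists)
    return(est)
  }

  all_est <- dplyr::bind_rows(per_tree, .id = "tree")
  out <- all_est |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n_trees = dplyr::n(),
      n_undefined = sum(.data$status != "ok"),
      spread_low = if (any(.data$status == "ok")) {
        unname(stats::quantile(.data$delta_hat[.data$status == "ok"], probs[1]))
      } else NA_real_,
      spread_high = if (any(.data$status == "ok")) {
        unname(stats::quantile(.data$delta_hat[.data$status == "ok"], probs[2]))
      } else NA_real_,
      # last: this summary takes the column's name
      delta_hat = if (any(.data$status == "ok")) {
        mean(.data$delta_hat[.data$status == "ok"])
      } else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(status = ifelse(.data$n_undefined < .data$n_trees, "ok", "undefined"))
  out[match(gt$group, out$group), ]
}
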
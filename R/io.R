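## File formats: plain UTF-8 CSV with headers for tabular data (empty
## infector_id marks an imported case); YAML or JSON (by extension) for
## scenario and ensemble configuration.

#' Read and write transmission-chain line lists
#'
#' CSV dialect: columns `case_id, group, onset_day, infection_day (optional),
#' infector_id`; days are 0-based integers from outbreak start; an empty
#' `infector_id` marks an imported case.
#'
#' @param path File path.
#' @return `read_linelist()`: a validated line-list tibble.
#' @export
read_linelist <- function(path) {
  if (!file.exists(path)) abort_validation("file not found: ", path)
  x <- readr::read_csv(path, col_types = readr::cols(
    case_id = readr::col_character(),
    group = readr::col_character(),
    onset_day = readr::col_integer(),
    infector_id = readr::col_character(),
    .default = readr::col_integer()
  ))
  report_parse_problems(x, path)
  validate_linelist(x)
}

#' @rdname read_linelist
#' @param linelist A line-list data frame.
#' @export
write_linelist <- function(linelist, path) {
  ll <- validate_linelist(linelist)
  readr::write_csv(ll, path, na = "")
  invisible(path)
}

#' Read a group census table
#'
#' CSV with columns `group, size`.
#'
#' @param path File path.
#' @return A tibble with columns `group` and `size`.
#' @export
read_group_table <- function(path) {
  if (!file.exists(path)) abort_validation("file not found: ", path)
  x <- readr::read_csv(path, col_types = readr::cols(
    group = readr::col_character(), size = readr::col_integer()))
  report_parse_problems(x, path)
  as_group_table(x)
}

report_parse_problems <- function(x, path) {
  p <- readr::problems(x)
  if (nrow(p) > 0) {
    abort_validation("malformed CSV in ", path, ": row ", p$row[1],
                     ", column ", p$col[1], " (", p$expected[1], ")")
  }
}

#' Write assortativity estimates to CSV or JSON
#'
#' @param estimates A `transmix_estimates` tibble.
#' @param path Output path; format chosen by extension (`.json` or `.csv`).
#' @export
write_estimates <- function(estimates, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(tibble::as_tibble(unclass(estimates)), path,
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    readr::write_csv(tibble::as_tibble(unclass(estimates)), path, na = "")
  }
  invisible(path)
}

#' Read and write scenario configuration files
#'
#' A scenario config is YAML or JSON (by extension) with keys `group_sizes`,
#' `delta`, `r0`, `imports`, optional `labels`, `horizon`, and optional
#' `generation_time: {mean, sd}` / `incubation: {mean, sd}` blocks
#' parameterising the discretised-gamma delay distributions.
#'
#' @param path File path (`.yaml`, `.yml` or `.json`).
#' @return `read_scenario()`: a validated [scenario()].
#' @export
read_scenario <- function(path) {
  cfg <- read_config(path)
  need <- c("group_sizes", "delta", "r0", "imports")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0) {
    abort_validation("scenario config ", path, " is missing key(s): ",
                     paste(missing, collapse = ", "))
  }
  gt <- cfg$generation_time %||% list(mean = 5, sd = 2)
  ip <- cfg$incubation %||% list(mean = 4, sd = 2)
  if (is.null(gt$mean) || is.null(gt$sd)) {
    abort_validation("key `generation_time` needs `mean` and `sd`.")
  }
  if (is.null(ip$mean) || is.null(ip$sd)) {
    abort_validation("key `incubation` needs `mean` and `sd`.")
  }
  scenario(
    group_sizes = unlist(cfg$group_sizes),
    delta = unlist(cfg$delta),
    r0 = unlist(cfg$r0),
    imports = unlist(cfg$imports),
    generation = generation_pmf(gt$mean, gt$sd),
    incubation = incubation_pmf(ip$mean, ip$sd),
    horizon = cfg$horizon %||% 365,
    labels = if (!is.null(cfg$labels)) unlist(cfg$labels) else NULL
  )
}

#' @rdname read_scenario
#' @param sc A `transmix_scenario`. Only the gamma parameterisation of the
#'   delay pmfs round-trips; custom pmf vectors are written in full.
#' @param gt,incubation Optional `list(mean, sd)` recorded in the file in
#'   place of the raw pmf vectors.
#' @export
write_scenario <- function(sc, path, gt = NULL, incubation = NULL) {
  validate_scenario(sc)
  cfg <- list(group_sizes = sc$group_sizes, labels = sc$labels,
              delta = sc$delta, r0 = sc$r0, imports = sc$imports,
              horizon = sc$horizon)
  if (!is.null(gt)) cfg$generation_time <- gt else cfg$generation_pmf <- sc$generation
  if (!is.null(incubation)) cfg$incubation <- incubation else cfg$incubation_pmf <- sc$incubation
  write_config(cfg, path)
}

#' Read an ensemble specification file
#'
#' YAML or JSON whose keys mirror the arguments of [ensemble_spec()]
#' (`n_scenarios`, `n_replicates`, ranges as two-element arrays, scalar
#' distribution parameters, `base_seed`). Missing keys take the default
#' nosocomial values.
#'
#' @param path File path.
#' @return A validated `transmix_ensemble_spec`.
#' @export
read_ensemble_spec <- function(path) {
  cfg <- read_config(path)
  need <- c("n_scenarios", "n_replicates")
  missing <- setdiff(need, names(cfg))
  if (length(missing) > 0) {
    abort_validation("ensemble spec ", path, " is missing key(s): ",
                     paste(missing, collapse = ", "))
  }
  known <- names(formals(ensemble_spec))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort_validation("unknown key(s) in ", path, ": ",
                     paste(unknown, collapse = ", "))
  }
  args <- lapply(cfg, unlist)
  do.call(ensemble_spec, args)
}

read_config <- function(path) {
  if (!file.exists(path)) abort_validation("file not found: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

write_config <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
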
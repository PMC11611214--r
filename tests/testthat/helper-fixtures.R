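# Shared fixtures, all built in code.

# Four-case toy chain: A (g1, import) infects B (g1) and C (g2); B infects D (g1).
toy_linelist <- function() {
  data.frame(
    case_id = c("A", "B", "C", "D"),
    group = c("g1", "g1", "g2", "g1"),
    onset_day = c(0L, 3L, 4L, 6L),
    infector_id = c(NA, "A", "A", "B")
  )
}

toy_groups <- function(sizes = c(50, 50)) {
  data.frame(group = c("g1", "g2"), size = sizes)
}

# small two-group nosocomial-scale scenario for fast simulation tests
small_scenario <- function(delta = c(0.5, 0), r0 = c(2, 1.5),
                           sizes = c(80, 120), imports = c(1, 0), ...) {
  scenario(group_sizes = sizes, delta = delta, r0 = r0, imports = imports, ...)
}

expect_validation_error <- function(expr) {
  expect_error(expr, class = "transmix_validation_error")
}
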
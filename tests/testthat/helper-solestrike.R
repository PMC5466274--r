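# Small builders shared across tests. Everything is generated in code; no
# stored fixtures.

tiny_spec <- function(n_subjects = 5, footfalls = 6, seed = 101, ...) {
  population_spec(n_subjects = n_subjects, footfalls_per_condition = footfalls,
                  seed = seed, ...)
}

# a single-surface spec sized to roughly n footfalls, for regression tests
surface_spec <- function(surface, n_subjects, footfalls = 10, seed = NULL, ...) {
  population_spec(n_subjects = n_subjects, surfaces = surface,
                  footfalls_per_condition = footfalls, seed = seed, ...)
}

# one footfall record as the trace generator expects it
toy_record <- function(si = 20, otd_raw = -40, foot_length = 24,
                       split_belt = FALSE) {
  list(si = si, otd_raw = otd_raw, foot_length = foot_length,
       split_belt = split_belt)
}

# peak-to-peak/2 amplitude of the central third of a series (transient-free)
steady_amplitude <- function(x) {
  n <- length(x)
  core <- x[floor(n / 3):ceiling(2 * n / 3)]
  (max(core) - min(core)) / 2
}

# closed-form OLS of y on x: the independent oracle for the lm-based fit
ols_oracle <- function(x, y) {
  n <- length(x)
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  res <- y - (a + b * x)
  se_b <- sqrt(sum(res^2) / (n - 2) / sum((x - mean(x))^2))
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  list(B = b, intercept = a, se_B = se_b, r_squared = r2)
}
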
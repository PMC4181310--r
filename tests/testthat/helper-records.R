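# Minimal known-age capture records for encounter/fitting tests.
# Event ages are on the true-age timeline, as the simulator records them.
make_records <- function(n = 1, hoof_growth = 2, death_age = NA_integer_,
                         shed_age = NA_integer_, true_age_at_capture = 0L,
                         last_alive_age = NA_integer_) {
  tibble::tibble(
    id = sprintf("A%02d", seq_len(n)),
    species = "white-tailed deer",
    cohort_site = "site1",
    true_birth_day = 1L,
    capture_day = 1L + true_age_at_capture,
    true_age_at_capture = rep_len(true_age_at_capture, n),
    hoof_growth = rep_len(hoof_growth, n),
    known_age = rep_len(true_age_at_capture, n) <= 1,
    death_age = as.integer(rep_len(death_age, n)),
    last_alive_age = as.integer(rep_len(last_alive_age, n)),
    shed_age = as.integer(rep_len(shed_age, n))
  )
}

# Grid-search oracle for the known-fate MLE: minimise the binomial -2logL of
# one pooled cell over a fine survival grid, independent of the fitting code.
grid_mle_surv <- function(exposures, deaths, grid = seq(0.0005, 0.9995, by = 0.0005)) {
  nll <- -2 * ((exposures - deaths) * log(grid) + deaths * log(1 - grid))
  grid[which.min(nll)]
}
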
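test_that("group specs parse into partitions and bad specs fail loudly", {
  gs <- parse_group_spec("KA=R,H", c("KA", "R", "H"))
  expect_equal(gs$cohort, c("KA", "R", "H"))
  expect_equal(gs$group, c(1, 1, 2))
  expect_equal(attr(gs, "spec_string"), "KA = R, H")

  gs5 <- parse_group_spec("{KA, B, H, S, HS}", c("KA", "B", "H", "S", "HS"))
  expect_equal(gs5$group, 1:5)

  expect_error(parse_group_spec("KA=KA", "KA"), "more than once")
  expect_error(parse_group_spec("KA=Z", c("KA", "H")), "unknown cohort")
  expect_error(parse_group_spec("KA", c("KA", "H")), "missing")
})

test_that("partition enumeration counts Bell numbers", {
  expect_equal(length(enumerate_partitions("A")), 1)
  expect_equal(length(enumerate_partitions(c("A", "B"))), 2)
  p3 <- enumerate_partitions(c("KA", "R", "H"))
  expect_equal(length(p3), 5)
  expect_setequal(p3, c("KA=R=H", "KA=R,H", "KA=H,R", "KA,R=H", "KA,R,H"))
  expect_equal(length(enumerate_partitions(letters[1:5])), 52)
  expect_error(enumerate_partitions(letters[1:7]), "1 and 6")
})

test_that("the -2 log likelihood is the binomial product form", {
  # one cell, 3 exposures, 2 deaths, beta = 0 (S = 0.5): -2 * 3 * log(0.5)
  h <- build_histories(
    make_records(n = 3, death_age = c(1L, 1L, NA), last_alive_age = c(0L, 0L, 1L)),
    occasion_map(1, "daily")
  )
  d <- known_fate_design(h, parse_group_spec("KA", "KA"))
  expect_equal(neg2_log_likelihood(d, 0), -2 * 3 * log(0.5), tolerance = 1e-12)
  expect_equal(neg2_log_likelihood(d, 0), 4.159, tolerance = 1e-3)

  # no deaths: the likelihood tends to 0 as beta grows
  h2 <- build_histories(make_records(n = 4), occasion_map(2, "daily"))
  d2 <- known_fate_design(h2, parse_group_spec("KA", "KA"), "constant")
  expect_lt(neg2_log_likelihood(d2, 30), 1e-10)
  expect_gt(neg2_log_likelihood(d2, 0), 1)
})

test_that("the MLE matches the grid-search oracle and the pooled closed form", {
  # 3 animals over 2 days: survivor (2 exposures), death day 1, death day 2
  h <- build_histories(
    make_records(n = 3, death_age = c(NA, 1L, 2L), last_alive_age = c(2L, 0L, 1L)),
    occasion_map(2, "daily")
  )
  d <- known_fate_design(h, parse_group_spec("KA", "KA"), "constant")
  expect_equal(d$n_eff, 5)
  fit <- fit_known_fate(d)
  expect_equal(fit$beta$surv, 0.6, tolerance = 1e-6)
  expect_equal(fit$beta$surv, grid_mle_surv(5, 2), tolerance = 5e-4)

  # random two-group occasion designs, K <= 3: optimizer vs oracle per cell
  for (seed in 1:5) {
    set.seed(seed)
    sim <- simulate_cohort(sim_config(n_neonates = 30, horizon = 3, seed = seed,
                                      daily_hazard = rep(0.15, 3)))
    h <- build_histories(field_filter(sim$records), occasion_map(3, "daily"))
    d <- known_fate_design(h, parse_group_spec("KA", "KA"))
    fit <- fit_known_fate(d)
    for (i in seq_len(nrow(fit$beta))) {
      b <- fit$beta[i, ]
      if (!b$boundary) {
        expect_equal(b$surv, grid_mle_surv(b$exposures, b$deaths), tolerance = 5e-4)
        expect_equal(b$surv, (b$exposures - b$deaths) / b$exposures, tolerance = 1e-6)
      }
    }
  }
})

test_that("boundary cells are clamped and flagged instead of diverging", {
  h <- build_histories(make_records(n = 5), occasion_map(4, "daily"))
  fit <- fit_known_fate(known_fate_design(h, parse_group_spec("KA", "KA"), "constant"))
  expect_true(all(fit$beta$boundary))
  expect_equal(fit$beta$estimate, 15)
  expect_gt(fit$beta$surv, 0.999)
  expect_equal(cumulative_survival(fit)$estimate, plogis(15)^4, tolerance = 1e-9)
})

test_that("saturated structures reproduce cell means and zero deviance", {
  sim <- simulate_cohort(sim_config(n_neonates = 80, seed = 23))
  f <- field_filter(sim$records)
  h <- dplyr::bind_rows(
    build_histories(f, occasion_map(30, "daily")),
    build_histories(f, occasion_map(30, "daily"),
      lookup_age_model("white-tailed deer", "Sams")
    )
  )
  gs <- parse_group_spec("KA,S", c("KA", "S"))
  d <- known_fate_design(h, gs)
  fit <- fit_known_fate(d, saturated_neg2ll = NULL)
  ok <- !fit$beta$boundary
  expect_equal(
    fit$beta$surv[ok],
    1 - fit$beta$deaths[ok] / fit$beta$exposures[ok],
    tolerance = 1e-8
  )
  # the saturated model is its own reference
  fit2 <- fit_known_fate(d, saturated_neg2ll = fit$neg2loglik)
  expect_equal(fit2$deviance, 0)
})

test_that("adding parameters never increases the minimised -2 log likelihood", {
  sim <- simulate_cohort(sim_config(n_neonates = 100, seed = 37))
  f <- field_filter(sim$records)
  map <- occasion_map(30, "weekly")
  h <- dplyr::bind_rows(
    build_histories(f, map),
    build_histories(f, map, lookup_age_model("white-tailed deer", "Brinkman")),
    build_histories(f, map, lookup_age_model("white-tailed deer", "Haskell"))
  )
  cohorts <- c("KA", "B", "H")
  nll <- function(spec, tstruct) {
    fit_known_fate(known_fate_design(h, parse_group_spec(spec, cohorts), tstruct))$neg2loglik
  }
  # partition refinement chain and time-structure refinement
  expect_gte(nll("KA=B=H", "occasion"), nll("KA=B,H", "occasion") - 1e-8)
  expect_gte(nll("KA=B,H", "occasion"), nll("KA,B,H", "occasion") - 1e-8)
  expect_gte(nll("KA=B=H", "constant"), nll("KA=B=H", "occasion") - 1e-8)
})

test_that("AICc follows the small-sample correction", {
  expect_equal(aicc(100, 3, 100), 100 + 6 + 24 / 96)
  expect_equal(aicc(100, 0, 100), 100)
  # equal-K models: AICc difference reduces to the likelihood difference
  expect_equal(aicc(110, 4, 80) - aicc(100, 4, 80), 10)
  expect_error(aicc(100, 99, 100), "n_eff")
})

test_that("cumulative survival multiplies occasion survivals with delta-method SE", {
  # 10 survivors over 30 occasions, 3 deaths in the last: pooled S = 297/300 = 0.99
  h <- build_histories(
    make_records(
      n = 10, death_age = c(rep(NA, 7), rep(30L, 3)),
      last_alive_age = c(rep(30L, 7), rep(29L, 3))
    ),
    occasion_map(30, "daily")
  )
  fit <- fit_known_fate(known_fate_design(h, parse_group_spec("KA", "KA"), "constant"))
  cs <- cumulative_survival(fit)
  expect_equal(fit$beta$surv, 0.99, tolerance = 1e-8)
  expect_equal(cs$estimate, 0.99^30, tolerance = 1e-6)
  # delta method: SE(S^30) = 30 * S^30 * (1 - S) * se_beta
  expect_equal(
    cs$se,
    30 * 0.99^30 * 0.01 * fit$beta$se,
    tolerance = 1e-6
  )
  expect_true(cs$lower < cs$estimate && cs$estimate < cs$upper)

  # single-occasion design: cumulative equals the interval survival
  h1 <- build_histories(
    make_records(n = 4, death_age = c(1L, NA, NA, NA), last_alive_age = c(0L, 1L, 1L, 1L)),
    occasion_map(1, "daily")
  )
  f1 <- fit_known_fate(known_fate_design(h1, parse_group_spec("KA", "KA")))
  c1 <- cumulative_survival(f1)
  expect_equal(c1$estimate, f1$beta$surv)
  expect_equal(c1$se, f1$beta$surv_se, tolerance = 1e-9)

  expect_error(cumulative_survival(f1, group = 9), "unknown group")
  expect_true(all(c1$estimate >= 0 & c1$estimate <= 1))
})

test_that("confidence intervals cover the true cumulative survival at ~95%", {
  reps <- 120
  truth <- 0.99^30
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    sim <- simulate_cohort(sim_config(
      n_neonates = 60, daily_hazard = rep(0.01, 30), shed_probability = 0,
      seed = 1000 + r
    ))
    h <- build_histories(sim$records, occasion_map(30, "daily"))
    fit <- fit_known_fate(known_fate_design(h, parse_group_spec("KA", "KA"), "constant"))
    cs <- cumulative_survival(fit)
    covered[r] <- cs$lower <= truth && truth <= cs$upper
  }
  # binomial tolerance around the nominal rate: 0.95 +/- 3*sqrt(.95*.05/reps)
  expect_gt(mean(covered), 0.95 - 3 * sqrt(0.95 * 0.05 / reps))
})

test_that("beta CI overlap-zero screening flags weak contrasts", {
  fake <- structure(
    list(beta = tibble::tibble(
      param = 1:3,
      estimate = c(2, 0.1, 0),
      se = c(0.5, 1, 0.2),
      lower = c(1.02, -1.86, -0.39),
      upper = c(2.98, 2.06, 0.39)
    )),
    class = "known_fate_fit"
  )
  expect_equal(beta_ci_overlaps_zero(fake)$overlaps_zero, c(FALSE, TRUE, TRUE))
})

test_that("tidy, glance and autoplot expose the fit", {
  sim <- simulate_cohort(sim_config(n_neonates = 50, seed = 41))
  h <- build_histories(field_filter(sim$records), occasion_map(30, "weekly"))
  fit <- fit_known_fate(known_fate_design(h, parse_group_spec("KA", "KA")))
  td <- tidy(fit)
  expect_true(all(c("param", "estimate", "se", "surv", "boundary") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$K, fit$K)
  expect_equal(gl$aicc, fit$aicc)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
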
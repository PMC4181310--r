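#' Parse a group-equality specification
#'
#' Survival models constrain cohorts to share parameters via specs such as
#' `"KA=B=S,H=HS"`: `=` joins cohorts into one shared-survival group, `,`
#' separates groups. Every cohort must appear exactly once.
#'
#' @param spec_string Specification string.
#' @param cohorts Character vector of the cohort labels present in the data.
#'
#' @return A tibble with columns `cohort` and `group` (integer ids contiguous
#'   from 1, in order of first appearance), with the canonical spec string as
#'   a `spec_string` attribute.
#' @export
#' @examples
#' parse_group_spec("KA=R,H", c("KA", "R", "H"))
parse_group_spec <- function(spec_string, cohorts) {
  spec <- gsub("\\s|\\{|\\}", "", spec_string)
  groups <- strsplit(spec, ",", fixed = TRUE)[[1]]
  labels <- strsplit(groups, "=", fixed = TRUE)
  flat <- unlist(labels)
  bad <- setdiff(flat, cohorts)
  if (length(bad)) {
    abort(sprintf(
      "unknown cohort label(s) %s at position %d in \"%s\"; known: %s",
      paste(bad, collapse = ", "), which(flat %in% bad)[1], spec_string,
      paste(cohorts, collapse = ", ")
    ))
  }
  if (anyDuplicated(flat)) {
    abort(sprintf(
      "cohort label %s appears more than once in \"%s\"",
      flat[duplicated(flat)][1], spec_string
    ))
  }
  missing <- setdiff(cohorts, flat)
  if (length(missing)) {
    abort(sprintf(
      "cohort(s) %s missing from \"%s\"", paste(missing, collapse = ", "), spec_string
    ))
  }
  out <- tibble::tibble(
    cohort = flat,
    group = rep(seq_along(labels), lengths(labels))
  )
  attr(out, "spec_string") <- paste(
    purrr::map_chr(labels, paste, collapse = " = "),
    collapse = ", "
  )
  out
}

#' Enumerate all set partitions of a cohort set
#'
#' All ways of assigning cohorts to shared-survival groups; the number of
#' partitions of n cohorts is the Bell number (5 for three cohorts, 52 for
#' five).
#'
#' @param cohorts Character vector of 1-6 cohort labels.
#' @return Character vector of group-spec strings, e.g. `"KA=R,H"`.
#' @export
#' @examples
#' enumerate_partitions(c("KA", "R", "H"))
enumerate_partitions <- function(cohorts) {
  n <- length(cohorts)
  if (n < 1 || n > 6) abort("between 1 and 6 cohorts supported")
  parts <- list(list(cohorts[1]))
  if (n > 1) {
    for (i in 2:n) {
      parts <- purrr::flatten(purrr::map(parts, function(p) {
        grown <- purrr::map(seq_along(p), function(j) {
          p[[j]] <- c(p[[j]], cohorts[i])
          p
        })
        c(grown, list(c(p, list(cohorts[i]))))
      }))
    }
  }
  purrr::map_chr(parts, function(p) {
    paste(purrr::map_chr(p, paste, collapse = "="), collapse = ",")
  })
}

#' Assemble a known-fate design from encounter histories
#'
#' Aggregates staggered-entry histories into per-cell exposure and death
#' counts, where a cell is a (shared-survival group) x (time block)
#' combination. Each animal is at risk in occasions `entry..exit`; a death is
#' counted in its exit occasion; a censored animal's exit occasion counts as
#' a survived exposure (the history ends after its last live pair). Time
#' structure `"occasion"` gives one parameter per group x occasion (weekly or
#' daily survival depending on the map the histories were built on);
#' `"constant"` shares one parameter per group across all occasions.
#'
#' Cells with zero exposure are dropped from the parameter vector and listed
#' in the design; cohorts with no animals are dropped with a warning.
#'
#' @param histories Encounter-history tibble ([build_histories()] rows, with
#'   all requested cohorts bound together).
#' @param groups Group structure from [parse_group_spec()].
#' @param time_structure `"occasion"` or `"constant"`.
#'
#' @return A list of class `known_fate_design`: `cells` (tibble of
#'   `group`, `occasion`, `param`, `exposures`, `deaths`), `K`, `n_eff`
#'   (total animal-occasion exposures), `n_occasions`, `groups`,
#'   `time_structure`, `spec_string`, `dropped_cells`.
#' @export
known_fate_design <- function(histories, groups,
                              time_structure = c("occasion", "constant")) {
  time_structure <- match.arg(time_structure)
  present <- unique(histories$cohort_label)
  absent <- setdiff(groups$cohort, present)
  if (length(absent)) {
    warn(sprintf("cohort(s) with zero animals dropped: %s", paste(absent, collapse = ", ")))
    groups <- dplyr::filter(groups, !.data$cohort %in% absent)
    groups$group <- match(groups$group, sort(unique(groups$group)))
  }
  n_occ <- histories$n_occasions[1]

  h <- dplyr::inner_join(histories, groups, by = c(cohort_label = "cohort"))
  len <- h$exit_occasion - h$entry_occasion + 1L
  idx <- rep(seq_len(nrow(h)), len)
  occ <- sequence(len, from = h$entry_occasion)
  cells <- tibble::tibble(
    group = h$group[idx],
    occasion = occ,
    death = h$fate[idx] == "died" & occ == h$exit_occasion[idx]
  ) |>
    dplyr::summarise(
      exposures = dplyr::n(), deaths = sum(.data$death),
      .by = c("group", "occasion")
    ) |>
    dplyr::arrange(.data$group, .data$occasion)

  # full cell grid; unexposed cells are reported and excluded from beta
  grid <- tidyr::expand_grid(group = sort(unique(groups$group)), occasion = seq_len(n_occ))
  cells <- dplyr::left_join(grid, cells, by = c("group", "occasion")) |>
    dplyr::mutate(
      exposures = dplyr::coalesce(.data$exposures, 0L),
      deaths = dplyr::coalesce(.data$deaths, 0L)
    )
  dropped <- dplyr::filter(cells, .data$exposures == 0)
  cells <- dplyr::filter(cells, .data$exposures > 0)

  block <- if (time_structure == "constant") rep(1L, nrow(cells)) else cells$occasion
  key <- paste(cells$group, block)
  cells$param <- as.integer(factor(key, levels = unique(key)))

  structure(
    list(
      cells = cells, K = max(cells$param), n_eff = sum(cells$exposures),
      n_occasions = n_occ, groups = groups, time_structure = time_structure,
      spec_string = attr(groups, "spec_string"),
      dropped_cells = dropped[, c("group", "occasion")]
    ),
    class = "known_fate_design"
  )
}

#' Known-fate -2 log likelihood
#'
#' The known-fate likelihood is a product of simple binomials, one per cell:
#' with interval survival `S = plogis(beta)` shared over a cell's exposures,
#' the contribution is `survivals * log(S) + deaths * log(1 - S)`.
#'
#' @param design A [known_fate_design()].
#' @param beta Numeric vector of logit-scale interval survivals, length
#'   `design$K`.
#' @return The value of -2 log L (0 for an empty design).
#' @export
neg2_log_likelihood <- function(design, beta) {
  cells <- design$cells
  if (nrow(cells) == 0) return(0)
  stopifnot(length(beta) == design$K)
  b <- beta[cells$param]
  # stable log(S), log(1-S) on the logit scale
  log_s <- -log1p(exp(-b))
  log_q <- -b - log1p(exp(-b))
  surv <- cells$exposures - cells$deaths
  -2 * sum(surv * log_s + cells$deaths * log_q)
}

#' Fit a known-fate interval-survival model
#'
#' Maximum-likelihood fit on the logit scale. The likelihood separates by
#' parameter, so each beta is found by one-dimensional numerical optimization
#' of its pooled binomial likelihood within ±15; parameters whose pooled data
#' lie on the boundary (no deaths, or no survivors) are clamped at ±15 and
#' flagged rather than allowed to diverge. Standard errors come from the
#' inverse observed information (diagonal, by separability); 95% intervals
#' are normal-theory on the logit scale.
#'
#' @param design A [known_fate_design()].
#' @param saturated_neg2ll Optional -2 log L of the saturated (all-singleton,
#'   occasion-varying) reference model at the same resolution, used to report
#'   deviance.
#'
#' @return An object of class `known_fate_fit` with components `beta`
#'   (per-parameter tibble: estimate, SE, CI, interval survival, boundary
#'   flag, pooled exposures/deaths), `neg2loglik`, `K`, `n_eff`, `aicc`,
#'   `deviance`, and the design metadata. Methods: [tidy()], [glance()],
#'   [autoplot()], `print`.
#' @export
fit_known_fate <- function(design, saturated_neg2ll = NULL) {
  stopifnot(inherits(design, "known_fate_design"))
  cells <- design$cells
  if (nrow(cells) == 0) abort("design has no exposed cells; nothing to fit")

  pooled <- cells |>
    dplyr::summarise(
      exposures = sum(.data$exposures), deaths = sum(.data$deaths),
      group = .data$group[1],
      occasions = paste(range(.data$occasion), collapse = "-"),
      .by = "param"
    ) |>
    dplyr::arrange(.data$param)

  bound <- 15
  fit_one <- function(e, d) {
    if (d == 0) return(list(beta = bound, boundary = TRUE))
    if (d == e) return(list(beta = -bound, boundary = TRUE))
    nll <- function(b) {
      -2 * ((e - d) * (-log1p(exp(-b))) + d * (-b - log1p(exp(-b))))
    }
    opt <- optimize(nll, interval = c(-bound, bound), tol = 1e-10)
    list(beta = opt$minimum, boundary = FALSE)
  }
  fits <- purrr::map2(pooled$exposures, pooled$deaths, fit_one)
  beta <- purrr::map_dbl(fits, "beta")
  boundary <- purrr::map_lgl(fits, "boundary")
  s <- plogis(beta)
  info <- pooled$exposures * s * (1 - s) # observed = expected information here
  se <- ifelse(boundary, NA_real_, 1 / sqrt(info))
  z <- qnorm(0.975)

  beta_tbl <- tibble::tibble(
    param = pooled$param,
    group = pooled$group,
    occasions = pooled$occasions,
    estimate = beta,
    se = se,
    lower = beta - z * se,
    upper = beta + z * se,
    surv = s,
    surv_se = ifelse(boundary, NA_real_, s * (1 - s) * se),
    boundary = boundary,
    exposures = pooled$exposures,
    deaths = pooled$deaths
  )

  n2ll <- neg2_log_likelihood(design, beta)
  K <- design$K
  res <- structure(
    list(
      beta = beta_tbl,
      neg2loglik = n2ll,
      K = K,
      n_eff = design$n_eff,
      aicc = aicc(n2ll, K, design$n_eff),
      deviance = if (is.null(saturated_neg2ll)) NA_real_ else n2ll - saturated_neg2ll,
      cells = cells,
      n_occasions = design$n_occasions,
      groups = design$groups,
      time_structure = design$time_structure,
      spec_string = design$spec_string
    ),
    class = "known_fate_fit"
  )
  res
}

#' Small-sample-corrected AIC
#'
#' `AICc = -2logL + 2K + 2K(K+1)/(n_eff - K - 1)`, with effective sample size
#' taken as the total number of animal-occasion exposures.
#'
#' @param neg2loglik Minimised -2 log likelihood.
#' @param K Number of estimated parameters.
#' @param n_eff Effective sample size; must exceed `K + 1`.
#' @return The AICc value.
#' @export
aicc <- function(neg2loglik, K, n_eff) {
  if (n_eff <= K + 1) {
    abort(sprintf("AICc undefined: n_eff (%s) must exceed K + 1 (%s)", n_eff, K + 1))
  }
  neg2loglik + 2 * K + 2 * K * (K + 1) / (n_eff - K - 1)
}

#' Cumulative survival over the horizon, by group
#'
#' Product over occasions of each occasion's interval survival for the group.
#' The standard error uses first-order (delta-method) propagation through the
#' product: `d log S_cum / d beta_k = m_k (1 - S_k)` with `m_k` the number of
#' occasions governed by parameter `k`. The 95% CI is computed on the logit
#' scale and back-transformed. Occasions with no exposure for a group (e.g.
#' pre-entry occasions under staggered entry) contribute survival 1 and no
#' variance.
#'
#' @param fit A [fit_known_fate()] result.
#' @param group Integer group id(s); default all groups in the fit.
#'
#' @return Tibble with one row per group: `group`, `cohorts`, `estimate`,
#'   `se`, `lower`, `upper`, `n_occasions`, `boundary` (whether any clamped
#'   parameter contributed).
#' @export
cumulative_survival <- function(fit, group = NULL) {
  stopifnot(inherits(fit, "known_fate_fit"))
  all_groups <- sort(unique(fit$groups$group))
  group <- group %||% all_groups
  if (!all(group %in% all_groups)) {
    abort(sprintf(
      "unknown group(s) %s; fit has groups %s",
      paste(setdiff(group, all_groups), collapse = ", "),
      paste(all_groups, collapse = ", ")
    ))
  }
  z <- qnorm(0.975)
  one <- function(g) {
    b <- dplyr::filter(fit$beta, .data$group == g)
    # structural block length per parameter: the constant structure's single
    # parameter spans every occasion; occasion-varying parameters span one
    # occasion each (unexposed occasions carry no parameter and multiply by 1)
    m <- if (fit$time_structure == "constant") rep(fit$n_occasions, nrow(b)) else rep(1, nrow(b))
    s_cum <- prod(b$surv^m)
    var_b <- ifelse(b$boundary, 0, b$se^2)
    grad_log <- m * (1 - b$surv) # d log S_cum / d beta_k
    se_log <- sqrt(sum(grad_log^2 * var_b))
    se <- s_cum * se_log
    if (s_cum > 0 && s_cum < 1 && se > 0) {
      se_logit <- se / (s_cum * (1 - s_cum))
      lo <- plogis(qlogis(s_cum) - z * se_logit)
      hi <- plogis(qlogis(s_cum) + z * se_logit)
    } else {
      lo <- hi <- s_cum
    }
    tibble::tibble(
      group = g,
      cohorts = paste(fit$groups$cohort[fit$groups$group == g], collapse = " = "),
      estimate = s_cum, se = se, lower = lo, upper = hi,
      n_occasions = fit$n_occasions,
      boundary = any(b$boundary)
    )
  }
  purrr::map_dfr(group, one)
}

#' Flag logit-scale confidence intervals that overlap zero
#'
#' Used to screen competing models: a model whose beta 95% CIs all overlap
#' zero on the logit contrast scale carries no evidence of the effect it
#' encodes and can be eliminated from consideration.
#'
#' @param fit A [fit_known_fate()] result.
#' @return Tibble `param`, `estimate`, `lower`, `upper`, `overlaps_zero`.
#' @export
beta_ci_overlaps_zero <- function(fit) {
  stopifnot(inherits(fit, "known_fate_fit"))
  b <- fit$beta
  tibble::tibble(
    param = b$param, estimate = b$estimate, lower = b$lower, upper = b$upper,
    overlaps_zero = !is.na(b$lower) & b$lower <= 0 & b$upper >= 0
  )
}

#' @export
print.known_fate_fit <- function(x, ...) {
  cat(sprintf(
    "Known-fate fit {%s} %s: K = %d, -2logL = %.2f, AICc = %.2f, n_eff = %d\n",
    x$spec_string %||% "", x$time_structure, x$K, x$neg2loglik, x$aicc, x$n_eff
  ))
  print(cumulative_survival(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.known_fate_fit <- function(x, ...) {
  dplyr::select(
    x$beta, "param", "group", "occasions", "estimate", "se",
    "lower", "upper", "surv", "surv_se", "boundary"
  )
}

#' @exportS3Method generics::glance
glance.known_fate_fit <- function(x, ...) {
  tibble::tibble(
    model = x$spec_string %||% NA_character_,
    time_structure = x$time_structure,
    neg2loglik = x$neg2loglik, K = x$K, n_eff = x$n_eff,
    aicc = x$aicc, deviance = x$deviance
  )
}

#' @exportS3Method ggplot2::autoplot
autoplot.known_fate_fit <- function(object, ...) {
  curves <- purrr::map_dfr(sort(unique(object$groups$group)), function(g) {
    cells_g <- dplyr::filter(object$cells, .data$group == g)
    s_occ <- rep(1, object$n_occasions)
    if (object$time_structure == "constant") {
      s_occ[] <- object$beta$surv[object$beta$group == g][1]
    } else {
      s_occ[cells_g$occasion] <- object$beta$surv[match(cells_g$param, object$beta$param)]
    }
    tibble::tibble(
      group = paste(object$groups$cohort[object$groups$group == g], collapse = " = "),
      occasion = seq_len(object$n_occasions),
      cum_survival = cumprod(s_occ)
    )
  })
  ggplot2::ggplot(curves, ggplot2::aes(
    .data$occasion, .data$cum_survival, colour = .data$group
  )) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "Occasion", y = "Cumulative survival", colour = "Group",
      title = sprintf("{%s} %s survival", object$spec_string %||% "", object$time_structure)
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
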
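#' Akaike weights from AICc values
#'
#' @param aicc Numeric vector of AICc values.
#' @return Tibble with `aicc`, `delta_aicc` (difference from the minimum) and
#'   `weight` (`exp(-delta/2)` normalised to sum to 1), in input order.
#' @export
#' @examples
#' akaike_weights(c(668.21, 674.49, 692.16))
akaike_weights <- function(aicc) {
  if (length(aicc) == 0) abort("no AICc values supplied")
  delta <- aicc - min(aicc)
  w <- exp(-delta / 2)
  tibble::tibble(aicc = aicc, delta_aicc = delta, weight = w / sum(w))
}

#' Rank fitted survival models by AICc
#'
#' Builds the model-selection table: models sorted by ascending AICc with
#' delta-AICc, Akaike weights, parameter counts and deviance. Models within
#' 2 AICc units of the best are flagged as viable alternatives. Sorting is
#' stable, so ties keep their input order.
#'
#' @param fits A list of [fit_known_fate()] objects (all fitted to the same
#'   records), or a tibble that already has an `aicc` column (and optionally
#'   `model`, `time_structure`, `K`, `deviance`).
#'
#' @return A tibble with columns `model`, `time_structure`, `aicc`,
#'   `delta_aicc`, `weight`, `K`, `deviance`, `viable`, sorted by AICc.
#' @export
rank_models <- function(fits) {
  if (is.data.frame(fits)) {
    tbl <- tibble::as_tibble(fits)
  } else {
    if (length(fits) == 0) abort("no fitted models to rank")
    tbl <- purrr::map_dfr(fits, glance)
  }
  if (!"aicc" %in% names(tbl)) abort("input must provide an `aicc` column")
  for (col in c("model", "time_structure")) {
    if (!col %in% names(tbl)) tbl[[col]] <- NA_character_
  }
  for (col in c("K", "deviance")) {
    if (!col %in% names(tbl)) tbl[[col]] <- NA_real_
  }
  w <- akaike_weights(tbl$aicc)
  tbl$delta_aicc <- w$delta_aicc
  tbl$weight <- w$weight
  tbl |>
    dplyr::mutate(viable = .data$delta_aicc < 2) |>
    dplyr::arrange(.data$aicc) |>
    dplyr::select(
      "model", "time_structure", "aicc", "delta_aicc", "weight",
      "K", "deviance", "viable"
    )
}

#' Chi-square contrast of survival estimates
#'
#' The CONTRAST-style test for differences among independent survival
#' estimates. For two groups the statistic is
#' `(S1 - S2)^2 / (SE1^2 + SE2^2)` on 1 df; for k groups it is the quadratic
#' form of the successive pairwise differences against the diagonal variance
#' matrix, on k - 1 df. Estimates are treated as independent (no covariances),
#' which is what the procedure assumes when fed estimates and standard errors.
#'
#' @param estimates Survival estimates (length >= 2).
#' @param ses Standard errors, all > 0.
#'
#' @return A one-row tibble: `chi2`, `df`, `p_value`.
#' @export
#' @examples
#' contrast_chi2(c(0.80, 0.72), c(0.03, 0.04)) # chi2 = 2.56
contrast_chi2 <- function(estimates, ses) {
  k <- length(estimates)
  if (k < 2) abort("need at least two estimates to contrast")
  if (length(ses) != k) abort("`estimates` and `ses` must have equal length")
  if (any(!is.finite(ses)) || any(ses <= 0)) abort("all standard errors must be > 0")
  C <- diff(diag(k)) # successive-difference contrasts, (k-1) x k
  d <- as.vector(C %*% estimates)
  V <- C %*% diag(ses^2, k) %*% t(C)
  chi2 <- as.numeric(t(d) %*% solve(V, d))
  df <- k - 1
  tibble::tibble(chi2 = chi2, df = df, p_value = pchisq(chi2, df, lower.tail = FALSE))
}

#' Pairwise contrasts between the groups of a fitted model
#'
#' Runs [contrast_chi2()] on every pair of group-level cumulative survival
#' estimates from a fit, mirroring the pairwise (1 df) comparisons reported
#' for top-ranked models.
#'
#' @param fit A [fit_known_fate()] result with at least two groups.
#' @return Tibble with one row per pair: the two group labels, estimates,
#'   SEs, `chi2`, `df`, `p_value`.
#' @export
contrast_groups <- function(fit) {
  cs <- cumulative_survival(fit)
  if (nrow(cs) < 2) abort("fit has a single group; nothing to contrast")
  pairs <- utils::combn(seq_len(nrow(cs)), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- cs[pairs[1, j], ]
    b <- cs[pairs[2, j], ]
    res <- contrast_chi2(c(a$estimate, b$estimate), c(a$se, b$se))
    tibble::tibble(
      group_1 = a$cohorts, group_2 = b$cohorts,
      estimate_1 = a$estimate, se_1 = a$se,
      estimate_2 = b$estimate, se_2 = b$se,
      chi2 = res$chi2, df = res$df, p_value = res$p_value
    )
  })
}
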
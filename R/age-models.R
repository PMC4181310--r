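#' Registry of published neonatal age-from-hoof-growth equations
#'
#' Each equation predicts age in days from new-hoof growth in millimetres as
#' `age = intercept + slope * hoof_growth`. The bundled registry holds the six
#' published equations for white-tailed deer (Haugen and Speake, Sams,
#' Brinkman, Haskell), mule deer (Robinette, Haskell) and pronghorn (Tucker
#' and Garner), together with the short cohort label used in survival model
#' specifications (`HS`, `S`, `B`, `H`, `R`, `TG`).
#'
#' @param path Optional path to a tab-separated file with columns
#'   `species`, `model`, `label`, `intercept`, `slope`. Rows are appended to
#'   the bundled registry, allowing additional equations to be registered.
#'
#' @return A tibble with columns `species`, `model`, `label`, `intercept`
#'   (days) and `slope` (days per mm). All slopes are positive.
#' @export
#' @examples
#' age_model_registry()
age_model_registry <- function(path = NULL) {
  bundled <- system.file("extdata", "age_models.tsv", package = "fawnsurv")
  reg <- read_registry_file(bundled)
  if (!is.null(path)) {
    reg <- dplyr::bind_rows(reg, read_registry_file(path))
  }
  if (any(reg$slope <= 0)) {
    abort("all registered age models must have a positive slope")
  }
  reg
}

read_registry_file <- function(path) {
  reg <- readr::read_tsv(path, col_types = readr::cols(
    species = readr::col_character(),
    model = readr::col_character(),
    label = readr::col_character(),
    intercept = readr::col_double(),
    slope = readr::col_double()
  ))
  tibble::as_tibble(reg)
}

# case/punctuation-insensitive key so "HaugenSpeake" matches "Haugen and Speake"
normalize_key <- function(x) gsub("[^a-z0-9]", "", tolower(gsub("\\band\\b", "", tolower(x))))

#' Look up a registered age model
#'
#' @param species Species name, one of `"white-tailed deer"`, `"mule deer"`,
#'   `"pronghorn"` (matching ignores case and punctuation).
#' @param model Model name, e.g. `"Brinkman"` or `"Haugen and Speake"`
#'   (`"HaugenSpeake"` also matches); the short cohort label (`"B"`, `"HS"`,
#'   ...) is accepted too.
#' @param registry Registry tibble, defaults to [age_model_registry()].
#'
#' @return A one-row tibble with the model's `species`, `model`, `label`,
#'   `intercept` and `slope`.
#' @export
#' @examples
#' lookup_age_model("white-tailed deer", "Brinkman")
lookup_age_model <- function(species, model, registry = age_model_registry()) {
  stopifnot(length(species) == 1, length(model) == 1)
  hit <- registry[normalize_key(registry$species) == normalize_key(species) &
    (normalize_key(registry$model) == normalize_key(model) |
      normalize_key(registry$label) == normalize_key(model)), ]
  if (nrow(hit) != 1) {
    valid <- paste0("(", registry$species, ", ", registry$model, ")", collapse = ", ")
    abort(sprintf(
      "no registered age model for (%s, %s); valid pairs: %s",
      species, model, valid
    ))
  }
  hit
}

#' Define a hoof-growth age model
#'
#' Constructor for an unregistered equation `age = intercept + slope * hoof`,
#' usable anywhere a registry row is accepted (e.g. sensitivity analyses with
#' artificially shifted intercepts).
#'
#' @param model Model name.
#' @param species Species label.
#' @param intercept Intercept in days (may be negative).
#' @param slope Slope in days per mm of new-hoof growth; must be positive.
#' @param label Short cohort label; defaults to the model name.
#'
#' @return A one-row tibble in registry layout.
#' @export
#' @examples
#' hoof_growth_model("Shifted", "white-tailed deer", intercept = 10, slope = 3.14)
hoof_growth_model <- function(model, species, intercept, slope, label = model) {
  if (!is.numeric(slope) || length(slope) != 1 || !is.finite(slope) || slope <= 0) {
    abort("`slope` must be a single positive finite number")
  }
  if (!is.numeric(intercept) || length(intercept) != 1 || !is.finite(intercept)) {
    abort("`intercept` must be a single finite number")
  }
  tibble::tibble(
    species = species, model = model, label = label,
    intercept = intercept, slope = slope
  )
}

#' Estimate neonatal age from new-hoof growth
#'
#' Applies an age model to hoof-growth measurements. Raw ages may be negative
#' (equations with negative intercepts predict negative age at small hoof
#' growth); the truncated age clamps at zero, and the integer age class is
#' `floor(truncated_age)` so that class 0 means 0-24 hours old. Known-age
#' newborns are class 0 by construction.
#'
#' @param model A one-row registry tibble ([lookup_age_model()] or
#'   [hoof_growth_model()]).
#' @param hoof_growth Numeric vector of new-hoof growth in mm; must be finite
#'   and non-negative.
#'
#' @return A tibble with one row per measurement: `model_name`, `label`,
#'   `hoof_growth`, `raw_age`, `truncated_age`, `age_class`.
#' @export
#' @examples
#' m <- lookup_age_model("mule deer", "Robinette")
#' estimate_age(m, c(0.5, 3.84))
estimate_age <- function(model, hoof_growth) {
  stopifnot(is.data.frame(model), nrow(model) == 1)
  if (!is.numeric(hoof_growth) || any(!is.finite(hoof_growth)) || any(hoof_growth < 0)) {
    abort("`hoof_growth` must be finite and >= 0 (mm)")
  }
  raw <- model$intercept + model$slope * hoof_growth
  trunc <- pmax(0, raw)
  tibble::tibble(
    model_name = model$model,
    label = model$label,
    hoof_growth = hoof_growth,
    raw_age = raw,
    truncated_age = trunc,
    age_class = floor(trunc)
  )
}

#' Score age-model accuracy against known ages
#'
#' Accuracy at tolerance `t` is the fraction of animals whose estimated integer
#' age class is within `t` days of the true class; tolerance 0 is the
#' proportion assigned to the exact correct age class.
#'
#' @param true_classes Integer vector of true age classes (known-age newborns
#'   are class 0).
#' @param estimates Either a tibble from [estimate_age()] (its `age_class`
#'   column is used) or an integer vector of estimated classes.
#' @param tolerances Integer vector of day tolerances (default `0:3`).
#'
#' @return A tibble with columns `model_name`, `tolerance`, `proportion`, `n`.
#'   Proportions are non-decreasing in tolerance.
#' @export
accuracy_table <- function(true_classes, estimates, tolerances = 0:3) {
  if (is.data.frame(estimates)) {
    est_classes <- estimates$age_class
    model_name <- estimates$model_name[1] %||% NA_character_
  } else {
    est_classes <- estimates
    model_name <- NA_character_
  }
  n <- length(true_classes)
  if (n == 0) abort("empty input: no known-age animals to score")
  if (length(est_classes) != n) {
    abort(sprintf(
      "length mismatch: %d true classes but %d estimates", n, length(est_classes)
    ))
  }
  err <- abs(est_classes - true_classes)
  tibble::tibble(
    model_name = model_name,
    tolerance = as.integer(tolerances),
    proportion = purrr::map_dbl(tolerances, ~ mean(err <= .x)),
    n = n
  )
}

#' Summarise a set of age estimates
#'
#' Mean, standard error (sample SD / sqrt(n)), and range of estimated ages.
#' By default raw (untruncated) ages are summarised, which is why equations
#' with strongly negative intercepts can show a negative mean; set
#' `use_truncated = TRUE` to summarise ages clamped at zero.
#'
#' @param estimates Tibble from [estimate_age()].
#' @param use_truncated Summarise `truncated_age` instead of `raw_age`.
#'
#' @return A one-row tibble: `model_name`, `mean`, `se`, `min`, `max`, `n`.
#'   A single estimate has `se = 0` by convention.
#' @export
summarize_estimates <- function(estimates, use_truncated = FALSE) {
  stopifnot(is.data.frame(estimates))
  if (nrow(estimates) == 0) abort("empty input: no age estimates to summarise")
  x <- if (use_truncated) estimates$truncated_age else estimates$raw_age
  n <- length(x)
  tibble::tibble(
    model_name = estimates$model_name[1],
    mean = mean(x),
    se = if (n > 1) sd(x) / sqrt(n) else 0,
    min = min(x),
    max = max(x),
    n = n
  )
}

#' Round half away from zero
#'
#' Reporting convention for replicated tables: 0.45 rounds to 0.5 and -0.45
#' to -0.5, unlike [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
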
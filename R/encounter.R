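#' Build an occasion map over the follow-up horizon
#'
#' Partitions age days `1..horizon` into sampling occasions. Daily resolution
#' gives one-day occasions. Weekly resolution uses piecewise 7-day blocks:
#' over days 1-30 the remainder is merged into the 4th block (1-7, 8-14,
#' 15-21, 22-30), and days beyond 30 are blocked in sevens with any remainder
#' merged into the final block, so a 120-day horizon yields 16 occasions
#' (4 to day 30, then 12 ending 108-120). This blocking matches the weekly
#' parameter counts of the staggered-entry analysis (4 per group at 30 days,
#' 16 per group at 120 days).
#'
#' @param horizon Positive integer number of days (30 or 120 in the
#'   replication, but any positive horizon is accepted).
#' @param resolution `"daily"` or `"weekly"`.
#'
#' @return A tibble with one row per occasion (`occasion`, `start_day`,
#'   `end_day`), with `horizon` and `resolution` attributes. Occasions
#'   partition `1..horizon` exactly.
#' @export
#' @examples
#' occasion_map(30, "weekly")
occasion_map <- function(horizon, resolution = c("daily", "weekly")) {
  resolution <- match.arg(resolution)
  horizon <- as.integer(horizon)
  if (is.na(horizon) || horizon < 1) abort("`horizon` must be a positive integer")
  if (resolution == "daily") {
    map <- tibble::tibble(
      occasion = seq_len(horizon),
      start_day = seq_len(horizon),
      end_day = seq_len(horizon)
    )
  } else {
    seg_blocks <- function(from, to) {
      len <- to - from + 1L
      nb <- max(1L, len %/% 7L)
      starts <- from + 7L * (seq_len(nb) - 1L)
      ends <- c(starts[-1] - 1L, to) # last block absorbs the remainder
      tibble::tibble(start_day = starts, end_day = ends)
    }
    blocks <- seg_blocks(1L, min(30L, horizon))
    if (horizon > 30L) blocks <- dplyr::bind_rows(blocks, seg_blocks(31L, horizon))
    map <- dplyr::mutate(blocks, occasion = dplyr::row_number(), .before = 1)
  }
  attr(map, "horizon") <- horizon
  attr(map, "resolution") <- resolution
  map
}

# occasion containing a given age day (days inside 1..horizon only)
occasion_of_day <- function(map, day) {
  findInterval(day, map$start_day)
}

#' Censoring day for a prematurely shed collar
#'
#' During daily monitoring an animal is right-censored on the day the collar
#' is retrieved. During the weekly relocation phase it is censored at the
#' midpoint between the last relocation alive and the retrieval day, rounded
#' down to an integer day.
#'
#' @param last_alive_age Age day of the last relocation alive.
#' @param retrieval_age Age day the collar was retrieved; must be >=
#'   `last_alive_age`.
#' @param daily_phase Logical: was the animal still under daily monitoring?
#'
#' @return Integer censoring day.
#' @export
#' @examples
#' censored_exit_day(60, 74, daily_phase = FALSE) # 67
censored_exit_day <- function(last_alive_age, retrieval_age, daily_phase) {
  if (any(retrieval_age < last_alive_age)) {
    abort("`retrieval_age` must be >= `last_alive_age`")
  }
  ifelse(daily_phase,
    as.integer(retrieval_age),
    as.integer(floor((last_alive_age + retrieval_age) / 2))
  )
}

#' Build staggered-entry encounter histories for a cohort
#'
#' Converts known-age capture records into live/dead encounter histories on an
#' occasion map, using either the animals' known ages (`model = NULL`, cohort
#' label `"KA"`) or ages estimated from hoof growth with a registered
#' equation. An animal of age class `c` at capture enters in the occasion
#' containing day `c + 1` (class 0, i.e. 0-24 hours old, enters the first
#' occasion). Events are indexed on the (estimated) age timeline: an event `t`
#' days after capture falls on age day `c + t`. Deaths and censorings map to
#' the occasion containing their day; events beyond the horizon count as
#' survival to the horizon. Animals whose truncated estimated age already
#' exceeds the horizon are excluded with a warning.
#'
#' @param records Capture records passed through [field_filter()].
#' @param map An [occasion_map()].
#' @param model `NULL` for the known-age cohort, otherwise a one-row age-model
#'   tibble ([lookup_age_model()] / [hoof_growth_model()]); its `label` is the
#'   cohort label.
#'
#' @return A tibble with one row per animal: `animal_id`, `cohort_label`,
#'   `n_occasions`, `entry_occasion`, `exit_occasion`, `fate` (one of
#'   `"died"`, `"censored"`, `"survived_to_horizon"`).
#' @export
build_histories <- function(records, map, model = NULL) {
  stopifnot(is.data.frame(records))
  horizon <- attr(map, "horizon")
  n_occ <- nrow(map)

  if (is.null(model)) {
    label <- "KA"
    age_class <- floor(records$true_age_at_capture)
  } else {
    if (any(is.na(records$hoof_growth))) {
      abort("records are missing `hoof_growth`, required for an equation-based cohort")
    }
    est <- estimate_age(model, records$hoof_growth)
    label <- model$label
    age_class <- est$age_class
  }

  keep <- age_class < horizon
  if (any(!keep)) {
    warn(sprintf(
      "%d animal(s) excluded: estimated age class at capture >= %d-day horizon",
      sum(!keep), horizon
    ))
    records <- records[keep, , drop = FALSE]
    age_class <- age_class[keep]
  }

  # shift events from the true-age to the estimated-age timeline
  t_after_capture <- function(event_age) event_age - floor(records$true_age_at_capture)
  death_day <- age_class + t_after_capture(records$death_age)
  censor_day <- age_class + t_after_capture(records$shed_age)

  entry <- occasion_of_day(map, age_class + 1)
  exit <- rep(n_occ, nrow(records))
  fate <- rep("survived_to_horizon", nrow(records))

  died <- !is.na(death_day) & death_day <= horizon
  exit[died] <- occasion_of_day(map, death_day[died])
  fate[died] <- "died"
  cens <- !died & !is.na(censor_day) & censor_day <= horizon & is.na(records$death_age)
  exit[cens] <- occasion_of_day(map, censor_day[cens])
  fate[cens] <- "censored"

  tibble::tibble(
    animal_id = records$id,
    cohort_label = label,
    n_occasions = n_occ,
    entry_occasion = as.integer(entry),
    exit_occasion = as.integer(exit),
    fate = fate
  )
}

#' Write encounter histories in Program MARK known-fate format
#'
#' Emits LDLD rows: one live/dead pair per occasion, `00` before entry, `10`
#' for an occasion entered and survived, `11` in the death occasion, and
#' censoring simply ends the history after the last `10` pair. One frequency
#' column per cohort group, in the order given by `groups`. A comment header
#' documents the occasion blocks and group order.
#'
#' @param histories Tibble from [build_histories()] (rows from several cohorts
#'   may be bound together); all rows must share one occasion count.
#' @param map The [occasion_map()] the histories were built on.
#' @param groups Cohort labels defining the frequency-column order; defaults
#'   to the sorted labels present.
#' @param path Optional file to write to.
#'
#' @return Character vector of `.inp` lines, invisibly if `path` is given.
#' @export
write_mark_inp <- function(histories, map, groups = NULL, path = NULL) {
  if (length(unique(histories$n_occasions)) > 1 ||
    histories$n_occasions[1] != nrow(map)) {
    abort("all histories must share the occasion map they were built on")
  }
  groups <- groups %||% sort(unique(histories$cohort_label))
  n_occ <- nrow(map)
  header <- c(
    sprintf(
      "/* known-fate LDLD histories; %d occasions (%s, days 1-%d) */",
      n_occ, attr(map, "resolution"), attr(map, "horizon")
    ),
    sprintf(
      "/* occasion blocks: %s */",
      paste(sprintf("%d-%d", map$start_day, map$end_day), collapse = " ")
    ),
    sprintf("/* groups: %s */", paste(groups, collapse = " "))
  )
  encode <- function(entry, exit, fate, label) {
    pairs <- rep("00", n_occ)
    pairs[seq(entry, exit)] <- "10"
    if (fate == "died") pairs[exit] <- "11"
    freq <- as.integer(groups == label)
    paste0(paste(pairs, collapse = " "), " ", paste(freq, collapse = " "), ";")
  }
  lines <- purrr::pmap_chr(
    list(histories$entry_occasion, histories$exit_occasion,
         histories$fate, histories$cohort_label),
    encode
  )
  out <- c(header, lines)
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

#' Parse Program MARK known-fate input back into encounter histories
#'
#' Inverse of [write_mark_inp()] for files written by this package: recovers
#' entry/exit occasions, fate and cohort label from the LDLD rows and the
#' group header. A history whose last pair is `10` at the final occasion is a
#' survivor; one ending earlier is censored.
#'
#' @param lines Character vector of `.inp` lines, or a file path.
#' @return Tibble in the layout of [build_histories()].
#' @export
read_mark_inp <- function(lines) {
  if (length(lines) == 1 && file.exists(lines)) lines <- readLines(lines)
  grp_line <- grep("/\\* groups:", lines, value = TRUE)
  groups <- strsplit(sub(".*groups: (.*) \\*/", "\\1", grp_line[1]), " ")[[1]]
  rows <- grep(";\\s*$", lines, value = TRUE)
  rows <- rows[!grepl("^/\\*", rows)]
  parse_row <- function(row) {
    toks <- strsplit(trimws(sub(";\\s*$", "", row)), "\\s+")[[1]]
    ng <- length(groups)
    pairs <- toks[seq_len(length(toks) - ng)]
    freq <- as.integer(toks[seq.int(length(toks) - ng + 1, length(toks))])
    live <- substr(pairs, 1, 1) == "1"
    dead <- substr(pairs, 2, 2) == "1"
    entry <- which(live)[1]
    exit <- max(which(live))
    fate <- if (any(dead)) "died" else if (exit < length(pairs)) "censored" else "survived_to_horizon"
    tibble::tibble(
      cohort_label = groups[which(freq == 1)[1]],
      n_occasions = length(pairs),
      entry_occasion = as.integer(entry),
      exit_occasion = as.integer(exit),
      fate = fate
    )
  }
  out <- purrr::map_dfr(rows, parse_row)
  dplyr::mutate(out, animal_id = sprintf("H%03d", dplyr::row_number()), .before = 1)
}

#' Read/write encounter-history CSV
#'
#' Plain CSV with columns `animal_id`, `cohort_label`, `n_occasions`,
#' `entry_occasion`, `exit_occasion`, `fate`.
#'
#' @param histories Tibble from [build_histories()].
#' @param path File path.
#' @return The histories tibble (invisibly for the writer).
#' @export
write_histories_csv <- function(histories, path) {
  readr::write_csv(histories, path)
  invisible(histories)
}

#' @rdname write_histories_csv
#' @export
read_histories_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    animal_id = readr::col_character(),
    cohort_label = readr::col_character(),
    n_occasions = readr::col_integer(),
    entry_occasion = readr::col_integer(),
    exit_occasion = readr::col_integer(),
    fate = readr::col_character()
  ))
}
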
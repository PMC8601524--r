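validate_labs <- function(labs) {
  need <- c("patient_id", "parameter", "day", "value", "unit")
  miss <- setdiff(need, names(labs))
  assert_that(length(miss) == 0,
              sprintf("lab table is missing column(s): %s",
                      paste(miss, collapse = ", ")))
  assert_that(all(labs$value > 0), "laboratory values must be positive")
  invisible(labs)
}

#' Nadir of a longitudinal laboratory series
#'
#' The lowest value per patient and parameter observed inside the
#' window, together with its day. Baseline records (day <= 0) are
#' excluded from the search; ties are resolved to the earliest day.
#'
#' @param labs tidy lab table: `patient_id`, `parameter`, `day`,
#'   `value`, `unit`.
#' @param window two days `(start, end]`; observations with
#'   `day > start` and `day <= end` (and `day > 0`) are searched.
#'   Defaults to the whole follow-up.
#' @param parameters parameters to include (default: all present).
#' @return a tibble: `patient_id`, `parameter`, `nadir_value`,
#'   `nadir_day`, `unit`.
#' @export
nadir <- function(labs, window = c(0, Inf), parameters = NULL) {
  validate_labs(labs)
  assert_that(length(window) == 2 && window[1] < window[2],
              "window must be (start, end] with start < end")
  if (!is.null(parameters)) {
    labs <- dplyr::filter(labs, .data$parameter %in% parameters)
  }
  inw <- dplyr::filter(labs, .data$day > 0, .data$day > window[1],
                       .data$day <= window[2])
  assert_that(nrow(inw) > 0, "no observations inside the nadir window")
  inw |>
    dplyr::group_by(.data$patient_id, .data$parameter) |>
    dplyr::arrange(.data$value, .data$day, .by_group = TRUE) |>
    dplyr::summarise(nadir_value = .data$value[1], nadir_day = .data$day[1],
                     unit = .data$unit[1], .groups = "drop")
}

.grade_group <- function(grade) {
  factor(dplyr::case_when(grade <= 1 ~ "0-1", grade == 2 ~ "2",
                          TRUE ~ "3-4"),
         levels = c("0-1", "2", "3-4"))
}

#' Overall CTCAE grade profile per patient
#'
#' Grades each parameter's whole-course nadir, takes the overall grade
#' as the maximum across the four parameters, and labels patients with
#' the grade groups 0-1, 2 and 3-4 used for cohort comparisons.
#'
#' @inheritParams nadir
#' @param rules a [ctcae_rules()] object.
#' @param sex `"female"`, `"male"`, or a tibble `patient_id`, `sex`.
#' @return a tibble with one row per patient: per-parameter
#'   `<parameter>_nadir`, `<parameter>_day`, `<parameter>_grade`,
#'   plus `overall_grade` and `grade_group`.
#' @export
overall_patient_grade <- function(labs, rules = ctcae_rules(),
                                  sex = "female", window = c(0, Inf)) {
  validate_labs(labs)
  pp <- unique(labs[, c("patient_id", "parameter")])
  by_pat <- split(pp$parameter, pp$patient_id)
  for (pid in names(by_pat)) {
    miss <- setdiff(.hem_parameters, by_pat[[pid]])
    assert_that(length(miss) == 0,
                sprintf("patient %s is missing parameter(s): %s", pid,
                        paste(miss, collapse = ", ")))
  }

  nad <- nadir(labs, window = window)
  sex_tbl <- if (is.data.frame(sex)) sex else
    tibble::tibble(patient_id = unique(labs$patient_id), sex = sex)
  nad <- dplyr::left_join(nad, sex_tbl, by = "patient_id")
  nad$grade <- vapply(seq_len(nrow(nad)), function(i) {
    grade_value(nad$parameter[i], nad$nadir_value[i], nad$unit[i],
                rules, nad$sex[i])
  }, integer(1))

  wide <- nad |>
    dplyr::select(dplyr::all_of(c("patient_id", "parameter")),
                  nadir = "nadir_value", day = "nadir_day",
                  grade = "grade") |>
    tidyr::pivot_wider(names_from = "parameter",
                       values_from = c("nadir", "day", "grade"),
                       names_glue = "{parameter}_{.value}")
  grades <- as.matrix(wide[, paste0(.hem_parameters, "_grade")])
  wide$overall_grade <- as.integer(apply(grades, 1, max))
  wide$grade_group <- .grade_group(wide$overall_grade)
  wide
}

#' Per-cycle highest CTCAE grades
#'
#' Splits the follow-up into half-open windows per treatment cycle —
#' `(day of cycle k, day of cycle k+1]`, the last cycle running 10 weeks
#' past its administration — and reports the highest grade per parameter
#' and overall inside each window. Observations falling outside every
#' window are ignored with a notice.
#'
#' @inheritParams overall_patient_grade
#' @param course course table: `patient_id`, `cycle`, `day`,
#'   `activity_gbq`.
#' @param tail_days length of the window after the last cycle (days).
#' @return a tibble: `patient_id`, `cycle`, one grade column per
#'   parameter (NA when a window holds no observation), and `overall`.
#' @export
per_cycle_grades <- function(labs, course, rules = ctcae_rules(),
                             sex = "female", tail_days = 70) {
  validate_labs(labs)
  assert_that(all(c("patient_id", "cycle", "day") %in% names(course)),
              "course table needs patient_id, cycle and day")
  sex_tbl <- if (is.data.frame(sex)) sex else
    tibble::tibble(patient_id = unique(labs$patient_id), sex = sex)

  out <- list()
  n_outside <- 0
  for (pid in unique(course$patient_id)) {
    cyc <- dplyr::arrange(course[course$patient_id == pid, ], .data$cycle)
    ends <- c(cyc$day[-1], cyc$day[nrow(cyc)] + tail_days)
    obs <- labs[labs$patient_id == pid & labs$day > 0, ]
    psex <- sex_tbl$sex[sex_tbl$patient_id == pid][1]
    in_any <- rep(FALSE, nrow(obs))
    for (k in seq_len(nrow(cyc))) {
      inw <- obs$day > cyc$day[k] & obs$day <= ends[k]
      in_any <- in_any | inw
      row <- tibble::tibble(patient_id = pid, cycle = cyc$cycle[k])
      for (p in .hem_parameters) {
        sel <- inw & obs$parameter == p
        row[[p]] <- if (!any(sel)) NA_integer_ else {
          m <- which.min(obs$value[sel])
          grade_value(p, obs$value[sel][m], obs$unit[sel][m], rules, psex)
        }
      }
      g <- unlist(row[.hem_parameters])
      row$overall <- if (all(is.na(g))) NA_integer_ else
        as.integer(max(g, na.rm = TRUE))
      out[[length(out) + 1]] <- row
    }
    n_outside <- n_outside + sum(!in_any)
  }
  if (n_outside > 0) {
    message(sprintf("%d observation(s) fell outside every cycle window and were ignored",
                    n_outside))
  }
  dplyr::bind_rows(out)
}

#' First cycle at which a grade level appears
#'
#' @param cycle_grades output of [per_cycle_grades()].
#' @param level grade level of interest (e.g. 2).
#' @return a tibble `patient_id`, `first_cycle` (NA when the level is
#'   never reached).
#' @export
first_occurrence_cycle <- function(cycle_grades, level = 2) {
  cycle_grades |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(
      first_cycle = {
        hit <- .data$cycle[!is.na(.data$overall) & .data$overall >= level]
        if (length(hit) == 0) NA_integer_ else min(hit)
      },
      .groups = "drop"
    )
}

#' Screening limits for starting or continuing therapy
#'
#' The bone-marrow and organ-function limits applied before each
#' administration; all are strict inequalities, so a value exactly at a
#' limit fails.
#'
#' @return named list of lower limits: haemoglobin (mmol/L), leucocytes,
#'   neutrophils, platelets (10^9/L), gfr (ml/min/1.73m2),
#'   albumin (g/L).
#' @export
eligibility_limits <- function() {
  list(haemoglobin = 5.5, leucocytes = 3.0, neutrophils = 1.0,
       platelets = 75, gfr = 50, albumin = 30)
}

#' Check eligibility against the screening limits
#'
#' @param baseline tibble with one row per patient and columns
#'   `haemoglobin` (mmol/L), `leucocytes`, `neutrophils`, `platelets`
#'   (10^9/L), `gfr`, `albumin` (and optionally `patient_id`).
#' @param limits named list of strict lower limits, see
#'   [eligibility_limits()].
#' @return a tibble `patient_id`, `eligible`, `failing` (comma-joined
#'   names of every failed criterion, empty when eligible).
#' @export
eligibility_check <- function(baseline, limits = eligibility_limits()) {
  miss <- setdiff(names(limits), names(baseline))
  assert_that(length(miss) == 0,
              sprintf("baseline table is missing input(s): %s",
                      paste(miss, collapse = ", ")))
  for (nm in names(limits)) {
    assert_that(!anyNA(baseline[[nm]]),
                sprintf("missing value(s) in eligibility input '%s'", nm))
  }
  if (!"patient_id" %in% names(baseline)) {
    baseline$patient_id <- seq_len(nrow(baseline))
  }
  fails <- vapply(seq_len(nrow(baseline)), function(i) {
    f <- names(limits)[vapply(names(limits), function(nm)
      !(baseline[[nm]][i] > limits[[nm]]), logical(1))]
    paste(f, collapse = ",")
  }, character(1))
  tibble::tibble(patient_id = baseline$patient_id,
                 eligible = fails == "", failing = fails)
}

#' Classify treatment-course adjustments
#'
#' Flags, per patient: postponement (any inter-cycle interval longer
#' than the planned interval plus tolerance), activity reduction (any
#' administered activity below the planned activity minus tolerance),
#' completion of the planned number of cycles, and discontinuation for
#' haematotoxicity (passed through from a `discontinuation_reason`
#' column when present).
#'
#' @param course course table: `patient_id`, `cycle`, `day`,
#'   `activity_gbq`, optional `discontinuation_reason`.
#' @param planned_interval_days planned inter-cycle interval (default 70
#'   days = 10 weeks).
#' @param planned_activity_gbq planned activity per cycle (default 7.4).
#' @param interval_tolerance_days slack on the interval (default 7).
#' @param activity_tolerance_gbq slack on the activity (default 0.2).
#' @param planned_cycles planned number of cycles (default 4).
#' @return a tibble with one row per patient: `n_cycles`, `completed`,
#'   `postponed`, `max_interval_days`, `reduced`, `min_activity_gbq`,
#'   `discontinued_haematotoxicity`.
#' @export
classify_course <- function(course, planned_interval_days = 70,
                            planned_activity_gbq = 7.4,
                            interval_tolerance_days = 7,
                            activity_tolerance_gbq = 0.2,
                            planned_cycles = 4) {
  assert_that(all(c("patient_id", "cycle", "day", "activity_gbq") %in%
                    names(course)),
              "course table needs patient_id, cycle, day and activity_gbq")
  course |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(.data$cycle, .by_group = TRUE) |>
    dplyr::summarise(
      n_cycles = dplyr::n(),
      completed = dplyr::n() == planned_cycles,
      postponed = dplyr::n() > 1 &&
        any(diff(.data$day) > planned_interval_days + interval_tolerance_days),
      max_interval_days = if (dplyr::n() > 1) max(diff(.data$day)) else
        NA_real_,
      reduced = any(.data$activity_gbq <
                      planned_activity_gbq - activity_tolerance_gbq),
      min_activity_gbq = min(.data$activity_gbq),
      discontinued_haematotoxicity =
        if ("discontinuation_reason" %in% names(course))
          any(.data$discontinuation_reason == "haematotoxicity",
              na.rm = TRUE) else FALSE,
      .groups = "drop"
    )
}
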
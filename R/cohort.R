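#' Specify a synthetic PRRT haematology cohort
#'
#' Describes a cohort of patients on a four-cycle radionuclide-therapy
#' schedule with longitudinal haemoglobin, leucocyte, neutrophil and
#' platelet measurements. Baselines are drawn per parameter (normal for
#' haemoglobin in mmol/L; log-normal for the count parameters in
#' 10^9/L, parameterised by median and interquartile range). After each
#' cycle a patient- and cycle-specific multiplicative decline pulls the
#' value down to `baseline * decline` at a configurable nadir offset,
#' after which the deficit recovers by a fixed fraction per week;
#' measurements carry multiplicative log-normal noise and are floored at
#' a small positive constant.
#'
#' @param n number of patients (positive).
#' @param baseline named list (one entry per parameter) of baseline
#'   distributions: `list(dist = "normal", mean, sd, unit)` or
#'   `list(dist = "lognormal", median, iqr = c(q25, q75), unit)`.
#' @param decline named list per parameter:
#'   `list(mean, sd, susceptibility_sd, recovery_per_week, cv)`. `mean`
#'   may be a vector of per-cycle decline means (recycled to
#'   `n_cycles`); the decline factor for patient i, cycle c is
#'   `clamp(mean[c] + u_i + e_ic, 0.05, 1)` with `u_i ~ N(0,
#'   susceptibility_sd)` and `e_ic ~ N(0, sd)`.
#' @param n_cycles planned number of cycles.
#' @param interval_weeks planned inter-cycle interval (weeks).
#' @param offsets_weeks sampling offsets after each cycle (weeks),
#'   strictly increasing and at most `interval_weeks`.
#' @param nadir_offset_weeks offset at which the post-cycle trajectory
#'   reaches its minimum; defaults to the first sampling offset so the
#'   noiseless observed nadir equals `baseline * decline` exactly.
#' @param activity_gbq administered activity per cycle (GBq).
#' @param baseline_day day of the baseline blood sample (must be `<= 0`).
#' @param floor lower floor for generated values (unit of the parameter).
#' @param seed integer seed; all randomness in [generate_cohort()] flows
#'   from it.
#' @return an object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n = 100L,
                        baseline = default_baseline_distributions(),
                        decline = default_decline_model(),
                        n_cycles = 4L,
                        interval_weeks = 10,
                        offsets_weeks = c(3, 6, 8.5),
                        nadir_offset_weeks = 3,
                        activity_gbq = 7.4,
                        baseline_day = -7,
                        floor = 0.1,
                        seed = 1L) {
  spec <- structure(
    list(n = as.integer(n), baseline = baseline, decline = decline,
         n_cycles = as.integer(n_cycles), interval_weeks = interval_weeks,
         offsets_weeks = offsets_weeks,
         nadir_offset_weeks = nadir_offset_weeks,
         activity_gbq = activity_gbq, baseline_day = baseline_day,
         floor = floor, seed = as.integer(seed)),
    class = "cohort_spec"
  )
  validate_cohort_spec(spec)
  spec
}

#' @rdname cohort_spec
#' @export
default_baseline_distributions <- function() {
  list(
    haemoglobin = list(dist = "normal", mean = 8.0, sd = 0.9,
                       unit = "mmol/L"),
    leucocytes  = list(dist = "lognormal", median = 6.8, iqr = c(5.6, 8.0),
                       unit = "10^9/L"),
    neutrophils = list(dist = "lognormal", median = 4.2, iqr = c(3.3, 5.2),
                       unit = "10^9/L"),
    platelets   = list(dist = "lognormal", median = 244, iqr = c(190, 329),
                       unit = "10^9/L")
  )
}

#' @rdname cohort_spec
#' @export
default_decline_model <- function() {
  list(
    haemoglobin = list(mean = 0.95, sd = 0.05, susceptibility_sd = 0.04,
                       recovery_per_week = 0.25, cv = 0.03),
    leucocytes  = list(mean = 0.70, sd = 0.10, susceptibility_sd = 0.08,
                       recovery_per_week = 0.25, cv = 0.03),
    neutrophils = list(mean = 0.73, sd = 0.10, susceptibility_sd = 0.08,
                       recovery_per_week = 0.25, cv = 0.03),
    platelets   = list(mean = 0.72, sd = 0.10, susceptibility_sd = 0.08,
                       recovery_per_week = 0.25, cv = 0.03)
  )
}

validate_cohort_spec <- function(spec) {
  assert_that(spec$n > 0, "number of patients must be positive")
  assert_that(all(.hem_parameters %in% names(spec$baseline)),
              "baseline distributions required for all four parameters")
  assert_that(all(.hem_parameters %in% names(spec$decline)),
              "decline model required for all four parameters")
  for (p in .hem_parameters) {
    d <- spec$decline[[p]]
    assert_that(all(d$mean > 0 & d$mean <= 1),
                sprintf("decline means for %s must lie in (0, 1]", p))
    assert_that(d$sd >= 0 && d$susceptibility_sd >= 0 && d$cv >= 0,
                sprintf("scale parameters for %s must be non-negative", p))
    assert_that(d$recovery_per_week >= 0 && d$recovery_per_week <= 1,
                sprintf("recovery fraction for %s must lie in [0, 1]", p))
    b <- spec$baseline[[p]]
    if (identical(b$dist, "normal")) {
      assert_that(b$sd > 0, sprintf("baseline SD for %s must be positive", p))
    } else {
      assert_that(b$iqr[1] < b$median && b$median < b$iqr[2],
                  sprintf("baseline IQR for %s must bracket the median", p))
    }
  }
  assert_that(all(diff(spec$offsets_weeks) > 0) &&
                all(spec$offsets_weeks <= spec$interval_weeks),
              "sampling offsets must be strictly increasing and <= the cycle interval")
  assert_that(spec$nadir_offset_weeks > 0 &&
                spec$nadir_offset_weeks <= spec$interval_weeks,
              "nadir offset must lie within the cycle interval")
  assert_that(spec$baseline_day <= 0, "baseline day must be <= 0")
  assert_that(spec$floor > 0, "value floor must be positive")
  invisible(spec)
}

# log-normal (meanlog, sdlog) from median and IQR
.lnorm_params <- function(median, iqr) {
  c(meanlog = log(median), sdlog = log(iqr[2] / iqr[1]) / (2 * qnorm(0.75)))
}

.draw_baseline <- function(b, n) {
  if (identical(b$dist, "normal")) {
    rnorm(n, b$mean, b$sd)
  } else {
    p <- .lnorm_params(b$median, b$iqr)
    rlnorm(n, p["meanlog"], p["sdlog"])
  }
}

# value at t weeks after a cycle (t scalar), relative decline D reached
# at t_nad; linear decline to the nadir, then exponential recovery of
# the deficit by `recovery` per week
.trajectory_value <- function(baseline, decline, t, t_nad, recovery) {
  deficit <- baseline * (1 - decline)
  if (t <= t_nad) {
    baseline - deficit * t / t_nad
  } else {
    baseline - deficit * (1 - recovery)^(t - t_nad)
  }
}

#' Generate a synthetic haematology cohort
#'
#' Draws the cohort described by a [cohort_spec()]: per patient one
#' baseline record per parameter plus one record at each sampling offset
#' after each cycle, and a treatment-course table with cycle days and
#' administered activities. Identical spec and seed reproduce the cohort
#' exactly.
#'
#' @param spec a [cohort_spec()].
#' @return a list with `labs` (tibble: `patient_id`, `parameter`, `day`,
#'   `value`, `unit`) and `course` (tibble: `patient_id`, `cycle`, `day`,
#'   `activity_gbq`); the spec is attached as attribute `"spec"` to each.
#' @export
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  n <- spec$n
  cycle_days <- (seq_len(spec$n_cycles) - 1) * spec$interval_weeks * 7
  mean_by_cycle <- lapply(spec$decline, function(d)
    rep_len(d$mean, spec$n_cycles))

  labs <- withr::with_seed(spec$seed, {
    purrr::map_dfr(.hem_parameters, function(p) {
      b <- spec$baseline[[p]]
      d <- spec$decline[[p]]
      base <- pmax(.draw_baseline(b, n), spec$floor)
      u <- rnorm(n, 0, d$susceptibility_sd)
      rows <- list(tibble::tibble(
        patient_id = seq_len(n), parameter = p, day = spec$baseline_day,
        value = base, unit = b$unit
      ))
      sdlog <- sqrt(log(1 + d$cv^2))
      for (c in seq_len(spec$n_cycles)) {
        decl <- pmin(1, pmax(0.05, mean_by_cycle[[p]][c] +
                               u + rnorm(n, 0, d$sd)))
        for (t in spec$offsets_weeks) {
          v <- .trajectory_value(base, decl, t, spec$nadir_offset_weeks,
                                 d$recovery_per_week)
          if (d$cv > 0) v <- v * exp(rnorm(n, -sdlog^2 / 2, sdlog))
          rows[[length(rows) + 1]] <- tibble::tibble(
            patient_id = seq_len(n), parameter = p,
            day = cycle_days[c] + t * 7,
            value = pmax(v, spec$floor), unit = b$unit
          )
        }
      }
      dplyr::bind_rows(rows)
    }) |>
      dplyr::arrange(.data$patient_id, .data$parameter, .data$day)
  })

  course <- tidyr::expand_grid(patient_id = seq_len(n),
                               cycle = seq_len(spec$n_cycles)) |>
    dplyr::mutate(day = cycle_days[.data$cycle],
                  activity_gbq = spec$activity_gbq)

  attr(labs, "spec") <- spec
  attr(course, "spec") <- spec
  list(labs = labs, course = course)
}

#' Write a generated cohort to tidy CSV files
#'
#' @param cohort the list returned by [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labs_path <- file.path(dir, "labs.csv")
  course_path <- file.path(dir, "course.csv")
  readr::write_csv(cohort$labs, labs_path)
  readr::write_csv(cohort$course, course_path)
  invisible(c(labs = labs_path, course = course_path))
}

#' @rdname write_cohort
#' @param labs_path,course_path paths to the tidy lab and course CSVs.
#' @export
read_cohort <- function(labs_path, course_path) {
  list(
    labs = readr::read_csv(labs_path, show_col_types = FALSE,
                           progress = FALSE),
    course = readr::read_csv(course_path, show_col_types = FALSE,
                             progress = FALSE)
  )
}
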
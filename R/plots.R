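#' @exportS3Method ggplot2::autoplot
autoplot.suv_histogram <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = object$bin_width, fill = "grey60") +
    ggplot2::labs(x = "SUV", y = "voxels", title = "Liver SUV histogram") +
    ggplot2::theme_minimal()
}

#' Plot a mixture fit over its histogram
#'
#' Overlays the three fitted Gaussian components (and their sum) on the
#' liver SUV histogram; the normal-parenchyma component, when
#' identified, is drawn with its mean + 1 SD threshold.
#'
#' @param object a [fit_three_gaussians()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mixture_fit <- function(object, ...) {
  h <- object$hist
  td <- tidy(h)
  xs <- seq(min(h$breaks), max(h$breaks), length.out = 512)
  comp <- object$components
  curves <- purrr::map_dfr(seq_len(nrow(comp)), function(q) {
    tibble::tibble(
      x = xs,
      y = h$total * h$bin_width * comp$weight[q] *
        dnorm(xs, comp$mean[q], comp$sd[q]),
      component = factor(comp$component[q])
    )
  })
  total <- curves |>
    dplyr::group_by(.data$x) |>
    dplyr::summarise(y = sum(.data$y), .groups = "drop")
  p <- ggplot2::ggplot() +
    ggplot2::geom_col(data = td,
                      ggplot2::aes(x = .data$mid, y = .data$count),
                      width = h$bin_width, fill = "grey80") +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$component)) +
    ggplot2::geom_line(data = total,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       linetype = "dashed") +
    ggplot2::labs(x = "SUV", y = "voxels",
                  title = "Three-Gaussian liver histogram fit",
                  colour = "component") +
    ggplot2::theme_minimal()
  if (!is.na(object$normal_index)) {
    mu <- comp$mean[comp$component == object$normal_index]
    sdv <- comp$sd[comp$component == object$normal_index]
    p <- p + ggplot2::geom_vline(xintercept = mu + sdv, linetype = "dotted")
  }
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.baseline_nadir_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$baseline, y = .data$nadir)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = object$beta, colour = "steelblue") +
    ggplot2::labs(
      title = sprintf("%s: r = %.3f, beta = %.3f, R2 = %.3f",
                      object$parameter, object$correlation, object$beta,
                      object$r_squared),
      x = sprintf("baseline (%s scale)", object$scale),
      y = sprintf("nadir (%s scale)", object$scale)) +
    ggplot2::theme_minimal()
}

#' Swimmers plot of treatment courses and per-cycle toxicity
#'
#' One horizontal lane per patient showing cycle administrations
#' (diamonds, filled when the activity was reduced) and the highest
#' overall CTCAE grade in each cycle window.
#'
#' @param course course table (`patient_id`, `cycle`, `day`,
#'   `activity_gbq`).
#' @param cycle_grades output of [per_cycle_grades()].
#' @param planned_activity_gbq activity below which a cycle is drawn as
#'   reduced.
#' @return a ggplot object.
#' @export
plot_swimmer <- function(course, cycle_grades,
                         planned_activity_gbq = 7.4) {
  dat <- dplyr::left_join(course, cycle_grades,
                          by = c("patient_id", "cycle")) |>
    dplyr::mutate(
      grade = factor(pmin(.data$overall, 4), levels = 0:4),
      reduced = .data$activity_gbq < planned_activity_gbq - 1e-9
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$day,
                                    y = factor(.data$patient_id))) +
    ggplot2::geom_line(ggplot2::aes(group = .data$patient_id),
                       colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$grade,
                                     shape = .data$reduced), size = 3) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 18, `TRUE` = 5)) +
    ggplot2::labs(x = "day from first administration", y = "patient",
                  colour = "CTCAE grade", shape = "reduced activity") +
    ggplot2::theme_minimal()
}

#' Per-cycle grade frequency plot
#'
#' Bar chart of the distribution of the highest overall grade after
#' each treatment cycle.
#'
#' @param cycle_grades output of [per_cycle_grades()].
#' @return a ggplot object.
#' @export
plot_grade_frequencies <- function(cycle_grades) {
  dat <- cycle_grades |>
    dplyr::filter(!is.na(.data$overall)) |>
    dplyr::mutate(grade = factor(.data$overall, levels = 0:4))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$cycle),
                                    fill = .data$grade)) +
    ggplot2::geom_bar(position = "stack") +
    ggplot2::labs(x = "treatment cycle", y = "patients",
                  fill = "CTCAE grade") +
    ggplot2::theme_minimal()
}
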
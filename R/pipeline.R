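#' Default configuration for the end-to-end demo pipeline
#'
#' Simulation, segmentation, grading and statistics options for a
#' complete run on one synthetic phantom and one synthetic cohort. The
#' grading rules path points at the packaged CTCAE v5 rules file and is
#' required: a config without it fails validation.
#'
#' @param out_dir output directory for all artifacts.
#' @param seed integer master seed; the phantom and cohort seeds are
#'   derived from it.
#' @return a named list understood by [run_pipeline()].
#' @export
default_run_config <- function(out_dir, seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    phantom = list(),     # phantom_spec() defaults
    cohort = list(n = 100L),
    segmentation = list(bin_width = 0.1, threshold_frac = 0.4,
                        connectivity = 26, normal_component = "auto",
                        fit_method = "wls"),
    grading = list(
      rules_path = system.file("extdata", "ctcae_v5_rules.json",
                               package = "prrtox"),
      sex = "female"
    ),
    stats = list(alpha = 0.05)
  )
}

#' Read a pipeline configuration from JSON or YAML
#'
#' @param path config file path (`.json`, `.yaml` or `.yml`).
#' @return the config list.
#' @export
load_run_config <- function(path) {
  assert_that(file.exists(path), sprintf("config file '%s' not found", path))
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    abort("config must be a .json or .yaml file")
  }
}

validate_run_config <- function(config) {
  assert_that(!is.null(config$seed) && config$seed == as.integer(config$seed),
              "run config needs an integer seed")
  assert_that(!is.null(config$out_dir), "run config needs an out_dir")
  rp <- config$grading$rules_path
  assert_that(!is.null(rp) && nzchar(rp),
              "run config is missing the grading rules path")
  assert_that(file.exists(rp),
              sprintf("grading rules file '%s' not found", rp))
  invisible(config)
}

.stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
  })
  message(sprintf("[%s] done in %.1fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full simulate - segment - grade - stats pipeline
#'
#' Generates a phantom and a cohort, segments the liver and the focal
#' lesions, grades the haematology series, runs the cohort statistics,
#' writes every intermediate artifact under `config$out_dir`, and
#' returns (and writes) a manifest listing options, seeds and the MD5
#' checksum of every artifact. Identical config and seed give identical
#' checksums; NIfTI artifacts are written uncompressed for this reason.
#'
#' @param config a config list, see [default_run_config()].
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  validate_run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  seg <- config$segmentation
  rules <- ctcae_rules(path = config$grading$rules_path)
  warnings <- character(0)

  # --- simulate ----------------------------------------------------------
  sim <- .stage("simulate", {
    pspec <- do.call(phantom_spec, c(config$phantom, list(seed = seed)))
    phantom <- generate_phantom(pspec)
    write_phantom(phantom, file.path(out, "phantom"))
    cspec <- do.call(cohort_spec, c(config$cohort, list(seed = seed + 1L)))
    cohort <- generate_cohort(cspec)
    write_cohort(cohort, file.path(out, "cohort"))
    list(phantom = phantom, cohort = cohort)
  })

  # --- segment -----------------------------------------------------------
  segres <- .stage("segment", {
    phantom <- sim$phantom
    hist <- build_liver_histogram(phantom, "liver",
                                  bin_width = seg$bin_width %||% 0.1)
    fit <- fit_three_gaussians(hist, method = seg$fit_method %||% "wls")
    if (!fit$converged) warnings <<- c(warnings, "mixture fit did not converge")
    fit <- if (identical(seg$normal_component %||% "auto", "auto")) {
      identify_normal_component(fit)
    } else {
      identify_normal_component(fit, override = as.integer(seg$normal_component))
    }
    liver <- liver_tumour_volume(phantom, fit)

    lesion_names <- grep("^lesion_", names(phantom$masks), value = TRUE)
    lesions <- lapply(lesion_names, function(nm) {
      segment_lesion_40pct(phantom, nm,
                           threshold_frac = seg$threshold_frac %||% 0.4,
                           connectivity = seg$connectivity %||% 26, id = nm)
    })
    labels <- vapply(seq_along(lesion_names), function(k) {
      phantom$truth$lesions[[k]]$label
    }, character(1))
    report <- compile_volume_report(liver$volume_ml, lesions, labels)

    readr::write_csv(tidy(hist), file.path(out, "liver_histogram.csv"))
    jsonlite::write_json(
      list(components = fit$components, normal_index = fit$normal_index,
           converged = fit$converged, gof = fit$gof,
           threshold = liver$threshold),
      file.path(out, "mixture_fit.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    tm <- RNifti::asNifti(array(as.integer(liver$mask),
                                dim = dim(phantom$suv)))
    RNifti::pixdim(tm) <- phantom$spacing
    RNifti::writeNifti(tm, file.path(out, "liver_tumour_mask.nii"))
    readr::write_csv(dplyr::bind_rows(lapply(lesions, tidy)),
                     file.path(out, "lesion_segments.csv"))
    readr::write_csv(report, file.path(out, "volume_report.csv"))
    list(fit = fit, liver = liver, lesions = lesions, report = report)
  })

  # --- grade -------------------------------------------------------------
  graded <- .stage("grade", {
    labs <- sim$cohort$labs
    course <- sim$cohort$course
    profiles <- overall_patient_grade(labs, rules,
                                      sex = config$grading$sex %||% "female")
    cyc <- suppressMessages(
      per_cycle_grades(labs, course, rules,
                       sex = config$grading$sex %||% "female"))
    flags <- classify_course(course)
    readr::write_csv(profiles, file.path(out, "grade_profiles.csv"))
    readr::write_csv(cyc, file.path(out, "cycle_grades.csv"))
    readr::write_csv(flags, file.path(out, "course_flags.csv"))
    timeline <- lapply(split(cyc, cyc$patient_id), function(d) {
      list(cycles = d$cycle, overall = d$overall)
    })
    jsonlite::write_json(timeline, file.path(out, "grade_timeline.json"),
                         auto_unbox = FALSE, digits = NA)
    list(profiles = profiles, cycle_grades = cyc, flags = flags)
  })

  # --- stats -------------------------------------------------------------
  statres <- .stage("stats", {
    tbl <- build_cohort_table(sim$cohort$labs, graded$profiles)
    comparisons <- purrr::map(
      paste0("baseline_", .hem_parameters),
      function(v) compare_groups(tbl, v, "grade_group",
                                 alpha = config$stats$alpha %||% 0.05))
    associations <- purrr::map(.hem_parameters, function(p) {
      baseline_nadir_association(tbl, paste0("baseline_", p),
                                 paste0(p, "_nadir"), parameter = p)
    })
    comp_tbl <- dplyr::bind_rows(lapply(comparisons, glance))
    assoc_tbl <- dplyr::bind_rows(lapply(associations, tidy))
    readr::write_csv(comp_tbl, file.path(out, "group_comparisons.csv"))
    readr::write_csv(assoc_tbl, file.path(out, "associations.csv"))
    jsonlite::write_json(
      list(comparisons = comp_tbl, associations = assoc_tbl,
           grade_groups = as.list(base::table(graded$profiles$grade_group))),
      file.path(out, "stats_bundle.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(comparisons = comparisons, associations = associations,
         table = tbl)
  })

  # --- manifest ----------------------------------------------------------
  manifest <- .stage("manifest", {
    files <- sort(list.files(out, recursive = TRUE))
    files <- setdiff(files, "manifest.json")
    sums <- tools::md5sum(file.path(out, files))
    m <- list(
      package = "prrtox",
      version = as.character(utils::packageVersion("prrtox")),
      seed = seed,
      options = list(
        segmentation = config$segmentation,
        grading = list(sex = config$grading$sex %||% "female",
                       rules = basename(config$grading$rules_path)),
        stats = config$stats
      ),
      warnings = warnings,
      artifacts = stats::setNames(as.list(unname(sums)), files)
    )
    jsonlite::write_json(m, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    m
  })

  invisible(list(manifest = manifest, segmentation = segres,
                 grading = graded, stats = statres))
}

#' Assemble the per-patient cohort table for statistics
#'
#' Joins baseline laboratory values (the day <= 0 record per parameter)
#' with the per-patient grade profile into the one-row-per-patient
#' table the comparison and association functions consume.
#'
#' @param labs tidy lab table.
#' @param profiles output of [overall_patient_grade()].
#' @return a tibble: `patient_id`, `baseline_<parameter>` columns,
#'   `<parameter>_nadir` columns, `overall_grade`, `grade_group`.
#' @export
build_cohort_table <- function(labs, profiles) {
  base <- labs |>
    dplyr::filter(.data$day <= 0) |>
    dplyr::select(dplyr::all_of(c("patient_id", "parameter", "value"))) |>
    tidyr::pivot_wider(names_from = "parameter", values_from = "value",
                       names_prefix = "baseline_")
  dplyr::left_join(base, profiles, by = "patient_id")
}
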
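#' CTCAE v5 laboratory grading rules
#'
#' Encodes the CTCAE v5.0 value-based grade bins for the four
#' haematological parameters, in canonical units (haemoglobin g/dL,
#' counts 10^9/L):
#'
#' * anaemia: grade 1 `<LLN-10.0`, grade 2 `<10.0-8.0`, grade 3 `<8.0`
#'   (grade 4 is defined clinically, so value-based anaemia grading caps
#'   at 3);
#' * white blood cell decreased: `<LLN-3.0`, `<3.0-2.0`, `<2.0-1.0`,
#'   `<1.0`;
#' * neutrophil count decreased: `<LLN-1.5`, `<1.5-1.0`, `<1.0-0.5`,
#'   `<0.5`;
#' * platelet count decreased: `<LLN-75`, `<75-50`, `<50-25`, `<25`.
#'
#' Bins are half-open: a value exactly at a bound takes the milder
#' grade. Values at or above the lower limit of normal (LLN) are grade
#' 0. Haemoglobin reported in mmol/L is converted with 1 mmol/L =
#' 1.6113 g/dL (the monomeric-iron convention used by Dutch
#' laboratories).
#'
#' @param path optional path to a JSON rules file with the same
#'   structure (see `inst/extdata/ctcae_v5_rules.json` for the template);
#'   `NULL` uses the built-in encoding.
#' @param lln lower limits of normal, as returned by [default_lln()].
#' @param hgb_conversion g/dL per mmol/L of haemoglobin.
#' @return an object of class `ctcae_rules`.
#' @export
ctcae_rules <- function(path = NULL, lln = default_lln(),
                        hgb_conversion = 1.6113) {
  if (!is.null(path)) {
    raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
    lln <- lapply(raw$lln, unlist)
    hgb_conversion <- raw$hgb_conversion
    bins <- lapply(raw$bins, unlist)
  } else {
    bins <- list(
      haemoglobin = c(8.0, 10.0),         # g/dL; capped at grade 3
      leucocytes  = c(1.0, 2.0, 3.0),
      neutrophils = c(0.5, 1.0, 1.5),
      platelets   = c(25, 50, 75)
    )
  }
  assert_that(hgb_conversion > 0, "haemoglobin conversion factor must be positive")
  structure(list(bins = bins, lln = lln, hgb_conversion = hgb_conversion),
            class = "ctcae_rules")
}

#' @rdname ctcae_rules
#' @export
default_lln <- function() {
  list(
    haemoglobin = c(male = 8.5, female = 7.5),  # mmol/L
    leucocytes = 4.0,
    neutrophils = 1.5,
    platelets = 150
  )
}

#' Write grading rules to an editable JSON file
#'
#' @param rules a [ctcae_rules()] object.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ctcae_rules <- function(rules, path) {
  jsonlite::write_json(
    list(bins = lapply(rules$bins, as.numeric),
         lln = lapply(rules$lln, as.list),
         hgb_conversion = rules$hgb_conversion),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

# value in the parameter's canonical unit
.to_canonical <- function(parameter, value, unit, rules) {
  if (parameter == "haemoglobin") {
    if (unit == "mmol/L") return(value * rules$hgb_conversion)
    if (unit == "g/dL") return(value)
    abort(sprintf("unknown haemoglobin unit '%s' (use mmol/L or g/dL)", unit))
  }
  if (unit %in% c("10^9/L", "1e9/L", "x10^9/L")) return(value)
  abort(sprintf("unknown unit '%s' for %s (use 10^9/L)", unit, parameter))
}

.lln_canonical <- function(parameter, rules, sex) {
  lln <- rules$lln[[parameter]]
  if (parameter == "haemoglobin") {
    if (length(lln) > 1) {
      assert_that(sex %in% names(lln),
                  sprintf("no haemoglobin LLN for sex '%s'", sex))
      lln <- lln[[sex]]
    }
    return(lln * rules$hgb_conversion)
  }
  unname(lln[1])
}

#' Grade a laboratory value on the CTCAE v5 scale
#'
#' Converts the value to canonical units, then assigns grade 0 (at or
#' above the LLN) through 4 by the half-open CTCAE bins; anaemia caps at
#' grade 3 because its grade 4 is a clinical, not a value, criterion.
#' Vectorised over `value`.
#'
#' @param parameter one of `"haemoglobin"`, `"leucocytes"`,
#'   `"neutrophils"`, `"platelets"`.
#' @param value numeric value(s), positive.
#' @param unit unit of `value` (`"mmol/L"` or `"g/dL"` for haemoglobin,
#'   `"10^9/L"` for counts).
#' @param rules a [ctcae_rules()] object.
#' @param sex `"female"` or `"male"`: selects the haemoglobin LLN (only
#'   the grade 0 vs 1 boundary depends on it).
#' @return integer grade(s) 0-4.
#' @export
grade_value <- function(parameter, value, unit, rules = ctcae_rules(),
                        sex = "female") {
  assert_that(parameter %in% .hem_parameters,
              sprintf("unknown parameter '%s'", parameter))
  assert_that(all(value > 0), "laboratory values must be positive")
  v <- .to_canonical(parameter, value, unit, rules)
  bounds <- c(rules$bins[[parameter]],
              .lln_canonical(parameter, rules, sex))
  vapply(v, function(x) sum(x < bounds), numeric(1)) |> as.integer()
}

#' @export
print.ctcae_rules <- function(x, ...) {
  cat("<ctcae_rules> CTCAE v5 value bins (canonical units)\n")
  for (p in names(x$bins)) {
    cat(sprintf("  %-12s bounds: %s | LLN: %s\n", p,
                paste(x$bins[[p]], collapse = ", "),
                paste(x$lln[[p]], collapse = "/")))
  }
  cat(sprintf("  haemoglobin conversion: 1 mmol/L = %.4f g/dL\n",
              x$hgb_conversion))
  invisible(x)
}
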
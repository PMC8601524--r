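#' Choose an analysis scale for a continuous variable
#'
#' Reproducible stand-in for visual normality assessment: a variable is
#' treated as normal when its absolute sample skewness is at most 1; a
#' skewed variable is log transformed when that brings the skewness
#' inside the band (which requires strictly positive values).
#'
#' @param values numeric vector (NAs dropped).
#' @param skew_limit absolute skewness above which the identity scale is
#'   rejected.
#' @return a list: `scale` (`"identity"` or `"log"`), `values`
#'   (transformed), `skewness` (on the chosen scale).
#' @export
choose_scale <- function(values, skew_limit = 1) {
  values <- values[!is.na(values)]
  assert_that(length(values) > 0, "no non-missing values")
  sk <- .skewness(values)
  if (abs(sk) <= skew_limit) {
    return(list(scale = "identity", values = values, skewness = sk))
  }
  assert_that(all(values > 0),
              "log transform selected but values are not all positive")
  lv <- log(values)
  lsk <- .skewness(lv)
  if (abs(lsk) < abs(sk)) {
    list(scale = "log", values = lv, skewness = lsk)
  } else {
    list(scale = "identity", values = values, skewness = sk)
  }
}

# sample skewness m3 / m2^(3/2); 0 for constant input
.skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)
  mean((x - m)^3) / m2^1.5
}

#' Compare a baseline variable between grade groups
#'
#' Applies the test a practitioner would pick for the variable type:
#' chi-square (without continuity correction) on the contingency table
#' for categorical variables; one-way ANOVA for continuous variables
#' that look normal after [choose_scale()]; Kruskal-Wallis otherwise.
#' When the omnibus p value is below `alpha`, pairwise post hoc tests
#' are added (Welch t tests after ANOVA, Dunn's rank tests after
#' Kruskal-Wallis) with Bonferroni adjustment.
#'
#' @param table cohort table, one row per patient.
#' @param variable name of the column to compare.
#' @param group name of the grouping column (e.g. `"grade_group"`).
#' @param alpha omnibus significance level gating the post hoc tests.
#' @return an object of class `group_comparison`: `variable`, `test`,
#'   `statistic`, `df`, `p_value`, `summaries` (per-group tibble),
#'   `posthoc` (tibble or NULL), `scale`, `warnings`.
#' @export
compare_groups <- function(table, variable, group, alpha = 0.05) {
  assert_that(all(c(variable, group) %in% names(table)),
              "variable and group columns must exist in the table")
  dat <- table[!is.na(table[[variable]]) & !is.na(table[[group]]), ]
  g <- factor(dat[[group]])
  g <- droplevels(g)
  assert_that(nlevels(g) >= 2, "need at least 2 non-empty groups")
  assert_that(all(base::table(g) > 0), "every group must be non-empty")
  x <- dat[[variable]]
  warn <- character(0)

  if (is.numeric(x)) {
    sc <- tryCatch(choose_scale(x), error = function(e)
      list(scale = "identity", values = x, skewness = .skewness(x)))
    xt <- sc$values
    # normal-looking (possibly after log) -> ANOVA; still skewed -> KW
    if (abs(sc$skewness) <= 1) {
      fit <- aov(xt ~ g)
      an <- summary(fit)[[1]]
      statistic <- an[["F value"]][1]
      df <- unname(an[["Df"]][1])
      p <- an[["Pr(>F)"]][1]
      test <- "ANOVA"
    } else {
      kw <- kruskal.test(x, g)
      statistic <- unname(kw$statistic)
      df <- unname(kw$parameter)
      p <- kw$p.value
      test <- "Kruskal-Wallis"
      sc$scale <- "identity"   # ranks are scale-free
      xt <- x
    }
    summaries <- tibble::tibble(
      group = levels(g),
      n = as.integer(base::table(g)),
      mean = tapply(x, g, mean),
      sd = tapply(x, g, sd),
      median = tapply(x, g, median),
      q25 = tapply(x, g, quantile, 0.25),
      q75 = tapply(x, g, quantile, 0.75)
    )
    posthoc <- NULL
    if (!is.na(p) && p < alpha) {
      posthoc <- if (test == "ANOVA") {
        .pairwise_welch(xt, g)
      } else {
        .dunn_test(x, g)
      }
    }
    scale_used <- if (test == "ANOVA") sc$scale else "identity"
  } else {
    tab <- base::table(x, g)
    suppressWarnings(ct <- chisq.test(tab, correct = FALSE))
    if (any(ct$expected < 1)) {
      warn <- c(warn, "chi-square expected cell count below 1")
    }
    statistic <- unname(ct$statistic)
    df <- unname(ct$parameter)
    p <- ct$p.value
    test <- "chi-square"
    summaries <- tibble::as_tibble(as.data.frame(tab)) |>
      stats::setNames(c("level", "group", "n"))
    posthoc <- NULL
    scale_used <- "identity"
  }

  structure(
    list(variable = variable, test = test, statistic = statistic,
         df = df, p_value = p, summaries = summaries, posthoc = posthoc,
         scale = scale_used, warnings = warn),
    class = "group_comparison"
  )
}

# pairwise Welch t tests with Bonferroni adjustment
.pairwise_welch <- function(x, g) {
  lev <- levels(g)
  pairs <- utils::combn(lev, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- x[g == pairs[1, j]]
    b <- x[g == pairs[2, j]]
    if (length(a) < 2 || length(b) < 2) {
      # Welch needs two observations per arm; tiny groups happen in
      # small severe-toxicity strata
      return(tibble::tibble(group1 = pairs[1, j], group2 = pairs[2, j],
                            statistic = NA_real_, p_raw = NA_real_))
    }
    tt <- t.test(a, b)
    tibble::tibble(group1 = pairs[1, j], group2 = pairs[2, j],
                   statistic = unname(tt$statistic), p_raw = tt$p.value)
  })
  res$p_adjusted <- p.adjust(res$p_raw, method = "bonferroni")
  res$method <- "Welch t (Bonferroni)"
  res
}

# Dunn's post hoc z tests on mean ranks, with tie correction and
# Bonferroni adjustment
.dunn_test <- function(x, g) {
  r <- rank(x)
  n <- length(x)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  lev <- levels(g)
  rbar <- tapply(r, g, mean)
  ng <- table(g)
  pairs <- utils::combn(lev, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / ng[i1] + 1 / ng[i2]))
    z <- unname((rbar[i1] - rbar[i2]) / se)
    tibble::tibble(group1 = i1, group2 = i2, statistic = z,
                   p_raw = 2 * pnorm(-abs(z)))
  })
  res$p_adjusted <- p.adjust(res$p_raw, method = "bonferroni")
  res$method <- "Dunn (Bonferroni)"
  res
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s by group: %s statistic %.3f, p = %.4g\n",
              x$variable, x$test, x$statistic, x$p_value))
  if (!is.null(x$posthoc)) {
    cat("post hoc:\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.group_comparison <- function(x, ...) {
  if (is.null(x$posthoc)) {
    tibble::tibble(variable = x$variable, test = x$test,
                   statistic = x$statistic, df = x$df, p_value = x$p_value)
  } else {
    dplyr::bind_cols(
      tibble::tibble(variable = x$variable, test = x$test)[
        rep(1, nrow(x$posthoc)), ],
      x$posthoc
    )
  }
}

#' @exportS3Method generics::glance
glance.group_comparison <- function(x, ...) {
  tibble::tibble(variable = x$variable, test = x$test,
                 statistic = x$statistic, df = x$df, p_value = x$p_value,
                 scale = x$scale, n_posthoc = if (is.null(x$posthoc)) 0L else
                   nrow(x$posthoc))
}

#' Baseline-to-nadir correlation and regression
#'
#' Pearson correlation and ordinary least-squares regression of the
#' nadir value on the baseline value of one haematological parameter
#' (optionally after log transform of both), with the slope's 95%
#' confidence interval and R-squared.
#'
#' @param table cohort table with one row per patient.
#' @param baseline name of the baseline column.
#' @param nadir name of the nadir column.
#' @param parameter label carried into the result.
#' @param scale `"identity"`, `"log"`, or `"auto"` (apply
#'   [choose_scale()] to the baseline values).
#' @param conf_level confidence level for the slope interval.
#' @return an object of class `baseline_nadir_fit`: `parameter`,
#'   `correlation`, `cor_p`, `beta`, `beta_ci`, `r_squared`, `reg_p`,
#'   `scale`, `n`, `data` (tibble of the pairs used, for plotting).
#' @export
baseline_nadir_association <- function(table, baseline, nadir,
                                       parameter = baseline,
                                       scale = "identity",
                                       conf_level = 0.95) {
  assert_that(all(c(baseline, nadir) %in% names(table)),
              "baseline and nadir columns must exist in the table")
  b <- table[[baseline]]
  v <- table[[nadir]]
  keep <- !is.na(b) & !is.na(v)
  b <- b[keep]; v <- v[keep]
  assert_that(length(b) >= 3, "need at least 3 complete pairs")
  assert_that(var(b) > 0, "baseline values have zero variance")
  if (scale == "auto") scale <- choose_scale(b)$scale
  if (scale == "log") {
    assert_that(all(b > 0) && all(v > 0),
                "log scale requires positive values")
    b <- log(b); v <- log(v)
  }
  ct <- cor.test(b, v, method = "pearson")
  fit <- lm(v ~ b)
  ci <- confint(fit, "b", level = conf_level)
  structure(
    list(parameter = parameter,
         correlation = unname(ct$estimate), cor_p = ct$p.value,
         beta = unname(coef(fit)["b"]), beta_ci = unname(ci[1, ]),
         intercept = unname(coef(fit)["(Intercept)"]),
         r_squared = summary(fit)$r.squared,
         reg_p = summary(fit)$coefficients["b", "Pr(>|t|)"],
         scale = scale, n = length(b),
         data = tibble::tibble(baseline = b, nadir = v)),
    class = "baseline_nadir_fit"
  )
}

#' @export
print.baseline_nadir_fit <- function(x, ...) {
  cat(sprintf(
    "<baseline_nadir_fit> %s (n=%d, %s scale): r = %.3f, beta = %.3f (%.3f-%.3f), R2 = %.3f\n",
    x$parameter, x$n, x$scale, x$correlation, x$beta, x$beta_ci[1],
    x$beta_ci[2], x$r_squared))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.baseline_nadir_fit <- function(x, ...) {
  tibble::tibble(
    parameter = x$parameter, correlation = x$correlation, cor_p = x$cor_p,
    beta = x$beta, beta_low = x$beta_ci[1], beta_high = x$beta_ci[2],
    r_squared = x$r_squared, reg_p = x$reg_p
  )
}

#' @exportS3Method generics::glance
glance.baseline_nadir_fit <- function(x, ...) {
  tibble::tibble(parameter = x$parameter, n = x$n, scale = x$scale,
                 r_squared = x$r_squared)
}

#' Descriptive summary of a cohort table
#'
#' Summarises each requested variable per group the way a baseline
#' characteristics table would: mean (SD) for variables on the identity
#' scale, median [IQR] for skewed variables (IQR as interpolated 25th
#' and 75th percentiles), and n (%) for categorical variables.
#'
#' @param table cohort table, one row per patient.
#' @param variables columns to summarise (default: all but the group).
#' @param group optional grouping column.
#' @return a tibble with one row per variable (x group x level).
#' @export
summarize_cohort <- function(table, variables = NULL, group = NULL) {
  assert_that(nrow(table) > 0, "cohort table is empty")
  if (is.null(variables)) variables <- setdiff(names(table), group)
  groups <- if (is.null(group)) list(all = rep(TRUE, nrow(table))) else
    split(seq_len(nrow(table)), table[[group]]) |>
    lapply(function(i) seq_len(nrow(table)) %in% i)

  purrr::map_dfr(variables, function(v) {
    purrr::map_dfr(names(groups), function(gname) {
      x <- table[[v]][groups[[gname]]]
      x <- x[!is.na(x)]
      if (is.numeric(x)) {
        sc <- if (length(x) > 2) choose_scale(x)$scale else "identity"
        tibble::tibble(
          variable = v, group = gname, level = NA_character_,
          n = length(x),
          summary = if (length(x) == 1) sprintf("%.3g", x)
          else if (sc == "identity")
            sprintf("%.3g ± %.3g", mean(x), sd(x))
          else sprintf("%.3g [%.3g-%.3g]", median(x),
                       quantile(x, 0.25), quantile(x, 0.75)),
          mean = mean(x), sd = if (length(x) > 1) sd(x) else NA_real_,
          median = median(x),
          q25 = unname(quantile(x, 0.25)), q75 = unname(quantile(x, 0.75))
        )
      } else {
        tab <- base::table(x)
        tibble::tibble(
          variable = v, group = gname, level = names(tab),
          n = as.integer(tab),
          summary = sprintf("%d (%.0f%%)", as.integer(tab),
                            100 * as.integer(tab) / length(x)),
          mean = NA_real_, sd = NA_real_, median = NA_real_,
          q25 = NA_real_, q75 = NA_real_
        )
      }
    })
  })
}
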
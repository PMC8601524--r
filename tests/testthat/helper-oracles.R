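# Independent oracles and small fixture builders shared across tests.
# These deliberately re-derive quantities with the most literal possible
# code so they stay independent of the package implementation.

# Brute-force SUVpeak: for every candidate centre, measure physical
# distances from every grid voxel centre and average those within the
# 1 mL sphere radius. Ties: first candidate in lexicographic (i, j, k)
# order wins.
brute_suvpeak <- function(suv, spacing, region_idx,
                          r = (3000 / (4 * pi))^(1 / 3)) {
  shape <- dim(suv)
  xs <- (seq_len(shape[1]) - 1) * spacing[1]
  ys <- (seq_len(shape[2]) - 1) * spacing[2]
  zs <- (seq_len(shape[3]) - 1) * spacing[3]
  X <- array(rep(xs, times = shape[2] * shape[3]), dim = shape)
  Y <- array(rep(rep(ys, each = shape[1]), times = shape[3]), dim = shape)
  Z <- array(rep(zs, each = shape[1] * shape[2]), dim = shape)
  ord <- order(region_idx[, 1], region_idx[, 2], region_idx[, 3])
  region_idx <- region_idx[ord, , drop = FALSE]
  best <- -Inf
  best_center <- NULL
  for (q in seq_len(nrow(region_idx))) {
    c_ijk <- region_idx[q, ]
    cx <- (c_ijk[1] - 1) * spacing[1]
    cy <- (c_ijk[2] - 1) * spacing[2]
    cz <- (c_ijk[3] - 1) * spacing[3]
    d2 <- (X - cx)^2 + (Y - cy)^2 + (Z - cz)^2
    m <- mean(suv[d2 <= r^2])
    if (m > best) {
      best <- m
      best_center <- c_ijk
    }
  }
  list(suvpeak = best, center = best_center)
}

# A small random SUV volume with a few warm spots, for oracle-equality
# checks. Returns the suv_volume and a random contiguous candidate box.
random_small_volume <- function(seed, max_dim = 25) {
  withr::with_seed(seed, {
    shape <- sample(15:max_dim, 3, replace = TRUE)
    spacing <- runif(3, 2, 4)
    suv <- array(runif(prod(shape), 0, 2), dim = shape)
    for (k in 1:2) {
      ctr <- sapply(shape, function(s) sample(4:(s - 3), 1))
      amp <- runif(1, 5, 20)
      for (dd in -2:2) {
        i <- pmin(pmax(ctr[1] + dd, 1), shape[1])
        suv[i, ctr[2], ctr[3]] <- suv[i, ctr[2], ctr[3]] + amp
      }
      suv[ctr[1], ctr[2], ctr[3]] <- suv[ctr[1], ctr[2], ctr[3]] + amp
    }
    lo <- sapply(shape, function(s) sample(2:(s - 7), 1))
    box <- as.matrix(expand.grid(lo[1]:(lo[1] + 5), lo[2]:(lo[2] + 5),
                                 lo[3]:(lo[3] + 5)))
    list(volume = suv_volume(suv, spacing), box = box)
  })
}

# Tail mass of the phantom's generating mixture above a threshold,
# using the realised tumour voxel fraction (non-tumour liver voxels
# split between blood and normal by their weight ratio).
mixture_tail_above <- function(truth, threshold) {
  w <- truth$weights
  f <- truth$tumour_fraction
  p_blood <- if (w[1] + w[2] > 0) w[1] / (w[1] + w[2]) else 0
  f * pnorm(threshold, truth$means[3], truth$sds[3], lower.tail = FALSE) +
    (1 - f) * (
      p_blood * pnorm(threshold, truth$means[1], truth$sds[1],
                      lower.tail = FALSE) +
        (1 - p_blood) * pnorm(threshold, truth$means[2], truth$sds[2],
                              lower.tail = FALSE)
    )
}

# --- analytic nadir distribution of the cohort generator (noiseless) ---
# With measurement CV 0 the observed nadir equals baseline * min over
# cycles of the decline factor. These integrals re-derive the induced
# grade probabilities directly from the configured distributions.

# P(min_c clamp(mu_c + u + e_c, 0.05, 1) <= x | u); valid for x < 1
.p_min_decline_le <- function(x, u, mu_cycles, se) {
  if (x < 0.05) return(rep(0, length(u)))
  keep <- vapply(u, function(uu) {
    1 - prod(1 - pnorm((x - mu_cycles - uu) / se))
  }, numeric(1))
  keep
}

# P(baseline * minD < v) by nested numeric integration over the
# susceptibility u and the baseline distribution
p_nadir_below <- function(v, baseline_dist, decline, n_cycles = 4) {
  mu_cycles <- rep_len(decline$mean, n_cycles)
  su <- decline$susceptibility_sd
  se <- decline$sd
  p_given_b <- function(b) {
    x <- v / b
    if (x >= 1) return(1)
    if (su == 0) {
      return(.p_min_decline_le(x, 0, mu_cycles, se))
    }
    integrate(function(u) {
      .p_min_decline_le(x, u, mu_cycles, se) * dnorm(u, 0, su)
    }, lower = -8 * su, upper = 8 * su, rel.tol = 1e-8)$value
  }
  if (identical(baseline_dist$dist, "normal")) {
    m <- baseline_dist$mean; s <- baseline_dist$sd
    integrate(function(b) {
      vapply(b, p_given_b, numeric(1)) * dnorm(b, m, s)
    }, lower = max(m - 8 * s, 1e-6), upper = m + 8 * s,
    rel.tol = 1e-7)$value
  } else {
    p <- c(meanlog = log(baseline_dist$median),
           sdlog = log(baseline_dist$iqr[2] / baseline_dist$iqr[1]) /
             (2 * qnorm(0.75)))
    integrate(function(b) {
      vapply(b, p_given_b, numeric(1)) * dlnorm(b, p[1], p[2])
    }, lower = exp(p[1] - 8 * p[2]), upper = exp(p[1] + 8 * p[2]),
    rel.tol = 1e-7)$value
  }
}

# native-unit grade bounds (value < bound k..1 => grade >= k), mildest
# (LLN) last; haemoglobin bins are stored in g/dL, LLN in mmol/L
native_grade_bounds <- function(parameter, rules, sex = "female") {
  bins <- rules$bins[[parameter]]
  lln <- rules$lln[[parameter]]
  if (parameter == "haemoglobin") {
    if (length(lln) > 1) lln <- lln[[sex]]
    c(bins / rules$hgb_conversion, lln)
  } else {
    c(bins, unname(lln[1]))
  }
}

# P(nadir grade >= level) for a generated (noiseless) cohort parameter
p_grade_at_least <- function(level, parameter, spec, rules,
                             sex = "female") {
  bounds <- native_grade_bounds(parameter, rules, sex)  # ascending
  k <- length(bounds)
  if (level > k) return(0)
  bound <- bounds[k - level + 1]
  p_nadir_below(bound, spec$baseline[[parameter]],
                spec$decline[[parameter]], spec$n_cycles)
}

# analytic probabilities of the overall grade groups {0-1, 2, 3-4}
# under parameter independence
analytic_grade_group_probs <- function(spec, rules, sex = "female") {
  p_le1 <- 1
  p_le2 <- 1
  for (p in .hem_parameters_test) {
    p_le1 <- p_le1 * (1 - p_grade_at_least(2, p, spec, rules, sex))
    p_le2 <- p_le2 * (1 - p_grade_at_least(3, p, spec, rules, sex))
  }
  c(`0-1` = p_le1, `2` = p_le2 - p_le1, `3-4` = 1 - p_le2)
}

.hem_parameters_test <- c("haemoglobin", "leucocytes", "neutrophils",
                          "platelets")

# small tidy lab table builder
make_labs <- function(patient_id, parameter, days, values,
                      unit = if (parameter == "haemoglobin") "mmol/L" else
                        "10^9/L") {
  tibble::tibble(patient_id = patient_id, parameter = parameter,
                 day = days, value = values, unit = unit)
}

# one patient's four-parameter series with given nadirs (baseline at
# day -7 set comfortably normal unless supplied)
four_param_labs <- function(nadirs,
                            baselines = c(haemoglobin = 8.5,
                                          leucocytes = 7, neutrophils = 4,
                                          platelets = 250),
                            patient_id = 1) {
  dplyr::bind_rows(lapply(names(nadirs), function(p) {
    make_labs(patient_id, p, c(-7, 21, 42), c(baselines[[p]], nadirs[[p]],
                                              baselines[[p]]))
  }))
}
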
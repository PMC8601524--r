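#' Histogram of liver SUV values
#'
#' Sorts all SUV values inside the liver mask into fixed-width bins
#' (default 0.1 SUV) running from 0 to one bin beyond the maximum value.
#' Bins are half-open `[lower, upper)`.
#'
#' @param volume an [suv_volume()].
#' @param mask a logical array, or the name of a mask stored in the
#'   volume (default `"liver"`).
#' @param bin_width bin width in SUV units.
#' @return an object of class `suv_histogram`: `breaks` (edges), `mids`,
#'   `counts`, `total`, `bin_width`.
#' @export
build_liver_histogram <- function(volume, mask = "liver", bin_width = 0.1) {
  if (is.character(mask)) {
    assert_that(mask %in% names(volume$masks),
                sprintf("volume has no mask named '%s'", mask))
    mask <- volume$masks[[mask]]
  }
  assert_that(sum(mask) > 0, "liver mask is empty")
  assert_that(bin_width > 0, "bin width must be positive")
  v <- volume$suv[mask]
  breaks <- seq(0, (floor(max(v) / bin_width) + 1) * bin_width,
                by = bin_width)
  counts <- tabulate(findInterval(v, breaks), nbins = length(breaks) - 1)
  structure(
    list(breaks = breaks, mids = breaks[-length(breaks)] + bin_width / 2,
         counts = counts, total = length(v), bin_width = bin_width),
    class = "suv_histogram"
  )
}

#' @export
print.suv_histogram <- function(x, ...) {
  cat(sprintf("<suv_histogram> %d voxels in %d bins of %.3g SUV\n",
              x$total, length(x$counts), x$bin_width))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.suv_histogram <- function(x, ...) {
  tibble::tibble(lower = x$breaks[-length(x$breaks)],
                 upper = x$breaks[-1], mid = x$mids, count = x$counts)
}

# deterministic quantile-based starting values from the histogram itself
.mixture_init <- function(hist) {
  cum <- cumsum(hist$counts) / hist$total
  qq <- vapply(c(0.1, 0.5, 0.9),
               function(p) hist$mids[which(cum >= p)[1]], numeric(1))
  sds <- pmax(c((qq[2] - qq[1]) / 2, (qq[2] - qq[1]) / 2,
                (qq[3] - qq[2]) / 2), hist$bin_width)
  list(weights = rep(1 / 3, 3), means = qq, sds = sds)
}

#' Fit three Gaussian components to a liver SUV histogram
#'
#' Decomposes the liver histogram into three Gaussian populations,
#' interpreted (in increasing mean order) as blood pool, normal liver
#' parenchyma and tumour tissue. The default method is weighted least
#' squares of the sum of three scaled Gaussian densities against the bin
#' counts (weights `1/max(count, 1)`, the Poisson chi-square weighting);
#' `method = "em"` runs expectation-maximisation on the binned values
#' instead. Both are deterministic given the histogram and the starting
#' values (quantile-based by default). A fit that does not converge is
#' returned at its best iterate with `converged = FALSE`.
#'
#' @param hist an [build_liver_histogram()] result.
#' @param method `"wls"` (default) or `"em"`.
#' @param init optional starting values:
#'   `list(weights, means, sds)` each of length 3.
#' @param max_iter iteration cap for the optimiser.
#' @return an object of class `mixture_fit`: `components` (tibble of
#'   `weight`, `mean`, `sd`, sorted by mean), `normal_index` (`NA` until
#'   [identify_normal_component()] is applied), `gof` (R-squared of
#'   fitted vs observed counts), `converged`, `method`.
#' @export
fit_three_gaussians <- function(hist, method = c("wls", "em"), init = NULL,
                                max_iter = 500) {
  method <- match.arg(method)
  assert_that(sum(hist$counts > 0) >= 3,
              "histogram must have at least 3 non-empty bins")
  assert_that(hist$total >= 100,
              "histogram must contain at least 100 voxels")
  if (is.null(init)) init <- .mixture_init(hist)

  res <- if (method == "wls") {
    .fit_wls(hist, init, max_iter)
  } else {
    .fit_em(hist, init, max_iter)
  }

  comp <- tibble::tibble(weight = res$weights, mean = res$means,
                         sd = res$sds)
  comp <- comp[order(comp$mean, -comp$weight), ]
  comp$component <- 1:3
  fitted_counts <- .mixture_counts(hist, comp)
  sst <- sum((hist$counts - mean(hist$counts))^2)
  gof <- if (sst > 0) 1 - sum((hist$counts - fitted_counts)^2) / sst else NA_real_
  structure(
    list(components = comp[, c("component", "weight", "mean", "sd")],
         normal_index = NA_integer_, normal_method = NA_character_,
         gof = gof, converged = res$converged, method = method,
         bin_width = hist$bin_width, total = hist$total, hist = hist),
    class = "mixture_fit"
  )
}

.mixture_counts <- function(hist, comp) {
  dens <- rep(0, length(hist$mids))
  for (q in 1:3) {
    dens <- dens + comp$weight[q] * dnorm(hist$mids, comp$mean[q], comp$sd[q])
  }
  hist$total * hist$bin_width * dens
}

.fit_wls <- function(hist, init, max_iter) {
  x <- hist$mids
  y <- hist$counts
  amp <- init$weights * hist$total * hist$bin_width
  start <- list(a1 = amp[1], a2 = amp[2], a3 = amp[3],
                m1 = init$means[1], m2 = init$means[2], m3 = init$means[3],
                s1 = init$sds[1], s2 = init$sds[2], s3 = init$sds[3])
  lo <- c(0, 0, 0, rep(min(x), 3), rep(hist$bin_width / 4, 3))
  hi <- c(rep(Inf, 3), rep(max(x), 3), rep(diff(range(x)) + 1, 3))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a1 * dnorm(x, m1, s1) + a2 * dnorm(x, m2, s2) +
        a3 * dnorm(x, m3, s3),
      start = start, weights = 1 / pmax(y, 1), lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = max_iter)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(list(weights = init$weights, means = init$means, sds = init$sds,
                converged = FALSE))
  }
  p <- coef(fit)
  a <- p[c("a1", "a2", "a3")]
  list(weights = unname(a / sum(a)),
       means = unname(p[c("m1", "m2", "m3")]),
       sds = unname(p[c("s1", "s2", "s3")]),
       converged = isTRUE(fit$convInfo$isConv))
}

.fit_em <- function(hist, init, max_iter) {
  x <- hist$mids
  cnt <- hist$counts
  keep <- cnt > 0
  x <- x[keep]; cnt <- cnt[keep]
  w <- init$weights; m <- init$means; s <- init$sds
  n <- sum(cnt)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    dens <- vapply(1:3, function(q) w[q] * dnorm(x, m[q], s[q]),
                   numeric(length(x)))
    rs <- rowSums(dens)
    rs[rs < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(cnt * log(rs))
    z <- dens / rs
    for (q in 1:3) {
      nq <- sum(cnt * z[, q])
      w[q] <- nq / n
      m[q] <- sum(cnt * z[, q] * x) / nq
      s[q] <- max(sqrt(sum(cnt * z[, q] * (x - m[q])^2) / nq),
                  hist$bin_width / 4)
    }
    if (abs(ll - ll_old) < 1e-10 * (1 + abs(ll))) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }
  list(weights = w, means = m, sds = s, converged = converged)
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat(sprintf("<mixture_fit method=%s converged=%s R2=%.4f>\n",
              x$method, x$converged, x$gof))
  print(x$components)
  if (!is.na(x$normal_index)) {
    cat(sprintf("normal-parenchyma component: %d (%s)\n",
                x$normal_index, x$normal_method))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mixture_fit <- function(x, ...) {
  out <- x$components
  out$is_normal <- if (is.na(x$normal_index)) NA else
    out$component == x$normal_index
  out
}

#' @exportS3Method generics::glance
glance.mixture_fit <- function(x, ...) {
  tibble::tibble(method = x$method, converged = x$converged, gof = x$gof,
                 normal_index = x$normal_index, n_voxels = x$total,
                 bin_width = x$bin_width)
}

#' Identify the normal-parenchyma component of a mixture fit
#'
#' By the ordering assumption blood pool < normal parenchyma < tumour,
#' the automatic rule picks the component with the middle mean; exactly
#' tied means are broken toward the larger weight (with a message). A
#' manual override always wins. The choice and how it was made are
#' recorded on the fit.
#'
#' @param fit a [fit_three_gaussians()] result.
#' @param override optional component index (1-3, in increasing-mean
#'   order) selecting the normal component manually.
#' @return the fit with `normal_index` and `normal_method` set.
#' @export
identify_normal_component <- function(fit, override = NULL) {
  if (!is.null(override)) {
    assert_that(override %in% 1:3,
                "normal-component override must be 1, 2 or 3")
    fit$normal_index <- as.integer(override)
    fit$normal_method <- "override"
    return(fit)
  }
  comp <- fit$components
  mid_mean <- comp$mean[2]
  cand <- which(comp$mean == mid_mean)
  if (length(cand) > 1) {
    message("tied component means; tie broken toward the larger weight")
  }
  pick <- cand[which.max(comp$weight[cand])]
  fit$normal_index <- comp$component[pick]
  fit$normal_method <- "auto (middle mean)"
  fit
}

#' Liver tumour volume from the mixture threshold rule
#'
#' All liver voxels with SUV strictly above the normal-parenchyma mean
#' plus one standard deviation are counted as tumour tissue.
#'
#' @param volume an [suv_volume()].
#' @param fit a [fit_three_gaussians()] result with the normal component
#'   identified (see [identify_normal_component()]).
#' @param mask liver mask (logical array or stored-mask name).
#' @param n_sd number of standard deviations above the normal mean
#'   (default 1, the method's rule).
#' @return a list with `volume_ml`, `threshold`, `mask` (tumour voxels),
#'   `normal_mean`, `normal_sd`.
#' @export
liver_tumour_volume <- function(volume, fit, mask = "liver", n_sd = 1) {
  assert_that(!is.na(fit$normal_index),
              "identify the normal component before computing tumour volume")
  if (is.character(mask)) mask <- volume$masks[[mask]]
  comp <- fit$components
  mu <- comp$mean[comp$component == fit$normal_index]
  sdv <- comp$sd[comp$component == fit$normal_index]
  threshold <- mu + n_sd * sdv
  tumour <- mask & (volume$suv > threshold)
  list(volume_ml = sum(tumour) * voxel_ml(volume$spacing),
       threshold = threshold, mask = tumour,
       normal_mean = mu, normal_sd = sdv)
}
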
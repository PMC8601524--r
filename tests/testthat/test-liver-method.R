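test_that("the liver histogram conserves counts and bins correctly", {
  arr <- array(0.25, dim = c(10, 10, 10))
  mask <- array(FALSE, dim = c(10, 10, 10))
  mask[1:10] <- TRUE
  arr[1:10] <- 2.05
  vol <- suv_volume(arr, c(2, 2, 2), masks = list(liver = mask))
  h <- build_liver_histogram(vol)
  td <- tidy(h)
  expect_equal(sum(h$counts), 10)
  nz <- td[td$count > 0, ]
  expect_equal(nrow(nz), 1)
  expect_true(nz$lower <= 2.05 && 2.05 < nz$upper)
  expect_equal(nz$count, 10)
})

test_that("histogram counts agree with an independent tally", {
  ph <- generate_phantom(phantom_spec(seed = 13))
  h <- build_liver_histogram(ph, bin_width = 0.25)
  v <- ph$suv[ph$masks$liver]
  # literal loop-free tally oracle with explicit half-open intervals
  tally <- vapply(seq_along(h$counts), function(i) {
    sum(v >= h$breaks[i] & v < h$breaks[i + 1])
  }, numeric(1))
  expect_equal(h$counts, as.integer(tally))
  expect_equal(sum(h$counts), sum(ph$masks$liver))
})

test_that("both fit methods recover the generating mixture", {
  ph <- generate_phantom(phantom_spec(seed = 17))
  h <- build_liver_histogram(ph)
  truth_mu <- c(1.5, 5, 15)
  truth_w <- c(0.1, 0.7, 0.2)
  for (method in c("wls", "em")) {
    fit <- fit_three_gaussians(h, method = method)
    expect_true(fit$converged)
    comp <- fit$components
    expect_equal(sum(comp$weight), 1, tolerance = 1e-6)
    expect_true(all(diff(comp$mean) >= 0))
    expect_lt(max(abs(comp$mean - truth_mu) / truth_mu), 0.05)
    expect_lt(max(abs(comp$weight - truth_w)), 0.05)
  }
})

test_that("the fit is deterministic for a fixed histogram and init", {
  ph <- generate_phantom(phantom_spec(seed = 23))
  h <- build_liver_histogram(ph)
  f1 <- fit_three_gaussians(h)
  f2 <- fit_three_gaussians(h)
  expect_identical(f1$components, f2$components)
})

test_that("single-Gaussian data collapse to the normal tail downstream", {
  withr::with_seed(31, {
    arr <- array(abs(rnorm(40^3, 5, 1)), dim = c(40, 40, 40))
  })
  mask <- array(TRUE, dim = c(40, 40, 40))
  vol <- suv_volume(arr, c(2.5, 2.5, 2.5), masks = list(liver = mask))
  h <- build_liver_histogram(vol)
  fit <- identify_normal_component(fit_three_gaussians(h))
  res <- liver_tumour_volume(vol, fit)
  liver_ml <- sum(mask) * prod(vol$spacing) / 1000
  # mass above mu + sd of a single Gaussian is the 15.9% normal tail;
  # allow slack for how the extra components split the density
  expect_lt(abs(res$volume_ml / liver_ml - pnorm(1, lower.tail = FALSE)),
            0.05)
})

test_that("mixture fits degrade gracefully on degenerate histograms", {
  arr <- array(2.05, dim = c(10, 10, 10))
  mask <- array(TRUE, dim = c(10, 10, 10))
  vol <- suv_volume(arr, c(2, 2, 2), masks = list(liver = mask))
  h <- build_liver_histogram(vol)
  expect_error(fit_three_gaussians(h), "3 non-empty bins")
})

test_that("normal-component identification follows mean order and override", {
  ph <- generate_phantom(phantom_spec(seed = 29))
  fit <- fit_three_gaussians(build_liver_histogram(ph))
  auto <- identify_normal_component(fit)
  expect_equal(auto$normal_index, 2L)      # means 1.5 < 5 < 15: middle
  comp <- auto$components
  expect_equal(comp$mean[comp$component == auto$normal_index], 5,
               tolerance = 0.1)
  over <- identify_normal_component(fit, override = 1)
  expect_equal(over$normal_index, 1L)
  expect_equal(over$normal_method, "override")
  expect_error(identify_normal_component(fit, override = 5), "1, 2 or 3")
})

test_that("tied component means break toward the larger weight", {
  fit <- fit_three_gaussians(build_liver_histogram(
    generate_phantom(phantom_spec(seed = 3))))
  fit$components$mean <- c(2, 2, 10)
  fit$components$weight <- c(0.2, 0.6, 0.2)
  # re-sort the way the constructor stores components: mean, then weight
  comp <- fit$components[order(fit$components$mean,
                               -fit$components$weight), ]
  comp$component <- 1:3
  fit$components <- comp
  expect_message(out <- identify_normal_component(fit), "tie")
  picked <- out$components[out$components$component == out$normal_index, ]
  expect_equal(picked$mean, 2)
  expect_equal(picked$weight, 0.6)  # larger weight wins the tie
})

test_that("liver tumour volume applies a strict threshold and is monotone", {
  ph <- generate_phantom(phantom_spec(seed = 37))
  fit <- identify_normal_component(fit_three_gaussians(
    build_liver_histogram(ph)))
  res1 <- liver_tumour_volume(ph, fit, n_sd = 1)
  res2 <- liver_tumour_volume(ph, fit, n_sd = 2)
  expect_lte(res2$volume_ml, res1$volume_ml)
  # strict inequality: voxels exactly at the threshold are excluded
  arr <- array(5, dim = c(10, 10, 10))
  mask <- array(TRUE, dim = c(10, 10, 10))
  vol <- suv_volume(arr, c(2, 2, 2), masks = list(liver = mask))
  fit$components$mean[fit$components$component == fit$normal_index] <- 4
  fit$components$sd[fit$components$component == fit$normal_index] <- 1
  expect_equal(liver_tumour_volume(vol, fit)$volume_ml, 0)
})

test_that("estimated liver tumour volume matches the analytic expectation", {
  ph <- generate_phantom(phantom_spec(seed = 41))
  fit <- identify_normal_component(fit_three_gaussians(
    build_liver_histogram(ph)))
  res <- liver_tumour_volume(ph, fit)
  expected_ml <- mixture_tail_above(ph$truth, res$threshold) *
    ph$truth$liver_ml
  expect_lt(abs(res$volume_ml - expected_ml) / expected_ml, 0.10)
})

test_that("an EM cross-check with mclust agrees on the component means", {
  skip_if_not_installed("mclust")
  withr::local_package("mclust")
  ph <- generate_phantom(phantom_spec(seed = 43))
  fit <- fit_three_gaussians(build_liver_histogram(ph))
  v <- ph$suv[ph$masks$liver]
  withr::with_seed(1, v_sub <- sample(v, 8000))
  mc <- Mclust(v_sub, G = 3, modelNames = "V", verbose = FALSE)
  mc_means <- sort(unname(mc$parameters$mean))
  expect_equal(fit$components$mean, mc_means, tolerance = 0.12)
})
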
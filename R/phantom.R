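#' Specify a synthetic somatostatin-receptor PET phantom
#'
#' A phantom is a 3D SUV grid holding a liver ellipsoid whose voxels are
#' drawn from three Gaussian populations (blood pool, normal parenchyma,
#' tumour), with tumour voxels arranged as spatially coherent blobs, plus
#' optional focal extra-hepatic lesions (plateau uptake on a low
#' background). The defaults give roughly 50,000 liver voxels and the
#' component parameters used throughout the package's examples.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param spacing numeric vector of length 3, voxel spacing in mm.
#' @param liver_center physical liver centre in mm; `NULL` for grid centre.
#' @param liver_semi_axes liver ellipsoid semi-axes in mm.
#' @param weights mixture weights `c(blood, normal, tumour)`; must sum to 1.
#' @param means component SUV means, strictly increasing
#'   (blood < normal < tumour).
#' @param sds component SUV standard deviations, all positive.
#' @param n_blobs number of tumour blobs carved inside the liver.
#' @param blob_radii blob radii in mm, or `NULL` to size `n_blobs` blobs
#'   (fixed relative sizes) so that their total volume equals the tumour
#'   weight times the liver volume — the setting under which the empirical
#'   liver histogram converges to the specified mixture.
#' @param lesions list of extra-hepatic lesions, each a list with `center`
#'   (mm), `semi_axes` (mm), `suv` (plateau SUV) and `label`
#'   (`"bone"` or `"soft tissue"`).
#' @param background background SUV level outside liver and lesions.
#' @param background_noise_sd Gaussian noise SD added to background and
#'   lesion plateaus.
#' @param seed integer seed; all randomness in [generate_phantom()] flows
#'   from it.
#' @return an object of class `phantom_spec` (a validated list).
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L),
                         spacing = c(2.5, 2.5, 2.5),
                         liver_center = NULL,
                         liver_semi_axes = c(72, 55, 47),
                         weights = c(blood = 0.1, normal = 0.7, tumour = 0.2),
                         means = c(1.5, 5, 15),
                         sds = c(0.4, 1, 4),
                         n_blobs = 5L,
                         blob_radii = NULL,
                         lesions = default_phantom_lesions(),
                         background = 0.5,
                         background_noise_sd = 0.05,
                         seed = 1L) {
  shape <- as.integer(shape)
  if (is.null(liver_center)) liver_center <- (shape - 1) * spacing / 2
  spec <- structure(
    list(
      shape = shape, spacing = as.numeric(spacing),
      liver_center = as.numeric(liver_center),
      liver_semi_axes = as.numeric(liver_semi_axes),
      weights = unname(as.numeric(weights)), means = as.numeric(means),
      sds = as.numeric(sds), n_blobs = as.integer(n_blobs),
      blob_radii = blob_radii, lesions = lesions,
      background = background, background_noise_sd = background_noise_sd,
      seed = as.integer(seed)
    ),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

default_phantom_lesions <- function() {
  list(
    list(center = c(22, 130, 125), semi_axes = c(9, 9, 9), suv = 12,
         label = "bone"),
    list(center = c(130, 25, 120), semi_axes = c(12, 10, 11), suv = 10,
         label = "soft tissue")
  )
}

validate_phantom_spec <- function(spec) {
  assert_that(length(spec$shape) == 3 && all(spec$shape >= 1),
              "phantom shape must be three positive integers")
  assert_that(all(spec$spacing > 0), "voxel spacing must be positive")
  assert_that(length(spec$weights) == 3 &&
                abs(sum(spec$weights) - 1) < 1e-8 &&
                all(spec$weights >= 0),
              "mixture weights must be three non-negatives summing to 1")
  assert_that(all(diff(spec$means) > 0),
              "component means must be strictly increasing (blood < normal < tumour)")
  assert_that(all(spec$sds > 0), "component SDs must be positive")
  assert_that(all(spec$means >= 0) && spec$background >= 0,
              "SUV levels must be non-negative")
  assert_that(all(spec$liver_semi_axes > 0), "liver semi-axes must be positive")
  for (les in spec$lesions) {
    assert_that(all(c("center", "semi_axes", "suv") %in% names(les)),
                "each lesion needs center, semi_axes and suv")
    assert_that(les$suv >= 0 && all(les$semi_axes > 0),
                "lesion SUV must be >= 0 and semi-axes positive")
  }
  invisible(spec)
}

#' Construct an SUV volume object
#'
#' The imaging substrate used by the segmentation functions: a 3D grid of
#' SUV values, its voxel spacing (mm), and named voxel masks. Voxel
#' `(i, j, k)` (1-based) has its physical centre at
#' `(i - 1, j - 1, k - 1) * spacing` mm; volumes in mL are voxel counts
#' times `prod(spacing) / 1000`.
#'
#' @param suv 3D numeric array of SUV values (all `>= 0`).
#' @param spacing voxel spacing in mm, length 3.
#' @param masks named list of logical arrays with the same dimensions.
#' @param truth optional list of generating-truth metadata.
#' @return an object of class `suv_volume`.
#' @export
suv_volume <- function(suv, spacing, masks = list(), truth = NULL) {
  assert_that(length(dim(suv)) == 3, "suv must be a 3D array")
  assert_that(all(suv >= 0), "SUV values must be non-negative")
  assert_that(length(spacing) == 3 && all(spacing > 0),
              "spacing must be three positive numbers")
  for (nm in names(masks)) {
    assert_that(identical(dim(masks[[nm]]), dim(suv)),
                sprintf("mask '%s' does not match the grid", nm))
  }
  structure(list(suv = suv, spacing = as.numeric(spacing), masks = masks,
                 truth = truth),
            class = "suv_volume")
}

#' @export
print.suv_volume <- function(x, ...) {
  cat(sprintf("<suv_volume> %s voxels @ %s mm\n",
              paste(dim(x$suv), collapse = "x"),
              paste(format(x$spacing), collapse = "x")))
  for (nm in names(x$masks)) {
    cat(sprintf("  mask %-14s %d voxels (%.1f mL)\n", nm,
                sum(x$masks[[nm]]), sum(x$masks[[nm]]) * voxel_ml(x$spacing)))
  }
  invisible(x)
}

# physical voxel-centre coordinate arrays for a grid
.coord_arrays <- function(shape, spacing) {
  x <- (seq_len(shape[1]) - 1) * spacing[1]
  y <- (seq_len(shape[2]) - 1) * spacing[2]
  z <- (seq_len(shape[3]) - 1) * spacing[3]
  list(
    X = array(rep(x, times = shape[2] * shape[3]), dim = shape),
    Y = array(rep(rep(y, each = shape[1]), times = shape[3]), dim = shape),
    Z = array(rep(z, each = shape[1] * shape[2]), dim = shape)
  )
}

.ellipsoid_mask <- function(co, center, semi) {
  ((co$X - center[1]) / semi[1])^2 +
    ((co$Y - center[2]) / semi[2])^2 +
    ((co$Z - center[3]) / semi[3])^2 <= 1
}

#' Generate a synthetic PET phantom
#'
#' Draws the phantom described by a [phantom_spec()]: liver voxels inside
#' the tumour blobs sample from the tumour component; the remaining liver
#' voxels sample from the blood-pool or normal-parenchyma component with
#' probability proportional to their weights; extra-hepatic lesions get
#' their plateau SUV plus noise; everything else is background plus noise.
#' Negative draws are clamped at 0 (negligible mass for physiological
#' parameters). The same spec and seed reproduce the volume bit for bit.
#'
#' @param spec a [phantom_spec()].
#' @return an [suv_volume()] with masks `liver`, `tumour` (generating
#'   truth) and `lesion_<k>`, and a `truth` list holding the component
#'   parameters, blob geometry and true volumes in mL.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  shape <- spec$shape
  co <- .coord_arrays(shape, spec$spacing)
  liver <- .ellipsoid_mask(co, spec$liver_center, spec$liver_semi_axes)
  n_liver <- sum(liver)
  assert_that(n_liver > 0, "liver ellipsoid contains no voxels")

  w <- spec$weights
  radii <- spec$blob_radii
  if (is.null(radii) && w[3] > 0) {
    rel <- seq(1.3, 0.5, length.out = spec$n_blobs)
    target <- w[3] * n_liver * prod(spec$spacing)     # mm^3
    radii <- rel * (target / sum(4 / 3 * pi * rel^3))^(1 / 3)
  }
  if (w[3] == 0) radii <- numeric(0)

  withr::with_seed(spec$seed, {
    # place non-overlapping spherical blobs fully inside the liver ellipsoid
    centers <- matrix(numeric(0), ncol = 3)
    for (k in seq_along(radii)) {
      r <- radii[k]
      shrunk <- spec$liver_semi_axes - r
      if (any(shrunk <= 0)) {
        abort(sprintf(
          "tumour blob %d (radius %.1f mm) cannot fit inside the liver ellipsoid",
          k, r))
      }
      placed <- FALSE
      for (try in seq_len(1000)) {
        u <- runif(3, -1, 1)
        if (sum(u^2) > 1) next
        cand <- spec$liver_center + u * shrunk
        if (nrow(centers) > 0) {
          d <- sqrt(rowSums((centers - matrix(cand, nrow(centers), 3,
                                              byrow = TRUE))^2))
          if (any(d <= radii[seq_len(k - 1)] + r)) next
        }
        centers <- rbind(centers, cand)
        placed <- TRUE
        break
      }
      if (!placed) {
        abort(sprintf("could not place tumour blob %d without overlap", k))
      }
    }

    tumour <- array(FALSE, dim = shape)
    for (k in seq_along(radii)) {
      d2 <- (co$X - centers[k, 1])^2 + (co$Y - centers[k, 2])^2 +
        (co$Z - centers[k, 3])^2
      tumour <- tumour | (d2 <= radii[k]^2)
    }
    tumour <- tumour & liver

    vol <- array(rnorm(prod(shape), spec$background,
                       spec$background_noise_sd), dim = shape)
    lesion_masks <- list()
    lesion_truth <- list()
    for (k in seq_along(spec$lesions)) {
      les <- spec$lesions[[k]]
      m <- .ellipsoid_mask(co, les$center, les$semi_axes)
      vol[m] <- rnorm(sum(m), les$suv, spec$background_noise_sd)
      lesion_masks[[paste0("lesion_", k)]] <- m
      lesion_truth[[k]] <- list(
        label = les$label %||% "soft tissue",
        plateau_suv = les$suv,
        analytic_ml = 4 / 3 * pi * prod(les$semi_axes) / 1000,
        voxel_ml = sum(m) * voxel_ml(spec$spacing)
      )
    }

    nontum <- liver & !tumour
    n_nt <- sum(nontum)
    p_blood <- if (w[1] + w[2] > 0) w[1] / (w[1] + w[2]) else 0
    is_blood <- runif(n_nt) < p_blood
    v_nt <- numeric(n_nt)
    v_nt[is_blood] <- rnorm(sum(is_blood), spec$means[1], spec$sds[1])
    v_nt[!is_blood] <- rnorm(sum(!is_blood), spec$means[2], spec$sds[2])
    vol[nontum] <- v_nt
    vol[tumour] <- rnorm(sum(tumour), spec$means[3], spec$sds[3])
    vol <- pmax(vol, 0)
  })

  masks <- c(list(liver = liver, tumour = tumour), lesion_masks)
  truth <- list(
    weights = w, means = spec$means, sds = spec$sds,
    liver_ml = n_liver * voxel_ml(spec$spacing),
    tumour_ml = sum(tumour) * voxel_ml(spec$spacing),
    tumour_fraction = sum(tumour) / n_liver,
    blob_centers = centers, blob_radii = radii,
    lesions = lesion_truth, seed = spec$seed
  )
  suv_volume(vol, spec$spacing, masks, truth)
}

#' Write and read phantom volumes as NIfTI
#'
#' The SUV grid and each mask are written as separate uncompressed `.nii`
#' files with the voxel spacing in the header; the generating truth (when
#' present) as JSON.
#'
#' @param volume an [suv_volume()].
#' @param dir output directory (created if needed).
#' @return `write_phantom()` invisibly returns the written paths;
#'   `read_suv_volume()` returns an [suv_volume()].
#' @export
write_phantom <- function(volume, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  img <- RNifti::asNifti(volume$suv)
  RNifti::pixdim(img) <- volume$spacing
  p <- file.path(dir, "suv.nii")
  RNifti::writeNifti(img, p)
  paths <- c(suv = p)
  for (nm in names(volume$masks)) {
    m <- RNifti::asNifti(array(as.integer(volume$masks[[nm]]),
                               dim = dim(volume$suv)))
    RNifti::pixdim(m) <- volume$spacing
    p <- file.path(dir, paste0("mask_", nm, ".nii"))
    RNifti::writeNifti(m, p)
    paths[paste0("mask_", nm)] <- p
  }
  if (!is.null(volume$truth)) {
    p <- file.path(dir, "truth.json")
    tr <- volume$truth
    if (is.matrix(tr$blob_centers)) {
      tr$blob_centers <- apply(tr$blob_centers, 1, identity, simplify = FALSE)
    }
    jsonlite::write_json(tr, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    paths["truth"] <- p
  }
  invisible(paths)
}

#' @rdname write_phantom
#' @param suv_path path to the SUV `.nii` file.
#' @param mask_paths named character vector of mask `.nii` paths.
#' @export
read_suv_volume <- function(suv_path, mask_paths = character(0)) {
  img <- RNifti::readNifti(suv_path)
  spacing <- RNifti::pixdim(img)[1:3]
  masks <- lapply(mask_paths, function(p) {
    array(as.logical(RNifti::readNifti(p) > 0.5), dim = dim(img))
  })
  suv_volume(array(as.numeric(img), dim = dim(img)), spacing, masks)
}

#' @exportS3Method generics::glance
glance.suv_volume <- function(x, ...) {
  tibble::tibble(
    nx = dim(x$suv)[1], ny = dim(x$suv)[2], nz = dim(x$suv)[3],
    spacing_x = x$spacing[1], spacing_y = x$spacing[2],
    spacing_z = x$spacing[3],
    n_masks = length(x$masks),
    liver_ml = if ("liver" %in% names(x$masks))
      sum(x$masks$liver) * voxel_ml(x$spacing) else NA_real_
  )
}
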
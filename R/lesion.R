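#' Segment a lesion at 40% of its SUVpeak
#'
#' Lesion-wise fixed-threshold segmentation: the threshold is
#' `threshold_frac` times the lesion's SUVpeak (1-mL sphere, see
#' [compute_suvpeak()]), and the segment is the connected component of
#' voxels at or above the threshold that contains the peak-sphere centre
#' (26-neighbour connectivity by default). The volume is the member
#' count times the voxel volume. Because SUVpeak is a sphere mean, the
#' peak-centre voxel itself can fall below a high threshold; the
#' segment is then empty (volume 0), keeping volume monotone in
#' `threshold_frac`.
#'
#' @inheritParams compute_suvpeak
#' @param threshold_frac fraction of SUVpeak used as threshold
#'   (default 0.40).
#' @param connectivity 26 (faces, edges, corners) or 6 (faces only).
#' @param id optional lesion identifier carried into the result.
#' @return an object of class `lesion_segment`: `id`, `suvpeak`,
#'   `threshold`, `peak_center`, `mask` (logical array), `n_voxels`,
#'   `volume_ml`, `connectivity`, `small_region`.
#' @export
segment_lesion_40pct <- function(volume, region, threshold_frac = 0.4,
                                 connectivity = 26, id = NULL) {
  assert_that(connectivity %in% c(6, 26), "connectivity must be 6 or 26")
  assert_that(threshold_frac > 0 && threshold_frac <= 1,
              "threshold fraction must lie in (0, 1]")
  peak <- compute_suvpeak(volume, region)
  threshold <- threshold_frac * peak$suvpeak
  above <- volume$suv >= threshold
  if (!any(above)) {
    abort("no voxel reaches the threshold; the lesion region must be empty")
  }
  ctr <- peak$center
  # the sphere mean can exceed the centre voxel's own value; when the
  # centre falls below the threshold its component is empty
  mask <- if (above[ctr[1], ctr[2], ctr[3]]) {
    .connected_component(above, ctr, connectivity)
  } else {
    array(FALSE, dim = dim(volume$suv))
  }
  structure(
    list(id = id %||% "lesion", suvpeak = peak$suvpeak,
         threshold = threshold, peak_center = ctr, mask = mask,
         n_voxels = sum(mask),
         volume_ml = sum(mask) * voxel_ml(volume$spacing),
         connectivity = connectivity, small_region = peak$small_region),
    class = "lesion_segment"
  )
}

# connected component of TRUE voxels containing `center`, by frontier growth
.connected_component <- function(above, center, connectivity) {
  shape <- dim(above)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  if (connectivity == 6) offs <- offs[rowSums(abs(offs)) == 1, , drop = FALSE]
  nx <- shape[1]; nxy <- shape[1] * shape[2]
  visited <- array(FALSE, dim = shape)
  lin0 <- center[1] + (center[2] - 1) * nx + (center[3] - 1) * nxy
  visited[lin0] <- TRUE
  frontier <- matrix(as.integer(center), 1, 3)
  K <- nrow(offs)
  while (nrow(frontier) > 0) {
    nb <- frontier[rep(seq_len(nrow(frontier)), each = K), , drop = FALSE] +
      offs[rep(seq_len(K), times = nrow(frontier)), , drop = FALSE]
    ok <- nb[, 1] >= 1 & nb[, 1] <= shape[1] &
      nb[, 2] >= 1 & nb[, 2] <= shape[2] &
      nb[, 3] >= 1 & nb[, 3] <= shape[3]
    nb <- nb[ok, , drop = FALSE]
    lin <- nb[, 1] + (nb[, 2] - 1) * nx + (nb[, 3] - 1) * nxy
    keep <- !duplicated(lin) & above[lin] & !visited[lin]
    lin <- lin[keep]
    visited[lin] <- TRUE
    frontier <- nb[keep, , drop = FALSE]
  }
  visited
}

#' @export
print.lesion_segment <- function(x, ...) {
  cat(sprintf(
    "<lesion_segment '%s'> SUVpeak %.2f, threshold %.2f, %d voxels (%.2f mL)%s\n",
    x$id, x$suvpeak, x$threshold, x$n_voxels, x$volume_ml,
    if (x$small_region) " [region smaller than 1 mL sphere]" else ""))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.lesion_segment <- function(x, ...) {
  tibble::tibble(
    id = x$id, suvpeak = x$suvpeak, threshold = x$threshold,
    n_voxels = x$n_voxels, volume_ml = x$volume_ml,
    connectivity = x$connectivity, small_region = x$small_region
  )
}

#' Compile a per-compartment tumour-volume report
#'
#' Sums lesion volumes into bone and soft-tissue compartments, adds the
#' liver tumour volume, and reports the total tumour load as their sum.
#'
#' @param liver_ml liver tumour volume in mL.
#' @param lesions a list of [segment_lesion_40pct()] results, or a
#'   numeric vector of lesion volumes in mL.
#' @param labels compartment label per lesion: `"bone"` or
#'   `"soft tissue"`.
#' @return a one-row tibble: `bone_ml`, `soft_tissue_ml`, `liver_ml`,
#'   `total_ml`.
#' @export
compile_volume_report <- function(liver_ml, lesions = list(),
                                  labels = character(0)) {
  vols <- if (is.numeric(lesions)) lesions else
    vapply(lesions, function(l) l$volume_ml, numeric(1))
  assert_that(length(vols) == length(labels),
              "one compartment label per lesion is required")
  bad <- setdiff(unique(labels), c("bone", "soft tissue"))
  if (length(bad) > 0) {
    abort(sprintf("unknown compartment label(s): %s",
                  paste(bad, collapse = ", ")))
  }
  assert_that(liver_ml >= 0 && all(vols >= 0), "volumes must be non-negative")
  tibble::tibble(
    bone_ml = sum(vols[labels == "bone"]),
    soft_tissue_ml = sum(vols[labels == "soft tissue"]),
    liver_ml = liver_ml,
    total_ml = sum(vols) + liver_ml
  )
}
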
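#' SUVpeak: the 1-mL sphere with the highest mean uptake
#'
#' Computes the SUVpeak of a lesion: the maximum, over candidate sphere
#' centres, of the mean SUV over all grid voxels whose centres lie within
#' the radius of a 1-mL sphere (`(4/3) pi r^3 = 1000` mm^3, so
#' `r ~ 6.2` mm) of the candidate centre. Candidate centres are the voxel
#' centres inside `region`; ties are broken toward the lexicographically
#' smallest voxel coordinate. If the region itself is smaller than one
#' sphere the mean is still taken over the full sphere (which then
#' extends beyond the region) and the result is flagged.
#'
#' @param volume an [suv_volume()].
#' @param region the lesion region: a logical array matching the grid or
#'   an n x 3 matrix of 1-based voxel indices.
#' @param sphere_ml sphere volume in mL (default 1).
#' @return a list with `suvpeak`, `center` (1-based voxel index of the
#'   best sphere centre), `radius_mm`, and `small_region` (TRUE when the
#'   region holds less than one sphere volume).
#' @export
compute_suvpeak <- function(volume, region, sphere_ml = 1) {
  idx <- .region_indices(volume, region)
  assert_that(nrow(idx) > 0, "lesion region is empty")
  r <- (3 * sphere_ml * 1000 / (4 * pi))^(1 / 3)
  shape <- dim(volume$suv)
  assert_that(all(shape * volume$spacing >= 2 * r),
              "grid is too small to hold a 1 mL sphere")

  offs <- .sphere_offsets(volume$spacing, r)
  nx <- shape[1]; nxy <- shape[1] * shape[2]
  # candidates in lexicographic (i, j, k) order so which.max() applies the
  # smallest-coordinate tie-break
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]

  means <- vapply(seq_len(nrow(idx)), function(q) {
    ni <- idx[q, 1] + offs[, 1]
    nj <- idx[q, 2] + offs[, 2]
    nk <- idx[q, 3] + offs[, 3]
    ok <- ni >= 1 & ni <= shape[1] & nj >= 1 & nj <= shape[2] &
      nk >= 1 & nk <= shape[3]
    lin <- sort(ni[ok] + (nj[ok] - 1) * nx + (nk[ok] - 1) * nxy)
    mean(volume$suv[lin])
  }, numeric(1))

  best <- which.max(means)
  list(
    suvpeak = means[best],
    center = idx[best, ],
    radius_mm = r,
    small_region = nrow(idx) * voxel_ml(volume$spacing) < sphere_ml
  )
}

# integer voxel offsets whose physical displacement is within radius r
.sphere_offsets <- function(spacing, r) {
  rng <- lapply(spacing, function(s) seq(-floor(r / s), floor(r / s)))
  g <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
  d2 <- (g[, 1] * spacing[1])^2 + (g[, 2] * spacing[2])^2 +
    (g[, 3] * spacing[3])^2
  g[d2 <= r^2, , drop = FALSE]
}

.region_indices <- function(volume, region) {
  if (is.logical(region)) {
    assert_that(identical(dim(region), dim(volume$suv)),
                "region mask does not match the grid")
    which(region, arr.ind = TRUE)
  } else if (is.character(region) && length(region) == 1) {
    assert_that(region %in% names(volume$masks),
                sprintf("volume has no mask named '%s'", region))
    which(volume$masks[[region]], arr.ind = TRUE)
  } else {
    m <- as.matrix(region)
    assert_that(ncol(m) == 3, "region indices must be an n x 3 matrix")
    storage.mode(m) <- "integer"
    m
  }
}
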
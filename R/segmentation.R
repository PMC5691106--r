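# Semi-automatic VOI delineation: manual 3D box, fixed-fraction threshold
# at a percentage of the box SUVmax, necrosis accounting, hottest-lesion
# selection. PET-1 and PET-2 are segmented independently, each against its
# own SUVmax.

#' Manual 3D bounding box
#'
#' Half-open, 0-based voxel index ranges `[x0, x1) x [y0, y1) x [z0, z1)`
#' locating the lesion; the fixed-fraction threshold is taken relative to
#' the maximum SUV inside this box.
#'
#' @param x0,x1,y0,y1,z0,z1 Integer index bounds, half-open, 0-based.
#' @return An object of class `bounding_box`.
#' @export
bounding_box <- function(x0, x1, y0, y1, z0, z1) {
  b <- as.integer(c(x0, x1, y0, y1, z0, z1))
  if (any(is.na(b)) || b[2L] <= b[1L] || b[4L] <= b[3L] || b[6L] <= b[5L])
    stop("bounding box must be nonempty (x1 > x0, y1 > y0, z1 > z0)",
         call. = FALSE)
  if (any(b[c(1L, 3L, 5L)] < 0L))
    stop("bounding box indices must be >= 0", call. = FALSE)
  structure(list(x0 = b[1L], x1 = b[2L], y0 = b[3L], y1 = b[4L],
                 z0 = b[5L], z1 = b[6L]),
            class = "bounding_box")
}

# R 1-based index ranges of a box, checked against the volume shape.
box_ranges <- function(box, dm) {
  stopifnot(inherits(box, "bounding_box"))
  if (box$x1 > dm[1L] || box$y1 > dm[2L] || box$z1 > dm[3L])
    stop("bounding box exceeds volume shape", call. = FALSE)
  list(x = (box$x0 + 1L):box$x1,
       y = (box$y0 + 1L):box$y1,
       z = (box$z0 + 1L):box$z1)
}

new_tumor_mask <- function(mask, box, fraction, threshold,
                           necrotic_voxels = NA_integer_) {
  structure(list(mask = mask, box = box, fraction = fraction,
                 threshold = threshold, necrotic_voxels = necrotic_voxels),
            class = "tumor_mask")
}

#' @export
print.tumor_mask <- function(x, ...) {
  cat("Tumor mask:", sum(x$mask), "voxels at threshold",
      signif(x$threshold, 4), sprintf("(%.0f%% of box SUVmax)",
                                      100 * x$fraction), "\n")
  if (!is.na(x$necrotic_voxels))
    cat("  enclosed necrotic voxels:", x$necrotic_voxels, "\n")
  invisible(x)
}

#' Fixed-fraction SUVmax threshold segmentation
#'
#' Selects every voxel in the box whose SUV is equal to or above
#' `fraction` times the maximum SUV in the box (inclusive comparison). The
#' default 40% fraction is the standard fixed-threshold delineation for
#' FDG-avid lesions. The returned mask lives on the full volume grid and
#' records its provenance (box, fraction, absolute threshold).
#'
#' @param volume A [pet_volume()].
#' @param box A [bounding_box()] inside the volume.
#' @param fraction Threshold fraction in (0, 1); default 0.40.
#' @return A `tumor_mask` object with fields `mask` (logical array
#'   congruent with the volume), `box`, `fraction`, `threshold`.
#' @export
threshold_voi <- function(volume, box, fraction = 0.40) {
  stopifnot(inherits(volume, "pet_volume"))
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must lie in (0, 1)", call. = FALSE)
  r <- box_ranges(box, dim(volume$suv))
  sub <- volume$suv[r$x, r$y, r$z, drop = FALSE]
  mx <- max(sub)
  if (mx <= 0)
    stop("empty segmentation: box contains no positive uptake", call. = FALSE)
  thr <- fraction * mx
  mask <- array(FALSE, dim = dim(volume$suv))
  mask[r$x, r$y, r$z] <- sub >= thr
  new_tumor_mask(mask, box, fraction, thr)
}

#' Account for an enclosed necrotic core
#'
#' Central hypometabolism — sub-threshold voxels inside the box that are
#' completely enclosed by the thresholded lesion (reachable from no box
#' face) — is treated as necrosis: it stays excluded from the VOI (no hole
#' filling is applied) and its voxel count is recorded in the mask's
#' provenance. Sub-threshold regions open to a box face are background,
#' not necrosis. Connectivity is 26-neighbour, matching the rest of the
#' pipeline.
#'
#' @param mask A `tumor_mask` from [threshold_voi()].
#' @param volume The [pet_volume()] the mask was computed on.
#' @return The same mask with `necrotic_voxels` filled in.
#' @export
exclude_necrotic_core <- function(mask, volume) {
  stopifnot(inherits(mask, "tumor_mask"), inherits(volume, "pet_volume"))
  r <- box_ranges(mask$box, dim(volume$suv))
  inmask <- mask$mask[r$x, r$y, r$z, drop = FALSE]
  cold <- !inmask                       # sub-threshold voxels in the box
  lab <- label_components26(cold)
  dm <- dim(cold)
  if (max(lab) == 0L) {
    mask$necrotic_voxels <- 0L
    return(mask)
  }
  face <- array(FALSE, dim = dm)
  face[c(1L, dm[1L]), , ] <- TRUE
  face[, c(1L, dm[2L]), ] <- TRUE
  face[, , c(1L, dm[3L])] <- TRUE
  open_ids <- unique(lab[face & cold])
  necrotic <- cold & !(lab %in% open_ids)
  mask$necrotic_voxels <- sum(necrotic)
  mask
}

#' Keep the hottest lesion
#'
#' With multifocal disease the threshold mask can contain several
#' 26-connected components; the component containing the voxel of highest
#' SUV is kept for analysis. Ties on the maximum are broken toward the
#' larger component, then the lowest linear index — deterministic on any
#' input.
#'
#' @param mask A `tumor_mask`.
#' @param volume The [pet_volume()] the mask was computed on.
#' @return The mask restricted to the selected component.
#' @export
pick_hottest_component <- function(mask, volume) {
  stopifnot(inherits(mask, "tumor_mask"), inherits(volume, "pet_volume"))
  if (!any(mask$mask)) stop("empty mask", call. = FALSE)
  # label on the mask's bounding region; connectivity is unaffected
  w <- which(mask$mask, arr.ind = TRUE)
  xs <- min(w[, 1L]):max(w[, 1L])
  ys <- min(w[, 2L]):max(w[, 2L])
  zs <- min(w[, 3L]):max(w[, 3L])
  sub <- mask$mask[xs, ys, zs, drop = FALSE]
  lab <- label_components26(sub)
  k <- max(lab)
  if (k == 1L) return(mask)
  suv <- volume$suv[xs, ys, zs, drop = FALSE]
  vox <- which(sub)
  comp <- lab[vox]
  maxima <- vapply(seq_len(k), function(i) max(suv[vox[comp == i]]),
                   numeric(1L))
  sizes <- tabulate(comp, nbins = k)
  firsts <- vapply(seq_len(k), function(i) min(vox[comp == i]), numeric(1L))
  best <- order(-maxima, -sizes, firsts)[1L]
  keep <- array(FALSE, dim = dim(mask$mask))
  keep[xs, ys, zs] <- lab == best
  mask$mask <- keep
  mask
}
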
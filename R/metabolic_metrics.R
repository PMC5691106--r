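# The five SUV/volume variables: SUVmax, SUVmean, SUVpeak, MTV, TLG.

#' Maximum and mean SUV over the VOI
#'
#' @param volume A [pet_volume()].
#' @param mask A `tumor_mask`.
#' @return Named numeric vector `c(suv_max, suv_mean)`.
#' @export
suv_stats <- function(volume, mask) {
  stopifnot(inherits(volume, "pet_volume"), inherits(mask, "tumor_mask"))
  v <- volume$suv[mask$mask]
  if (length(v) == 0L) stop("empty mask", call. = FALSE)
  c(suv_max = max(v), suv_mean = mean(v))
}

#' Peak SUV
#'
#' The maximum, over 3x3x3-voxel cubes centred on VOI voxels, of the mean
#' SUV within the cube. By default the cube uses every image voxel it
#' covers (the physical neighbourhood), truncated at the image boundary;
#' with `masked_only = TRUE` only in-VOI voxels contribute to the cube
#' mean.
#'
#' @param volume A [pet_volume()].
#' @param mask A `tumor_mask`.
#' @param masked_only Restrict cube means to masked voxels. Default FALSE.
#' @return SUVpeak, a scalar.
#' @export
suv_peak <- function(volume, mask, masked_only = FALSE) {
  stopifnot(inherits(volume, "pet_volume"), inherits(mask, "tumor_mask"))
  if (!any(mask$mask)) stop("empty mask", call. = FALSE)
  u <- volume$suv
  msk <- mask$mask
  # cube radius is 1 voxel, so computing on the mask's bounding region
  # expanded by one voxel (clipped to the image) is exact
  dmf <- dim(u)
  w <- which(msk, arr.ind = TRUE)
  xs <- max(1L, min(w[, 1L]) - 1L):min(dmf[1L], max(w[, 1L]) + 1L)
  ys <- max(1L, min(w[, 2L]) - 1L):min(dmf[2L], max(w[, 2L]) + 1L)
  zs <- max(1L, min(w[, 3L]) - 1L):min(dmf[3L], max(w[, 3L]) + 1L)
  # interior crop faces are not image boundaries: cubes there still see
  # all their voxels because the crop includes the 1-voxel margin
  u <- u[xs, ys, zs, drop = FALSE]
  msk <- msk[xs, ys, zs, drop = FALSE]
  dm <- dim(u)
  include <- if (masked_only) msk else array(TRUE, dim = dm)
  acc <- array(0, dim = dm)     # sum over the 27-cube of included voxels
  cnt <- array(0L, dim = dm)    # number of included voxels in the cube
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    sx <- max(1L, 1L - dx):min(dm[1L], dm[1L] - dx)
    sy <- max(1L, 1L - dy):min(dm[2L], dm[2L] - dy)
    sz <- max(1L, 1L - dz):min(dm[3L], dm[3L] - dz)
    inc <- include[sx + dx, sy + dy, sz + dz, drop = FALSE]
    acc[sx, sy, sz] <- acc[sx, sy, sz] +
      u[sx + dx, sy + dy, sz + dz, drop = FALSE] * inc
    cnt[sx, sy, sz] <- cnt[sx, sy, sz] + inc
  }
  centers <- which(msk & cnt > 0L)
  max(acc[centers] / cnt[centers])
}

#' Metabolic tumor volume
#'
#' Physical volume of the segmented VOI: voxel count times voxel volume,
#' reported in cm^3 (the scale of the usual <=10 / >10 cm^3
#' stratification).
#'
#' @param mask A `tumor_mask`.
#' @param spacing Voxel spacing `(dx, dy, dz)` in mm.
#' @return MTV in cm^3.
#' @export
mtv <- function(mask, spacing) {
  stopifnot(inherits(mask, "tumor_mask"))
  n <- sum(mask$mask)
  if (n == 0L) stop("empty mask has no volume", call. = FALSE)
  n * prod(spacing) / 1000
}

#' Total lesion glycolysis
#'
#' TLG = SUVmean x MTV.
#'
#' @param suv_mean Mean SUV over the VOI.
#' @param mtv_cm3 MTV in cm^3.
#' @return TLG in SUV * cm^3.
#' @export
tlg <- function(suv_mean, mtv_cm3) suv_mean * mtv_cm3

#' All five SUV/volume metrics for one scan
#'
#' @param volume A [pet_volume()].
#' @param mask A `tumor_mask`.
#' @param peak_masked_only Passed to [suv_peak()].
#' @return Named numeric vector `suv_max`, `suv_mean`, `suv_peak`,
#'   `mtv_cm3`, `tlg`.
#' @export
metabolic_metrics <- function(volume, mask, peak_masked_only = FALSE) {
  s <- suv_stats(volume, mask)
  m <- mtv(mask, volume$spacing)
  c(s, suv_peak = suv_peak(volume, mask, masked_only = peak_masked_only),
    mtv_cm3 = m, tlg = tlg(s[["suv_mean"]], m))
}
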
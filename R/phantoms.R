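# Synthetic paired dual-time-point PET tumor phantoms.
#
# Each phantom is an ellipsoidal lesion on a flat background: a smooth
# radial uptake profile modulated by a smoothed Gaussian random texture
# field (heterogeneity that survives PET-like resolution), optional
# enclosed necrotic core, additive acquisition noise. The delayed
# acquisition (PET-2) raises lesion uptake by a multiplicative gain and
# sharpens the profile with a contrast exponent, so that SUV-based
# metrics rise while the fixed-fraction threshold volume shrinks — the
# two knobs reproduce the characteristic dual-time-point dynamics.

#' Phantom specification
#'
#' @param grid_shape Volume shape in voxels, default `c(128, 128, 32)`
#'   (128 x 128 acquisition matrix).
#' @param spacing Voxel spacing in mm, default `c(5.47, 5.47, 3.27)`.
#' @param lesion_axes Ellipsoid diameters in mm, each at least 20 mm
#'   (lesions of at least 2 cm).
#' @param base_uptake Lesion peak uptake above background, SUV.
#' @param background_uptake Background uptake, SUV.
#' @param texture_amplitude Relative amplitude of the multiplicative
#'   texture field (0 = homogeneous lesion).
#' @param correlation_length Texture correlation length in mm.
#' @param necrotic_radius Radius (mm) of a central sub-threshold core;
#'   0 = none.
#' @param pet2_gain Multiplicative lesion uptake gain at PET-2 (> 0;
#'   > 1 models continued FDG accumulation).
#' @param pet2_contrast Exponent (> 0) sharpening the PET-2 uptake
#'   profile; > 1 shrinks the fixed-fraction threshold volume.
#' @param noise_sd Additive acquisition noise SD, SUV.
#' @param seed Integer seed; generation is fully reproducible given the
#'   spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(128, 128, 32),
                         spacing = c(5.47, 5.47, 3.27),
                         lesion_axes = c(30, 30, 30),
                         base_uptake = 8,
                         background_uptake = 1,
                         texture_amplitude = 0.2,
                         correlation_length = 8,
                         necrotic_radius = 0,
                         pet2_gain = 1.18,
                         pet2_contrast = 1.06,
                         noise_sd = 0.1,
                         seed = 1L) {
  if (any(lesion_axes < 20))
    stop("lesion axes must each be at least 20 mm", call. = FALSE)
  if (pet2_gain <= 0 || pet2_contrast <= 0)
    stop("pet2_gain and pet2_contrast must be positive", call. = FALSE)
  if (any(lesion_axes / 2 + 2 * spacing > grid_shape * spacing / 2))
    stop("lesion does not fit in the grid", call. = FALSE)
  structure(list(grid_shape = as.integer(grid_shape), spacing = spacing,
                 lesion_axes = lesion_axes, base_uptake = base_uptake,
                 background_uptake = background_uptake,
                 texture_amplitude = texture_amplitude,
                 correlation_length = correlation_length,
                 necrotic_radius = necrotic_radius,
                 pet2_gain = pet2_gain, pet2_contrast = pet2_contrast,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_spec")
}

# Separable Gaussian smoothing of a small 3D array, edge-renormalized.
gaussian_smooth3 <- function(a, sigma_vox) {
  w <- array(1, dim = dim(a))
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    dvec <- c(0L, 0L, 0L)
    outa <- array(0, dim = dim(a))
    outw <- array(0, dim = dim(a))
    for (off in -r:r) {
      dvec[axis] <- off
      outa <- outa + k[off + r + 1L] * shift_arr(a, dvec)
      outw <- outw + k[off + r + 1L] * shift_arr(w, dvec)
    }
    a <- outa
    w <- outw
  }
  a / w
}

#' Generate one paired dual-time-point phantom
#'
#' Builds PET-1 as background + ellipsoidal lesion profile x (1 + texture)
#' + noise (floored at 0), and PET-2 from the same texture field with the
#' lesion gain applied and the profile sharpened, with independent noise.
#' The optional necrotic core is set to sub-threshold uptake in both. The
#' scans carry acquisition metadata with uptake times of 60 and 187
#' minutes.
#'
#' @param spec A [phantom_spec()].
#' @return A list: `pet1`, `pet2` ([pet_volume()]s) and `truth` with the
#'   true lesion and necrotic masks, the noiseless 40%-threshold region
#'   (`threshold_mask`), an analysis [bounding_box()], and the programmed
#'   effect directions per variable class.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dm <- spec$grid_shape
  sp <- spec$spacing
  ctr <- (dm + 1) / 2
  ax <- spec$lesion_axes / 2                      # semi-axes, mm
  # squared ellipsoidal radius, separable in the three axes
  e1 <- (((seq_len(dm[1L]) - ctr[1L]) * sp[1L]) / ax[1L])^2
  e2 <- (((seq_len(dm[2L]) - ctr[2L]) * sp[2L]) / ax[2L])^2
  e3 <- (((seq_len(dm[3L]) - ctr[3L]) * sp[3L]) / ax[3L])^2
  rho2 <- outer(outer(e1, e2, "+"), e3, "+")
  profile <- pmax(1 - rho2, 0)
  lesion <- rho2 < 1
  # spherical necrotic core in physical mm about the lesion centre
  r1 <- ((seq_len(dm[1L]) - ctr[1L]) * sp[1L])^2
  r2 <- ((seq_len(dm[2L]) - ctr[2L]) * sp[2L])^2
  r3 <- ((seq_len(dm[3L]) - ctr[3L]) * sp[3L])^2
  necro <- if (spec$necrotic_radius > 0)
    outer(outer(r1, r2, "+"), r3, "+") <= spec$necrotic_radius^2
  else array(FALSE, dim = dm)

  with_seed(spec$seed, {
    # texture on the lesion's bounding region only (it multiplies the
    # profile, which vanishes elsewhere)
    w <- which(lesion, arr.ind = TRUE)
    xs <- min(w[, 1L]):max(w[, 1L])
    ys <- min(w[, 2L]):max(w[, 2L])
    zs <- min(w[, 3L]):max(w[, 3L])
    tex <- array(0, dim = dm)
    if (spec$texture_amplitude > 0) {
      sub <- array(stats::rnorm(length(xs) * length(ys) * length(zs)),
                   dim = c(length(xs), length(ys), length(zs)))
      sub <- gaussian_smooth3(sub, spec$correlation_length / sp)
      sub <- (sub - mean(sub)) / stats::sd(sub)
      tex[xs, ys, zs] <- spec$texture_amplitude * sub
    }
    modul <- pmax(1 + tex, 0)
    core_uptake <- 0.3 * spec$background_uptake   # well below threshold
    u1 <- spec$background_uptake + spec$base_uptake * profile * modul
    u1[necro] <- core_uptake
    u2 <- spec$background_uptake +
      spec$base_uptake * spec$pet2_gain * profile^spec$pet2_contrast * modul
    u2[necro] <- core_uptake
    box <- bounding_box(max(0L, min(w[, 1L]) - 3L), min(dm[1L], max(w[, 1L]) + 2L),
                        max(0L, min(w[, 2L]) - 3L), min(dm[2L], max(w[, 2L]) + 2L),
                        max(0L, min(w[, 3L]) - 3L), min(dm[3L], max(w[, 3L]) + 2L))
    # noiseless 40%-threshold region inside the box: what threshold
    # segmentation recovers exactly when noise and texture are absent
    bx <- (box$x0 + 1L):box$x1
    by <- (box$y0 + 1L):box$y1
    bz <- (box$z0 + 1L):box$z1
    thr_mask <- array(FALSE, dim = dm)
    sub1 <- u1[bx, by, bz, drop = FALSE]
    thr_mask[bx, by, bz] <- sub1 >= 0.4 * max(sub1)
    if (spec$noise_sd > 0) {
      u1 <- u1 + stats::rnorm(length(u1), sd = spec$noise_sd)
      u2 <- u2 + stats::rnorm(length(u2), sd = spec$noise_sd)
    }
    u1 <- pmax(u1, 0)
    u2 <- pmax(u2, 0)
    meta1 <- acquisition_meta(patient_weight = 70000, injected_dose = 3.7e8,
                              timepoint = "PET1", uptake_time = 60)
    meta2 <- acquisition_meta(patient_weight = 70000, injected_dose = 3.7e8,
                              timepoint = "PET2", uptake_time = 187)
    list(pet1 = pet_volume(u1, sp, meta1),
         pet2 = pet_volume(u2, sp, meta2),
         truth = list(lesion_mask = lesion & !necro, necrotic_mask = necro,
                      threshold_mask = thr_mask, box = box,
                      effects = c(suv = if (spec$pet2_gain > 1) "up" else "none",
                                  mtv = if (spec$pet2_contrast > 1) "down" else "none")))
  })
}

#' Default specification sampler for synthetic cohorts
#'
#' Returns a function mapping a per-patient seed to a [phantom_spec()].
#' Lesion diameters are drawn uniformly between `diameter_range` (default
#' 20-50 mm, spanning both sides of the 10 cm^3 MTV stratification), peak
#' uptake uniformly over `uptake_range`, and texture amplitude over
#' `amplitude_range`; the dual-time-point dynamics (`pet2_gain`,
#' `pet2_contrast`) are fixed across the cohort.
#'
#' @param grid_shape,spacing,noise_sd,pet2_gain,pet2_contrast,
#'   correlation_length Passed to [phantom_spec()].
#' @param diameter_range Lesion diameter range, mm.
#' @param uptake_range Lesion peak uptake range, SUV.
#' @param amplitude_range Texture amplitude range.
#' @return A function `(seed) -> phantom_spec`.
#' @export
default_spec_sampler <- function(grid_shape = c(128, 128, 32),
                                 spacing = c(5.47, 5.47, 3.27),
                                 diameter_range = c(20, 50),
                                 uptake_range = c(5, 14),
                                 amplitude_range = c(0.1, 0.3),
                                 correlation_length = 8,
                                 noise_sd = 0.1,
                                 pet2_gain = 1.18,
                                 pet2_contrast = 1.06) {
  function(seed) {
    with_seed(seed, {
      d <- stats::runif(1, diameter_range[1L], diameter_range[2L])
      aniso <- stats::runif(3, 0.9, 1.1)
      axes <- pmax(20, d * aniso)
      phantom_spec(grid_shape = grid_shape, spacing = spacing,
                   lesion_axes = axes,
                   base_uptake = stats::runif(1, uptake_range[1L],
                                              uptake_range[2L]),
                   texture_amplitude = stats::runif(1, amplitude_range[1L],
                                                    amplitude_range[2L]),
                   correlation_length = correlation_length,
                   noise_sd = noise_sd,
                   pet2_gain = pet2_gain, pet2_contrast = pet2_contrast,
                   seed = sample.int(.Machine$integer.max, 1L))
    })
  }
}

#' Generate a synthetic paired cohort
#'
#' Draws `n` independent phantoms from a specification sampler, runs the
#' full per-scan pipeline (segmentation inside the true lesion box at the
#' given threshold fraction, then feature extraction) on both timepoints,
#' and assembles the feature table. Fully reproducible per seed.
#'
#' @param n Number of patients.
#' @param seed Integer master seed.
#' @param spec_sampler A function `(seed) -> phantom_spec`, e.g. from
#'   [default_spec_sampler()].
#' @param fraction Segmentation threshold fraction, default 0.40.
#' @param n_levels Gray classes for discretization, default 16.
#' @return A list: `cohort` (a [paired_cohort()]) and `truth` (per-patient
#'   ground truth list).
#' @export
make_cohort <- function(n, seed = 1L, spec_sampler = default_spec_sampler(),
                        fraction = 0.40, n_levels = 16) {
  stopifnot(n >= 0)
  patient_seeds <- with_seed(seed,
                             sample.int(.Machine$integer.max, max(1L, n)))
  rows <- list()
  truth <- list()
  for (i in seq_len(n)) {
    spec <- spec_sampler(patient_seeds[i])
    ph <- make_phantom(spec)
    truth[[i]] <- ph$truth
    id <- sprintf("P%03d", i)
    for (tp in c("pet1", "pet2")) {
      vol <- ph[[tp]]
      mask <- segment_lesion(vol, ph$truth$box, fraction = fraction)
      fv <- extract_features(vol, mask, n_levels = n_levels)
      rows[[length(rows) + 1L]] <-
        data.frame(patient = id, timepoint = toupper(tp), t(fv))
    }
  }
  df <- if (length(rows) > 0L) do.call(rbind, rows) else
    as.data.frame(stats::setNames(
      rep(list(numeric(0)), length(feature_columns()) + 2L),
      c("patient", "timepoint", feature_columns())))
  if (length(rows) > 0L) df$patient <- as.character(df$patient)
  list(cohort = suppressWarnings(paired_cohort(df)), truth = truth)
}
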
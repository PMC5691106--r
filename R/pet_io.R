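# Reading PET volumes, SUV decay correction, and feature-table IO.

#' Feature column names
#'
#' Column order used in every feature table: the five SUV/volume metrics
#' followed by the eighteen textural features.
#'
#' @return Character vector of feature column names.
#' @export
feature_columns <- function() {
  c("suv_max", "suv_mean", "suv_peak", "mtv_cm3", "tlg",
    "ENT", "HOM", "CON", "DIS", "UNI",
    "SRE", "LRE", "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE",
    "GLNU", "RLNU", "RPC",
    "SE", "TE")
}

#' Acquisition metadata for one PET scan
#'
#' Bundles the quantities entering the body-weight SUV computation:
#' patient weight (g), injected dose (Bq), radionuclide half-life (s), a
#' decay factor for exports that pre-apply decay correction (1 = none
#' applied), the elapsed time from injection for each slice (s), and the
#' DICOM rescale slope. Weight in grams and dose in Bq make the resulting
#' SUV dimensionally g/ml.
#'
#' @param patient_weight Patient weight in grams.
#' @param injected_dose Injected activity in Bq.
#' @param half_life Radionuclide half-life in seconds (18F: 6588 s).
#' @param decay_factor Decay factor already applied by the scanner export;
#'   default 1 (no pre-applied correction). Supplying the vendor's factor
#'   here while also using nonzero `elapsed_time` double-corrects; avoiding
#'   that is the caller's responsibility.
#' @param elapsed_time Elapsed time from injection, in seconds; either a
#'   scalar (applied to every slice) or one value per slice.
#' @param rescale_slope DICOM rescale slope mapping stored values to
#'   activity concentration; default 1.
#' @param timepoint `"PET1"` (standard, ~60 min) or `"PET2"` (delayed).
#' @param uptake_time Nominal injection-to-scan uptake time in minutes.
#' @return An object of class `acquisition_meta`.
#' @export
acquisition_meta <- function(patient_weight, injected_dose, half_life = 6588,
                             decay_factor = 1, elapsed_time = 0,
                             rescale_slope = 1,
                             timepoint = c("PET1", "PET2"),
                             uptake_time = NA_real_) {
  timepoint <- match.arg(timepoint)
  if (!is.numeric(patient_weight) || patient_weight <= 0)
    stop("invalid metadata: patient_weight must be positive", call. = FALSE)
  if (!is.numeric(injected_dose) || injected_dose <= 0)
    stop("invalid metadata: injected_dose must be positive", call. = FALSE)
  if (!is.numeric(half_life) || half_life <= 0)
    stop("invalid metadata: half_life must be positive", call. = FALSE)
  if (!is.numeric(decay_factor) || decay_factor <= 0)
    stop("invalid metadata: decay_factor must be positive", call. = FALSE)
  if (any(elapsed_time < 0))
    stop("invalid metadata: elapsed_time must be non-negative", call. = FALSE)
  structure(list(patient_weight = patient_weight,
                 injected_dose = injected_dose,
                 half_life = half_life,
                 decay_factor = decay_factor,
                 elapsed_time = as.numeric(elapsed_time),
                 rescale_slope = rescale_slope,
                 timepoint = timepoint,
                 uptake_time = uptake_time),
            class = "acquisition_meta")
}

#' Decay-corrected standardized uptake value
#'
#' Converts stored pixel values to SUV (g/ml) with an explicit correction
#' for the elapsed time from injection, so that raw data from a standard
#' and a delayed acquisition after one injection are directly comparable:
#'
#' \deqn{SUV = \frac{SV \cdot RS \cdot W}{(RTD \cdot DF)\; e^{-\ln 2\, Et/HF}}}
#'
#' with SV the stored value, RS the rescale slope, W the patient weight,
#' RTD the injected dose, DF the decay factor, Et the per-slice elapsed
#' time and HF the half-life. SUV is strictly increasing in Et (the
#' exponential in the denominator shrinks as the dose decays).
#'
#' @param stored_value Numeric scalar, vector or 3D array of stored values.
#' @param meta An [acquisition_meta()] object. If `stored_value` is a 3D
#'   array and `meta$elapsed_time` has one value per slice, each slice gets
#'   its own correction.
#' @return SUV values with the shape of `stored_value`.
#' @export
decay_corrected_suv <- function(stored_value, meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  et <- meta$elapsed_time
  denom0 <- meta$injected_dose * meta$decay_factor
  scale <- meta$rescale_slope * meta$patient_weight / denom0
  dm <- dim(stored_value)
  if (!is.null(dm) && length(dm) == 3L && length(et) == dm[3L]) {
    decay <- exp(-log(2) * et / meta$half_life)   # one factor per slice
    out <- stored_value * scale
    out <- sweep(out, 3L, decay, "/")
    return(out)
  }
  if (length(et) != 1L)
    stop("elapsed_time must be scalar or match the number of slices",
         call. = FALSE)
  stored_value * scale / exp(-log(2) * et / meta$half_life)
}

#' PET volume in SUV units
#'
#' A 3D SUV field with its physical voxel spacing and acquisition metadata.
#'
#' @param suv 3D numeric array of SUV values (all non-negative).
#' @param spacing Numeric length-3 voxel spacing `(dx, dy, dz)` in mm.
#' @param meta Optional [acquisition_meta()].
#' @return An object of class `pet_volume` with fields `suv`, `spacing`,
#'   `meta`.
#' @export
pet_volume <- function(suv, spacing, meta = NULL) {
  if (length(dim(suv)) != 3L)
    stop("suv must be a 3D array", call. = FALSE)
  if (any(dim(suv) < 2L))
    stop("volume must have at least 2 voxels along each axis", call. = FALSE)
  if (any(suv < 0)) stop("SUV values must be non-negative", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be three positive lengths (mm)", call. = FALSE)
  structure(list(suv = suv, spacing = spacing, meta = meta),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  cat("PET volume:", paste(dim(x$suv), collapse = " x "), "voxels,",
      "spacing", paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  cat("  SUV range:", signif(min(x$suv), 4), "-", signif(max(x$suv), 4), "\n")
  if (!is.null(x$meta))
    cat("  timepoint:", x$meta$timepoint,
        "uptake time:", x$meta$uptake_time, "min\n")
  invisible(x)
}

#' Load a PET volume from NIfTI
#'
#' Reads a NIfTI-1 volume and converts it to SUV. If the file already
#' stores SUV (`suv_precomputed = TRUE`) the field passes through
#' unchanged; otherwise acquisition metadata must be supplied, either as an
#' [acquisition_meta()] object or as a JSON sidecar (written by
#' [write_pet_volume()]), and the decay-corrected SUV formula is applied
#' slice by slice. Slice ordering along the scan axis follows the NIfTI
#' header. When only a scan-level elapsed time is available it is applied
#' uniformly to every slice (a note is emitted).
#'
#' @param path Path to a `.nii`/`.nii.gz` file.
#' @param meta Optional [acquisition_meta()]; overrides any sidecar.
#' @param suv_precomputed Logical; if `TRUE` the stored field is taken to
#'   be SUV already.
#' @return A [pet_volume()].
#' @export
load_pet_volume <- function(path, meta = NULL, suv_precomputed = FALSE) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("load error: expected a 3D volume in ", path, call. = FALSE)
  spacing <- RNifti::pixdim(img)[1:3]
  if (suv_precomputed) {
    if (is.null(meta)) meta <- read_meta_sidecar(path, required = FALSE)
    return(pet_volume(arr, spacing, meta))
  }
  if (is.null(meta)) meta <- read_meta_sidecar(path, required = TRUE)
  if (length(meta$elapsed_time) == 1L && dim(arr)[3L] > 1L)
    message("note: scan-level elapsed time applied uniformly to all slices")
  pet_volume(decay_corrected_suv(arr, meta), spacing, meta)
}

read_meta_sidecar <- function(path, required = TRUE) {
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
  if (!file.exists(sidecar)) {
    if (required)
      stop("load error: no metadata supplied and no sidecar found at ",
           sidecar, call. = FALSE)
    return(NULL)
  }
  j <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (f in c("patient_weight", "injected_dose", "half_life"))
    if (is.null(j[[f]]))
      stop("load error: sidecar is missing required field '", f, "'",
           call. = FALSE)
  acquisition_meta(patient_weight = j$patient_weight,
                   injected_dose = j$injected_dose,
                   half_life = j$half_life,
                   decay_factor = j$decay_factor %||% 1,
                   elapsed_time = j$elapsed_time %||% 0,
                   rescale_slope = j$rescale_slope %||% 1,
                   timepoint = j$timepoint %||% "PET1",
                   uptake_time = j$uptake_time %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a PET volume to NIfTI
#'
#' Writes the SUV field to a NIfTI-1 file with the volume's voxel spacing,
#' plus a JSON metadata sidecar when metadata is present. Voxel ordering is
#' preserved so that save/load round-trips leave voxel indices (e.g. the
#' argmax position) unchanged.
#'
#' @param volume A [pet_volume()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_pet_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  img <- RNifti::asNifti(volume$suv)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  if (!is.null(volume$meta)) {
    sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
    m <- unclass(volume$meta)
    jsonlite::write_json(m[!vapply(m, function(v) all(is.na(v)), TRUE)],
                         sidecar, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Paired dual-time-point feature cohort
#'
#' A feature table with one row per (patient, timepoint): a `patient`
#' column, a `timepoint` column (`PET1`/`PET2`) and the 23 feature columns
#' of [feature_columns()]. Patients missing one of the two timepoints
#' trigger a paired-completeness warning; paired statistics use complete
#' pairs only.
#'
#' @param data A data.frame with columns `patient`, `timepoint` and all of
#'   [feature_columns()].
#' @return An object of classes `paired_cohort` and `data.frame`.
#' @export
paired_cohort <- function(data) {
  need <- c("patient", "timepoint", feature_columns())
  missing <- setdiff(need, names(data))
  if (length(missing) > 0L)
    stop("feature table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(data) > 0L) {
    if (!all(data$timepoint %in% c("PET1", "PET2")))
      stop("timepoint must be 'PET1' or 'PET2'", call. = FALSE)
    key <- paste(data$patient, data$timepoint)
    if (anyDuplicated(key))
      stop("duplicated (patient, timepoint) keys: ",
           paste(unique(key[duplicated(key)]), collapse = ", "),
           call. = FALSE)
    tab <- table(data$patient)
    lone <- names(tab)[tab < 2L]
    if (length(lone) > 0L)
      warning("patients missing one timepoint: ",
              paste(lone, collapse = ", "), call. = FALSE)
  }
  data <- as.data.frame(data)[, need]
  class(data) <- c("paired_cohort", "data.frame")
  data
}

#' @export
print.paired_cohort <- function(x, ...) {
  cat("Paired PET cohort:", length(unique(x$patient)), "patients,",
      nrow(x), "scans\n")
  NextMethod()
}

# Patients with both timepoints present.
complete_pairs <- function(cohort) {
  tab <- table(cohort$patient)
  names(tab)[tab == 2L]
}

#' Save / load a feature table
#'
#' CSV round-trip of a [paired_cohort()]: one row per (patient, timepoint),
#' lossless to full double precision.
#'
#' @param cohort A [paired_cohort()].
#' @param path CSV path.
#' @return `save_feature_table` returns `path` invisibly;
#'   `load_feature_table` returns a [paired_cohort()].
#' @export
save_feature_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "paired_cohort"))
  df <- as.data.frame(cohort)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname save_feature_table
#' @export
load_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(patient = "character"))
  paired_cohort(df)
}
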
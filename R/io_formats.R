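#' @importFrom stats as.formula glm binomial coef cor.test kruskal.test median
#'   plogis pnorm qlogis qnorm rbeta rbinom rnorm runif sd shapiro.test t.test
#'   var wilcox.test predict setNames
#' @importFrom utils read.csv write.csv
NULL

# plain array from a NIfTI image (drop RNifti header attributes)
.nifti_array <- function(img) {
  a <- as.array(img)
  array(as.vector(a), dim = dim(a))
}

# ---- DWI series ----------------------------------------------------------

#' Construct a multi-b-value DWI series
#'
#' Bundles a 4-D signal array with its diffusion-weighting scheme. The fourth
#' array dimension indexes b-values; frames are stored in ascending b order.
#'
#' @param signal 4-D numeric array (x, y, z, b-index) of non-negative signal
#'   intensities, arbitrary units.
#' @param bvalues Numeric vector of b-values in s/mm^2, one per 4th-dimension
#'   frame. Must contain 0 and at least 3 distinct values.
#' @param voxel_size Positive numeric length-3, voxel edge lengths in mm.
#' @return An object of class `dwi_series` with elements `signal`, `bvalues`,
#'   `voxel_size`.
#' @export
dwi_series <- function(signal, bvalues, voxel_size = c(1, 1, 1)) {
  if (length(dim(signal)) != 4L)
    stop("format error: `signal` must be a 4-D array (x, y, z, b-index)")
  bvalues <- as.numeric(bvalues)
  if (dim(signal)[4] != length(bvalues))
    stop("format error: 4th dimension (", dim(signal)[4],
         ") does not match number of b-values (", length(bvalues), ")")
  if (anyDuplicated(bvalues))
    stop("validation error: duplicate b-values")
  if (is.unsorted(bvalues)) {
    ord <- order(bvalues)
    bvalues <- bvalues[ord]
    signal <- signal[, , , ord, drop = FALSE]
  }
  if (bvalues[1] != 0)
    stop("validation error: b-value scheme must include b = 0")
  if (length(bvalues) < 3L)
    stop("validation error: at least 3 distinct b-values are required")
  if (any(signal < 0, na.rm = TRUE))
    stop("validation error: negative signal intensities")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("validation error: voxel_size must be 3 positive reals (mm)")
  structure(list(signal = signal, bvalues = bvalues,
                 voxel_size = as.numeric(voxel_size)),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  d <- dim(x$signal)
  cat("DWI series: ", paste(d[1:3], collapse = " x "), " voxels, b = ",
      paste(x$bvalues, collapse = ", "), " s/mm^2\n", sep = "")
  invisible(x)
}

#' Read a 4-D DWI NIfTI volume
#'
#' @param series_path Path to a 4-D NIfTI file (.nii or .nii.gz).
#' @param bvalue_spec Numeric b-values (s/mm^2) for the stored frames, in
#'   stored order. Frames are reordered to ascending b internally.
#' @return A [dwi_series].
#' @export
read_dwi <- function(series_path, bvalue_spec) {
  img <- RNifti::readNifti(series_path)
  arr <- .nifti_array(img)
  if (length(dim(arr)) != 4L)
    stop("format error: ", series_path, " is not a 4-D volume")
  if (dim(arr)[4] != length(bvalue_spec))
    stop("format error: volume has ", dim(arr)[4], " frames but ",
         length(bvalue_spec), " b-values were specified")
  vox <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(vox)) || any(vox <= 0)) vox <- c(1, 1, 1)
  dwi_series(arr, bvalue_spec, voxel_size = vox)
}

# ---- Lesion masks --------------------------------------------------------

#' Construct a lesion label mask
#'
#' @param labels 3-D array of non-negative integers; 0 is background, each
#'   positive value is a lesion id.
#' @param dwi Optional [dwi_series] whose spatial geometry the mask must match.
#' @return Object of class `lesion_mask` (the validated integer array).
#' @export
lesion_mask <- function(labels, dwi = NULL) {
  if (length(dim(labels)) != 3L)
    stop("format error: lesion mask must be a 3-D volume")
  if (any(labels < 0) || any(labels != round(labels)))
    stop("format error: lesion mask must contain non-negative integers")
  if (!is.null(dwi)) {
    if (!identical(dim(labels), dim(dwi$signal)[1:3]))
      stop("validation error: mask geometry ",
           paste(dim(labels), collapse = "x"),
           " does not match DWI spatial geometry ",
           paste(dim(dwi$signal)[1:3], collapse = "x"))
  }
  structure(array(as.integer(round(labels)), dim = dim(labels)),
            class = "lesion_mask")
}

#' Read a lesion mask NIfTI and validate it against a DWI series
#'
#' @param mask_path Path to a 3-D integer-valued NIfTI.
#' @param dwi The paired [dwi_series] (geometry check).
#' @return A `lesion_mask`.
#' @export
read_lesion_mask <- function(mask_path, dwi) {
  arr <- .nifti_array(RNifti::readNifti(mask_path))
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L) arr <- arr[, , , 1]
  if (any(abs(arr - round(arr)) > 1e-6))
    stop("format error: ", mask_path, " contains non-integer label values")
  lesion_mask(round(arr), dwi)
}

#' Lesion ids present in a mask
#' @param mask A `lesion_mask`.
#' @return Sorted integer vector of positive labels.
#' @export
lesion_ids <- function(mask) sort(unique(as.integer(mask[mask > 0])))

# ---- Cohort metadata table ----------------------------------------------

.cohort_cols <- c("patient_id", "cohort", "lesion_id", "pGG", "pTstage",
                  "age", "psa")

#' Validate a cohort metadata table
#'
#' Checks the clinical table linking patients and lesions to pathology:
#' pathological Grade Group (pGG, 1-5), pathological T-stage (2 or 3), age and
#' PSA, with a cohort label (`reference` or `target`).
#'
#' @param df Data frame with columns `patient_id`, `cohort`, `lesion_id`,
#'   `pGG`, `pTstage`, `age`, `psa`.
#' @return The validated data frame (class `cohort_table` prepended).
#' @export
cohort_table <- function(df) {
  missing_cols <- setdiff(.cohort_cols, names(df))
  if (length(missing_cols))
    stop("validation error: missing columns: ",
         paste(missing_cols, collapse = ", "))
  df <- df[, .cohort_cols]
  df$patient_id <- as.character(df$patient_id)
  df$cohort <- as.character(df$cohort)
  bad <- function(cond, what) {
    if (any(cond))
      stop("validation error: ", what, " in row(s) ",
           paste(utils::head(which(cond), 5), collapse = ", "))
  }
  bad(!df$cohort %in% c("reference", "target"),
      "cohort must be 'reference' or 'target'")
  bad(!(df$lesion_id == round(df$lesion_id) & df$lesion_id >= 1),
      "lesion_id must be a positive integer")
  bad(!df$pGG %in% 1:5, "pGG out of range 1-5")
  bad(!df$pTstage %in% c(2, 3), "pTstage must be 2 or 3")
  bad(duplicated(df[, c("patient_id", "lesion_id")]),
      "duplicate (patient_id, lesion_id)")
  df$lesion_id <- as.integer(df$lesion_id)
  df$pGG <- as.integer(df$pGG)
  df$pTstage <- as.integer(df$pTstage)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Read a cohort metadata CSV
#' @param csv_path CSV with header `patient_id,cohort,lesion_id,pGG,pTstage,age,psa`.
#' @return A `cohort_table` data frame.
#' @export
read_cohort_table <- function(csv_path) {
  cohort_table(read.csv(csv_path, stringsAsFactors = FALSE))
}

#' Write a cohort metadata CSV
#' @param df A `cohort_table`.
#' @param csv_path Output path.
#' @export
write_cohort_table <- function(df, csv_path) {
  write.csv(as.data.frame(df)[, .cohort_cols], csv_path, row.names = FALSE,
            quote = FALSE)
  invisible(csv_path)
}

#' Reduce a cohort table to one row per patient (index lesion)
#'
#' For patients with multiple lesions, keeps the lesion with the highest pGG
#' (ties broken by lowest lesion id), giving the per-patient index grade used
#' for matching and patient-level statistics.
#'
#' @param df A `cohort_table`.
#' @return Data frame with one row per patient.
#' @export
index_lesions <- function(df) {
  ord <- order(df$patient_id, -df$pGG, df$lesion_id)
  df <- df[ord, ]
  df[!duplicated(df$patient_id), , drop = FALSE]
}

# ---- Results and voxel-pool tables --------------------------------------

.hf_cols <- c("patient_id", "lesion_id", "n_voxels", "n_valid_voxels",
              "hf_dwi", "median_adc", "median_fbv")

#' Write per-lesion hypoxia-fraction results to CSV
#' @param results Data frame (or list of `hypoxia_result`) with columns
#'   `patient_id, lesion_id, n_voxels, n_valid_voxels, hf_dwi, median_adc,
#'   median_fbv`.
#' @param csv_path Output path.
#' @export
write_hf_table <- function(results, csv_path) {
  if (!is.data.frame(results)) results <- do.call(rbind, lapply(results, function(r)
    data.frame(patient_id = r$patient_id, lesion_id = r$lesion_id,
               n_voxels = r$n_voxels, n_valid_voxels = r$n_valid_voxels,
               hf_dwi = r$hf_dwi, median_adc = r$median_adc,
               median_fbv = r$median_fbv, stringsAsFactors = FALSE)))
  missing_cols <- setdiff(.hf_cols, names(results))
  if (length(missing_cols))
    stop("validation error: missing columns: ",
         paste(missing_cols, collapse = ", "))
  out <- results[, .hf_cols]
  for (cl in c("hf_dwi", "median_adc", "median_fbv"))
    out[[cl]] <- signif(out[[cl]], 6)
  write.csv(out, csv_path, row.names = FALSE, quote = FALSE)
  invisible(csv_path)
}

#' Read a per-lesion hypoxia-fraction results CSV
#' @param csv_path Path written by [write_hf_table()].
#' @return Data frame.
#' @export
read_hf_table <- function(csv_path) {
  df <- read.csv(csv_path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.hf_cols, names(df))
  if (length(missing_cols))
    stop("validation error: missing columns: ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Write / read a voxel-pool CSV (one row per voxel)
#'
#' The interchange dialect for pooled lesion voxel values: columns
#' `patient_id, lesion_id, adc_mm2_per_s, fbv`.
#'
#' @param voxels Data frame with columns `patient_id`, `lesion_id`,
#'   `adc_mm2_per_s`, `fbv`.
#' @param csv_path File path.
#' @export
write_voxel_pool <- function(voxels, csv_path) {
  cols <- c("patient_id", "lesion_id", "adc_mm2_per_s", "fbv")
  missing_cols <- setdiff(cols, names(voxels))
  if (length(missing_cols))
    stop("validation error: missing columns: ",
         paste(missing_cols, collapse = ", "))
  write.csv(voxels[, cols], csv_path, row.names = FALSE, quote = FALSE)
  invisible(csv_path)
}

#' @rdname write_voxel_pool
#' @export
read_voxel_pool <- function(csv_path) {
  df <- read.csv(csv_path, stringsAsFactors = FALSE)
  cols <- c("patient_id", "lesion_id", "adc_mm2_per_s", "fbv")
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop("validation error: missing columns: ",
         paste(missing_cols, collapse = ", "))
  df
}

# ---- Parameter-map NIfTI IO ---------------------------------------------

#' Write an ADC/fBV parameter map to NIfTI files
#'
#' ADC (mm^2/s) and fBV (unitless) are written as float32 volumes, the
#' validity mask as uint8.
#'
#' @param pmap A `param_map` (see [fit_map()]).
#' @param adc_path,fbv_path,valid_path Output NIfTI paths (`valid_path`
#'   optional).
#' @export
write_param_map <- function(pmap, adc_path, fbv_path, valid_path = NULL) {
  wr <- function(arr, path, dt) {
    img <- RNifti::asNifti(arr)
    RNifti::writeNifti(img, path, datatype = dt)
  }
  wr(pmap$adc, adc_path, "float")
  wr(pmap$fbv, fbv_path, "float")
  if (!is.null(valid_path)) wr(array(as.integer(pmap$valid),
                                     dim = dim(pmap$valid)),
                               valid_path, "uint8")
  invisible(NULL)
}

#' Read an ADC/fBV parameter map from NIfTI files
#' @param adc_path,fbv_path,valid_path NIfTI paths; if `valid_path` is NULL,
#'   voxels with finite ADC and fBV are marked valid.
#' @return A `param_map`.
#' @export
read_param_map <- function(adc_path, fbv_path, valid_path = NULL) {
  adc <- .nifti_array(RNifti::readNifti(adc_path))
  fbv <- .nifti_array(RNifti::readNifti(fbv_path))
  if (!identical(dim(adc), dim(fbv)))
    stop("validation error: ADC and fBV geometries differ")
  if (is.null(valid_path)) {
    valid <- is.finite(adc) & is.finite(fbv)
  } else {
    valid <- .nifti_array(RNifti::readNifti(valid_path)) > 0
    if (!identical(dim(valid), dim(adc)))
      stop("validation error: validity-mask geometry differs")
  }
  param_map(adc, fbv, valid)
}

#' Write a lesion mask or 3-D map to NIfTI
#' @param arr 3-D array.
#' @param path Output path.
#' @param datatype NIfTI datatype string (e.g. "int16", "float").
#' @export
write_volume <- function(arr, path, datatype = "float") {
  RNifti::writeNifti(RNifti::asNifti(unclass(arr)), path, datatype = datatype)
  invisible(path)
}
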
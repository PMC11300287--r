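# The Consumption-and-Supply Hypoxia (CSH) model.
#
# A voxel is scored by s = ADC/ADC0 + fBV/fBV0, where ADC0 and fBV0 are the
# axis intercepts of the linear discrimination line separating hypoxic from
# non-hypoxic tissue in the (ADC, fBV) plane: low ADC is read as high oxygen
# consumption (cellularity) and low fBV as poor oxygen supply. Voxels
# strictly below the line (s < 1) are hypoxic; the lesion-level hypoxia
# fraction HF_DWI is the fraction of fit-valid lesion voxels classified
# hypoxic.

#' CSH model intercepts
#'
#' Defaults are the published intercepts trained against pimonidazole
#' staining in the original cohort: ADC0 = 0.79e-3 mm^2/s, fBV0 = 0.43 a.u.
#' They are never refit here; override only to transfer a differently
#' calibrated line.
#'
#' @param adc0 ADC axis intercept, mm^2/s (> 0).
#' @param fbv0 fBV axis intercept, unitless (> 0).
#' @return Object of class `csh_params`.
#' @export
csh_params <- function(adc0 = 0.79e-3, fbv0 = 0.43) {
  if (!is.finite(adc0) || adc0 <= 0 || !is.finite(fbv0) || fbv0 <= 0)
    stop("validation error: intercepts must be positive")
  structure(list(adc0 = adc0, fbv0 = fbv0), class = "csh_params")
}

#' CSH voxel score
#'
#' s = adc/adc0 + fbv/fbv0. Values below 1 fall on the hypoxic side of the
#' discrimination line.
#'
#' @param adc ADC value(s), mm^2/s, >= 0.
#' @param fbv fBV value(s), unitless fraction, >= 0.
#' @param params A [csh_params()].
#' @return Numeric score(s), unitless.
#' @export
csh_score <- function(adc, fbv, params = csh_params()) {
  if (any(adc < 0, na.rm = TRUE) || any(fbv < 0, na.rm = TRUE))
    stop("validation error: adc and fbv must be non-negative")
  adc / params$adc0 + fbv / params$fbv0
}

#' Classify voxels as hypoxic
#'
#' Hypoxic means strictly below the discrimination line (score < 1);
#' boundary voxels are non-hypoxic.
#'
#' @inheritParams csh_score
#' @return Logical vector.
#' @export
is_hypoxic <- function(adc, fbv, params = csh_params()) {
  csh_score(adc, fbv, params) < 1
}

#' Per-voxel hypoxia level
#'
#' The clipped linear deficit HL = max(0, 1 - score): zero on or above the
#' discrimination line, 1 at the origin. Exported for visualization only;
#' no downstream statistic uses it.
#'
#' @inheritParams csh_score
#' @return Numeric in \[0, 1\].
#' @export
hypoxia_level <- function(adc, fbv, params = csh_params()) {
  pmax(0, 1 - csh_score(adc, fbv, params))
}

#' Lesion-level hypoxia fraction
#'
#' HF_DWI = (number of fit-valid lesion voxels with score < 1) /
#' (number of fit-valid lesion voxels). Invalid voxels are excluded from
#' numerator and denominator alike.
#'
#' @param pmap A [param_map()].
#' @param mask A `lesion_mask`.
#' @param lesion_id Positive integer label to evaluate.
#' @param params A [csh_params()].
#' @param patient_id Optional patient identifier carried into the result.
#' @param keep_hl_map Also return the 3-D hypoxia-level map (zero outside
#'   the lesion).
#' @return Object of class `hypoxia_result`: `patient_id`, `lesion_id`,
#'   `hf_dwi`, `n_voxels`, `n_valid_voxels`, `median_adc`, `median_fbv`, and
#'   optionally `hl_map`.
#' @export
lesion_hf <- function(pmap, mask, lesion_id, params = csh_params(),
                      patient_id = NA_character_, keep_hl_map = FALSE) {
  vox <- which(mask == lesion_id)
  if (!length(vox))
    stop("validation error: lesion ", lesion_id, " not present in mask")
  ok <- vox[pmap$valid[vox]]
  if (!length(ok))
    stop("degenerate-lesion error: lesion ", lesion_id,
         " has no valid voxels")
  adc <- pmap$adc[ok]; fbv <- pmap$fbv[ok]
  hyp <- is_hypoxic(adc, fbv, params)
  res <- list(patient_id = patient_id, lesion_id = as.integer(lesion_id),
              hf_dwi = mean(hyp), n_voxels = length(vox),
              n_valid_voxels = length(ok),
              median_adc = median(adc), median_fbv = median(fbv))
  if (keep_hl_map) {
    hl <- array(0, dim = dim(pmap$adc))
    hl[ok] <- hypoxia_level(adc, fbv, params)
    res$hl_map <- hl
  }
  structure(res, class = "hypoxia_result")
}

#' @export
print.hypoxia_result <- function(x, ...) {
  cat(sprintf("Lesion %d (%s): HF_DWI = %.3f over %d/%d valid voxels\n",
              x$lesion_id, x$patient_id, x$hf_dwi, x$n_valid_voxels,
              x$n_voxels))
  invisible(x)
}

#' Hypoxia fraction for every lesion in a voxel pool
#'
#' Data-frame analogue of [lesion_hf()] for pooled voxel tables (columns
#' `patient_id, lesion_id, adc_mm2_per_s, fbv`, one row per valid voxel).
#'
#' @param voxels Voxel-pool data frame.
#' @param params A [csh_params()].
#' @return Data frame with one row per (patient_id, lesion_id):
#'   `n_voxels`, `n_valid_voxels`, `hf_dwi`, `median_adc`, `median_fbv`.
#' @export
hf_from_voxels <- function(voxels, params = csh_params()) {
  if (!nrow(voxels)) stop("validation error: empty voxel pool")
  key <- interaction(voxels$patient_id, voxels$lesion_id, drop = TRUE)
  hyp <- is_hypoxic(voxels$adc_mm2_per_s, voxels$fbv, params)
  out <- do.call(rbind, lapply(split(seq_len(nrow(voxels)), key), function(i) {
    data.frame(patient_id = voxels$patient_id[i[1]],
               lesion_id = voxels$lesion_id[i[1]],
               n_voxels = length(i), n_valid_voxels = length(i),
               hf_dwi = mean(hyp[i]),
               median_adc = median(voxels$adc_mm2_per_s[i]),
               median_fbv = median(voxels$fbv[i]),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$patient_id, out$lesion_id), , drop = FALSE]
}
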
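# Segmented IVIM estimation of ADC and fractional blood volume.
#
# The segmented approach suppresses the perfusion (pseudo-diffusion)
# compartment by fitting only b-values at or above a threshold: log-linear
# OLS of log S(b) on b gives the tissue diffusion coefficient (ADC) as the
# negative slope, and the zero-b extrapolated intercept S_int. The perfusion
# fraction is the part of the measured b=0 signal not explained by the
# diffusion compartment: fBV = 1 - S_int / S(0). D* is never estimated.

#' Configuration for the segmented IVIM fit
#'
#' @param b_threshold Perfusion-suppression cutoff in s/mm^2 (inclusive);
#'   b-values >= this enter the log-linear diffusion fit. Default 200, the
#'   conventional cutoff, so scheme \{0,200,800\} uses \{200,800\} and
#'   \{0,50,300,800\} uses \{300,800\}.
#' @param min_high_b_points Minimum number of high-b samples for a valid fit
#'   (>= 2).
#' @param adc_bounds Length-2 clamp interval for ADC, mm^2/s.
#' @param fbv_bounds Length-2 clamp interval for fBV.
#' @return Object of class `ivim_fit_config`.
#' @export
ivim_fit_config <- function(b_threshold = 200, min_high_b_points = 2L,
                            adc_bounds = c(0, 4e-3), fbv_bounds = c(0, 1)) {
  if (b_threshold <= 0) stop("validation error: b_threshold must be > 0")
  if (min_high_b_points < 2) stop("validation error: min_high_b_points >= 2")
  if (adc_bounds[1] > adc_bounds[2] || fbv_bounds[1] > fbv_bounds[2])
    stop("validation error: bounds must be ordered")
  structure(list(b_threshold = b_threshold,
                 min_high_b_points = as.integer(min_high_b_points),
                 adc_bounds = adc_bounds, fbv_bounds = fbv_bounds),
            class = "ivim_fit_config")
}

#' Parameter map container
#'
#' @param adc 3-D array of ADC values, mm^2/s.
#' @param fbv 3-D array of fractional blood volume, unitless.
#' @param valid 3-D logical array flagging voxels with a successful fit.
#' @return Object of class `param_map`.
#' @export
param_map <- function(adc, fbv, valid) {
  if (!identical(dim(adc), dim(fbv)) || !identical(dim(adc), dim(valid)))
    stop("validation error: adc/fbv/valid geometries differ")
  if (any(adc[valid] < 0, na.rm = TRUE))
    stop("validation error: negative ADC in valid voxels")
  if (any(fbv[valid] < 0 | fbv[valid] > 1, na.rm = TRUE))
    stop("validation error: fBV outside [0,1] in valid voxels")
  structure(list(adc = adc, fbv = fbv,
                 valid = array(as.logical(valid), dim = dim(adc))),
            class = "param_map")
}

#' @export
print.param_map <- function(x, ...) {
  cat("Parameter map ", paste(dim(x$adc), collapse = " x "), ": ",
      sum(x$valid), " valid voxels\n", sep = "")
  invisible(x)
}

# Core vectorized segmented fit. `sig` is an n_voxel x n_b matrix.
# Returns an n_voxel x 3 matrix (adc, fbv, valid).
.segmented_fit_matrix <- function(sig, bvalues, config) {
  hi <- which(bvalues >= config$b_threshold)
  if (length(hi) < config$min_high_b_points)
    stop("validation error: fewer than ", config$min_high_b_points,
         " b-values at or above the threshold (", config$b_threshold, ")")
  if (bvalues[1] != 0)
    stop("validation error: b-value scheme must include 0 (fBV undefined)")
  s0 <- sig[, 1]
  shi <- sig[, hi, drop = FALSE]
  valid <- s0 > 0 & apply(shi > 0, 1, all) &
    rowSums(!is.na(shi)) >= config$min_high_b_points
  adc <- rep(NA_real_, nrow(sig))
  fbv <- rep(NA_real_, nrow(sig))
  if (any(valid)) {
    b <- bvalues[hi]
    bc <- b - mean(b)
    logS <- log(shi[valid, , drop = FALSE])
    # OLS slope/intercept in closed form, shared design across voxels
    # (rowSums, not %*%: keeps per-voxel arithmetic bit-reproducible)
    slope <- rowSums(sweep(logS, 2, bc, "*")) / sum(bc^2)
    intercept <- rowMeans(logS) - slope * mean(b)
    d <- pmin(pmax(-slope, config$adc_bounds[1]), config$adc_bounds[2])
    f <- 1 - exp(intercept) / s0[valid]
    f <- pmin(pmax(f, config$fbv_bounds[1]), config$fbv_bounds[2])
    adc[valid] <- d
    fbv[valid] <- f
  }
  cbind(adc = adc, fbv = fbv, valid = as.numeric(valid))
}

#' Segmented IVIM fit of a single voxel
#'
#' Step 1: ordinary least squares of log signal against b over all
#' b >= `b_threshold`; the negative slope is the ADC and the intercept the
#' zero-b extrapolated diffusion signal S_int. Step 2: fBV = 1 - S_int/S(0).
#' Both estimates are clamped to the configured bounds. The fit is invalid
#' when S(0) <= 0, any high-b signal is <= 0, or fewer than
#' `min_high_b_points` high-b samples exist.
#'
#' @param signal Numeric vector of signal intensities, one per b-value.
#' @param bvalues Numeric b-values, s/mm^2, including 0.
#' @param config An [ivim_fit_config()].
#' @return List with `adc` (mm^2/s), `fbv` (fraction) and `valid` (logical);
#'   `adc`/`fbv` are `NA` when invalid.
#' @examples
#' s <- c(1000, 900 * exp(-200 * 7e-4), 900 * exp(-800 * 7e-4))
#' fit_voxel_segmented(s, c(0, 200, 800))
#' @export
fit_voxel_segmented <- function(signal, bvalues, config = ivim_fit_config()) {
  if (length(signal) != length(bvalues))
    stop("validation error: signal and bvalues lengths differ")
  ord <- order(bvalues)
  res <- .segmented_fit_matrix(matrix(signal[ord], nrow = 1),
                               bvalues[ord], config)
  list(adc = unname(res[1, "adc"]), fbv = unname(res[1, "fbv"]),
       valid = res[1, "valid"] > 0)
}

#' Fit ADC and fBV maps over a volume
#'
#' Applies the segmented voxel fit to every voxel carrying a nonzero lesion
#' label (or to the whole volume). Untouched voxels are marked invalid.
#'
#' @param dwi A [dwi_series].
#' @param mask A `lesion_mask` co-registered with `dwi`, or `NULL` with
#'   `whole_volume = TRUE`.
#' @param config An [ivim_fit_config()].
#' @param whole_volume Fit every voxel regardless of labels.
#' @return A [param_map()].
#' @export
fit_map <- function(dwi, mask = NULL, config = ivim_fit_config(),
                    whole_volume = FALSE) {
  sdim <- dim(dwi$signal)[1:3]
  if (whole_volume) {
    idx <- seq_len(prod(sdim))
  } else {
    if (is.null(mask) || !any(mask > 0))
      stop("validation error: empty mask and whole_volume = FALSE")
    if (!identical(dim(unclass(mask)), sdim))
      stop("validation error: mask geometry does not match DWI")
    idx <- which(mask > 0)
  }
  nb <- length(dwi$bvalues)
  sig <- matrix(dwi$signal, ncol = nb)[idx, , drop = FALSE]
  res <- .segmented_fit_matrix(sig, dwi$bvalues, config)
  adc <- array(NA_real_, sdim); fbv <- array(NA_real_, sdim)
  valid <- array(FALSE, sdim)
  adc[idx] <- res[, "adc"]; fbv[idx] <- res[, "fbv"]
  valid[idx] <- res[, "valid"] > 0
  param_map(adc, fbv, valid)
}
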
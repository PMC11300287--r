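# Cross-cohort transfer of the CSH model.
#
# Quantitative ADC/fBV values shift between centers (vendor, sequence,
# analysis differences). The calibration recipe: (1) propensity-score
# optimal 1:1 matching of the target cohort onto the reference cohort on
# pGG and pTstage, with the "average treatment effect on the control"
# estimand — every reference patient is kept, only target patients may be
# dropped; (2) median scaling of the matched pooled voxel distributions,
# F_ADC = median ADC(reference) / median ADC(target), likewise F_fBV; the
# target voxels are multiplied by these factors, the reference is never
# altered. The CSH score is invariant under jointly rescaling values and
# intercepts, which is why median scaling transfers the discrimination line.

#' Fit a propensity model of target-cohort membership
#'
#' Logistic regression of the cohort indicator (target vs reference) on
#' indicator-coded covariates, fitted by maximum likelihood at the patient
#' level (index lesion per patient). When some covariate stratum occurs in
#' only one cohort the logistic fit is separable; the function then falls
#' back to empirical stratum proportions (equivalent to stratum-exact
#' distances) with a warning.
#'
#' @param cohort_tbl A [cohort_table()] (lesion-level; reduced internally via
#'   [index_lesions()]).
#' @param covariates Character vector of covariate columns; default
#'   `c("pGG", "pTstage")`, both treated as categorical.
#' @return Data frame, one row per patient: `patient_id`, `cohort`,
#'   covariates, `propensity` (probability of target membership) and `logit`
#'   (linear predictor), plus attribute `separable` (logical).
#' @export
fit_propensity <- function(cohort_tbl, covariates = c("pGG", "pTstage")) {
  pts <- index_lesions(cohort_tbl)
  if (!all(c("reference", "target") %in% pts$cohort))
    stop("validation error: both cohort labels must be present")
  miss <- setdiff(covariates, names(pts))
  if (length(miss))
    stop("validation error: unknown covariates: ", paste(miss, collapse = ", "))
  stratum <- interaction(pts[covariates], drop = TRUE)
  tab <- table(stratum, pts$cohort)
  separable <- any(tab == 0)
  if (separable) {
    warning("perfect separation in covariate strata; ",
            "falling back to empirical stratum proportions")
    prop <- (tab[, "target"] / rowSums(tab))[as.character(stratum)]
    # degenerate strata sit at 0/1; nudge into (0,1) for a finite logit
    prop <- pmin(pmax(as.numeric(prop), 1e-8), 1 - 1e-8)
  } else {
    dat <- pts[covariates]
    for (cv in covariates) dat[[cv]] <- factor(dat[[cv]])
    dat$.target <- as.integer(pts$cohort == "target")
    fml <- stats::as.formula(paste(".target ~", paste(covariates, collapse = " + ")))
    fit <- suppressWarnings(glm(fml, family = binomial(), data = dat))
    prop <- as.numeric(predict(fit, type = "response"))
  }
  out <- data.frame(patient_id = pts$patient_id, cohort = pts$cohort,
                    pts[covariates], propensity = prop,
                    logit = qlogis(prop), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "separable") <- separable
  out
}

# Optimal 1:1 assignment of every reference point to a distinct target point
# minimizing total |logit difference|. For 1-D points with absolute-value
# cost an optimal assignment exists that is monotone (non-crossing) in the
# sorted orders, so a dynamic program over (sorted refs) x (sorted targets)
# is exact: cost(i, j) = min(cost(i, j-1), cost(i-1, j-1) + |r_i - t_j|).
.assign_1d <- function(ref, target) {
  n <- length(ref); m <- length(target)
  ro <- order(ref); to <- order(target)
  r <- ref[ro]; t <- target[to]
  big <- Inf
  cost <- matrix(big, n + 1, m + 1)
  cost[1, ] <- 0
  for (i in seq_len(n)) {
    for (j in i:m) {
      take <- cost[i, j] + abs(r[i] - t[j])
      skip <- if (j > i) cost[i + 1, j] else big
      cost[i + 1, j + 1] <- min(take, skip)
    }
  }
  # backtrack: at (i, j) we either matched r_i with t_j or skipped t_j
  pair_t <- integer(n)
  i <- n; j <- m
  while (i >= 1) {
    if (j > i && cost[i + 1, j + 1] == cost[i + 1, j]) {
      j <- j - 1
    } else {
      pair_t[i] <- j
      i <- i - 1; j <- j - 1
    }
  }
  list(ref_idx = ro, target_idx = to[pair_t],
       total = cost[n + 1, m + 1])
}

#' Optimal 1:1 propensity matching (ATC)
#'
#' Matches every reference patient to a distinct target patient, minimizing
#' the total absolute difference of propensity logits over all assignments.
#' Only target patients may be dropped; the reference cohort is kept whole.
#' Ties are broken deterministically by (reference id, target id) order.
#'
#' @param ref_logits Named numeric vector of reference-patient logits (names
#'   are patient ids).
#' @param target_logits Named numeric vector of target-patient logits.
#' @return List of class `match_result`: `pairs` (data frame
#'   `reference_patient_id`, `target_patient_id`, `distance`) and
#'   `total_distance`.
#' @export
optimal_match <- function(ref_logits, target_logits) {
  n <- length(ref_logits); m <- length(target_logits)
  if (m < n)
    stop("infeasible error: target cohort (", m,
         ") smaller than reference cohort (", n, ")")
  if (is.null(names(ref_logits))) names(ref_logits) <- paste0("R", seq_len(n))
  if (is.null(names(target_logits))) names(target_logits) <- paste0("T", seq_len(m))
  # stable sort keys (value, id) make the DP's tie-breaking deterministic
  ro <- order(ref_logits, names(ref_logits))
  to <- order(target_logits, names(target_logits))
  sol <- .assign_1d(ref_logits[ro], target_logits[to])
  ref_ids <- names(ref_logits)[ro][sol$ref_idx]
  tgt_ids <- names(target_logits)[to][sol$target_idx]
  ord <- order(ref_ids)
  pairs <- data.frame(reference_patient_id = ref_ids[ord],
                      target_patient_id = tgt_ids[ord],
                      distance = abs(ref_logits[ref_ids[ord]] -
                                       target_logits[tgt_ids[ord]]),
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, total_distance = sol$total),
            class = "match_result")
}

#' Standardized mean difference
#'
#' (meanA - meanB) / sqrt((varA + varB)/2) with sample variances; the 0/0
#' case (both groups constant and equal) is defined as 0.
#'
#' @param groupA,groupB Numeric vectors, each of length >= 2.
#' @return Scalar SMD.
#' @export
standardized_mean_difference <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("validation error: each group needs >= 2 values")
  num <- mean(groupA) - mean(groupB)
  den <- sqrt((var(groupA) + var(groupB)) / 2)
  if (den == 0) {
    if (num == 0) return(0)
    return(sign(num) * Inf)
  }
  num / den
}

# indicator-code covariates to columns of 0/1, one per observed level
.indicator_columns <- function(df, covariates) {
  cols <- list()
  for (cv in covariates) {
    lv <- sort(unique(df[[cv]]))
    for (l in lv) cols[[paste0(cv, "_", l)]] <- as.numeric(df[[cv]] == l)
  }
  as.data.frame(cols)
}

#' Propensity-score match two cohorts with balance diagnostics
#'
#' End-to-end matching: fits the propensity model ([fit_propensity()]), runs
#' [optimal_match()] on the logits, and reports standardized mean differences
#' on indicator-coded covariate columns before (full cohorts) and after
#' (reference vs matched targets).
#'
#' @inheritParams fit_propensity
#' @return `match_result` augmented with `propensity` (the per-patient score
#'   table), `smd_before` and `smd_after` (named per-indicator SMDs).
#' @export
match_cohorts <- function(cohort_tbl, covariates = c("pGG", "pTstage")) {
  ps <- fit_propensity(cohort_tbl, covariates)
  is_ref <- ps$cohort == "reference"
  res <- optimal_match(setNames(ps$logit[is_ref], ps$patient_id[is_ref]),
                       setNames(ps$logit[!is_ref], ps$patient_id[!is_ref]))
  ind <- .indicator_columns(ps, covariates)
  smd_of <- function(sel_target) {
    vapply(ind, function(col)
      standardized_mean_difference(col[is_ref], col[sel_target]),
      numeric(1))
  }
  matched <- ps$patient_id %in% res$pairs$target_patient_id
  res$propensity <- ps
  res$smd_before <- smd_of(!is_ref)
  res$smd_after <- smd_of(matched)
  res
}

#' @export
print.match_result <- function(x, ...) {
  cat("Optimal 1:1 match: ", nrow(x$pairs), " pairs, total logit distance ",
      format(x$total_distance, digits = 4), "\n", sep = "")
  if (!is.null(x$smd_before))
    cat("max |SMD| before/after: ",
        format(max(abs(x$smd_before)), digits = 3), " / ",
        format(max(abs(x$smd_after)), digits = 3), "\n", sep = "")
  invisible(x)
}

#' Median scaling factors between pooled voxel distributions
#'
#' F_ADC = median ADC(reference) / median ADC(target) and likewise F_fBV,
#' computed on voxels pooled over all lesions of the matched cohorts.
#'
#' @param ref_voxels,target_voxels Voxel-pool data frames (columns
#'   `adc_mm2_per_s`, `fbv`), or lists with `adc`/`fbv` vectors.
#' @return Object of class `scaling_factors`: `f_adc`, `f_fbv`.
#' @export
compute_scaling_factors <- function(ref_voxels, target_voxels) {
  get <- function(v, what) {
    if (is.data.frame(v)) {
      if (what == "adc") v$adc_mm2_per_s else v$fbv
    } else v[[what]]
  }
  m <- list(ra = median(get(ref_voxels, "adc")),
            ta = median(get(target_voxels, "adc")),
            rf = median(get(ref_voxels, "fbv")),
            tf = median(get(target_voxels, "fbv")))
  if (any(vapply(m, function(z) !length(z) || !is.finite(z), logical(1))))
    stop("calibration error: empty or non-finite voxel pool")
  if (m$ta <= 0 || m$tf <= 0)
    stop("calibration error: target median must be > 0")
  structure(list(f_adc = m$ra / m$ta, f_fbv = m$rf / m$tf),
            class = "scaling_factors")
}

#' @export
print.scaling_factors <- function(x, ...) {
  cat(sprintf("Scaling factors: F_ADC = %.4f, F_fBV = %.4f\n",
              x$f_adc, x$f_fbv))
  invisible(x)
}

#' Apply scaling factors to target-cohort values
#'
#' Multiplies ADC by `f_adc` and fBV by `f_fbv`. fBV is re-clamped to
#' \[0, 1\]; the number of clamped voxels is reported as a message. Works on
#' voxel-pool data frames and on [param_map()] objects (validity untouched).
#'
#' @param x Voxel-pool data frame or `param_map`.
#' @param factors A `scaling_factors`.
#' @param quiet Suppress the clamp-count message.
#' @return Scaled object of the same class.
#' @export
apply_scaling <- function(x, factors, quiet = FALSE) {
  if (factors$f_adc <= 0 || factors$f_fbv <= 0)
    stop("calibration error: factors must be positive")
  clamped <- 0L
  if (inherits(x, "param_map")) {
    x$adc <- x$adc * factors$f_adc
    f <- x$fbv * factors$f_fbv
    clamped <- sum(f[x$valid] > 1, na.rm = TRUE)
    x$fbv <- pmin(pmax(f, 0), 1)
  } else {
    x$adc_mm2_per_s <- x$adc_mm2_per_s * factors$f_adc
    f <- x$fbv * factors$f_fbv
    clamped <- sum(f > 1, na.rm = TRUE)
    x$fbv <- pmin(pmax(f, 0), 1)
  }
  if (clamped > 0 && !quiet)
    message(clamped, " fBV voxel(s) clamped to 1 after scaling")
  x
}
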
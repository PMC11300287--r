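# Shared fixture builders and independent oracles.

# ideal-mode IVIM signal: perfusion contributes only at b = 0
ideal_signal <- function(s0, f, d, bvalues) {
  ifelse(bvalues == 0, s0, s0 * (1 - f) * exp(-bvalues * d))
}

biexp_signal <- function(s0, f, d, dstar, bvalues) {
  s0 * (f * exp(-bvalues * dstar) + (1 - f) * exp(-bvalues * d))
}

# closed-form two-point segmented-fit oracle for b = (0, b1, b2)
twopoint_oracle <- function(s, b) {
  d <- log(s[2] / s[3]) / (b[3] - b[2])
  sint <- exp(log(s[2]) + b[2] * d)
  list(adc = d, fbv = 1 - sint / s[1])
}

# uniform single-lesion phantom: every voxel carries the same signal vector
phantom_dwi <- function(signal, bvalues, dims = c(3, 3, 2)) {
  nb <- length(bvalues)
  sig <- array(rep(signal, each = prod(dims)), dim = c(dims, nb))
  dwi_series(sig, bvalues)
}

full_mask <- function(dims = c(3, 3, 2), label = 1L) {
  lesion_mask(array(label, dim = dims))
}

# minimal valid cohort rows
make_cohort <- function(n_ref = 4, n_tgt = 4, pGG_ref = NULL, pGG_tgt = NULL,
                        pT_ref = NULL, pT_tgt = NULL) {
  if (is.null(pGG_ref)) pGG_ref <- rep_len(1:2, n_ref)
  if (is.null(pGG_tgt)) pGG_tgt <- rep_len(1:2, n_tgt)
  if (is.null(pT_ref)) pT_ref <- rep_len(c(2, 3), n_ref)
  if (is.null(pT_tgt)) pT_tgt <- rep_len(c(2, 3), n_tgt)
  cohort_table(data.frame(
    patient_id = c(sprintf("R%02d", seq_len(n_ref)),
                   sprintf("T%02d", seq_len(n_tgt))),
    cohort = rep(c("reference", "target"), c(n_ref, n_tgt)),
    lesion_id = 1L,
    pGG = c(pGG_ref, pGG_tgt),
    pTstage = c(pT_ref, pT_tgt),
    age = 65, psa = 8.9, stringsAsFactors = FALSE))
}

# exhaustive-enumeration oracle for the 1:1 assignment problem:
# minimum total |ref - target| over all injective ref -> target maps
brute_force_assignment <- function(ref, target) {
  ref <- unname(ref); target <- unname(target)
  n <- length(ref); m <- length(target)
  best <- Inf
  rec <- function(i, used, acc) {
    if (acc >= best) return()
    if (i > n) { best <<- acc; return() }
    for (j in seq_len(m)) if (!used[j]) {
      used[j] <- TRUE
      rec(i + 1, used, acc + abs(ref[i] - target[j]))
      used[j] <- FALSE
    }
  }
  rec(1L, logical(m), 0)
  best
}
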
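# Assumption-gated group comparisons of lesion hypoxia fractions.
#
# Two-sample comparisons use a parametric/nonparametric gate: a t-test only
# when both groups pass Shapiro-Wilk normality AND Levene's homogeneity test
# at the gate alpha, otherwise Mann-Whitney. Multi-group grade analysis uses
# Kruskal-Wallis; the HF-grade association uses Pearson correlation on the
# integer grade codes 1-5. All tests are two-sided; no multiplicity
# correction is applied.

.shapiro_p <- function(x) {
  # degenerate (constant/near-constant) samples are maximally non-normal
  if (length(unique(x)) < 3 || sd(x) == 0) return(0)
  out <- tryCatch(shapiro.test(x)$p.value, error = function(e) 0)
  out
}

#' Choose between t-test and Mann-Whitney for two samples
#'
#' Returns `"t_test"` iff Shapiro-Wilk p >= alpha in both groups and
#' Levene's test (mean-centered) p >= alpha; otherwise `"mann_whitney"`.
#'
#' @param groupA,groupB Numeric vectors, each of length >= 3.
#' @param alpha Gate significance level (default 0.05).
#' @return List with `choice` ("t_test"/"mann_whitney") and the gate
#'   p-values `shapiro_A`, `shapiro_B`, `levene`.
#' @export
choose_two_sample_test <- function(groupA, groupB, alpha = 0.05) {
  if (length(groupA) < 3 || length(groupB) < 3)
    stop("validation error: each group needs >= 3 values")
  pA <- .shapiro_p(groupA)
  pB <- .shapiro_p(groupB)
  y <- c(groupA, groupB)
  g <- factor(rep(c("A", "B"), c(length(groupA), length(groupB))))
  pL <- tryCatch(
    car::leveneTest(y, g, center = "mean")[1, "Pr(>F)"],
    error = function(e) 0)
  if (!is.finite(pL)) pL <- 0
  choice <- if (pA >= alpha && pB >= alpha && pL >= alpha)
    "t_test" else "mann_whitney"
  list(choice = choice, shapiro_A = pA, shapiro_B = pB, levene = pL)
}

.group_comparison <- function(grouping, test_used, statistic, p_value,
                              medians, sizes, gate = NULL) {
  structure(list(grouping = grouping, test_used = test_used,
                 statistic = unname(statistic), p_value = unname(p_value),
                 group_medians = medians, group_sizes = sizes, gate = gate),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(x$grouping, ": ", x$test_used, ", statistic = ",
      format(x$statistic, digits = 4), ", p = ",
      format.pval(x$p_value, digits = 3), "\n  medians: ",
      paste(names(x$group_medians), round(unlist(x$group_medians), 3),
            sep = " = ", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Gated two-group comparison of hypoxia fractions
#'
#' Splits a per-patient HF table by the requested clinical grouping, applies
#' the assumption gate and runs the chosen two-sided test. Groupings:
#' `"pGG_low_vs_high"` splits at pGG < 3 vs >= 3; `"pTstage_2_vs_3"` splits
#' by pathological T-stage.
#'
#' @param hf_tbl Data frame with one HF per patient (use the index lesion),
#'   columns `hf_dwi` and `pGG`/`pTstage` as needed.
#' @param grouping One of `"pGG_low_vs_high"`, `"pTstage_2_vs_3"`.
#' @param alpha Gate significance level.
#' @param force_test Bypass the gate and run `"t_test"` or `"mann_whitney"`
#'   unconditionally (`NULL`, the default, applies the gate).
#' @return A `group_comparison`.
#' @export
compare_groups <- function(hf_tbl,
                           grouping = c("pGG_low_vs_high", "pTstage_2_vs_3"),
                           alpha = 0.05, force_test = NULL) {
  grouping <- match.arg(grouping)
  if (grouping == "pGG_low_vs_high") {
    if (!"pGG" %in% names(hf_tbl))
      stop("validation error: column pGG required")
    a <- hf_tbl$hf_dwi[hf_tbl$pGG < 3]
    b <- hf_tbl$hf_dwi[hf_tbl$pGG >= 3]
    labels <- c("pGG<3", "pGG>=3")
  } else {
    if (!"pTstage" %in% names(hf_tbl))
      stop("validation error: column pTstage required")
    a <- hf_tbl$hf_dwi[hf_tbl$pTstage == 2]
    b <- hf_tbl$hf_dwi[hf_tbl$pTstage == 3]
    labels <- c("pTstage=2", "pTstage=3")
  }
  if (!length(a) || !length(b))
    stop("validation error: empty group for ", grouping)
  gate <- choose_two_sample_test(a, b, alpha)
  if (!is.null(force_test)) {
    gate$choice <- match.arg(force_test, c("t_test", "mann_whitney"))
    gate$forced <- TRUE
  }
  if (gate$choice == "t_test") {
    # gate established equal variances, so the pooled-variance t-test applies
    tt <- t.test(a, b, var.equal = TRUE)
    stat <- tt$statistic; p <- tt$p.value
  } else {
    wt <- suppressWarnings(wilcox.test(a, b, exact = NULL))
    stat <- wt$statistic; p <- wt$p.value
  }
  .group_comparison(grouping, gate$choice, stat, p,
                    medians = setNames(list(median(a), median(b)), labels),
                    sizes = setNames(list(length(a), length(b)), labels),
                    gate = gate)
}

#' Kruskal-Wallis test of HF across individual grade groups
#'
#' Tie-corrected Kruskal-Wallis H with chi-square p on (k - 1) df. The
#' all-identical degenerate case returns H = 0, p = 1.
#'
#' @param hf Numeric HF values (per lesion or per patient).
#' @param pGG Integer grades 1-5, parallel to `hf`.
#' @return A `group_comparison` with `test_used = "kruskal_wallis"`.
#' @export
kruskal_wallis_by_grade <- function(hf, pGG) {
  if (length(hf) != length(pGG))
    stop("validation error: hf and pGG lengths differ")
  g <- factor(pGG)
  if (nlevels(g) < 2)
    stop("validation error: need >= 2 non-empty grade groups")
  if (length(unique(hf)) == 1L) {
    stat <- 0; p <- 1
  } else {
    kt <- kruskal.test(hf, g)
    stat <- kt$statistic; p <- kt$p.value
  }
  meds <- lapply(split(hf, g), median)
  .group_comparison("pGG_1_to_5", "kruskal_wallis", stat, p,
                    medians = meds, sizes = lapply(split(hf, g), length))
}

#' Pearson correlation between HF and grade group
#'
#' Grades are used as numeric codes 1-5; the p-value is the two-sided
#' t-approximation. Set `method = "spearman"` for the rank alternative.
#'
#' @param hf Numeric HF values.
#' @param pGG Integer grades 1-5.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `rho`, `p_value`, `n`.
#' @export
pearson_hf_vs_grade <- function(hf, pGG, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(hf) != length(pGG))
    stop("validation error: hf and pGG lengths differ")
  if (length(hf) < 3) stop("validation error: need >= 3 pairs")
  if (sd(hf) == 0 || sd(pGG) == 0)
    stop("undefined-correlation error: zero variance")
  ct <- suppressWarnings(cor.test(hf, as.numeric(pGG), method = method))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(hf))
}
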
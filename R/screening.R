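# Per-feature benign-vs-malignant significance screening with a
# normality-gated choice between the unpaired t-test and Mann-Whitney U.

significance_tier <- function(p) {
  if (is.na(p)) return("ns")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}

#' Screen one feature for a benign-vs-malignant difference
#'
#' Shapiro-Wilk normality is assessed in each group at alpha = 0.05; if
#' both groups look normal an unpaired two-sided pooled-variance t-test is
#' used, otherwise a two-sided Mann-Whitney U test (exact when both groups
#' have 20 or fewer observations and no ties, normal approximation with
#' continuity and tie correction otherwise). No multiple-testing
#' correction is applied. Tiers: `*` p < 0.05, `**` p < 0.01, `***`
#' p < 0.001, `ns` otherwise.
#'
#' @param benign,malignant numeric vectors (>= 3 observations each).
#' @param shapiro_alpha significance level of the normality gate.
#' @return list with `test` ("t-test" or "mann-whitney"), `p_value`,
#'   `tier`. A feature constant in both groups is reported `ns` with
#'   `p_value = NA`.
#' @export
significance_screen <- function(benign, malignant, shapiro_alpha = 0.05) {
  benign <- benign[is.finite(benign)]
  malignant <- malignant[is.finite(malignant)]
  if (length(benign) < 3 || length(malignant) < 3)
    stop("need at least 3 observations per group")
  const_b <- diff(range(benign)) == 0
  const_m <- diff(range(malignant)) == 0
  if (const_b && const_m)
    return(list(test = "none", p_value = NA_real_, tier = "ns"))
  normal <- function(x, is_const) {
    if (is_const || length(x) < 3) return(FALSE)
    stats::shapiro.test(x)$p.value >= shapiro_alpha
  }
  both_normal <- normal(benign, const_b) && normal(malignant, const_m)
  if (both_normal) {
    p <- stats::t.test(benign, malignant, var.equal = TRUE)$p.value
    test <- "t-test"
  } else {
    exact <- length(benign) <= 20 && length(malignant) <= 20 &&
      !anyDuplicated(c(benign, malignant))
    p <- suppressWarnings(
      stats::wilcox.test(benign, malignant, exact = exact,
                         correct = TRUE)$p.value)
    test <- "mann-whitney"
  }
  list(test = test, p_value = p, tier = significance_tier(p))
}

#' Screen every feature column of a cohort table
#'
#' @param table data.frame from [assemble_feature_table()] with a `label`
#'   column.
#' @return data.frame with `feature`, `test`, `p_value`, `tier`.
#' @export
screen_features <- function(table) {
  stopifnot("label" %in% names(table))
  feats <- setdiff(names(table), "label")
  b <- table$label == "benign"
  rows <- lapply(feats, function(f) {
    r <- significance_screen(table[[f]][b], table[[f]][!b])
    data.frame(feature = f, test = r$test, p_value = r$p_value,
               tier = r$tier, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
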
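#' Construct an epigenetic clock model
#'
#' A clock is a linear predictor over a subset of age-associated CpGs
#' plus an optional monotone calibration mapping the linear score to
#' years. Coefficient tables for published clocks are supplied by the
#' user as TSV ([read_clock_tsv()]); tests use synthetic clocks with
#' known truth.
#'
#' @param cpg_ids Character clock CpG ids.
#' @param weights Numeric per-CpG coefficients (finite).
#' @param intercept Intercept of the linear score.
#' @param calibration Either `NULL` (identity) or a list
#'   `list(a =, b =)` applying the monotone affine map `a + b * score`
#'   (`b > 0`).
#' @return Object of class `clock_model`.
#' @export
clock_model <- function(cpg_ids, weights, intercept = 0, calibration = NULL) {
  stopifnot(length(cpg_ids) == length(weights))
  if (any(!is.finite(weights))) stop("clock weights must be finite")
  if (!is.null(calibration)) {
    stopifnot(is.list(calibration), calibration$b > 0)
  }
  structure(list(
    cpg_ids = as.character(cpg_ids),
    weights = setNames(as.numeric(weights), cpg_ids),
    intercept = intercept,
    calibration = calibration
  ), class = "clock_model")
}

#' Read a clock coefficient table from TSV
#'
#' Expected columns `cpg` and `weight`; a row with cpg `"(Intercept)"`
#' supplies the intercept.
#'
#' @param path Path to the TSV file.
#' @return A [clock_model()].
#' @export
read_clock_tsv <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cpg", "weight") %in% names(tab)))
  ic <- tab$cpg == "(Intercept)"
  clock_model(
    cpg_ids = tab$cpg[!ic],
    weights = tab$weight[!ic],
    intercept = if (any(ic)) tab$weight[ic][1] else 0
  )
}

#' Apply an epigenetic clock to a beta matrix
#'
#' Age per sample is `calibration(intercept + sum(weights * beta))`.
#' At least 90% of the clock CpGs must be present in the matrix; each
#' missing clock CpG contributes its weight times the cohort mean beta
#' of the present clock CpGs, and the imputation is reported in a
#' message.
#'
#' @param beta Probes x samples beta matrix or [methylation_matrix()].
#' @param clock A [clock_model()].
#' @param min_coverage Minimum fraction of clock CpGs required (default
#'   0.9).
#' @return Named numeric vector of methylation ages (years) per sample.
#' @export
clock_age <- function(beta, clock, min_coverage = 0.9) {
  b <- get_beta(beta)
  present <- clock$cpg_ids[clock$cpg_ids %in% rownames(b)]
  coverage <- length(present) / length(clock$cpg_ids)
  if (coverage < min_coverage) {
    stop(sprintf("only %.0f%% of clock CpGs present (minimum %.0f%%)",
                 100 * coverage, 100 * min_coverage))
  }
  sub <- b[present, , drop = FALSE]
  score <- clock$intercept + drop(clock$weights[present] %*% sub)
  missing <- setdiff(clock$cpg_ids, present)
  if (length(missing)) {
    message(length(missing), " clock CpGs missing; imputed by cohort mean beta")
    imputed <- mean(sub)
    score <- score + sum(clock$weights[missing]) * imputed
  }
  cal <- clock$calibration
  if (!is.null(cal)) score <- cal$a + cal$b * score
  setNames(score, colnames(b))
}

#' Methylation age acceleration (MAA) as regression residuals
#'
#' MAA is the residual from regressing chronological age on methylation
#' age (the reported convention); `direction = "methyl_on_chron"` gives
#' the more common reverse regression. Residuals sum to zero over the
#' regression cohort and are orthogonal to the predictor.
#'
#' @param chron_age Chronological ages (years) per sample.
#' @param methyl_age Methylation age estimates per sample.
#' @param direction `"chron_on_methyl"` (default) or
#'   `"methyl_on_chron"`.
#' @return List with `maa` (residuals), `fit` (the `lm`), `direction`.
#' @export
compute_maa <- function(chron_age, methyl_age,
                        direction = c("chron_on_methyl", "methyl_on_chron")) {
  direction <- match.arg(direction)
  if (length(chron_age) < 3) stop("at least 3 samples required")
  predictor <- if (direction == "chron_on_methyl") methyl_age else chron_age
  outcome <- if (direction == "chron_on_methyl") chron_age else methyl_age
  if (var(predictor) == 0) stop("constant predictor: cannot regress")
  fit <- lm(outcome ~ predictor)
  list(maa = setNames(resid(fit), names(chron_age)), fit = fit,
       direction = direction)
}

# Shapiro-Wilk-gated two-group comparison: t-test when both groups look
# normal (p > 0.05), rank-based test otherwise.
normality_gated_test <- function(x, y, rank_test = wilcox.test) {
  normal <- function(v) {
    n <- length(v)
    n >= 3 && n <= 5000 && var(v) > 0 && shapiro.test(v)$p.value > 0.05
  }
  if (normal(x) && normal(y)) {
    tst <- t.test(x, y)
    list(test = "t", statistic = unname(tst$statistic), p_value = tst$p.value,
         mean_difference = mean(x) - mean(y))
  } else {
    tst <- suppressWarnings(rank_test(x, y))
    list(test = "rank", statistic = unname(tst$statistic),
         p_value = tst$p.value, mean_difference = mean(x) - mean(y))
  }
}

#' Compare methylation age acceleration between severity groups
#'
#' Shapiro-Wilk normality check per group; t-test of the mean difference
#' when both pass, Wilcoxon rank-sum otherwise.
#'
#' @param maa Residual MAA values per sample.
#' @param labels `mild`/`severe` per sample.
#' @return List with `test`, `statistic`, `p_value`, `mean_difference`
#'   (severe minus mild).
#' @export
compare_maa <- function(maa, labels) {
  labels <- factor(as.character(labels), levels = c("mild", "severe"))
  r <- normality_gated_test(maa[labels == "severe"], maa[labels == "mild"])
  r
}

#' Compare DNA-methylation smoking pack-years between groups
#'
#' Per-sample pack-year estimates (an external clock output, or
#' synthetic) are compared between severity groups with a Shapiro-Wilk
#' gate and a rank-based test.
#'
#' @param dnam_packyears Per-sample estimates.
#' @param labels `mild`/`severe` per sample.
#' @return As [compare_maa()].
#' @export
compare_smoking <- function(dnam_packyears, labels) {
  labels <- factor(as.character(labels), levels = c("mild", "severe"))
  normality_gated_test(dnam_packyears[labels == "severe"],
                       dnam_packyears[labels == "mild"])
}

#' Overlap of clock CpGs with a DMP list
#'
#' @param clock A [clock_model()].
#' @param dmp_ids Character DMP probe ids.
#' @return Character vector of shared CpG ids.
#' @export
clock_dmp_overlap <- function(clock, dmp_ids) {
  intersect(clock$cpg_ids, dmp_ids)
}
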
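#' Build an age-stratified EDSS reference for ARMSS scoring
#'
#' The age-related MS severity (ARMSS) score re-expresses an EDSS value as
#' its rank within an age-matched reference population, scaled to 0-10.
#' The reference is a long table of (age, EDSS) observations; ages are
#' binned to integers when scoring.
#'
#' @param age Integer-valued ages, one per reference observation.
#' @param edss EDSS values (0-10 in 0.5 steps), one per observation.
#' @return An object of class `armss_reference`.
#' @export
armss_reference <- function(age, edss) {
  stopifnot(length(age) == length(edss))
  if (any(edss < 0 | edss > 10)) stop("EDSS values must lie in [0, 10]")
  out <- data.frame(age = as.integer(round(age)), edss = as.numeric(edss))
  if (any(table(out$age) < 1)) stop("each age stratum must be non-empty")
  class(out) <- c("armss_reference", "data.frame")
  out
}

#' ARMSS score for a single visit
#'
#' The score is 10 times the mid-rank fraction of the observed EDSS within
#' the reference EDSS distribution at the (rounded) age: the mean of the
#' "at or below" and "strictly below" fractions. It is bounded in
#' \[0, 10\] and monotone non-decreasing in EDSS at fixed age.
#'
#' @param age Age at visit, years.
#' @param edss EDSS at visit.
#' @param ref An [armss_reference()].
#' @return ARMSS score in \[0, 10\].
#' @export
armss_score <- function(age, edss, ref) {
  stopifnot(inherits(ref, "armss_reference"))
  a <- as.integer(round(age))
  stratum <- ref$edss[ref$age == a]
  if (length(stratum) == 0) {
    stop(sprintf(
      "age %d outside reference range [%d, %d]", a, min(ref$age), max(ref$age)
    ))
  }
  f_le <- mean(stratum <= edss)
  f_lt <- mean(stratum < edss)
  10 * (f_le + f_lt) / 2
}

#' Check a visit history against the cohort eligibility rules
#'
#' Eligibility requires at least five years between first and last visit
#' and at least three relapse-independent EDSS scores.
#'
#' @param history Data frame with columns `age_at_visit`, `edss`,
#'   `relapse_independent`.
#' @param min_followup Minimum follow-up span in years (default 5).
#' @param min_scores Minimum number of relapse-independent EDSS scores
#'   (default 3).
#' @return Invisibly `TRUE`; otherwise an error listing failed criteria.
#' @export
check_eligibility <- function(history, min_followup = 5, min_scores = 3) {
  span <- max(history$age_at_visit) - min(history$age_at_visit)
  n_ri <- sum(history$relapse_independent)
  fails <- character(0)
  if (span < min_followup) {
    fails <- c(fails, sprintf(
      "follow-up span %.2f y below minimum %g y", span, min_followup
    ))
  }
  if (n_ri < min_scores) {
    fails <- c(fails, sprintf(
      "%d relapse-independent EDSS scores below minimum %d", n_ri, min_scores
    ))
  }
  if (length(fails)) {
    stop("history fails eligibility: ", paste(fails, collapse = "; "))
  }
  invisible(TRUE)
}

#' Longitudinal (median) ARMSS over a visit history
#'
#' Relapse-associated visits are dropped, each remaining visit is scored
#' with [armss_score()], and the median of the per-visit scores is the
#' longitudinal ARMSS. Histories failing eligibility raise an error.
#'
#' @inheritParams check_eligibility
#' @param ref An [armss_reference()].
#' @return A list with `median_armss`, `n_scores_used`, `follow_up_years`.
#' @export
longitudinal_armss <- function(history, ref, min_followup = 5, min_scores = 3) {
  check_eligibility(history, min_followup, min_scores)
  ri <- history[history$relapse_independent, , drop = FALSE]
  scores <- mapply(armss_score, ri$age_at_visit, ri$edss,
                   MoreArgs = list(ref = ref))
  list(
    median_armss = median(scores),
    n_scores_used = nrow(ri),
    follow_up_years = max(history$age_at_visit) - min(history$age_at_visit)
  )
}

#' Percentile-based severity labels from longitudinal ARMSS scores
#'
#' Scores at or below the cohort 20th percentile are labelled `mild`,
#' those at or above the 80th percentile `severe`, and the middle of the
#' distribution `excluded`. Percentiles use linear interpolation
#' (`quantile` type 7); the "at or" rule makes both thresholds inclusive.
#'
#' @param medians Numeric vector of longitudinal ARMSS scores.
#' @param lower_pct,upper_pct Percentile cut points (defaults 20 and 80).
#' @return Factor with levels `mild`, `excluded`, `severe`.
#' @export
classify_severity <- function(medians, lower_pct = 20, upper_pct = 80) {
  if (length(medians) == 0) stop("no scores supplied")
  if (length(medians) < 5) stop("at least 5 scores required")
  q <- quantile(medians, c(lower_pct, upper_pct) / 100, type = 7, names = FALSE)
  labels <- rep("excluded", length(medians))
  if (q[1] == q[2]) {
    warning("degenerate score distribution: percentile thresholds coincide; ",
            "all samples labelled excluded")
  } else {
    labels[medians <= q[1]] <- "mild"
    labels[medians >= q[2]] <- "severe"
  }
  factor(labels, levels = c("mild", "excluded", "severe"))
}

#' Cohen's d between two groups
#'
#' (mean1 - mean2) / pooled SD. Returns `NA` when either group has fewer
#' than two members.
#'
#' @param x,y Numeric vectors.
#' @return Cohen's d, or `NA_real_`.
#' @export
cohens_d <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) return(NA_real_)
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

#' Per-group cohort summary statistics
#'
#' Median, IQR (type-7 quantiles), range and Cohen's d (mild vs severe)
#' for each continuous characteristic, per severity group and overall.
#'
#' @param phenotypes Data frame with columns `sample_id`, `label`, and
#'   `median_armss`; additional numeric columns are summarised too.
#' @param histories Optional data frame of visits (columns `sample_id`,
#'   `age_at_visit`, `edss`, `relapse_independent`); adds follow-up years
#'   and number of EDSS scores per sample.
#' @return Data frame with one row per (characteristic, group) plus a
#'   Cohen's d column repeated per characteristic.
#' @export
cohort_summary <- function(phenotypes, histories = NULL) {
  stopifnot(all(c("sample_id", "label", "median_armss") %in% names(phenotypes)))
  ph <- phenotypes
  if (!is.null(histories)) {
    sp <- split(histories, histories$sample_id)
    fu <- vapply(sp, function(h) max(h$age_at_visit) - min(h$age_at_visit), 0)
    ne <- vapply(sp, function(h) sum(h$relapse_independent), 0)
    ph$follow_up_years <- fu[ph$sample_id]
    ph$n_edss_scores <- ne[ph$sample_id]
  }
  num_cols <- setdiff(names(ph)[vapply(ph, is.numeric, TRUE)], "sample_id")
  rows <- list()
  for (col in num_cols) {
    x_mild <- ph[[col]][ph$label == "mild"]
    x_sev <- ph[[col]][ph$label == "severe"]
    d <- cohens_d(x_mild, x_sev)
    for (grp in c("mild", "severe", "all")) {
      x <- if (grp == "all") ph[[col]] else ph[[col]][ph$label == grp]
      x <- x[!is.na(x)]
      q <- if (length(x)) quantile(x, c(.25, .5, .75), type = 7, names = FALSE) else rep(NA_real_, 3)
      rows[[length(rows) + 1]] <- data.frame(
        characteristic = col, group = grp, n = length(x),
        median = q[2], q1 = q[1], q3 = q[3],
        min = if (length(x)) min(x) else NA_real_,
        max = if (length(x)) max(x) else NA_real_,
        cohens_d = d, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Longitudinal phenotyping of a whole cohort
#'
#' Applies [longitudinal_armss()] per sample and [classify_severity()]
#' across the resulting medians.
#'
#' @param histories Data frame of visits with a `sample_id` column.
#' @param ref An [armss_reference()].
#' @return Data frame with `sample_id`, `median_armss`, `n_scores_used`,
#'   `follow_up_years`, `label`.
#' @export
phenotype_cohort <- function(histories, ref) {
  sp <- split(histories, histories$sample_id)
  res <- lapply(sp, longitudinal_armss, ref = ref)
  out <- data.frame(
    sample_id = names(sp),
    median_armss = vapply(res, `[[`, 0, "median_armss"),
    n_scores_used = vapply(res, `[[`, 0, "n_scores_used"),
    follow_up_years = vapply(res, `[[`, 0, "follow_up_years"),
    stringsAsFactors = FALSE
  )
  out$label <- classify_severity(out$median_armss)
  rownames(out) <- NULL
  out
}
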
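#' Probe-level quality and annotation filtering
#'
#' Removes probes failing any of six rules, attributing each removed
#' probe to the first rule that catches it (so report counts sum to the
#' total removed):
#' 1. detection p-value > 0.01 in >= 5% of samples,
#' 2. bead count < 3 in >= 5% of samples,
#' 3. non-CpG probes,
#' 4. SNP-related probes,
#' 5. multi-hit probes,
#' 6. non-autosomal probes.
#'
#' @param m A [methylation_matrix()] with `detection_p` and `bead_count`.
#' @param ann A [probe_annotation()] covering every probe in `m`.
#' @param detection_p_max Detection p-value threshold (default 0.01).
#' @param fail_fraction Fraction of samples at which a probe fails
#'   (default 0.05, inclusive bound).
#' @param min_beads Minimum bead count (default 3).
#' @return List with `matrix` (filtered [methylation_matrix()]) and
#'   `report` (named removal counts per rule plus `total`).
#' @export
filter_probes <- function(m, ann, detection_p_max = 0.01,
                          fail_fraction = 0.05, min_beads = 3) {
  stopifnot(inherits(m, "methylation_matrix"))
  if (is.null(m$detection_p) || is.null(m$bead_count)) {
    stop("detection_p and bead_count are required for probe filtering")
  }
  probes <- rownames(m$beta)
  missing <- setdiff(probes, ann$probe_id)
  if (length(missing)) {
    stop("annotation missing for probes: ", paste(missing, collapse = ", "))
  }
  a <- ann[match(probes, ann$probe_id), ]
  fails <- list(
    detection_p = rowMeans(m$detection_p > detection_p_max) >= fail_fraction,
    bead_count = rowMeans(m$bead_count < min_beads) >= fail_fraction,
    non_cpg = a$non_cpg,
    snp_related = a$snp_related,
    multi_hit = a$multi_hit,
    non_autosomal = !a$autosomal
  )
  removed <- rep(FALSE, length(probes))
  report <- integer(length(fails))
  names(report) <- names(fails)
  for (rule in names(fails)) {
    hit <- fails[[rule]] & !removed
    report[rule] <- sum(hit)
    removed <- removed | fails[[rule]]
  }
  out <- subset_methylation(m, probes = probes[!removed])
  list(matrix = out, report = c(as.list(report), total = sum(removed)))
}

#' Sample-level quality filtering
#'
#' A sample is removed when its failed-to-successful probe ratio exceeds
#' 0.1: (number of probes with detection p > 0.01) / (number passing).
#'
#' @inheritParams filter_probes
#' @param max_ratio Failed/successful ratio threshold (default 0.1,
#'   strict).
#' @return List with `matrix` (filtered) and `removed` (sample ids).
#' @export
filter_samples <- function(m, detection_p_max = 0.01, max_ratio = 0.1) {
  stopifnot(inherits(m, "methylation_matrix"))
  if (is.null(m$detection_p)) stop("detection_p is required")
  n_fail <- colSums(m$detection_p > detection_p_max)
  n_pass <- nrow(m$beta) - n_fail
  ratio <- n_fail / n_pass
  drop <- ratio > max_ratio
  if (all(drop)) stop("all samples removed by quality filtering")
  list(
    matrix = subset_methylation(m, samples = colnames(m$beta)[!drop]),
    removed = colnames(m$beta)[drop]
  )
}

#' SVD-based detection of technical variation
#'
#' Row-centres the M-value matrix, takes its singular value
#' decomposition, and tests each of the top components against each
#' technical factor: one-way ANOVA for categorical factors, a Pearson
#' correlation test for continuous ones. Pairs with p < `p_flag` are
#' flagged as significant sources of technical variation. Constant
#' factors are skipped with a note.
#'
#' @param m A [methylation_matrix()] or beta matrix.
#' @param technical_factors Data frame, one row per sample, of candidate
#'   technical factors (plate, chip, position, ...).
#' @param n_components Number of leading components to test (default 10).
#' @param p_flag Flagging threshold (default 0.01).
#' @return Data frame with columns `component`, `factor`, `p_value`,
#'   `flagged`, `note`.
#' @export
svd_batch_detect <- function(m, technical_factors, n_components = 10,
                             p_flag = 0.01) {
  mv <- get_m(m)
  stopifnot(nrow(technical_factors) == ncol(mv))
  centred <- mv - rowMeans(mv)
  k <- min(n_components, ncol(mv) - 1, nrow(mv))
  sv <- svd(centred, nu = 0, nv = k)
  rows <- list()
  for (f in names(technical_factors)) {
    x <- technical_factors[[f]]
    categorical <- is.character(x) || is.factor(x) || is.logical(x)
    constant <- length(unique(x[!is.na(x)])) < 2
    for (comp in seq_len(k)) {
      v <- sv$v[, comp]
      if (constant) {
        rows[[length(rows) + 1]] <- data.frame(
          component = comp, factor = f, p_value = NA_real_,
          flagged = FALSE, note = "constant factor skipped",
          stringsAsFactors = FALSE
        )
        next
      }
      p <- if (categorical) {
        xf <- factor(x)
        if (any(table(xf) < 2)) {
          rows[[length(rows) + 1]] <- data.frame(
            component = comp, factor = f, p_value = NA_real_,
            flagged = FALSE, note = "level with < 2 samples skipped",
            stringsAsFactors = FALSE
          )
          next
        }
        anova(aov(v ~ xf))[["Pr(>F)"]][1]
      } else {
        cor.test(v, as.numeric(x))$p.value
      }
      rows[[length(rows) + 1]] <- data.frame(
        component = comp, factor = f, p_value = p,
        flagged = is.finite(p) && p < p_flag, note = "",
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Empirical-Bayes batch correction on M-values
#'
#' Parametric ComBat location/scale adjustment applied on the M-value
#' scale, with the corrected matrix mapped back to beta values. Requires
#' at least two batches with at least two samples each (the shrinkage
#' estimates are undefined for singleton batches).
#'
#' @param m A [methylation_matrix()] or beta matrix.
#' @param batch Factor or character vector of batch labels per sample.
#' @return Corrected matrix of the same class as the input.
#' @export
combat_correct <- function(m, batch) {
  beta <- get_beta(m)
  batch <- factor(batch)
  if (nlevels(batch) < 2) stop("at least two batches required")
  if (any(table(batch) < 2)) {
    stop("every batch needs >= 2 samples (shrinkage undefined for singletons)")
  }
  mv <- beta_to_m(beta)
  # constant probes break the standardization step; pass through untouched
  keep <- apply(mv, 1, function(x) var(x) > 0)
  corrected <- mv
  utils::capture.output(
    corrected[keep, ] <- sva::ComBat(
      dat = mv[keep, , drop = FALSE], batch = batch,
      par.prior = TRUE, prior.plots = FALSE
    )
  )
  out_beta <- m_to_beta(corrected)
  if (inherits(m, "methylation_matrix")) {
    methylation_matrix(out_beta, design_type = m$design_type,
                       detection_p = m$detection_p, bead_count = m$bead_count)
  } else {
    out_beta
  }
}
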
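#' Clip beta values away from 0 and 1
#'
#' M-values are only finite for beta strictly inside (0, 1), so beta values
#' are clipped to `[eps, 1 - eps]` before any logit transform.
#'
#' @param beta Numeric vector or matrix of methylation beta values.
#' @param eps Clipping margin (default 1e-6).
#' @return Object of the same shape with values in `[eps, 1 - eps]`.
#' @export
clip_beta <- function(beta, eps = 1e-6) {
  pmin(pmax(beta, eps), 1 - eps)
}

#' Convert beta values to M-values
#'
#' M = log2(beta / (1 - beta)). Values are clipped to `[eps, 1 - eps]`
#' first so the transform is finite; on the clipped domain it is a
#' bijection and [m_to_beta()] inverts it.
#'
#' @inheritParams clip_beta
#' @return M-values, same shape as `beta`.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]")
  }
  b <- clip_beta(beta, eps)
  log2(b / (1 - b))
}

#' Convert M-values back to beta values
#'
#' @param m Numeric vector or matrix of M-values.
#' @return Beta values in (0, 1), same shape as `m`.
#' @export
m_to_beta <- function(m) {
  2^m / (1 + 2^m)
}

#' Construct a methylation matrix container
#'
#' Bundles a probes x samples beta matrix with the per-probe assay design
#' type and per-entry quality metrics (detection p-values, bead counts)
#' used by the filtering stage. Only `beta` is required.
#'
#' @param beta Numeric matrix, probes in rows and samples in columns, with
#'   dimnames; values in `[0, 1]` (clipped internally to (0, 1)).
#' @param design_type Optional character vector per probe, `"I"` or `"II"`.
#' @param detection_p Optional matrix of detection p-values, same dim as
#'   `beta`.
#' @param bead_count Optional integer matrix of bead counts, same dim.
#' @return An object of class `methylation_matrix` (a list).
#' @export
methylation_matrix <- function(beta, design_type = NULL, detection_p = NULL,
                               bead_count = NULL) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("beta must have probe rownames and sample colnames")
  }
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]")
  }
  beta <- clip_beta(beta)
  check_dim <- function(x, nm) {
    if (!is.null(x) && !identical(dim(x), dim(beta))) {
      stop(sprintf("%s must have the same dimensions as beta", nm))
    }
    x
  }
  if (!is.null(design_type)) {
    design_type <- as.character(design_type)
    if (length(design_type) != nrow(beta)) {
      stop("design_type must have one entry per probe")
    }
    if (!all(design_type %in% c("I", "II"))) {
      stop("design_type entries must be \"I\" or \"II\"")
    }
  }
  structure(
    list(
      beta = beta,
      design_type = design_type,
      detection_p = check_dim(detection_p, "detection_p"),
      bead_count = check_dim(bead_count, "bead_count")
    ),
    class = "methylation_matrix"
  )
}

#' @export
print.methylation_matrix <- function(x, ...) {
  cat(sprintf(
    "<methylation_matrix> %d probes x %d samples\n",
    nrow(x$beta), ncol(x$beta)
  ))
  if (!is.null(x$design_type)) {
    tab <- table(x$design_type)
    cat("  design types:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract the beta matrix from a methylation container or plain matrix
#'
#' @param x A `methylation_matrix` or a plain numeric matrix.
#' @return The beta matrix.
#' @export
get_beta <- function(x) {
  if (inherits(x, "methylation_matrix")) x$beta else as.matrix(x)
}

#' M-value view of a methylation matrix
#'
#' @param x A `methylation_matrix` or plain beta matrix.
#' @return Matrix of M-values.
#' @export
get_m <- function(x) {
  beta_to_m(get_beta(x))
}

# Replace the beta matrix, keeping quality slots aligned to surviving rows
# and columns.
subset_methylation <- function(x, probes = NULL, samples = NULL) {
  stopifnot(inherits(x, "methylation_matrix"))
  pr <- if (is.null(probes)) rownames(x$beta) else probes
  sm <- if (is.null(samples)) colnames(x$beta) else samples
  idx_p <- match(pr, rownames(x$beta))
  idx_s <- match(sm, colnames(x$beta))
  methylation_matrix(
    beta = x$beta[idx_p, idx_s, drop = FALSE],
    design_type = x$design_type[idx_p],
    detection_p = if (!is.null(x$detection_p)) x$detection_p[idx_p, idx_s, drop = FALSE],
    bead_count = if (!is.null(x$bead_count)) x$bead_count[idx_p, idx_s, drop = FALSE]
  )
}

#' Construct a probe annotation table
#'
#' @param probe_id Character probe identifiers.
#' @param chromosome Chromosome labels (e.g. `"1"`..`"22"`, `"X"`).
#' @param position 1-based base-pair positions.
#' @param gene Gene symbol, `""` for intergenic probes.
#' @param feature Genomic feature class (`TSS200`, `TSS1500`, `body`,
#'   `3'UTR`, `IGR`, ...).
#' @param cgi_context One of `island`, `shore`, `shelf`, `opensea`.
#' @param non_cpg,snp_related,multi_hit Logical per-probe exclusion flags.
#' @param autosomal Logical; `TRUE` for probes on chromosomes 1-22.
#' @return A data frame of class `probe_annotation`.
#' @export
probe_annotation <- function(probe_id, chromosome, position, gene = "",
                             feature = "IGR", cgi_context = "opensea",
                             non_cpg = FALSE, snp_related = FALSE,
                             multi_hit = FALSE,
                             autosomal = chromosome %in% as.character(1:22)) {
  if (any(position <= 0)) stop("positions must be positive")
  ok_ctx <- c("island", "shore", "shelf", "opensea")
  if (!all(cgi_context %in% ok_ctx)) {
    stop("cgi_context must be one of: ", paste(ok_ctx, collapse = ", "))
  }
  out <- data.frame(
    probe_id = as.character(probe_id),
    chromosome = as.character(chromosome),
    position = as.integer(position),
    gene = gene,
    feature = feature,
    cgi_context = cgi_context,
    non_cpg = non_cpg,
    snp_related = snp_related,
    multi_hit = multi_hit,
    autosomal = autosomal,
    stringsAsFactors = FALSE
  )
  class(out) <- c("probe_annotation", "data.frame")
  out
}
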
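#' Select cell-type marker probes from reference profiles
#'
#' For each cell type, ranks probes by how far that type's reference beta
#' lies from the mean of the other types and keeps the top
#' `n_per_type`; the union over types is returned.
#'
#' @param reference Marker-candidate probes x cell types beta matrix.
#' @param n_per_type Markers per cell type (default 100).
#' @return Character vector of marker probe ids.
#' @export
select_markers <- function(reference, n_per_type = 100) {
  stopifnot(!is.null(rownames(reference)))
  picked <- character(0)
  for (k in seq_len(ncol(reference))) {
    contrast <- abs(reference[, k] - rowMeans(reference[, -k, drop = FALSE]))
    picked <- union(picked,
                    rownames(reference)[order(contrast, decreasing = TRUE)][seq_len(min(n_per_type, nrow(reference)))])
  }
  picked
}

#' Reference-based estimation of leukocyte proportions
#'
#' Whole-blood methylation is modelled per sample as a non-negative
#' mixture of cell-type reference profiles: beta values at marker probes
#' are fitted onto the reference columns by non-negative least squares
#' and the solution is renormalized to sum to one.
#'
#' @param beta Probes x samples beta matrix or [methylation_matrix()].
#' @param reference Probes x cell types reference beta profiles.
#' @param markers Optional probe ids to restrict the fit to; default
#'   [select_markers()] on the reference.
#' @return Samples x cell types matrix of proportions (rows sum to 1).
#' @export
estimate_proportions <- function(beta, reference, markers = NULL) {
  b <- get_beta(beta)
  if (is.null(markers)) markers <- select_markers(reference)
  markers <- intersect(markers, intersect(rownames(b), rownames(reference)))
  if (length(markers) < ncol(reference)) {
    stop("need at least as many marker probes as cell types")
  }
  R <- reference[markers, , drop = FALSE]
  qrR <- qr(R)
  if (qrR$rank < ncol(R)) {
    bad <- colnames(R)[qrR$pivot[(qrR$rank + 1):ncol(R)]]
    stop("reference is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  props <- t(apply(b[markers, , drop = FALSE], 2, function(y) {
    w <- pracma::lsqnonneg(R, y)$x
    if (sum(w) == 0) rep(1 / ncol(R), ncol(R)) else w / sum(w)
  }))
  dimnames(props) <- list(colnames(b), colnames(reference))
  props
}

#' Compare estimated cell proportions between severity groups
#'
#' Per cell type, a two-sample t-test when both groups pass a
#' Shapiro-Wilk normality check (p > 0.05), otherwise a Wilcoxon
#' rank-sum test; BH adjustment across cell types.
#'
#' @param proportions Samples x cell types matrix.
#' @param labels `mild`/`severe` per sample.
#' @return Data frame with `cell_type`, `test`, `mean_mild`,
#'   `mean_severe`, `p_value`, `fdr`.
#' @export
compare_proportions <- function(proportions, labels) {
  labels <- factor(as.character(labels), levels = c("mild", "severe"))
  rows <- lapply(colnames(proportions), function(ct) {
    x <- proportions[labels == "mild", ct]
    y <- proportions[labels == "severe", ct]
    normal <- function(v) {
      length(v) >= 3 && var(v) > 0 && shapiro.test(v)$p.value > 0.05
    }
    if (normal(x) && normal(y)) {
      tst <- t.test(x, y)
      data.frame(cell_type = ct, test = "t", mean_mild = mean(x),
                 mean_severe = mean(y), p_value = tst$p.value,
                 stringsAsFactors = FALSE)
    } else {
      tst <- suppressWarnings(wilcox.test(x, y))
      data.frame(cell_type = ct, test = "wilcoxon", mean_mild = mean(x),
                 mean_severe = mean(y), p_value = tst$p.value,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p_value)
  out
}

#' Cell-type-specific differential methylation (csDMPs)
#'
#' Per probe, fits a linear model of the M-value on all cell-type
#' proportions and their interactions with severity, without an
#' intercept (the proportions sum to one, so they absorb it and the
#' design stays full rank with an interaction coefficient for every cell
#' type):
#' `M ~ 0 + w_1 + ... + w_K + w_1:severe + ... + w_K:severe`.
#' The Wald p-value of each interaction term tests cell-type-specific
#' differential methylation; type k is called a csDMP carrier when its
#' interaction p-value is at or below the genome-wide threshold `alpha`.
#' Probes whose design is collinear (e.g. constant proportions) are
#' skipped with a flag.
#'
#' @param m Probes x samples M-value matrix (see [get_m()]).
#' @param proportions Samples x cell types matrix, rows summing to 1.
#' @param labels `mild`/`severe` per sample.
#' @param alpha Genome-wide significance threshold (default 9e-8,
#'   inclusive).
#' @return List with `stats` (long data frame: `probe_id`, `cell_type`,
#'   `estimate`, `p_value`, `csdmp`) and `skipped` (probe ids with
#'   collinear designs).
#' @export
cell_specific_dmps <- function(m, proportions, labels, alpha = 9e-8) {
  labels <- factor(as.character(labels), levels = c("mild", "severe"))
  sev <- as.integer(labels == "severe")
  W <- as.matrix(proportions)
  K <- ncol(W)
  X <- cbind(W, W * sev)
  colnames(X) <- c(colnames(W), paste0(colnames(W), ":severe"))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    # degenerate design (e.g. constant proportions): nothing testable
    return(list(
      stats = data.frame(probe_id = character(0), cell_type = character(0),
                         estimate = numeric(0), p_value = numeric(0),
                         csdmp = logical(0)),
      skipped = rownames(m)
    ))
  }
  xtx_inv <- chol2inv(chol(crossprod(X)))
  hat <- xtx_inv %*% t(X)
  df <- ncol(m) - ncol(X)
  rows <- vector("list", nrow(m))
  skipped <- character(0)
  for (i in seq_len(nrow(m))) {
    yv <- m[i, ]
    bhat <- drop(hat %*% yv)
    res <- yv - drop(X %*% bhat)
    s2 <- sum(res^2) / df
    se <- sqrt(s2 * diag(xtx_inv))
    tstat <- bhat / se
    p <- 2 * stats::pt(-abs(tstat), df = df)
    j <- K + seq_len(K)  # interaction columns
    rows[[i]] <- data.frame(
      probe_id = rownames(m)[i],
      cell_type = colnames(W),
      estimate = bhat[j],
      p_value = p[j],
      csdmp = p[j] <= alpha,
      stringsAsFactors = FALSE
    )
  }
  stats <- do.call(rbind, rows)
  rownames(stats) <- NULL
  list(stats = stats, skipped = skipped)
}
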
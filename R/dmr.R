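#' Proximity/direction-based DMR calling
#'
#' Kernel-based region finders can miss regions in studies with small
#' effect sizes, so regions are called directly from the DMP list:
#' probes passing a stringent FDR cut are sorted by genomic position and
#' chained into maximal runs in which every adjacent pair is at most
#' `max_gap` bp apart and shares the same effect direction; a sign flip
#' splits the run at the flip. Runs of at least `min_cpgs` members are
#' emitted, with region bounds at the first and last member positions and
#' width defined as `end - start`.
#'
#' @param dmps Data frame with columns `probe_id`, `chromosome`,
#'   `position`, `delta_meth`, `fdr` (e.g. a `dmp_result` joined to its
#'   annotation; see [add_positions()]).
#' @param max_gap Maximum adjacent-member gap in bp (default 1000,
#'   inclusive).
#' @param min_cpgs Minimum members per region (default 2).
#' @param fdr_max FDR threshold for member probes (default 0.01, strict).
#' @return Data frame of class `dmr_result`: `chromosome`, `start_bp`,
#'   `end_bp`, `width`, `n_cpgs`, `max_delta` (signed value of the member
#'   with largest magnitude), `mean_delta`, `member_probes`
#'   (comma-separated ids).
#' @export
call_dmrs <- function(dmps, max_gap = 1000, min_cpgs = 2, fdr_max = 0.01) {
  need <- c("probe_id", "chromosome", "position", "delta_meth", "fdr")
  if (!all(need %in% names(dmps))) {
    stop("dmps must have columns: ", paste(need, collapse = ", "))
  }
  sig <- dmps[dmps$fdr < fdr_max, , drop = FALSE]
  out <- list()
  for (ch in unique(sig$chromosome)) {
    d <- sig[sig$chromosome == ch, , drop = FALSE]
    d <- d[order(d$position), , drop = FALSE]
    if (anyDuplicated(d$position)) {
      stop("duplicate probe positions on chromosome ", ch)
    }
    if (nrow(d) < min_cpgs) next
    gap_ok <- diff(d$position) <= max_gap
    sign_ok <- diff(sign(d$delta_meth)) == 0
    breaks <- c(0, which(!(gap_ok & sign_ok)), nrow(d))
    for (k in seq_len(length(breaks) - 1)) {
      idx <- (breaks[k] + 1):breaks[k + 1]
      if (length(idx) < min_cpgs) next
      r <- d[idx, , drop = FALSE]
      out[[length(out) + 1]] <- data.frame(
        chromosome = ch,
        start_bp = min(r$position),
        end_bp = max(r$position),
        width = max(r$position) - min(r$position),
        n_cpgs = nrow(r),
        max_delta = r$delta_meth[which.max(abs(r$delta_meth))],
        mean_delta = mean(r$delta_meth),
        member_probes = paste(r$probe_id, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    chromosome = character(0), start_bp = integer(0), end_bp = integer(0),
    width = integer(0), n_cpgs = integer(0), max_delta = numeric(0),
    mean_delta = numeric(0), member_probes = character(0)
  )
  class(res) <- c("dmr_result", "data.frame")
  res
}

#' Join genomic coordinates onto a DMP result
#'
#' @param dmps A `dmp_result` data frame.
#' @param ann A [probe_annotation()].
#' @return `dmps` with `chromosome`, `position`, `gene`, `feature`,
#'   `cgi_context` columns added.
#' @export
add_positions <- function(dmps, ann) {
  i <- match(dmps$probe_id, ann$probe_id)
  if (anyNA(i)) {
    stop("annotation missing for: ",
         paste(dmps$probe_id[is.na(i)], collapse = ", "))
  }
  dmps$chromosome <- ann$chromosome[i]
  dmps$position <- ann$position[i]
  dmps$gene <- ann$gene[i]
  dmps$feature <- ann$feature[i]
  dmps$cgi_context <- ann$cgi_context[i]
  dmps
}

#' Export DMRs as a BED-like table
#'
#' BED convention is 0-based half-open, so `bed_start = start_bp - 1`;
#' the 1-based inclusive columns are retained alongside.
#'
#' @param dmrs A `dmr_result` data frame.
#' @return Data frame with BED columns (`chrom`, `chromStart`,
#'   `chromEnd`, `name`, `n_cpgs`, `strand`, `max_delta`, `mean_delta`)
#'   plus `start_1based`, `end_1based`.
#' @export
dmrs_to_bed <- function(dmrs) {
  data.frame(
    chrom = paste0("chr", dmrs$chromosome),
    chromStart = dmrs$start_bp - 1L,
    chromEnd = dmrs$end_bp,
    name = sprintf("DMR_%s_%d", dmrs$chromosome, dmrs$start_bp),
    n_cpgs = dmrs$n_cpgs,
    strand = ".",
    max_delta = dmrs$max_delta,
    mean_delta = dmrs$mean_delta,
    start_1based = dmrs$start_bp,
    end_1based = dmrs$end_bp,
    stringsAsFactors = FALSE
  )
}
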
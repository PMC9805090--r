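# Exact Hardy-Weinberg test (Wigginton-style enumeration of heterozygote
# counts conditional on allele counts), used when expected genotype
# counts are small.
hwe_exact_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_A <- 2 * n_AA + n_Aa
  rare <- min(n_A, 2 * n - n_A)
  het_vals <- seq(rare %% 2, rare, by = 2)
  logp <- vapply(het_vals, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(h + 1) - lgamma(hom_r + 1) - lgamma(hom_c + 1) +
      h * log(2) + lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  }, 0)
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- probs[match(n_Aa, het_vals)]
  sum(probs[probs <= obs + 1e-12])
}

#' Hardy-Weinberg equilibrium test
#'
#' Chi-square test with one degree of freedom against the genotype
#' counts expected from the observed allele frequencies; when the
#' smallest expected count is below 5 (and `exact = "auto"`), an exact
#' enumeration test is used instead.
#'
#' @param n_AA,n_Aa,n_aa Observed genotype counts.
#' @param exact `"auto"` (default), `"never"` or `"always"`.
#' @return List with `p_value`, `chisq` (NA for the exact branch),
#'   `method`.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa, exact = c("auto", "never", "always")) {
  exact <- match.arg(exact)
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("zero total genotype count")
  p <- (2 * n_AA + n_Aa) / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  use_exact <- exact == "always" ||
    (exact == "auto" && min(expected) < 5)
  if (use_exact) {
    return(list(p_value = hwe_exact_p(n_AA, n_Aa, n_aa), chisq = NA_real_,
                method = "exact"))
  }
  if (any(expected == 0)) {
    return(list(p_value = 1, chisq = 0, method = "chisq"))
  }
  chisq <- sum((c(n_AA, n_Aa, n_aa) - expected)^2 / expected)
  list(p_value = pchisq(chisq, df = 1, lower.tail = FALSE), chisq = chisq,
       method = "chisq")
}

snv_maf <- function(g) {
  g <- g[!is.na(g)]
  if (!length(g)) return(NA_real_)
  f <- mean(g) / 2
  min(f, 1 - f)
}

#' Genotype quality control
#'
#' SNVs are dropped by five rules applied in order (each SNV attributed
#' to the first rule that catches it): call rate < 95%, minor allele
#' frequency < 0.05, Hardy-Weinberg violation (p < 1e-5), monomorphism,
#' and non-autosomal location. Samples with call rate < 95% over the
#' surviving SNVs are then dropped.
#'
#' @param genotypes Samples x SNVs matrix of allele counts 0/1/2 with
#'   `NA` for missing calls.
#' @param metadata Data frame with `snv_id`, `chromosome`, `position`
#'   rows matching the genotype columns.
#' @param call_rate_min,maf_min,hwe_p_min Thresholds (defaults 0.95,
#'   0.05, 1e-5; call rate and MAF are strict `<` exclusions).
#' @return List with `genotypes`, `metadata` (filtered), and `report`
#'   (removal counts per rule plus removed sample ids).
#' @export
genotype_qc <- function(genotypes, metadata, call_rate_min = 0.95,
                        maf_min = 0.05, hwe_p_min = 1e-5) {
  stopifnot(ncol(genotypes) == nrow(metadata))
  report <- c(call_rate = 0L, maf = 0L, hwe = 0L, monomorphic = 0L,
              non_autosomal = 0L)
  removed <- rep(FALSE, ncol(genotypes))
  rule <- function(name, hit) {
    hit <- hit & !removed
    report[name] <<- sum(hit)
    removed <<- removed | hit
  }
  call_rate <- colMeans(!is.na(genotypes))
  rule("call_rate", call_rate < call_rate_min)
  mafs <- apply(genotypes, 2, snv_maf)
  rule("maf", mafs < maf_min)
  hwe_p <- apply(genotypes, 2, function(g) {
    g <- g[!is.na(g)]
    if (!length(g)) return(1)
    hwe_test(sum(g == 0), sum(g == 1), sum(g == 2))$p_value
  })
  rule("hwe", hwe_p < hwe_p_min)
  rule("monomorphic", apply(genotypes, 2, function(g) {
    length(unique(g[!is.na(g)])) <= 1
  }))
  rule("non_autosomal", !metadata$chromosome %in% as.character(1:22))
  g2 <- genotypes[, !removed, drop = FALSE]
  meta2 <- metadata[!removed, , drop = FALSE]
  sample_cr <- if (ncol(g2)) rowMeans(!is.na(g2)) else rep(1, nrow(g2))
  keep_s <- sample_cr >= call_rate_min
  list(
    genotypes = g2[keep_s, , drop = FALSE],
    metadata = meta2,
    report = c(as.list(report), snvs_removed = sum(removed),
               samples_removed = list(rownames(genotypes)[!keep_s]))
  )
}

#' Find SNVs within a cis window of a CpG
#'
#' @param dmp_position 1-based position of the CpG.
#' @param dmp_chromosome Chromosome of the CpG.
#' @param snv_metadata Data frame with `snv_id`, `chromosome`,
#'   `position`.
#' @param window Half-window in bp (default 5000; the bound is
#'   inclusive, so a SNV exactly `window` bp away is kept).
#' @return Character vector of SNV ids.
#' @export
find_cis_snvs <- function(dmp_position, dmp_chromosome, snv_metadata,
                          window = 5000) {
  hit <- snv_metadata$chromosome == as.character(dmp_chromosome) &
    abs(snv_metadata$position - dmp_position) <= window
  snv_metadata$snv_id[hit]
}

#' Greedy linkage-disequilibrium pruning
#'
#' SNVs are visited in descending minor-allele-frequency order; a SNV is
#' kept unless its genotype vector is significantly correlated
#' (Pearson test p < `p_max`) with any already-kept SNV.
#'
#' @param genotypes Samples x candidate SNVs allele-count matrix.
#' @param p_max Correlation-test significance threshold (default 0.05).
#' @return Character vector of retained (independent) SNV ids.
#' @export
ld_prune <- function(genotypes, p_max = 0.05) {
  if (ncol(genotypes) == 0) return(character(0))
  mafs <- apply(genotypes, 2, snv_maf)
  order_idx <- order(mafs, decreasing = TRUE)
  kept <- integer(0)
  for (j in order_idx) {
    gj <- genotypes[, j]
    if (var(gj, na.rm = TRUE) == 0) next
    linked <- any(vapply(kept, function(k) {
      ct <- suppressWarnings(cor.test(gj, genotypes[, k]))
      is.finite(ct$p.value) && ct$p.value < p_max
    }, TRUE))
    if (!linked) kept <- c(kept, j)
  }
  colnames(genotypes)[sort(kept)]
}

#' Kruskal-Wallis mQTL test
#'
#' Tests whether methylation beta values differ across genotype classes
#' (0/1/2) with a tie-corrected Kruskal-Wallis rank test. Beta values
#' follow a bounded, typically non-normal distribution, which motivates
#' the rank test.
#'
#' @param beta_cpg Beta values at one CpG, one per sample.
#' @param genotypes Allele counts at one SNV, one per sample.
#' @return List with `p_value`, `statistic`, `df`; p is `NA` with a note
#'   when only one genotype class is present.
#' @export
mqtl_test <- function(beta_cpg, genotypes) {
  ok <- !is.na(beta_cpg) & !is.na(genotypes)
  g <- factor(genotypes[ok])
  if (nlevels(g) < 2) {
    return(list(p_value = NA_real_, statistic = NA_real_, df = NA_integer_,
                note = "only one genotype class present"))
  }
  kw <- kruskal.test(beta_cpg[ok], g)
  list(p_value = kw$p.value, statistic = unname(kw$statistic),
       df = unname(kw$parameter), note = "")
}

#' Genotype-adjusted severity association at a CpG
#'
#' Joint logistic regression of severity group on methylation and
#' genotype, reporting both Wald p-values; used to check whether a
#' methylation-severity association survives adjustment for a cis
#' genotype. A constant genotype column is dropped (reducing to the
#' unadjusted model) and separated fits fall back to a ridge-penalized
#' fit with a flag.
#'
#' @param labels `mild`/`severe` per sample.
#' @param beta_cpg Beta values at the CpG.
#' @param genotypes Allele counts at the SNV.
#' @return List with `methylation_p`, `genotype_p`, `flag`.
#' @export
adjusted_association <- function(labels, beta_cpg, genotypes) {
  labels <- factor(as.character(labels), levels = c("mild", "severe"))
  y <- as.integer(labels == "severe")
  if (var(genotypes, na.rm = TRUE) == 0) {
    r <- logistic_probe_test(beta_cpg, y)
    return(list(methylation_p = r$p, genotype_p = NA_real_,
                flag = paste0("genotype constant, dropped",
                              if (nzchar(r$flag)) paste0("; ", r$flag))))
  }
  X <- cbind(meth = beta_cpg, geno = genotypes)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm.fit(cbind(1, X), y, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) sep <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (sep || !fit$converged || any(abs(fit$coefficients[-1]) > 15)) {
    r <- ridge_logistic(X, y)
    return(list(methylation_p = unname(r$p[2]), genotype_p = unname(r$p[3]),
                flag = "separation_penalized"))
  }
  w <- fit$weights
  info <- t(cbind(1, X) * w) %*% cbind(1, X)
  se <- sqrt(diag(solve(info)))
  z <- fit$coefficients / se
  p <- 2 * pnorm(-abs(z))
  list(methylation_p = unname(p[2]), genotype_p = unname(p[3]), flag = "")
}

#' Targeted mQTL scan around major DMPs
#'
#' For each major DMP: collect SNVs in the cis window, prune them for
#' linkage disequilibrium, Kruskal-Wallis-test each independent SNV
#' against the probe's beta values, and fit the genotype-adjusted
#' severity model for the best SNV.
#'
#' @param beta Probes x samples beta matrix or [methylation_matrix()].
#' @param dmps Data frame of major DMPs with `probe_id`, `chromosome`,
#'   `position`.
#' @param genotypes Samples x SNVs allele-count matrix (post-QC).
#' @param snv_metadata SNV metadata data frame.
#' @param labels `mild`/`severe` per sample.
#' @param window Cis half-window in bp (default 5000).
#' @return Data frame with one row per tested CpG-SNV pair: `probe_id`,
#'   `snv_id`, `kw_p`, `adjusted_methylation_p`, `adjusted_genotype_p`.
#' @export
mqtl_scan <- function(beta, dmps, genotypes, snv_metadata, labels,
                      window = 5000) {
  b <- get_beta(beta)
  rows <- list()
  for (i in seq_len(nrow(dmps))) {
    pid <- dmps$probe_id[i]
    cis <- find_cis_snvs(dmps$position[i], dmps$chromosome[i],
                         snv_metadata, window)
    cis <- intersect(cis, colnames(genotypes))
    if (!length(cis)) next
    indep <- ld_prune(genotypes[, cis, drop = FALSE])
    for (s in indep) {
      kw <- mqtl_test(b[pid, ], genotypes[, s])
      adj <- adjusted_association(labels, b[pid, ], genotypes[, s])
      rows[[length(rows) + 1]] <- data.frame(
        probe_id = pid, snv_id = s, kw_p = kw$p_value,
        adjusted_methylation_p = adj$methylation_p,
        adjusted_genotype_p = adj$genotype_p,
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows)) do.call(rbind, rows) else data.frame(
    probe_id = character(0), snv_id = character(0), kw_p = numeric(0),
    adjusted_methylation_p = numeric(0), adjusted_genotype_p = numeric(0)
  )
}
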
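# Independent brute-force oracles used to cross-check the package against
# first-principles definitions. These deliberately avoid the code paths
# (and where possible the library routines) used by the implementation.

# Benjamini-Hochberg step-up from the definition: sort p ascending,
# raw_(i) = p_(i) * m / i, adjusted_(i) = min_{j >= i} raw_(j), capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  raw <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(raw)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# AUC by all-pairs counting: fraction of (severe, mild) pairs where the
# severe score is larger, ties counting one half.
oracle_auc <- function(scores, labels) {
  s <- scores[labels == "severe"]
  m <- scores[labels == "mild"]
  cmp <- outer(s, m, ">") + 0.5 * outer(s, m, "==")
  mean(cmp)
}

# Exhaustive-enumeration DMR oracle: within each chromosome, sort the
# FDR-passing probes by position and enumerate every contiguous index
# range; a range is valid when every adjacent pair is within max_gap and
# all effects share one sign. Validity is interval-closed, so the maximal
# valid ranges are disjoint; those with >= min_cpgs members are the DMRs.
oracle_dmrs <- function(dmps, max_gap = 1000, min_cpgs = 2, fdr_max = 0.01) {
  sig <- dmps[dmps$fdr < fdr_max, , drop = FALSE]
  out <- list()
  for (ch in unique(sig$chromosome)) {
    d <- sig[sig$chromosome == ch, , drop = FALSE]
    d <- d[order(d$position), , drop = FALSE]
    n <- nrow(d)
    valid <- function(i, j) {
      if (i < 1 || j > n || i >= j) return(i == j && i >= 1 && j <= n)
      idx <- i:j
      all(diff(d$position[idx]) <= max_gap) &&
        length(unique(sign(d$delta_meth[idx]))) == 1
    }
    for (i in seq_len(n)) {
      for (j in i:n) {
        if (j - i + 1 < min_cpgs) next
        if (!valid(i, j)) next
        maximal <- !( (i > 1 && valid(i - 1, j)) || (j < n && valid(i, j + 1)) )
        if (!maximal) next
        idx <- i:j
        out[[length(out) + 1]] <- data.frame(
          chromosome = ch,
          start_bp = d$position[i],
          end_bp = d$position[j],
          width = d$position[j] - d$position[i],
          n_cpgs = length(idx),
          member_probes = paste(d$probe_id[idx], collapse = ","),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out)) do.call(rbind, out) else data.frame(
    chromosome = character(0), start_bp = integer(0), end_bp = integer(0),
    width = integer(0), n_cpgs = integer(0), member_probes = character(0)
  )
}

# Tie-corrected Kruskal-Wallis statistic from hand-computed ranks.
oracle_kruskal <- function(x, g) {
  g <- factor(g)
  r <- rank(x)
  N <- length(x)
  rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(ni * (rbar - (N + 1) / 2)^2)
  ties <- table(x)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / C
  list(statistic = H,
       p_value = pchisq(H, df = nlevels(g) - 1, lower.tail = FALSE))
}

# Closed-form 1-df Hardy-Weinberg chi-square from allele frequencies.
oracle_hwe_chisq <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  p <- (2 * n_AA + n_Aa) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  chisq <- sum((c(n_AA, n_Aa, n_aa) - e)^2 / e)
  list(chisq = chisq, p_value = pchisq(chisq, df = 1, lower.tail = FALSE))
}
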
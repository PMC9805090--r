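# Ridge-penalized logistic fit by IRLS, used as a fallback when an
# unpenalized fit separates. Penalty applies to slopes only; Wald p-values
# come from the penalized information matrix.
ridge_logistic <- function(X, y, lambda = 0.05, max_iter = 50) {
  X <- cbind(`(Intercept)` = 1, X)
  pvec <- ncol(X)
  pen <- diag(c(0, rep(lambda, pvec - 1)), pvec)
  b <- rep(0, pvec)
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtw <- t(X * w)
    b_new <- solve(xtw %*% X + pen, xtw %*% z)
    if (max(abs(b_new - b)) < 1e-8) {
      b <- b_new
      break
    }
    b <- b_new
  }
  eta <- drop(X %*% b)
  mu <- 1 / (1 + exp(-eta))
  w <- pmax(mu * (1 - mu), 1e-10)
  info <- t(X * w) %*% X + pen
  se <- sqrt(diag(solve(info)))
  zstat <- drop(b) / se
  list(coef = drop(b), p = 2 * pnorm(-abs(zstat)))
}

# Logistic Wald p for the first predictor, with separation fallback.
# The predictor is standardized internally: the Wald p is invariant under
# linear rescaling, and it makes the |coef| separation heuristic (and the
# ridge penalty in the fallback) scale-free.
logistic_probe_test <- function(x, y, covariates = NULL) {
  x <- (x - mean(x)) / sd(x)
  X <- cbind(meth = x, covariates)
  sep <- FALSE
  fit <- withCallingHandlers(
    glm.fit(cbind(1, X), y, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
      }
      invokeRestart("muffleWarning")
    }
  )
  co <- fit$coefficients
  if (sep || !fit$converged || any(!is.finite(co)) || abs(co[2]) > 15) {
    r <- ridge_logistic(X, y)
    return(list(p = unname(r$p[2]), flag = "separation_penalized"))
  }
  # Wald p from the weighted QR of the final IRLS iteration
  w <- fit$weights
  info <- t(cbind(1, X) * w) %*% cbind(1, X)
  se <- sqrt(diag(solve(info)))
  z <- co / se
  list(p = unname(2 * pnorm(-abs(z[2]))), flag = "")
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment with monotonicity enforcement, order-preserving.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  p.adjust(p_values, method = "BH")
}

#' Per-CpG differential methylation between severity groups
#'
#' Default mode regresses severity group (logistic) on the probe's beta
#' value plus covariates and reports the Wald p-value of the methylation
#' coefficient; the alternative linear mode fits M-value ~ group +
#' covariates and reports the group coefficient's p-value. Either way the
#' effect size is the raw beta difference, severe mean minus mild mean,
#' so a positive delta means hypermethylated in the severe group.
#' Separated logistic fits fall back to a ridge-penalized fit and are
#' flagged; constant probes get p = 1. BH FDR is computed over all
#' probes tested.
#'
#' @param beta Probes x samples beta matrix or [methylation_matrix()].
#' @param labels Factor/character per sample: `mild` or `severe`.
#' @param covariates Optional numeric matrix/data frame of per-sample
#'   adjustment covariates (e.g. NK cell proportion).
#' @param method `"logistic"` (default) or `"linear"`.
#' @param major_delta Threshold for flagging major DMPs (default 0.05 on
#'   |delta| rounded to 3 decimals).
#' @return Data frame of class `dmp_result`: `probe_id`, `delta_meth`,
#'   `p_value`, `fdr`, `direction`, `is_major`, `flag`.
#' @export
test_dmps <- function(beta, labels, covariates = NULL,
                      method = c("logistic", "linear"), major_delta = 0.05) {
  method <- match.arg(method)
  b <- get_beta(beta)
  labels <- factor(as.character(labels), levels = c("mild", "severe"))
  if (nlevels(droplevels(labels)) != 2) stop("two groups (mild, severe) required")
  if (length(labels) != ncol(b)) stop("one label per sample required")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != ncol(b)) {
      stop("covariates must be aligned to samples")
    }
  }
  y <- as.integer(labels == "severe")
  sev <- labels == "severe"
  delta <- rowMeans(b[, sev, drop = FALSE]) - rowMeans(b[, !sev, drop = FALSE])
  mv <- if (method == "linear") beta_to_m(b) else NULL
  p <- numeric(nrow(b))
  flag <- character(nrow(b))
  for (i in seq_len(nrow(b))) {
    x <- b[i, ]
    if (var(x) == 0) {
      p[i] <- 1
      flag[i] <- "constant"
      next
    }
    if (method == "logistic") {
      r <- logistic_probe_test(x, y, covariates)
      p[i] <- r$p
      flag[i] <- r$flag
    } else {
      X <- cbind(group = y, covariates)
      fit <- lm(mv[i, ] ~ X)
      sm <- summary(fit)$coefficients
      # group is the first predictor after the intercept
      p[i] <- sm[2, 4]
      flag[i] <- ""
    }
  }
  out <- data.frame(
    probe_id = rownames(b),
    delta_meth = unname(delta),
    p_value = p,
    fdr = bh_fdr(p),
    direction = ifelse(delta > 0, "hyper", "hypo"),
    is_major = round(abs(delta), 3) >= major_delta,
    flag = flag,
    stringsAsFactors = FALSE
  )
  class(out) <- c("dmp_result", "data.frame")
  out
}

#' Significance and effect-size filtering of DMP results
#'
#' Keeps probes with FDR strictly below `fdr_max` and |delta| strictly
#' above `min_delta`. Major DMPs are marked when |delta| rounded to three
#' decimals reaches `major_delta` (so a printed 0.050 counts as major).
#'
#' @param results A `dmp_result` data frame from [test_dmps()].
#' @param fdr_max FDR threshold (default 0.05, strict `<`).
#' @param min_delta Minimum |delta beta| (default 0.01, strict `>`).
#' @param major_delta Major-DMP threshold (default 0.05, `>=` after
#'   3-decimal rounding).
#' @return Filtered `dmp_result` data frame.
#' @export
filter_dmps <- function(results, fdr_max = 0.05, min_delta = 0.01,
                        major_delta = 0.05) {
  keep <- results$fdr < fdr_max & abs(results$delta_meth) > min_delta
  out <- results[keep, , drop = FALSE]
  out$is_major <- round(abs(out$delta_meth), 3) >= major_delta
  rownames(out) <- NULL
  out
}

#' CpG-island context and direction tallies for a DMP list
#'
#' @param dmps A `dmp_result` data frame (needs `probe_id`, `direction`).
#' @param ann A [probe_annotation()] covering every DMP.
#' @return List with `context` (count and percentage per CGI class) and
#'   `direction` (hypo/hyper counts and percentages); percentages rounded
#'   to one decimal.
#' @export
annotate_context <- function(dmps, ann) {
  missing <- setdiff(dmps$probe_id, ann$probe_id)
  if (length(missing)) {
    stop("annotation missing for: ", paste(missing, collapse = ", "))
  }
  n <- nrow(dmps)
  ctx_levels <- c("opensea", "shore", "shelf", "island")
  ctx <- factor(ann$cgi_context[match(dmps$probe_id, ann$probe_id)],
                levels = ctx_levels)
  ctx_tab <- table(ctx)
  dir_tab <- table(factor(dmps$direction, levels = c("hypo", "hyper")))
  pct <- function(k) if (n == 0) rep(0, length(k)) else round(100 * k / n, 1)
  list(
    context = data.frame(
      cgi_context = ctx_levels, n = as.integer(ctx_tab),
      pct = pct(as.integer(ctx_tab)), stringsAsFactors = FALSE
    ),
    direction = data.frame(
      direction = c("hypo", "hyper"), n = as.integer(dir_tab),
      pct = pct(as.integer(dir_tab)), stringsAsFactors = FALSE
    )
  )
}

#' Remove smoking-associated CpGs from a DMP list
#'
#' Smoking leaves a strong, well-catalogued methylation signature;
#' overlap with a user-supplied list of smoking-associated CpGs is
#' removed to avoid confounding.
#'
#' @param dmps A `dmp_result` data frame.
#' @param smoking_list Character vector of smoking-associated probe ids.
#' @return List with `retained` and `removed` `dmp_result` data frames.
#' @export
exclude_smoking_cpgs <- function(dmps, smoking_list) {
  hit <- dmps$probe_id %in% smoking_list
  list(
    retained = dmps[!hit, , drop = FALSE],
    removed = dmps[hit, , drop = FALSE]
  )
}

#' Greedy 1:1 age matching of mild to severe samples
#'
#' Repeatedly pairs the globally closest mild-severe age pair within the
#' cap, each sample used at most once; unmatched extras are dropped and
#' reported.
#'
#' @param phenotypes Data frame with `sample_id`, `label`, `age`.
#' @param max_age_diff Maximum allowed within-pair age difference in
#'   years (default 2).
#' @return Data frame with one row per pair: `mild_id`, `severe_id`,
#'   `age_diff`; unmatched sample ids in `attr(, "unmatched")`.
#' @export
match_pairs <- function(phenotypes, max_age_diff = 2) {
  mild <- phenotypes[phenotypes$label == "mild", ]
  sev <- phenotypes[phenotypes$label == "severe", ]
  pairs <- list()
  used_m <- rep(FALSE, nrow(mild))
  used_s <- rep(FALSE, nrow(sev))
  d <- abs(outer(mild$age, sev$age, "-"))
  repeat {
    d_open <- d
    d_open[used_m, ] <- Inf
    d_open[, used_s] <- Inf
    best <- which(d_open == min(d_open), arr.ind = TRUE)
    if (!length(best) || min(d_open) > max_age_diff) break
    i <- best[1, 1]
    j <- best[1, 2]
    pairs[[length(pairs) + 1]] <- data.frame(
      mild_id = mild$sample_id[i], severe_id = sev$sample_id[j],
      age_diff = d[i, j], stringsAsFactors = FALSE
    )
    used_m[i] <- TRUE
    used_s[j] <- TRUE
  }
  out <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(mild_id = character(0), severe_id = character(0),
               age_diff = numeric(0))
  attr(out, "unmatched") <- c(mild$sample_id[!used_m], sev$sample_id[!used_s])
  out
}

#' Matched-pair sensitivity analysis of covariate effects
#'
#' Mild and severe samples are 1:1 age-matched, the within-pair
#' methylation difference (severe minus mild) is computed at every probe,
#' and each covariate is tested for association with those differences:
#' Pearson correlation against the within-pair covariate difference for
#' continuous covariates, one-way ANOVA across the shared covariate level
#' for categorical covariates (restricted to pairs concordant on that
#' covariate). BH FDR is applied per covariate across probes.
#'
#' @param beta Probes x samples beta matrix or [methylation_matrix()].
#' @param phenotypes Data frame with `sample_id`, `label`, `age`.
#' @param covariates Data frame of per-sample covariates, rownames or a
#'   `sample_id` column aligned to samples.
#' @param max_age_diff Age-matching cap in years (default 2).
#' @return List with `pairs` (the matching) and `tests`, a named list per
#'   covariate of data frames `probe_id`, `p_value`, `fdr` (or a skip
#'   note for untestable categorical covariates).
#' @export
matched_pair_sensitivity <- function(beta, phenotypes, covariates,
                                     max_age_diff = 2) {
  b <- get_beta(beta)
  if (!is.null(covariates$sample_id)) {
    rownames(covariates) <- covariates$sample_id
    covariates$sample_id <- NULL
  }
  pairs <- match_pairs(phenotypes, max_age_diff = max_age_diff)
  if (nrow(pairs) < 3) stop("fewer than 3 matched pairs")
  delta <- b[, pairs$severe_id, drop = FALSE] - b[, pairs$mild_id, drop = FALSE]
  tests <- list()
  for (cv in names(covariates)) {
    x <- covariates[[cv]]
    names(x) <- rownames(covariates)
    if (is.numeric(x)) {
      dx <- x[pairs$severe_id] - x[pairs$mild_id]
      if (var(dx) == 0) {
        tests[[cv]] <- "skipped: constant covariate difference"
        next
      }
      n <- length(dx)
      r <- drop(cor(t(delta), dx))
      r <- pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)
      tstat <- r * sqrt((n - 2) / (1 - r^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
      tests[[cv]] <- data.frame(
        probe_id = rownames(b), p_value = p, fdr = bh_fdr(p),
        stringsAsFactors = FALSE
      )
    } else {
      concordant <- x[pairs$severe_id] == x[pairs$mild_id]
      lev <- x[pairs$severe_id][concordant]
      if (sum(concordant) < 3 || length(unique(lev)) < 2) {
        tests[[cv]] <- "skipped: too few concordant pairs or single level"
        next
      }
      dsub <- delta[, concordant, drop = FALSE]
      lev <- factor(lev)
      p <- apply(dsub, 1, function(dd) {
        anova(aov(dd ~ lev))[["Pr(>F)"]][1]
      })
      tests[[cv]] <- data.frame(
        probe_id = rownames(b), p_value = unname(p), fdr = bh_fdr(unname(p)),
        stringsAsFactors = FALSE
      )
    }
  }
  list(pairs = pairs, tests = tests)
}
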
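test_that("bh_fdr matches p.adjust and the step-up definition", {
  set.seed(2)
  p <- runif(50)
  expect_equal(bh_fdr(p), p.adjust(p, "BH"))
  expect_equal(bh_fdr(p), oracle_bh(p))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 1)),
               oracle_bh(c(0.01, 0.02, 0.03, 1)))
})

test_that("delta_meth is the severe-minus-mild mean beta difference", {
  b <- matrix(c(0.2, 0.2, 0.4, 0.4,
                0.6, 0.6, 0.5, 0.5), 2, 4, byrow = TRUE,
              dimnames = list(c("up", "down"), paste0("s", 1:4)))
  b <- b + matrix(rnorm(8, 0, 1e-3), 2, 4)  # break exact separation
  labels <- c("mild", "mild", "severe", "severe")
  res <- test_dmps(b, labels)
  expect_equal(res$delta_meth,
               rowMeans(b[, 3:4]) - rowMeans(b[, 1:2]),
               ignore_attr = TRUE)
  expect_identical(res$direction, c("hyper", "hypo"))
})

test_that("constant probes get p = 1 and a flag", {
  b <- matrix(c(rep(0.5, 6), runif(6)), 2, 6, byrow = TRUE,
              dimnames = list(c("const", "var"), paste0("s", 1:6)))
  res <- test_dmps(b, rep(c("mild", "severe"), each = 3))
  expect_equal(res$p_value[1], 1)
  expect_identical(res$flag[1], "constant")
})

test_that("test_dmps validates labels and covariate alignment", {
  b <- matrix(runif(8), 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
  expect_error(test_dmps(b, rep("mild", 4)), "two groups")
  expect_error(test_dmps(b, c("mild", "severe")), "one label per sample")
  expect_error(test_dmps(b, rep(c("mild", "severe"), 2),
                         covariates = matrix(0, 3, 1)), "aligned")
})

test_that("planted effects are detected and nulls are not (both modes)", {
  # n = 60 gives limited per-probe power; the study-scale sensitivity
  # floor lives in the acceptance suite
  co <- tiny_cohort()
  b <- get_beta(co$beta)
  for (mode in c("logistic", "linear")) {
    res <- filter_dmps(test_dmps(b, co$group, method = mode))
    hits <- res$probe_id
    expect_gte(mean(co$truth$dmp_ids %in% hits), 0.5)
    if (nrow(res) > 0) {
      expect_lte(mean(!hits %in% co$truth$dmp_ids), 0.2)
    }
  }
})

test_that("the linear mode p-value equals a direct lm fit", {
  co <- tiny_cohort()
  b <- get_beta(co$beta)[1:5, , drop = FALSE]
  age <- co$ages
  res <- test_dmps(b, co$group, covariates = cbind(age = age),
                   method = "linear")
  y <- as.integer(co$group == "severe")
  for (i in 1:5) {
    fit <- summary(lm(beta_to_m(b[i, ]) ~ y + age))
    expect_equal(res$p_value[i], fit$coefficients["y", 4], tolerance = 1e-12)
  }
})

test_that("the logistic mode p-value equals a direct glm Wald test", {
  co <- tiny_cohort()
  b <- get_beta(co$beta)
  # pick background probes so the fits are unseparated
  bg <- setdiff(rownames(b), co$truth$dmp_ids)[1:5]
  y <- as.integer(co$group == "severe")
  res <- test_dmps(b[bg, , drop = FALSE], co$group)
  for (i in seq_along(bg)) {
    x <- scale(b[bg[i], ])[, 1]
    fit <- summary(glm(y ~ x, family = binomial()))
    expect_equal(res$p_value[i], fit$coefficients["x", 4], tolerance = 1e-6)
  }
})

test_that("separated fits fall back to a flagged penalized fit", {
  x <- c(rnorm(10, 0.2, 0.01), rnorm(10, 0.8, 0.01))
  b <- matrix(clip_beta(x), 1, 20,
              dimnames = list("sep", paste0("s", 1:20)))
  res <- test_dmps(b, rep(c("mild", "severe"), each = 10))
  expect_identical(res$flag, "separation_penalized")
  expect_lt(res$p_value, 0.05)  # signal survives the penalty
})

test_that("filter_dmps uses strict thresholds and the 3-decimal major rule", {
  res <- data.frame(
    probe_id = paste0("p", 1:5),
    delta_meth = c(0.02, 0.01, 0.0495, 0.0494, -0.06),
    p_value = rep(0.001, 5),
    fdr = c(0.01, 0.01, 0.05, 0.01, 0.04),
    direction = c("hyper", "hyper", "hyper", "hyper", "hypo"),
    is_major = FALSE, flag = "", stringsAsFactors = FALSE
  )
  out <- filter_dmps(res)
  # p2 fails |delta| > 0.01 (strict), p3 fails fdr < 0.05 (strict)
  expect_setequal(out$probe_id, c("p1", "p4", "p5"))
  # 0.0494 rounds to 0.049 -> not major; 0.0495 would round to 0.05
  expect_identical(out$is_major[out$probe_id == "p4"], FALSE)
  expect_identical(out$is_major[out$probe_id == "p5"], TRUE)
  single <- filter_dmps(data.frame(
    probe_id = "q", delta_meth = 0.0495, p_value = 0.001, fdr = 0.01,
    direction = "hyper", is_major = FALSE, flag = "",
    stringsAsFactors = FALSE
  ))
  expect_identical(single$is_major, TRUE)
})

test_that("annotate_context tallies contexts and directions with 1-dp percents", {
  dmps <- data.frame(
    probe_id = paste0("p", 1:6),
    direction = c("hypo", "hypo", "hypo", "hyper", "hyper", "hyper"),
    stringsAsFactors = FALSE
  )
  ann <- probe_annotation(
    paste0("p", 1:6), "1", seq(100L, 600L, 100L),
    cgi_context = c("opensea", "opensea", "island", "shore", "shelf", "opensea")
  )
  out <- annotate_context(dmps, ann)
  expect_equal(out$context$n[out$context$cgi_context == "opensea"], 3)
  expect_equal(out$context$pct[out$context$cgi_context == "opensea"], 50)
  expect_equal(out$direction$n, c(3, 3))
  expect_equal(sum(out$context$n), 6)
  expect_error(annotate_context(dmps, ann[-1, ]), "annotation missing")
})

test_that("exclude_smoking_cpgs partitions the DMP list", {
  dmps <- data.frame(probe_id = c("a", "b", "c"), stringsAsFactors = FALSE)
  out <- exclude_smoking_cpgs(dmps, c("b", "zz"))
  expect_identical(out$retained$probe_id, c("a", "c"))
  expect_identical(out$removed$probe_id, "b")
})

test_that("match_pairs is globally greedy with an inclusive-use cap", {
  ph <- data.frame(
    sample_id = c("m1", "m2", "s1", "s2"),
    label = c("mild", "mild", "severe", "severe"),
    age = c(30, 31, 30.9, 33),
    stringsAsFactors = FALSE
  )
  pairs <- match_pairs(ph, max_age_diff = 2)
  # global closest pair is (m2, s1); (m1, s2) is 3 y apart and stays unmatched
  expect_identical(nrow(pairs), 1L)
  expect_identical(pairs$mild_id, "m2")
  expect_identical(pairs$severe_id, "s1")
  expect_setequal(attr(pairs, "unmatched"), c("m1", "s2"))
})

test_that("matched_pair_sensitivity detects a planted covariate association", {
  set.seed(9)
  n_pairs <- 40
  ids <- c(paste0("m", 1:n_pairs), paste0("s", 1:n_pairs))
  ph <- data.frame(
    sample_id = ids,
    label = rep(c("mild", "severe"), each = n_pairs),
    age = c(30 + 3 * (1:n_pairs), 30.5 + 3 * (1:n_pairs)),
    stringsAsFactors = FALSE
  )
  dose <- setNames(c(rep(0, n_pairs), runif(n_pairs, 0, 2)), ids)
  beta <- matrix(runif(3 * 2 * n_pairs, 0.3, 0.4), 3, 2 * n_pairs,
                 dimnames = list(paste0("p", 1:3), ids))
  # probe p1's severe-minus-mild difference tracks the dose difference
  beta["p1", paste0("s", 1:n_pairs)] <-
    beta["p1", paste0("m", 1:n_pairs)] + 0.1 * dose[paste0("s", 1:n_pairs)]
  covs <- data.frame(sample_id = ids, dose = unname(dose), sex = "F",
                     stringsAsFactors = FALSE)
  res <- matched_pair_sensitivity(beta, ph, covs)
  expect_identical(nrow(res$pairs), as.integer(n_pairs))
  dosed <- res$tests$dose
  expect_lt(dosed$fdr[dosed$probe_id == "p1"], 0.01)
  expect_gt(min(dosed$p_value[dosed$probe_id != "p1"]), 0.01)
  # single-level categorical covariates are skipped with a note
  expect_match(res$tests$sex, "skipped")
})
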
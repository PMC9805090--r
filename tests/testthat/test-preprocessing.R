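test_that("filter_probes removes by rule in order and the report sums", {
  mm <- handmade_matrix()
  ann <- handmade_annotation()
  res <- filter_probes(mm, ann)
  expect_identical(rownames(res$matrix$beta), "p5")
  rep <- res$report
  expect_identical(rep$detection_p, 1L)
  expect_identical(rep$bead_count, 1L)
  expect_identical(rep$non_cpg, 1L)
  expect_identical(rep$snp_related, 1L)
  expect_identical(rep$multi_hit, 0L)
  expect_identical(rep$non_autosomal, 1L)
  expect_identical(rep$total, 5L)
  # first-hit attribution: a probe failing two rules is counted once
  ann2 <- ann
  ann2$non_cpg[1] <- TRUE  # p1 also fails detection, listed first
  res2 <- filter_probes(mm, ann2)
  expect_identical(res2$report$detection_p, 1L)
  expect_identical(res2$report$non_cpg, 1L)  # still only p3
  expect_identical(res2$report$total, 5L)
})

test_that("filter_probes requires quality slots and full annotation", {
  b <- matrix(0.5, 2, 2, dimnames = list(c("p1", "p2"), c("s1", "s2")))
  expect_error(filter_probes(methylation_matrix(b), handmade_annotation()),
               "detection_p and bead_count")
  mm <- handmade_matrix()
  ann <- handmade_annotation()[-1, ]
  expect_error(filter_probes(mm, ann), "annotation missing")
})

test_that("the detection fail fraction bound is inclusive", {
  probes <- paste0("p", 1:2)
  samples <- paste0("s", 1:20)
  beta <- matrix(0.5, 2, 20, dimnames = list(probes, samples))
  detp <- matrix(0.001, 2, 20, dimnames = list(probes, samples))
  detp["p1", 1] <- 0.5  # exactly 5% of samples fail
  mm <- methylation_matrix(beta, detection_p = detp,
                           bead_count = matrix(10L, 2, 20, dimnames = list(probes, samples)))
  ann <- probe_annotation(probes, "1", c(100L, 200L))
  res <- filter_probes(mm, ann)
  expect_identical(res$report$detection_p, 1L)
})

test_that("filter_samples drops samples with fail ratio strictly above 0.1", {
  probes <- paste0("p", 1:11)
  samples <- c("good", "edge", "bad")
  beta <- matrix(0.5, 11, 3, dimnames = list(probes, samples))
  detp <- matrix(0.001, 11, 3, dimnames = list(probes, samples))
  detp[1, "edge"] <- 0.5       # 1 fail / 10 pass = 0.1, kept (strict >)
  detp[1:2, "bad"] <- 0.5      # 2 fail / 9 pass > 0.1, removed
  mm <- methylation_matrix(beta, detection_p = detp)
  res <- filter_samples(mm)
  expect_identical(res$removed, "bad")
  expect_identical(colnames(res$matrix$beta), c("good", "edge"))
})

test_that("svd_batch_detect flags a planted batch and not a null factor", {
  set.seed(11)
  n <- 40
  batch <- rep(c("A", "B"), each = n / 2)
  m <- matrix(rnorm(300 * n), 300, n,
              dimnames = list(paste0("p", 1:300), paste0("s", 1:n)))
  m[, batch == "B"] <- m[, batch == "B"] + 2
  fac <- data.frame(plate = batch, noise = rnorm(n))
  res <- svd_batch_detect(m_to_beta(m / 4), fac, n_components = 5)
  expect_true(any(res$flagged[res$factor == "plate" & res$component == 1]))
  expect_false(any(res$flagged[res$factor == "noise"], na.rm = TRUE))
  # constant factors are skipped with a note
  res2 <- svd_batch_detect(m_to_beta(m / 4), data.frame(k = rep("x", n)),
                           n_components = 2)
  expect_true(all(res2$note == "constant factor skipped"))
  expect_false(any(res2$flagged))
})

test_that("combat_correct equalizes planted batch means and contracts", {
  co <- simulate_cohort(tiny_config(batch_shift = c(0, 1.5)))
  batch <- co$truth$batch
  m_before <- get_m(co$beta)
  gap_before <- mean(m_before[, batch == "plate2"]) -
    mean(m_before[, batch == "plate1"])
  expect_gt(gap_before, 1)

  corrected <- combat_correct(co$beta, batch)
  m_after <- get_m(corrected)
  gap_after <- mean(m_after[, batch == "plate2"]) -
    mean(m_after[, batch == "plate1"])
  expect_lt(abs(gap_after), 0.05)
  # no component should associate with batch afterwards
  det <- svd_batch_detect(corrected, data.frame(batch = batch),
                          n_components = 5)
  expect_false(any(det$flagged))
  # second application changes far less than the batch effect it removed:
  # empirical-Bayes shrinkage leaves sampling-noise residuals, so exact
  # idempotence is not attainable, but the map must be strongly contractive
  twice <- combat_correct(corrected, batch)
  change2 <- max(abs(get_m(twice) - m_after))
  change1 <- max(abs(m_after - m_before))
  expect_lt(change2, change1 / 10)
})

test_that("combat_correct validates its batch argument", {
  co <- tiny_cohort()
  expect_error(combat_correct(co$beta, rep("A", length(co$group))),
               "two batches")
  b2 <- rep("A", length(co$group))
  b2[1] <- "B"
  expect_error(combat_correct(co$beta, b2), "singleton")
})

test_that("BMIQ leaves type-I probes untouched and output is valid", {
  co <- tiny_cohort()
  norm <- bmiq_normalize(co$beta)
  t1 <- co$beta$design_type == "I"
  expect_equal(norm$beta[t1, ], co$beta$beta[t1, ])
  expect_true(all(norm$beta > 0 & norm$beta < 1))
  expect_identical(norm$design_type, co$beta$design_type)
})

test_that("BMIQ is close to the identity when both designs share one distribution", {
  set.seed(5)
  p <- 600
  probes <- paste0("p", seq_len(p))
  state <- sample(c(0.1, 0.5, 0.9), p, replace = TRUE)
  beta <- clip_beta(matrix(state + rnorm(p * 4, 0, 0.04), p, 4,
                           dimnames = list(probes, paste0("s", 1:4))), 0.01)
  mm <- methylation_matrix(beta, design_type = rep(c("I", "II"), length.out = p))
  norm <- bmiq_normalize(mm)
  t2 <- mm$design_type == "II"
  dev <- abs(norm$beta[t2, ] - mm$beta[t2, ])
  expect_lt(mean(dev), 0.01)
  expect_lt(max(dev), 0.05)
})

test_that("BMIQ corrects a planted type-II compression toward type I", {
  set.seed(6)
  p <- 600
  probes <- paste0("p", seq_len(p))
  state <- sample(c(0.1, 0.5, 0.9), p, replace = TRUE)
  raw <- clip_beta(state + rnorm(p, 0, 0.04), 0.01)
  design <- rep(c("I", "II"), length.out = p)
  t2 <- design == "II"
  # compress type-II values toward 0.5, a caricature of the design bias
  raw[t2] <- 0.5 + 0.7 * (raw[t2] - 0.5)
  beta <- matrix(raw, p, 2, dimnames = list(probes, c("s1", "s2")))
  mm <- methylation_matrix(beta, design_type = design)
  norm <- bmiq_normalize(mm)
  # unmethylated-state type-II probes should move back down toward type I
  lowI <- mean(mm$beta[!t2 & state == 0.1, 1])
  low2_before <- mean(mm$beta[t2 & state == 0.1, 1])
  low2_after <- mean(norm$beta[t2 & state == 0.1, 1])
  expect_lt(abs(low2_after - lowI), abs(low2_before - lowI))
})

test_that("bmiq_normalize validates design information", {
  b <- matrix(0.5, 150, 2,
              dimnames = list(paste0("p", 1:150), c("s1", "s2")))
  expect_error(bmiq_normalize(methylation_matrix(b)), "design_type")
  mm <- methylation_matrix(b, design_type = c("I", rep("II", 149)))
  expect_error(bmiq_normalize(mm), ">= 100 probes")
})
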
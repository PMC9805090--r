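test_that("the HWE chi-square branch matches the closed form", {
  cases <- list(c(25, 50, 25), c(40, 40, 20), c(60, 30, 10), c(50, 0, 50))
  for (cs in cases) {
    got <- hwe_test(cs[1], cs[2], cs[3], exact = "never")
    want <- oracle_hwe_chisq(cs[1], cs[2], cs[3])
    expect_equal(got$chisq, want$chisq, tolerance = 1e-12)
    expect_equal(got$p_value, want$p_value, tolerance = 1e-12)
    expect_identical(got$method, "chisq")
  }
  # perfect HWE proportions give chi-square 0, p = 1
  expect_equal(hwe_test(25, 50, 25, exact = "never")$chisq, 0)
  expect_equal(hwe_test(25, 50, 25, exact = "never")$p_value, 1)
  # complete heterozygote deficit at MAF 0.5: chi-square = n
  expect_equal(hwe_test(50, 0, 50, exact = "never")$chisq, 100)
})

test_that("the exact branch engages when expected counts are small", {
  got <- hwe_test(90, 9, 1)  # expected aa count well below 5
  expect_identical(got$method, "exact")
  expect_true(is.na(got$chisq))
  expect_gte(got$p_value, 0)
  expect_lte(got$p_value, 1)
  # symmetric in allele relabelling
  expect_equal(hwe_test(90, 9, 1)$p_value, hwe_test(1, 9, 90)$p_value)
  # forced exact agrees with chi-square asymptotically for big balanced counts
  ex <- hwe_test(2500, 5000, 2500, exact = "always")$p_value
  expect_gt(ex, 0.9)
  # a complete heterozygote deficit at MAF 0.5 is a strong HWE violation
  expect_lt(hwe_test(5, 0, 5, exact = "always")$p_value, 0.05)
  expect_error(hwe_test(0, 0, 0), "zero total")
})

test_that("snv_maf folds the allele frequency", {
  expect_equal(msewas:::snv_maf(c(0, 0, 1, 1)), 0.25)
  expect_equal(msewas:::snv_maf(c(2, 2, 1, 1)), 0.25)
  expect_equal(msewas:::snv_maf(c(0, NA, 2)), 0.5)
  expect_true(is.na(msewas:::snv_maf(NA)))
})

test_that("genotype_qc attributes removals to the first matching rule", {
  set.seed(21)
  n <- 120
  good <- rbinom(n, 2, 0.3)
  low_cr <- good
  low_cr[1:10] <- NA                       # call rate 110/120 < 0.95
  rare <- rbinom(n, 2, 0.01)               # MAF < 0.05
  hwe_bad <- rep(c(0L, 2L), each = n / 2)   # no heterozygotes at MAF 0.5
  mono <- rep(0L, n)                       # monomorphic (also MAF 0)
  sexchr <- rbinom(n, 2, 0.3)              # fine except chromosome X
  g <- cbind(good = good, low_cr = low_cr, rare = rare, hwe_bad = hwe_bad,
             mono = mono, sexchr = sexchr)
  rownames(g) <- sprintf("S%03d", seq_len(n))
  meta <- data.frame(
    snv_id = colnames(g),
    chromosome = c("1", "2", "3", "4", "5", "X"),
    position = 1:6 * 1000L,
    stringsAsFactors = FALSE
  )
  res <- genotype_qc(g, meta)
  expect_identical(colnames(res$genotypes), "good")
  rep <- res$report
  expect_identical(rep$call_rate, 1L)
  # the monomorphic SNV has MAF 0 < 0.05, so the MAF rule claims it first
  expect_identical(rep$maf, 2L)
  expect_identical(rep$hwe, 1L)
  expect_identical(rep$monomorphic, 0L)
  expect_identical(rep$non_autosomal, 1L)
  expect_identical(rep$snvs_removed, 5L)
  expect_identical(rep$samples_removed, character(0))
})

test_that("genotype_qc drops samples with low call rate over surviving SNVs", {
  set.seed(25)
  n <- 40
  g <- matrix(rbinom(n * 10, 2, 0.4), n, 10,
              dimnames = list(sprintf("S%02d", 1:n), paste0("v", 1:10)))
  g["S01", 1:3] <- NA  # sample call rate 7/10 < 0.95; per-SNV 39/40 passes
  meta <- data.frame(snv_id = colnames(g), chromosome = "1",
                     position = 1:10 * 1000L, stringsAsFactors = FALSE)
  res <- genotype_qc(g, meta)
  expect_identical(res$report$snvs_removed, 0L)
  expect_identical(res$report$samples_removed, "S01")
  expect_false("S01" %in% rownames(res$genotypes))
})

test_that("find_cis_snvs applies an inclusive +/- 5 kb window", {
  meta <- data.frame(
    snv_id = c("at_bound", "inside", "outside", "other_chr"),
    chromosome = c("7", "7", "7", "8"),
    position = c(105000L, 101000L, 105001L, 101000L),
    stringsAsFactors = FALSE
  )
  hits <- find_cis_snvs(100000, "7", meta)
  expect_setequal(hits, c("at_bound", "inside"))
})

test_that("ld_prune keeps independent SNVs, visiting by descending MAF", {
  n <- 96
  a <- rep(c(0L, 0L, 1L, 1L, 2L, 2L), n / 6)
  b <- a                                       # perfectly linked to a
  c_ <- rep(c(0L, 1L, 2L, 2L, 1L, 0L), n / 6)  # exactly uncorrelated with a
  const <- rep(1L, n)
  g <- cbind(a = a, b = b, c = c_, const = const)
  kept <- ld_prune(g)
  expect_true("c" %in% kept)
  expect_identical(sum(c("a", "b") %in% kept), 1L)
  expect_false("const" %in% kept)
  expect_identical(ld_prune(g[, 0, drop = FALSE]), character(0))
})

test_that("mqtl_test equals kruskal.test and the hand-rank oracle", {
  set.seed(23)
  g <- rbinom(80, 2, 0.4)
  x <- 0.4 + 0.05 * g + rnorm(80, 0, 0.05)
  got <- mqtl_test(x, g)
  ref <- kruskal.test(x, factor(g))
  expect_equal(got$p_value, ref$p.value)
  expect_equal(got$statistic, unname(ref$statistic))
  hand <- oracle_kruskal(x, g)
  expect_equal(got$statistic, hand$statistic, tolerance = 1e-12)
  expect_equal(got$p_value, hand$p_value, tolerance = 1e-12)
  # ties handled identically
  xt <- round(x, 1)
  expect_equal(mqtl_test(xt, g)$statistic,
               oracle_kruskal(xt, g)$statistic, tolerance = 1e-12)
  # single genotype class: NA with a note
  one <- mqtl_test(x, rep(1, 80))
  expect_true(is.na(one$p_value))
  expect_match(one$note, "one genotype class")
})

test_that("adjusted_association drops a constant genotype with a flag", {
  set.seed(24)
  y <- rep(c("mild", "severe"), each = 30)
  x <- clip_beta(0.4 + 0.1 * (y == "severe") + rnorm(60, 0, 0.1))
  res <- adjusted_association(y, x, rep(2, 60))
  expect_match(res$flag, "genotype constant")
  expect_true(is.na(res$genotype_p))
  expect_lt(res$methylation_p, 0.05)
})

test_that("mqtl_scan recovers the planted cis pairs", {
  co <- tiny_cohort()
  dmps <- data.frame(
    probe_id = co$truth$mqtl_pairs$probe_id,
    stringsAsFactors = FALSE
  )
  dmps <- add_positions(dmps, co$annotation)
  res <- mqtl_scan(co$beta, dmps, co$genotypes, co$snv_metadata, co$group)
  planted <- merge(res, co$truth$mqtl_pairs, by = c("probe_id", "snv_id"))
  expect_identical(nrow(planted), nrow(co$truth$mqtl_pairs))
  expect_true(all(planted$kw_p < 1e-4))
})

test_that("a genuine severity DMP survives genotype adjustment", {
  co <- tiny_cohort()
  pid <- co$truth$dmp_ids[1]
  b <- get_beta(co$beta)[pid, ]
  g <- co$genotypes[, ncol(co$genotypes)]  # a null SNV
  res <- adjusted_association(co$group, b, g)
  expect_lt(res$methylation_p, 0.01)
  expect_gt(res$genotype_p, 0.01)
})
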
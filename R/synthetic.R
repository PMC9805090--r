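#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror the study design the pipeline targets: 235 female
#' relapse-onset MS patients split 119 mild / 116 severe, whole-blood
#' methylation as a mixture over six leukocyte types, planted
#' differentially methylated positions (DMPs), cis-mQTL genotype effects,
#' age-linear clock CpGs, and plate-level batch structure. The probe count
#' defaults to a desk-scale 2000 so that end-to-end runs stay fast; every
#' dimension is configurable.
#'
#' @param n_samples Number of patients.
#' @param n_probes Number of CpG probes.
#' @param n_truth_dmps Number of planted DMPs (must be <= `n_probes`).
#' @param effect_sizes Planted group differences in beta (fraction,
#'   0-0.15); recycled across truth DMPs with alternating sign.
#' @param n_cell_types Number of leukocyte types (<= 6 named types).
#' @param dirichlet_concentration Positive Dirichlet concentration per
#'   cell type; defaults approximate whole-blood proportions
#'   (granulocyte-dominated).
#' @param n_mqtl_pairs Number of planted cis CpG-SNV pairs.
#' @param mqtl_effect Additive M-value shift per alternate allele.
#' @param n_clock_cpgs Number of age-linear clock CpGs.
#' @param batch_labels Character/factor of length `n_samples`, or `NULL`
#'   for two alternating plates.
#' @param batch_shift Additive M-value shift per batch level (recycled).
#' @param batch_scale Multiplicative noise-SD inflation per batch level.
#' @param noise_sd Gaussian noise SD on the M-value (logit) scale.
#' @param cell_specific_effect If `TRUE`, DMP effects are planted within
#'   one cell type's contribution (scaled by that type's proportion) so
#'   the cell-type interaction model has signal to find.
#' @param cell_specific_type Cell type carrying the effect when
#'   `cell_specific_effect = TRUE`.
#' @param n_null_snvs Extra SNVs with no methylation effect.
#' @param maf_range Range of minor allele frequencies for simulated SNVs.
#' @param n_markers_per_type Cell-type marker probes per type in the
#'   reference profiles.
#' @param group_sizes Named vector `c(mild = , severe = )`; defaults to
#'   119/116 at `n_samples = 235`, else a near-even split.
#' @param seed Integer seed; fully determines the cohort.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_samples = 235,
                              n_probes = 2000,
                              n_truth_dmps = 50,
                              effect_sizes = 0.05,
                              n_cell_types = 6,
                              dirichlet_concentration = NULL,
                              n_mqtl_pairs = 5,
                              mqtl_effect = 0.5,
                              n_clock_cpgs = 20,
                              batch_labels = NULL,
                              batch_shift = 0,
                              batch_scale = 1,
                              noise_sd = 0.2,
                              cell_specific_effect = FALSE,
                              cell_specific_type = "CD8T",
                              n_null_snvs = 20,
                              maf_range = c(0.1, 0.4),
                              n_markers_per_type = 50,
                              group_sizes = NULL,
                              seed = 1L) {
  all_types <- c("CD4T", "CD8T", "B", "NK", "Mono", "Gran")
  if (n_cell_types < 2 || n_cell_types > length(all_types)) {
    stop("n_cell_types must be between 2 and ", length(all_types))
  }
  types <- all_types[seq_len(n_cell_types)]
  if (is.null(dirichlet_concentration)) {
    # roughly whole-blood: CD4 15%, CD8 8%, B 5%, NK 5%, Mono 8%, Gran 58%
    conc <- c(CD4T = 9, CD8T = 5, B = 3, NK = 3, Mono = 5, Gran = 35)
    dirichlet_concentration <- conc[types]
  }
  if (length(dirichlet_concentration) != n_cell_types ||
      any(dirichlet_concentration <= 0)) {
    stop("dirichlet_concentration must be ", n_cell_types, " positive values")
  }
  names(dirichlet_concentration) <- types
  if (is.null(group_sizes)) {
    group_sizes <- if (n_samples == 235) {
      c(mild = 119, severe = 116)
    } else {
      c(mild = ceiling(n_samples / 2), severe = floor(n_samples / 2))
    }
  }
  if (sum(group_sizes) != n_samples) {
    stop("group_sizes must sum to n_samples")
  }
  if (is.null(batch_labels)) {
    batch_labels <- rep(c("plate1", "plate2"), length.out = n_samples)
  }
  if (length(batch_labels) != n_samples) {
    stop("batch_labels must have one entry per sample")
  }
  n_batches <- length(unique(batch_labels))
  cfg <- structure(list(
    n_samples = as.integer(n_samples),
    n_probes = as.integer(n_probes),
    n_truth_dmps = as.integer(n_truth_dmps),
    effect_sizes = effect_sizes,
    n_cell_types = as.integer(n_cell_types),
    cell_types = types,
    dirichlet_concentration = dirichlet_concentration,
    n_mqtl_pairs = as.integer(n_mqtl_pairs),
    mqtl_effect = mqtl_effect,
    n_clock_cpgs = as.integer(n_clock_cpgs),
    batch_labels = as.character(batch_labels),
    batch_shift = rep(batch_shift, length.out = n_batches),
    batch_scale = rep(batch_scale, length.out = n_batches),
    noise_sd = noise_sd,
    cell_specific_effect = isTRUE(cell_specific_effect),
    cell_specific_type = cell_specific_type,
    n_null_snvs = as.integer(n_null_snvs),
    maf_range = maf_range,
    n_markers_per_type = as.integer(n_markers_per_type),
    group_sizes = group_sizes,
    seed = as.integer(seed)
  ), class = "simulation_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$n_truth_dmps > cfg$n_probes) {
    stop("invalid n_truth_dmps: must be <= n_probes")
  }
  if (cfg$n_truth_dmps < 0) stop("invalid n_truth_dmps: must be >= 0")
  if (any(cfg$effect_sizes < 0 | cfg$effect_sizes > 0.15)) {
    stop("invalid effect_sizes: planted deltas must lie in [0, 0.15]")
  }
  if (cfg$noise_sd < 0) stop("invalid noise_sd: must be >= 0")
  if (cfg$n_clock_cpgs + cfg$n_truth_dmps +
      cfg$n_cell_types * cfg$n_markers_per_type > cfg$n_probes) {
    stop("invalid n_probes: too small for requested DMPs, clock CpGs and markers")
  }
  if (cfg$cell_specific_effect &&
      !cfg$cell_specific_type %in% cfg$cell_types) {
    stop("invalid cell_specific_type: not among configured cell types")
  }
  if (cfg$maf_range[1] <= 0 || cfg$maf_range[2] >= 0.5) {
    stop("invalid maf_range: must lie inside (0, 0.5)")
  }
  invisible(cfg)
}

rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), nrow = n, byrow = TRUE)
  w <- g / rowSums(g)
  colnames(w) <- names(alpha)
  w
}

# EDSS grid rounding (0.5 steps, clipped to [0, 10])
round_edss <- function(x) pmin(10, pmax(0, round(x * 2) / 2))

#' Simulate visit-level EDSS histories
#'
#' Every generated history satisfies the cohort eligibility rules by
#' construction: at least five years of follow-up and at least three
#' relapse-independent EDSS scores. Severe-group trajectories are drawn
#' with high EDSS for age and mild-group trajectories with low EDSS, so
#' that longitudinal ARMSS scoring separates the groups downstream.
#'
#' @param config A [simulation_config()].
#' @param group_labels Character vector (`"mild"`/`"severe"`) per sample.
#' @param ages Optional age at the last visit per sample; drawn uniformly
#'   over 28-76 years if `NULL`.
#' @return Data frame of visits: `sample_id`, `age_at_visit`, `edss`,
#'   `relapse_independent`.
#' @export
simulate_histories <- function(config, group_labels, ages = NULL) {
  if (length(group_labels) != config$n_samples) {
    stop("one group label per sample required")
  }
  set.seed(config$seed + 1L)
  n <- config$n_samples
  if (is.null(ages)) ages <- runif(n, 45, 70)
  ids <- sprintf("S%03d", seq_len(n))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    span <- runif(1, 5.5, 15)
    n_visits <- max(6L, rpois(1, 10))
    visit_age <- sort(ages[i] - span * seq(1, 0, length.out = n_visits))
    ri <- runif(n_visits) < 0.85
    # guarantee >= 3 relapse-independent scores
    if (sum(ri) < 3) ri[sample.int(n_visits, 3)] <- TRUE
    base <- if (group_labels[i] == "severe") runif(1, 5.5, 8.5) else runif(1, 0, 2)
    drift <- if (group_labels[i] == "severe") 0.08 else 0.02
    edss <- round_edss(base + drift * (visit_age - visit_age[1]) +
                         rnorm(n_visits, 0, 0.4))
    out[[i]] <- data.frame(
      sample_id = ids[i],
      age_at_visit = visit_age,
      edss = edss,
      relapse_independent = ri,
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Synthetic age-stratified EDSS reference population
#'
#' A large reference table of EDSS by integer age in which disability
#' increases slowly with age, used to convert EDSS to age-relative ARMSS
#' ranks. The table stands in for an external reference matrix and is
#' labelled synthetic throughout.
#'
#' @param ages Integer ages to cover (default 18-80).
#' @param n_per_age Reference individuals per age stratum.
#' @param seed Integer seed.
#' @return An [armss_reference()].
#' @export
simulate_armss_reference <- function(ages = 18:80, n_per_age = 200, seed = 99L) {
  set.seed(seed)
  age <- rep(ages, each = n_per_age)
  edss <- round_edss(rnorm(length(age), mean = 0.5 + 0.055 * (age - 18), sd = 2))
  armss_reference(age, edss)
}

#' Inject cis-mQTL effects into a beta matrix
#'
#' For each CpG-SNV pair the probe's M-value is shifted by
#' `effect x allele count`; all other probes are untouched.
#'
#' @param beta Probes x samples beta matrix.
#' @param genotypes Samples x SNVs matrix of allele counts 0/1/2.
#' @param pairs Data frame with columns `probe_id` and `snv_id`.
#' @param effect Additive M-value shift per alternate allele.
#' @return Beta matrix with shifted probes.
#' @export
inject_mqtl <- function(beta, genotypes, pairs, effect) {
  beta <- get_beta(beta)
  for (i in seq_len(nrow(pairs))) {
    p <- pairs$probe_id[i]
    s <- pairs$snv_id[i]
    if (!p %in% rownames(beta)) stop("unknown CpG id: ", p)
    if (!s %in% colnames(genotypes)) stop("unknown SNV id: ", s)
    m <- beta_to_m(beta[p, ]) + effect * genotypes[, s]
    beta[p, ] <- m_to_beta(m)
  }
  beta
}

#' Simulate a complete synthetic cohort
#'
#' Generates, deterministically from `config$seed`: a cell-type reference
#' profile matrix with marker probes, per-sample Dirichlet cell mixtures,
#' a whole-blood beta matrix with planted group effects at truth DMPs
#' (including adjacent same-sign pairs forming truth DMRs), age-linear
#' clock CpGs with a matching synthetic clock model, cis-mQTL genotype
#' effects, batch shifts, logit-scale Gaussian noise, probe annotation,
#' genotypes in Hardy-Weinberg proportions, visit histories, and a
#' machine-readable `truth` list for parameter-recovery tests.
#'
#' @param config A [simulation_config()].
#' @return A list of class `synthetic_cohort` with elements `beta`
#'   (a [methylation_matrix()]), `annotation`, `histories`, `genotypes`,
#'   `snv_metadata`, `group`, `ages`, `armss_ref`, `reference`
#'   (cell-type profiles), and `truth`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_probes
  types <- config$cell_types
  ids <- sprintf("S%03d", seq_len(n))
  probes <- sprintf("cg%07d", seq_len(p))
  group <- rep(c("mild", "severe"), times = config$group_sizes)

  # --- probe annotation: probes laid out along chromosomes 1..22 with
  # inter-probe gaps > 1 kb so no spurious DMR adjacency arises
  chrom <- as.character(rep_len(1:22, p))
  position <- integer(p)
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    position[idx] <- cumsum(sample(2000:50000, length(idx), replace = TRUE)) + 10000L
  }

  # --- role assignment
  n_markers <- config$n_cell_types * config$n_markers_per_type
  roles <- rep("background", p)
  pool <- sample.int(p)
  marker_idx <- pool[seq_len(n_markers)]
  pool <- pool[-seq_len(n_markers)]
  dmp_idx <- sort(pool[seq_len(config$n_truth_dmps)])
  if (config$n_truth_dmps > 0) pool <- pool[-seq_len(config$n_truth_dmps)]
  clock_idx <- sort(pool[seq_len(config$n_clock_cpgs)])
  roles[marker_idx] <- "marker"
  roles[dmp_idx] <- "dmp"
  roles[clock_idx] <- "clock"

  # truth DMRs: re-position the first few DMP pairs as same-chromosome
  # neighbours < 1000 bp apart with matching effect sign
  n_dmr <- min(3L, floor(config$n_truth_dmps / 2))
  dmr_truth <- list()
  if (n_dmr > 0) {
    for (k in seq_len(n_dmr)) {
      i1 <- dmp_idx[2 * k - 1]
      i2 <- dmp_idx[2 * k]
      chrom[i2] <- chrom[i1]
      position[i2] <- position[i1] + sample(200:900, 1)
      dmr_truth[[k]] <- list(
        chromosome = chrom[i1], start_bp = position[i1], end_bp = position[i2],
        member_probes = probes[c(i1, i2)]
      )
    }
  }

  # --- cell-type reference profiles
  state <- sample(c(0.12, 0.5, 0.85), p, replace = TRUE, prob = c(.4, .2, .4))
  base <- clip_beta(state + rnorm(p, 0, 0.03), 0.02)
  base[dmp_idx] <- runif(length(dmp_idx), 0.35, 0.55)  # headroom for effects
  reference <- matrix(base, nrow = p, ncol = length(types),
                      dimnames = list(probes, types))
  for (k in seq_along(types)) {
    mk <- marker_idx[seq_len(config$n_markers_per_type) +
                       (k - 1) * config$n_markers_per_type]
    hi <- seq_along(mk) %% 2 == 0
    reference[mk[hi], ] <- 0.1
    reference[mk[hi], k] <- 0.9
    reference[mk[!hi], ] <- 0.9
    reference[mk[!hi], k] <- 0.1
  }

  # --- mixtures and mixed signal
  W <- rdirichlet(n, config$dirichlet_concentration)
  rownames(W) <- ids
  beta_mix <- reference %*% t(W)
  colnames(beta_mix) <- ids

  # --- planted group effects
  deltas <- numeric(0)
  if (config$n_truth_dmps > 0) {
    deltas <- rep_len(config$effect_sizes, config$n_truth_dmps) *
      rep_len(c(1, -1), config$n_truth_dmps)
    # members of a truth DMR share one sign
    if (n_dmr > 0) {
      for (k in seq_len(n_dmr)) deltas[2 * k] <- abs(deltas[2 * k - 1]) * sign(deltas[2 * k - 1])
    }
    severe <- which(group == "severe")
    for (j in seq_along(dmp_idx)) {
      i <- dmp_idx[j]
      shift <- if (config$cell_specific_effect) {
        wk <- W[severe, config$cell_specific_type]
        deltas[j] * wk / mean(W[, config$cell_specific_type])
      } else {
        deltas[j]
      }
      beta_mix[i, severe] <- beta_mix[i, severe] + shift
    }
  }

  # --- ages, histories, clock CpGs
  ages <- runif(n, 45, 70)
  names(ages) <- ids
  histories <- simulate_histories(config, group, ages = ages)
  clock_b0 <- runif(config$n_clock_cpgs, 0.1, 0.3)
  clock_slope <- runif(config$n_clock_cpgs, 0.3, 0.6)  # per 100 years
  if (config$n_clock_cpgs > 0) {
    beta_mix[clock_idx, ] <- clock_b0 + outer(clock_slope, ages / 100)
  }
  # synthetic clock: weights invert the planted age-linear relationship
  clock_w <- if (config$n_clock_cpgs > 0) {
    (100 / clock_slope) / config$n_clock_cpgs
  } else {
    numeric(0)
  }
  clock <- clock_model(
    cpg_ids = probes[clock_idx],
    weights = clock_w,
    intercept = -sum(clock_w * clock_b0)
  )

  # --- genotypes and mQTL injection
  n_snvs <- config$n_mqtl_pairs + config$n_null_snvs
  mafs <- runif(n_snvs, config$maf_range[1], config$maf_range[2])
  genotypes <- matrix(rbinom(n * n_snvs, 2, rep(mafs, each = n)),
                      nrow = n, ncol = n_snvs)
  rownames(genotypes) <- ids
  mqtl_cpg_idx <- if (config$n_mqtl_pairs > 0) {
    dmp_or_bg <- setdiff(seq_len(p), c(marker_idx, clock_idx))
    sort(sample(dmp_or_bg, config$n_mqtl_pairs))
  } else {
    integer(0)
  }
  snv_chr <- character(n_snvs)
  snv_pos <- integer(n_snvs)
  if (config$n_mqtl_pairs > 0) {
    snv_chr[seq_len(config$n_mqtl_pairs)] <- chrom[mqtl_cpg_idx]
    snv_pos[seq_len(config$n_mqtl_pairs)] <-
      position[mqtl_cpg_idx] + sample(c(-4000:-200, 200:4000), config$n_mqtl_pairs)
  }
  if (config$n_null_snvs > 0) {
    j <- (config$n_mqtl_pairs + 1):n_snvs
    snv_chr[j] <- as.character(sample(1:22, length(j), replace = TRUE))
    snv_pos[j] <- sample(1e6:2e8, length(j))
  }
  snv_ids <- paste0(snv_chr, ":", snv_pos)
  colnames(genotypes) <- snv_ids
  snv_metadata <- data.frame(
    snv_id = snv_ids, chromosome = snv_chr, position = snv_pos,
    ref = "A", alt = "G", maf = mafs, stringsAsFactors = FALSE
  )
  mqtl_pairs <- data.frame(
    probe_id = probes[mqtl_cpg_idx],
    snv_id = snv_ids[seq_len(config$n_mqtl_pairs)],
    stringsAsFactors = FALSE
  )
  beta_mix <- clip_beta(beta_mix, 0.01)
  if (config$n_mqtl_pairs > 0) {
    beta_mix <- inject_mqtl(beta_mix, genotypes, mqtl_pairs, config$mqtl_effect)
  }

  # --- batch shifts and noise on the M (logit) scale
  batch <- config$batch_labels
  levels_b <- unique(batch)
  m <- beta_to_m(beta_mix)
  for (b in seq_along(levels_b)) {
    cols <- which(batch == levels_b[b])
    sdev <- config$noise_sd * config$batch_scale[b]
    m[, cols] <- m[, cols] + config$batch_shift[b] +
      matrix(rnorm(p * length(cols), 0, sdev), nrow = p)
  }
  beta_final <- m_to_beta(m)

  annotation <- probe_annotation(
    probe_id = probes, chromosome = chrom, position = position,
    gene = ifelse(seq_len(p) %% 3 == 0, sprintf("GENE%04d", seq_len(p)), ""),
    feature = sample(c("TSS200", "TSS1500", "body", "3'UTR", "IGR"), p,
                     replace = TRUE, prob = c(.1, .1, .3, .05, .45)),
    cgi_context = sample(c("island", "shore", "shelf", "opensea"), p,
                         replace = TRUE, prob = c(.1, .15, .1, .65))
  )
  mm <- methylation_matrix(
    beta = beta_final,
    design_type = sample(c("I", "II"), p, replace = TRUE, prob = c(.3, .7)),
    detection_p = matrix(runif(p * n, 0, 0.005), p, n,
                         dimnames = list(probes, ids)),
    bead_count = matrix(rpois(p * n, 12) + 3L, p, n,
                        dimnames = list(probes, ids))
  )
  structure(list(
    beta = mm,
    annotation = annotation,
    histories = histories,
    genotypes = genotypes,
    snv_metadata = snv_metadata,
    group = setNames(group, ids),
    ages = ages,
    armss_ref = simulate_armss_reference(seed = config$seed + 2L),
    reference = reference,
    clock = clock,
    truth = list(
      dmp_ids = probes[dmp_idx],
      dmp_deltas = setNames(deltas, probes[dmp_idx]),
      dmr_intervals = dmr_truth,
      mqtl_pairs = mqtl_pairs,
      clock_cpg_ids = probes[clock_idx],
      cell_proportions = W,
      batch = setNames(batch, ids)
    ),
    config = config
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d samples (%d mild / %d severe), %d probes\n",
    length(x$group), sum(x$group == "mild"), sum(x$group == "severe"),
    nrow(x$beta$beta)
  ))
  cat(sprintf(
    "  truth: %d DMPs, %d DMRs, %d mQTL pairs, %d clock CpGs\n",
    length(x$truth$dmp_ids), length(x$truth$dmr_intervals),
    nrow(x$truth$mqtl_pairs), length(x$truth$clock_cpg_ids)
  ))
  invisible(x)
}
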
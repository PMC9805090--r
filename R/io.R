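#' Write / read a beta matrix as TSV (probes as rows)
#'
#' @param beta Probes x samples matrix or [methylation_matrix()].
#' @param path Output path.
#' @export
write_beta_tsv <- function(beta, path) {
  b <- get_beta(beta)
  df <- data.frame(probe_id = rownames(b), b, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_beta_tsv
#' @return `read_beta_tsv` returns a probes x samples numeric matrix.
#' @export
read_beta_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a genotype table (samples x SNVs, 0/1/2 coded) from TSV
#'
#' First column is the sample id; remaining columns are SNV ids.
#'
#' @param path Path to the TSV.
#' @return Samples x SNVs integer matrix.
#' @export
read_genotypes_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  g <- as.matrix(df[, -1, drop = FALSE])
  rownames(g) <- df[[1]]
  storage.mode(g) <- "integer"
  g
}

#' Read genotypes from a VCF file (GT field)
#'
#' Requires the vcfR package. Genotypes are converted to alternate
#' allele counts 0/1/2 (`NA` for missing).
#'
#' @param path Path to a VCF file.
#' @return List with `genotypes` (samples x SNVs matrix) and `metadata`
#'   (`snv_id`, `chromosome`, `position`, `ref`, `alt`).
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  counts <- apply(gt, c(1, 2), function(x) {
    if (is.na(x)) return(NA_integer_)
    sum(as.integer(strsplit(x, "[/|]")[[1]]) > 0)
  })
  fix <- vcfR::getFIX(v)
  meta <- data.frame(
    snv_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                    paste0(fix[, "CHROM"], ":", fix[, "POS"]), fix[, "ID"]),
    chromosome = sub("^chr", "", fix[, "CHROM"]),
    position = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )
  g <- t(counts)
  colnames(g) <- meta$snv_id
  list(genotypes = g, metadata = meta)
}

#' Write genotypes as a minimal VCFv4.2 file (GT field only)
#'
#' @param genotypes Samples x SNVs allele-count matrix.
#' @param metadata Data frame with `snv_id`, `chromosome`, `position`,
#'   `ref`, `alt`.
#' @param path Output path.
#' @export
write_genotypes_vcf <- function(genotypes, metadata, path) {
  gt_str <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")
  )
  for (j in seq_len(ncol(genotypes))) {
    g <- genotypes[, j]
    cells <- ifelse(is.na(g), "./.", gt_str[g + 1])
    lines <- c(lines, paste(c(
      metadata$chromosome[j], metadata$position[j], metadata$snv_id[j],
      metadata$ref[j], metadata$alt[j], ".", "PASS", ".", "GT", cells
    ), collapse = "\t"))
  }
  writeLines(lines, path)
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Emits `beta.tsv`, `samples.csv` (id, group, age, batch),
#' `visits.csv`, `annotation.csv`, `genotypes.tsv`, `genotypes.vcf`,
#' `cell_reference.tsv`, `armss_reference.csv` and `truth.json`.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(dir, x)
  write_beta_tsv(cohort$beta, fp("beta.tsv"))
  write.csv(data.frame(
    sample_id = names(cohort$group),
    group = unname(cohort$group),
    age = unname(cohort$ages),
    batch = unname(cohort$truth$batch),
    stringsAsFactors = FALSE
  ), fp("samples.csv"), row.names = FALSE)
  write.csv(cohort$histories, fp("visits.csv"), row.names = FALSE)
  write.csv(as.data.frame(cohort$annotation), fp("annotation.csv"),
            row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = rownames(cohort$genotypes), cohort$genotypes,
               check.names = FALSE),
    fp("genotypes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  write_genotypes_vcf(cohort$genotypes, cohort$snv_metadata,
                      fp("genotypes.vcf"))
  utils::write.table(
    data.frame(probe_id = rownames(cohort$reference), cohort$reference,
               check.names = FALSE),
    fp("cell_reference.tsv"), sep = "\t", quote = FALSE, row.names = FALSE
  )
  write.csv(as.data.frame(unclass(cohort$armss_ref)),
            fp("armss_reference.csv"), row.names = FALSE)
  truth <- cohort$truth
  truth$cell_proportions <- as.data.frame(truth$cell_proportions)
  jsonlite::write_json(truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read the bundled worked-example table of major DMPs
#'
#' A 22-row table of major differentially methylated positions
#' (|delta beta| > 5%) with genomic coordinates, annotation and effect
#' sizes, used in worked examples for the DMR caller and the major-DMP
#' rule.
#'
#' @return Data frame with columns `probe_id`, `chromosome`, `position`,
#'   `gene`, `feature`, `cgi_context`, `delta_meth`, `fdr`.
#' @export
example_major_dmps <- function() {
  read.delim(system.file("extdata", "major_dmps.tsv", package = "msewas"),
             stringsAsFactors = FALSE, colClasses = c(chromosome = "character"))
}

#' Read the bundled worked-example DMR member table
#'
#' Four DMPs forming two suggestive two-CpG regions (one on chromosome
#' 11, one on chromosome 15), used in worked examples for the
#' proximity/direction DMR caller.
#'
#' @return Data frame with columns `probe_id`, `chromosome`, `position`,
#'   `delta_meth`, `fdr`.
#' @export
example_dmr_members <- function() {
  read.delim(system.file("extdata", "dmr_member_dmps.tsv", package = "msewas"),
             stringsAsFactors = FALSE, colClasses = c(chromosome = "character"))
}
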
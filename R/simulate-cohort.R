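#' Simulate case/control cohort variants with SUN-bearing reads
#'
#' Generates the inputs of the variant pipeline with known truth: carrier
#' genotypes for each spec'd variant (carriers drawn per sample with the
#' given carrier frequency), genotyping dropout, a VCF 4.2 file, per-read
#' SUN support labels for paralog assignment, and the truth table of
#' expected counts.
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param variant_specs Data frame with one row per variant:
#'   \describe{
#'     \item{id}{variant identifier,}
#'     \item{pos}{1-based position,}
#'     \item{ref, alt}{alleles,}
#'     \item{paralog}{`"A"`, `"B"` or `"unassigned"` — which paralog's SUN
#'       alleles the supporting reads carry (`"unassigned"` reads cover no
#'       SUN),}
#'     \item{effect}{effect class label carried into the truth table,}
#'     \item{freq_cases, freq_controls}{carrier frequencies in [0, 1]
#'       (a single `freq` column is accepted for both),}
#'     \item{dropout}{per-sample genotyping dropout probability.}
#'   }
#' @param sun_table SUN table used to label supporting reads (one SUN per
#'   variant is picked round-robin); required when any spec'd paralog is
#'   `"A"` or `"B"`.
#' @param seed Integer RNG seed.
#' @param reads_per_variant Supporting reads simulated per variant.
#' @return List with
#'   `genotypes` (samples x variants character matrix: "0/0", "0/1", "./."),
#'   `vcf_lines` (VCF 4.2 text, one element per line),
#'   `variant_reads` (named list of read-level SUN observations per variant),
#'   `truth` (data frame of realized and expected counts; variants with zero
#'   genotyped samples are flagged `undefined`).
#' @export
simulate_cohort_variants <- function(n_cases, n_controls, variant_specs,
                                     sun_table = NULL, seed = 1L,
                                     reads_per_variant = 8L) {
  set.seed(seed)
  vs <- as.data.frame(variant_specs)
  if (!is.null(vs$freq) && is.null(vs$freq_cases)) {
    vs$freq_cases <- vs$freq
    vs$freq_controls <- vs$freq
  }
  if (is.null(vs$dropout)) vs$dropout <- 0
  for (col in c("freq_cases", "freq_controls")) {
    if (any(vs[[col]] < 0 | vs[[col]] > 1)) {
      stop("carrier frequency outside [0, 1]", call. = FALSE)
    }
  }
  if (is.null(vs$id)) vs$id <- sprintf("var%02d", seq_len(nrow(vs)))
  samples <- c(sprintf("case%04d", seq_len(n_cases)),
               sprintf("ctrl%04d", seq_len(n_controls)))
  is_case <- c(rep(TRUE, n_cases), rep(FALSE, n_controls))
  nv <- nrow(vs)
  G <- matrix("0/0", length(samples), nv, dimnames = list(samples, vs$id))
  truth_rows <- list()
  variant_reads <- list()
  for (j in seq_len(nv)) {
    p <- ifelse(is_case, vs$freq_cases[j], vs$freq_controls[j])
    carrier <- stats::rbinom(length(samples), 1L, p) == 1L
    dropped <- stats::rbinom(length(samples), 1L, vs$dropout[j]) == 1L
    G[carrier, j] <- "0/1"
    G[dropped, j] <- "./."
    cg <- sum(!dropped & is_case)
    kg <- sum(!dropped & !is_case)
    truth_rows[[j]] <- data.frame(
      id = vs$id[j], paralog = vs$paralog[j], effect = vs$effect[j],
      case_count = sum(carrier & !dropped & is_case),
      control_count = sum(carrier & !dropped & !is_case),
      cases_genotyped = cg, controls_genotyped = kg,
      expected_case_count = vs$freq_cases[j] * n_cases * (1 - vs$dropout[j]),
      expected_control_count = vs$freq_controls[j] * n_controls *
        (1 - vs$dropout[j]),
      undefined = cg == 0 & kg == 0,
      stringsAsFactors = FALSE
    )
    variant_reads[[vs$id[j]]] <- simulate_variant_reads(
      vs$paralog[j], sun_table, reads_per_variant)
  }
  truth <- do.call(rbind, truth_rows)
  vcf_lines <- build_vcf(vs, G, samples)
  list(genotypes = G, vcf_lines = vcf_lines, variant_reads = variant_reads,
       truth = truth, samples = samples, is_case = is_case)
}

# reads for one variant: either covering a SUN with the right paralog's
# allele, or covering no SUN at all ("unassigned" truth)
simulate_variant_reads <- function(paralog, sun_table, n_reads) {
  if (is.na(paralog) || paralog == "unassigned" || is.null(sun_table) ||
      nrow(sun_table) == 0L) {
    return(data.frame(read_id = sprintf("r%02d", seq_len(n_reads)),
                      pos0 = NA_integer_, allele = NA_character_,
                      stringsAsFactors = FALSE)[0, ])
  }
  sun <- sun_table[sample.int(nrow(sun_table), 1L), ]
  allele <- if (paralog == "A") sun$allele_A else sun$allele_B
  data.frame(read_id = sprintf("r%02d", seq_len(n_reads)),
             pos0 = rep(sun$pos0, n_reads),
             allele = rep(allele, n_reads), stringsAsFactors = FALSE)
}

build_vcf <- function(vs, G, samples, chrom = "locus", depth = 50L,
                      qual = 60) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=paraloci",
    sprintf("##contig=<ID=%s>", chrom),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(vs)), function(j) {
    paste(c(chrom, vs$pos[j], vs$id[j], vs$ref[j], vs$alt[j],
            format(qual), "PASS", sprintf("DP=%d", depth), "GT", G[, j]),
          collapse = "\t")
  }, character(1))
  c(header, body)
}

#' Write simulated cohort variants as VCF 4.2
#' @param sim Result of [simulate_cohort_variants()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_cohort_vcf <- function(sim, path) {
  writeLines(sim$vcf_lines, path)
  invisible(path)
}

#' Read variant records and genotype counts from a VCF
#'
#' Parses a VCF (via \pkg{vcfR}) and tallies carriers and genotyped samples
#' per variant, splitting samples into cases and controls by name.
#'
#' @param path VCF file.
#' @param case_samples Character vector of sample names counted as cases;
#'   all others are controls.
#' @return Data frame with `id`, `pos`, `ref`, `alt`, `qual`, `depth`,
#'   `case_count`, `control_count`, `cases_genotyped`, `controls_genotyped`.
#' @export
read_cohort_vcf <- function(path, case_samples) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fixm <- vcfR::getFIX(v)
  if (is.null(dim(fixm))) fixm <- t(fixm)   # single-variant VCF
  fix <- as.data.frame(fixm, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  is_case <- colnames(gt) %in% case_samples
  carrier <- !is.na(gt) & grepl("1", gt, fixed = TRUE)
  genotyped <- !is.na(gt) & gt != "./."
  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  data.frame(
    id = fix$ID, pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)), depth = dp,
    case_count = rowSums(carrier[, is_case, drop = FALSE]),
    control_count = rowSums(carrier[, !is_case, drop = FALSE]),
    cases_genotyped = rowSums(genotyped[, is_case, drop = FALSE]),
    controls_genotyped = rowSums(genotyped[, !is_case, drop = FALSE]),
    stringsAsFactors = FALSE
  )
}
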
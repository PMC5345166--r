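#' Read and write SUN site tables
#'
#' SUN (singly unique nucleotide) tables are BED-like TSVs with columns
#' `chrom pos0 pos1 allele_A allele_B` (0-based, half-open positions);
#' `allele_A` is the base carried by the ancestral paralog at that position,
#' `allele_B` by the derived duplicate.
#'
#' @param path File path.
#' @param suns Data frame with the five columns above.
#' @return `read_sun_table()` returns a data frame; `write_sun_table()`
#'   returns `path` invisibly.
#' @export
read_sun_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("chrom", "pos0", "pos1", "allele_A", "allele_B")
  if (!all(req %in% names(df))) {
    stop("SUN table needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_sun_table
#' @export
write_sun_table <- function(suns, path) {
  utils::write.table(suns, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Hard-filter variant records
#'
#' Applies the exon-sequencing QC filters: remove variants with read depth
#' <= 10, quality score <= 20, no alternate alleles, or lying in a
#' homopolymer (run of one base >= `homopolymer_min`) or trinucleotide
#' repeat (>= `trinuc_min_copies` tandem copies of a 3-mer) overlapping the
#' variant. Records with missing depth or quality are failed with an
#' explicit `missing_qc` flag rather than silently kept. All flags are
#' retained on the full table, returned as the `"audit"` attribute.
#'
#' @param records Data frame with at least `pos` (1-based), `ref`, `alt`,
#'   `depth`, `qual`.
#' @param context_sequence Locus sequence used for the repeat checks.
#' @param homopolymer_min Minimum run length counted as a homopolymer
#'   (default 5).
#' @param trinuc_min_copies Minimum tandem copies of a 3-mer counted as a
#'   trinucleotide repeat (default 3).
#' @return The records that pass, with the fully flagged table (extra
#'   columns `pass`, `filter_flags`) attached as attribute `"audit"`.
#' @export
filter_variants <- function(records, context_sequence,
                            homopolymer_min = 5, trinuc_min_copies = 3) {
  records <- as.data.frame(records)
  context_sequence <- toupper(paste0(context_sequence, collapse = ""))
  n <- nrow(records)
  flags <- character(n)
  add_flag <- function(i, f) {
    flags[i] <<- ifelse(flags[i] == "", f, paste(flags[i], f, sep = ","))
  }
  for (i in seq_len(n)) {
    depth <- records$depth[i]; qual <- records$qual[i]
    if (is.na(depth) || is.na(qual)) add_flag(i, "missing_qc")
    if (!is.na(depth) && depth <= 10) add_flag(i, "low_depth")
    if (!is.na(qual) && qual <= 20) add_flag(i, "low_qual")
    alt <- records$alt[i]
    if (is.na(alt) || alt %in% c("", ".")) add_flag(i, "no_alleles")
    span <- variant_span(records$pos[i], records$ref[i], records$alt[i])
    if (spans_homopolymer(context_sequence, span, homopolymer_min)) {
      add_flag(i, "homopolymer")
    }
    if (spans_trinuc_repeat(context_sequence, span, trinuc_min_copies)) {
      add_flag(i, "trinucleotide_repeat")
    }
  }
  audit <- records
  audit$filter_flags <- flags
  audit$pass <- flags == ""
  out <- records[audit$pass, , drop = FALSE]
  attr(out, "audit") <- audit
  out
}

# 1-based inclusive genomic span touched by a variant
variant_span <- function(pos, ref, alt) {
  ref <- as.character(ref)
  c(pos, pos + max(nchar(ref), 1L) - 1L)
}

spans_homopolymer <- function(seq, span, min_run) {
  lo <- max(1L, span[1] - (min_run - 1L))
  hi <- min(nchar(seq), span[2] + (min_run - 1L))
  window <- substr(seq, lo, hi)
  m <- gregexpr("A{2,}|C{2,}|G{2,}|T{2,}", window)[[1]]
  if (m[1] == -1) return(FALSE)
  runs_start <- lo + m - 1L
  runs_end <- runs_start + attr(m, "match.length") - 1L
  any(attr(m, "match.length") >= min_run &
        runs_start <= span[2] & runs_end >= span[1])
}

spans_trinuc_repeat <- function(seq, span, min_copies) {
  need <- 3L * min_copies
  lo <- max(1L, span[1] - (need - 1L))
  hi <- min(nchar(seq), span[2] + (need - 1L))
  window <- strsplit(substr(seq, lo, hi), "")[[1]]
  W <- length(window)
  if (W < need) return(FALSE)
  for (s in 1:(W - need + 1L)) {
    unit <- window[s:(s + 2L)]
    copies <- 1L
    while (s + 3L * copies + 2L <= W &&
           all(window[(s + 3L * copies):(s + 3L * copies + 2L)] == unit)) {
      copies <- copies + 1L
    }
    if (copies >= min_copies) {
      rs <- lo + s - 1L
      re <- rs + 3L * copies - 1L
      if (rs <= span[2] && re >= span[1]) return(TRUE)
    }
  }
  FALSE
}

#' Assign a variant to a paralog from SUN-bearing reads
#'
#' Each read supporting the variant reports the alleles it observed at the
#' SUN positions it covers. Reads matching one paralog's SUN alleles vote
#' for that paralog; if every informative read agrees, the variant is
#' assigned, conflicting reads leave it unassigned with a conflict flag, and
#' with no SUN-informative reads it cannot be assigned at all.
#'
#' @param variant_reads Data frame with columns `read_id`, `pos0` (0-based
#'   SUN position covered) and `allele` (observed base).
#' @param sun_table SUN table as from [read_sun_table()].
#' @return List with `paralog` (`"A"`, `"B"` or `"unassigned"`),
#'   `n_informative` reads, and logical `conflict`.
#' @export
assign_paralog <- function(variant_reads, sun_table) {
  if (is.null(sun_table) || nrow(sun_table) == 0L) {
    warning("empty SUN table: no variant can be assigned", call. = FALSE)
    return(list(paralog = "unassigned", n_informative = 0L, conflict = FALSE))
  }
  variant_reads <- as.data.frame(variant_reads)
  if (nrow(variant_reads) == 0L) {
    return(list(paralog = "unassigned", n_informative = 0L, conflict = FALSE))
  }
  idx <- match(variant_reads$pos0, sun_table$pos0)
  vote <- ifelse(is.na(idx), NA_character_,
                 ifelse(variant_reads$allele == sun_table$allele_A[idx], "A",
                        ifelse(variant_reads$allele == sun_table$allele_B[idx],
                               "B", NA_character_)))
  per_read <- tapply(vote, variant_reads$read_id, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) return(NA_character_)
    u <- unique(v)
    if (length(u) == 1L) u else "conflict"
  })
  calls <- per_read[!is.na(per_read)]
  if (length(calls) == 0L) {
    return(list(paralog = "unassigned", n_informative = 0L, conflict = FALSE))
  }
  u <- setdiff(unique(calls), character(0))
  if (identical(u, "A") || identical(u, "B")) {
    return(list(paralog = unname(u), n_informative = length(calls),
                conflict = FALSE))
  }
  list(paralog = "unassigned", n_informative = length(calls), conflict = TRUE)
}

# half-up rounding, as printed in cohort tables
round_half_up <- function(x, digits = 2) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Case/control carrier-frequency table
#'
#' Builds the cohort summary table for classified, paralog-assigned
#' variants. Frequencies are carrier frequencies — carriers divided by the
#' number of samples successfully genotyped for that variant — reported both
#' as raw fractions and as percent rounded half-up to 2 decimals. Variants
#' with zero genotyped samples get an undefined (NA) frequency and a flag.
#' A common-variant screen flags allele frequencies above 1% (alleles
#' approximated as one per carrier over `2 * genotyped` chromosomes).
#'
#' @param records Data frame with columns `case_count`, `control_count`,
#'   `cases_genotyped`, `controls_genotyped` (plus any annotation columns,
#'   which are carried through).
#' @return The input with added columns `freq_cases`, `freq_controls`
#'   (fractions), `freq_cases_pct`, `freq_controls_pct` (rounded percent),
#'   `undefined_cases`, `undefined_controls`, and `common` (allele
#'   frequency > 1% in either cohort).
#' @examples
#' frequency_table(data.frame(case_count = 11, control_count = 10,
#'                            cases_genotyped = 3427,
#'                            controls_genotyped = 2598))
#' @export
frequency_table <- function(records) {
  records <- as.data.frame(records)
  with_counts <- function(k, n, label) {
    if (any(k > n, na.rm = TRUE)) {
      stop("carrier count exceeds number genotyped (", label, ")",
           call. = FALSE)
    }
    f <- ifelse(n > 0, k / n, NA_real_)
    list(freq = f, pct = round_half_up(100 * f, 2), undef = n == 0)
  }
  ca <- with_counts(records$case_count, records$cases_genotyped, "cases")
  co <- with_counts(records$control_count, records$controls_genotyped,
                    "controls")
  records$freq_cases <- ca$freq
  records$freq_controls <- co$freq
  records$freq_cases_pct <- ca$pct
  records$freq_controls_pct <- co$pct
  records$undefined_cases <- ca$undef
  records$undefined_controls <- co$undef
  af_cases <- ifelse(records$cases_genotyped > 0,
                     records$case_count / (2 * records$cases_genotyped), 0)
  af_controls <- ifelse(records$controls_genotyped > 0,
                        records$control_count /
                          (2 * records$controls_genotyped), 0)
  records$common <- af_cases > 0.01 | af_controls > 0.01
  records
}

#' Carrier frequency of an event in a cohort
#' @param carriers Number of carriers observed.
#' @param genotyped Number of samples genotyped.
#' @return Carrier frequency as a fraction (NA if `genotyped` is 0).
#' @examples
#' carrier_frequency(2, 2981)
#' @export
carrier_frequency <- function(carriers, genotyped) {
  if (genotyped == 0) return(NA_real_)
  if (carriers > genotyped) stop("carriers exceed genotyped", call. = FALSE)
  carriers / genotyped
}
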
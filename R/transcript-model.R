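#' Transcript model for effect classification
#'
#' Holds the exon structure of a gene on a (synthetic or real) genomic
#' sequence: ordered, non-overlapping exons in 0-based half-open genomic
#' coordinates, the CDS span, and the locus sequence. Splice sites are the
#' canonical 2 bp intronic flanks (GT donor on the 5' side of each intron,
#' AG acceptor on the 3' side). Only the forward strand is supported.
#'
#' @param exons Data frame with columns `start`, `end` (0-based half-open
#'   genomic coordinates), ordered, non-overlapping. Exons are numbered
#'   1..n in order.
#' @param cds_start,cds_end 0-based half-open CDS span (genomic); must fall
#'   within the exon union.
#' @param sequence Genomic sequence of the locus (single string).
#' @param strand Only "+" is supported.
#' @return An object of class `transcript_model`.
#' @seealso [classify_effect()], [synthetic_transcript_model()]
#' @export
transcript_model <- function(exons, cds_start, cds_end, sequence,
                             strand = "+") {
  if (!identical(strand, "+")) {
    stop("only forward-strand models are supported", call. = FALSE)
  }
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$end <= exons$start)) stop("empty exon", call. = FALSE)
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)])) {
    stop("exons overlap or are unordered", call. = FALSE)
  }
  sequence <- toupper(paste0(sequence, collapse = ""))
  if (max(exons$end) > nchar(sequence)) {
    stop("exons extend beyond the supplied sequence", call. = FALSE)
  }
  in_exon <- function(p) any(p >= exons$start & p < exons$end)
  if (!in_exon(cds_start) || !in_exon(cds_end - 1L)) {
    stop("CDS boundaries must fall within exons", call. = FALSE)
  }
  structure(
    list(exons = exons, n_exons = nrow(exons),
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
         sequence = sequence, strand = strand),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %d exons, CDS [%d, %d), %d bp locus\n",
              x$n_exons, x$cds_start, x$cds_end, nchar(x$sequence)))
  invisible(x)
}

#' Build a random synthetic transcript model
#'
#' Generates a locus with `n_exons` exons of the given length separated by
#' introns with canonical GT..AG splice sites, a CDS starting with ATG at the
#' beginning of exon 1 and ending with a stop codon at the end of the last
#' exon. Used throughout the test suite as a stand-in gene structure
#' (synthetic, not the real locus).
#'
#' @param n_exons Number of exons.
#' @param exon_len Exon length in bp (scalar or per-exon vector).
#' @param intron_len Intron length in bp (>= 20).
#' @param seed RNG seed.
#' @return A `transcript_model`.
#' @export
synthetic_transcript_model <- function(n_exons = 10, exon_len = 90,
                                       intron_len = 200, seed = 1L) {
  set.seed(seed)
  exon_len <- rep_len(exon_len, n_exons)
  if (sum(exon_len) %% 3 != 0) {
    exon_len[n_exons] <- exon_len[n_exons] + (3 - sum(exon_len) %% 3)
  }
  if (intron_len < 20) stop("intron_len must be >= 20", call. = FALSE)
  # codons without stops so the reading frame stays open until the end
  sense <- setdiff(
    apply(expand.grid(BASES, BASES, BASES)[, 3:1], 1, paste0, collapse = ""),
    c("TAA", "TAG", "TGA"))
  n_codons <- sum(exon_len) / 3
  cds <- paste0(c("ATG", sample(sense, n_codons - 2, replace = TRUE), "TAA"),
                collapse = "")
  starts <- integer(n_exons); ends <- integer(n_exons)
  seq_parts <- character(0)
  pos <- 0L; cds_pos <- 0L
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    ex <- substr(cds, cds_pos + 1L, cds_pos + exon_len[i])
    cds_pos <- cds_pos + exon_len[i]
    seq_parts <- c(seq_parts, ex)
    pos <- pos + exon_len[i]
    ends[i] <- pos
    if (i < n_exons) {
      mid <- paste0(sample(BASES, intron_len - 4L, replace = TRUE),
                    collapse = "")
      seq_parts <- c(seq_parts, paste0("GT", mid, "AG"))
      pos <- pos + intron_len
    }
  }
  transcript_model(data.frame(start = starts, end = ends),
                   cds_start = 0L, cds_end = ends[n_exons],
                   sequence = paste0(seq_parts, collapse = ""))
}

#' Read a transcript model from GFF3
#'
#' Uses \pkg{rtracklayer} to import exon and CDS features of the first
#' transcript found; requires a `sequence` for the locus since GFF3 carries
#' none.
#'
#' @param path GFF3 file with `exon` and `CDS` features (forward strand).
#' @param sequence Genomic sequence of the locus.
#' @return A `transcript_model`.
#' @export
read_transcript_gff3 <- function(path, sequence) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
  }
  gr <- rtracklayer::import(path)
  ex <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  if (length(ex) == 0L) stop("no exon features in GFF3", call. = FALSE)
  exons <- data.frame(start = BiocGenerics::start(ex) - 1L,
                      end = BiocGenerics::end(ex))
  cs <- if (length(cds)) min(BiocGenerics::start(cds)) - 1L else
    min(exons$start)
  ce <- if (length(cds)) max(BiocGenerics::end(cds)) else max(exons$end)
  transcript_model(exons, cs, ce, sequence)
}

# 0-based genomic position -> list(exon index or NA, intronic offset info)
locate_position <- function(model, pos) {
  ex <- model$exons
  hit <- which(pos >= ex$start & pos < ex$end)
  if (length(hit)) {
    return(list(where = "exon", exon = hit))
  }
  # intron i lies between exon i and i+1
  for (i in seq_len(nrow(ex) - 1L)) {
    if (pos >= ex$end[i] && pos < ex$start[i + 1L]) {
      return(list(where = "intron", intron = i,
                  from_donor = pos - ex$end[i],              # 0-based
                  from_acceptor = ex$start[i + 1L] - 1L - pos))
    }
  }
  list(where = "outside")
}

# spliced CDS sequence and a map from CDS index (1-based) to genomic pos
cds_map <- function(model) {
  ex <- model$exons
  pos <- integer(0)
  for (i in seq_len(nrow(ex))) {
    lo <- max(ex$start[i], model$cds_start)
    hi <- min(ex$end[i], model$cds_end)
    if (hi > lo) pos <- c(pos, lo:(hi - 1L))
  }
  pos
}

#' Classify the coding effect of a variant
#'
#' VCF-style variant (POS is 1-based; `ref`/`alt` share their first base for
#' indels) classified against a [transcript_model()]:
#' indels changing CDS length by a non-multiple of 3 are `frameshift`
#' (in-frame indels are `other`); SNVs creating or removing a stop codon are
#' `stop_gained`/`stop_lost`; SNVs in the 2 bp intronic flanks are
#' `splice_donor` (5' side of the intron) or `splice_acceptor` (3' side);
#' remaining CDS SNVs are `missense` or `synonymous`. Variants outside the
#' MIP design footprint (exons plus 5 bp of flanking intron) raise an
#' out-of-design error.
#'
#' @param pos 1-based position of the variant (VCF POS).
#' @param ref,alt Reference and alternate alleles (VCF style).
#' @param model A `transcript_model`.
#' @return One of `"frameshift"`, `"stop_gained"`, `"stop_lost"`,
#'   `"splice_donor"`, `"splice_acceptor"`, `"missense"`, `"synonymous"`,
#'   `"other"`.
#' @export
classify_effect <- function(pos, ref, alt, model) {
  stopifnot(inherits(model, "transcript_model"))
  ref <- toupper(ref); alt <- toupper(alt)
  p0 <- as.integer(pos) - 1L                      # 0-based
  ex <- model$exons
  dist_to_exon <- min(abs(c(p0 - ex$start, p0 - (ex$end - 1L))),
                      ifelse(any(p0 >= ex$start & p0 < ex$end), 0L, Inf))
  if (dist_to_exon > 5L) {
    stop("variant outside the design footprint (exons +/- 5 bp)",
         call. = FALSE)
  }
  is_indel <- nchar(ref) != nchar(alt)
  if (is_indel) {
    # affected genomic span: the bases deleted/inserted after the anchor base
    if (nchar(ref) > nchar(alt)) {
      span <- (p0 + nchar(alt)):(p0 + nchar(ref) - 1L)   # deleted bases
    } else {
      span <- p0                                          # insertion anchor
    }
    cds_pos <- cds_map(model)
    n_cds_changed <- if (nchar(ref) > nchar(alt)) {
      sum(span %in% cds_pos)
    } else if (p0 %in% cds_pos) nchar(alt) - nchar(ref) else 0L
    if (n_cds_changed > 0L) {
      return(if (n_cds_changed %% 3L != 0L) "frameshift" else "other")
    }
    sp <- splice_site_class(model, span)
    return(if (!is.null(sp)) sp else "other")
  }
  # SNV
  loc <- locate_position(model, p0)
  if (loc$where == "intron") {
    sp <- splice_site_class(model, p0)
    return(if (!is.null(sp)) sp else "other")
  }
  if (loc$where == "outside") return("other")
  cds_pos <- cds_map(model)
  ci <- match(p0, cds_pos)
  if (is.na(ci)) return("other")                  # exonic UTR
  codon_i <- (ci - 1L) %/% 3L
  cpos <- cds_pos[(codon_i * 3L + 1L):(codon_i * 3L + 3L)]
  ref_codon <- substring(model$sequence, cpos + 1L, cpos + 1L)
  obs <- ref_codon[which(cpos == p0)]
  if (!identical(obs, ref)) {
    stop(sprintf("ref allele %s does not match model sequence %s at %d",
                 ref, obs, pos), call. = FALSE)
  }
  alt_codon <- ref_codon
  alt_codon[which(cpos == p0)] <- alt
  codon_table()
  aa_ref <- ng86_env$aa[paste0(ref_codon, collapse = "")]
  aa_alt <- ng86_env$aa[paste0(alt_codon, collapse = "")]
  if (aa_alt == "*" && aa_ref != "*") return("stop_gained")
  if (aa_ref == "*" && aa_alt != "*") return("stop_lost")
  if (aa_ref == aa_alt) "synonymous" else "missense"
}

# NULL, "splice_donor" or "splice_acceptor" for a genomic position (vector ok)
splice_site_class <- function(model, pos0) {
  ex <- model$exons
  for (i in seq_len(nrow(ex) - 1L)) {
    donor <- ex$end[i] + 0:1                       # first 2 intronic bases
    acceptor <- ex$start[i + 1L] - 2:1             # last 2 intronic bases
    if (any(pos0 %in% donor)) return("splice_donor")
    if (any(pos0 %in% acceptor)) return("splice_acceptor")
  }
  NULL
}
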
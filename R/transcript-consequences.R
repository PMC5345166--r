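#' Predict ORF and amplicon consequences of transcript edits
#'
#' Works on the mature (spliced) transcript: the reference transcript is the
#' concatenation of exon sequences, and every edit is expressed as a
#' keep-mask over its bases. An exonic deletion removes the deleted bases; a
#' deletion destroying an exon's splice acceptor causes that exon to be
#' skipped, removing all its bases from the mature transcript. The open
#' reading frame is scanned from the first ATG to the first stop codon, for
#' the reference and the mutant, and a premature-stop flag is raised when
#' the mutant stop maps to a different reference position than the reference
#' stop. Amplicon lengths for primer pairs are the number of surviving bases
#' between the primer coordinates.
#'
#' @param exon_seqs Named character vector of exon sequences in transcript
#'   order (names are exon labels), or a [transcript_model()] whose exon
#'   sequences are extracted.
#' @param edits Data frame describing deletions, with columns
#'   \describe{
#'     \item{type}{`"exonic_deletion"` or `"splice_acceptor_deletion"`,}
#'     \item{exon}{exon label or 1-based index,}
#'     \item{start}{1-based start of the deletion within the exon
#'       (ignored for splice-acceptor deletions),}
#'     \item{length}{number of exonic bases deleted (ignored for
#'       splice-acceptor deletions, which drop the whole exon).}
#'   }
#' @param primers Optional data frame `name`, `start`, `end` of primer-pair
#'   coordinates (1-based, inclusive) on the reference spliced transcript.
#' @return A list of class `orf_report`: `ref_seq`, `mut_seq`, `mask`,
#'   `ref_protein_len`, `mut_protein_len`, `frameshift`, `premature_stop`,
#'   `deleted_bases`, and `amplicons` (data frame with `ref_len`, `mut_len`).
#' @examples
#' exons <- c(e1 = "ATGAAACCCGGG", e2 = "TTTAAACCCTAA")
#' transcript_consequences(exons,
#'   data.frame(type = "exonic_deletion", exon = "e2", start = 1, length = 3))
#' @export
transcript_consequences <- function(exon_seqs, edits = NULL, primers = NULL) {
  if (inherits(exon_seqs, "transcript_model")) {
    exon_seqs <- spliced_exons(exon_seqs)
  }
  exon_seqs <- toupper(exon_seqs)
  if (is.null(names(exon_seqs))) {
    names(exon_seqs) <- sprintf("exon%d", seq_along(exon_seqs))
  }
  lens <- nchar(exon_seqs)
  offsets <- c(0L, cumsum(lens))                 # exon i spans offsets[i]+1..
  ref_seq <- paste0(exon_seqs, collapse = "")
  L <- nchar(ref_seq)
  mask <- rep(TRUE, L)
  if (!is.null(edits) && nrow(as.data.frame(edits)) > 0) {
    edits <- as.data.frame(edits)
    for (r in seq_len(nrow(edits))) {
      ei <- edits$exon[r]
      if (is.character(ei) || is.factor(ei)) {
        ei <- match(as.character(ei), names(exon_seqs))
      }
      if (is.na(ei) || ei < 1 || ei > length(exon_seqs)) {
        stop("edit refers to an unknown exon", call. = FALSE)
      }
      if (edits$type[r] == "splice_acceptor_deletion") {
        mask[(offsets[ei] + 1L):offsets[ei + 1L]] <- FALSE
      } else if (edits$type[r] == "exonic_deletion") {
        s <- edits$start[r]; len <- edits$length[r]
        if (s < 1 || s + len - 1L > lens[ei]) {
          stop("exonic deletion outside the exon", call. = FALSE)
        }
        idx <- (offsets[ei] + s):(offsets[ei] + s + len - 1L)
        mask[idx] <- FALSE
      } else {
        stop("unknown edit type: ", edits$type[r], call. = FALSE)
      }
    }
  }
  keep_idx <- which(mask)
  mut_seq <- paste0(strsplit(ref_seq, "")[[1]][mask], collapse = "")
  ref_orf <- orf_from_first_atg(ref_seq)
  mut_orf <- orf_from_first_atg(mut_seq)
  # map the mutant stop codon back to reference coordinates
  premature <- FALSE
  if (!is.na(mut_orf$stop_start)) {
    mapped <- keep_idx[mut_orf$stop_start]
    premature <- is.na(ref_orf$stop_start) || mapped != ref_orf$stop_start
  }
  del_in_orf <- if (is.na(ref_orf$start)) 0L else {
    orf_span <- ref_orf$start:(if (is.na(ref_orf$stop_start)) L else
      ref_orf$stop_start + 2L)
    sum(!mask[orf_span])
  }
  amp <- NULL
  if (!is.null(primers)) {
    primers <- as.data.frame(primers)
    if (any(primers$start < 1 | primers$end > L)) {
      stop("primer coordinates outside the transcript", call. = FALSE)
    }
    amp <- data.frame(
      name = primers$name,
      ref_len = primers$end - primers$start + 1L,
      mut_len = vapply(seq_len(nrow(primers)), function(i) {
        sum(mask[primers$start[i]:primers$end[i]])
      }, integer(1))
    )
  }
  structure(
    list(ref_seq = ref_seq, mut_seq = mut_seq, mask = mask,
         ref_protein_len = ref_orf$aa_len, mut_protein_len = mut_orf$aa_len,
         frameshift = del_in_orf %% 3L != 0L,
         premature_stop = premature, deleted_bases = sum(!mask),
         amplicons = amp),
    class = "orf_report"
  )
}

#' @export
print.orf_report <- function(x, ...) {
  cat(sprintf(
    "<orf_report> %d bp deleted; protein %d -> %d aa; frameshift %s; premature stop %s\n",
    x$deleted_bases, x$ref_protein_len, x$mut_protein_len,
    x$frameshift, x$premature_stop))
  if (!is.null(x$amplicons)) {
    for (i in seq_len(nrow(x$amplicons))) {
      cat(sprintf("  amplicon %s: %d bp -> %d bp\n", x$amplicons$name[i],
                  x$amplicons$ref_len[i], x$amplicons$mut_len[i]))
    }
  }
  invisible(x)
}

# ORF from the first ATG to the first in-frame stop.
# Returns 1-based start, protein length (aa, stop excluded), and the
# 1-based start of the stop codon (NA if the frame runs off the end).
orf_from_first_atg <- function(seq) {
  start <- regexpr("ATG", seq, fixed = TRUE)[1]
  if (start < 0) return(list(start = NA_integer_, aa_len = 0L,
                             stop_start = NA_integer_))
  codon_table()
  aa <- ng86_env$aa
  n <- nchar(seq)
  aa_len <- 0L
  p <- start
  while (p + 2L <= n) {
    cd <- substr(seq, p, p + 2L)
    a <- if (grepl("^[ACGT]{3}$", cd)) aa[cd] else "X"
    if (!is.na(a) && a == "*") {
      return(list(start = start, aa_len = aa_len, stop_start = p))
    }
    aa_len <- aa_len + 1L
    p <- p + 3L
  }
  list(start = start, aa_len = aa_len, stop_start = NA_integer_)
}

#' Exon sequences of a transcript model
#' @param model A [transcript_model()].
#' @return Named character vector of exon sequences in order.
#' @export
spliced_exons <- function(model) {
  stopifnot(inherits(model, "transcript_model"))
  ex <- model$exons
  out <- substring(model$sequence, ex$start + 1L, ex$end)
  names(out) <- sprintf("exon%d", seq_len(nrow(ex)))
  out
}
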
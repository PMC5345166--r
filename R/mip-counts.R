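#' MIP read-count matrices
#'
#' Container for per-sample, per-target paralog-supporting read counts. Each
#' MIP target overlaps one or more SUNs (singly unique nucleotides), so every
#' captured read can be attributed to paralog A (the ancestral locus) or
#' paralog B (the derived duplicate). Reads matching neither paralog allele
#' are assumed to have been excluded upstream.
#'
#' @param reads_A,reads_B Integer matrices (samples x targets) of reads
#'   supporting each paralog; dimnames give sample and target identifiers.
#' @return An object of class `mip_counts` with elements `reads_A`, `reads_B`,
#'   `samples`, `targets`.
#' @export
mip_counts <- function(reads_A, reads_B) {
  reads_A <- as.matrix(reads_A)
  reads_B <- as.matrix(reads_B)
  if (!identical(dim(reads_A), dim(reads_B))) {
    stop("reads_A and reads_B must have identical dimensions", call. = FALSE)
  }
  if (any(reads_A < 0, na.rm = TRUE) || any(reads_B < 0, na.rm = TRUE)) {
    stop("read counts must be non-negative", call. = FALSE)
  }
  if (is.null(rownames(reads_A))) {
    rownames(reads_A) <- rownames(reads_B) <-
      sprintf("S%03d", seq_len(nrow(reads_A)))
  }
  if (is.null(colnames(reads_A))) {
    colnames(reads_A) <- colnames(reads_B) <-
      sprintf("T%03d", seq_len(ncol(reads_A)))
  }
  structure(
    list(reads_A = reads_A, reads_B = reads_B,
         samples = rownames(reads_A), targets = colnames(reads_A)),
    class = "mip_counts"
  )
}

#' @export
print.mip_counts <- function(x, ...) {
  cat("<mip_counts> ", length(x$samples), " sample(s) x ",
      length(x$targets), " target(s)\n", sep = "")
  tot <- x$reads_A + x$reads_B
  cat("  mean total reads/target: ",
      format(mean(tot, na.rm = TRUE), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
`[.mip_counts` <- function(x, i, j, ...) {
  mip_counts(x$reads_A[i, j, drop = FALSE], x$reads_B[i, j, drop = FALSE])
}

#' Combine per-sample MIP counts into one cohort matrix
#' @param ... `mip_counts` objects sharing the same targets.
#' @return A single `mip_counts` object.
#' @export
rbind_mip_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1]]) && !inherits(xs[[1]], "mip_counts")) {
    xs <- xs[[1]]
  }
  tg <- xs[[1]]$targets
  for (x in xs) {
    if (!identical(x$targets, tg)) stop("targets differ", call. = FALSE)
  }
  mip_counts(do.call(rbind, lapply(xs, `[[`, "reads_A")),
             do.call(rbind, lapply(xs, `[[`, "reads_B")))
}

#' Read and write MIP count tables
#'
#' The on-disk format is a tab-separated long table with header
#' `sample target reads_A reads_B`; targets keep their first-appearance
#' (coordinate) order.
#'
#' @param x A `mip_counts` object.
#' @param path File path.
#' @return `read_mip_counts()` returns a `mip_counts` object;
#'   `write_mip_counts()` returns `path` invisibly.
#' @export
write_mip_counts <- function(x, path) {
  stopifnot(inherits(x, "mip_counts"))
  df <- data.frame(
    sample = rep(x$samples, times = length(x$targets)),
    target = rep(x$targets, each = length(x$samples)),
    reads_A = as.vector(x$reads_A),
    reads_B = as.vector(x$reads_B)
  )
  df <- df[order(match(df$sample, x$samples), match(df$target, x$targets)), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mip_counts
#' @export
read_mip_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  samples <- unique(df$sample)
  targets <- unique(df$target)
  A <- matrix(NA_integer_, length(samples), length(targets),
              dimnames = list(samples, targets))
  B <- A
  A[cbind(match(df$sample, samples), match(df$target, targets))] <- df$reads_A
  B[cbind(match(df$sample, samples), match(df$target, targets))] <- df$reads_B
  mip_counts(A, B)
}
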
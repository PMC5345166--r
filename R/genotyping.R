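#' Aggregate copy number from WGS read depth
#'
#' The aggregate (summed) diploid copy number of both paralogs is estimated
#' from mean sequencing depth over the duplication interval relative to
#' copy-number-2 reference regions: `2 * region / baseline`. The estimate is
#' continuous; any rounding is presentation-only.
#'
#' @param region_mean_depth Mean read depth over the segmental duplication,
#'   or a data frame with columns `region_mean_depth`, `baseline_mean_depth`
#'   (and optionally `sample`).
#' @param baseline_mean_depth Mean depth over diploid reference regions.
#' @return Numeric aggregate copy number(s), named by sample when available.
#' @examples
#' aggregate_cn(40, 20)   # 4 copies
#' aggregate_cn(30, 20)   # 3 copies
#' @export
aggregate_cn <- function(region_mean_depth, baseline_mean_depth = NULL) {
  if (is.data.frame(region_mean_depth)) {
    df <- region_mean_depth
    out <- aggregate_cn(df$region_mean_depth, df$baseline_mean_depth)
    if ("sample" %in% names(df)) names(out) <- df$sample
    return(out)
  }
  if (any(baseline_mean_depth <= 0)) {
    stop("baseline_mean_depth must be positive", call. = FALSE)
  }
  2 * region_mean_depth / baseline_mean_depth
}

#' Read a WGS depth summary table
#' @param path TSV with columns `sample`, `region_mean_depth`,
#'   `baseline_mean_depth`.
#' @return Data frame.
#' @export
read_depth_summary <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Per-target paralog-specific copy-number point estimates
#'
#' Splits a sample's aggregate copy number between paralogs according to the
#' SUN-supporting read fractions at each MIP target:
#' `cnA_hat = aggregate * reads_A / (reads_A + reads_B)` and
#' `cnB_hat = aggregate - cnA_hat`. Targets with zero total reads yield a
#' missing estimate (NA), never zero. Estimates conserve the aggregate and
#' are invariant to rescaling all counts.
#'
#' @param counts A [mip_counts()] object.
#' @param aggregate Aggregate copy number: a scalar (recycled) or a vector
#'   named by (or ordered as) the samples.
#' @return A data frame in long form: `sample`, `target`, `target_index`
#'   (0-based), `cnA_hat`, `cnB_hat`.
#' @export
paralog_point_estimates <- function(counts, aggregate) {
  stopifnot(inherits(counts, "mip_counts"))
  ns <- length(counts$samples)
  if (!is.null(names(aggregate))) {
    aggregate <- aggregate[counts$samples]
    if (anyNA(aggregate)) stop("aggregate missing for some samples",
                               call. = FALSE)
  } else if (length(aggregate) == 1L) {
    aggregate <- rep(aggregate, ns)
  } else if (length(aggregate) != ns) {
    stop("aggregate must be scalar or one value per sample", call. = FALSE)
  }
  tot <- counts$reads_A + counts$reads_B
  frac <- counts$reads_A / tot          # NaN where total == 0
  frac[tot == 0] <- NA_real_
  cnA <- frac * aggregate               # recycles aggregate by sample (rows)
  cnB <- aggregate - cnA
  nt <- length(counts$targets)
  data.frame(
    sample = rep(counts$samples, times = nt),
    target = rep(counts$targets, each = ns),
    target_index = rep(seq_len(nt) - 1L, each = ns),
    cnA_hat = as.vector(cnA),
    cnB_hat = as.vector(cnB),
    stringsAsFactors = FALSE
  )
}

#' Write per-target paralog-specific estimates as TSV
#' @param estimates Data frame from [paralog_point_estimates()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path) {
  utils::write.table(estimates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
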
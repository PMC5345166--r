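#' Simulate MIP read counts from a known copy-number truth
#'
#' Forward model, the inverse of the copy-number caller: per target the total
#' read count is Poisson with mean `mean_depth * (cnA + cnB) / 4` (Gamma-mixed
#' when `overdispersion > 0`), and the paralog-A count is Binomial with
#' success probability `f = f_true * (1 - 2 * mismap_rate) + mismap_rate`,
#' where `f_true = cnA / (cnA + cnB)` (0.5 when both copy numbers are zero —
#' any residual reads are then symmetric mismappings).
#'
#' @param scenario A [sim_scenario()].
#' @param sample_id Sample identifier used in the returned count matrix.
#' @return A list with elements
#'   \describe{
#'     \item{counts}{a one-sample [mip_counts()] object,}
#'     \item{truth}{a `cn_path` holding the generating segments and states,}
#'     \item{scenario}{the input scenario.}
#'   }
#' @examples
#' sim <- simulate_mip_counts(sim_scenario(20, segments_single(20, 2, 2)))
#' sim$counts
#' @export
simulate_mip_counts <- function(scenario, sample_id = "S001") {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  n <- scenario$n_targets
  seg <- scenario$segments
  cnA <- integer(n)
  cnB <- integer(n)
  for (k in seq_len(nrow(seg))) {
    idx <- (seg$start[k] + 1L):seg$end[k]
    cnA[idx] <- seg$cnA[k]
    cnB[idx] <- seg$cnB[k]
  }
  cn_tot <- cnA + cnB
  if (all(cn_tot == 0L)) {
    warning("whole locus has copy number 0; read depth collapses to zero",
            call. = FALSE)
  }
  mu <- scenario$mean_depth * cn_tot / 4
  if (scenario$overdispersion > 0) {
    od <- scenario$overdispersion
    # Gamma mixing on the mean: Var(total) = mu + od * mu^2
    lam <- ifelse(mu > 0, stats::rgamma(n, shape = 1 / od, rate = 1 / (od * mu)), 0)
  } else {
    lam <- mu
  }
  total <- stats::rpois(n, lam)
  f_true <- ifelse(cn_tot > 0, cnA / pmax(cn_tot, 1L), 0.5)
  f <- f_true * (1 - 2 * scenario$mismap_rate) + scenario$mismap_rate
  reads_A <- stats::rbinom(n, total, f)
  reads_B <- total - reads_A
  A <- matrix(reads_A, 1L, n, dimnames = list(sample_id, sprintf("T%03d", 1:n)))
  B <- matrix(reads_B, 1L, n, dimnames = list(sample_id, sprintf("T%03d", 1:n)))
  truth <- cn_path(
    breakpoints = if (nrow(seg) > 1) seg$start[-1] else integer(0),
    states = data.frame(cnA = seg$cnA, cnB = seg$cnB),
    score = NA_real_, n_targets = n
  )
  list(counts = mip_counts(A, B), truth = truth, scenario = scenario)
}

#' Simulate a cohort of MIP samples
#'
#' Applies [simulate_mip_counts()] to a list of scenarios (one per sample)
#' and row-binds the results. Each scenario carries its own seed, so the
#' cohort is bit-reproducible.
#'
#' @param scenarios List of [sim_scenario()] objects.
#' @param sample_ids Optional character vector of sample names.
#' @return A list with `counts` (a cohort [mip_counts()]) and `truths`
#'   (list of `cn_path` truth objects, named by sample).
#' @export
simulate_mip_cohort <- function(scenarios, sample_ids = NULL) {
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("S%04d", seq_along(scenarios))
  }
  sims <- Map(simulate_mip_counts, scenarios, sample_ids)
  counts <- rbind_mip_counts(lapply(sims, `[[`, "counts"))
  truths <- lapply(sims, `[[`, "truth")
  names(truths) <- sample_ids
  list(counts = counts, truths = truths)
}

#' Write a truth path (or any call set) as JSON
#' @param truth A `cn_path` or list of them.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  ser <- function(p) {
    list(breakpoints = p$breakpoints, states = p$states,
         n_targets = p$n_targets)
  }
  obj <- if (inherits(truth, "cn_path")) ser(truth) else lapply(truth, ser)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
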
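#' Declare a MIP copy-number simulation scenario
#'
#' A `sim_scenario` describes the hidden truth for one simulated sample: a
#' tiling of the MIP targets along the locus into segments, each with a joint
#' paralog copy-number state `(cnA, cnB)`, plus the sequencing-depth model.
#' [simulate_mip_counts()] turns a scenario into per-target read counts.
#'
#' @param n_targets Number of MIP targets along the locus.
#' @param segments A data frame with columns `start`, `end`, `cnA`, `cnB`.
#'   `start`/`end` are 0-based half-open target-index intervals that must tile
#'   `[0, n_targets)` without gaps or overlap. Copy numbers are integers in
#'   0..4. At most two internal breakpoints (three segments) are allowed so
#'   that the truth stays inside the caller's model class; pass
#'   `allow_extra_segments = TRUE` to test model misspecification.
#' @param mean_depth Expected total reads per target for a sample with
#'   aggregate copy number 4 (the diploid two-plus-two baseline).
#' @param overdispersion Non-negative real; 0 gives pure Poisson totals,
#'   positive values Gamma-mix the Poisson mean so that
#'   `Var(total) = mu + overdispersion * mu^2`.
#' @param mismap_rate Probability that a read supports the wrong paralog.
#'   Mixing is symmetric: the paralog-A read fraction is
#'   `f_true * (1 - 2 * mismap_rate) + mismap_rate`, which keeps the fraction
#'   strictly inside (0, 1) so zero-copy states remain identifiable.
#' @param seed Integer RNG seed; generation is bit-reproducible given the seed.
#' @param allow_extra_segments Permit more than three segments (default FALSE).
#'
#' @return An object of class `sim_scenario`.
#' @seealso [simulate_mip_counts()], [segments_single()]
#' @examples
#' sc <- sim_scenario(40, segments_single(40, 2, 2))
#' sc$segments
#' @export
sim_scenario <- function(n_targets, segments, mean_depth = 200,
                         overdispersion = 0, mismap_rate = 0.01, seed = 1L,
                         allow_extra_segments = FALSE) {
  stopifnot(is.numeric(n_targets), length(n_targets) == 1L, n_targets >= 1)
  n_targets <- as.integer(n_targets)
  segments <- as.data.frame(segments)
  req <- c("start", "end", "cnA", "cnB")
  if (!all(req %in% names(segments))) {
    stop("`segments` needs columns start, end, cnA, cnB", call. = FALSE)
  }
  segments <- segments[order(segments$start), req, drop = FALSE]
  if (segments$start[1] != 0L || segments$end[nrow(segments)] != n_targets ||
      (nrow(segments) > 1 &&
       any(segments$start[-1] != segments$end[-nrow(segments)]))) {
    stop("segments must tile [0, n_targets) without gaps or overlap",
         call. = FALSE)
  }
  if (any(segments$end <= segments$start)) {
    stop("each segment must be non-empty", call. = FALSE)
  }
  cn <- c(segments$cnA, segments$cnB)
  if (any(cn != round(cn)) || any(cn < 0) || any(cn > 4)) {
    stop("cnA and cnB must be integers in 0..4", call. = FALSE)
  }
  if (nrow(segments) > 3 && !allow_extra_segments) {
    stop("at most 2 internal breakpoints allowed; set allow_extra_segments ",
         "= TRUE to simulate outside the caller's model class", call. = FALSE)
  }
  if (mean_depth <= 0) stop("mean_depth must be positive", call. = FALSE)
  if (overdispersion < 0) stop("overdispersion must be >= 0", call. = FALSE)
  if (mismap_rate < 0 || mismap_rate >= 0.5) {
    stop("mismap_rate must be in [0, 0.5)", call. = FALSE)
  }
  structure(
    list(n_targets = n_targets, segments = segments, mean_depth = mean_depth,
         overdispersion = overdispersion, mismap_rate = mismap_rate,
         seed = as.integer(seed)),
    class = "sim_scenario"
  )
}

#' Convenience segment tables for simulation scenarios
#'
#' `segments_single()` builds a one-segment (whole-locus) truth;
#' `segments_event()` a flank/event/flank truth with an internal event over
#' `[ev_start, ev_end)`; `segments_terminal()` a two-segment truth with a
#' change from `bp` onward.
#'
#' @param n_targets Number of MIP targets.
#' @param cnA,cnB Copy numbers of the flanking (or only) state.
#' @param ev_start,ev_end 0-based half-open event interval in target indices.
#' @param ev_cnA,ev_cnB Copy numbers inside the event.
#' @param bp Breakpoint target index for a terminal event.
#' @return A data frame usable as the `segments` argument of [sim_scenario()].
#' @export
segments_single <- function(n_targets, cnA, cnB) {
  data.frame(start = 0L, end = as.integer(n_targets), cnA = cnA, cnB = cnB)
}

#' @rdname segments_single
#' @export
segments_event <- function(n_targets, cnA, cnB, ev_start, ev_end,
                           ev_cnA, ev_cnB) {
  data.frame(
    start = as.integer(c(0L, ev_start, ev_end)),
    end = as.integer(c(ev_start, ev_end, n_targets)),
    cnA = c(cnA, ev_cnA, cnA),
    cnB = c(cnB, ev_cnB, cnB)
  )
}

#' @rdname segments_single
#' @export
segments_terminal <- function(n_targets, cnA, cnB, bp, ev_cnA, ev_cnB) {
  data.frame(
    start = as.integer(c(0L, bp)),
    end = as.integer(c(bp, n_targets)),
    cnA = c(cnA, ev_cnA),
    cnB = c(cnB, ev_cnB)
  )
}

#' Declare a quartet sequence-evolution scenario
#'
#' Describes the forward model used to test duplication dating: a fixed
#' four-taxon topology `((paralogA, paralogB), chimp, orang)` in which the two
#' human paralogs split `t_dup` million years ago (mya), the human and
#' chimpanzee lineages split `t_cc` mya, and orangutan is the outgroup at
#' `t_out` mya. Sequences evolve site-independently under the Kimura
#' two-parameter model with no indels.
#'
#' @param t_dup Duplication time in mya; must be `< t_cc`.
#' @param t_cc Human-chimpanzee divergence used as the dating calibration
#'   (default 6 mya).
#' @param t_out Orangutan divergence (default 16 mya; must be `> t_cc`).
#' @param subs_rate Substitution rate in substitutions/site/my (default 1e-3,
#'   giving ~1.2% human-chimp divergence at 6 mya calibration).
#' @param kappa Expected transition:transversion substitution-count ratio
#'   (ts/tv ratio `R`). `kappa = 0.5` corresponds to equal instantaneous rates
#'   for all substitution types (the Jukes-Cantor limit, where transitions and
#'   transversions occur at counts 1:2); primate nuclear DNA is typically
#'   around 2.
#' @param seq_len Number of alignment columns.
#' @param seed Integer RNG seed.
#'
#' @return An object of class `evo_scenario`.
#' @seealso [simulate_k2p_quartet()], [date_duplication()]
#' @export
evo_scenario <- function(t_dup, t_cc = 6, t_out = 16, subs_rate = 1e-3,
                         kappa = 2, seq_len = 10000L, seed = 1L) {
  stopifnot(t_dup >= 0, seq_len >= 1, kappa > 0, subs_rate >= 0)
  if (t_dup >= t_cc) stop("t_dup must be < t_cc", call. = FALSE)
  if (t_cc >= t_out) stop("t_cc must be < t_out", call. = FALSE)
  structure(
    list(t_dup = t_dup, t_cc = t_cc, t_out = t_out, subs_rate = subs_rate,
         kappa = kappa, seq_len = as.integer(seq_len), seed = as.integer(seed)),
    class = "evo_scenario"
  )
}

#' Sample a cohort of event scenarios for caller evaluation
#'
#' Draws random single-sample truths around the human modal state (2,2):
#' no event, whole-locus gains/losses, terminal and internal duplications
#' and deletions of one paralog, and copy-neutral interlocus gene
#' conversion, with breakpoints placed so every segment spans at least
#' `min_seg` targets. Event class probabilities (0.30 none, 0.10 whole-locus
#' gain, 0.10 whole-locus loss, 0.125 terminal duplication, 0.125 terminal
#' deletion, 0.10 internal duplication, 0.10 internal deletion, 0.05 gene
#' conversion) keep most samples copy-number typical, as in human cohorts.
#'
#' @param n Number of samples.
#' @param n_targets Targets per sample (default 40).
#' @param mean_depth Expected total reads/target at aggregate CN 4
#'   (default 200).
#' @param mismap_rate Read mismapping probability (default 0.01).
#' @param min_seg Minimum segment length in targets (default 5).
#' @param seed Integer seed; per-sample scenario seeds are derived from it.
#' @return List with `scenarios` (list of [sim_scenario()]) and `truth`
#'   (data frame: per-sample true event `kind`, `paralog`, span and states,
#'   from [classify_event()] applied to the generating path).
#' @export
sample_event_scenarios <- function(n, n_targets = 40, mean_depth = 200,
                                   mismap_rate = 0.01, min_seg = 5,
                                   seed = 1L) {
  set.seed(seed)
  # length-safe draw: sample(v, 1) on a length-one vector samples 1:v
  draw1 <- function(v) v[sample.int(length(v), 1L)]
  kinds <- c("none", "wl_gain", "wl_loss", "term_dup", "term_del",
             "int_dup", "int_del", "gene_conv")
  probs <- c(0.30, 0.10, 0.10, 0.125, 0.125, 0.10, 0.10, 0.05)
  draw <- sample(kinds, n, replace = TRUE, prob = probs)
  pick_paralog <- sample(c("A", "B"), n, replace = TRUE)
  seeds <- sample.int(.Machine$integer.max, n)
  scenarios <- vector("list", n)
  for (i in seq_len(n)) {
    k <- draw[i]
    pa <- pick_paralog[i]
    segs <- switch(k,
      none = segments_single(n_targets, 2, 2),
      wl_gain = if (pa == "A") segments_single(n_targets, 3, 2) else
        segments_single(n_targets, 2, 3),
      wl_loss = if (pa == "A") segments_single(n_targets, 1, 2) else
        segments_single(n_targets, 2, 1),
      term_dup = ,
      term_del = {
        bp <- draw1(min_seg:(n_targets - min_seg))
        dcn <- if (k == "term_dup") 1L else -1L
        if (pa == "A") segments_terminal(n_targets, 2, 2, bp, 2 + dcn, 2) else
          segments_terminal(n_targets, 2, 2, bp, 2, 2 + dcn)
      },
      int_dup = ,
      int_del = ,
      gene_conv = {
        s <- draw1(min_seg:(n_targets - 2 * min_seg))
        e <- draw1((s + min_seg):(n_targets - min_seg))
        if (k == "gene_conv") {
          ev <- if (pa == "A") c(3, 1) else c(1, 3)  # donor = raised paralog
        } else {
          dcn <- if (k == "int_dup") 1L else -1L
          ev <- if (pa == "A") c(2 + dcn, 2) else c(2, 2 + dcn)
        }
        segments_event(n_targets, 2, 2, s, e, ev[1], ev[2])
      }
    )
    scenarios[[i]] <- sim_scenario(n_targets, segs, mean_depth = mean_depth,
                                   mismap_rate = mismap_rate,
                                   seed = seeds[i])
  }
  truth <- do.call(rbind, lapply(seq_len(n), function(i) {
    seg <- scenarios[[i]]$segments
    pth <- cn_path(if (nrow(seg) > 1) seg$start[-1] else integer(0),
                   seg[, c("cnA", "cnB")], NA_real_, n_targets)
    ev <- classify_event(pth)
    data.frame(sample = sprintf("S%04d", i), kind = ev$kind,
               paralog = ev$paralog, start_target = ev$span[1],
               end_target = ev$span[2],
               cnA_flank = ev$flanking_state[["cnA"]],
               cnB_flank = ev$flanking_state[["cnB"]],
               stringsAsFactors = FALSE)
  }))
  list(scenarios = scenarios, truth = truth)
}
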
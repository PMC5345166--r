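#' The 25-state joint paralog copy-number state space
#'
#' Both paralogs are allowed copy numbers 0..4, giving 5 x 5 = 25 joint
#' hidden states.
#'
#' @return A data frame with integer columns `cnA`, `cnB` (25 rows).
#' @export
paralog_states <- function() {
  expand.grid(cnA = 0:4, cnB = 0:4, KEEP.OUT.ATTRS = FALSE)
}

#' Prior log-likelihoods for initial single-paralog copy number
#'
#' Reflects that most humans carry two copies of each paralog: log-likelihoods
#' of -15, -7.5, 0, -7.5 and -15 for single-paralog copy numbers 0..4. The
#' prior is applied once, additively across the two paralogs, to the path's
#' leftmost state.
#'
#' @return A named numeric vector with names "0".."4".
#' @export
cn_prior_table <- function() {
  c(`0` = -15, `1` = -7.5, `2` = 0, `3` = -7.5, `4` = -15)
}

#' Construct a copy-number path
#'
#' A `cn_path` is a segmentation of the target axis into 1-3 segments
#' (`breakpoints` internal boundaries, 0-based target indices; spans are
#' half-open) with one joint state per segment.
#'
#' @param breakpoints Integer vector of 0, 1 or 2 internal boundaries.
#' @param states Data frame with one `(cnA, cnB)` row per segment.
#' @param score Total path log-likelihood (prior + emissions).
#' @param n_targets Number of targets spanned.
#' @return An object of class `cn_path`.
#' @export
cn_path <- function(breakpoints, states, score, n_targets) {
  breakpoints <- as.integer(breakpoints)
  if (length(breakpoints) > 2) stop("at most 2 breakpoints", call. = FALSE)
  if (is.unsorted(breakpoints, strictly = TRUE)) {
    stop("breakpoints must be strictly increasing", call. = FALSE)
  }
  if (any(breakpoints <= 0L) || any(breakpoints >= n_targets)) {
    stop("breakpoints must lie strictly inside (0, n_targets)", call. = FALSE)
  }
  states <- as.data.frame(states)
  if (nrow(states) != length(breakpoints) + 1L) {
    stop("need one state per segment (breakpoints + 1)", call. = FALSE)
  }
  structure(
    list(breakpoints = breakpoints, states = states, score = score,
         n_targets = as.integer(n_targets)),
    class = "cn_path"
  )
}

#' @export
print.cn_path <- function(x, ...) {
  bounds <- c(0L, x$breakpoints, x$n_targets)
  segs <- vapply(seq_len(nrow(x$states)), function(i) {
    sprintf("[%d,%d)=(%d,%d)", bounds[i], bounds[i + 1],
            x$states$cnA[i], x$states$cnB[i])
  }, character(1))
  cat("<cn_path> ", paste(segs, collapse = " -> "),
      if (!is.na(x$score)) sprintf("  score %.2f", x$score), "\n", sep = "")
  invisible(x)
}

#' Expand a path to per-target states
#' @param path A `cn_path`.
#' @return Data frame with `cnA`, `cnB` per target (one row per target).
#' @export
path_states_per_target <- function(path) {
  bounds <- c(0L, path$breakpoints, path$n_targets)
  len <- diff(bounds)
  data.frame(cnA = rep(path$states$cnA, len), cnB = rep(path$states$cnB, len))
}

#' Emission log-likelihood of MIP counts under a joint state
#'
#' Two independent terms: a binomial on the paralog-A reads given the total,
#' with success probability `f = cnA / (cnA + cnB)` clamped into
#' `[eps, 1 - eps]` (residual cross-mapping keeps zero-copy states
#' falsifiable), and a Poisson on the total reads with mean
#' `lambda * (cnA + cnB) / 4`. The binomial term discriminates states by
#' allele fraction; the depth term separates states of equal fraction such as
#' (2,2) and (3,3). For `cnA + cnB = 0` the binomial uses `f = 0.5` and the
#' Poisson mean is `lambda * eps_depth`.
#'
#' @param reads_A,reads_B Non-negative counts (vectorized over targets).
#' @param cnA,cnB Joint state, integers 0..4 (scalars).
#' @param lambda Expected total reads per target at aggregate copy number 4.
#' @param eps Allele-fraction clamp (default 0.01, matching the default
#'   simulated mismap rate).
#' @param eps_depth Relative residual depth assumed for total copy number 0
#'   (default 0.05).
#' @return Numeric vector of per-target log-likelihoods.
#' @export
emission_loglik <- function(reads_A, reads_B, cnA, cnB, lambda,
                            eps = 0.01, eps_depth = 0.05) {
  stopifnot(all(reads_A >= 0, na.rm = TRUE), all(reads_B >= 0, na.rm = TRUE),
            lambda > 0)
  total <- reads_A + reads_B
  cn_tot <- cnA + cnB
  if (cn_tot == 0) {
    f <- 0.5
    mu <- lambda * eps_depth
  } else {
    f <- min(max(cnA / cn_tot, eps), 1 - eps)
    mu <- lambda * cn_tot / 4
  }
  stats::dbinom(reads_A, total, f, log = TRUE) +
    stats::dpois(total, mu, log = TRUE)
}

# 25 x n matrix of emission log-likelihoods; NA counts contribute 0.
emission_matrix <- function(reads_A, reads_B, lambda, eps = 0.01,
                            eps_depth = 0.05) {
  st <- paralog_states()
  n <- length(reads_A)
  E <- matrix(0, nrow = nrow(st), ncol = n)
  ok <- !is.na(reads_A) & !is.na(reads_B)
  for (i in seq_len(nrow(st))) {
    E[i, ok] <- emission_loglik(reads_A[ok], reads_B[ok], st$cnA[i], st$cnB[i],
                                lambda, eps, eps_depth)
  }
  E
}

# Index pairs (from, to) of permitted single transitions:
# delta(cnA, cnB) in {(+-1, 0), (0, +-1), (+1, -1), (-1, +1)}.
allowed_transitions <- function() {
  st <- paralog_states()
  deltas <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1), c(-1, 1))
  out <- list()
  for (i in seq_len(nrow(st))) {
    for (d in seq_len(nrow(deltas))) {
      a <- st$cnA[i] + deltas[d, 1]
      b <- st$cnB[i] + deltas[d, 2]
      if (a >= 0 && a <= 4 && b >= 0 && b <= 4) {
        j <- which(st$cnA == a & st$cnB == b)
        out[[length(out) + 1L]] <- c(i, j)
      }
    }
  }
  do.call(rbind, out)
}

#' Estimate the depth scale from a cohort of MIP counts
#'
#' `lambda` is the expected total read count per target for a sample at
#' aggregate copy number 4. Assuming the modal sample is diploid for both
#' paralogs, the cohort estimate is the median across samples of the
#' per-sample mean total reads per target. With a single sample the estimate
#' is that sample's own mean (adequate when the sample is copy-number
#' typical; supply a WGS aggregate to [best_paths()] otherwise).
#'
#' @param counts A [mip_counts()] object.
#' @return A single positive number.
#' @export
estimate_lambda <- function(counts) {
  stopifnot(inherits(counts, "mip_counts"))
  tot <- counts$reads_A + counts$reads_B
  per_sample <- rowMeans(tot, na.rm = TRUE)
  lam <- stats::median(per_sample)
  if (!is.finite(lam) || lam <= 0) {
    stop("cannot estimate lambda: no usable counts", call. = FALSE)
  }
  lam
}

#' Highest-scoring copy-number path for one sample
#'
#' Scores all 25 joint states per target and searches, exactly, the highest
#' scoring segmentations with 0, 1 and 2 transitions between states.
#' Transitions are restricted to single-copy changes of one paralog or a
#' reciprocal exchange (`(+1,-1)`/`(-1,+1)`), and a 2-transition path must
#' return to its flanking state (the second transition is the inverse of the
#' first) — the model class that covers internal duplications, deletions and
#' copy-neutral interlocus gene conversion. The path score is
#' `prior(cnA_0) + prior(cnB_0) + sum of emissions`; an additional transition
#' is accepted only if it improves the total log-likelihood by at least
#' `delta` natural-log units.
#'
#' @param reads_A,reads_B Per-target counts for one sample (either vectors,
#'   or pass a one-sample [mip_counts()] as `reads_A`).
#' @param lambda Expected total reads per target at aggregate CN 4; when a
#'   WGS `aggregate` estimate is supplied, `lambda` is derived as
#'   `mean(total) * 4 / aggregate`.
#' @param aggregate Optional WGS aggregate copy number anchoring the depth
#'   scale.
#' @param prior Named prior table as from [cn_prior_table()].
#' @param max_transitions 0, 1 or 2.
#' @param delta Per-added-transition acceptance threshold in log units
#'   (default 10).
#' @param eps,eps_depth Emission clamps, see [emission_loglik()].
#' @return A `cn_path` with attributes `candidates` (best score per
#'   transition count) and `lambda`.
#' @export
best_paths <- function(reads_A, reads_B = NULL, lambda = NULL,
                       aggregate = NULL, prior = cn_prior_table(),
                       max_transitions = 2, delta = 10,
                       eps = 0.01, eps_depth = 0.05) {
  if (inherits(reads_A, "mip_counts")) {
    stopifnot(length(reads_A$samples) == 1L)
    reads_B <- as.vector(reads_A$reads_B)
    reads_A <- as.vector(reads_A$reads_A)
  }
  if (length(reads_A) == 0L) stop("no targets", call. = FALSE)
  ok <- !is.na(reads_A) & !is.na(reads_B)
  if (!any(ok)) stop("all targets missing: no call possible", call. = FALSE)
  if (is.null(lambda)) {
    mean_tot <- mean(reads_A[ok] + reads_B[ok])
    lambda <- if (!is.null(aggregate)) {
      if (aggregate <= 0) stop("aggregate must be positive", call. = FALSE)
      mean_tot * 4 / aggregate
    } else {
      mean_tot
    }
  }
  n <- length(reads_A)
  st <- paralog_states()
  E <- emission_matrix(reads_A, reads_B, lambda, eps, eps_depth)
  # C[i, k+1] = sum of emissions of state i over targets 1..k
  C <- cbind(0, t(apply(E, 1L, cumsum)))
  p0 <- unname(prior[as.character(st$cnA)] + prior[as.character(st$cnB)])

  cand <- list()
  # 0 transitions
  sc0 <- p0 + C[, n + 1L]
  i0 <- which.max(sc0)
  cand[["0"]] <- list(score = sc0[i0], bp = integer(0), states = i0)

  trans <- allowed_transitions()
  if (max_transitions >= 1 && n >= 2) {
    best1 <- -Inf; best1_bp <- NA_integer_; best1_states <- NULL
    for (r in seq_len(nrow(trans))) {
      i <- trans[r, 1]; j <- trans[r, 2]
      k <- 1:(n - 1)
      sc <- p0[i] + C[i, k + 1L] + (C[j, n + 1L] - C[j, k + 1L])
      m <- which.max(sc)
      if (sc[m] > best1) {
        best1 <- sc[m]; best1_bp <- k[m]; best1_states <- c(i, j)
      }
    }
    cand[["1"]] <- list(score = best1, bp = best1_bp, states = best1_states)
  }
  if (max_transitions >= 2 && n >= 3) {
    best2 <- -Inf; best2_bp <- NULL; best2_states <- NULL
    for (r in seq_len(nrow(trans))) {
      i <- trans[r, 1]; j <- trans[r, 2]
      # score(k1,k2) = p0[i] + C[i,n+1] + D[k1+1] - D[k2+1], 1 <= k1 < k2 <= n-1
      D <- C[i, ] - C[j, ]
      k <- 1:(n - 1)
      Dk <- D[k + 1L]
      pref <- cummax(Dk)            # best D over k1 <= k
      k2 <- 2:(n - 1)
      sc <- p0[i] + C[i, n + 1L] + pref[k2 - 1L] - Dk[k2]
      m <- which.max(sc)
      if (sc[m] > best2) {
        kk2 <- k2[m]
        kk1 <- which(Dk[1:(kk2 - 1L)] == pref[kk2 - 1L])[1]
        best2 <- sc[m]; best2_bp <- c(kk1, kk2); best2_states <- c(i, j, i)
      }
    }
    cand[["2"]] <- list(score = best2, bp = best2_bp, states = best2_states)
  }

  # model selection: extra transition must improve by >= delta per transition
  ts <- as.integer(names(cand))
  pen <- vapply(cand, `[[`, numeric(1), "score") - delta * ts
  pick <- names(cand)[max(which(pen == max(pen)))]
  best <- cand[[pick]]
  path <- cn_path(best$bp, st[best$states, , drop = FALSE], best$score, n)
  attr(path, "candidates") <- vapply(cand, `[[`, numeric(1), "score")
  attr(path, "lambda") <- lambda
  path
}

#' Classify a copy-number path as a structural event
#'
#' Maps a segmentation to an event call: whole-locus gains/losses (0
#' transitions away from the diploid (2,2) state), terminal events (1
#' transition), and internal events (2 transitions returning to the flanking
#' state) — internal duplication/deletion when one paralog changes, or
#' interlocus gene conversion when the middle segment is copy-neutral
#' (`cnA + cnB` unchanged); the conversion donor is the paralog whose
#' apparent copy number rose.
#'
#' @param path A `cn_path` (typically from [best_paths()]).
#' @return An object of class `event_call`: list with `kind`, `paralog`,
#'   `span` (0-based half-open target interval), `flanking_state`,
#'   `event_state`, `score`.
#' @export
classify_event <- function(path) {
  stopifnot(inherits(path, "cn_path"))
  st <- path$states
  n <- path$n_targets
  nt <- length(path$breakpoints)
  mk <- function(kind, paralog, span, flank, event) {
    structure(list(kind = kind, paralog = paralog, span = span,
                   flanking_state = flank, event_state = event,
                   score = path$score),
              class = "event_call")
  }
  if (nt >= 1) check_path_transitions(path)
  if (nt == 0L) {
    a <- st$cnA[1]; b <- st$cnB[1]
    flank <- c(cnA = 2L, cnB = 2L); ev <- c(cnA = a, cnB = b)
    if (a == 2 && b == 2) return(mk("none", NA_character_, c(0L, n), ev, ev))
    da <- a - 2L; db <- b - 2L
    if (da >= 0 && db >= 0) {
      return(mk("whole_locus_gain", paralog_label(da > 0, db > 0),
                c(0L, n), flank, ev))
    }
    if (da <= 0 && db <= 0) {
      return(mk("whole_locus_loss", paralog_label(da < 0, db < 0),
                c(0L, n), flank, ev))
    }
    # opposite directions
    if (a + b == 4L) {
      donor <- if (da > 0) "A" else "B"
      return(mk("gene_conversion", donor, c(0L, n), flank, ev))
    }
    if (a + b > 4L) {
      return(mk("whole_locus_gain", if (da > 0) "A" else "B",
                c(0L, n), flank, ev))
    }
    return(mk("whole_locus_loss", if (da < 0) "A" else "B",
              c(0L, n), flank, ev))
  }
  if (nt == 1L) {
    # terminal event: the segment farther from (2,2) is the event
    d <- abs(st$cnA - 2L) + abs(st$cnB - 2L)
    ev_i <- if (d[2] >= d[1]) 2L else 1L
    fl_i <- 3L - ev_i
    span <- if (ev_i == 2L) c(path$breakpoints[1], n) else
      c(0L, path$breakpoints[1])
    flank <- c(cnA = st$cnA[fl_i], cnB = st$cnB[fl_i])
    ev <- c(cnA = st$cnA[ev_i], cnB = st$cnB[ev_i])
    return(mk(event_kind(flank, ev), event_paralog(flank, ev), span, flank, ev))
  }
  # 2 transitions: restriction guarantees return to the flanking state
  if (st$cnA[1] != st$cnA[3] || st$cnB[1] != st$cnB[3]) {
    stop("2-transition path does not return to its flanking state",
         call. = FALSE)
  }
  flank <- c(cnA = st$cnA[1], cnB = st$cnB[1])
  ev <- c(cnA = st$cnA[2], cnB = st$cnB[2])
  span <- c(path$breakpoints[1], path$breakpoints[2])
  kind <- event_kind(flank, ev)
  if (kind == "gene_conversion" && sum(ev) != sum(flank)) {
    stop("internal error: gene conversion call is not copy-neutral",
         call. = FALSE)
  }
  mk(kind, event_paralog(flank, ev), span, flank, ev)
}

paralog_label <- function(a_changed, b_changed) {
  if (a_changed && b_changed) "both" else if (a_changed) "A" else "B"
}

event_kind <- function(flank, ev) {
  da <- ev[["cnA"]] - flank[["cnA"]]
  db <- ev[["cnB"]] - flank[["cnB"]]
  if (da == 0 && db == 0) return("none")
  if (da + db == 0) return("gene_conversion")  # copy-neutral exchange
  if (da + db > 0) "internal_duplication" else "internal_deletion"
}

event_paralog <- function(flank, ev) {
  da <- ev[["cnA"]] - flank[["cnA"]]
  db <- ev[["cnB"]] - flank[["cnB"]]
  if (da + db == 0 && da != 0) return(if (da > 0) "A" else "B")  # donor
  if (da != 0 && db != 0) return("both")
  if (da != 0) "A" else if (db != 0) "B" else NA_character_
}

# validate that consecutive states differ by a permitted transition
check_path_transitions <- function(path) {
  st <- path$states
  for (i in seq_len(nrow(st) - 1L)) {
    da <- st$cnA[i + 1] - st$cnA[i]
    db <- st$cnB[i + 1] - st$cnB[i]
    legal <- (abs(da) == 1 && db == 0) || (da == 0 && abs(db) == 1) ||
      (da == 1 && db == -1) || (da == -1 && db == 1)
    if (!legal) {
      stop(sprintf("illegal transition (%d,%d) -> (%d,%d)",
                   st$cnA[i], st$cnB[i], st$cnA[i + 1], st$cnB[i + 1]),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.event_call <- function(x, ...) {
  cat(sprintf("<event_call> %s (paralog %s) span [%d,%d) event (%d,%d)\n",
              x$kind, x$paralog, x$span[1], x$span[2],
              x$event_state[["cnA"]], x$event_state[["cnB"]]))
  invisible(x)
}

#' Call copy-number events across a cohort
#'
#' Runs [best_paths()] and [classify_event()] on every sample of a count
#' matrix and returns a tidy call table. The depth scale `lambda` is shared
#' across samples ([estimate_lambda()]) unless per-sample WGS aggregate
#' copy numbers are supplied.
#'
#' @param counts A [mip_counts()] object.
#' @param aggregate Optional named numeric vector of per-sample WGS aggregate
#'   copy numbers.
#' @param lambda Optional fixed depth scale (overrides estimation).
#' @inheritParams best_paths
#' @return A data frame with one row per sample: `sample`, `kind`, `paralog`,
#'   `start_target`, `end_target`, flanking and event states, and `score`.
#'   The underlying `cn_path` objects are attached as attribute `paths`.
#' @export
call_cn <- function(counts, aggregate = NULL, lambda = NULL,
                    prior = cn_prior_table(), max_transitions = 2,
                    delta = 10, eps = 0.01, eps_depth = 0.05) {
  stopifnot(inherits(counts, "mip_counts"))
  if (is.null(lambda) && is.null(aggregate)) {
    lambda <- estimate_lambda(counts)
  }
  paths <- list()
  rows <- lapply(counts$samples, function(s) {
    agg <- if (!is.null(aggregate)) unname(aggregate[s]) else NULL
    p <- best_paths(counts$reads_A[s, ], counts$reads_B[s, ], lambda = lambda,
                    aggregate = agg, prior = prior,
                    max_transitions = max_transitions, delta = delta,
                    eps = eps, eps_depth = eps_depth)
    paths[[s]] <<- p
    ev <- classify_event(p)
    data.frame(sample = s, kind = ev$kind, paralog = ev$paralog,
               start_target = ev$span[1], end_target = ev$span[2],
               cnA_flank = ev$flanking_state[["cnA"]],
               cnB_flank = ev$flanking_state[["cnB"]],
               cnA_event = ev$event_state[["cnA"]],
               cnB_event = ev$event_state[["cnB"]],
               score = ev$score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "paths") <- paths
  out
}

#' Export event spans as BED
#'
#' Writes the called spans in BED format using target indices as coordinates
#' (or genomic coordinates when a target position table is given).
#'
#' @param calls Call table from [call_cn()].
#' @param path Output file.
#' @param target_pos Optional data frame `target, chrom, start, end` mapping
#'   target indices to genomic coordinates.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path, target_pos = NULL) {
  ev <- calls[calls$kind != "none", , drop = FALSE]
  if (is.null(target_pos)) {
    bed <- data.frame(chrom = rep("targets", nrow(ev)),
                      start = ev$start_target,
                      end = ev$end_target,
                      name = paste(ev$sample, ev$kind, ev$paralog, sep = "|"))
  } else {
    i1 <- match(ev$start_target + 1L, seq_len(nrow(target_pos)))
    i2 <- match(ev$end_target, seq_len(nrow(target_pos)))
    bed <- data.frame(chrom = target_pos$chrom[i1],
                      start = target_pos$start[i1], end = target_pos$end[i2],
                      name = paste(ev$sample, ev$kind, ev$paralog, sep = "|"))
  }
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
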
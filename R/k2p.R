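BASES <- c("A", "C", "G", "T")
# transition partner of each base (A<->G, C<->T), indexed as in BASES
TS_PARTNER <- c(3L, 4L, 1L, 2L)

stop_saturation <- function(msg) {
  stop(structure(class = c("paraloci_saturation", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Normalize sequence input to an alignment matrix
#'
#' Accepts a character matrix (rows = taxa), a named character vector of
#' equal-length strings, a list of strings, or a `Biostrings::DNAStringSet`.
#' Characters outside A/C/G/T/- are treated as N (missing).
#'
#' @param x Sequences in any supported representation.
#' @return Uppercase character matrix with one row per sequence.
#' @export
as_alignment <- function(x) {
  if (is.matrix(x)) {
    m <- toupper(x)
  } else {
    if (inherits(x, "DNAStringSet")) x <- as.character(x)
    if (is.list(x)) x <- unlist(x)
    len <- unique(nchar(x))
    if (length(len) != 1L) stop("sequences have unequal lengths", call. = FALSE)
    m <- do.call(rbind, strsplit(toupper(x), ""))
    rownames(m) <- names(x)
  }
  if (is.null(rownames(m))) {
    rownames(m) <- sprintf("seq%d", seq_len(nrow(m)))
  }
  if (anyDuplicated(rownames(m))) stop("sequence names must be unique",
                                       call. = FALSE)
  m[!(m %in% c(BASES, "-"))] <- "N"
  m
}

#' Read and write FASTA alignments
#' @param path FASTA file.
#' @param aln Alignment (anything [as_alignment()] accepts).
#' @return `read_fasta_alignment()` returns a character matrix;
#'   `write_fasta_alignment()` returns `path` invisibly.
#' @export
read_fasta_alignment <- function(path) {
  as_alignment(Biostrings::readDNAStringSet(path))
}

#' @rdname read_fasta_alignment
#' @export
write_fasta_alignment <- function(aln, path) {
  m <- as_alignment(aln)
  ss <- Biostrings::DNAStringSet(apply(m, 1L, paste0, collapse = ""))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

# K2P substitution probabilities for a branch of length d (subs/site), with
# kappa the expected ts:tv substitution-count ratio (alpha / (2 beta)).
k2p_branch_probs <- function(d, kappa) {
  at <- d * kappa / (kappa + 1)       # alpha * t
  bt <- d / (2 * (kappa + 1))         # beta * t
  e1 <- exp(-4 * bt)
  e2 <- exp(-2 * (at + bt))
  c(same = 0.25 + 0.25 * e1 + 0.5 * e2,
    ts   = 0.25 + 0.25 * e1 - 0.5 * e2,
    tv   = 0.25 - 0.25 * e1)          # each of the two transversions
}

# evolve integer-coded sequence (1..4) along one branch
k2p_evolve <- function(idx, d, kappa) {
  if (d == 0) return(idx)
  pr <- k2p_branch_probs(d, kappa)
  out <- idx
  for (b in 1:4) {
    at_b <- which(idx == b)
    if (!length(at_b)) next
    p <- rep(pr[["tv"]], 4)
    p[b] <- pr[["same"]]
    p[TS_PARTNER[b]] <- pr[["ts"]]
    out[at_b] <- sample.int(4L, length(at_b), replace = TRUE, prob = p)
  }
  out
}

#' Simulate a K2P-evolved duplication quartet
#'
#' Evolves a four-taxon alignment `((paralogA, paralogB), chimp, orang)`
#' site-independently under the Kimura two-parameter model with no indels.
#' The two paralogs split `t_dup` mya, human and chimp `t_cc` mya, orangutan
#' `t_out` mya; every branch length is `subs_rate * time`.
#'
#' @param scenario An [evo_scenario()].
#' @return Character matrix alignment with rows `paralogA`, `paralogB`,
#'   `chimp`, `orang`.
#' @examples
#' aln <- simulate_k2p_quartet(evo_scenario(t_dup = 3, seq_len = 1000))
#' dim(aln)
#' @export
simulate_k2p_quartet <- function(scenario) {
  stopifnot(inherits(scenario, "evo_scenario"))
  set.seed(scenario$seed)
  L <- scenario$seq_len
  r <- scenario$subs_rate
  k <- scenario$kappa
  root <- sample.int(4L, L, replace = TRUE)
  hc_anc <- k2p_evolve(root, r * (scenario$t_out - scenario$t_cc), k)
  orang <- k2p_evolve(root, r * scenario$t_out, k)
  chimp <- k2p_evolve(hc_anc, r * scenario$t_cc, k)
  dup_anc <- k2p_evolve(hc_anc, r * (scenario$t_cc - scenario$t_dup), k)
  pA <- k2p_evolve(dup_anc, r * scenario$t_dup, k)
  pB <- k2p_evolve(dup_anc, r * scenario$t_dup, k)
  m <- rbind(paralogA = BASES[pA], paralogB = BASES[pB],
             chimp = BASES[chimp], orang = BASES[orang])
  m
}

# columns usable (A/C/G/T in every row of m)
usable_columns <- function(m) {
  colSums(matrix(m %in% BASES, nrow = nrow(m))) == nrow(m)
}

# 0 = identical, 1 = transition, 2 = transversion (inputs integer-coded 1..4)
pair_category <- function(i, j) {
  ifelse(i == j, 0L, ifelse(TS_PARTNER[i] == j, 1L, 2L))
}

k2p_from_PQ <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  d <- ifelse(w1 > 0 & w2 > 0, -0.5 * log(w1) - 0.25 * log(w2), NA_real_)
  d
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Computes the transition proportion `P`, transversion proportion `Q` and
#' the K2P distance `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` after removing
#' columns with gaps or ambiguous bases. Under the default `complete`
#' deletion a column is removed if any sequence of the supplied alignment is
#' missing there; under `pairwise` deletion only the two compared sequences
#' are consulted.
#'
#' @param aln Alignment ([as_alignment()] input) containing the sequences.
#' @param pair Length-2 vector of row names or indices to compare (defaults
#'   to the first two rows).
#' @param deletion `"complete"` (default) or `"pairwise"`.
#' @return A list of class `k2p_distance`: `P`, `Q`, `d`, `usable_sites`.
#'   Saturated pairs (`1 - 2P - Q <= 0` or `1 - 2Q <= 0`) raise an error of
#'   class `paraloci_saturation`.
#' @export
k2p_distance <- function(aln, pair = c(1L, 2L),
                         deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  m <- as_alignment(aln)
  if (is.character(pair)) pair <- match(pair, rownames(m))
  if (anyNA(pair) || length(pair) != 2L) stop("invalid pair", call. = FALSE)
  keep <- if (deletion == "complete") usable_columns(m) else
    usable_columns(m[pair, , drop = FALSE])
  x <- match(m[pair[1], keep], BASES)
  y <- match(m[pair[2], keep], BASES)
  L <- length(x)
  if (L == 0L) stop("no usable sites after deletion", call. = FALSE)
  cat_ <- pair_category(x, y)
  P <- sum(cat_ == 1L) / L
  Q <- sum(cat_ == 2L) / L
  d <- k2p_from_PQ(P, Q)
  if (is.na(d)) {
    stop_saturation(sprintf(
      "K2P distance undefined (saturation): P = %.3f, Q = %.3f", P, Q))
  }
  structure(list(P = P, Q = Q, d = d, usable_sites = L),
            class = "k2p_distance")
}

#' @export
print.k2p_distance <- function(x, ...) {
  cat(sprintf("<k2p_distance> d = %.6g (P = %.4g, Q = %.4g, %d sites)\n",
              x$d, x$P, x$Q, x$usable_sites))
  invisible(x)
}

#' Pairwise K2P distance matrix for an alignment
#'
#' @inheritParams k2p_distance
#' @return A symmetric numeric matrix of K2P distances.
#' @export
k2p_matrix <- function(aln, deletion = c("complete", "pairwise")) {
  deletion <- match.arg(deletion)
  m <- as_alignment(aln)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      D[i, j] <- D[j, i] <- k2p_distance(m, c(i, j), deletion)$d
    }
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via \pkg{ape}), returning an
#' unrooted tree. Negative branch lengths, which NJ can produce on
#' non-additive input, are clamped to zero and flagged in the
#' `"clamped_negative"` attribute.
#'
#' @param D Symmetric numeric distance matrix with zero diagonal, >= 3 taxa.
#' @return An object of class `phylo`.
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least 3 taxa", call. = FALSE)
  if (!isSymmetric(unname(D), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  if (any(abs(diag(D)) > 1e-12)) {
    stop("distance matrix must have zero diagonal", call. = FALSE)
  }
  tr <- ape::nj(D)
  neg <- tr$edge.length < 0
  if (any(neg)) tr$edge.length[neg] <- 0
  attr(tr, "clamped_negative") <- sum(neg)
  tr
}

#' Tajima's relative rate test
#'
#' Tests whether two ingroup sequences evolve at equal rates using an
#' outgroup: with `m1` the usable sites where only sequence 1 differs (2 and
#' the outgroup agree) and `m2` the converse, the statistic
#' `(m1 - m2)^2 / (m1 + m2)` is chi-squared with 1 degree of freedom.
#' Columns with gaps or ambiguity in any of the three sequences are removed
#' first. When `m1 + m2 = 0` the test is undefined and `p = 1` is returned
#' with `undefined = TRUE`.
#'
#' @param aln Alignment containing the three sequences.
#' @param seq1,seq2 Names or indices of the two ingroup sequences.
#' @param outgroup Name or index of the outgroup.
#' @return List with `m1`, `m2`, `chi2`, `p`, `undefined`.
#' @export
tajima_relative_rate <- function(aln, seq1 = 1L, seq2 = 2L, outgroup = 3L) {
  m <- as_alignment(aln)
  pick <- function(z) if (is.character(z)) match(z, rownames(m)) else z
  i1 <- pick(seq1); i2 <- pick(seq2); io <- pick(outgroup)
  sub <- m[c(i1, i2, io), , drop = FALSE]
  keep <- usable_columns(sub)
  s1 <- sub[1, keep]; s2 <- sub[2, keep]; so <- sub[3, keep]
  m1 <- sum(s1 != s2 & s2 == so)
  m2 <- sum(s1 != s2 & s1 == so)
  if (m1 + m2 == 0L) {
    return(list(m1 = m1, m2 = m2, chi2 = 0, p = 1, undefined = TRUE))
  }
  chi2 <- (m1 - m2)^2 / (m1 + m2)
  list(m1 = m1, m2 = m2, chi2 = chi2,
       p = stats::pchisq(chi2, df = 1, lower.tail = FALSE), undefined = FALSE)
}
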
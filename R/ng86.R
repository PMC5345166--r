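# Codon machinery for Nei-Gojobori (1986) dN/dS. The standard genetic code
# comes from Biostrings; everything else (site fractions, pathway averaging)
# is computed here.

ng86_env <- new.env(parent = emptyenv())

codon_table <- function() {
  if (!is.null(ng86_env$aa)) return(invisible(NULL))
  codons <- apply(expand.grid(BASES, BASES, BASES,
                              stringsAsFactors = FALSE)[, 3:1], 1L,
                  paste0, collapse = "")
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  names(aa) <- codons
  # synonymous site count per codon: at each position, the fraction of
  # non-stop single-nucleotide changes that preserve the amino acid
  # ("nonsense mutations are disregarded", i.e. excluded from numerator
  # and denominator)
  syn_sites <- vapply(codons, function(cd) {
    ch <- strsplit(cd, "")[[1]]
    s <- 0
    for (p in 1:3) {
      alts <- setdiff(BASES, ch[p])
      neigh <- vapply(alts, function(b) {
        x <- ch; x[p] <- b; paste0(x, collapse = "")
      }, character(1))
      a <- aa[neigh]
      nonstop <- a != "*"
      if (any(nonstop)) s <- s + sum(a[nonstop] == aa[cd]) / sum(nonstop)
    }
    s
  }, numeric(1))
  ng86_env$codons <- codons
  ng86_env$aa <- aa
  ng86_env$syn_sites <- syn_sites
  invisible(NULL)
}

# average synonymous/nonsynonymous differences between two codons over all
# minimal mutational pathways; pathways passing through a stop codon are
# excluded (if every pathway is blocked, all are used and `blocked` is TRUE)
codon_pathway_diffs <- function(c1, c2) {
  codon_table()
  aa <- ng86_env$aa
  ch1 <- strsplit(c1, "")[[1]]
  ch2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(ch1 != ch2)
  k <- length(diff_pos)
  if (k == 0L) return(list(sd = 0, nd = 0, blocked = FALSE))
  perms <- if (k == 1L) list(diff_pos) else {
    idx <- if (k == 2L) list(c(1, 2), c(2, 1)) else
      list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
           c(3, 1, 2), c(3, 2, 1))
    lapply(idx, function(o) diff_pos[o])
  }
  walk <- function(order_pos) {
    cur <- ch1
    sd <- 0; nd <- 0
    for (p in order_pos) {
      nxt <- cur
      nxt[p] <- ch2[p]
      a1 <- aa[paste0(cur, collapse = "")]
      a2 <- aa[paste0(nxt, collapse = "")]
      if (a2 == "*" && !identical(nxt, ch2)) return(NULL)  # stop intermediate
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- lapply(perms, walk)
  ok <- !vapply(res, is.null, logical(1))
  blocked <- !any(ok)
  if (blocked) {
    res <- lapply(perms, function(o) {  # fall back: allow stop intermediates
      cur <- ch1; sd <- 0; nd <- 0
      for (p in o) {
        nxt <- cur; nxt[p] <- ch2[p]
        if (aa[paste0(cur, collapse = "")] == aa[paste0(nxt, collapse = "")])
          sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    })
    ok <- rep(TRUE, length(res))
  }
  mm <- do.call(rbind, res[ok])
  list(sd = mean(mm[, 1]), nd = mean(mm[, 2]), blocked = blocked)
}

#' Nei-Gojobori (1986) pairwise dN/dS
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per sequence (averaged
#' over the pair), counts synonymous and nonsynonymous differences averaging
#' equally over all minimal mutational pathways between differing codons
#' (pathways through stop codons excluded), and applies the Jukes-Cantor
#' correction `d = -3/4 ln(1 - 4p/3)` to the proportions `pN = nd/N`,
#' `pS = sd/S`. Codon columns containing a gap, an ambiguous base, or a stop
#' codon in either sequence are dropped (pairwise deletion). Site counting
#' disregards mutations to stop codons.
#'
#' @param seqA,seqB In-frame aligned coding sequences (equal length, a
#'   multiple of 3); strings or character vectors.
#' @return An object of class `ng86`: `S`, `N`, `sd`, `nd`, `pS`, `pN`,
#'   `dS`, `dN`, `omega`, `n_codons` (codons used), `omega_undefined`
#'   (TRUE when `dS = 0`, in which case `omega` is `NaN`),
#'   `n_blocked_pathways`.
#' @examples
#' ng86_dnds("ATGAAACCCGGGTTT", "ATGAGACCCGGGTTC")
#' @export
ng86_dnds <- function(seqA, seqB) {
  codon_table()
  a <- toupper(paste0(seqA, collapse = ""))
  b <- toupper(paste0(seqB, collapse = ""))
  if (nchar(a) != nchar(b)) stop("sequences must be aligned", call. = FALSE)
  if (nchar(a) %% 3 != 0) stop("length must be a multiple of 3", call. = FALSE)
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  clean <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  aa <- ng86_env$aa
  clean <- clean & ifelse(clean, aa[ca] != "*" & aa[cb] != "*", FALSE)
  ca <- ca[clean]; cb <- cb[clean]
  n_codons <- length(ca)
  if (n_codons == 0L) stop("no usable codons after deletion", call. = FALSE)
  S <- (sum(ng86_env$syn_sites[ca]) + sum(ng86_env$syn_sites[cb])) / 2
  N <- 3 * n_codons - S
  sd_ <- 0; nd_ <- 0; blocked <- 0L
  for (i in which(ca != cb)) {
    pw <- codon_pathway_diffs(ca[i], cb[i])
    sd_ <- sd_ + pw$sd
    nd_ <- nd_ + pw$nd
    blocked <- blocked + pw$blocked
  }
  pS <- sd_ / S
  pN <- nd_ / N
  if (pS >= 0.75 || pN >= 0.75) {
    stop_saturation(sprintf(
      "proportion of differences saturated (pS = %.3f, pN = %.3f)", pS, pN))
  }
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  dS <- jc(pS)
  dN <- jc(pN)
  omega_undefined <- dS == 0
  omega <- if (omega_undefined) NaN else dN / dS
  structure(
    list(S = S, N = N, sd = sd_, nd = nd_, pS = pS, pN = pN, dS = dS, dN = dN,
         omega = omega, n_codons = n_codons,
         omega_undefined = omega_undefined, n_blocked_pathways = blocked),
    class = "ng86"
  )
}

#' @export
print.ng86 <- function(x, ...) {
  cat(sprintf(
    "<ng86> dN = %.5g, dS = %.5g, omega = %s (S = %.2f, N = %.2f, %d codons)\n",
    x$dN, x$dS, if (x$omega_undefined) "undefined (dS = 0)" else
      sprintf("%.4g", x$omega), x$S, x$N, x$n_codons))
  invisible(x)
}
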
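# Independent oracles used across the suite. These deliberately re-derive
# results by exhaustive enumeration or closed forms, sharing as little code
# as possible with the implementation under test.

# --- exhaustive path search -------------------------------------------------
# Enumerates every legal segmentation with <= 2 transitions and every state
# assignment, scoring each candidate by direct summation of emissions, and
# returns the best penalized candidate (ties to more transitions, matching
# the acceptance rule "improvement >= delta accepts").
brute_force_paths <- function(reads_A, reads_B, lambda, delta = 10,
                              prior = cn_prior_table()) {
  n <- length(reads_A)
  states <- expand.grid(cnA = 0:4, cnB = 0:4)
  seg_score <- function(si, from, to) { # targets from..to (1-based incl)
    sum(emission_loglik(reads_A[from:to], reads_B[from:to],
                        states$cnA[si], states$cnB[si], lambda))
  }
  legal_step <- function(i, j) {
    da <- states$cnA[j] - states$cnA[i]
    db <- states$cnB[j] - states$cnB[i]
    (abs(da) == 1 && db == 0) || (da == 0 && abs(db) == 1) ||
      (da == 1 && db == -1) || (da == -1 && db == 1)
  }
  p0 <- unname(prior[as.character(states$cnA)] +
                 prior[as.character(states$cnB)])
  best <- NULL
  consider <- function(score, ntrans, bp, sts) {
    pen <- score - delta * ntrans
    if (is.null(best) || pen > best$pen ||
        (pen == best$pen && ntrans > best$ntrans)) {
      best <<- list(score = score, pen = pen, ntrans = ntrans, bp = bp,
                    states = sts)
    }
  }
  for (i in 1:25) consider(p0[i] + seg_score(i, 1, n), 0L, integer(0), i)
  if (n >= 2) {
    for (i in 1:25) for (j in 1:25) {
      if (!legal_step(i, j)) next
      for (k in 1:(n - 1)) {
        consider(p0[i] + seg_score(i, 1, k) + seg_score(j, k + 1, n),
                 1L, k, c(i, j))
      }
    }
  }
  if (n >= 3) {
    for (i in 1:25) for (j in 1:25) {
      if (!legal_step(i, j)) next   # second transition must invert the first
      for (k1 in 1:(n - 2)) for (k2 in (k1 + 1):(n - 1)) {
        consider(p0[i] + seg_score(i, 1, k1) + seg_score(j, k1 + 1, k2) +
                   seg_score(i, k2 + 1, n), 2L, c(k1, k2), c(i, j, i))
      }
    }
  }
  best
}

random_counts_instance <- function(seed, n_targets = sample(3:12, 1)) {
  set.seed(seed)
  n <- n_targets
  lambda <- sample(c(60, 100, 200), 1)
  cn_tot <- sample(0:8, n, replace = TRUE, prob = c(1, 2, 3, 8, 3, 2, 1, 1, 1))
  total <- rpois(n, lambda * cn_tot / 4 + 1)
  reads_A <- rbinom(n, total, runif(n))
  list(reads_A = reads_A, reads_B = total - reads_A, lambda = lambda)
}

# --- NG86 brute-force pathway oracle ----------------------------------------
# Independent recursive enumerator over mutational pathways plus its own
# site counter; only the genetic code table is shared.
.gc_oracle <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) gc <<- Biostrings::GENETIC_CODE
    gc
  }
})

oracle_syn_sites <- function(codon) {
  gc <- .gc_oracle()
  ch <- strsplit(codon, "")[[1]]
  total <- 0
  for (p in 1:3) {
    syn <- 0; denom <- 0
    for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
      alt <- ch; alt[p] <- b
      aa <- gc[[paste(alt, collapse = "")]]
      if (aa == "*") next
      denom <- denom + 1
      if (aa == gc[[codon]]) syn <- syn + 1
    }
    if (denom > 0) total <- total + syn / denom
  }
  total
}

oracle_pathways <- function(c1, c2) {
  gc <- .gc_oracle()
  ch1 <- strsplit(c1, "")[[1]]
  ch2 <- strsplit(c2, "")[[1]]
  res <- list()
  recurse <- function(cur, sd, nd) {
    dp <- which(cur != ch2)
    if (length(dp) == 0) {
      res[[length(res) + 1L]] <<- c(sd, nd)
      return(invisible(NULL))
    }
    for (p in dp) {
      nxt <- cur; nxt[p] <- ch2[p]
      aa1 <- gc[[paste(cur, collapse = "")]]
      aa2 <- gc[[paste(nxt, collapse = "")]]
      if (aa2 == "*" && any(nxt != ch2)) next   # stop intermediate: prune
      recurse(nxt, sd + (aa1 == aa2), nd + (aa1 != aa2))
    }
  }
  recurse(ch1, 0, 0)
  if (length(res) == 0) return(NULL)            # all pathways blocked
  m <- do.call(rbind, res)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

oracle_ng86 <- function(seqA, seqB) {
  gc <- .gc_oracle()
  split_codons <- function(s) {
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  }
  ca <- split_codons(toupper(seqA))
  cb <- split_codons(toupper(seqB))
  keep <- grepl("^[ACGT]{3}$", ca) & grepl("^[ACGT]{3}$", cb)
  keep <- keep & vapply(seq_along(ca), function(i) {
    if (!keep[i]) return(FALSE)
    gc[[ca[i]]] != "*" && gc[[cb[i]]] != "*"
  }, logical(1))
  ca <- ca[keep]; cb <- cb[keep]
  S <- (sum(vapply(ca, oracle_syn_sites, numeric(1))) +
          sum(vapply(cb, oracle_syn_sites, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  sd <- 0; nd <- 0
  for (i in which(ca != cb)) {
    pw <- oracle_pathways(ca[i], cb[i])
    if (is.null(pw)) {                       # blocked: average over all paths
      pw <- oracle_all_pathways(ca[i], cb[i])
    }
    sd <- sd + pw[["sd"]]; nd <- nd + pw[["nd"]]
  }
  pS <- sd / S; pN <- nd / N
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, sd = sd, nd = nd, pS = pS, pN = pN,
       dS = jc(pS), dN = jc(pN))
}

oracle_all_pathways <- function(c1, c2) {
  gc <- .gc_oracle()
  ch1 <- strsplit(c1, "")[[1]]
  ch2 <- strsplit(c2, "")[[1]]
  res <- list()
  recurse <- function(cur, sd, nd) {
    dp <- which(cur != ch2)
    if (length(dp) == 0) {
      res[[length(res) + 1L]] <<- c(sd, nd)
      return(invisible(NULL))
    }
    for (p in dp) {
      nxt <- cur; nxt[p] <- ch2[p]
      aa1 <- gc[[paste(cur, collapse = "")]]
      aa2 <- gc[[paste(nxt, collapse = "")]]
      recurse(nxt, sd + (aa1 == aa2), nd + (aa1 != aa2))
    }
  }
  recurse(ch1, 0, 0)
  m <- do.call(rbind, res)
  c(sd = mean(m[, 1]), nd = mean(m[, 2]))
}

random_codon_seq <- function(n_codons) {
  sense <- setdiff(names(.gc_oracle()), c("TAA", "TAG", "TGA"))
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

mutate_codon_seq <- function(seq, n_mut) {
  ch <- strsplit(seq, "")[[1]]
  gc <- .gc_oracle()
  for (k in seq_len(n_mut)) {
    repeat {
      p <- sample(length(ch), 1)
      b <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      new <- ch; new[p] <- b
      cd_start <- 3 * ((p - 1) %/% 3) + 1
      if (gc[[paste(new[cd_start:(cd_start + 2)], collapse = "")]] != "*") {
        ch <- new
        break
      }
    }
  }
  paste(ch, collapse = "")
}

# --- brute-force protein-level effect classifier ----------------------------
# Classifies a CDS SNV/indel by translating the full mutant CDS and
# comparing proteins (used against classify_effect on synthetic models).
oracle_effect_from_proteins <- function(model, pos, ref, alt) {
  gc <- .gc_oracle()
  translate <- function(dna) {
    n <- nchar(dna) - nchar(dna) %% 3
    if (n < 3) return("")
    cods <- substring(dna, seq(1, n, 3), seq(3, n, 3))
    aa <- vapply(cods, function(cd) gc[[cd]], character(1))
    stop_at <- which(aa == "*")[1]
    if (!is.na(stop_at)) aa <- aa[seq_len(stop_at - 1)]
    paste(aa, collapse = "")
  }
  splice <- function(seq) {
    ex <- model$exons
    paste(substring(seq, ex$start + 1, ex$end), collapse = "")
  }
  ref_cds <- splice(model$sequence)
  p0 <- pos - 1
  mut_genome <- paste0(substr(model$sequence, 1, p0),
                       alt,
                       substr(model$sequence, p0 + 1 + nchar(ref),
                              nchar(model$sequence)))
  # indels shift downstream exon coordinates; only valid for variants whose
  # edited bases stay inside one exon, which the generator guarantees
  shift <- nchar(alt) - nchar(ref)
  ex <- model$exons
  ex$start <- ex$start + ifelse(ex$start > p0, shift, 0)
  ex$end <- ex$end + ifelse(ex$end > p0 + nchar(ref) - 1, shift, 0)
  mut_cds <- paste(substring(mut_genome, ex$start + 1, ex$end), collapse = "")
  ref_prot <- translate(ref_cds)
  mut_prot <- translate(mut_cds)
  if (shift != 0) {
    if (abs(shift) %% 3 != 0) return("frameshift")
    return("other")
  }
  if (identical(ref_prot, mut_prot)) return("synonymous")
  if (nchar(mut_prot) < nchar(ref_prot) &&
      startsWith(ref_prot, mut_prot)) return("stop_gained")
  if (nchar(mut_prot) > nchar(ref_prot)) return("stop_lost")
  "missense"
}
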
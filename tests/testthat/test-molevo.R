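# K2P distances, neighbor joining, relative-rate test, duplication dating
# and NG86 dN/dS.

test_that("K2P distance matches the closed form and handles saturation", {
  same <- c(a = strrep("ACGT", 50), b = strrep("ACGT", 50))
  d0 <- k2p_distance(same)
  expect_equal(c(d0$P, d0$Q, d0$d), c(0, 0, 0))

  # construct exactly P = 0.1, Q = 0.05 over 1000 sites
  a <- rep("A", 1000)
  b <- a
  b[1:100] <- "G"            # transitions
  b[101:150] <- "C"          # transversions
  d <- k2p_distance(rbind(a = a, b = b))
  expect_equal(d$P, 0.1)
  expect_equal(d$Q, 0.05)
  expect_equal(d$d, -0.5 * log(0.75) - 0.25 * log(0.9), tolerance = 1e-12)

  sat <- a
  sat[1:300] <- "G"
  sat[301:750] <- "C"        # P = 0.3, Q = 0.45 -> 1 - 2P - Q < 0
  expect_error(k2p_distance(rbind(a = a, b = sat)),
               class = "paraloci_saturation")
})

test_that("complete deletion removes columns missing in any sequence", {
  aln <- rbind(a = c("A", "C", "G", "T", "A"),
               b = c("A", "C", "A", "T", "A"),
               c = c("A", "-", "G", "N", "A"))
  d_complete <- k2p_distance(aln, c("a", "b"))
  expect_equal(d_complete$usable_sites, 3L)     # cols 2 and 4 dropped
  d_pair <- k2p_distance(aln, c("a", "b"), deletion = "pairwise")
  expect_equal(d_pair$usable_sites, 5L)
})

test_that("K2P agrees with an established implementation on simulated data", {
  aln <- simulate_k2p_quartet(evo_scenario(t_dup = 2, seq_len = 20000,
                                           seed = 12))
  ours <- k2p_matrix(aln)
  bin <- ape::as.DNAbin(tolower(aln))
  ref <- as.matrix(ape::dist.dna(bin, model = "K80",
                                 pairwise.deletion = FALSE))
  expect_equal(ours, ref[rownames(ours), colnames(ours)], tolerance = 1e-9)
})

test_that("K2P reduces to Jukes-Cantor when transitions:transversions = 1:2", {
  a <- rep("A", 1000)
  b <- a
  b[1:100] <- "G"            # P = 0.1
  b[101:300] <- c("C", "T")  # Q = 0.2
  d <- k2p_distance(rbind(a = a, b = b))
  p <- d$P + d$Q
  expect_equal(d$d, -0.75 * log(1 - 4 * p / 3), tolerance = 1e-12)
})

test_that("neighbor joining recovers additive trees exactly", {
  # three taxa: unique solution of the three-point equations
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(letters[1:3], letters[1:3]))
  tr <- neighbor_joining(D3)
  dd <- ape::cophenetic.phylo(tr)
  expect_equal(dd[letters[1:3], letters[1:3]], D3, tolerance = 1e-9)

  # additive 4-taxon matrix from a known tree ((a:1,b:2):1,(c:3,d:1))
  true_tree <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:1):0);")
  D4 <- ape::cophenetic.phylo(true_tree)
  tr4 <- neighbor_joining(D4)
  expect_equal(ape::cophenetic.phylo(tr4)[rownames(D4), colnames(D4)],
               D4, tolerance = 1e-9)
  expect_true(ape::is.monophyletic(ape::root(tr4, "d"), c("a", "b")))

  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2)), "3 taxa")
  bad <- D3; bad[1, 2] <- 10
  expect_error(neighbor_joining(bad), "symmetric")
})

test_that("simulated quartets place the two paralogs as sisters", {
  aln <- simulate_k2p_quartet(evo_scenario(t_dup = 1, t_cc = 6,
                                           seq_len = 30000, seed = 14))
  tr <- neighbor_joining(k2p_matrix(aln))
  rooted <- ape::root(tr, "orang")
  expect_true(ape::is.monophyletic(rooted, c("paralogA", "paralogB")))
})

test_that("the relative-rate statistic follows its counting definition", {
  # outgroup O all A; seq1 differs alone at 10 sites; seq2 never
  o <- rep("A", 500)
  s1 <- o; s1[1:10] <- "G"
  s2 <- o
  res <- tajima_relative_rate(rbind(s1 = s1, s2 = s2, o = o), "s1", "s2", "o")
  expect_equal(res$m1, 10)
  expect_equal(res$m2, 0)
  expect_equal(res$chi2, 10)
  expect_equal(res$p, pchisq(10, 1, lower.tail = FALSE))

  sym <- tajima_relative_rate(rbind(s1 = s1, s2 = s1, o = o))
  expect_equal(sym$chi2, 0)
  expect_equal(sym$p, 1)

  ident <- tajima_relative_rate(rbind(a = o, b = o, c = o))
  expect_true(ident$undefined)
  expect_equal(ident$p, 1)
})

test_that("duplication dating follows the distance-ratio definition", {
  # equidistant triplet: ratio 1 -> t_hat = t_cc
  a <- rep("A", 3000)
  mk <- function(n_ts, offset) { x <- a; x[offset:(offset + n_ts - 1)] <- "G"; x }
  A <- mk(60, 1); B <- mk(60, 61); O <- mk(60, 121)
  # d(A,B), d(A,O), d(B,O) all have P = 120/3000
  res <- date_duplication(rbind(paralogA = A, paralogB = B, chimp = O),
                          n_boot = 50, seed = 1)
  expect_equal(res$t_hat, 6, tolerance = 1e-9)

  # zero-divergence paralogs
  res0 <- date_duplication(rbind(paralogA = A, paralogB = A, chimp = O),
                           n_boot = 50, seed = 1)
  expect_equal(res0$t_hat, 0)
  expect_equal(res0$ci_low, 0)
})

test_that("dating warns when the paralog rates are unequal", {
  o <- rep("A", 2000)
  fast <- o; fast[1:300] <- "G"
  slow <- o; slow[301:310] <- "G"
  expect_warning(
    date_duplication(rbind(paralogA = fast, paralogB = slow, chimp = o),
                     n_boot = 20, seed = 1),
    "relative-rate")
})

test_that("NG86 matches a hand-checked five-codon example", {
  # one synonymous difference (TTT>TTC) and one two-step difference
  # (CCT>CAA: pathways CCT>CAT>CAA and CCT>CCA>CAA, averaging
  # sd = 0.5, nd = 1.5)
  sA <- "ATGTTTCCTGGGAAA"
  sB <- "ATGTTCCAAGGGAAA"
  res <- ng86_dnds(sA, sB)
  expect_equal(res$sd, 1 + 0.5, tolerance = 1e-12)
  expect_equal(res$nd, 1.5, tolerance = 1e-12)
  orc <- oracle_ng86(sA, sB)
  expect_equal(res$S, orc$S, tolerance = 1e-12)
  expect_equal(res$dN, orc$dN, tolerance = 1e-12)
  expect_equal(res$dS, orc$dS, tolerance = 1e-12)
})

test_that("NG86 handles identical and dS-free pairs", {
  s <- random_codon_seq(120)
  same <- ng86_dnds(s, s)
  expect_equal(same$dN, 0)
  expect_equal(same$dS, 0)
  expect_true(same$omega_undefined)

  # single nonsynonymous change: dN > 0, dS = 0, omega flagged
  sA <- paste0("ATG", strrep("GGA", 100))
  sB <- paste0("ATG", "CGA", strrep("GGA", 99))
  res <- ng86_dnds(sA, sB)
  expect_gt(res$dN, 0)
  expect_equal(res$dS, 0)
  expect_true(res$omega_undefined)
})

test_that("NG86 drops gapped and stop codons under pairwise deletion", {
  sA <- paste0("ATGAAA---TTT", strrep("GGG", 10), "TAA")
  sB <- paste0("ATGAAGCCCTTC", strrep("GGG", 10), "TAA")
  res <- ng86_dnds(sA, sB)   # gap codon and stop codon dropped
  expect_equal(res$n_codons, 13L)
  expect_equal(res$sd, 2)    # AAA>AAG and TTT>TTC, both synonymous
  expect_equal(res$nd, 0)
  expect_error(ng86_dnds("ATG", "ATGG"), "aligned")
  expect_error(ng86_dnds("ATGA", "ATGA"), "multiple of 3")
})

test_that("NG86 agrees with the brute-force pathway enumerator", {
  set.seed(60)
  for (rep in 1:80) {
    n_cod <- sample(2:6, 1)
    sA <- random_codon_seq(n_cod)
    sB <- mutate_codon_seq(sA, sample(1:4, 1))
    res <- tryCatch(ng86_dnds(sA, sB),
                    paraloci_saturation = function(e) NULL)
    if (is.null(res)) next
    orc <- oracle_ng86(sA, sB)
    expect_equal(res$sd, orc$sd, tolerance = 1e-9)
    expect_equal(res$nd, orc$nd, tolerance = 1e-9)
    expect_equal(res$S, orc$S, tolerance = 1e-9)
    expect_equal(res$N, orc$N, tolerance = 1e-9)
    expect_equal(res$dN, orc$dN, tolerance = 1e-9)
    expect_equal(res$dS, orc$dS, tolerance = 1e-9)
  }
})

test_that("alignments survive a FASTA round trip", {
  aln <- simulate_k2p_quartet(evo_scenario(t_dup = 2, seq_len = 300,
                                           seed = 17))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta_alignment(aln, f)
  expect_identical(read_fasta_alignment(f), aln)
})
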
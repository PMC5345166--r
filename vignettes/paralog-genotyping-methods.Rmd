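---
title: "Methods: paralog-specific copy-number genotyping and duplicate dating"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paralog-specific copy-number genotyping and duplicate dating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paraloci)
```

# Scope

`paraloci` models a pair of high-identity paralogous loci — an ancestral
locus A and a derived duplicate B — and provides:

1. a forward simulator for molecular-inversion-probe (MIP) read counts over
   targets containing singly unique nucleotides (SUNs),
2. paralog-specific copy-number estimation and a 25-state likelihood-path
   caller for duplications, deletions and interlocus gene conversion,
3. a case/control variant pipeline (QC filters, SUN-based paralog
   assignment, carrier-frequency tables) and spliced-transcript consequence
   prediction,
4. molecular-evolution statistics: Kimura two-parameter (K2P) distances,
   neighbor joining, Tajima's relative-rate test, distance-ratio dating of
   the duplication with a bootstrap confidence interval, and Nei–Gojobori
   (NG86) dN/dS.

Everything operates on simulated or user-supplied tabular data; no external
reference genomes or cohort resources are required.

# Read-count model

Each MIP target is covered by `reads_A + reads_B = total` reads, where a
read's paralog is determined by the SUN allele it carries. For a sample
whose hidden state at a target is `(cnA, cnB)`:

- `total ~ Poisson(lambda * (cnA + cnB) / 4)`, where `lambda` is the
  expected total per target for the modal aggregate copy number 4 (two
  copies of each paralog). Optional overdispersion Gamma-mixes the Poisson
  mean so that `Var(total) = mu + overdispersion * mu^2`.
- `reads_A ~ Binomial(total, f)` with
  `f = f_true * (1 - 2 m) + m`, where `f_true = cnA / (cnA + cnB)` and `m`
  is the read mismapping rate. The symmetric mixing keeps `f` strictly
  inside (0, 1), so zero-copy states remain identifiable from data.
- When `cnA + cnB = 0` the expected total is `lambda * 0.05` (residual
  background capture) and `f = 1/2`.

`aggregate_cn()` estimates the summed copy number of both paralogs as twice
the ratio of the region's mean read depth to a diploid baseline region.
`paralog_point_estimates()` splits that aggregate by the per-target
paralog-A read fraction; targets with zero coverage yield `NA` rather than
a spurious zero.

# The 25-state caller

`best_paths()` segments a sample's targets under a joint hidden state
`(cnA, cnB)` with each copy number in 0..4 (25 states). The score of a
candidate path is

```
prior(first state) + sum of per-target emission log-likelihoods
  - delta * (number of transitions)
```

with these choices:

- **Emissions.** Binomial log-likelihood of `reads_A` given `total` and the
  state's mismap-free expected fraction clamped to `[0.01, 0.99]`, plus a
  Poisson log-likelihood of `total` given `lambda * (cnA + cnB) / 4`.
- **Priors.** The leftmost state receives `{-15, -7.5, 0, -7.5, -15}` for
  copy numbers 0..4, applied additively for the two paralogs. This encodes
  that most samples are (2,2) without forbidding rarer states.
- **Transitions.** A transition may change one paralog by ±1 copy, or
  exchange one copy between paralogs (`(+1,-1)` / `(-1,+1)`, the
  gene-conversion move). At most two transitions are considered, and a
  two-transition path must return to its flanking state — the model class
  is "at most one rearranged interval per sample".
- **Model selection.** The transition penalty `delta = 10` (log-likelihood
  units per breakpoint) makes the search parsimony-guarded: an extra
  breakpoint must improve the fit by at least 10 log-units. Exact ties
  resolve toward the path with more transitions, so an event whose evidence
  exactly meets the threshold is reported.
- **Exactness.** The search is not heuristic. Cumulative emission sums give
  every 0- and 1-transition score directly, and a prefix-maximum over
  cumulative differences gives the best 2-transition score, so the returned
  path is the global optimum of the objective. The test suite verifies this
  against full enumeration on hundreds of random instances.

`classify_event()` maps the optimal path onto event classes: no event,
whole-locus gain/loss, internal or terminal duplication/deletion of one
paralog, and copy-neutral interlocus gene conversion (reciprocal ±1 change;
the donor is reported as the paralog whose copy number rose, because
conversion overwrites the acceptor's sequence with donor sequence, which
moves SUN-supporting reads toward the donor).

# Variant pipeline

`filter_variants()` applies conservative QC: records with depth ≤ 10,
quality ≤ 20, missing alleles, or whose footprint overlaps a homopolymer
run (≥ 5 of one base) or a tandem trinucleotide repeat (≥ 3 copies of a
3-mer) are dropped; records missing any QC field fail closed. All removals
are retained with flags in an audit attribute. `assign_paralog()` assigns a
variant to a paralog only when every SUN-informative read supports the same
paralog; any conflict or absence of informative reads leaves it
unassigned. `frequency_table()` reports carrier counts over genotyped
individuals with percentages rounded half-up to two decimals, and flags
"common" screening variants at allele frequency
`count / (2 * genotyped) > 1%`.

`transcript_consequences()` works on the mature spliced transcript via a
keep-mask over exon bases: exonic deletions remove their bases, a
splice-acceptor deletion removes its whole exon (exon skipping). The open
reading frame is rescanned from the first ATG; a frameshift is a masked ORF
length not divisible by three, and a premature stop is a mutant stop codon
that maps to a different reference position than the reference stop. RT-PCR
amplicon sizes are the surviving bases between primer coordinates.

# Molecular evolution

- **K2P.** From the proportions of transitions `P` and transversions `Q`,
  `d = -0.5 ln(1 - 2P - Q) - 0.25 ln(1 - 2Q)`. Saturated pairs
  (non-positive log arguments) raise a typed condition
  (`paraloci_saturation`) rather than returning silent `NaN`s. Columns with
  gaps or ambiguity codes are removed across all sequences ("complete
  deletion", the default) or per pair.
- **kappa convention.** In the quartet simulator, `kappa` is the expected
  transition:transversion *count* ratio; `kappa = 0.5` is the Jukes–Cantor
  limit where all substitution types have equal instantaneous rates and
  transitions:transversions accumulate 1:2.
- **Neighbor joining** delegates to the standard agglomerative
  implementation in `ape`, with tiny negative branch lengths clamped to
  zero (recorded in an attribute).
- **Dating.** With an outgroup calibration time `t_cc`, the duplication age
  is `t_hat = t_cc * d(A,B) / mean(d(A,out), d(B,out))`. Uncertainty comes
  from a nonparametric bootstrap of alignment columns, implemented by
  multinomial resampling of the 27 joint site-pattern categories (identical
  to resampling columns, but independent of alignment length in cost), with
  a percentile 95% interval. Tajima's relative-rate test is run first and a
  warning is issued if the two paralogs' rates differ, since rate asymmetry
  biases the ratio estimate.
- **NG86.** Synonymous site counts per codon exclude mutations to stop
  codons from both numerator and denominator. Multi-step codon differences
  average synonymous/nonsynonymous counts over all orderings of the single
  steps, excluding pathways through stop codons (falling back to all
  pathways only if every ordering is blocked). Codon columns containing
  gaps, ambiguity codes or stop codons are removed pairwise. Proportions
  are Jukes–Cantor corrected; `p >= 0.75` raises the saturation condition.
  When `dS = 0`, `omega` is reported as undefined rather than infinite.

# Numerical and reproducibility choices

- All generators take integer seeds and are bit-reproducible; cohort-level
  generators derive per-sample seeds below 2^31 from the master seed.
- The expected-fraction clamp (0.01), background-depth factor (0.05),
  transition penalty (10) and prior table are fixed model constants, chosen
  before evaluation and documented here; they are not tuned per dataset.
- Rounding follows the conventions of the reporting functions: carrier
  percentages round half-up to two decimals; rearrangement percentages
  round to the nearest integer.

# Limitations

- The caller's model class allows at most one rearranged interval (two
  breakpoints) per sample; nested or multiple independent events are
  outside it. The simulator can generate such truths
  (`allow_extra_segments = TRUE`) for misspecification studies.
- Copy numbers are capped at 4 per paralog; higher amplifications collapse
  onto the boundary state.
- The quartet simulator evolves sites independently under K2P with no
  indels, rate variation or gene conversion between paralogs after the
  duplication; the dating estimator assumes clock-like evolution, which is
  why the relative-rate check is bundled.
- Transcript models are single-transcript, plus-strand, with canonical
  GT/AG splice sites; effect classification considers the designed
  footprint (exons ± 5 bp) only.
- The variant pipeline models one bi-allelic variant per record and
  dominant carrier counting; it does not compute genotype-level association
  statistics.
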
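# Effect classification, QC filters, SUN paralog assignment and
# case/control frequency tables.

model <- synthetic_transcript_model(n_exons = 8, exon_len = 90,
                                    intron_len = 120, seed = 31)

test_that("indel length modulo three separates frameshift from in-frame", {
  ex <- model$exons
  pos <- ex$start[3] + 11            # 1-based position inside exon 3
  ref1 <- substr(model$sequence, pos, pos + 1)   # anchor + 1 deleted base
  expect_equal(classify_effect(pos, ref1, substr(ref1, 1, 1), model),
               "frameshift")
  ref15 <- substr(model$sequence, pos, pos + 15)
  expect_equal(classify_effect(pos, ref15, substr(ref15, 1, 1), model),
               "other")  # in-frame deletion is not gene-disruptive
})

test_that("intronic flank SNVs are splice-site variants", {
  ex <- model$exons
  donor_pos <- ex$end[2] + 1                      # first intron base, 1-based
  ref <- substr(model$sequence, donor_pos, donor_pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_equal(classify_effect(donor_pos, ref, alt, model), "splice_donor")
  acc_pos <- ex$start[3]                          # last intron base, 1-based
  ref <- substr(model$sequence, acc_pos, acc_pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_equal(classify_effect(acc_pos, ref, alt, model), "splice_acceptor")
  # 3-5 bp into the intron: inside the design footprint but not splice-site
  mid_pos <- ex$end[2] + 4
  ref <- substr(model$sequence, mid_pos, mid_pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_equal(classify_effect(mid_pos, ref, alt, model), "other")
  far_pos <- ex$end[2] + 30
  ref <- substr(model$sequence, far_pos, far_pos)
  expect_error(classify_effect(far_pos, ref, "A", model), "footprint")
})

test_that("SNV classification agrees with full-CDS translation", {
  set.seed(55)
  ex <- model$exons
  checked <- 0
  while (checked < 300) {
    e <- sample(nrow(ex), 1)
    pos <- sample((ex$start[e] + 1):ex$end[e], 1)  # 1-based within exon
    ref <- substr(model$sequence, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    got <- classify_effect(pos, ref, alt, model)
    want <- oracle_effect_from_proteins(model, pos, ref, alt)
    expect_equal(got, want,
                 label = sprintf("effect at %d %s>%s", pos, ref, alt))
    checked <- checked + 1
  }
})

test_that("indel classification agrees with full-CDS translation", {
  set.seed(56)
  ex <- model$exons
  for (rep in 1:100) {
    e <- sample(nrow(ex), 1)
    len <- sample(1:6, 1)
    pos <- sample((ex$start[e] + 1):(ex$end[e] - len), 1)
    ref <- substr(model$sequence, pos, pos + len)
    alt <- substr(ref, 1, 1)
    got <- classify_effect(pos, ref, alt, model)
    want <- oracle_effect_from_proteins(model, pos, ref, alt)
    expect_equal(got, want, label = sprintf("del of %d at %d", len, pos))
  }
})

test_that("QC filters drop low-depth, low-quality, repeat and empty records", {
  ctx <- paste0("GGTCT", "AAAAAA", "GGTCT", strrep("ACG", 4), "TCTC",
                "TGCATGCA")
  recs <- data.frame(
    pos = c(8, 20, 2, 2, 2, 2),
    ref = c("A", "A", "G", "G", "G", "G"),
    alt = c("T", "T", "C", "C", "C", NA),
    depth = c(50, 50, 10, 50, NA, 50),
    qual = c(60, 60, 60, 20, 60, 60)
  )
  out <- filter_variants(recs, ctx)
  audit <- attr(out, "audit")
  expect_true(grepl("homopolymer", audit$filter_flags[1]))
  expect_true(grepl("trinucleotide_repeat", audit$filter_flags[2]))
  expect_true(grepl("low_depth", audit$filter_flags[3]))   # depth 10 removed
  expect_true(grepl("low_qual", audit$filter_flags[4]))    # qual 20 removed
  expect_true(grepl("missing_qc", audit$filter_flags[5]))
  expect_true(grepl("no_alleles", audit$filter_flags[6]))
  expect_equal(nrow(out), 0)
  keep <- data.frame(pos = 2, ref = "G", alt = "C", depth = 50, qual = 21)
  expect_equal(nrow(filter_variants(keep, ctx)), 1)        # qual 21 passes
  depth11 <- data.frame(pos = 2, ref = "G", alt = "C", depth = 11, qual = 60)
  expect_equal(nrow(filter_variants(depth11, ctx)), 1)     # boundary: > 10
})

test_that("homopolymer and trinucleotide scans match a direct window scan", {
  set.seed(57)
  scan_homopolymer <- function(seq, pos, min_run = 5) {
    # direct oracle: check every window of length min_run containing pos
    for (s in max(1, pos - min_run + 1):min(nchar(seq) - min_run + 1, pos)) {
      w <- substr(seq, s, s + min_run - 1)
      if (length(unique(strsplit(w, "")[[1]])) == 1) return(TRUE)
    }
    FALSE
  }
  for (rep in 1:60) {
    ctx <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE,
                        prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    pos <- sample(5:55, 1)
    rec <- data.frame(pos = pos, ref = substr(ctx, pos, pos), alt = "N",
                      depth = 50, qual = 60)
    rec$alt <- setdiff(c("A", "C"), rec$ref)[1]
    audit <- attr(filter_variants(rec, ctx), "audit")
    expect_equal(grepl("homopolymer", audit$filter_flags),
                 scan_homopolymer(ctx, pos),
                 label = sprintf("homopolymer at %d in %s", pos, ctx))
  }
})

test_that("paralog assignment requires unanimous SUN-informative reads", {
  suns <- data.frame(chrom = "locus", pos0 = c(100, 200), pos1 = c(101, 201),
                     allele_A = c("A", "G"), allele_B = c("T", "C"))
  reads_B <- data.frame(read_id = c("r1", "r2"), pos0 = c(100, 100),
                        allele = c("T", "T"))
  expect_equal(assign_paralog(reads_B, suns)$paralog, "B")
  none <- data.frame(read_id = "r1", pos0 = 999, allele = "A")
  res <- assign_paralog(none, suns)
  expect_equal(res$paralog, "unassigned")
  expect_equal(res$n_informative, 0)
  split <- data.frame(read_id = c("r1", "r2"), pos0 = c(100, 100),
                      allele = c("A", "T"))
  res <- assign_paralog(split, suns)
  expect_equal(res$paralog, "unassigned")
  expect_true(res$conflict)
  expect_warning(res0 <- assign_paralog(reads_B, suns[0, ]), "empty SUN")
  expect_equal(res0$paralog, "unassigned")
})

test_that("carrier frequencies reproduce the printed cohort table cells", {
  recs <- data.frame(
    case_count = c(11, 11, 4, 0),
    control_count = c(10, 6, 2, 1),
    cases_genotyped = c(3427, 3430, 3429, 3429),
    controls_genotyped = c(2598, 2601, 2605, 2599)
  )
  tab <- frequency_table(recs)
  expect_equal(tab$freq_cases_pct, c(0.32, 0.32, 0.12, 0.00))
  expect_equal(tab$freq_controls_pct, c(0.38, 0.23, 0.08, 0.04))
  expect_false(any(tab$common))
  expect_error(
    frequency_table(data.frame(case_count = 5, control_count = 0,
                               cases_genotyped = 4, controls_genotyped = 10)),
    "exceeds")
  undef <- frequency_table(data.frame(case_count = 0, control_count = 0,
                                      cases_genotyped = 0,
                                      controls_genotyped = 10))
  expect_true(undef$undefined_cases)
  expect_true(is.na(undef$freq_cases))
})

test_that("the frequency table is invariant to record order", {
  recs <- data.frame(case_count = c(1, 5, 3), control_count = c(0, 2, 9),
                     cases_genotyped = c(100, 120, 90),
                     controls_genotyped = c(80, 70, 200))
  t1 <- frequency_table(recs)
  t2 <- frequency_table(recs[c(3, 1, 2), ])
  expect_equal(t2[order(as.integer(rownames(t2))), ], t1, ignore_attr = TRUE)
})

test_that("VCF round trip preserves carrier and genotyped counts", {
  suns <- data.frame(chrom = "locus", pos0 = 100, pos1 = 101,
                     allele_A = "A", allele_B = "T")
  specs <- data.frame(id = c("v1", "v2"), pos = c(10, 30),
                      ref = c("C", "GA"), alt = c("T", "G"),
                      paralog = c("A", "B"),
                      effect = c("stop_gained", "frameshift"),
                      freq = c(0.02, 0.05), dropout = c(0, 0.1))
  sim <- simulate_cohort_variants(150, 250, specs, sun_table = suns, seed = 9)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_cohort_vcf(sim, f)
  recs <- read_cohort_vcf(f, case_samples = sim$samples[sim$is_case])
  expect_equal(recs$case_count, sim$truth$case_count)
  expect_equal(recs$control_count, sim$truth$control_count)
  expect_equal(recs$cases_genotyped, sim$truth$cases_genotyped)
  expect_equal(recs$controls_genotyped, sim$truth$controls_genotyped)
  expect_equal(assign_paralog(sim$variant_reads$v1, suns)$paralog, "A")
  expect_equal(assign_paralog(sim$variant_reads$v2, suns)$paralog, "B")
})
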
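test_that("reference generation is seed-deterministic", {
  spec <- fixture_spec(seed = 5, chrom_len = 5000L)
  r1 <- gen_reference(spec)
  r2 <- gen_reference(spec)
  expect_identical(r1$sequences, r2$sequences)
  r3 <- gen_reference(fixture_spec(seed = 6, chrom_len = 5000L))
  expect_false(identical(r1$sequences, r3$sequences))
  # repeat tracts are annotated in the sidecar
  spec_rep <- fixture_spec(seed = 5, chrom_len = 5000L,
                           repeat_fraction = 0.05)
  rr <- gen_reference(spec_rep)
  expect_gt(nrow(rr$repeats), 0L)
  expect_gte(region_total_length(rr$repeats), 0.05 * 5000 * 0.5)
})

test_that("zero mutation rates give empty truth and reference haplotypes", {
  spec <- fixture_spec(seed = 2, chrom_len = 5000L, snv_rate = 0,
                       indel_rate = 0)
  ref <- gen_reference(spec)
  hs <- gen_haplotypes(ref$sequences, spec)
  expect_identical(nrow(hs$sites), 0L)
  for (h in hs$haplotypes) expect_identical(h, ref$sequences[[1]])
  for (s in hs$samples) expect_identical(nrow(s$vcf), 0L)
})

test_that("haplotype FASTA equals applying the truth variants", {
  for (seed in 1:8) {
    spec <- fixture_spec(seed = seed, chrom_len = 8000L, n_haplotypes = 4L,
                         repeat_fraction = 0.02)
    ref <- gen_reference(spec)
    hs <- gen_haplotypes(ref$sequences, spec)
    for (h in seq_len(4L)) {
      al <- vapply(hs$sites$hap_alleles, `[[`, integer(1), h)
      sel <- which(al > 0L)
      want <- if (length(sel)) {
        oracle_apply(ref$sequences[[1]], hs$sites$pos[sel],
                     hs$sites$ref[sel],
                     vapply(sel, function(i) hs$sites$alts[[i]][al[i]],
                            character(1)))
      } else ref$sequences[[1]]
      expect_identical(hs$haplotypes[[h]], want)
    }
    # diploid truth genotypes are the sorted per-haplotype allele pairs
    for (k in seq_along(hs$samples)) {
      v <- hs$samples[[k]]$vcf
      a1 <- vapply(hs$sites$hap_alleles, `[[`, integer(1), 2L * k - 1L)
      a2 <- vapply(hs$sites$hap_alleles, `[[`, integer(1), 2L * k)
      sel <- which(a1 > 0L | a2 > 0L)
      expect_identical(v$pos, hs$sites$pos[sel])
      expect_identical(v$gt, mapply(function(x, y) sort(c(x, y)),
                                    a1[sel], a2[sel], SIMPLIFY = FALSE))
    }
  }
})

test_that("alignment-block defects yield the closed-form confidence regions", {
  # no events: confidence is the whole chromosome for any haplotype count
  for (nh in c(2L, 4L, 6L)) {
    spec <- fixture_spec(seed = 3, chrom_len = 20000L, n_haplotypes = nh,
                         pav_events = 0L)
    ref <- gen_reference(spec)
    ab <- gen_alignment_blocks(ref$sequences, spec)
    conf <- derive_confidence_regions(ab$blocks, min_len = 100, min_mapq = 5)
    expect_identical(conf, region_set("chr1", 0, 20000))
  }
  # events punch out exactly their intervals
  for (seed in 1:10) {
    spec <- fixture_spec(seed = seed, chrom_len = 50000L, n_haplotypes = 4L,
                         pav_events = 3L, pav_len = 2000L)
    ref <- gen_reference(spec)
    ab <- gen_alignment_blocks(ref$sequences, spec)
    conf <- derive_confidence_regions(ab$blocks, min_len = 100, min_mapq = 5)
    expect_identical(conf, ab$expected_confidence)
    # per-base check against the block list itself
    L <- 50000L
    masks <- lapply(split(ab$blocks, ab$blocks$haplotype_id), function(b) {
      oracle_cover_count(b$ref_start, b$ref_end, L) == 1L
    })
    expect_identical(oracle_rs_mask(conf, "chr1", L), Reduce(`&`, masks))
  }
})

test_that("an uncorrupted callset evaluates to perfection", {
  fx <- run_fixture(19, chrom_len = 10000L, fn_rate = 0, fp_rate = 0,
                    dosage_err_rate = 0)
  expect_identical(nrow(fx$corr$query), nrow(fx$truth$records))
  g <- glance(fx$ev)
  expect_equal(c(g$detection_precision, g$detection_recall,
                 g$genotyping_precision, g$genotyping_recall), rep(1, 4))
})

test_that("corruption bookkeeping predicts evaluation counts exactly", {
  for (seed in c(101, 202)) {
    fx <- run_fixture(seed, n_haplotypes = 4L, chrom_len = 40000L)
    expect_counts_equal(fx$ev, fx$corr$expected)
    led <- fx$corr$ledger
    expect_identical(sum(led$action == "drop") + sum(led$action == "spurious"),
                     as.integer(glance(fx$ev)$detection_FN +
                                  glance(fx$ev)$detection_FP))
  }
})

test_that("spurious calls forced simplex give simplex FP fraction 1", {
  fx <- run_fixture(55, chrom_len = 30000L, fn_rate = 0,
                    dosage_err_rate = 0, fp_rate = 0.08, fp_indel_frac = 1,
                    fp_dosage = 1L)
  expect_equal(simplex_fp_fraction(fx$ev, "indel"), 1.0)
})

test_that("dosage shifts to zero become FNs, not FPs", {
  fx <- run_fixture(66, chrom_len = 40000L, fn_rate = 0, fp_rate = 0,
                    dosage_err_rate = 0.3, dosage_to_zero = TRUE)
  led <- fx$corr$ledger
  expect_gt(sum(!is.na(led$new_dosage) & led$new_dosage == 0L), 0L)
  expect_counts_equal(fx$ev, fx$corr$expected)
})

test_that("read placements carry exact overlap bookkeeping", {
  spec <- fixture_spec(seed = 9, chrom_len = 50000L, pav_events = 2L,
                       pav_len = 3000L, n_reads = 1500L, read_length = 800L)
  ref <- gen_reference(spec)
  ab <- gen_alignment_blocks(ref$sequences, spec)
  rp <- gen_read_placements(spec, ab$expected_confidence,
                            c(chr1 = 50000L))
  res <- reliable_read_filter(rp$placements, ab$expected_confidence)
  res <- res[match(rp$ledger$read_id, res$read_id), ]
  expect_identical(res$overlap, rp$ledger$overlap)
  expect_identical(res$keep, rp$ledger$expected_keep)
})

test_that("simulate_benchmark writes the full artifact set", {
  dir <- withr::local_tempdir()
  spec <- fixture_spec(seed = 4, chrom_len = 10000L)
  sim <- simulate_benchmark(spec, dir = dir)
  files <- c("ref.fa", "hap1.fa", "hap4.fa", "sample1.vcf", "sample1.bed",
             "sample2.vcf", "blocks.paf", "truth.vcf", "conf.bed",
             "query.vcf", "ledger.json", "reads.tsv")
  for (f in files) expect_true(file.exists(file.path(dir, f)), label = f)
  # written truth round-trips to the in-memory records
  back <- read_vcf(file.path(dir, "truth.vcf"))
  expect_identical(back$pos, sim$truth$records$pos)
  expect_identical(back$gt, sim$truth$records$gt)
  # PAF parses back to the block table
  pb <- read_paf(file.path(dir, "blocks.paf"))
  expect_identical(nrow(pb), nrow(sim$blocks$blocks))
})
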
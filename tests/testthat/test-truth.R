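toy_ref <- function(seed = 1, len = 2000L) {
  set.seed(seed)
  c(chr1 = rand_dna(len))
}

ts <- function(id, v, conf, ploidy = 2L) truth_sample(id, v, conf, ploidy)

test_that("a site present in one sample gets dosage from that sample only", {
  ref <- toy_ref()
  conf <- region_set("chr1", 0, 2000)
  a <- variant_tbl("chr1", 100L, substr(ref[[1]], 100, 100),
                   alt_base(ref[[1]], 100), "0/1")
  m <- merge_truth(list(ts("A", a, conf), ts("B", variant_tbl(), conf)), ref)
  expect_identical(m$ploidy, 4L)
  expect_identical(nrow(m$records), 1L)
  expect_identical(m$records$gt[[1]], c(0L, 0L, 0L, 1L))
})

test_that("different ALTs at one site merge into a multiallelic record", {
  ref <- toy_ref(2)
  conf <- region_set("chr1", 0, 2000)
  p <- 100L
  rb <- substr(ref[[1]], p, p)
  others <- setdiff(c("A", "C", "G", "T"), rb)
  # A: 0/1 on alt1, B: 1/1 on alt2 -> dosages 1 and 2 at ploidy 4
  a <- variant_tbl("chr1", p, rb, others[1], "0/1")
  b <- variant_tbl("chr1", p, rb, others[2], "1/1")
  m <- merge_truth(list(ts("A", a, conf), ts("B", b, conf)), ref)
  rec <- m$records
  expect_identical(rec$alts[[1]], sort(others[1:2]))  # lexicographic ALTs
  d1 <- gt_dosage(rec$gt, match(others[1], rec$alts[[1]]))
  d2 <- gt_dosage(rec$gt, match(others[2], rec$alts[[1]]))
  expect_identical(c(d1, d2), c(1L, 2L))
  expect_identical(sum(rec$gt[[1]] == 0L), 1L)
})

test_that("three diploid samples give a hexaploid truth set", {
  ref <- toy_ref(3)
  conf <- region_set("chr1", 0, 2000)
  p <- 500L
  rb <- substr(ref[[1]], p, p)
  alt <- alt_base(ref[[1]], p)
  samples <- list(
    ts("A", variant_tbl("chr1", p, rb, alt, "0/1"), conf),
    ts("B", variant_tbl(), conf),
    ts("C", variant_tbl(), conf))
  m <- merge_truth(samples, ref)
  expect_identical(m$ploidy, 6L)
  # one copy among six haplotypes: a hexaploid simplex site
  expect_identical(m$records$gt[[1]], c(0L, 0L, 0L, 0L, 0L, 1L))
  # and all three carrying 0/1 sums the dosages instead
  m3 <- merge_truth(list(
    ts("A", variant_tbl("chr1", p, rb, alt, "0/1"), conf),
    ts("B", variant_tbl("chr1", p, rb, alt, "0/1"), conf),
    ts("C", variant_tbl("chr1", p, rb, alt, "1/1"), conf)), ref)
  expect_identical(m3$records$gt[[1]], c(0L, 0L, 1L, 1L, 1L, 1L))
})

test_that("overlapping representations harmonize onto a padded REF", {
  # A spells an SNV, B deletes the base after it: footprints overlap
  ref <- c(chr1 = "GGATCCCCGG")
  sk <- harmonize_sites(
    variant_tbl("chr1", c(3L, 3L), c("A", "AT"), list("T", "A"),
                c("0/1", "0/1")), ref)
  expect_identical(sk$ref, "AT")
  expect_identical(sk$alts[[1]], c("A", "TT"))
  expect_error(harmonize_sites(
    variant_tbl("chr1", c(3L, 8L), c("A", "C"), list("T", "G"),
                c("0/1", "0/1")), ref), "overlapping")
})

test_that("merged records stay inside the intersected confident regions", {
  ref <- toy_ref(4)
  a <- variant_tbl("chr1", c(100L, 900L),
                   substring(ref[[1]], c(100, 900), c(100, 900)),
                   list(alt_base(ref[[1]], 100), alt_base(ref[[1]], 900)),
                   c("0/1", "0/1"))
  m <- merge_truth(list(
    ts("A", a, region_set("chr1", 0, 2000)),
    ts("B", variant_tbl(), region_set("chr1", 0, 500))), ref)
  expect_identical(m$records$pos, 100L)  # site at 900 outside intersection
  expect_identical(m$regions$end, 500L)
})

test_that("dosage conservation, commutativity and self-merge doubling hold", {
  set.seed(5)
  for (trial in 1:25) {
    ref <- c(chr1 = rand_dna(5000L))
    conf <- region_set("chr1", 0, 5000)
    mk_sample <- function(id) {
      n <- sample(3:8, 1)
      pos <- sort(sample(seq(50L, 4900L, by = 40L), n))
      rb <- substring(ref[[1]], pos, pos)
      v <- variant_tbl("chr1", pos, rb,
                       as.list(vapply(pos, function(p) alt_base(ref[[1]], p),
                                      character(1))),
                       sample(c("0/1", "1/1"), n, replace = TRUE))
      ts(id, v, conf)
    }
    sa <- mk_sample("A"); sb <- mk_sample("B")
    m <- merge_truth(list(sa, sb), ref)
    # per-allele dosage equals the sum over contributing samples
    for (i in seq_len(nrow(m$records))) {
      rec <- m$records[i, ]
      for (j in seq_along(rec$alts[[1]])) {
        alt <- rec$alts[[1]][j]
        want <- 0L
        for (s in list(sa, sb)) {
          hit <- which(s$vcf$pos == rec$pos & s$vcf$ref == rec$ref)
          if (length(hit)) {
            k <- match(alt, s$vcf$alts[[hit]])
            if (!is.na(k)) want <- want + sum(s$vcf$gt[[hit]] == k)
          }
        }
        expect_identical(gt_dosage(rec$gt, j), want)
      }
      expect_identical(length(rec$gt[[1]]), 4L)
    }
    # sample order does not matter
    m2 <- merge_truth(list(sb, sa), ref)
    expect_identical(m$records$pos, m2$records$pos)
    expect_identical(m$records$alts, m2$records$alts)
    expect_identical(m$records$gt, m2$records$gt)
    # self-merge doubles ploidy and every dosage
    md <- merge_truth(list(sa, ts("A2", sa$vcf, conf)), ref)
    expect_identical(md$ploidy, 4L)
    for (i in seq_len(nrow(md$records))) {
      orig <- which(sa$vcf$pos == md$records$pos[i])
      expect_identical(gt_dosage(md$records$gt[i], 1L),
                       2L * sum(sa$vcf$gt[[orig]] > 0L))
    }
  }
})

test_that("haplotype spell-out from merged truth matches the input haplotypes", {
  # generator fixtures carry per-haplotype alleles; spelling each haplotype
  # from the merged records must reproduce the generated haplotype FASTA
  for (seed in 1:10) {
    spec <- fixture_spec(seed = seed, chrom_len = 8000L, n_haplotypes = 4L,
                         fn_rate = 0, fp_rate = 0, dosage_err_rate = 0)
    ref <- gen_reference(spec)
    hs <- gen_haplotypes(ref$sequences, spec)
    m <- merge_truth(hs$samples, ref$sequences)
    # region-restricted sites only; margin sites are absent from the merge
    sites <- filter_by_regions(hs$sites, m$regions)
    expect_identical(nrow(m$records), nrow(sites))
    for (h in seq_len(spec$n_haplotypes)) {
      al_site <- vapply(sites$hap_alleles, `[[`, integer(1), h)
      sel <- which(al_site > 0L)
      # map each site allele onto the merged record's (possibly reordered) ALTs
      al_merged <- vapply(sel, function(i) {
        ri <- which(m$records$pos == sites$pos[i])
        match(sites$alts[[i]][al_site[i]], m$records$alts[[ri]])
      }, integer(1))
      spelled <- apply_variants(ref$sequences[[1]],
                                m$records[match(sites$pos[sel], m$records$pos), ],
                                al_merged)
      direct <- if (length(sel)) {
        oracle_apply(ref$sequences[[1]], sites$pos[sel],
                     sites$ref[sel],
                     vapply(sel, function(i) sites$alts[[i]][al_site[i]],
                            character(1)))
      } else ref$sequences[[1]]
      expect_identical(spelled, direct)
    }
  }
})

test_that("incompatible same-sample overlaps abort with a diagnostic", {
  ref <- c(chr1 = "GGATCCCCGGAAAA")
  conf <- region_set("chr1", 0, 14)
  # two records whose summed dosage exceeds the sample's ploidy
  v <- variant_tbl("chr1", c(3L, 3L), c("A", "AT"), list("T", "A"),
                   c("1/1", "0/1"))
  expect_error(merge_truth(list(ts("A", v, conf)), ref), "exceeds ploidy")
})

test_that("coverage arithmetic reports totals and per-haplotype depth", {
  got <- plan_coverage(30, n_samples = 2)
  expect_identical(got$total_depth, 60)
  expect_identical(got$per_haplotype_depth, 15)
  expect_identical(got$ploidy_out, 4L)
  got3 <- plan_coverage(10, n_samples = 3)
  expect_identical(got3$total_depth, 30)
  expect_identical(got3$per_haplotype_depth, 5)
  grid <- plan_coverage(c(10, 30, 50, 70, 90), n_samples = 2)
  expect_identical(nrow(grid), 5L)
  expect_error(plan_coverage(-1, 2), "positive")
})
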
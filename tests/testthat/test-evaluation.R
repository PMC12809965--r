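eval_ref <- function(seed = 1, len = 5000L) {
  set.seed(seed)
  c(chr1 = rand_dna(len))
}

snv_at <- function(ref, pos, gt, alt = NULL, ...) {
  rb <- substring(ref[[1]], pos, pos)
  if (is.null(alt)) alt <- vapply(pos, function(p) alt_base(ref[[1]], p),
                                  character(1))
  variant_tbl("chr1", as.integer(pos), rb, as.list(alt), gt, ...)
}

test_that("a callset evaluated against itself is perfect in both modes", {
  ref <- eval_ref(1)
  alts <- list(
    alt_base(ref[[1]], 100),
    setdiff(c("A", "C", "G", "T"), substr(ref[[1]], 500, 500))[1:2],
    alt_base(ref[[1]], 900))
  v <- snv_at(ref, c(100, 500, 900), c("0/0/0/1", "0/1/1/2", "1/1/1/1"),
              alt = alts)
  ev <- evaluate_calls(v, v, reference = ref)
  g <- glance(ev)
  expect_identical(c(g$detection_precision, g$detection_recall,
                     g$genotyping_precision, g$genotyping_recall,
                     g$genotyping_f1), rep(1, 5))
})

test_that("wrong dosage is a detection TP but a genotyping FP+FN", {
  ref <- eval_ref(2)
  truth <- snv_at(ref, 100, "0/0/0/1")
  query <- snv_at(ref, 100, "0/0/1/1")
  ev <- evaluate_calls(truth, query, reference = ref)
  g <- glance(ev)
  expect_identical(c(g$detection_TP, g$detection_FP, g$detection_FN),
                   c(1L, 0L, 0L))
  expect_identical(c(g$genotyping_TP, g$genotyping_FP, g$genotyping_FN),
                   c(0L, 1L, 1L))
})

test_that("the hand-countable 3-site example yields the stated metrics", {
  ref <- eval_ref(3)
  truth <- snv_at(ref, c(100, 500, 900),
                  c("0/0/0/1", "0/0/1/1", "0/0/0/1"))
  # site1 wrong dosage, site2 exact, site3 missed, plus one spurious site
  query <- dplyr::bind_rows(
    snv_at(ref, c(100, 500), c("0/0/1/1", "0/0/1/1")),
    snv_at(ref, 1500, "0/0/0/1"))
  ev <- evaluate_calls(truth, query, reference = ref)
  g <- glance(ev)
  expect_identical(c(g$detection_TP, g$detection_FP, g$detection_FN),
                   c(2L, 1L, 1L))
  expect_identical(c(g$genotyping_TP, g$genotyping_FP, g$genotyping_FN),
                   c(1L, 2L, 2L))
  expect_equal(g$detection_precision, 2 / 3)
  expect_equal(g$detection_recall, 2 / 3)
  expect_equal(g$genotyping_precision, 1 / 3)
  expect_equal(g$genotyping_recall, 1 / 3)
})

test_that("all-reference and missing-genotype query records are no-calls", {
  ref <- eval_ref(4)
  truth <- snv_at(ref, 100, "0/0/0/1")
  query <- snv_at(ref, c(100, 500), c("0/0/0/0", "./."))
  ev <- evaluate_calls(truth, query, reference = ref)
  g <- glance(ev)
  expect_identical(g$detection_FP, 0L)   # neither no-call is an FP
  expect_identical(g$detection_FN, 1L)   # covered truth site still missed
  expect_identical(g$n_nocall, 2L)
})

test_that("differently spelled equivalent indels pair after normalization", {
  # one T deleted from a T-run, spelled at two different offsets
  ref <- c(chr1 = paste0("GGACC", "TTTTT", "GGACCGGACCGGACC"))
  truth <- variant_tbl("chr1", 6L, "TT", "T", "0/0/1/1")
  query <- variant_tbl("chr1", 8L, "TT", "T", "0/0/1/1")
  ev <- evaluate_calls(truth, query, reference = ref)
  g <- glance(ev)
  expect_identical(c(g$detection_TP, g$genotyping_TP), c(1L, 1L))
  expect_identical(c(g$detection_FP, g$genotyping_FN), c(0L, 0L))
})

test_that("metric formulas implement the zero-denominator convention", {
  expect_equal(as.numeric(eval_metrics(0, 0, 0)), c(0, 0, 0))
  expect_equal(as.numeric(eval_metrics(2, 1, 1)), c(2 / 3, 2 / 3, 2 / 3))
  m <- eval_metrics(c(1, 5), c(1, 0), c(0, 5))
  expect_equal(m$precision, c(0.5, 1))
  expect_equal(m$recall, c(1, 0.5))
  expect_equal(m$f1, c(2 / 3, 2 / 3))
  expect_error(eval_metrics(-1, 0, 0), "non-negative")
})

test_that("stratification restricts counts by footprint containment", {
  ref <- eval_ref(5)
  truth <- snv_at(ref, c(100, 2100), c("0/0/0/1", "0/0/0/1"))
  # FP lies outside the coding stratum
  query <- dplyr::bind_rows(truth, snv_at(ref, 3000, "0/0/0/1"))
  coding <- region_set("chr1", 0, 2500)
  ev <- evaluate_calls(truth, query, reference = ref,
                       strata = list(coding = coding))
  cells <- tidy(ev)
  all_cell <- cells[cells$mode == "detection" & cells$vtype == "all" &
                      cells$gt_class == "all" & cells$stratum == "all", ]
  cod_cell <- cells[cells$mode == "detection" & cells$vtype == "all" &
                      cells$gt_class == "all" & cells$stratum == "coding", ]
  expect_identical(all_cell$FP, 1L)
  expect_identical(cod_cell$FP, 0L)
  expect_equal(cod_cell$precision, 1)
  expect_identical(cod_cell$TP, 2L)
  # a stratum covering everything reproduces the unstratified counts
  ev2 <- evaluate_calls(truth, query, reference = ref,
                        strata = list(whole = region_set("chr1", 0, 5000)))
  c2 <- tidy(ev2)
  expect_identical(
    c2[c2$stratum == "whole" & c2$vtype == "all" & c2$gt_class == "all",
       c("TP", "FP", "FN")],
    c2[c2$stratum == "all" & c2$vtype == "all" & c2$gt_class == "all",
       c("TP", "FP", "FN")])
  # the simplex class cell counts only truth sites with dosage 1
  simplex_cell <- cells[cells$mode == "detection" & cells$vtype == "all" &
                          cells$gt_class == "simplex" &
                          cells$stratum == "all", ]
  expect_identical(simplex_cell$TP + simplex_cell$FN, 2L)
  expect_error(evaluate_calls(truth, query, reference = ref,
                              strata = list(all = coding)), "duplicate")
})

test_that("dosage confusion counts per-allele truth vs called dosages", {
  ref <- eval_ref(6)
  truth <- snv_at(ref, c(100, 500, 900),
                  c("0/0/0/1", "0/0/1/1", "0/1/1/1"))
  query <- dplyr::bind_rows(
    snv_at(ref, 500, "0/0/1/1"),   # exact duplex
    snv_at(ref, 900, "0/0/1/1"))   # triplex undercalled to duplex
  # truth simplex at 100 entirely missed -> (1, 0)
  ev <- evaluate_calls(truth, query, reference = ref)
  conf <- dosage_confusion(ev)
  get_n <- function(t, c) {
    r <- conf$n[conf$truth_dosage == t & conf$called_dosage == c]
    if (length(r)) r else 0L
  }
  expect_identical(get_n(1, 0), 1L)
  expect_identical(get_n(2, 2), 1L)
  expect_identical(get_n(3, 2), 1L)
  # row sums equal truth-class counts
  sums <- tapply(conf$n, conf$truth_dosage, sum)
  expect_identical(as.integer(sums[c("1", "2", "3")]), c(1L, 1L, 1L))
})

test_that("simplex FP fraction is computed over genotyping-mode FPs by type", {
  ref <- c(chr1 = paste0(strrep("GGACC", 200)))
  # four spurious indel calls: three simplex, one duplex
  pos <- c(101L, 301L, 501L, 701L)
  rb <- substring(ref[[1]], pos, pos)
  query <- variant_tbl("chr1", pos, rb,
                       lapply(rb, function(b) paste0(b, "TTA")),
                       c("0/0/0/1", "0/0/0/1", "0/0/0/1", "0/0/1/1"))
  truth <- snv_at(ref, 903, "0/0/0/1")
  ev <- evaluate_calls(truth, query, reference = ref)
  expect_equal(simplex_fp_fraction(ev, "indel"), 0.75)
  expect_equal(simplex_fp_fraction(ev, "SNV"), 0)
})

test_that("counts are invariant to record order and conserve truth sites", {
  fx <- run_fixture(31, n_haplotypes = 4L, chrom_len = 20000L)
  g1 <- glance(fx$ev)
  set.seed(7)
  perm <- sample(nrow(fx$corr$query))
  ev2 <- evaluate_calls(fx$truth, fx$corr$query[perm, ],
                        reference = fx$ref$sequences)
  expect_identical(glance(ev2), g1)
  # detection TP + FN equals the number of truth records in regions
  expect_identical(g1$detection_TP + g1$detection_FN,
                   nrow(fx$truth$records))
  # dosage confusion row sums match truth per-dosage allele counts
  conf <- dosage_confusion(fx$ev)
  sums <- tapply(conf$n, conf$truth_dosage, sum)
  truth_d <- unlist(lapply(fx$truth$records$gt, function(g) {
    a <- unique(g[g > 0L]); vapply(a, function(x) sum(g == x), integer(1))
  }))
  want <- table(truth_d)
  expect_identical(as.integer(sums[names(want)]), as.integer(want))
})

test_that("genotyping dominance holds and ploidy mismatches are rejected", {
  fx <- run_fixture(77, n_haplotypes = 6L, chrom_len = 20000L)
  g <- glance(fx$ev)
  expect_gte(g$detection_precision, g$genotyping_precision)
  expect_gte(g$detection_recall, g$genotyping_recall)
  ref <- eval_ref(9)
  truth <- snv_at(ref, 100, "0/0/0/1")
  query <- snv_at(ref, 100, "0/1")
  expect_error(evaluate_calls(truth, query, reference = ref),
               "common ploidy")
  # detection alone tolerates differing ploidies
  ev <- evaluate_calls(truth, query, reference = ref, modes = "detection")
  expect_identical(glance(ev)$detection_TP, 1L)
})
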
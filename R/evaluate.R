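# Comparison of a polyploid callset with a truth set under two semantics:
#   detection  — a matched site is TP iff truth and query share at least one
#                ALT allele with dosage >= 1 on both sides;
#   genotyping — TP iff the full genotype multisets are identical after
#                allele harmonization (allelic composition and copy number).
# A matched site failing the criterion counts as FP and FN simultaneously
# (the vcfeval wrong-genotype convention); unmatched truth records are FN;
# unmatched query records asserting an ALT are FP. Query records asserting
# no ALT (hom-ref or missing genotype) are ignored up front, so they are
# never FPs and any truth site they cover scores FN.

#' Match truth and query records at harmonized loci
#'
#' Pairs records (1:1) whose normalized REF footprints overlap on the same
#' chromosome. Ties are broken deterministically: nearest start first, then
#' lexicographically smallest first ALT; losers stay unmatched.
#'
#' @param truth,query Variant tables, normalized and restricted to the same
#'   confidence regions.
#' @return A list with `pairs` (tibble of `t_idx`, `q_idx` row indices),
#'   `truth_only` and `query_only` (integer row indices).
#' @export
match_sites <- function(truth, query) {
  if (nrow(truth) == 0L || nrow(query) == 0L) {
    return(list(pairs = tibble(t_idx = integer(), q_idx = integer()),
                truth_only = seq_len(nrow(truth)),
                query_only = seq_len(nrow(query))))
  }
  tf <- variant_footprints(truth)
  qf <- variant_footprints(query)
  ov <- suppressWarnings(GenomicRanges::findOverlaps(rs_to_gr(tf),
                                                     rs_to_gr(qf)))
  cand <- tibble(t_idx = S4Vectors::queryHits(ov),
                 q_idx = S4Vectors::subjectHits(ov))
  if (nrow(cand) == 0L) {
    return(list(pairs = cand, truth_only = seq_len(nrow(truth)),
                query_only = seq_len(nrow(query))))
  }
  cand$dist <- abs(truth$pos[cand$t_idx] - query$pos[cand$q_idx])
  cand$alt_key <- vapply(query$alts[cand$q_idx], `[[`, character(1), 1L)
  cand <- cand[order(cand$dist, cand$alt_key, cand$t_idx, cand$q_idx), ]
  t_free <- rep(TRUE, nrow(truth)); q_free <- rep(TRUE, nrow(query))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ti <- cand$t_idx[i]; qi <- cand$q_idx[i]
    if (t_free[ti] && q_free[qi]) {
      keep[i] <- TRUE; t_free[ti] <- FALSE; q_free[qi] <- FALSE
    }
  }
  pairs <- cand[keep, c("t_idx", "q_idx")]
  pairs <- arrange(pairs, .data$t_idx)
  list(pairs = pairs, truth_only = which(t_free), query_only = which(q_free))
}

# Spell the genotype of one record as a multiset of allele strings over a
# unified footprint [upos, uend) (1-based inclusive-exclusive on reference).
spell_gt <- function(rec_pos, rec_ref, rec_alts, rec_gt, chrom_seq, upos, uend) {
  pre <- substr(chrom_seq, upos, rec_pos - 1L)
  suf <- substr(chrom_seq, rec_pos + nchar(rec_ref), uend - 1L)
  alleles <- c(paste0(pre, rec_ref, suf), paste0(pre, rec_alts, suf))
  sort(alleles[rec_gt + 1L])
}

# Compare one truth/query record pair; returns shared_alt and gt_equal.
compare_pair <- function(truth, ti, query, qi, reference) {
  t_gt <- truth$gt[[ti]]; q_gt <- query$gt[[qi]]
  same_locus <- truth$pos[ti] == query$pos[qi] &&
    truth$ref[ti] == query$ref[qi]
  if (same_locus) {
    t_alt <- truth$alts[[ti]][unique(t_gt[t_gt > 0L])]
    q_alt <- query$alts[[qi]][unique(q_gt[q_gt > 0L])]
    shared <- length(intersect(t_alt, q_alt)) > 0L
    gt_eq <- identical(
      sort(c(truth$ref[ti], truth$alts[[ti]])[t_gt + 1L]),
      sort(c(query$ref[qi], query$alts[[qi]])[q_gt + 1L]))
    return(c(shared_alt = shared, gt_equal = gt_eq))
  }
  chrom_seq <- reference[[truth$chrom[ti]]]
  upos <- min(truth$pos[ti], query$pos[qi])
  uend <- max(truth$pos[ti] + nchar(truth$ref[ti]),
              query$pos[qi] + nchar(query$ref[qi]))
  uref <- substr(chrom_seq, upos, uend - 1L)
  t_spell <- spell_gt(truth$pos[ti], truth$ref[ti], truth$alts[[ti]],
                      truth$gt[[ti]], chrom_seq, upos, uend)
  q_spell <- spell_gt(query$pos[qi], query$ref[qi], query$alts[[qi]],
                      query$gt[[qi]], chrom_seq, upos, uend)
  shared <- length(intersect(setdiff(t_spell, uref),
                             setdiff(q_spell, uref))) > 0L
  c(shared_alt = shared, gt_equal = identical(t_spell, q_spell))
}

#' Precision, recall and F1 from TP/FP/FN counts
#'
#' `precision = TP/(TP+FP)`, `recall = TP/(TP+FN)`,
#' `F1 = 2PR/(P+R)`; each is 0 when its denominator is 0.
#'
#' @param tp,fp,fn Non-negative counts (vectorized).
#' @return A tibble with columns `precision`, `recall`, `f1`.
#' @examples
#' eval_metrics(2, 1, 1)
#' @export
eval_metrics <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) abort("counts must be non-negative")
  p <- ifelse(tp + fp == 0, 0, tp / (tp + fp))
  r <- ifelse(tp + fn == 0, 0, tp / (tp + fn))
  f1 <- ifelse(p + r == 0, 0, 2 * p * r / (p + r))
  tibble(precision = p, recall = r, f1 = f1)
}

#' Evaluate a polyploid callset against a truth set
#'
#' Runs the full comparison: normalization (when a reference is supplied),
#' restriction to confidence regions, 1:1 site matching, detection- and
#' genotyping-mode counting, stratified metric cells, the per-allele dosage
#' confusion matrix, and the simplex FP fraction.
#'
#' @param truth A variant table or `merged_truth` object.
#' @param query A variant table (the callset under evaluation).
#' @param reference Named character vector of chromosome sequences (or
#'   FASTA path). When supplied, both callsets are normalized first.
#' @param regions A region set restricting evaluation (defaults to the
#'   `merged_truth` regions when `truth` is one; `NULL` = no restriction).
#' @param strata Named list of region sets for annotation stratification
#'   (an `"all"` stratum is always included).
#' @param modes Character subset of `c("detection", "genotyping")`.
#' @param split_multiallelic Logical; if `TRUE`, biallelic MNV records are
#'   decomposed into SNVs before evaluation ([decompose_mnv()]). Default
#'   `FALSE`: multiallelic and MNV records are compared jointly.
#' @return A `poly_eval` object; see [tidy.poly_eval()], [glance.poly_eval()],
#'   [dosage_confusion()], [simplex_fp_fraction()], [autoplot.poly_eval()].
#' @export
evaluate_calls <- function(truth, query, reference = NULL, regions = NULL,
                           strata = list(),
                           modes = c("detection", "genotyping"),
                           split_multiallelic = FALSE) {
  modes <- match.arg(modes, several.ok = TRUE)
  if (inherits(truth, "merged_truth")) {
    if (is.null(regions)) regions <- truth$regions
    truth <- truth$records
  }
  if (is.character(reference) && is.null(names(reference))) {
    reference <- read_fasta(reference)
  }
  if (!is.null(reference)) {
    reference <- as_reference(reference)
    truth <- normalize_variants(truth, reference)
    query <- normalize_variants(query, reference)
  }
  if (!is.null(regions)) {
    truth <- filter_by_regions(truth, regions)
    query <- filter_by_regions(query, regions)
  }
  if (split_multiallelic) {
    truth <- decompose_mnv(truth)
    query <- decompose_mnv(query)
  }
  # query records asserting no ALT are no-calls: ignored, never FPs
  asserts_alt <- vapply(query$gt, function(g) {
    !gt_is_missing_one(g) && any(g > 0L)
  }, logical(1))
  n_nocall <- sum(!asserts_alt)
  query <- query[asserts_alt, , drop = FALSE]
  t_asserts <- vapply(truth$gt, function(g) {
    !gt_is_missing_one(g) && any(g > 0L)
  }, logical(1))
  truth <- truth[t_asserts, , drop = FALSE]

  truth <- new_variant_tbl(arrange(as_tibble(truth), .data$chrom, .data$pos))
  query <- new_variant_tbl(arrange(as_tibble(query), .data$chrom, .data$pos))

  if ("genotyping" %in% modes) {
    tp_ <- gt_ploidy(truth$gt); qp_ <- gt_ploidy(query$gt)
    pl <- unique(stats::na.omit(c(tp_, qp_)))
    if (length(pl) > 1L) {
      abort(paste0("genotyping mode requires one common ploidy; found ",
                   paste(pl, collapse = ", ")))
    }
  }

  m <- match_sites(truth, query)
  cmp <- if (nrow(m$pairs)) {
    t(mapply(function(ti, qi) compare_pair(truth, ti, query, qi, reference),
             m$pairs$t_idx, m$pairs$q_idx))
  } else matrix(logical(0), ncol = 2,
                dimnames = list(NULL, c("shared_alt", "gt_equal")))
  pairs <- m$pairs
  pairs$shared_alt <- as.logical(cmp[, 1])
  pairs$gt_equal <- as.logical(cmp[, 2]) & pairs$shared_alt

  t_meta <- dplyr::bind_cols(
    tibble(vtype = record_variant_type(truth),
           gt_class = as.character(classify_genotype(truth$gt))),
    variant_footprints(truth))
  q_meta <- dplyr::bind_cols(
    tibble(vtype = record_variant_type(query),
           gt_class = as.character(classify_genotype(query$gt))),
    variant_footprints(query))

  with_outcome <- function(mode, outcome, meta) {
    if (nrow(meta) == 0L) return(NULL)
    dplyr::bind_cols(tibble(mode = mode, outcome = outcome), meta)
  }
  events <- bind_rows(lapply(modes, function(mode) {
    ok <- if (mode == "detection") pairs$shared_alt else pairs$gt_equal
    bind_rows(
      with_outcome(mode, ifelse(ok, "TP", "FN"), t_meta[pairs$t_idx, ]),
      with_outcome(mode, "FN", t_meta[m$truth_only, ]),
      with_outcome(mode, "FP", q_meta[pairs$q_idx[!ok], ]),
      with_outcome(mode, "FP", q_meta[m$query_only, ]))
  }))
  if (is.null(events) || nrow(events) == 0L) {
    events <- tibble(mode = character(), outcome = character(),
                     vtype = character(), gt_class = character(),
                     chrom = character(), start = integer(), end = integer())
  }

  cells <- build_cells(events, strata, modes)
  confusion <- build_confusion(truth, query, pairs, m$truth_only, reference)

  structure(list(
    cells = cells, confusion = confusion, events = events,
    pairs = pairs, truth = truth, query = query,
    n_truth = nrow(truth), n_query = nrow(query), n_nocall = n_nocall,
    modes = modes), class = "poly_eval")
}

# Metric cells over mode x variant type x genotype class x stratum, with
# "all" aggregates for type, class and stratum always present.
build_cells <- function(events, strata, modes) {
  stratum_sets <- c(list(all = NULL), strata)
  if (anyDuplicated(names(stratum_sets))) {
    abort("duplicate stratum labels")
  }
  per_stratum <- bind_rows(imap(stratum_sets, function(rs, label) {
    ev <- events
    if (!is.null(rs)) {
      if (nrow(ev) > 0L) {
        fp <- tibble(chrom = ev$chrom, start = ev$start, end = ev$end)
        hit <- suppressWarnings(
          GenomicRanges::countOverlaps(rs_to_gr(fp), rs_to_gr(rs),
                                       type = "within"))
        ev <- ev[hit > 0L, , drop = FALSE]
      }
    }
    ev$stratum <- label
    ev
  }))
  expand <- bind_rows(
    per_stratum,
    mutate(per_stratum, vtype = "all"),
    mutate(per_stratum, gt_class = "all"),
    mutate(per_stratum, vtype = "all", gt_class = "all"))
  counts <- expand %>%
    count(.data$mode, .data$vtype, .data$gt_class, .data$stratum,
          .data$outcome) %>%
    tidyr::pivot_wider(names_from = "outcome", values_from = "n",
                       values_fill = 0L)
  for (col in c("TP", "FP", "FN")) {
    if (!col %in% names(counts)) counts[[col]] <- 0L
  }
  base <- tidyr::expand_grid(mode = modes, vtype = "all", gt_class = "all",
                             stratum = names(stratum_sets),
                             TP = 0L, FP = 0L, FN = 0L)
  counts <- bind_rows(counts,
                      dplyr::anti_join(base, counts,
                                       by = c("mode", "vtype", "gt_class",
                                              "stratum")))
  dplyr::bind_cols(counts,
                   eval_metrics(counts$TP, counts$FP, counts$FN)) %>%
    arrange(.data$mode, .data$stratum, .data$vtype, .data$gt_class)
}

# Per-allele dosage confusion: one entry per truth site and truth ALT allele
# with dosage >= 1; called dosage 0 encodes missed / hom-ref / absent allele.
build_confusion <- function(truth, query, pairs, truth_only, reference) {
  q_of_t <- rep(NA_integer_, nrow(truth))
  q_of_t[pairs$t_idx] <- pairs$q_idx
  acc_t <- vector("list", nrow(truth))
  acc_c <- vector("list", nrow(truth))
  for (ti in seq_len(nrow(truth))) {
    g <- truth$gt[[ti]]
    if (gt_is_missing_one(g)) next
    alt_idx <- sort(unique(g[g > 0L]))
    if (length(alt_idx) == 0L) next
    d_t <- vapply(alt_idx, function(a) sum(g == a), integer(1))
    qi <- q_of_t[ti]
    d_c <- rep(0L, length(alt_idx))
    if (!is.na(qi)) {
      qg <- query$gt[[qi]]
      same_locus <- truth$pos[ti] == query$pos[qi] &&
        truth$ref[ti] == query$ref[qi]
      for (j in seq_along(alt_idx)) {
        a_str <- truth$alts[[ti]][alt_idx[j]]
        if (same_locus) {
          k <- match(a_str, query$alts[[qi]])
          if (!is.na(k)) d_c[j] <- sum(qg == k)
        } else if (!is.null(reference)) {
          chrom_seq <- reference[[truth$chrom[ti]]]
          upos <- min(truth$pos[ti], query$pos[qi])
          uend <- max(truth$pos[ti] + nchar(truth$ref[ti]),
                      query$pos[qi] + nchar(query$ref[qi]))
          t_spell <- paste0(
            substr(chrom_seq, upos, truth$pos[ti] - 1L), a_str,
            substr(chrom_seq, truth$pos[ti] + nchar(truth$ref[ti]), uend - 1L))
          q_alleles <- c(query$ref[qi], query$alts[[qi]])
          q_spelled <- paste0(
            substr(chrom_seq, upos, query$pos[qi] - 1L), q_alleles,
            substr(chrom_seq, query$pos[qi] + nchar(query$ref[qi]), uend - 1L))
          k <- match(t_spell, q_spelled) - 1L
          if (!is.na(k) && k > 0L) d_c[j] <- sum(qg == k)
        }
      }
    }
    acc_t[[ti]] <- d_t
    acc_c[[ti]] <- d_c
  }
  conf <- tibble(truth_dosage = unlist(acc_t, use.names = FALSE),
                 called_dosage = unlist(acc_c, use.names = FALSE))
  if (nrow(conf) == 0L) {
    return(tibble(truth_dosage = integer(), called_dosage = integer(),
                  n = integer()))
  }
  count(conf, .data$truth_dosage, .data$called_dosage, name = "n")
}

#' Dosage confusion matrix of an evaluation
#'
#' Long-format confusion counts over (truth dosage, called dosage) for the
#' truth ALT allele at every truth site; called dosage 0 encodes sites
#' missed or called hom-ref. Row sums over called dosage equal the number
#' of truth alleles at each truth dosage.
#'
#' @param x A `poly_eval` object.
#' @return A tibble with columns `truth_dosage`, `called_dosage`, `n`.
#' @export
dosage_confusion <- function(x) {
  stopifnot(inherits(x, "poly_eval"))
  x$confusion
}

#' Fraction of false-positive calls with simplex genotypes
#'
#' Among genotyping-mode FP records of the given variant type, the share
#' whose called genotype carries exactly one non-reference allele copy —
#' the diagnostic for low-allele-fraction indel artifacts.
#'
#' @param x A `poly_eval` object (evaluated with genotyping mode).
#' @param type `"indel"` (INS or DEL) or `"SNV"`.
#' @return A fraction in `[0, 1]`; 0 when there are no such FPs.
#' @export
simplex_fp_fraction <- function(x, type = c("indel", "SNV")) {
  stopifnot(inherits(x, "poly_eval"))
  type <- match.arg(type)
  fp <- x$events[x$events$mode == "genotyping" & x$events$outcome == "FP", ]
  fp <- if (type == "indel") fp[fp$vtype %in% c("INS", "DEL"), ] else
    fp[fp$vtype == "SNV", ]
  if (nrow(fp) == 0L) return(0)
  mean(fp$gt_class == "simplex")
}

#' @export
print.poly_eval <- function(x, ...) {
  cat("<poly_eval>", x$n_truth, "truth sites,", x$n_query,
      "query sites evaluated\n")
  print(glance(x))
  invisible(x)
}
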
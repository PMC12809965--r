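# Synthetic polyploid truth construction: the union of per-sample diploid
# truth sites restricted to jointly confident regions, with per-allele
# dosages summed across samples. Within the intersected confident regions,
# a sample with no record at a site asserts hom-ref there (dosage 0), which
# is what makes the union a complete polyploid truth set.

#' Describe one diploid (or other fixed-ploidy) truth sample
#'
#' @param sample_id Sample label.
#' @param vcf A variant table or a path to the sample's truth VCF.
#' @param confident A region set or a path to the sample's confident-region
#'   BED.
#' @param ploidy Sample ploidy (2 for typical diploid truth sets).
#' @return A `truth_sample` list.
#' @export
truth_sample <- function(sample_id, vcf, confident, ploidy = 2L) {
  structure(list(sample_id = sample_id, vcf = vcf, confident = confident,
                 ploidy = as.integer(ploidy)),
            class = "truth_sample")
}

load_truth_sample <- function(s, reference) {
  v <- if (is.character(s$vcf)) read_vcf(s$vcf) else s$vcf
  conf <- if (is.character(s$confident)) read_bed(s$confident) else
    region_set(s$confident)
  v <- normalize_variants(v, reference)
  list(sample_id = s$sample_id, variants = v, confident = conf,
       ploidy = s$ploidy)
}

#' Merge diploid truth samples into a polyploid truth set
#'
#' Builds the synthetic polyploid truth: confident regions are intersected
#' across samples; the record set is the union of normalized sites whose
#' footprint lies inside the intersection; at each site every sample
#' contributes its allele dosages (absence inside a confident region
#' contributes dosage 0 for every ALT, i.e. hom-ref); the output genotype is
#' the dosage-preserving multiset at `ploidy_out = sum(ploidies)`.
#' Overlapping representations are unified by [harmonize_sites()] and ALTs
#' are ordered lexicographically, so the result is invariant to sample
#' order. Sites that end up with no ALT dosage (possible only through
#' harmonization of overlapping records) are dropped and counted.
#'
#' @param samples A list of [truth_sample()] objects (>= 2, or >= 1 for
#'   degenerate uses such as self-merge tests).
#' @param reference Named character vector of chromosome sequences (or
#'   `DNAStringSet`, or FASTA path).
#' @return A `merged_truth` object: list with elements `records` (variant
#'   table at `ploidy_out`), `regions` (region set), `ploidy` (integer),
#'   `n_hom_ref_dropped`, and `provenance` (per input allele: which output
#'   site/allele it became).
#' @export
merge_truth <- function(samples, reference) {
  if (is.character(reference) && is.null(names(reference))) {
    reference <- read_fasta(reference)
  }
  reference <- as_reference(reference)
  if (length(samples) < 1L) abort("merge_truth() needs >= 1 sample")
  loaded <- lapply(samples, load_truth_sample, reference = reference)
  ploidy_out <- sum(vapply(loaded, `[[`, integer(1), "ploidy"))
  regions <- region_intersect_all(lapply(loaded, `[[`, "confident"))

  pool <- bind_rows(lapply(loaded, function(s) {
    v <- filter_by_regions(s$variants, regions)
    if (nrow(v) == 0L) return(NULL)
    # one row per (record, ALT) with that ALT's dosage in the sample
    k <- lengths(v$alts)
    idx <- rep(seq_len(nrow(v)), k)
    dos <- unlist(mapply(function(g, kk) {
      if (gt_is_missing_one(g)) rep(0L, kk) else tabulate(g, nbins = kk)
    }, v$gt, k, SIMPLIFY = FALSE), use.names = FALSE)
    tibble(sample_id = s$sample_id, sample_ploidy = s$ploidy,
           chrom = v$chrom[idx], pos = v$pos[idx], ref = v$ref[idx],
           alt = unlist(v$alts, use.names = FALSE),
           dosage = as.integer(dos))
  }))
  merge_pool(pool, regions, reference, ploidy_out,
             n_samples = length(loaded))
}

merge_pool <- function(pool, regions, reference, ploidy_out, n_samples) {
  if (is.null(pool) || nrow(pool) == 0L) {
    rec <- variant_tbl()
    return(new_merged_truth(rec, regions, ploidy_out, 0L, empty_provenance()))
  }
  pool <- pool[pool$dosage > 0L, , drop = FALSE]
  pool <- arrange(pool, .data$chrom, .data$pos)
  # chain-overlap clusters of REF footprints per chromosome
  fp_end <- pool$pos + nchar(pool$ref)  # exclusive, 1-based
  cl <- integer(nrow(pool))
  cur <- 0L; run_end <- -1L; run_chrom <- ""
  for (i in seq_len(nrow(pool))) {
    if (pool$chrom[i] != run_chrom || pool$pos[i] >= run_end) {
      cur <- cur + 1L
      run_chrom <- pool$chrom[i]
      run_end <- fp_end[i]
    } else {
      run_end <- max(run_end, fp_end[i])
    }
    cl[i] <- cur
  }
  pool$cluster <- cl

  # unified spelling per cluster
  uni <- pool %>%
    group_by(.data$cluster) %>%
    summarise(chrom = .data$chrom[1], upos = min(.data$pos),
              uend = max(.data$pos + nchar(.data$ref)),
              simple = all(.data$pos == .data$pos[1]) &&
                all(.data$ref == .data$ref[1]),
              .groups = "drop")
  uni$uref <- ifelse(
    uni$simple, NA_character_,
    substr(reference[uni$chrom], uni$upos, uni$uend - 1L))
  pool <- left_join(pool, uni, by = c("cluster", "chrom"))
  pool$uref <- ifelse(pool$simple, pool$ref, pool$uref)
  pool$ualt <- ifelse(
    pool$simple, pool$alt,
    paste0(substr(reference[pool$chrom], pool$upos, pool$pos - 1L),
           pool$alt,
           substr(reference[pool$chrom], pool$pos + nchar(pool$ref),
                  pool$uend - 1L)))
  bad_alt <- pool$ualt == pool$uref
  if (any(bad_alt)) {
    # an input ALT that re-spells to the unified REF asserts no variant
    pool <- pool[!bad_alt, , drop = FALSE]
  }

  # per-sample dosage totals must fit the sample's ploidy
  chk <- pool %>%
    group_by(.data$cluster, .data$sample_id) %>%
    summarise(d = sum(.data$dosage), p = .data$sample_ploidy[1],
              chrom = .data$chrom[1], upos = .data$upos[1], .groups = "drop")
  bad <- which(chk$d > chk$p)
  if (length(bad)) {
    abort(paste0("incompatible overlapping records for sample ",
                 chk$sample_id[bad[1]], " at ", chk$chrom[bad[1]], ":",
                 chk$upos[bad[1]], ": summed ALT dosage ", chk$d[bad[1]],
                 " exceeds ploidy ", chk$p[bad[1]]))
  }

  agg <- pool %>%
    group_by(.data$cluster, .data$chrom, .data$upos, .data$uref, .data$ualt) %>%
    summarise(dosage = sum(.data$dosage), .groups = "drop") %>%
    arrange(.data$cluster, .data$ualt)

  cl_idx <- split(seq_len(nrow(agg)), agg$cluster)
  d_tot <- vapply(cl_idx, function(ix) sum(agg$dosage[ix]), integer(1))
  n_hom_ref <- sum(d_tot == 0L)
  cl_idx <- cl_idx[d_tot > 0L]
  d_tot <- d_tot[d_tot > 0L]
  if (any(d_tot > ploidy_out)) {
    bad <- cl_idx[[which(d_tot > ploidy_out)[1]]][1]
    abort(paste0("summed dosage exceeds output ploidy at ", agg$chrom[bad],
                 ":", agg$upos[bad]))
  }
  first <- vapply(cl_idx, `[[`, integer(1), 1L)
  rec <- tibble(
    chrom = agg$chrom[first],
    pos = as.integer(agg$upos[first]),
    ref = agg$uref[first],
    alts = unname(lapply(cl_idx, function(ix) agg$ualt[ix])),
    gt = mapply(function(ix, dt) {
      sort(c(rep(0L, ploidy_out - dt),
             rep(seq_along(ix), agg$dosage[ix])))
    }, cl_idx, d_tot, SIMPLIFY = FALSE, USE.NAMES = FALSE),
    cluster = agg$cluster[first])
  if (is.null(rec) || nrow(rec) == 0L) {
    rec <- variant_tbl()
    prov <- empty_provenance()
  } else {
    alt_index <- pool %>%
      left_join(rec[, c("cluster", "alts")], by = "cluster") %>%
      mutate(out_alt = map2_int_safe(.data$alts, .data$ualt))
    prov <- tibble(sample_id = alt_index$sample_id,
                   chrom = alt_index$chrom, in_pos = alt_index$pos,
                   in_ref = alt_index$ref, in_alt = alt_index$alt,
                   out_pos = as.integer(alt_index$upos),
                   out_ref = alt_index$uref, out_alt = alt_index$out_alt,
                   dosage = alt_index$dosage)
    rec$cluster <- NULL
    rec <- new_variant_tbl(arrange(rec, .data$chrom, .data$pos))
    validate_variants(rec)
  }
  new_merged_truth(rec, regions, ploidy_out, n_hom_ref, prov)
}

map2_int_safe <- function(alts, ualt) {
  mapply(function(a, u) {
    i <- match(u, a)
    if (is.na(i)) NA_integer_ else as.integer(i)
  }, alts, ualt)
}

empty_provenance <- function() {
  tibble(sample_id = character(), chrom = character(), in_pos = integer(),
         in_ref = character(), in_alt = character(), out_pos = integer(),
         out_ref = character(), out_alt = integer(), dosage = integer())
}

new_merged_truth <- function(records, regions, ploidy, n_hom_ref_dropped,
                             provenance) {
  structure(list(records = records, regions = regions,
                 ploidy = as.integer(ploidy),
                 n_hom_ref_dropped = as.integer(n_hom_ref_dropped),
                 provenance = provenance),
            class = "merged_truth")
}

#' @export
print.merged_truth <- function(x, ...) {
  cat("<merged_truth> ploidy", x$ploidy, "|", nrow(x$records), "sites |",
      region_total_length(x$regions), "confident bases\n")
  invisible(x)
}

#' Harmonize co-located variant records onto a unified REF
#'
#' Unifies the representations of records whose normalized REF footprints
#' overlap: the unified REF spans the union of footprints (padded with
#' reference bases), each ALT is re-spelled against it, and duplicate ALT
#' spellings collapse to one index. Used by [merge_truth()] and by
#' genotype comparison in evaluation.
#'
#' @param variants A variant table whose rows all overlap pairwise (same
#'   chromosome).
#' @param reference Named character vector of chromosome sequences.
#' @return A variant table skeleton (one row; genotype dropped) with the
#'   unified REF and the lexicographically sorted unique ALT spellings.
#' @export
harmonize_sites <- function(variants, reference) {
  reference <- as_reference(reference)
  if (nrow(variants) < 1L) abort("harmonize_sites() needs >= 1 record")
  if (length(unique(variants$chrom)) != 1L) {
    abort("harmonize_sites() records must share a chromosome")
  }
  fp <- variant_footprints(variants)
  if (max(fp$start) >= min(fp$end)) {
    abort("harmonize_sites() requires overlapping REF footprints")
  }
  chrom <- variants$chrom[1]
  upos <- min(variants$pos)
  uend <- max(variants$pos + nchar(variants$ref))
  uref <- substr(reference[[chrom]], upos, uend - 1L)
  ualts <- unlist(lapply(seq_len(nrow(variants)), function(i) {
    pre <- substr(reference[[chrom]], upos, variants$pos[i] - 1L)
    suf <- substr(reference[[chrom]], variants$pos[i] + nchar(variants$ref[i]),
                  uend - 1L)
    paste0(pre, variants$alts[[i]], suf)
  }), use.names = FALSE)
  ualts <- sort(unique(ualts[ualts != uref]))
  variant_tbl(chrom, upos, uref, list(ualts), list(NA_integer_))
}

#' Coverage arithmetic for pooled-read experiment designs
#'
#' Pure arithmetic aid: pooling `n_samples` read sets of `per_sample_depth`
#' fold-coverage each gives `total = n_samples * per_sample_depth` and
#' `per_haplotype = total / ploidy_out` (e.g. two diploid samples at 30x
#' give 60x total, 15x per haplotype in the tetraploid).
#'
#' @param per_sample_depth Numeric vector of per-sample fold-coverages (a
#'   grid yields one row per value).
#' @param n_samples Number of pooled samples.
#' @param sample_ploidy Ploidy of each input sample.
#' @return A tibble with columns `per_sample_depth`, `n_samples`,
#'   `ploidy_out`, `total_depth`, `per_haplotype_depth`.
#' @examples
#' plan_coverage(30, n_samples = 2)
#' plan_coverage(c(10, 30, 50, 70, 90), n_samples = 2)
#' @export
plan_coverage <- function(per_sample_depth, n_samples, sample_ploidy = 2L) {
  if (any(per_sample_depth <= 0)) abort("depths must be positive")
  ploidy_out <- as.integer(n_samples * sample_ploidy)
  tibble(per_sample_depth = per_sample_depth,
         n_samples = as.integer(n_samples),
         ploidy_out = ploidy_out,
         total_depth = per_sample_depth * n_samples,
         per_haplotype_depth = per_sample_depth * n_samples / ploidy_out)
}
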
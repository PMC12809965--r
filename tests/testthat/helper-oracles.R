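# Independent brute-force oracles used across tests. These deliberately use
# per-base boolean/counting arrays and direct string surgery, never the
# package's interval or normalization code paths.

alt_base <- function(chrom_seq, pos) {
  setdiff(c("A", "C", "G", "T"), substr(chrom_seq, pos, pos))[1]
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# per-base coverage counts of raw intervals (0-based half-open) on [0, L)
oracle_cover_count <- function(start, end, L) {
  cov <- integer(L)
  for (i in seq_along(start)) {
    if (end[i] > start[i]) {
      idx <- (start[i] + 1L):min(end[i], L)
      cov[idx] <- cov[idx] + 1L
    }
  }
  cov
}

# boolean membership mask of a region set (single chromosome) on [0, L)
oracle_rs_mask <- function(rs, chrom, L) {
  m <- logical(L)
  rr <- rs[rs$chrom == chrom, , drop = FALSE]
  for (i in seq_len(nrow(rr))) m[(rr$start[i] + 1L):rr$end[i]] <- TRUE
  m
}

# region set from a boolean mask, via run-length encoding (independent of
# the package's interval code)
mask_to_intervals <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# random raw interval collection on [0, L)
rand_intervals <- function(n, L, max_len = 20000L) {
  start <- sample.int(L - 10L, n, replace = TRUE) - 1L
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(start = start, end = pmin(start + len, L))
}

# spell a haplotype by direct string surgery from (pos, ref, alt) records
oracle_apply <- function(seq, pos, ref, alt) {
  o <- order(pos, decreasing = TRUE)
  for (i in o) {
    seq <- paste0(substr(seq, 1, pos[i] - 1), alt[i],
                  substr(seq, pos[i] + nchar(ref[i]), nchar(seq)))
  }
  seq
}

# random small variant (SNV / INS / DEL) on a reference string, spelled
# VCF-style with an anchor base, at a position clear of the ends
rand_variant <- function(chrom_seq, min_pos = 20L, max_indel = 10L) {
  L <- nchar(chrom_seq)
  p <- sample(min_pos:(L - max_indel - 20L), 1)
  type <- sample(c("snv", "ins", "del"), 1)
  rb <- substr(chrom_seq, p, p)
  if (type == "snv") {
    list(pos = p, ref = rb, alt = sample(setdiff(c("A", "C", "G", "T"), rb), 1))
  } else if (type == "ins") {
    ins <- rand_dna(sample.int(max_indel, 1))
    list(pos = p, ref = rb, alt = paste0(rb, ins))
  } else {
    len <- sample.int(max_indel, 1)
    list(pos = p, ref = substr(chrom_seq, p, p + len), alt = rb)
  }
}

# re-spell a variant record non-minimally: pad REF and ALT with the shared
# reference suffix, and/or prepend the preceding reference base
obfuscate_variant <- function(chrom_seq, v) {
  pad <- sample(0:3, 1)
  ref <- v$ref; alt <- v$alt; pos <- v$pos
  if (pad > 0) {
    suf <- substr(chrom_seq, pos + nchar(ref), pos + nchar(ref) + pad - 1L)
    ref <- paste0(ref, suf); alt <- paste0(alt, suf)
  }
  lead <- sample(0:2, 1)
  while (lead > 0 && pos > 1) {
    pos <- pos - 1L
    b <- substr(chrom_seq, pos, pos)
    ref <- paste0(b, ref); alt <- paste0(b, alt)
    lead <- lead - 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

# quick single-chromosome fixture pipeline for evaluation tests
run_fixture <- function(seed, n_haplotypes = 4L, chrom_len = 30000L, ...) {
  spec <- fixture_spec(seed = seed, chrom_len = chrom_len,
                       n_haplotypes = n_haplotypes, ...)
  ref <- gen_reference(spec)
  hs <- gen_haplotypes(ref$sequences, spec)
  truth <- merge_truth(hs$samples, ref$sequences)
  corr <- corrupt_callset(truth, spec, ref$sequences)
  ev <- evaluate_calls(truth, corr$query, reference = ref$sequences)
  list(spec = spec, ref = ref, hs = hs, truth = truth, corr = corr, ev = ev)
}

expect_counts_equal <- function(ev, expected) {
  g <- glance(ev)
  expect_identical(
    c(g$detection_TP, g$detection_FP, g$detection_FN,
      g$genotyping_TP, g$genotyping_FP, g$genotyping_FN),
    as.integer(c(expected$TP[expected$mode == "detection"],
                 expected$FP[expected$mode == "detection"],
                 expected$FN[expected$mode == "detection"],
                 expected$TP[expected$mode == "genotyping"],
                 expected$FP[expected$mode == "genotyping"],
                 expected$FN[expected$mode == "genotyping"])))
}
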
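# Deterministic synthetic benchmark generator. Everything downstream of a
# fixture_spec is a pure function of the spec (including its seed):
# reference, haplotypes, diploid truth samples, alignment blocks with
# PAV-like defects, corrupted callsets and read placements, each with
# bookkeeping sufficient to predict every evaluation count exactly.

#' Parameters of a synthetic polyploid benchmark
#'
#' @param seed Integer RNG seed; the same spec always produces
#'   byte-identical artifacts.
#' @param n_chrom,chrom_len Number and length (bp) of reference chromosomes.
#' @param n_haplotypes Haplotype count: 2, 4 or 6 (paired into diploid
#'   samples).
#' @param snv_rate,indel_rate Per-base probability of placing an SNV /
#'   indel truth site (site density, shared across haplotypes).
#' @param indel_len_geom_p Geometric parameter for indel lengths
#'   (`length = 1 + rgeom(p)`).
#' @param multiallelic_rate Probability that an SNV site carries two
#'   distinct ALT bases.
#' @param carrier_prob Per-haplotype probability of carrying the ALT at a
#'   site (conditioned on at least one carrier).
#' @param margin Bases excluded from each chromosome end in the per-sample
#'   confident regions.
#' @param repeat_fraction Approximate fraction of the reference implanted
#'   as tandem-repeat tracts (exercises left-alignment).
#' @param pav_events Number of presence/absence-like alignment defects
#'   (coverage gaps or duplicated blocks) across haplotypes.
#' @param pav_len Length (bp) of each such event.
#' @param fn_rate,fp_rate,dosage_err_rate Callset corruption probabilities:
#'   per-site drop probability, spurious-call count as a fraction of truth
#'   sites, and per-site dosage mis-assignment probability.
#' @param dosage_to_zero If `TRUE`, dosage shifts may reach 0 (the
#'   simplex-to-hom-ref failure mode); default shifts stay in
#'   `[1, ploidy - 1]` so detection still succeeds.
#' @param fp_indel_frac Fraction of spurious calls that are indels.
#' @param fp_dosage Called dosage of spurious records (1 = simplex).
#' @param read_length,n_reads Geometry of simulated read placements.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_chrom = 1L, chrom_len = 100000L,
                         n_haplotypes = 4L, snv_rate = 0.008,
                         indel_rate = 0.002, indel_len_geom_p = 0.5,
                         multiallelic_rate = 0.02, carrier_prob = 0.5,
                         margin = 200L, repeat_fraction = 0,
                         pav_events = 2L, pav_len = 1000L,
                         fn_rate = 0.03, fp_rate = 0.05,
                         dosage_err_rate = 0.02, dosage_to_zero = FALSE,
                         fp_indel_frac = 0.5, fp_dosage = 1L,
                         read_length = 1000L, n_reads = 2000L) {
  rates <- c(snv_rate, indel_rate, multiallelic_rate, carrier_prob,
             repeat_fraction, fn_rate, fp_rate, dosage_err_rate,
             fp_indel_frac)
  if (any(rates < 0 | rates > 1)) abort("all rates must lie in [0, 1]")
  if (!n_haplotypes %in% c(2L, 4L, 6L)) {
    abort("n_haplotypes must be 2, 4 or 6")
  }
  structure(as.list(environment())[names(formals(fixture_spec))],
            class = "fixture_spec")
}

fixture_seed <- function(spec, offset, k = 0L) {
  as.integer((as.numeric(spec$seed) * 7919 + offset * 104729 + k * 131) %%
               2147483647)
}

#' Generate a deterministic random reference
#'
#' Uniform-random ACGT sequences, optionally with implanted tandem-repeat
#' tracts (annotated in a sidecar region set) to exercise indel
#' left-alignment.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `sequences` (named character vector) and `repeats`
#'   (region set of implanted tracts).
#' @export
gen_reference <- function(spec) {
  seqs <- character(spec$n_chrom)
  names(seqs) <- paste0("chr", seq_len(spec$n_chrom))
  rep_rows <- list()
  for (ci in seq_len(spec$n_chrom)) {
    set.seed(fixture_seed(spec, 1L, ci))
    bases <- sample(c("A", "C", "G", "T"), spec$chrom_len, replace = TRUE)
    if (spec$repeat_fraction > 0) {
      total <- 0L
      target <- spec$repeat_fraction * spec$chrom_len
      while (total < target) {
        motif_len <- sample(1:4, 1)
        motif <- sample(c("A", "C", "G", "T"), motif_len, replace = TRUE)
        n_copies <- sample(8:15, 1)
        tract <- rep(motif, n_copies)
        at <- sample(spec$chrom_len - length(tract), 1)
        bases[at:(at + length(tract) - 1L)] <- tract
        rep_rows[[length(rep_rows) + 1L]] <-
          tibble(chrom = names(seqs)[ci], start = at - 1L,
                 end = at - 1L + length(tract))
        total <- total + length(tract)
      }
    }
    seqs[ci] <- paste(bases, collapse = "")
  }
  reps <- if (length(rep_rows)) region_set(bind_rows(rep_rows)) else
    empty_region_set()
  list(sequences = seqs, repeats = reps)
}

#' Generate haplotype variant sets and diploid truth samples
#'
#' Places truth sites at the spec's density, assigns each haplotype a
#' carrier state per site (at least one carrier), normalizes the records,
#' spells the haplotype sequences by applying each haplotype's alleles to
#' the reference, and pairs consecutive haplotypes into diploid truth
#' samples (VCF-equivalent variant tables plus confident regions = the
#' chromosome minus the spec margin).
#'
#' @param reference Named character vector of chromosome sequences, e.g.
#'   `gen_reference(spec)$sequences`.
#' @param spec A [fixture_spec()].
#' @return A list with `sites` (variant table plus `hap_alleles`
#'   list-column of per-haplotype allele indices), `haplotypes` (named
#'   character vector of spelled sequences), `samples` (list of
#'   [truth_sample()] objects) and `confident` (the shared region set).
#' @export
gen_haplotypes <- function(reference, spec) {
  n_hap <- spec$n_haplotypes
  all_sites <- list()
  haps <- setNames(rep("", n_hap), paste0("hap", seq_len(n_hap)))
  for (ci in seq_along(reference)) {
    chrom <- names(reference)[ci]
    chrom_seq <- reference[[ci]]
    L <- nchar(chrom_seq)
    set.seed(fixture_seed(spec, 2L, ci))
    rate <- spec$snv_rate + spec$indel_rate
    cand <- which(runif(L) < rate)
    cand <- cand[cand > spec$margin + 20L & cand < L - spec$margin - 40L]
    # greedy spacing so footprints and left-shifts cannot collide
    pos <- integer(0); last <- -100L
    for (p in cand) {
      if (p - last >= 30L) { pos <- c(pos, p); last <- p }
    }
    rows <- gen_sites(pos, chrom, chrom_seq, spec, n_hap)
    if (nrow(rows) > 0L) {
      # normalize; drop any site whose normalized footprint drifted into a
      # neighbour's or the margin (rare, homopolymer shifts)
      norm <- lapply(seq_len(nrow(rows)), function(i) {
        normalize_one(rows$pos[i], rows$ref[i], rows$alts[[i]], chrom_seq)
      })
      rows$pos <- vapply(norm, `[[`, integer(1), "pos")
      rows$ref <- vapply(norm, `[[`, character(1), "ref")
      rows$alts <- lapply(norm, `[[`, "alts")
      rows <- arrange(rows, .data$pos)
      ends <- rows$pos + nchar(rows$ref)
      ok <- logical(nrow(rows)); last_end <- -1L
      for (i in seq_len(nrow(rows))) {
        if (rows$pos[i] > spec$margin && rows$pos[i] > last_end + 1L) {
          ok[i] <- TRUE; last_end <- ends[i]
        }
      }
      rows <- rows[ok, , drop = FALSE]
      all_sites[[ci]] <- rows
    }
    for (h in seq_len(n_hap)) {
      sel <- if (nrow(rows) > 0L)
        which(vapply(rows$hap_alleles, `[[`, integer(1), h) > 0L) else
        integer(0)
      hseq <- if (length(sel)) {
        apply_variants(chrom_seq, rows[sel, ],
                       vapply(rows$hap_alleles[sel], `[[`, integer(1), h))
      } else chrom_seq
      haps[h] <- paste0(haps[h], hseq)
    }
  }
  sites <- bind_rows(all_sites)
  if (nrow(sites) == 0L) {
    sites <- variant_tbl()
    sites$hap_alleles <- list()
  }
  confident <- region_set(tibble(
    chrom = names(reference),
    start = spec$margin,
    end = nchar(reference) - spec$margin))
  samples <- lapply(seq_len(n_hap / 2L), function(k) {
    h1 <- 2L * k - 1L; h2 <- 2L * k
    a1 <- vapply(sites$hap_alleles, `[[`, integer(1), h1)
    a2 <- vapply(sites$hap_alleles, `[[`, integer(1), h2)
    sel <- which(a1 > 0L | a2 > 0L)
    v <- sites[sel, c("chrom", "pos", "ref", "alts")]
    v$gt <- mapply(function(x, y) sort(c(x, y)), a1[sel], a2[sel],
                   SIMPLIFY = FALSE)
    truth_sample(paste0("sample", k), new_variant_tbl(as_tibble(v)),
                 confident, ploidy = 2L)
  })
  list(sites = sites, haplotypes = haps, samples = samples,
       confident = confident)
}

gen_sites <- function(pos, chrom, chrom_seq, spec, n_hap) {
  n <- length(pos)
  if (n == 0L) {
    return(tibble(chrom = character(), pos = integer(), ref = character(),
                  alts = list(), gt = list(), hap_alleles = list()))
  }
  ref <- character(n); alts <- vector("list", n)
  hap_alleles <- vector("list", n)
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n)) {
    p <- pos[i]
    ref_base <- substr(chrom_seq, p, p)
    is_snv <- runif(1) < spec$snv_rate / (spec$snv_rate + spec$indel_rate)
    if (is_snv) {
      n_alt <- if (runif(1) < spec$multiallelic_rate) 2L else 1L
      a <- sample(setdiff(bases, ref_base), n_alt)
      r <- ref_base
    } else {
      len <- min(1L + rgeom(1, spec$indel_len_geom_p), 10L)
      if (runif(1) < 0.5) {  # insertion
        r <- ref_base
        a <- paste0(ref_base,
                    paste(sample(bases, len, replace = TRUE), collapse = ""))
      } else {               # deletion
        r <- substr(chrom_seq, p, p + len)
        a <- ref_base
      }
      n_alt <- 1L
    }
    # carrier states: at least one haplotype carries some ALT
    repeat {
      carried <- sample.int(n_alt + 1L, n_hap, replace = TRUE,
                            prob = c(1 - spec$carrier_prob,
                                     rep(spec$carrier_prob / n_alt, n_alt))) - 1L
      if (any(carried > 0L)) break
    }
    present <- sort(unique(carried[carried > 0L]))
    ref[i] <- r
    alts[[i]] <- a[present]
    hap_alleles[[i]] <- match(carried, present, nomatch = 0L)
  }
  tibble(chrom = chrom, pos = as.integer(pos), ref = ref, alts = alts,
         gt = rep(list(NA_integer_), n), hap_alleles = hap_alleles)
}

#' Generate assembly-alignment blocks with PAV-like defects
#'
#' By default every haplotype aligns each chromosome in one full-length
#' block (mapq 60). Each PAV event either removes a segment from one
#' haplotype's block (a reference-only segment: coverage gap) or adds a
#' duplicated block (a sample repeat: coverage 2), so the expected joint
#' confidence region is the chromosome minus the union of event intervals
#' — returned as `expected_confidence` in closed form.
#'
#' @param reference Named character vector of chromosome sequences.
#' @param spec A [fixture_spec()].
#' @return A list with `blocks` (alignment-block tibble for
#'   [derive_confidence_regions()]), `events` (tibble of injected defects)
#'   and `expected_confidence` (region set).
#' @export
gen_alignment_blocks <- function(reference, spec) {
  set.seed(fixture_seed(spec, 3L))
  n_hap <- spec$n_haplotypes
  chrom_len <- setNames(nchar(reference), names(reference))
  events <- list()
  if (spec$pav_events > 0L) {
    for (e in seq_len(spec$pav_events)) {
      for (try in 1:100) {
        chrom <- sample(names(chrom_len), 1)
        s <- sample(chrom_len[[chrom]] - spec$pav_len - 2L, 1)
        ok <- !any(vapply(events, function(ev) {
          ev$chrom == chrom && s < ev$end + 1L && ev$start < s + spec$pav_len + 1L
        }, logical(1)))
        if (ok) break
      }
      events[[e]] <- tibble(
        chrom = chrom, start = as.integer(s),
        end = as.integer(s + spec$pav_len),
        haplotype = sample(n_hap, 1),
        type = sample(c("gap", "dup"), 1))
    }
  }
  events <- if (length(events)) bind_rows(events) else
    tibble(chrom = character(), start = integer(), end = integer(),
           haplotype = integer(), type = character())
  blocks <- list()
  for (h in seq_len(n_hap)) {
    for (chrom in names(chrom_len)) {
      L <- chrom_len[[chrom]]
      ev <- events[events$haplotype == h & events$chrom == chrom, ]
      segs <- tibble(ref_start = 0L, ref_end = L)
      gaps <- ev[ev$type == "gap", ]
      for (i in seq_len(nrow(gaps))) {
        segs <- bind_rows(lapply(seq_len(nrow(segs)), function(j) {
          s <- segs$ref_start[j]; e <- segs$ref_end[j]
          if (gaps$start[i] >= e || gaps$end[i] <= s) {
            return(tibble(ref_start = s, ref_end = e))
          }
          bind_rows(
            if (gaps$start[i] > s) tibble(ref_start = s,
                                          ref_end = gaps$start[i]),
            if (gaps$end[i] < e) tibble(ref_start = gaps$end[i],
                                        ref_end = e))
        }))
      }
      dups <- ev[ev$type == "dup", ]
      if (nrow(dups)) {
        segs <- bind_rows(segs, tibble(ref_start = dups$start,
                                       ref_end = dups$end))
      }
      blocks[[length(blocks) + 1L]] <- tibble(
        haplotype_id = paste0("hap", h), chrom = chrom,
        ref_start = segs$ref_start, ref_end = segs$ref_end,
        query_name = paste0("hap", h, "_", chrom), mapq = 60L)
    }
  }
  blocks <- bind_rows(blocks)
  whole <- region_set(tibble(chrom = names(chrom_len), start = 0L,
                             end = unname(chrom_len)))
  expected <- if (nrow(events)) {
    region_subtract(whole, region_set(events[, c("chrom", "start", "end")]))
  } else whole
  list(blocks = blocks, events = events, expected_confidence = expected)
}

#' Corrupt a truth set into a query callset with bookkept errors
#'
#' Independently per truth site: dropped with probability `fn_rate`;
#' otherwise dosage-shifted with probability `dosage_err_rate` (one ALT
#' copy moved to or from REF, staying in `[1, ploidy - 1]` unless
#' `dosage_to_zero` — a shift to 0 emits a hom-ref record, the
#' simplex-to-hom-ref failure mode). `round(fp_rate * n_truth)` spurious
#' records with called dosage `fp_dosage` are added at positions disjoint
#' from truth footprints inside the confidence regions. The ledger records
#' every action; `expected` gives the exact TP/FP/FN each evaluation mode
#' must report.
#'
#' @param truth A `merged_truth` object (see [merge_truth()]).
#' @param spec A [fixture_spec()].
#' @param reference Named character vector of chromosome sequences.
#' @return A list with `query` (variant table), `ledger` (per-site action
#'   tibble) and `expected` (tibble: mode, TP, FP, FN).
#' @export
corrupt_callset <- function(truth, spec, reference) {
  stopifnot(inherits(truth, "merged_truth"))
  reference <- as_reference(reference)
  rec <- truth$records
  ploidy <- truth$ploidy
  set.seed(fixture_seed(spec, 4L))
  n <- nrow(rec)
  u_drop <- runif(n) < spec$fn_rate
  u_shift <- !u_drop & runif(n) < spec$dosage_err_rate
  action <- ifelse(u_drop, "drop", ifelse(u_shift, "shift", "keep"))
  old_d <- rep(NA_integer_, n); new_d <- rep(NA_integer_, n)
  new_gt <- rec$gt
  for (i in which(action == "shift")) {
    g <- rec$gt[[i]]
    alt_ids <- unique(g[g > 0L])
    a <- if (length(alt_ids) == 1L) alt_ids else
      alt_ids[sample(length(alt_ids), 1)]
    d <- sum(g == a)
    # a shift to dosage 0 is only bookkeepable as an FN when the record
    # has no other ALT left to detect
    lo <- if (spec$dosage_to_zero && length(alt_ids) == 1L) 0L else 1L
    cand <- c(d - 1L, d + 1L)
    cand <- cand[cand >= lo & cand + sum(g > 0L & g != a) <= ploidy]
    if (length(cand) == 0L) {
      action[i] <- "keep"
      next
    }
    nd <- if (length(cand) == 1L) cand else cand[sample(2L, 1)]
    old_d[i] <- d; new_d[i] <- nd
    g2 <- c(g[g != a], rep(a, nd))   # zeros + other ALTs + shifted ALT
    if (length(g2) > ploidy) {
      zeros <- which(g2 == 0L)
      g2 <- g2[-zeros[seq_len(length(g2) - ploidy)]]
    } else if (length(g2) < ploidy) {
      g2 <- c(g2, rep(0L, ploidy - length(g2)))
    }
    new_gt[[i]] <- sort(g2)
  }
  kept <- rec[action != "drop", , drop = FALSE]
  kept$gt <- new_gt[action != "drop"]

  n_fp <- round(spec$fp_rate * n)
  occupied <- variant_footprints(rec)
  spurious <- gen_spurious(n_fp, truth$regions, occupied, reference, spec,
                           ploidy)
  query <- bind_rows(kept, spurious)
  query <- new_variant_tbl(arrange(as_tibble(query), .data$chrom, .data$pos))

  shift_zero <- !is.na(new_d) & new_d == 0L
  n_drop <- sum(action == "drop")
  n_shift <- sum(action == "shift" & !is.na(new_d))
  n_shift_nz <- sum(action == "shift" & !is.na(new_d) & new_d > 0L)
  n_sz <- sum(shift_zero)
  expected <- tibble(
    mode = c("detection", "genotyping"),
    TP = c(n - n_drop - n_sz, n - n_drop - n_shift),
    FP = c(n_fp, n_fp + n_shift_nz),
    FN = c(n_drop + n_sz, n_drop + n_shift))
  ledger <- tibble(chrom = rec$chrom, pos = rec$pos, action = action,
                   old_dosage = old_d, new_dosage = new_d)
  ledger <- bind_rows(ledger,
                      tibble(chrom = spurious$chrom, pos = spurious$pos,
                             action = "spurious", old_dosage = NA_integer_,
                             new_dosage = spec$fp_dosage))
  list(query = query, ledger = ledger, expected = expected)
}

# spurious records: normalized, in-region, disjoint from truth and each other
gen_spurious <- function(n_fp, regions, occupied, reference, spec, ploidy) {
  out <- list()
  if (n_fp == 0L) return(variant_tbl())
  reg <- regions[regions$end - regions$start > 50L, , drop = FALSE]
  taken <- occupied
  tries <- 0L
  while (length(out) < n_fp && tries < n_fp * 200L) {
    tries <- tries + 1L
    ri <- sample(nrow(reg), 1)
    chrom <- reg$chrom[ri]
    p <- sample((reg$start[ri] + 2L):(reg$end[ri] - 15L), 1)  # 1-based pos
    chrom_seq <- reference[[chrom]]
    is_indel <- runif(1) < spec$fp_indel_frac
    if (is_indel) {
      len <- 1L + rgeom(1, spec$indel_len_geom_p)
      len <- min(len, 8L)
      if (runif(1) < 0.5) {
        ref <- substr(chrom_seq, p, p)
        alt <- paste0(ref, paste(sample(c("A", "C", "G", "T"), len,
                                        replace = TRUE), collapse = ""))
      } else {
        ref <- substr(chrom_seq, p, p + len)
        alt <- substr(chrom_seq, p, p)
      }
    } else {
      ref <- substr(chrom_seq, p, p)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    }
    nr <- normalize_one(as.integer(p), ref, alt, chrom_seq)
    s <- nr$pos - 1L; e <- nr$pos - 1L + nchar(nr$ref)
    clash <- any(taken$chrom == chrom & s < taken$end + 1L &
                   taken$start - 1L < e)
    in_reg <- any(regions$chrom == chrom & regions$start <= s &
                    e <= regions$end)
    if (clash || !in_reg) next
    d <- min(spec$fp_dosage, ploidy)
    out[[length(out) + 1L]] <- tibble(
      chrom = chrom, pos = nr$pos, ref = nr$ref, alts = list(nr$alts),
      gt = list(sort(c(rep(0L, ploidy - d), rep(1L, d)))))
    taken <- bind_rows(taken, tibble(chrom = chrom, start = s, end = e))
  }
  if (length(out) < n_fp) {
    abort("could not place the requested number of spurious records")
  }
  new_variant_tbl(bind_rows(out))
}

#' Generate read placements with known reliable-region overlap
#'
#' Places single-block reads of fixed length uniformly on the reference and
#' records each read's exact overlap with the reliable regions via an
#' independent per-base count, so the expected keep/drop set of
#' [reliable_read_filter()] is known in advance.
#'
#' @param spec A [fixture_spec()].
#' @param reliable A region set of reliable intervals.
#' @param chrom_len Named integer vector of chromosome lengths.
#' @return A list with `placements` (tibble for [reliable_read_filter()])
#'   and `ledger` (read_id, overlap, expected_keep at `min_frac = 0.5`).
#' @export
gen_read_placements <- function(spec, reliable, chrom_len) {
  set.seed(fixture_seed(spec, 5L))
  # per-base reliability masks, the independent accounting
  masks <- lapply(names(chrom_len), function(chrom) {
    m <- logical(chrom_len[[chrom]])
    rr <- reliable[reliable$chrom == chrom, ]
    for (i in seq_len(nrow(rr))) m[(rr$start[i] + 1L):rr$end[i]] <- TRUE
    m
  })
  names(masks) <- names(chrom_len)
  chroms <- sample(names(chrom_len), spec$n_reads, replace = TRUE,
                   prob = chrom_len / sum(chrom_len))
  starts <- vapply(chroms, function(chrom) {
    sample(chrom_len[[chrom]] - spec$read_length, 1)
  }, integer(1))
  placements <- tibble(read_id = sprintf("read%05d", seq_len(spec$n_reads)),
                       chrom = chroms, start = as.integer(starts),
                       end = as.integer(starts + spec$read_length),
                       read_length = spec$read_length)
  overlap <- vapply(seq_len(spec$n_reads), function(i) {
    sum(masks[[chroms[i]]][(starts[i] + 1L):(starts[i] + spec$read_length)])
  }, integer(1))
  ledger <- tibble(read_id = placements$read_id, overlap = overlap,
                   expected_keep = 2L * overlap > spec$read_length)
  list(placements = placements, ledger = ledger)
}

#' Run the full synthetic benchmark and write its artifacts
#'
#' Generates reference, haplotypes, per-sample truth VCF/BED pairs,
#' alignment blocks (PAF), the merged polyploid truth, a corrupted query
#' callset with its ledger, and read placements; optionally writes
#' everything under `dir` as plain-text artifacts (`ref.fa`, `hapN.fa`,
#' `sampleK.vcf` + `.bed`, `blocks.paf`, `truth.vcf`, `conf.bed`,
#' `query.vcf`, `ledger.json`, `reads.tsv`).
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed); `NULL` = in-memory only.
#' @return Invisibly, a list with all in-memory objects: `reference`,
#'   `haplotype_set`, `blocks`, `truth`, `corruption`, `reads`.
#' @export
simulate_benchmark <- function(spec, dir = NULL) {
  ref <- gen_reference(spec)
  hs <- gen_haplotypes(ref$sequences, spec)
  ab <- gen_alignment_blocks(ref$sequences, spec)
  truth <- merge_truth(hs$samples, ref$sequences)
  corr <- corrupt_callset(truth, spec, ref$sequences)
  chrom_len <- setNames(nchar(ref$sequences), names(ref$sequences))
  reads <- gen_read_placements(spec, ab$expected_confidence, chrom_len)
  out <- list(reference = ref, haplotype_set = hs, blocks = ab,
              truth = truth, corruption = corr, reads = reads)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(ref$sequences, file.path(dir, "ref.fa"))
    for (h in names(hs$haplotypes)) {
      write_fasta(setNames(hs$haplotypes[h], h),
                  file.path(dir, paste0(h, ".fa")))
    }
    for (s in hs$samples) {
      write_vcf(s$vcf, file.path(dir, paste0(s$sample_id, ".vcf")),
                contigs = chrom_len, sample_name = s$sample_id)
      write_bed(s$confident, file.path(dir, paste0(s$sample_id, ".bed")))
    }
    write_paf(ab$blocks, chrom_len, file.path(dir, "blocks.paf"))
    write_vcf(truth$records, file.path(dir, "truth.vcf"),
              contigs = chrom_len, sample_name = "TRUTH")
    write_bed(truth$regions, file.path(dir, "conf.bed"))
    write_vcf(corr$query, file.path(dir, "query.vcf"),
              contigs = chrom_len, sample_name = "QUERY")
    jsonlite::write_json(
      list(spec = unclass(spec), ledger = corr$ledger,
           expected = corr$expected),
      file.path(dir, "ledger.json"), dataframe = "rows", na = "null",
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    readr::write_tsv(dplyr::left_join(reads$placements, reads$ledger,
                                      by = "read_id"),
                     file.path(dir, "reads.tsv"), progress = FALSE)
  }
  invisible(out)
}

write_paf <- function(blocks, chrom_len, path) {
  alen <- blocks$ref_end - blocks$ref_start
  lines <- paste(blocks$query_name, alen, 0L, alen, "+",
                 blocks$chrom, chrom_len[blocks$chrom],
                 blocks$ref_start, blocks$ref_end,
                 alen, alen, blocks$mapq, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
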
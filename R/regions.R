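# Region sets: per-chromosome sorted disjoint 0-based half-open intervals,
# stored as a tibble (chrom, start, end). Interval algebra is delegated to
# IRanges/GenomicRanges; conversion happens inside this file only.

#' Construct a region set
#'
#' A region set is a tibble of 0-based half-open intervals, normalized so
#' intervals are sorted and pairwise disjoint per chromosome (overlapping or
#' bookended input intervals are merged, union semantics).
#'
#' @param chrom Character chromosome names (or a data frame with columns
#'   `chrom`, `start`, `end`).
#' @param start,end Integer interval bounds, `start < end`.
#' @return A tibble of class `region_set` with columns `chrom`, `start`, `end`.
#' @examples
#' region_set("chr1", c(0, 50), c(100, 150))
#' @export
region_set <- function(chrom = character(), start = integer(), end = integer()) {
  if (inherits(chrom, "region_set")) return(chrom)  # already normalized
  if (is.data.frame(chrom)) {
    df <- chrom
    stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  } else {
    df <- tibble(chrom = as.character(chrom), start = as.integer(start),
                 end = as.integer(end))
  }
  if (nrow(df) > 0 && any(df$end <= df$start)) {
    abort("region_set intervals require start < end")
  }
  merge_intervals(df)
}

# union-merge of raw intervals (overlapping or bookended) by sorted sweep
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(empty_region_set())
  o <- order(df$chrom, df$start, df$end, method = "radix")
  chrom <- df$chrom[o]; start <- as.integer(df$start[o])
  end <- as.integer(df$end[o])
  out_c <- character(0); out_s <- integer(0); out_e <- integer(0)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    s <- start[i]; e <- end[i]
    run_max <- cummax(e)
    new_run <- c(TRUE, s[-1] > run_max[-length(run_max)])
    cl <- cumsum(new_run)
    out_c <- c(out_c, rep(ch, max(cl)))
    out_s <- c(out_s, s[new_run])
    out_e <- c(out_e, as.integer(tapply(e, cl, max)))
  }
  new_region_set(tibble(chrom = out_c, start = out_s, end = out_e))
}

new_region_set <- function(df) {
  class(df) <- unique(c("region_set", class(df)))
  df
}

empty_region_set <- function() {
  new_region_set(tibble(chrom = character(), start = integer(),
                        end = integer()))
}

# tibble (0-based half-open) <-> GRanges (1-based closed)
rs_to_gr <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

gr_to_rs <- function(gr) {
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start <- GenomicRanges::start(gr) - 1L
  o <- order(chrom, start, method = "radix")
  new_region_set(tibble(chrom = chrom[o], start = start[o],
                        end = GenomicRanges::end(gr)[o]))
}

#' Total length of a region set
#' @param regions A region set.
#' @return Total covered bases, `sum(end - start)`.
#' @export
region_total_length <- function(regions) sum(regions$end - regions$start)

#' Intersect region sets across haplotypes
#'
#' Positions present in every input set; per shared chromosome, chromosomes
#' absent from any input contribute nothing. Associative and commutative.
#' This is the "consistently represented across all haplotypes" step of
#' confidence-region construction.
#'
#' @param sets A list of region sets (at least one).
#' @return A region set.
#' @export
region_intersect_all <- function(sets) {
  if (length(sets) == 0L) abort("region_intersect_all() needs >= 1 set")
  Reduce(intersect_two, lapply(sets, region_set))
}

#' Subtract one region set from another
#' @param a,b Region sets.
#' @return Positions in `a` and not in `b`, as a region set.
#' @export
region_subtract <- function(a, b) {
  a <- region_set(a); b <- region_set(b)
  if (nrow(b) == 0L || nrow(a) == 0L) return(a)
  rows <- lapply(unique(a$chrom), function(ch) {
    ai <- a[a$chrom == ch, ]
    bi <- b[b$chrom == ch, ]
    if (nrow(bi) == 0L) return(ai)
    out_s <- integer(0); out_e <- integer(0)
    for (i in seq_len(nrow(ai))) {
      cur <- ai$start[i]; end_i <- ai$end[i]
      ov <- which(bi$end > cur & bi$start < end_i)
      for (j in ov) {
        if (bi$start[j] > cur) {
          out_s <- c(out_s, cur); out_e <- c(out_e, bi$start[j])
        }
        cur <- max(cur, bi$end[j])
      }
      if (cur < end_i) { out_s <- c(out_s, cur); out_e <- c(out_e, end_i) }
    }
    tibble(chrom = ch, start = out_s, end = out_e)
  })
  rows <- bind_rows(rows)
  new_region_set(arrange(rows, .data$chrom, .data$start))
}

# intersection of two normalized region sets by two-pointer sweep
intersect_two <- function(a, b) {
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  rows <- lapply(chroms, function(ch) {
    as <- a$start[a$chrom == ch]; ae <- a$end[a$chrom == ch]
    bs <- b$start[b$chrom == ch]; be <- b$end[b$chrom == ch]
    ia <- 1L; ib <- 1L
    out_s <- integer(0); out_e <- integer(0)
    while (ia <= length(as) && ib <= length(bs)) {
      s <- max(as[ia], bs[ib]); e <- min(ae[ia], be[ib])
      if (s < e) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
      if (ae[ia] < be[ib]) ia <- ia + 1L else ib <- ib + 1L
    }
    tibble(chrom = ch, start = out_s, end = out_e)
  })
  rows <- bind_rows(rows)
  if (is.null(rows) || nrow(rows) == 0L) return(empty_region_set())
  new_region_set(arrange(rows, .data$chrom, .data$start))
}

#' Uniquely covered reference positions of one haplotype's alignments
#'
#' Retains alignment blocks passing length and mapping-quality thresholds,
#' then returns the reference positions covered by exactly one retained
#' block: positions covered zero times (unaligned) or two or more times
#' (ambiguously aligned) are excluded. This is the per-haplotype
#' "one-to-one alignable" mask of assembly-based benchmark construction.
#'
#' @param blocks A tibble of alignment blocks with columns `haplotype_id`,
#'   `chrom`, `ref_start`, `ref_end` (0-based half-open) and `mapq`
#'   (see [read_paf()]). All rows must share one `haplotype_id`.
#' @param min_len Minimum block length in bases (default 50000, mirroring
#'   common dipcall practice).
#' @param min_mapq Minimum mapping quality (default 5).
#' @return A region set.
#' @export
unique_cover <- function(blocks, min_len = 50000, min_mapq = 5) {
  if (nrow(blocks) > 0 && length(unique(blocks$haplotype_id)) > 1L) {
    abort("unique_cover() expects blocks from a single haplotype")
  }
  keep <- blocks$ref_end - blocks$ref_start >= min_len & blocks$mapq >= min_mapq
  blocks <- blocks[keep, , drop = FALSE]
  if (nrow(blocks) == 0L) return(empty_region_set())
  rows <- lapply(unique(blocks$chrom), function(ch) {
    b <- blocks[blocks$chrom == ch, ]
    cov <- IRanges::coverage(IRanges::IRanges(start = b$ref_start + 1L,
                                              end = b$ref_end))
    ir <- IRanges::ranges(IRanges::slice(cov, lower = 1L, upper = 1L))
    if (length(ir) == 0L) return(NULL)
    tibble(chrom = ch, start = IRanges::start(ir) - 1L,
           end = IRanges::end(ir))
  })
  rows <- bind_rows(rows)
  if (is.null(rows) || nrow(rows) == 0L) return(empty_region_set())
  new_region_set(arrange(rows, .data$chrom, .data$start))
}

#' Derive joint confidence regions from per-haplotype alignment blocks
#'
#' Convenience wrapper: [unique_cover()] per haplotype, then
#' [region_intersect_all()] across haplotypes — reference intervals uniquely
#' aligned by every haplotype assembly.
#'
#' @param blocks A tibble of alignment blocks for all haplotypes.
#' @inheritParams unique_cover
#' @return A region set.
#' @export
derive_confidence_regions <- function(blocks, min_len = 50000, min_mapq = 5) {
  sets <- lapply(split(blocks, blocks$haplotype_id), unique_cover,
                 min_len = min_len, min_mapq = min_mapq)
  region_intersect_all(unname(sets))
}

#' Restrict variant records to confidence regions
#'
#' Keeps a record iff its full REF footprint `[pos-1, pos-1+nchar(ref))`
#' lies within a single interval of `regions`; an insertion (1-base
#' footprint) is inside iff its anchor base is inside. Prevents edge
#' variants from being half-evaluated.
#'
#' @param variants A variant table.
#' @param regions A region set.
#' @return The retained subset of `variants`.
#' @export
filter_by_regions <- function(variants, regions) {
  if (nrow(variants) == 0L || nrow(regions) == 0L) {
    return(variants[integer(0), , drop = FALSE])
  }
  fp <- variant_footprints(variants)
  hit <- suppressWarnings(
    GenomicRanges::countOverlaps(rs_to_gr(fp), rs_to_gr(regions),
                                 type = "within"))
  variants[hit > 0L, , drop = FALSE]
}

#' Read BED3 intervals as a region set
#'
#' Overlapping input intervals are merged on read (union semantics).
#'
#' @param path Path to a BED file (0-based half-open).
#' @return A region set.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                        col_types = "cii", comment = "#", progress = FALSE)
  region_set(df)
}

#' Write a region set as BED3
#' @param regions A region set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  readr::write_tsv(regions[, c("chrom", "start", "end")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read minimap2-style PAF alignment blocks
#'
#' Maps the PAF target columns to reference intervals: column 1 is the query
#' (contig) name, columns 6/8/9 the target name and 0-based half-open target
#' interval, column 12 the mapping quality.
#'
#' @param path Path to a PAF file.
#' @param haplotype_id Label attached to every block (default: the file
#'   name without extension).
#' @return A tibble with columns `haplotype_id`, `chrom`, `ref_start`,
#'   `ref_end`, `query_name`, `mapq`.
#' @export
read_paf <- function(path, haplotype_id = NULL) {
  if (is.null(haplotype_id)) {
    haplotype_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 12L)
  if (length(bad)) {
    abort(paste0("malformed PAF line ", bad[1], " in ", path,
                 ": fewer than 12 columns"))
  }
  tibble(
    haplotype_id = haplotype_id,
    chrom = vapply(fields, `[[`, character(1), 6L),
    ref_start = as.integer(vapply(fields, `[[`, character(1), 8L)),
    ref_end = as.integer(vapply(fields, `[[`, character(1), 9L)),
    query_name = vapply(fields, `[[`, character(1), 1L),
    mapq = as.integer(vapply(fields, `[[`, character(1), 12L)))
}
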
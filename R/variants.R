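# A variant table is a tibble with one row per VCF site:
#   chrom  <chr>  chromosome name
#   pos    <int>  1-based position of the first REF base
#   ref    <chr>  REF allele over {A,C,G,T,N}
#   alts   <list of chr>  ordered ALT alleles
#   gt     <list of int>  unphased allele-index multiset (0 = REF); NA = missing
# plus optional numeric annotation columns (qual, QD, MQM, DP, ...).
# All interval arithmetic inside the package is 0-based half-open; VCF
# coordinates are converted only at the I/O boundary.

#' Construct a variant table
#'
#' Builds the tibble representation of a set of small-variant records used
#' throughout the package.
#'
#' @param chrom Character chromosome names.
#' @param pos Integer 1-based positions of the first REF base.
#' @param ref Character REF alleles.
#' @param alts List of character vectors of ALT alleles (a plain character
#'   vector is taken as one ALT per record).
#' @param gt List of integer allele-index multisets (see [gt_parse()]), or a
#'   character vector of genotype strings.
#' @param ... Further per-record columns (e.g. `qual`, `QD`, `DP`).
#' @return A tibble of class `variant_tbl`, sorted by (chrom, pos).
#' @examples
#' variant_tbl("chr1", 100L, "A", "T", "0/0/0/1")
#' @export
variant_tbl <- function(chrom = character(), pos = integer(),
                        ref = character(), alts = list(), gt = list(), ...) {
  if (is.character(alts)) alts <- as.list(alts)
  if (is.character(gt)) gt <- gt_parse(gt)
  out <- tibble(chrom = as.character(chrom), pos = as.integer(pos),
                ref = as.character(ref), alts = alts, gt = gt, ...)
  validate_variants(out)
  new_variant_tbl(arrange(out, .data$chrom, .data$pos))
}

new_variant_tbl <- function(x) {
  class(x) <- unique(c("variant_tbl", class(x)))
  x
}

validate_variants <- function(x) {
  stopifnot(all(c("chrom", "pos", "ref", "alts", "gt") %in% names(x)))
  if (nrow(x) == 0L) return(invisible(x))
  bad <- which(nchar(x$ref) == 0L |
                 vapply(x$alts, function(a) any(nchar(a) == 0L) || anyDuplicated(a) > 0L,
                        logical(1)) |
                 mapply(function(r, a) any(a == r), x$ref, x$alts))
  if (length(bad)) {
    abort(paste0("invalid alleles at ", site_label(x, bad[1]),
                 ": REF/ALT must be non-empty, distinct, and ALT != REF"))
  }
  n_alt <- lengths(x$alts)
  bad_gt <- which(mapply(function(g, k) {
    !gt_is_missing_one(g) && (any(g < 0L) || any(g > k))
  }, x$gt, n_alt))
  if (length(bad_gt)) {
    abort(paste0("genotype allele index out of range at ",
                 site_label(x, bad_gt[1])))
  }
  invisible(x)
}

site_label <- function(x, i) paste0(x$chrom[i], ":", x$pos[i])

#' 0-based half-open REF footprints of variant records
#'
#' The footprint of a record is the reference interval its REF allele spans:
#' `[pos - 1, pos - 1 + nchar(ref))`. Insertions have a 1-base footprint
#' (their anchor base).
#'
#' @param variants A variant table.
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
variant_footprints <- function(variants) {
  tibble(chrom = variants$chrom,
         start = variants$pos - 1L,
         end = variants$pos - 1L + nchar(variants$ref))
}

#' Classify REF/ALT allele pairs
#'
#' `SNV` iff both alleles are single bases; `MNV` iff equal length > 1;
#' otherwise `INS`/`DEL` with `indel_len = |nchar(ref) - nchar(alt)|`.
#'
#' @param ref,alt Character vectors of alleles (recycled to common length).
#' @return A tibble with columns `kind` (factor SNV/INS/DEL/MNV) and
#'   `indel_len` (integer, 0 for SNV/MNV).
#' @examples
#' classify_variant(c("A", "AT", "A"), c("T", "A", "ATTT"))
#' @export
classify_variant <- function(ref, alt) {
  if (any(nchar(ref) == 0L) || any(nchar(alt) == 0L)) {
    abort("empty allele passed to classify_variant()")
  }
  n <- max(length(ref), length(alt))
  ref <- rep_len(ref, n); alt <- rep_len(alt, n)
  lr <- nchar(ref); la <- nchar(alt)
  kind <- ifelse(lr == la, ifelse(lr == 1L, "SNV", "MNV"),
                 ifelse(la > lr, "INS", "DEL"))
  tibble(kind = factor(kind, levels = c("SNV", "INS", "DEL", "MNV")),
         indel_len = as.integer(abs(lr - la)))
}

# Flat per-ALT kinds for a variant table: list(kind, idx, lr, la) with one
# entry per (record, ALT), idx = record row.
flat_alt_kinds <- function(variants) {
  k <- lengths(variants$alts)
  idx <- rep.int(seq_len(nrow(variants)), k)
  lr <- nchar(variants$ref)[idx]
  la <- nchar(unlist(variants$alts, use.names = FALSE))
  kind <- ifelse(lr == la, ifelse(lr == 1L, "SNV", "MNV"),
                 ifelse(la > lr, "INS", "DEL"))
  list(kind = kind, idx = idx, lr = lr, la = la)
}

# Per-record variant type: the kind if all ALTs agree, else "mixed".
record_variant_type <- function(variants) {
  if (nrow(variants) == 0L) return(character(0))
  f <- flat_alt_kinds(variants)
  vapply(split(f$kind, f$idx),
         function(x) if (length(unique(x)) == 1L) x[1] else "mixed",
         character(1), USE.NAMES = FALSE)
}

# Does a record contain any 1-bp indel allele, used by the per-type QD
# filter (most stringent applicable threshold for multiallelics).
record_has_1bp_indel <- function(variants) {
  if (nrow(variants) == 0L) return(logical(0))
  f <- flat_alt_kinds(variants)
  is1 <- f$kind %in% c("INS", "DEL") & abs(f$lr - f$la) == 1L
  vapply(split(is1, f$idx), any, logical(1), USE.NAMES = FALSE)
}

#' Decompose multi-nucleotide substitutions into SNVs
#'
#' Optionally splits biallelic MNV records (equal-length REF/ALT, length > 1)
#' into one SNV record per differing base, copying genotype and annotations.
#' Records that are not biallelic MNVs pass through unchanged.
#'
#' @param variants A variant table.
#' @return A variant table with MNVs replaced by their component SNVs.
#' @export
decompose_mnv <- function(variants) {
  if (nrow(variants) == 0L) return(variants)
  is_mnv <- lengths(variants$alts) == 1L &
    nchar(variants$ref) > 1L &
    nchar(variants$ref) == vapply(variants$alts, function(a) nchar(a[1]), integer(1))
  if (!any(is_mnv)) return(variants)
  keep <- variants[!is_mnv, ]
  parts <- lapply(which(is_mnv), function(i) {
    r <- strsplit(variants$ref[i], "")[[1]]
    a <- strsplit(variants$alts[[i]][1], "")[[1]]
    d <- which(r != a)
    out <- variants[rep(i, length(d)), ]
    out$pos <- variants$pos[i] + d - 1L
    out$ref <- r[d]
    out$alts <- as.list(a[d])
    out
  })
  res <- arrange(bind_rows(keep, bind_rows(parts)), .data$chrom, .data$pos)
  new_variant_tbl(res)
}
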
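# Allele normalization: minimal representation + left alignment against the
# reference, the standard trim/extend algorithm used by vt normalize and
# bcftools norm. Required so that unions and site matching across callsets
# are well-defined when the same edit is spelled differently.

#' Normalize variant records against a reference
#'
#' Trims shared trailing then leading bases (keeping at least one base per
#' allele, so indels retain their VCF anchor base) and shifts indels to
#' their leftmost equivalent position. SNVs are fixed points. The operation
#' is idempotent, and the normalized record spells the same edited sequence
#' as the input (see [apply_variants()]).
#'
#' @param variants A variant table (see [variant_tbl()]).
#' @param reference Named character vector of chromosome sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @return The normalized variant table, re-sorted by (chrom, pos).
#' @export
normalize_variants <- function(variants, reference) {
  reference <- as_reference(reference)
  if (nrow(variants) == 0L) return(variants)
  check_ref_consistency(variants, reference)
  norm <- lapply(seq_len(nrow(variants)), function(i) {
    normalize_one(variants$pos[i], variants$ref[i], variants$alts[[i]],
                  reference[[variants$chrom[i]]])
  })
  variants$pos <- vapply(norm, `[[`, integer(1), "pos")
  variants$ref <- vapply(norm, `[[`, character(1), "ref")
  variants$alts <- lapply(norm, `[[`, "alts")
  new_variant_tbl(arrange(variants, .data$chrom, .data$pos))
}

as_reference <- function(reference) {
  if (methods::is(reference, "DNAStringSet")) {
    reference <- setNames(as.character(reference), names(reference))
  }
  if (!is.character(reference) || is.null(names(reference))) {
    abort("reference must be a named character vector or DNAStringSet")
  }
  toupper(reference)
}

check_ref_consistency <- function(variants, reference) {
  chrom <- variants$chrom
  absent <- !chrom %in% names(reference)
  if (any(absent)) {
    abort(paste0("chromosome ", chrom[which(absent)[1]],
                 " absent from reference"))
  }
  pos <- variants$pos
  end <- pos + nchar(variants$ref) - 1L
  L <- nchar(reference)[chrom]
  oob <- which(pos < 1L | end > L)
  if (length(oob)) {
    abort(paste0("record at ", site_label(variants, oob[1]),
                 " outside reference bounds"))
  }
  obs <- substr(reference[chrom], pos, end)
  bad <- which(obs != variants$ref)
  if (length(bad)) {
    abort(paste0("REF mismatch at ", site_label(variants, bad[1]),
                 ": VCF has ", variants$ref[bad[1]], ", reference has ",
                 obs[bad[1]]))
  }
}

# Core trim/extend left-alignment for one record (possibly multiallelic).
normalize_one <- function(pos, ref, alts, chrom_seq) {
  alleles <- c(ref, alts)
  repeat {
    last <- substr(alleles, nchar(alleles), nchar(alleles))
    if (all(nchar(alleles) >= 1L) && length(unique(last)) == 1L &&
        nchar(alleles[1]) > 0L) {
      if (any(nchar(alleles) == 1L) && pos == 1L) break
      trimmed <- substr(alleles, 1L, nchar(alleles) - 1L)
      if (any(nchar(trimmed) == 0L)) {
        pos <- pos - 1L
        b <- substr(chrom_seq, pos, pos)
        alleles <- paste0(b, trimmed)
      } else {
        alleles <- trimmed
      }
    } else break
  }
  # trim shared leading bases while every allele keeps >= 2 bases
  repeat {
    first <- substr(alleles, 1L, 1L)
    if (all(nchar(alleles) >= 2L) && length(unique(first)) == 1L) {
      alleles <- substr(alleles, 2L, nchar(alleles))
      pos <- pos + 1L
    } else break
  }
  list(pos = as.integer(pos), ref = alleles[1], alts = alleles[-1])
}

#' Apply variant records to a reference sequence
#'
#' Spells the haplotype obtained by substituting, for each record, the
#' chosen allele for its REF footprint. This is the ground-truth oracle for
#' normalization and harmonization: two representations are equivalent iff
#' they spell the same sequence.
#'
#' @param chrom_seq A single chromosome sequence (character scalar).
#' @param variants A variant table restricted to that chromosome, with
#'   non-overlapping footprints.
#' @param allele Integer vector (recycled): which allele to substitute per
#'   record (0 = REF, 1 = first ALT, ...).
#' @return The edited sequence (character scalar).
#' @export
apply_variants <- function(chrom_seq, variants, allele = 1L) {
  if (nrow(variants) == 0L) return(chrom_seq)
  allele <- vctrs_recycle_int(allele, nrow(variants))
  o <- order(variants$pos)
  variants <- variants[o, ]; allele <- allele[o]
  ends <- variants$pos + nchar(variants$ref) - 1L
  if (any(variants$pos[-1] <= ends[-length(ends)])) {
    abort("apply_variants() requires non-overlapping footprints")
  }
  pieces <- character(0)
  cur <- 1L
  for (i in seq_len(nrow(variants))) {
    pieces <- c(pieces, substr(chrom_seq, cur, variants$pos[i] - 1L))
    al <- allele[i]
    pieces <- c(pieces,
                if (al == 0L) variants$ref[i] else variants$alts[[i]][al])
    cur <- ends[i] + 1L
  }
  pieces <- c(pieces, substr(chrom_seq, cur, nchar(chrom_seq)))
  paste(pieces, collapse = "")
}
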
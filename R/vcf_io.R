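# VCF input goes through vcfR (plain or bgzip); records are mapped onto the
# tidy variant table. Output is formatted directly as VCF 4.2 text so that
# polyploid genotypes and contig headers round-trip losslessly.

#' Read a VCF file into a variant table
#'
#' Parses a single sample's genotypes into unphased allele-index multisets
#' and lifts the requested INFO annotations into numeric columns. Symbolic
#' ALTs (`<DEL>`, breakends, `*` spanning deletions) are skipped with a
#' warning: only small sequence-resolved variants are in scope.
#'
#' @param path Path to a VCF file (plain or bgzip/gzip compressed).
#' @param sample Sample name to read; default the first sample column.
#' @param expected_ploidy If given, an error is raised when any non-missing
#'   genotype has a different ploidy, naming the offending site.
#' @param info_fields INFO keys lifted into numeric columns (missing keys
#'   become `NA`).
#' @return A variant table (see [variant_tbl()]) with columns `qual` and one
#'   per requested INFO field.
#' @export
read_vcf <- function(path, sample = NULL, expected_ploidy = NULL,
                     info_fields = c("QD", "MQM", "DP")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    out <- variant_tbl()
    out$qual <- numeric(0)
    for (f in info_fields) out[[f]] <- numeric(0)
    return(out)
  }
  gt_str <- rep("./.", nrow(fix))
  if (ncol(v@gt) >= 2L) {
    samples <- colnames(v@gt)[-1]
    if (is.null(sample)) sample <- samples[1]
    if (!sample %in% samples) {
      abort(paste0("sample ", sample, " not present in ", path))
    }
    fmt <- strsplit(v@gt[, "FORMAT"], ":", fixed = TRUE)
    val <- strsplit(v@gt[, sample], ":", fixed = TRUE)
    gt_str <- mapply(function(f, x) {
      i <- match("GT", f)
      if (is.na(i) || i > length(x)) "./." else x[i]
    }, fmt, val, USE.NAMES = FALSE)
  }
  alts <- strsplit(ifelse(is.na(fix$ALT), "", fix$ALT), ",", fixed = TRUE)
  # sequence-resolved small variants only: any ALT outside {A,C,G,T,N}
  # (symbolic <DEL>, breakends, spanning '*', missing '.') is skipped
  symbolic <- vapply(alts, function(a) {
    length(a) == 0L || any(grepl("[^ACGTNacgtn]", a))
  }, logical(1))
  if (any(symbolic)) {
    warn(paste0("skipping ", sum(symbolic),
                " record(s) with symbolic/breakend/spanning ALT alleles"))
  }
  keep <- !symbolic
  out <- tibble(
    chrom = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    ref = toupper(fix$REF[keep]),
    alts = lapply(alts[keep], toupper),
    gt = gt_parse(gt_str[keep]),
    qual = suppressWarnings(as.numeric(fix$QUAL[keep])))
  info <- fix$INFO[keep]
  for (f in info_fields) {
    out[[f]] <- suppressWarnings(as.numeric(
      stringr::str_match(info, paste0("(?:^|;)", f, "=([^;]+)"))[, 2]))
  }
  if (!is.null(expected_ploidy)) {
    pl <- gt_ploidy(out$gt)
    bad <- which(!is.na(pl) & pl != expected_ploidy)
    if (length(bad)) {
      abort(paste0("ploidy ", pl[bad[1]], " != expected ", expected_ploidy,
                   " at ", site_label(out, bad[1])))
    }
  }
  validate_variants(out)
  new_variant_tbl(arrange(out, .data$chrom, .data$pos))
}

#' Write a variant table as single-sample VCF 4.2
#'
#' @param variants A variant table, coordinate-sorted.
#' @param path Output path; a `.gz` suffix writes gzip-compressed text.
#' @param contigs Named integer vector of contig lengths for the header
#'   (optional but recommended; required by many downstream tools).
#' @param sample_name Sample column name.
#' @param info_fields Numeric columns of `variants` emitted as INFO
#'   `key=value` entries when non-missing.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, contigs = NULL, sample_name = "SAMPLE",
                      info_fields = intersect(c("QD", "MQM", "DP"),
                                              names(variants))) {
  if (nrow(variants) > 1L) {
    o <- order(variants$chrom, variants$pos)
    if (!identical(o, seq_len(nrow(variants)))) {
      abort("write_vcf() requires records sorted by (chrom, pos)")
    }
  }
  hdr <- c("##fileformat=VCFv4.2",
           "##source=polybench",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                   as.integer(contigs)),
           sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                   info_fields, info_fields),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sample_name), collapse = "\t"))
  body <- character(0)
  if (nrow(variants) > 0L) {
    qual <- if ("qual" %in% names(variants)) variants$qual else NA_real_
    qual <- ifelse(is.na(qual), ".", format(qual, trim = TRUE, digits = 6))
    info <- rep(".", nrow(variants))
    if (length(info_fields)) {
      mat <- vapply(info_fields, function(f) {
        v <- variants[[f]]
        ifelse(is.na(v), NA_character_,
               paste0(f, "=", format(v, trim = TRUE, digits = 6)))
      }, character(nrow(variants)))
      mat <- matrix(mat, nrow = nrow(variants))
      info_str <- apply(mat, 1, function(r) paste(r[!is.na(r)], collapse = ";"))
      info <- ifelse(nzchar(info_str), info_str, ".")
    }
    body <- paste(variants$chrom, variants$pos, ".", variants$ref,
                  vapply(variants$alts, paste, character(1), collapse = ","),
                  qual, ".", info, "GT", gt_format(variants$gt),
                  sep = "\t")
  }
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#' @param path Path to a FASTA file.
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), sub("\\s.*$", "", names(x)))
}

#' Write named sequences as FASTA
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path, width = 70L)
  invisible(path)
}
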
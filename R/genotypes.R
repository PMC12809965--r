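# Genotypes are unphased multisets of allele indices (0 = REF), stored as
# sorted integer vectors of length = ploidy in a list-column. A missing
# genotype is NA_integer_. Phase separators ('|') are accepted on input and
# discarded: the package evaluates allelic dosage, not phase.

#' Parse genotype strings into allele-index multisets
#'
#' Converts VCF-style genotype strings (`"0/0/0/1"`, `"0|1"`, `"./."`) into
#' sorted integer vectors of allele indices (0 = REF, 1 = first ALT, ...).
#' Any fully or partially missing genotype becomes `NA_integer_`.
#'
#' @param x Character vector of genotype strings.
#' @return A list of sorted integer vectors (one per input string); missing
#'   genotypes are `NA_integer_`.
#' @examples
#' gt_parse(c("0/0/0/1", "0|1", "./."))
#' @export
gt_parse <- function(x) {
  lapply(strsplit(x, "[/|]"), function(a) {
    ai <- suppressWarnings(as.integer(a))
    if (length(ai) == 0L || anyNA(ai)) NA_integer_ else sort(ai)
  })
}

#' Format allele-index multisets as genotype strings
#'
#' Canonical text form: indices ascending, `/`-separated (unphased).
#'
#' @param gt A list of integer vectors as produced by [gt_parse()].
#' @return Character vector; missing genotypes become `"."`.
#' @export
gt_format <- function(gt) {
  vapply(gt, function(a) {
    if (gt_is_missing_one(a)) "." else paste(sort(a), collapse = "/")
  }, character(1))
}

gt_is_missing_one <- function(a) length(a) == 0L || anyNA(a)

#' Test genotypes for missingness
#' @param gt A list of integer allele-index vectors.
#' @return Logical vector.
#' @export
gt_is_missing <- function(gt) vapply(gt, gt_is_missing_one, logical(1))

#' Allelic dosage of a given allele index
#'
#' Dosage is the number of copies of allele `allele` in the genotype
#' multiset (e.g. 1 of 4 for `0/0/0/1` with `allele = 1`).
#'
#' @param gt A list of integer allele-index vectors.
#' @param allele Integer allele index (0 = REF), recycled along `gt`.
#' @return Integer vector of dosages; `NA` for missing genotypes.
#' @export
gt_dosage <- function(gt, allele) {
  allele <- vctrs_recycle_int(allele, length(gt))
  mapply(function(a, al) {
    if (gt_is_missing_one(a)) NA_integer_ else sum(a == al)
  }, gt, allele, USE.NAMES = FALSE)
}

vctrs_recycle_int <- function(x, n) {
  if (length(x) == 1L) rep.int(as.integer(x), n) else as.integer(x)
}

#' Ploidy of genotypes
#' @param gt A list of integer allele-index vectors.
#' @return Integer vector of multiset sizes (`NA` for missing genotypes).
#' @export
gt_ploidy <- function(gt) {
  vapply(gt, function(a) if (gt_is_missing_one(a)) NA_integer_ else length(a),
         integer(1))
}

#' Genotype class labels
#'
#' Ordered label set used for dosage-class stratification.
#' `simplex` is a genotype with exactly one non-reference allele copy
#' (AAAa at 4x, AAAAAa at 6x); `duplex` .. `sextuplex` carry a single ALT
#' allele at dosage 2..6; `multi_allelic` carries two or more distinct ALT
#' alleles.
#'
#' @return Character vector of levels.
#' @export
genotype_class_levels <- function() {
  c("hom_ref", "simplex", "duplex", "triplex", "quadruplex", "quintuplex",
    "sextuplex", "multi_allelic", "missing")
}

#' Classify genotypes by allelic dosage
#'
#' @param gt A list of integer allele-index vectors (see [gt_parse()]).
#' @return Factor with levels [genotype_class_levels()].
#' @examples
#' classify_genotype(gt_parse(c("0/0/0/1", "0/0/1/1", "0/1/1/2", "./.")))
#' @export
classify_genotype <- function(gt) {
  lab <- vapply(gt, function(a) {
    if (gt_is_missing_one(a)) return("missing")
    alt <- a[a > 0L]
    if (length(alt) == 0L) return("hom_ref")
    if (length(unique(alt)) > 1L) return("multi_allelic")
    d <- length(alt)
    if (d > 6L) abort("single-ALT dosage > 6: ploidies above 6 are unsupported")
    c("simplex", "duplex", "triplex", "quadruplex", "quintuplex",
      "sextuplex")[d]
  }, character(1))
  factor(lab, levels = genotype_class_levels())
}
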
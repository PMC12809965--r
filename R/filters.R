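# Post-call hard filtering: community-style per-type QD thresholds, a
# configurable threshold policy for FreeBayes-style annotations, and the
# reliable-region read-retention rule. Fraction comparisons at the read
# filter boundary use integer cross-multiplication so the strict "more
# than 50%" rule is exact.

#' Per-type quality-by-depth (QD) hard filter
#'
#' Keeps or drops records using the per-type QD thresholds: SNVs, MNVs and
#' indels longer than 1 bp are dropped iff `QD < 2`; 1-bp indels are
#' dropped iff `QD < 5` (strict inequalities). Multiallelic records use the
#' most stringent threshold applicable to any of their alleles. Records
#' without a QD annotation are kept with a warning (QD is emitted only for
#' variant sites; penalizing absence would silently drop valid records)
#' unless `missing_fails = TRUE`.
#'
#' @param variants A variant table with a numeric `QD` column.
#' @param missing_fails Drop records lacking QD instead of keeping them.
#' @return Logical vector: `TRUE` = keep.
#' @examples
#' v <- variant_tbl("chr1", c(100L, 200L), c("A", "AT"), c("T", "A"),
#'                  c("0/1", "0/1"), QD = c(1.9, 4.9))
#' qd_filter(v)
#' @export
qd_filter <- function(variants, missing_fails = FALSE) {
  if (nrow(variants) == 0L) return(logical(0))
  qd <- if ("QD" %in% names(variants)) variants$QD else
    rep(NA_real_, nrow(variants))
  thr <- ifelse(record_has_1bp_indel(variants), 5, 2)
  keep <- qd >= thr  # drop iff QD < threshold, strict
  if (anyNA(keep)) {
    if (missing_fails) {
      keep[is.na(keep)] <- FALSE
    } else {
      warn(paste0(sum(is.na(keep)), " record(s) lack QD; kept"))
      keep[is.na(keep)] <- TRUE
    }
  }
  keep
}

#' Threshold policies for FreeBayes-style post hoc filtering
#'
#' A filter policy is an ordered set of minimum-threshold rules over record
#' annotations (`QUAL`, `MQM`, `DP`, ...). The shipped `minimal` and
#' `strict` presets are reconstructions of common FreeBayes post hoc
#' practice (the thresholds are deliberately editable: see the YAML at
#' `system.file("extdata", "freebayes_filters.yaml", package = "polybench")`).
#'
#' @param preset `"minimal"` or `"strict"`, or `NULL` when `rules` given.
#' @param rules Named numeric vector of minimum thresholds, e.g.
#'   `c(QUAL = 20, MQM = 40)`; overrides the preset.
#' @param missing `"keep"` (fail-open) or `"drop"` (fail-closed) for records
#'   lacking a referenced annotation.
#' @param config Optional path to a YAML file defining presets (defaults to
#'   the shipped file).
#' @return A `filter_policy` object.
#' @export
filter_policy <- function(preset = c("minimal", "strict"), rules = NULL,
                          missing = c("keep", "drop"), config = NULL) {
  missing <- match.arg(missing)
  if (is.null(rules)) {
    preset <- match.arg(preset)
    if (is.null(config)) {
      config <- system.file("extdata", "freebayes_filters.yaml",
                            package = "polybench")
    }
    cfg <- yaml::read_yaml(config)
    if (!preset %in% names(cfg)) {
      abort(paste0("preset ", preset, " not found in ", config))
    }
    rules <- unlist(cfg[[preset]])
    name <- preset
  } else {
    rules <- unlist(rules)
    name <- "custom"
  }
  if (is.null(names(rules)) || any(!nzchar(names(rules)))) {
    abort("filter_policy rules must be a named numeric vector")
  }
  structure(list(name = name, rules = rules, missing = missing),
            class = "filter_policy")
}

#' @export
print.filter_policy <- function(x, ...) {
  cat("<filter_policy>", x$name, "| missing =", x$missing, "\n")
  for (n in names(x$rules)) cat("  ", n, ">=", x$rules[[n]], "\n")
  invisible(x)
}

#' Apply a threshold policy to variant records
#'
#' A record is kept iff every rule passes (`annotation >= threshold`).
#' Missing annotations follow the policy's missing-value rule.
#'
#' @param variants A variant table with annotation columns.
#' @param policy A [filter_policy()].
#' @return Logical vector: `TRUE` = keep.
#' @export
freebayes_filter <- function(variants, policy) {
  stopifnot(inherits(policy, "filter_policy"))
  if (nrow(variants) == 0L) return(logical(0))
  keep <- rep(TRUE, nrow(variants))
  for (ann in names(policy$rules)) {
    col <- if (ann == "QUAL") "qual" else ann
    v <- if (col %in% names(variants)) variants[[col]] else
      rep(NA_real_, nrow(variants))
    pass <- v >= policy$rules[[ann]]
    pass[is.na(pass)] <- policy$missing == "keep"
    keep <- keep & pass
  }
  keep
}

#' Filter a variant table, keeping a drop log
#'
#' Order-preserving and idempotent. The drop log records each removed
#' site, the rule that fired and the annotation value.
#'
#' @param variants A variant table.
#' @param policy A [filter_policy()], or the string `"gatk-qd"` for the
#'   per-type QD hard filter.
#' @param ... Passed to [qd_filter()] when `policy = "gatk-qd"`.
#' @return A list with `kept` (variant table) and `dropped` (tibble:
#'   `chrom`, `pos`, `rule`, `value`).
#' @export
filter_variants <- function(variants, policy, ...) {
  if (identical(policy, "gatk-qd")) {
    keep <- qd_filter(variants, ...)
    rule <- ifelse(record_has_1bp_indel(variants), "QD<5", "QD<2")
    value <- if ("QD" %in% names(variants)) variants$QD else NA_real_
  } else {
    keep <- freebayes_filter(variants, policy)
    rule <- rep(paste0(policy$name, " policy"), nrow(variants))
    value <- NA_real_
  }
  dropped <- tibble(chrom = variants$chrom[!keep], pos = variants$pos[!keep],
                    rule = rule[!keep],
                    value = rep_len(value, nrow(variants))[!keep])
  list(kept = variants[keep, , drop = FALSE], dropped = dropped)
}

#' Reliable-region read-retention filter
#'
#' A read is retained iff strictly more than `min_frac` of its bases derive
#' from reliable regions: `sum(overlap of aligned reference blocks with
#' reliable) / read_length > min_frac`. The comparison is done by integer
#' cross-multiplication, so a read with exactly 50 of 100 bases inside is
#' dropped at `min_frac = 0.5`. Bases counted are reference-projected
#' aligned blocks only: read insertions and clipped bases contribute to
#' `read_length` but never to the overlap.
#'
#' @param placements A tibble with columns `read_id`, `chrom`, `start`,
#'   `end` (0-based half-open aligned blocks; several rows per read allowed)
#'   and `read_length`.
#' @param reliable A region set of reliable intervals. A read on a
#'   chromosome absent from `reliable` has overlap 0.
#' @param min_frac Retention threshold (default 0.5, i.e. "more than 50%").
#' @return A tibble with one row per read: `read_id`, `read_length`,
#'   `overlap`, `keep`.
#' @export
reliable_read_filter <- function(placements, reliable, min_frac = 0.5) {
  if (any(placements$read_length <= 0)) {
    abort("read_length must be positive")
  }
  if (nrow(placements) == 0L) {
    return(tibble(read_id = character(), read_length = integer(),
                  overlap = integer(), keep = logical()))
  }
  gr <- rs_to_gr(tibble(chrom = placements$chrom, start = placements$start,
                        end = placements$end))
  shared <- intersect(unique(placements$chrom), unique(reliable$chrom))
  ov <- rep(0L, nrow(placements))
  if (length(shared)) {
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(gr, rs_to_gr(reliable)))
    if (length(hits)) {
      qi <- S4Vectors::queryHits(hits)
      w <- GenomicRanges::width(GenomicRanges::pintersect(
        gr[qi], rs_to_gr(reliable)[S4Vectors::subjectHits(hits)]))
      agg <- rowsum(w, qi)
      ov[as.integer(rownames(agg))] <- as.integer(agg[, 1])
    }
  }
  per_read <- tibble(read_id = placements$read_id,
                     read_length = as.integer(placements$read_length),
                     overlap = ov) %>%
    group_by(.data$read_id) %>%
    summarise(read_length = .data$read_length[1],
              overlap = sum(.data$overlap), .groups = "drop")
  # exact rational comparison: overlap / len > num / den
  frac <- rational_frac(min_frac)
  per_read$keep <- per_read$overlap * frac$den >
    frac$num * per_read$read_length
  per_read
}

# smallest power-of-ten rational representation of a threshold like 0.5
rational_frac <- function(x) {
  for (k in 0:9) {
    num <- x * 10^k
    if (abs(num - round(num)) < 1e-9) {
      return(list(num = round(num), den = 10^k))
    }
  }
  list(num = x * 1e9, den = 1e9)
}
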
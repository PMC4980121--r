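# Shared domain types. DNM records, trio metadata and CNV events are plain
# data.frames with validated columns; interval sets are GRanges. Coordinates:
# VCF/record positions are 1-based, interval sets are BED-style 0-based
# half-open, and conversion happens only at I/O boundaries.

#' Predictor score column names carried by DNM records
#'
#' Numeric score columns are optional per record (NA = score absent; tier
#' rules treat an absent score as "criterion not met"). Logical columns are
#' annotation flags set by the upstream annotator.
#'
#' @return Character vector of column names.
#' @export
score_columns <- function() {
  c("sift", "polyphen2", "mut_assessor", "mut_taster", "cadd_phred",
    "phylop_mam", "phylop_vert100", "phastcons", "dpsi",
    "deepbind_wt_pct", "deepbind_var_pct",
    "is_lof", "is_missense", "is_synonymous", "dhs_overlap", "tx_proximal")
}

.score_numeric <- function() score_columns()[1:11]
.score_logical <- function() score_columns()[12:16]

.region_classes <- c("coding_exonic", "splice_core", "splicing_site",
                     "utr5", "utr3", "intronic", "lncRNA", "nongenic")

#' Construct a validated table of de novo mutation records
#'
#' One row per de novo variant call in one proband. `var_type` is derived
#' from the alleles (SNV iff both alleles are single bases), and all
#' invariants of the record model are enforced: positive 1-based positions,
#' `ref != alt`, `ad_alt >= 1`, mutually exclusive coding-impact flags, and
#' score ranges (SIFT/PolyPhen2/phastCons in [0,1], DeepBind percentiles in
#' [0,100]).
#'
#' @param df data.frame with at least sample_id, cohort ("case"/"control"),
#'   chrom, pos, ref, alt, ad_ref, ad_alt, origin
#'   ("paternal"/"maternal"/"unknown"), region_class. Optional: gene and any
#'   of [score_columns()]; missing ones are filled with NA / FALSE.
#' @return data.frame of class `dnm_records`, ordered by (chrom, pos,
#'   sample_id).
#' @export
dnm_records <- function(df) {
  req <- c("sample_id", "cohort", "chrom", "pos", "ref", "alt",
           "ad_ref", "ad_alt", "origin", "region_class")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$pos <- as.integer(df$pos)
  df$ad_ref <- as.integer(df$ad_ref)
  df$ad_alt <- as.integer(df$ad_alt)
  if (!"gene" %in% names(df)) df$gene <- NA_character_
  for (sc in .score_numeric()) if (!sc %in% names(df)) df[[sc]] <- NA_real_
  for (sc in .score_logical()) if (!sc %in% names(df)) df[[sc]] <- FALSE
  df$var_type <- ifelse(nchar(df$ref) == 1L & nchar(df$alt) == 1L, "SNV", "indel")
  validate_dnm_records(df)
  df <- df[order(df$chrom, df$pos, df$sample_id), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("dnm_records", "data.frame")
  df
}

#' @rdname dnm_records
#' @export
validate_dnm_records <- function(df) {
  if (nrow(df) == 0L) return(invisible(df))
  if (any(df$pos < 1L)) stop("pos must be >= 1")
  if (any(df$ref == df$alt)) stop("ref and alt must differ")
  if (any(df$ad_ref < 0L) || any(df$ad_alt < 1L)) {
    stop("allele depths must satisfy ad_ref >= 0, ad_alt >= 1")
  }
  if (!all(df$cohort %in% c("case", "control"))) stop("cohort must be case/control")
  if (!all(df$origin %in% c("paternal", "maternal", "unknown"))) {
    stop("origin must be paternal/maternal/unknown")
  }
  if (!all(df$region_class %in% .region_classes)) {
    stop("unknown region_class: ",
         paste(unique(setdiff(df$region_class, .region_classes)), collapse = ", "))
  }
  excl <- df$is_lof + df$is_missense + df$is_synonymous
  if (any(excl > 1L, na.rm = TRUE)) {
    stop("is_lof, is_missense, is_synonymous are mutually exclusive")
  }
  for (sc in c("sift", "polyphen2", "phastcons")) {
    v <- df[[sc]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) stop(sc, " must lie in [0, 1]")
  }
  for (sc in c("deepbind_wt_pct", "deepbind_var_pct")) {
    v <- df[[sc]]
    if (any(v < 0 | v > 100, na.rm = TRUE)) stop(sc, " must lie in [0, 100]")
  }
  invisible(df)
}

#' Allelic fraction of each record
#'
#' Alternate reads over total reads at the site; in (0, 1] by the record
#' invariants.
#'
#' @param records A [dnm_records] table.
#' @return Numeric vector.
#' @export
allelic_fraction <- function(records) {
  records$ad_alt / (records$ad_ref + records$ad_alt)
}

#' Construct trio metadata
#'
#' Samples whose DNA source is not whole blood (cell-line or leucocyte
#' derived) are force-flagged `excluded`: their DNM calls carry cell-line
#' artefacts and are dropped from cohort denominators.
#'
#' @param df data.frame with sample_id, paternal_age, maternal_age, sex,
#'   dna_source ("whole_blood"/"LCL"/"leucocyte"); optional cohort.
#' @return Validated data.frame with an `excluded` column.
#' @export
trio_meta <- function(df) {
  req <- c("sample_id", "paternal_age", "maternal_age", "sex", "dna_source")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (any(df$paternal_age <= 0 | df$maternal_age <= 0)) stop("ages must be > 0")
  if (!all(df$dna_source %in% c("whole_blood", "LCL", "leucocyte"))) {
    stop("dna_source must be whole_blood/LCL/leucocyte")
  }
  df$excluded <- df$dna_source != "whole_blood"
  df
}

#' Construct a table of de novo CNV events
#'
#' Intervals are 0-based half-open. De novo CNVs are unbalanced changes
#' larger than 10 kb, enforced as an invariant.
#'
#' @param df data.frame with sample_id, chrom, start, end, cnv_type
#'   ("gain"/"loss"), origin.
#' @return Validated data.frame.
#' @export
cnv_events <- function(df) {
  req <- c("sample_id", "chrom", "start", "end", "cnv_type", "origin")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$end <= df$start)) stop("CNV end must exceed start")
  if (any(df$end - df$start <= 10000L)) {
    stop("de novo CNVs must span more than 10 kb")
  }
  if (!all(df$cnv_type %in% c("gain", "loss"))) stop("cnv_type must be gain/loss")
  if (!all(df$origin %in% c("paternal", "maternal", "unknown"))) {
    stop("origin must be paternal/maternal/unknown")
  }
  df
}

#' Build a labelled genomic interval set
#'
#' Intervals are supplied in 0-based half-open coordinates (BED convention)
#' and stored as a sorted `GRanges` (1-based closed internally; converted
#' once, here). Overlapping intervals are preserved; use
#' [interval_union_length()] for union arithmetic.
#'
#' @param chrom,start,end Parallel vectors (start/end 0-based half-open).
#' @param label Single string naming the set (e.g. "DHS").
#' @return A `GRanges` with metadata column `label`.
#' @export
interval_set <- function(chrom, start, end, label = "intervals") {
  if (any(end <= start)) stop("intervals must have end > start")
  lev <- sort(unique(as.character(chrom)))
  gr <- GenomicRanges::GRanges(factor(chrom, levels = lev),
                               IRanges::IRanges(start + 1L, end))
  gr <- GenomicRanges::sort(gr)
  S4Vectors::metadata(gr)$label <- label
  gr
}

#' Total length of the union of an interval set
#'
#' @param gr A `GRanges`.
#' @return Integer number of bases covered by at least one interval.
#' @export
interval_union_length <- function(gr) {
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(gr))))
}
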
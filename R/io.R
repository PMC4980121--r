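# Readers and writers for the standard formats the pipeline touches:
# VCF 4.x (AD genotype field) for DNM calls, BED3/4 for interval tracks,
# indexed FASTA via Biostrings, and TSV sidecars for predictor scores.

#' Read de novo mutation calls from a VCF
#'
#' Produces one record per ALT allele per carrier sample. Multi-allelic rows
#' are decomposed. Carriers are the samples with a non-missing genotype;
#' allele depths come from the AD genotype field. Parent-of-origin
#' (`ORIGIN`), region class (`REGION`) and gene (`GENE`) are read from INFO
#' when present. Records lacking sidecar scores get all-absent scores.
#'
#' @param path VCF file (plain text or gzipped).
#' @param cohort_label "case" or "control", applied to every record.
#' @param sidecar_scores_path Optional TSV of predictor scores keyed by
#'   (sample_id, chrom, pos, ref, alt); duplicate keys are an error.
#' @return A [dnm_records] table ordered by (chrom, pos, sample_id).
#' @export
read_dnm_vcf <- function(path, cohort_label, sidecar_scores_path = NULL) {
  stopifnot(cohort_label %in% c("case", "control"))
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (length(body) && any(nf < 8L)) {
    stop("malformed VCF at line ", body[which(nf < 8L)[1]],
         ": fewer than 8 tab-separated fields")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- v@gt
  samples <- colnames(gt)[-1]
  info_tag <- function(info, tag) {
    has <- grepl(paste0("(^|;)", tag, "="), info)
    out <- rep(NA_character_, length(info))
    out[has] <- sub(paste0(".*(^|;)", tag, "=([^;]*).*"), "\\2", info[has])
    out
  }
  origin <- info_tag(fix$INFO, "ORIGIN")
  region <- info_tag(fix$INFO, "REGION")
  gene <- info_tag(fix$INFO, "GENE")
  recs <- list()
  for (i in seq_len(nrow(fix))) {
    fmt <- strsplit(gt[i, 1], ":", fixed = TRUE)[[1]]
    ad_idx <- match("AD", fmt)
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (s in samples) {
      cell <- gt[i, s]
      if (is.na(cell) || startsWith(cell, "./.") || cell == ".") next
      parts <- strsplit(cell, ":", fixed = TRUE)[[1]]
      if (is.na(ad_idx) || length(parts) < ad_idx) {
        stop("VCF record ", fix$CHROM[i], ":", fix$POS[i],
             " lacks an AD genotype field for sample ", s)
      }
      ad <- as.integer(strsplit(parts[ad_idx], ",", fixed = TRUE)[[1]])
      for (k in seq_along(alts)) {
        recs[[length(recs) + 1L]] <- data.frame(
          sample_id = s, cohort = cohort_label,
          chrom = fix$CHROM[i], pos = as.integer(fix$POS[i]),
          ref = fix$REF[i], alt = alts[k],
          ad_ref = ad[1], ad_alt = ad[k + 1L],
          origin = if (is.na(origin[i])) "unknown" else origin[i],
          region_class = if (is.na(region[i])) "nongenic" else region[i],
          gene = gene[i],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  df <- if (length(recs)) do.call(rbind, recs) else {
    data.frame(sample_id = character(), cohort = character(), chrom = character(),
               pos = integer(), ref = character(), alt = character(),
               ad_ref = integer(), ad_alt = integer(), origin = character(),
               region_class = character(), gene = character(),
               stringsAsFactors = FALSE)
  }
  if (!is.null(sidecar_scores_path)) {
    df <- attach_scores(df, read_scores_tsv(sidecar_scores_path))
  }
  dnm_records(df)
}

#' Write de novo mutation records as a multi-sample VCF
#'
#' Inverse of [read_dnm_vcf] for all fields the data model stores except
#' predictor scores (use [write_scores_tsv] for the sidecar). Each record
#' becomes one row; the carrier sample gets `GT:AD`, all others `./.`.
#'
#' @param records A [dnm_records] table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dnm_vcf <- function(records, path) {
  samples <- sort(unique(records$sample_id))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=ORIGIN,Number=1,Type=String,Description=\"Parent of origin\">",
    "##INFO=<ID=REGION,Number=1,Type=String,Description=\"Region class\">",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  ord <- order(records$chrom, records$pos, records$sample_id)
  records <- records[ord, , drop = FALSE]
  info <- paste0("ORIGIN=", records$origin, ";REGION=", records$region_class,
                 ifelse(is.na(records$gene), "", paste0(";GENE=", records$gene)))
  gtcell <- paste0("0/1:", records$ad_ref, ",", records$ad_alt)
  body <- vapply(seq_len(nrow(records)), function(i) {
    cells <- rep("./.", length(samples))
    cells[match(records$sample_id[i], samples)] <- gtcell[i]
    paste(c(records$chrom[i], records$pos[i], ".", records$ref[i],
            records$alt[i], ".", "PASS", info[i], "GT:AD", cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write the predictor-score sidecar TSV
#'
#' The sidecar is keyed by (sample_id, chrom, pos, ref, alt) and carries the
#' columns of [score_columns()]. A duplicated key is an error.
#'
#' @param path TSV with a header row.
#' @return data.frame of scores.
#' @export
read_scores_tsv <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  key <- paste(df$sample_id, df$chrom, df$pos, df$ref, df$alt, sep = "\r")
  if (anyDuplicated(key)) {
    stop("sidecar key collision: duplicated (sample, chrom, pos, ref, alt)")
  }
  df
}

#' @rdname read_scores_tsv
#' @param records A [dnm_records] table.
#' @export
write_scores_tsv <- function(records, path) {
  cols <- c("sample_id", "chrom", "pos", "ref", "alt", score_columns())
  write.table(records[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

# Left-join sidecar scores onto bare records by the 5-part key.
attach_scores <- function(df, scores) {
  key <- function(d) paste(d$sample_id, d$chrom, d$pos, d$ref, d$alt, sep = "\r")
  idx <- match(key(df), key(scores))
  for (sc in intersect(score_columns(), names(scores))) {
    v <- scores[[sc]][idx]
    if (sc %in% .score_logical()) {
      v <- as.logical(v)
      v[is.na(v)] <- FALSE
    } else {
      v <- as.numeric(v)   # all-NA columns read as logical otherwise
    }
    df[[sc]] <- v
  }
  df
}

#' Read a BED3/BED4 file into an interval set
#'
#' BED coordinates are 0-based half-open; the conversion to the internal
#' 1-based `GRanges` representation happens here and only here.
#'
#' @param path BED file (whitespace-separated, >= 3 columns).
#' @param label Label attached to the set.
#' @return A sorted `GRanges` (overlaps preserved).
#' @export
read_bed <- function(path, label = basename(path)) {
  df <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("BED file needs at least 3 columns")
  bad <- which(df[[3]] <= df[[2]])
  if (length(bad)) stop("BED interval with start >= end at line ", bad[1])
  interval_set(df[[1]], df[[2]], df[[3]], label = label)
}

#' Write an interval set as BED3 (plus name column if present)
#'
#' @param gr A `GRanges`.
#' @param path Output file.
#' @export
write_bed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  if (!is.null(gr$name)) df$name <- gr$name
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Fetch the reference context around a position
#'
#' Returns the uppercase sequence of length `2*flank + 1` centered on `pos`
#' (1-based). Near contig ends the window is truncated and the result
#' carries attribute `truncated = TRUE`.
#'
#' @param reference A `DNAStringSet` (e.g. from `Biostrings::readDNAStringSet`
#'   or [simulate_reference]).
#' @param chrom Contig name.
#' @param pos 1-based position within the contig.
#' @param flank Flank size in bp (>= 1).
#' @return Character scalar with attribute `truncated`.
#' @export
fetch_context <- function(reference, chrom, pos, flank) {
  stopifnot(flank >= 1)
  i <- match(chrom, names(reference))
  if (is.na(i)) stop("unknown chrom: ", chrom)
  len <- Biostrings::width(reference)[i]
  if (pos < 1 || pos > len) stop("pos outside contig ", chrom)
  lo <- max(1L, pos - flank)
  hi <- min(len, pos + flank)
  s <- toupper(as.character(Biostrings::subseq(reference[[i]], lo, hi)))
  attr(s, "truncated") <- (lo > pos - flank) || (hi < pos + flank)
  s
}

#' Read a GMT gene-set file
#'
#' @param path GMT file: one set per line, tab-separated
#'   `name<TAB>description<TAB>gene1<TAB>gene2...`.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  stats::setNames(lapply(lines, function(x) unique(x[-(1:2)])),
                  vapply(lines, `[`, character(1), 1))
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output file.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}
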
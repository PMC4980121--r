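# Cohort summary: the descriptive arithmetic reported for a trio DNM study.
# Rates are per retained genome (excluded samples out of the denominators),
# percentages to one decimal (half-up), rates to two decimals.

#' Summarise a characterized trio cohort
#'
#' Pure arithmetic over the upstream outputs: per-genome germline SNV,
#' indel and CNV rates, the somatic count and rate, paternal/maternal
#' fractions of phased germline SNVs, the clustered-DNM count with its
#' sub-200 bp fraction, and the damaging (tier-1) breakdown by category.
#' Samples flagged `excluded` in the trio metadata are removed from all
#' denominators and their records ignored.
#'
#' @param records A [dnm_records] table.
#' @param cnvs A [cnv_events] table (possibly empty).
#' @param trios A [trio_meta] table.
#' @param somatic_labels Per-record labels from [classify_somatic].
#' @param clusters Output of [find_clusters] on the same `records` table
#'   (somatic-candidate members are excluded from the clustered counts).
#' @param tier_summary Summary table from [classify_cohort] (optional).
#' @param cohort Which cohort the per-genome rates describe (default
#'   "case").
#' @return List of class `cohort_summary`.
#' @export
summarize_cohort <- function(records, cnvs, trios, somatic_labels,
                             clusters, tier_summary = NULL,
                             cohort = "case") {
  retained <- trios[!trios$excluded, , drop = FALSE]
  if ("cohort" %in% names(retained)) {
    retained <- retained[retained$cohort == cohort, , drop = FALSE]
  }
  n_ret <- nrow(retained)
  if (n_ret == 0) stop("no retained trios")
  keep <- records$sample_id %in% retained$sample_id
  rec <- records[keep, , drop = FALSE]
  som <- somatic_labels[keep] == "somatic_candidate"
  germ <- rec[!som, , drop = FALSE]
  phased <- germ$origin %in% c("paternal", "maternal") & germ$var_type == "SNV"
  cl_rows <- clusters$members$row
  cl_ok <- keep[cl_rows] & somatic_labels[cl_rows] != "somatic_candidate"
  cl_keep <- cl_rows[cl_ok]
  nn <- cluster_member_distances(records, clusters)
  nn <- nn[cl_ok]
  out <- list(
    n_retained_trios = n_ret,
    germline_snv_per_genome = round_half_up(sum(germ$var_type == "SNV") / n_ret, 2),
    germline_indel_per_genome = round_half_up(sum(germ$var_type == "indel") / n_ret, 2),
    cnv_per_genome = round_half_up(
      sum(cnvs$sample_id %in% retained$sample_id) / n_ret, 3),
    somatic_count = sum(som),
    somatic_per_genome = round_half_up(sum(som) / n_ret, 2),
    paternal_fraction = round_half_up(
      100 * sum(germ$origin[phased] == "paternal") / max(1, sum(phased)), 1),
    clustered_count = length(cl_keep),
    clustered_sub200_count = sum(nn < 200),
    clustered_sub200_pct = round_half_up(
      100 * sum(nn < 200) / max(1, length(cl_keep)), 1),
    damaging_breakdown = tier_summary
  )
  class(out) <- "cohort_summary"
  out
}

# Nearest-neighbour distance of every clustered member, aligned with
# clusters$members rows.
cluster_member_distances <- function(records, clusters) {
  m <- clusters$members
  if (!nrow(m)) return(numeric(0))
  nn <- numeric(nrow(m))
  for (rows in split(seq_len(nrow(m)), m$cluster_id)) {
    p <- records$pos[m$row[rows]]
    nn[rows] <- vapply(seq_along(p), function(i) min(abs(p[-i] - p[i])),
                       numeric(1))
  }
  nn
}

#' Damaging-category percentage breakdown from printed counts
#'
#' The worked arithmetic behind a damaging summary table: category counts
#' to percentages of the damaging total, one decimal, half-up.
#'
#' @param counts Named integer vector of damaging counts per category.
#' @return data.frame with n and pct columns.
#' @export
damaging_breakdown <- function(counts) {
  data.frame(category = names(counts), n = as.integer(counts),
             pct = round_half_up(100 * counts / sum(counts), 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Trio cohort summary (", x$n_retained_trios, " retained genomes)\n",
      sep = "")
  cat(sprintf("  germline SNVs/genome:   %.2f\n", x$germline_snv_per_genome))
  cat(sprintf("  germline indels/genome: %.2f\n", x$germline_indel_per_genome))
  cat(sprintf("  de novo CNVs/genome:    %.3f\n", x$cnv_per_genome))
  cat(sprintf("  somatic: %d calls (%.2f/genome)\n", x$somatic_count,
              x$somatic_per_genome))
  cat(sprintf("  paternal origin (phased germline SNVs): %.1f%%\n",
              x$paternal_fraction))
  cat(sprintf("  clustered DNMs: %d (%.1f%% within 200 bp)\n",
              x$clustered_count, x$clustered_sub200_pct))
  invisible(x)
}
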
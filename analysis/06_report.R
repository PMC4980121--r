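#!/usr/bin/env Rscript
# Stage 6: cohort summary report. Pure arithmetic over the upstream
# outputs, written as Markdown + JSON with the seed for provenance.

suppressMessages(library(dnmtrio))

ref <- Biostrings::readDNAStringSet("scratch/sim/reference.fa")
names(ref) <- sub(" .*", "", names(ref))
rec <- read_dnm_vcf("scratch/sim/dnms.vcf", "case",
                    sidecar_scores_path = "scratch/sim/scores.tsv")
trios_df <- read.table("scratch/sim/trios.tsv", header = TRUE, sep = "\t",
                       stringsAsFactors = FALSE)
rec$cohort <- trios_df$cohort[match(rec$sample_id, trios_df$sample_id)]
cnvs <- read.table("scratch/sim/cnvs.tsv", header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)

som <- classify_somatic(rec)
cl <- find_clusters(rec)  # row indices align with rec; somatic members
                          # are excluded inside summarize_cohort
cc <- classify_cohort(rec)
s <- summarize_cohort(rec, cnvs, trio_meta(trios_df), som$labels, cl,
                      tier_summary = cc$summary, cohort = "case")
print(s)

jsonlite::write_json(list(seed = 20160803, summary = unclass(s)),
                     "results/06_cohort_summary.json", auto_unbox = TRUE,
                     digits = 10, pretty = TRUE)

md <- c(
  "# Trio DNM cohort report (synthetic)",
  "",
  sprintf("- retained genomes: %d", s$n_retained_trios),
  sprintf("- germline SNVs / genome: %.2f", s$germline_snv_per_genome),
  sprintf("- germline indels / genome: %.2f", s$germline_indel_per_genome),
  sprintf("- de novo CNVs / genome: %.3f", s$cnv_per_genome),
  sprintf("- somatic candidates: %d (%.2f / genome)", s$somatic_count,
          s$somatic_per_genome),
  sprintf("- paternal origin among phased germline SNVs: %.1f%%",
          s$paternal_fraction),
  sprintf("- clustered DNMs: %d (%.1f%% within 200 bp)", s$clustered_count,
          s$clustered_sub200_pct),
  "",
  "## Damaging (tier 1) breakdown",
  "",
  paste(capture.output(print(cc$summary, row.names = FALSE)), collapse = "\n")
)
writeLines(md, "results/06_report.md")
message("report written to results/06_report.md")
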
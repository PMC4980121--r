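#!/usr/bin/env Rscript
# Stage 1: generate the study's synthetic inputs -- a reference genome, a
# 200-trio case cohort with a 258-trio control cohort (germline, clustered,
# somatic DNMs, de novo CNVs, predictor scores with GC confounding), and a
# 185-sample methylation matrix with two injected outlier samples.
# Bulky intermediates go to scratch/; small overview tables to results/.

suppressMessages(library(dnmtrio))
dir.create("results", showWarnings = FALSE)
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)

seed <- 20160803

message("simulating reference genome (8 x 12.5 Mb)...")
ref <- simulate_reference(n_contigs = 8, contig_length = 12.5e6,
                          gc_target = 0.41, seed = seed)
Biostrings::writeXStringSet(ref, "scratch/sim/reference.fa")

message("simulating trio cohort...")
params <- trio_sim_params(n_case_trios = 200, n_control_trios = 258,
                          gc_confounding = 0.5, seed = seed)
sim <- simulate_trio_cohort(params, ref)

write_dnm_vcf(sim$records, "scratch/sim/dnms.vcf")
write_scores_tsv(sim$records, "scratch/sim/scores.tsv")
if (nrow(sim$cnvs)) {
  gr <- interval_set(sim$cnvs$chrom, sim$cnvs$start, sim$cnvs$end, "cnv")
  gr$name <- sim$cnvs$sample_id[order(sim$cnvs$chrom, sim$cnvs$start)]
  write_bed(gr, "scratch/sim/cnvs.bed")
}
write.table(sim$cnvs, "scratch/sim/cnvs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sim$trios, "scratch/sim/trios.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sim$truth, "scratch/sim/truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

message("simulating methylation cohort (185 x 20000, 2 injected outliers)...")
meth <- simulate_methylation(meth_sim_params(
  seed = seed, outlier_samples = list(c(28, 1, 8), c(127, 2, 8))))
saveRDS(meth, "scratch/sim/methylation.rds")

overview <- data.frame(
  quantity = c("case trios", "control trios", "DNM records", "de novo CNVs",
               "methylation samples", "methylation probes"),
  value = c(params$n_case_trios, params$n_control_trios, nrow(sim$records),
            nrow(sim$cnvs), nrow(meth$beta), ncol(meth$beta))
)
write.table(overview, "results/01_cohort_overview.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("cohort: ", nrow(sim$records), " DNM records, ", nrow(sim$cnvs),
        " CNVs; overview written to results/01_cohort_overview.tsv")
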
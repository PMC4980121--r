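#!/usr/bin/env Rscript
# Stage 2: DNM characterization. Reads the simulated inputs back through
# the package's format readers (exercising the VCF/BED path), classifies
# somatic candidates by allelic fraction, finds 20 kb clusters, contrasts
# parent-of-origin between clustered and unclustered DNMs and by
# intra-cluster distance, tests the mutation-rate elevation around de novo
# CNVs, and fits the parental-age models.

suppressMessages(library(dnmtrio))

ref <- Biostrings::readDNAStringSet("scratch/sim/reference.fa")
names(ref) <- sub(" .*", "", names(ref))
rec <- read_dnm_vcf("scratch/sim/dnms.vcf", "case",
                    sidecar_scores_path = "scratch/sim/scores.tsv")
# cohort labels live in the trio table, not the VCF
trios <- read.table("scratch/sim/trios.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
rec$cohort <- trios$cohort[match(rec$sample_id, trios$sample_id)]
cnvs <- read.table("scratch/sim/cnvs.tsv", header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)

som <- classify_somatic(rec)
message(sum(som$labels == "somatic_candidate"), " somatic candidates (AF < ",
        round(som$threshold, 3), ")")
germ <- rec[som$labels != "somatic_candidate", , drop = FALSE]

cl <- find_clusters(germ)
write.table(cl$calls, "results/02_cluster_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message(nrow(cl$calls), " clusters / ", nrow(cl$members), " clustered DNMs")

oc <- origin_contrast(germ, cl)
dc <- distance_contrast(germ, cl)
px <- cnv_proximity_test(rec, cnvs,
                         genome_bp = sum(as.numeric(Biostrings::width(ref))))
am <- age_models(trio_meta(trios), per_trio_counts(germ, trios))

tests <- list(
  somatic = list(count = sum(som$labels == "somatic_candidate"),
                 threshold = som$threshold),
  origin_contrast = list(table = as.vector(oc$table), odds_ratio = oc$odds_ratio,
                         p = oc$p,
                         maternal_fraction = as.list(oc$maternal_fraction)),
  distance_contrast = list(p = dc$p,
                           maternal_fraction = as.list(dc$maternal_fraction)),
  cnv_proximity = list(observed = px$observed, expected = px$expected,
                       window_bp = px$window_bp, p = px$p),
  age_models = am
)
jsonlite::write_json(tests, "results/02_characterization.json",
                     auto_unbox = TRUE, digits = 10, pretty = TRUE)
message("clustered DNMs are ",
        round(100 * oc$maternal_fraction[["clustered"]], 1),
        "% maternal vs ", round(100 * oc$maternal_fraction[["unclustered"]], 1),
        "% unclustered (Fisher p = ", signif(oc$p, 2), ")")
message("DNMs near de novo CNVs: ", px$observed, " observed vs ",
        round(px$expected, 1), " expected (binomial p = ", signif(px$p, 2), ")")
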
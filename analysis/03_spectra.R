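#!/usr/bin/env Rscript
# Stage 3: sequence context. Ti/Tv per mutation class and the 96-channel
# pyrimidine-centered trinucleotide spectra, compared between case and
# control germline DNMs (and against the somatic candidates).

suppressMessages(library(dnmtrio))

ref <- Biostrings::readDNAStringSet("scratch/sim/reference.fa")
names(ref) <- sub(" .*", "", names(ref))
rec <- read_dnm_vcf("scratch/sim/dnms.vcf", "case")
trios <- read.table("scratch/sim/trios.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
rec$cohort <- trios$cohort[match(rec$sample_id, trios$sample_id)]
som <- classify_somatic(rec)

groups <- list(
  germline_case = rec[som$labels == "germline" & rec$cohort == "case", ],
  germline_control = rec[som$labels == "germline" & rec$cohort == "control", ],
  somatic = rec[som$labels == "somatic_candidate", ]
)
spectra <- lapply(groups, build_spectrum, reference = ref)

tab <- data.frame(channel = spectrum_channels())
for (nm in names(spectra)) tab[[nm]] <- spectra[[nm]]$counts
write.table(tab, "results/03_spectra96.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

titvs <- vapply(groups, titv, numeric(1))
cmp <- spectrum_correlation(spectra$germline_case, spectra$germline_control)
cmp_som <- spectrum_correlation(spectra$germline_case, spectra$somatic)
jsonlite::write_json(list(titv = as.list(round(titvs, 3)),
                          case_vs_control = cmp, case_vs_somatic = cmp_som),
                     "results/03_spectrum_tests.json", auto_unbox = TRUE,
                     digits = 10, pretty = TRUE)
message("Ti/Tv: ", paste(names(titvs), round(titvs, 2), collapse = ", "))
message("case vs control spectrum: r = ", round(cmp$r, 3),
        ", p = ", signif(cmp$p, 2))
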
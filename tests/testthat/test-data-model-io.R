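# Domain types and format I/O: record invariants, VCF/BED round-trips,
# reference context fetching.

test_that("record construction derives var_type and enforces invariants", {
  r <- make_records(ref = "A", alt = "G", ad_ref = 20L, ad_alt = 10L)
  expect_equal(r$var_type, "SNV")
  expect_equal(allelic_fraction(r), 1 / 3)
  r2 <- make_records(ref = "AT", alt = "A")
  expect_equal(r2$var_type, "indel")
  expect_error(make_records(ref = "A", alt = "A"), "differ")
  expect_error(make_records(ad_alt = 0L), "ad_alt")
  expect_error(make_records(pos = 0L), "pos")
  expect_error(make_records(is_lof = TRUE, is_missense = TRUE),
               "mutually exclusive")
  expect_error(make_records(sift = 1.2), "sift")
  expect_error(make_records(deepbind_wt_pct = 101), "deepbind_wt_pct")
})

test_that("trio metadata forces exclusion of non-whole-blood samples", {
  tm <- trio_meta(data.frame(
    sample_id = c("a", "b", "c"), paternal_age = c(30, 35, 40),
    maternal_age = c(28, 33, 38), sex = "male",
    dna_source = c("whole_blood", "LCL", "leucocyte"),
    stringsAsFactors = FALSE
  ))
  expect_equal(tm$excluded, c(FALSE, TRUE, TRUE))
  expect_error(trio_meta(data.frame(sample_id = "a", paternal_age = 0,
                                    maternal_age = 30, sex = "m",
                                    dna_source = "whole_blood")), "ages")
})

test_that("CNV events must exceed 10 kb", {
  ok <- data.frame(sample_id = "a", chrom = "c1", start = 0L, end = 20000L,
                   cnv_type = "loss", origin = "maternal")
  expect_silent(cnv_events(ok))
  bad <- ok; bad$end <- 5000L
  expect_error(cnv_events(bad), "10 kb")
})

test_that("VCF round-trip is lossless for all stored fields", {
  set.seed(101)
  n <- 100
  df <- data.frame(
    sample_id = sample(sprintf("s%02d", 1:8), n, TRUE),
    cohort = "case", chrom = sample(names(test_ref), n, TRUE),
    pos = sample.int(4e4, n), ref = sample(c("A", "C", "G", "T"), n, TRUE),
    alt = NA_character_, ad_ref = sample.int(30, n, TRUE),
    ad_alt = sample.int(30, n, TRUE),
    origin = sample(c("paternal", "maternal", "unknown"), n, TRUE),
    region_class = sample(c("coding_exonic", "utr3", "intronic", "nongenic"),
                          n, TRUE),
    gene = ifelse(runif(n) < 0.5, sprintf("G%03d", sample.int(99, n, TRUE)),
                  NA_character_),
    sift = ifelse(runif(n) < 0.3, NA, round(runif(n), 4)),
    cadd_phred = round(runif(n, 0, 40), 3),
    is_missense = runif(n) < 0.2,
    dhs_overlap = runif(n) < 0.3,
    stringsAsFactors = FALSE
  )
  df$alt <- vapply(df$ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                   character(1))
  df$is_missense[df$region_class != "coding_exonic"] <- FALSE
  rec <- dnm_records(df)
  vcf <- tempfile(fileext = ".vcf"); tsv <- tempfile(fileext = ".tsv")
  write_dnm_vcf(rec, vcf)
  write_scores_tsv(rec, tsv)
  back <- read_dnm_vcf(vcf, "case", sidecar_scores_path = tsv)
  for (col in names(rec)) {
    expect_equal(back[[col]], rec[[col]], info = col)
  }
})

test_that("VCF reader decomposes multi-allelic rows and validates input", {
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "sampleA"), collapse = "\t"),
    paste(c("chr1", "500", ".", "A", "G,T", ".", "PASS", ".",
            "GT:AD", "1/2:5,12,8"), collapse = "\t")
  ), vcf)
  rec <- read_dnm_vcf(vcf, "control")
  expect_equal(nrow(rec), 2L)
  expect_setequal(rec$alt, c("G", "T"))
  expect_equal(rec$ad_alt[rec$alt == "G"], 12L)
  expect_equal(rec$ad_alt[rec$alt == "T"], 8L)
  expect_equal(unique(rec$origin), "unknown")

  bad <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s"), collapse = "\t"),
               "chr1\t100\t.\tA"), bad)
  expect_error(read_dnm_vcf(bad, "case"), "line 3")
})

test_that("sidecar score key collisions are rejected", {
  tsv <- tempfile(fileext = ".tsv")
  df <- make_records(2, pos = c(100L, 100L))
  df2 <- rbind(df, df[1, ])
  write.table(df2[, c("sample_id", "chrom", "pos", "ref", "alt", "sift")],
              tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_scores_tsv(tsv), "collision")
})

test_that("BED reading, sorting and union arithmetic are correct", {
  bed <- tempfile(fileext = ".bed")
  writeLines(c("chr2\t150\t300", "chr1\t100\t200", "chr2\t100\t200"), bed)
  gr <- read_bed(bed, label = "t")
  expect_equal(as.character(GenomicRanges::seqnames(gr)),
               c("chr1", "chr2", "chr2"))
  expect_equal(GenomicRanges::start(gr), c(101L, 101L, 151L))
  expect_equal(interval_union_length(gr[2:3]), 200)
  expect_equal(interval_union_length(read_bed(bed)), 300)

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200", "chr1\t500\t400"), bad)
  expect_error(read_bed(bad), "line 2")

  # single interval "chr1 100 200" covers 100 bases
  one <- tempfile(fileext = ".bed")
  writeLines("chr1\t100\t200", one)
  expect_equal(interval_union_length(read_bed(one)), 100)
})

test_that("interval union matches per-base membership oracle", {
  set.seed(7)
  for (rep in 1:10) {
    k <- sample(3:12, 1)
    start <- sample.int(9000, k)
    end <- pmin(10000, start + sample.int(800, k))
    gr <- interval_set(rep("c", k), start, end)
    covered <- logical(10000)
    for (i in seq_len(k)) covered[(start[i] + 1):end[i]] <- TRUE
    expect_equal(interval_union_length(gr), sum(covered))
  }
})

test_that("BED round-trip preserves intervals", {
  gr <- interval_set(c("a", "a", "b"), c(10, 500, 0), c(100, 900, 50), "x")
  f <- tempfile(fileext = ".bed")
  write_bed(gr, f)
  back <- read_bed(f)
  expect_equal(GenomicRanges::start(back), GenomicRanges::start(gr))
  expect_equal(GenomicRanges::end(back), GenomicRanges::end(gr))
})

test_that("fetch_context matches a naive substring oracle", {
  chr1 <- as.character(test_ref[[1]])
  set.seed(11)
  for (i in 1:50) {
    pos <- sample.int(nchar(chr1), 1)
    flank <- sample.int(30, 1)
    got <- fetch_context(test_ref, "contig1", pos, flank)
    want <- substr(chr1, max(1, pos - flank), min(nchar(chr1), pos + flank))
    expect_equal(as.character(got), want)
    expect_equal(attr(got, "truncated"),
                 pos - flank < 1 || pos + flank > nchar(chr1))
  }
  small <- Biostrings::DNAStringSet(c(c1 = "ACGT"))
  expect_equal(as.character(fetch_context(small, "c1", 2, 1)), "ACG")
  edge <- fetch_context(small, "c1", 1, 1)
  expect_equal(as.character(edge), "AC")
  expect_true(attr(edge, "truncated"))
  expect_error(fetch_context(small, "nope", 1, 1), "unknown chrom")
})

test_that("GMT round-trip preserves gene sets", {
  sets <- list(alpha = sprintf("G%02d", 1:60), beta = sprintf("G%02d", 30:99))
  f <- tempfile(fileext = ".gmt")
  write_gmt(sets, f)
  expect_equal(read_gmt(f), sets)
})
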
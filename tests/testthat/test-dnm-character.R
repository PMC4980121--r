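# Somatic classification, clustering, origin contrasts, CNV proximity and
# age models.

test_that("somatic classification applies the fixed and adaptive rules", {
  r <- make_records(3, ad_ref = c(15L, 42L, 10L), ad_alt = c(15L, 8L, 10L))
  out <- classify_somatic(r)
  expect_equal(out$labels, c("germline", "somatic_candidate", "germline"))
  expect_equal(out$threshold, 1 / 3)
  # AF = 0.16 (the early post-zygotic regime) is a somatic candidate
  r16 <- make_records(1, ad_ref = 84L, ad_alt = 16L)
  expect_equal(classify_somatic(r16)$labels, "somatic_candidate")

  # adaptive threshold = mean - 2 SD of the cohort AF distribution
  set.seed(3)
  af <- pmin(0.95, pmax(0.05, rnorm(500, 0.5, 0.05)))
  ra <- make_records(500, pos = seq_len(500) * 100L,
                     ad_ref = as.integer(round(1000 * (1 - af))),
                     ad_alt = as.integer(round(1000 * af)))
  ad <- classify_somatic(ra, mode = "adaptive")
  afr <- allelic_fraction(ra)
  expect_equal(ad$threshold, mean(afr) - 2 * sd(afr))
  expect_lt(abs(ad$threshold - 0.40), 0.01)
  expect_error(classify_somatic(make_records(5), mode = "adaptive"), "30")
})

test_that("cluster chaining respects the inclusive 20 kb gap boundary", {
  one <- make_records(1)
  expect_equal(nrow(find_clusters(one)$calls), 0L)
  at <- function(gap) make_records(2, pos = c(10000L, 10000L + gap))
  expect_equal(nrow(find_clusters(at(20000L))$calls), 1L)
  expect_equal(nrow(find_clusters(at(20001L))$calls), 0L)
  # different samples never cluster
  two <- make_records(2, sample_id = c("a", "b"), pos = c(100L, 200L))
  expect_equal(nrow(find_clusters(two)$calls), 0L)
})

test_that("cluster output is invariant to input order and matches the oracle", {
  set.seed(23)
  for (rep in 1:40) {
    n <- sample(5:25, 1)
    df <- data.frame(
      sample_id = sample(c("s1", "s2"), n, TRUE),
      chrom = sample(c("c1", "c2"), n, TRUE),
      pos = sample.int(2e5, n),
      stringsAsFactors = FALSE
    )
    got <- cluster_partition(find_clusters(df))
    want <- cluster_oracle(df)
    expect_equal(got, want)
    # permutation invariance: remap oracle through the permutation
    perm <- sample.int(n)
    got_p <- cluster_partition(find_clusters(df[perm, ]))
    want_p <- lapply(want, function(x) sort(match(x, perm)))
    want_p <- want_p[order(vapply(want_p, min, integer(1)))]
    expect_equal(got_p, want_p)
  }
})

test_that("span rule caps cluster extent while gap rule chains", {
  r <- make_records(3, pos = c(0L, 15000L, 30000L) + 1L)
  expect_equal(nrow(find_clusters(r, rule = "gap")$calls), 1L)
  sp <- find_clusters(r, rule = "span")
  expect_equal(sp$calls$n_members, 2L)
})

test_that("origin contrast matches Fisher enumeration and handles margins", {
  # 10 homogeneous 2-member clusters (5 paternal, 5 maternal) plus 20
  # isolated records (10/10) -> the balanced 2x2 [[10,10],[10,10]]
  cl_pos <- as.integer(rep(1e5 * (1:10), each = 2) + c(0, 100))
  unc_pos <- as.integer(3e7 + 1e6 * (1:20))
  bal <- make_records(40, pos = c(cl_pos, unc_pos),
                      origin = c(rep(c("paternal", "maternal"), each = 10),
                                 rep(c("paternal", "maternal"), 10)))
  cl <- find_clusters(bal)
  oc <- origin_contrast(bal, cl)
  expect_equal(unname(oc$p), 1)
  expect_equal(unname(as.vector(oc$table)), c(10, 10, 10, 10))

  # crafted [[1,9],[9,1]] vs exact hypergeometric enumeration
  tab <- matrix(c(1, 9, 9, 1), 2, byrow = TRUE)
  expect_equal(fisher.test(tab)$p.value, fisher_oracle(tab), tolerance = 1e-12)

  # zero margin warns and returns p = 1
  r0 <- make_records(4, pos = c(1L, 1001L, 5e6L, 6e6L), origin = "maternal")
  cl0 <- find_clusters(r0)
  expect_warning(out0 <- origin_contrast(r0, cl0), "margin")
  expect_equal(out0$p, 1)
})

test_that("somatic candidates are excluded from the origin table", {
  r <- make_records(4, pos = c(1L, 101L, 5e6L, 6e6L),
                    ad_ref = c(15L, 45L, 15L, 15L),
                    ad_alt = c(15L, 5L, 15L, 15L))
  lab <- classify_somatic(r)$labels
  expect_equal(lab[2], "somatic_candidate")
  oc <- suppressWarnings(origin_contrast(r, find_clusters(r), lab))
  expect_equal(sum(oc$table), 3)
})

test_that("distance contrast splits by nearest-neighbour distance", {
  # two clusters: one tight (50 bp), one loose (5 kb), known origins
  r <- dnm_records(rbind(
    make_records(2, pos = c(1000L, 1050L), origin = "maternal"),
    make_records(2, pos = c(1e6L, 1e6L + 5000L), origin = "paternal")
  ))
  cl <- find_clusters(r)
  dc <- distance_contrast(r, cl, cutoff = 200)
  expect_equal(unname(dc$maternal_fraction), c(1, 0))
  expect_equal(sum(dc$table), 4)

  # the published 2x2 [[88,12],[68,32]] against the enumeration oracle
  tab <- matrix(c(12, 88, 32, 68), 2, byrow = TRUE)
  expect_equal(fisher.test(tab)$p.value, fisher_oracle(tab), tolerance = 1e-10)

  tight <- dnm_records(make_records(2, pos = c(1000L, 1050L), origin = "maternal"))
  cl_t <- find_clusters(tight)
  expect_error(distance_contrast(tight, cl_t, cutoff = 200), "empty")
  expect_error(distance_contrast(r, cl, cutoff = Inf), "finite")
  unk <- dnm_records(make_records(2, pos = c(1000L, 1050L), origin = "unknown"))
  expect_error(distance_contrast(unk, find_clusters(unk)), "known origin")
})

test_that("CNV proximity test reproduces exact binomial tails", {
  cnv <- cnv_events(data.frame(sample_id = "s1", chrom = "c1",
                               start = 100000L, end = 150000L,
                               cnv_type = "loss", origin = "maternal"))
  # no DNM in the window: upper tail at zero is 1
  far <- make_records(5, chrom = "c1", pos = seq(5e6, 9e6, length.out = 5))
  res0 <- cnv_proximity_test(far, cnv, genome_bp = 1e8)
  expect_equal(res0$observed, 0L)
  expect_equal(res0$p, 1)
  expect_error(cnv_proximity_test(far, cnv, flank = -1, genome_bp = 1e8),
               "flank")

  # window arithmetic: body + two flanks
  expect_equal(res0$window_bp, 50000 + 2 * 1e5)

  # p equals the exact tail-sum oracle across configurations
  for (cfg in list(c(n = 1000, k = 11), c(n = 500, k = 3), c(n = 2000, k = 30))) {
    pr <- res0$window_bp / 1e8
    expect_equal(pbinom(cfg["k"] - 1, cfg["n"], pr, lower.tail = FALSE),
                 binom_tail_oracle(cfg["k"], cfg["n"], pr),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }

  # overlapping windows contribute their union, not their sum
  cnv2 <- cnv_events(data.frame(
    sample_id = "s1", chrom = "c1", start = c(100000L, 120000L),
    end = c(150000L, 170000L), cnv_type = "loss", origin = "maternal"
  ))
  res2 <- cnv_proximity_test(far, cnv2, genome_bp = 1e8)
  expect_equal(res2$window_bp, (170000 + 1e5) - (100000 - 1e5))

  # carrier restriction: another sample's DNM in the window does not count
  near_other <- make_records(1, sample_id = "s2", chrom = "c1", pos = 120000L)
  reso <- cnv_proximity_test(near_other, cnv, genome_bp = 1e8,
                             same_individual = TRUE)
  expect_equal(reso$observed, 0L)
  resa <- cnv_proximity_test(near_other, cnv, genome_bp = 1e8,
                             same_individual = FALSE)
  expect_equal(resa$observed, 1L)
})

test_that("age models recover their generating parameters", {
  tm <- trio_meta(data.frame(
    sample_id = sprintf("t%02d", 1:40), paternal_age = seq(20, 45, length.out = 40),
    maternal_age = 19 + 0.5 * (0:39) + rep(c(0, 1.3, 0.2, 2.1), 10),
    sex = "male",
    dna_source = "whole_blood", stringsAsFactors = FALSE
  ))
  # flat counts: correlation collapses to zero
  flat <- data.frame(sample_id = tm$sample_id, paternal_snv = 30L,
                     maternal_snv = 10L, indel_total = 4L)
  am_flat <- age_models(tm, flat)
  expect_equal(am_flat$pearson_r_paternal, 0)

  # noiseless exponential indel counts: Poisson slope recovered to 1e-4
  exact <- data.frame(sample_id = tm$sample_id,
                      paternal_snv = round(tm$paternal_age),
                      maternal_snv = 10L,
                      indel_total = exp(0.05 * tm$paternal_age))
  am <- suppressWarnings(age_models(tm, exact))
  expect_lt(abs(am$poisson_beta_paternal - 0.05), 1e-4)
  expect_equal(am$pearson_r_paternal, 1, tolerance = 1e-3)

  tm0 <- tm; tm0$paternal_age <- 30
  expect_error(age_models(tm0, flat), "zero variance")
  expect_error(age_models(tm[1:5, ], flat[1:5, ]), ">= 10")
})

test_that("origin category counts are conserved through the contrast", {
  ref <- simulate_reference(n_contigs = 2, contig_length = 2e6, seed = 31)
  p <- trio_sim_params(n_case_trios = 30, n_control_trios = 0, seed = 31,
                       phased_fraction = 0.7)
  s <- simulate_trio_cohort(p, ref)
  r <- s$records
  n_pat <- sum(r$origin == "paternal"); n_mat <- sum(r$origin == "maternal")
  n_unk <- sum(r$origin == "unknown")
  expect_equal(n_pat + n_mat + n_unk, nrow(r))
  oc <- origin_contrast(r, find_clusters(r))
  expect_equal(sum(oc$table), n_pat + n_mat)
})
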
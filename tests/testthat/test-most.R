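# MOST: probe filtering, PCA retention against prcomp, covariate
# adjustment, Grubbs, the dual FDR rule and loading enrichment.

small_meth <- function(seed = 1, n = 50, m = 3000, ...) {
  simulate_methylation(meth_sim_params(n_samples = n, n_probes = m,
                                       seed = seed, ...))
}

test_that("probe filtering applies all three removal rules strictly", {
  ms <- small_meth(4)
  ann <- ms$annotation
  # force known memberships
  ann$chrom[1] <- "chrX"; ann$snp_overlap[2] <- TRUE
  detp <- ms$detection_p; detp[,] <- 0.01
  detp[5, 3] <- 0.06  # a single failing sample kills the probe
  fb <- filter_probes(ms$beta, ann, detp)
  expect_false(any(c("cg000001", "cg000002", "cg000003") %in%
                     colnames(fb$beta)))
  expect_gte(fb$removed["detection"], 1)
  # clean matrix passes through unchanged
  ann2 <- ms$annotation; ann2$chrom <- "chr1"; ann2$snp_overlap <- FALSE
  detp2 <- ms$detection_p; detp2[,] <- 0.001
  fb2 <- filter_probes(ms$beta, ann2, detp2)
  expect_equal(dim(fb2$beta), dim(ms$beta))
  ann3 <- ms$annotation; ann3$chrom <- "chrX"
  expect_error(filter_probes(ms$beta, ann3, detp2), "no probes")
})

test_that("PCA eigenvalues and scores agree with prcomp", {
  set.seed(6)
  x <- matrix(rnorm(40 * 500), 40, 500)
  x[, 1:50] <- x[, 1:50] + rnorm(40, 0, 2)  # one real component
  pr <- prcomp(x, center = TRUE, scale. = TRUE)
  pc <- pca_retain(x, n_pcs = 10, n_perm = 5, seed = 2)
  expect_equal(pc$eigenvalues, unname(pr$sdev[1:10]^2), tolerance = 1e-8)
  for (j in 1:5) {
    expect_equal(abs(cor(pc$scores[, j], pr$x[, j])), 1, tolerance = 1e-6)
  }
  # trace conservation: eigenvalues sum to the number of scaled probes
  expect_equal(sum(pc$all_eigenvalues), 500, tolerance = 1e-6)
})

test_that("parallel analysis retains planted structure and rejects noise", {
  # pure noise: retention stays minimal in most seeds
  set.seed(8)
  ks <- vapply(1:10, function(s) {
    x <- matrix(rnorm(100 * 2000), 100, 2000)
    pca_retain(x, n_pcs = 10, n_perm = 10, seed = s)$retained_k
  }, integer(1))
  expect_gte(mean(ks <= 2), 0.9)
  # a planted factor explaining ~20% variance is always retained
  set.seed(9)
  for (s in 1:5) {
    f <- rnorm(100)
    x <- outer(f, rnorm(2000, 0, 0.5)) + matrix(rnorm(100 * 2000), 100, 2000)
    expect_gte(pca_retain(x, n_pcs = 10, n_perm = 10, seed = s)$retained_k, 1)
  }
})

test_that("zero-variance probes are dropped with a warning", {
  x <- matrix(rnorm(30 * 200), 30, 200)
  x[, 7] <- 1
  expect_warning(pc <- pca_retain(x, n_pcs = 5, n_perm = 3, seed = 1),
                 "zero-variance")
  expect_equal(pc$n_probes, 199L)
})

test_that("covariate adjustment is OLS residualization", {
  set.seed(14)
  n <- 80
  cov <- data.frame(age = runif(n, 5, 15),
                    batch = factor(sample(c("a", "b"), n, TRUE)))
  # perfect fit: score twice the age
  sc <- cbind(PC1 = 2 * cov$age, PC2 = rnorm(n))
  adj <- adjust_covariates(sc, cov)
  expect_lt(max(abs(adj[, 1])), 1e-10)
  # orthogonal covariates leave centered scores untouched
  sc2 <- cbind(PC1 = rnorm(n))
  cov0 <- data.frame(flag = rep(c(-1, 1), n / 2))
  sc2o <- sc2 - outer(cov0$flag, colSums(sc2 * cov0$flag) / n)  # orthogonalize
  adj2 <- adjust_covariates(sc2o, cov0)
  expect_equal(adj2[, 1], sc2o[, 1] - mean(sc2o[, 1]), tolerance = 1e-10)
  # batch means vanish after adjustment (ANOVA oracle)
  sc3 <- cbind(PC1 = rnorm(n) + 3 * (cov$batch == "b"))
  adj3 <- adjust_covariates(sc3, cov)
  expect_lt(abs(mean(adj3[cov$batch == "b", 1]) -
                  mean(adj3[cov$batch == "a", 1])), 1e-8)
  dup <- cbind(cov, age2 = cov$age)
  expect_error(adjust_covariates(sc, dup), "age2")
})

test_that("Grubbs statistic and p follow the closed form", {
  out <- grubbs_test(c(0, 0, 0, 10))
  # hand oracle: mean 2.5, sd 5, G = 7.5/5
  expect_equal(out$G, 1.5)
  expect_equal(out$index, 4L)
  n <- 4; G <- 1.5
  tstar <- sqrt(n * (n - 2) * G^2 / ((n - 1)^2 - n * G^2))
  expect_equal(out$p, min(1, 2 * n * pt(tstar, n - 2, lower.tail = FALSE)))
  expect_error(grubbs_test(c(-1, 1)), "n >= 3")
  expect_error(grubbs_test(rep(2, 5)), "zero standard deviation")
})

test_that("the dual FDR rule suppresses batch-confounded shifts", {
  # an 8-SD shift on a retained factor, carried by a sample that is alone
  # in its batch level: raw Grubbs flags it, covariate adjustment absorbs
  # it exactly, so the dual rule must not report it
  ms <- small_meth(21, n = 60, m = 4000, outlier_samples = list(c(12, 1, 8)))
  cov <- ms$covariates
  levels(cov$batch) <- c(levels(cov$batch), "b_solo")
  cov$batch[12] <- "b_solo"
  res <- most_detect(ms$beta, cov, ms$annotation, ms$detection_p, seed = 3)
  expect_gte(res$pca$retained_k, 1)
  expect_true("S012" %in% res$grubbs_raw$sample[res$grubbs_raw$fdr < 0.1])
  expect_false("S012" %in% res$outliers$sample)
  # without the confounding, the same shift is reported
  res2 <- most_detect(ms$beta, ms$covariates, ms$annotation, ms$detection_p,
                      seed = 3)
  expect_true("S012" %in% res2$outliers$sample)
})

test_that("full MOST is deterministic and invariant to sample order", {
  ms <- small_meth(31, n = 60, m = 4000, outlier_samples = list(c(5, 1, 8)))
  r1 <- most_detect(ms$beta, ms$covariates, ms$annotation, ms$detection_p,
                    seed = 9)
  r2 <- most_detect(ms$beta, ms$covariates, ms$annotation, ms$detection_p,
                    seed = 9)
  expect_identical(r1$outliers, r2$outliers)
  perm <- sample(nrow(ms$beta))
  r3 <- most_detect(ms$beta[perm, ], ms$covariates[perm, ],
                    ms$annotation, ms$detection_p[perm, ], seed = 9)
  expect_setequal(paste(r3$outliers$sample, r3$outliers$pc),
                  paste(r1$outliers$sample, r1$outliers$pc))
})

test_that("loading enrichment finds planted sets and has sane fixed points", {
  set.seed(44)
  m <- 2000
  probes <- sprintf("cg%05d", 1:m)
  genes <- sprintf("G%03d", rep(1:200, each = 10))
  pg <- data.frame(probe = probes, gene = genes, stringsAsFactors = FALSE)
  ld <- setNames(rnorm(m, 0, 0.01), probes)
  planted <- pg$gene %in% sprintf("G%03d", 1:20)
  ld[planted] <- abs(rnorm(sum(planted), 0.5, 0.05))
  sets <- list(planted = sprintf("G%03d", 1:20),
               decoy1 = sprintf("G%03d", 50:90),
               decoy2 = sprintf("G%03d", 100:140))
  out <- loading_enrichment(ld, pg, sets, top_fraction = 0.1)
  pos <- out[out$sign == "positive", ]
  expect_equal(pos$set[1], "planted")
  expect_lt(pos$p[1], 1e-6)
  # selecting everything makes every set unenriched by construction
  all_out <- loading_enrichment(ld, pg, sets, top_fraction = 1.0)
  expect_true(all(all_out$p == 1))
  # insufficient probe-gene coverage is an error
  pg_half <- pg; pg_half$gene[1:1500] <- NA
  expect_error(loading_enrichment(ld, pg_half, sets), "half")
})
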
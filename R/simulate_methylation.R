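# Synthetic methylation matrices with latent factor structure, covariate
# effects and injected outlier samples -- the structure MOST assumes.

#' Parameters for the methylation simulator
#'
#' The generator emulates a blood-derived 450k-style beta matrix after
#' normalization: per-probe baselines drawn from the familiar bimodal
#' (hypo/hyper) methylation mixture on the logit scale, a low-rank latent
#' factor component shared across probes (biology, cell composition and
#' technical structure all present as such factors), additive covariate
#' effects on probe subsets, i.i.d. logit-scale noise, and beta values
#' squashed back to (0, 1). Outlier samples are injected by shifting a
#' sample's score on a chosen latent factor by a stated number of factor
#' SDs.
#'
#' @param n_samples,n_probes Matrix dimensions (n_samples >= 10).
#' @param n_latent_factors Number of latent factors (default 5).
#' @param factor_sd Per-factor loading scale, decreasing across factors;
#'   controls how much variance each factor explains.
#' @param outlier_samples List of `c(sample, factor, shift)` triples: shift
#'   the given sample's score on the given factor by `shift` SDs.
#' @param covariate_effects Named effect sizes (logit scale) for the
#'   generated covariates: sex, age (per year), batch.
#' @param noise_sd Logit-scale i.i.d. noise SD.
#' @param detection_fail_rate Per-entry probability of a failed detection
#'   p-value (> 0.05); must be in [0, 1).
#' @param seed Integer seed.
#' @return List of class `meth_sim_params`.
#' @export
meth_sim_params <- function(n_samples = 185, n_probes = 20000,
                            n_latent_factors = 5,
                            factor_sd = 0.2 * 0.8^(seq_len(n_latent_factors) - 1),
                            outlier_samples = list(),
                            covariate_effects = c(sex = 0.3, age = 0.01,
                                                  batch = 0.25),
                            noise_sd = 0.4,
                            detection_fail_rate = 1e-4,
                            seed = 1L) {
  if (n_samples < 10) stop("n_samples must be >= 10")
  if (detection_fail_rate < 0 || detection_fail_rate >= 1) {
    stop("detection_fail_rate must lie in [0, 1)")
  }
  for (o in outlier_samples) {
    if (length(o) != 3) stop("each outlier spec is c(sample, factor, shift)")
    if (o[1] < 1 || o[1] > n_samples) stop("outlier sample index out of range")
    if (o[2] < 1 || o[2] > n_latent_factors) stop("outlier factor index out of range")
    if (!is.finite(o[3])) stop("outlier shift must be finite")
  }
  p <- as.list(environment())
  class(p) <- "meth_sim_params"
  p
}

#' Simulate a methylation beta matrix with known outliers
#'
#' @param params A [meth_sim_params] object.
#' @return List: `beta` (samples x probes, in (0,1)), `detection_p` (same
#'   shape), `annotation` (probe, chrom, snp_overlap), `covariates`
#'   (sex, age, ethnicity, batch, chip_order, cell fractions), `truth`
#'   (data.frame of injected outliers: sample, sample_id, factor, shift).
#' @export
simulate_methylation <- function(params) {
  stopifnot(inherits(params, "meth_sim_params"))
  p <- params
  n <- p$n_samples; m <- p$n_probes; k <- p$n_latent_factors
  ids <- sprintf("S%03d", seq_len(n))
  probes <- sprintf("cg%06d", seq_len(m))

  covars <- with_substream(p$seed, "meth_covariates", {
    cf <- matrix(rbeta(n * 5, 2, 6), n, 5)
    cf <- cf / rowSums(cf)
    colnames(cf) <- paste0("cell_", c("gran", "mono", "bcell", "cd4t", "nk"))
    # compositions sum to 1; drop the reference component so the covariate
    # design stays full rank alongside an intercept
    cf <- cf[, -1, drop = FALSE]
    data.frame(
      sex = factor(sample(c("male", "female"), n, TRUE, prob = c(0.8, 0.2))),
      age = round(runif(n, 3, 18), 1),
      ethnicity = factor(sample(c("eur", "eas", "afr"), n, TRUE,
                                prob = c(0.7, 0.15, 0.15))),
      batch = factor(sample(paste0("b", 1:4), n, TRUE)),
      chip_order = factor(sample(paste0("chip", 1:8), n, TRUE)),
      cf, stringsAsFactors = FALSE
    )
  })

  parts <- with_substream(p$seed, "meth_matrix", {
    # bimodal hypo/hyper baselines kept in the moderately methylated band:
    # saturated probes would make the logit squash strongly nonlinear and
    # manufacture single-sample components out of large factor scores,
    # which is not the null structure the outlier test assumes
    base <- qlogis(ifelse(runif(m) < 0.45, rbeta(m, 4, 12), rbeta(m, 12, 4)))
    L <- matrix(rnorm(m * k), m, k) * rep(p$factor_sd, each = m)
    FS <- matrix(rnorm(n * k), n, k)
    # covariate effects hit random probe subsets (affected w.p. 0.05)
    eff <- matrix(0, n, m)
    sexv <- as.integer(covars$sex == "male")
    batchv <- as.integer(covars$batch)
    for (nm in names(p$covariate_effects)) {
      hit <- runif(m) < 0.05
      v <- switch(nm, sex = sexv, age = covars$age, batch = batchv,
                  stop("unknown covariate effect: ", nm))
      eff[, hit] <- eff[, hit] +
        outer(v * p$covariate_effects[[nm]], rnorm(sum(hit)))
    }
    noise <- matrix(rnorm(n * m, 0, p$noise_sd), n, m)
    list(base = base, L = L, FS = FS, eff = eff, noise = noise)
  })

  FS <- parts$FS
  for (o in p$outlier_samples) FS[o[1], o[2]] <- FS[o[1], o[2]] + o[3]
  eta <- rep(parts$base, each = n) + tcrossprod(FS, parts$L) +
    parts$eff + parts$noise
  beta <- plogis(eta)
  beta <- pmin(pmax(beta, 1e-6), 1 - 1e-6)
  dimnames(beta) <- list(ids, probes)

  detp <- with_substream(p$seed, "meth_detection", {
    d <- matrix(runif(n * m, 0, 0.01), n, m)
    fail <- runif(n * m) < p$detection_fail_rate
    d[fail] <- runif(sum(fail), 0.051, 0.8)
    dimnames(d) <- list(ids, probes)
    d
  })

  annotation <- with_substream(p$seed, "meth_annotation", {
    data.frame(
      probe = probes,
      chrom = sample(c(paste0("chr", 1:22), "chrX", "chrY"), m, TRUE,
                     prob = c(rep(0.96 / 22, 22), 0.03, 0.01)),
      snp_overlap = runif(m) < 0.05,
      stringsAsFactors = FALSE
    )
  })

  truth <- if (length(p$outlier_samples)) {
    do.call(rbind, lapply(p$outlier_samples, function(o) {
      data.frame(sample = o[1], sample_id = ids[o[1]], factor = o[2],
                 shift = o[3], stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(sample = integer(), sample_id = character(),
               factor = integer(), shift = numeric(),
               stringsAsFactors = FALSE)
  }
  truth <- truth[truth$shift != 0, , drop = FALSE]

  list(beta = beta, detection_p = detp, annotation = annotation,
       covariates = covars, truth = truth)
}
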
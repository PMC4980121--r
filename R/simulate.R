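# Synthetic trio cohorts with known ground truth. The generator emulates the
# statistical structure the downstream analyses assume: Poisson DNM counts
# rising with paternal age, a ~75/25 paternal/maternal origin split for
# unclustered germline SNVs, maternally biased clustered DNMs preferentially
# placed near de novo CNVs, a low-allelic-fraction somatic component, and
# predictor scores drawn from benign/damaging mixtures whose weights (not the
# simulator) decide tier membership through the tier engine.

#' Parameters for the trio cohort simulator
#'
#' Defaults reproduce the headline cohort conditions of a 200-trio autism
#' whole-genome study with a 258-trio population control set: 50.9 germline
#' de novo SNVs, 3.9 indels and 0.052 de novo CNVs per genome, 75.6% of
#' phased germline SNVs paternal, 85% of clustered DNMs maternal, 44% of
#' clustered DNMs within 200 bp, and a somatic (post-zygotic) component with
#' allelic fractions centred near 0.2.
#'
#' Predictor scores are drawn from two-component benign/damaging mixtures.
#' The per-region damaging weights (`damaging_weights`, on top of the region
#' composition `region_probs`) are the only dials: a damaging draw receives
#' scores that satisfy the corresponding tier-1 rule, a benign draw receives
#' scores that do not, so the realized tier-1 fraction equals
#' `sum(region_probs * damaging_weights)` up to binomial noise, and the
#' case/control odds ratio on the damaging label is `damaging_or` (applied
#' as a logit shift on each region weight).
#'
#' @param n_case_trios,n_control_trios Cohort sizes.
#' @param mean_dnm_per_genome Mean germline de novo SNVs per genome.
#' @param indel_mean Mean germline de novo indels per genome.
#' @param paternal_fraction Probability an unclustered germline DNM is
#'   paternal in origin.
#' @param paternal_age_slope Additional expected germline SNVs per year of
#'   paternal age (applied around the centre of `age_range`). Indel counts
#'   use the same slope scaled by `indel_mean / mean_dnm_per_genome`.
#' @param age_range Paternal age range (years), sampled uniformly.
#' @param somatic_fraction Fraction of all DNM calls that are somatic
#'   (post-zygotic) rather than germline.
#' @param somatic_af_beta,germline_af_beta Beta shape parameters for allelic
#'   fractions. Defaults Beta(4,16) (mean 0.2) and Beta(30,30) (mean 0.5):
#'   the <1/3 classifier separates the classes but with overlap.
#' @param cluster_rate Mean number of DNM clusters per genome.
#' @param cluster_maternal_fraction Probability a cluster originates on the
#'   maternal lineage.
#' @param sub200_cluster_mass Probability a cluster spans under 200 bp.
#' @param cnv_per_genome Mean de novo CNVs (>10 kb) per genome.
#' @param near_cnv_rate_multiplier Rate elevation for cluster placement
#'   inside +/-100 kb windows around a carrier's de novo CNVs (>= 1).
#' @param damaging_or Case/control odds ratio applied to the damaging
#'   mixture weights.
#' @param gc_confounding Strength of the GC placement bias for case-cohort
#'   variants (log-weight per SD of 50 bp flanking GC); 0 disables it.
#' @param phased_fraction Fraction of records whose parent-of-origin is
#'   observed (the rest are reported `unknown`; truth is retained).
#' @param depth_mean Mean sequencing depth for allele-depth draws.
#' @param ti_fraction Probability an SNV is a transition (default 2/3,
#'   i.e. Ti/Tv = 2, the value typical of germline point mutations).
#' @param region_probs Named composition of region classes.
#' @param damaging_weights Named per-region damaging mixture weights.
#' @param seed Integer seed; identical seed gives identical output.
#' @return A list of class `trio_sim_params`.
#' @export
trio_sim_params <- function(n_case_trios = 200, n_control_trios = 258,
                            mean_dnm_per_genome = 50.9,
                            indel_mean = 3.9,
                            paternal_fraction = 0.756,
                            paternal_age_slope = 1.0,
                            age_range = c(20, 45),
                            somatic_fraction = 0.059,
                            somatic_af_beta = c(4, 16),
                            germline_af_beta = c(30, 30),
                            cluster_rate = 0.55,
                            cluster_maternal_fraction = 0.85,
                            sub200_cluster_mass = 0.44,
                            cnv_per_genome = 0.052,
                            near_cnv_rate_multiplier = 200,
                            damaging_or = 1.84,
                            gc_confounding = 0,
                            phased_fraction = 1.0,
                            depth_mean = 32,
                            ti_fraction = 2/3,
                            region_probs = c(coding_exonic = 0.019,
                                             splice_core = 0.001,
                                             splicing_site = 0.004,
                                             utr5 = 0.002, utr3 = 0.008,
                                             intronic = 0.35, lncRNA = 0.02,
                                             nongenic = 0.596),
                            damaging_weights = c(coding_exonic = 0.8,
                                                 splice_core = 1,
                                                 splicing_site = 0.5,
                                                 utr5 = 1, utr3 = 0.3,
                                                 intronic = 0.005, lncRNA = 0,
                                                 nongenic = 0.006),
                            seed = 1L) {
  p <- as.list(environment())
  fracs <- c(paternal_fraction, somatic_fraction, cluster_maternal_fraction,
             sub200_cluster_mass, phased_fraction)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (near_cnv_rate_multiplier < 1) stop("near_cnv_rate_multiplier must be >= 1")
  if (damaging_or <= 0) stop("damaging_or must be positive")
  stopifnot(abs(sum(region_probs) - 1) < 1e-8,
            all(names(damaging_weights) == names(region_probs)))
  class(p) <- "trio_sim_params"
  p
}

#' Simulate a reference genome
#'
#' I.i.d. bases with expected GC content `gc_target` (A/T and G/C split
#' evenly within their classes); byte-identical for identical seeds.
#'
#' @param n_contigs Number of contigs.
#' @param contig_length Length of each contig (>= 1000 bp).
#' @param gc_target Target GC fraction, strictly inside (0, 1).
#' @param seed Integer seed.
#' @return A named `DNAStringSet` (contig1, contig2, ...).
#' @export
simulate_reference <- function(n_contigs = 8, contig_length = 12.5e6,
                               gc_target = 0.41, seed = 1L) {
  if (gc_target <= 0 || gc_target >= 1) stop("gc_target must lie strictly in (0, 1)")
  if (contig_length < 1000) stop("contig_length must be >= 1000")
  with_substream(seed, "reference", {
    # ASCII codes for A, C, G, T; rawToChar keeps this fast at genome scale
    codes <- as.raw(c(65L, 67L, 71L, 84L))
    prob <- c((1 - gc_target) / 2, gc_target / 2, gc_target / 2,
              (1 - gc_target) / 2)
    seqs <- vapply(seq_len(n_contigs), function(i) {
      rawToChar(sample(codes, contig_length, replace = TRUE, prob = prob))
    }, character(1))
    ref <- Biostrings::DNAStringSet(seqs)
    names(ref) <- paste0("contig", seq_len(n_contigs))
    ref
  })
}

# Map uniform draws over the concatenated genome to (contig index, pos).
.place_uniform <- function(n, contig_len) {
  total <- sum(contig_len)
  u <- floor(runif(n) * total)
  cs <- cumsum(c(0, contig_len))
  ci <- findInterval(u, cs, rightmost.closed = TRUE)
  list(contig = ci, pos = as.integer(u - cs[ci] + 1L))
}

# Vectorized 50 bp flanking GC for (contig index, pos) pairs.
.flank_gc <- function(reference, contig, pos, flank = 50L) {
  len <- Biostrings::width(reference)
  gc <- numeric(length(pos))
  for (i in unique(contig)) {
    sel <- contig == i
    v <- Biostrings::Views(reference[[i]],
                           start = pmax(1L, pos[sel] - flank),
                           end = pmin(len[i], pos[sel] + flank))
    lf <- Biostrings::letterFrequency(v, c("G", "C"))
    gc[sel] <- rowSums(lf) / BiocGenerics::width(v)
  }
  gc
}

# Reference base(s) at (contig index, pos); width 1 or 2.
.ref_base <- function(reference, contig, pos, width = 1L) {
  out <- character(length(pos))
  for (i in unique(contig)) {
    sel <- contig == i
    out[sel] <- as.character(Biostrings::Views(reference[[i]], pos[sel],
                                               pos[sel] + width - 1L))
  }
  out
}

#' Simulate a trio cohort with known ground truth
#'
#' Generates trio metadata, de novo CNV events, and per-trio DNM records
#' (germline unclustered, clustered, and somatic), with predictor scores
#' drawn from benign/damaging mixtures. Every latent label is recorded in
#' the returned truth table.
#'
#' @param params A [trio_sim_params] object.
#' @param reference A `DNAStringSet`, e.g. from [simulate_reference].
#' @return List with elements `records` ([dnm_records]), `cnvs`
#'   ([cnv_events] table, possibly empty), `trios` ([trio_meta]), and
#'   `truth` (one row per record: true_class, clustered, cluster_id,
#'   true_origin, damaging, near_cnv).
#' @export
simulate_trio_cohort <- function(params, reference) {
  stopifnot(inherits(params, "trio_sim_params"))
  p <- params
  contig_len <- Biostrings::width(reference)
  genome_bp <- sum(as.numeric(contig_len))
  n_trios <- p$n_case_trios + p$n_control_trios
  exp_total <- n_trios * (p$mean_dnm_per_genome + p$indel_mean + 3) * 1.5
  if (exp_total > genome_bp / 100) {
    stop("reference too short to place the requested cohort's variants")
  }

  trios <- with_substream(p$seed, "trios", {
    ids <- c(sprintf("case_%03d", seq_len(p$n_case_trios)),
             sprintf("ctrl_%03d", seq_len(p$n_control_trios)))
    cohort <- rep(c("case", "control"), c(p$n_case_trios, p$n_control_trios))
    pat <- runif(n_trios, p$age_range[1], p$age_range[2])
    mat <- pmax(18, pat - 2 + rnorm(n_trios, 0, 3))
    sex <- ifelse(runif(n_trios) < ifelse(cohort == "case", 0.8, 0.5),
                  "male", "female")
    trio_meta(data.frame(sample_id = ids, paternal_age = pat,
                         maternal_age = mat, sex = sex,
                         dna_source = "whole_blood", cohort = cohort,
                         stringsAsFactors = FALSE))
  })

  cnvs <- with_substream(p$seed, "cnvs", {
    k <- rpois(n_trios, p$cnv_per_genome)
    if (sum(k) == 0) {
      df <- data.frame(sample_id = character(), chrom = character(),
                       start = integer(), end = integer(),
                       cnv_type = character(), origin = character(),
                       stringsAsFactors = FALSE)
    } else {
      carrier <- rep(trios$sample_id, k)
      len <- as.integer(runif(sum(k), 2e4, 3e5))
      pl <- .place_uniform(sum(k), contig_len)
      start <- pmin(pl$pos, contig_len[pl$contig] - len - 1L)
      start <- pmax(start, 0L)
      df <- data.frame(sample_id = carrier,
                       chrom = names(reference)[pl$contig],
                       start = start, end = start + len,
                       cnv_type = sample(c("gain", "loss"), sum(k), TRUE),
                       origin = sample(c("paternal", "maternal"), sum(k), TRUE),
                       stringsAsFactors = FALSE)
    }
    if (nrow(df)) cnv_events(df) else df
  })

  mid_age <- mean(p$age_range)
  counts <- with_substream(p$seed, "counts", {
    lam_snv <- pmax(1, p$mean_dnm_per_genome +
                      p$paternal_age_slope * (trios$paternal_age - mid_age))
    scale <- p$indel_mean / p$mean_dnm_per_genome
    lam_ind <- pmax(0.1, p$indel_mean +
                      p$paternal_age_slope * scale * (trios$paternal_age - mid_age))
    lam_som <- p$mean_dnm_per_genome * p$somatic_fraction / (1 - p$somatic_fraction)
    list(snv = rpois(n_trios, lam_snv), indel = rpois(n_trios, lam_ind),
         somatic = rpois(n_trios, lam_som),
         clusters = rpois(n_trios, p$cluster_rate))
  })

  # -- placement ------------------------------------------------------------
  # Unclustered records are uniform genome-wide; when gc_confounding > 0,
  # case-cohort records are weight-resampled toward GC-rich 50 bp flanks.
  # Clusters of CNV carriers fall inside the +/-100 kb CNV windows with
  # probability min(1, multiplier * window_fraction).
  placed <- with_substream(p$seed, "placement", {
    n_unc <- counts$snv + counts$indel + counts$somatic
    tot_unc <- sum(n_unc)
    prop_n <- if (p$gc_confounding > 0) tot_unc * 3L else tot_unc
    pl <- .place_uniform(prop_n, contig_len)
    keep <- seq_len(tot_unc)
    if (p$gc_confounding > 0) {
      owner_case <- rep(trios$cohort, n_unc) == "case"
      gc <- .flank_gc(reference, pl$contig, pl$pos)
      z <- (gc - mean(gc)) / max(sd(gc), 1e-8)
      w <- exp(p$gc_confounding * z)
      idx_all <- seq_len(prop_n)
      case_n <- sum(owner_case)
      pick_case <- sample(idx_all, case_n, replace = FALSE, prob = w)
      rest <- setdiff(idx_all, pick_case)
      pick_ctrl <- rest[seq_len(tot_unc - case_n)]
      keep <- integer(tot_unc)
      keep[owner_case] <- pick_case
      keep[!owner_case] <- pick_ctrl
    }
    list(contig = pl$contig[keep], pos = pl$pos[keep], n_unc = n_unc)
  })

  clusters <- with_substream(p$seed, "clusters", {
    n_cl <- counts$clusters
    if (sum(n_cl) == 0) NULL else {
    owner <- rep(seq_len(n_trios), n_cl)
    sizes <- 2L + rpois(sum(n_cl), 0.25)
    span <- ifelse(runif(sum(n_cl)) < p$sub200_cluster_mass,
                   runif(sum(n_cl), 2, 200), runif(sum(n_cl), 200, 20000))
    maternal <- runif(sum(n_cl)) < p$cluster_maternal_fraction
    pl <- .place_uniform(sum(n_cl), contig_len)
    contig <- pl$contig; center <- pl$pos; near_cnv <- logical(sum(n_cl))
    flank <- 1e5
    for (j in seq_len(sum(n_cl))) {
      sid <- trios$sample_id[owner[j]]
      cv <- cnvs[cnvs$sample_id == sid, , drop = FALSE]
      if (!nrow(cv)) next
      wlo <- pmax(0, cv$start - flank)
      whi <- pmin(contig_len[match(cv$chrom, names(reference))], cv$end + flank)
      wbp <- sum(whi - wlo)
      if (runif(1) < min(1, p$near_cnv_rate_multiplier * wbp / genome_bp)) {
        k <- sample.int(nrow(cv), 1, prob = whi - wlo)
        contig[j] <- match(cv$chrom[k], names(reference))
        center[j] <- as.integer(runif(1, wlo[k] + 1, whi[k]))
        near_cnv[j] <- TRUE
      }
    }
    offs <- lapply(seq_len(sum(n_cl)), function(j) {
      s <- sizes[j]
      off <- if (s == 2L) c(0, span[j]) else c(0, sort(runif(s - 2L, 0, span[j])), span[j])
      as.integer(round(off))
    })
    list(owner = owner, sizes = sizes, contig = contig, center = center,
         maternal = maternal, near_cnv = near_cnv, offs = offs)
    }
  })

  # -- assemble per-record frames -------------------------------------------
  n_unc <- placed$n_unc
  owner_unc <- rep(seq_len(n_trios), n_unc)
  class_unc <- unlist(lapply(seq_len(n_trios), function(i) {
    rep(c("germline", "indel", "somatic"),
        c(counts$snv[i], counts$indel[i], counts$somatic[i]))
  }), use.names = FALSE)
  rec <- data.frame(owner = owner_unc, contig = placed$contig,
                    pos = placed$pos, true_class = class_unc,
                    clustered = FALSE, cluster_id = NA_integer_,
                    near_cnv = FALSE, stringsAsFactors = FALSE)
  if (!is.null(clusters)) {
    cl_rows <- do.call(rbind, lapply(seq_along(clusters$owner), function(j) {
      pos <- pmin(pmax(clusters$center[j] + clusters$offs[[j]], 2L),
                  contig_len[clusters$contig[j]] - 1L)
      data.frame(owner = clusters$owner[j], contig = clusters$contig[j],
                 pos = unique(pos), true_class = "germline",
                 clustered = TRUE, cluster_id = j,
                 near_cnv = clusters$near_cnv[j], stringsAsFactors = FALSE)
    }))
    rec <- rbind(rec, cl_rows)
  }
  n <- nrow(rec)

  origins <- with_substream(p$seed, "origins", {
    o <- character(n)
    unc_g <- !rec$clustered & rec$true_class %in% c("germline", "indel")
    o[unc_g] <- ifelse(runif(sum(unc_g)) < p$paternal_fraction,
                       "paternal", "maternal")
    som <- rec$true_class == "somatic"
    o[som] <- sample(c("paternal", "maternal"), sum(som), TRUE)
    if (!is.null(clusters)) {
      cl <- which(rec$clustered)
      o[cl] <- ifelse(clusters$maternal[rec$cluster_id[cl]],
                      "maternal", "paternal")
    }
    o
  })

  depths <- with_substream(p$seed, "depths", {
    som <- rec$true_class == "somatic"
    af <- numeric(n)
    af[som] <- rbeta(sum(som), p$somatic_af_beta[1], p$somatic_af_beta[2])
    af[!som] <- rbeta(sum(!som), p$germline_af_beta[1], p$germline_af_beta[2])
    dp <- pmax(10L, rpois(n, p$depth_mean))
    alt <- pmax(1L, rbinom(n, dp, af))
    list(dp = dp, alt = alt)
  })

  alleles <- with_substream(p$seed, "alleles", {
    is_indel <- rec$true_class == "indel"
    ref1 <- .ref_base(reference, rec$contig, rec$pos)
    # transition partner, and the two transversion partners, per base
    ti_map <- c(A = "G", G = "A", C = "T", T = "C")
    tv_map <- rbind(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))
    is_ti <- runif(n) < p$ti_fraction
    alt <- ifelse(is_ti, ti_map[ref1],
                  tv_map[cbind(match(ref1, rownames(tv_map)),
                               1L + (runif(n) < 0.5))])
    ref <- ref1
    if (any(is_indel)) {
      del <- is_indel & runif(n) < 0.5
      ins <- is_indel & !del
      ref[del] <- .ref_base(reference, rec$contig[del], rec$pos[del], width = 2L)
      alt[del] <- substr(ref[del], 1, 1)
      ref[ins] <- ref1[ins]
      alt[ins] <- paste0(ref1[ins], sample(c("A", "C", "G", "T"), sum(ins), TRUE))
    }
    list(ref = ref, alt = alt)
  })

  # Damaging label first, at the aggregate qualifying rate (logit-shifted
  # by log(damaging_or) for case records), then region conditional on the
  # label: the case/control odds ratio of tier-qualifying status equals
  # damaging_or without saturating the per-region weights, and cases end
  # up modestly enriched for high-weight regions (coding), as real cohorts
  # are.
  scored <- with_substream(p$seed, "scores", {
    d0 <- sum(p$region_probs * p$damaging_weights)
    is_case <- trios$cohort[rec$owner] == "case"
    pq <- ifelse(is_case, plogis(qlogis(d0) + log(p$damaging_or)), d0)
    D <- runif(n) < pq
    pr1 <- p$region_probs * p$damaging_weights
    pr0 <- p$region_probs * (1 - p$damaging_weights)
    region <- character(n)
    region[D] <- sample(names(pr1), sum(D), TRUE, prob = pr1)
    region[!D] <- sample(names(pr0), sum(!D), TRUE, prob = pr0)
    .draw_scores(region, D)
  })

  phased <- with_substream(p$seed, "phasing", {
    runif(n) < p$phased_fraction
  })

  records <- data.frame(
    sample_id = trios$sample_id[rec$owner],
    cohort = trios$cohort[rec$owner],
    chrom = names(reference)[rec$contig],
    pos = rec$pos, ref = alleles$ref, alt = alleles$alt,
    ad_ref = depths$dp - depths$alt, ad_alt = depths$alt,
    origin = ifelse(phased, origins, "unknown"),
    region_class = scored$region, gene = scored$gene,
    stringsAsFactors = FALSE
  )
  records <- cbind(records, scored$scores)
  ord <- order(records$chrom, records$pos, records$sample_id)
  truth <- data.frame(
    true_class = ifelse(rec$true_class == "somatic", "somatic", "germline"),
    var_type = ifelse(rec$true_class == "indel", "indel", "SNV"),
    clustered = rec$clustered, cluster_id = rec$cluster_id,
    true_origin = origins, damaging = scored$damaging,
    near_cnv = rec$near_cnv, stringsAsFactors = FALSE
  )[ord, , drop = FALSE]
  rownames(truth) <- NULL
  list(records = dnm_records(records[ord, , drop = FALSE]),
       cnvs = cnvs, trios = trios, truth = truth)
}

# Benign/damaging score mixtures. A damaging draw satisfies the tier-1 rule
# of its region; a benign draw does not. Tier-2 sub-rules then fire with the
# documented conditional rates (missense criteria each met w.p. 0.85;
# qualifying dPSI uniform on (-10, -3.6); 3'UTR PhyloP >= 1.5 w.p. 0.7;
# DeepBind-loss sites in DHS w.p. 0.6).
.draw_scores <- function(region, D) {
  n <- length(region)
  sc <- data.frame(
    sift = runif(n, 0.1, 1), polyphen2 = runif(n, 0, 0.8),
    mut_assessor = runif(n, -1, 1.5), mut_taster = runif(n, 0, 0.45),
    cadd_phred = runif(n, 0, 12), phylop_mam = rnorm(n, 0, 1),
    phylop_vert100 = rnorm(n, 0, 1.5), phastcons = 0,
    dpsi = NA_real_, deepbind_wt_pct = runif(n, 0, 99),
    deepbind_var_pct = runif(n, 0, 100),
    is_lof = FALSE, is_missense = FALSE, is_synonymous = FALSE,
    dhs_overlap = runif(n) < 0.15, tx_proximal = runif(n) < 0.2,
    stringsAsFactors = FALSE
  )
  # sprinkle missingness over optional numeric scores
  for (cc in c("sift", "polyphen2", "mut_assessor", "mut_taster", "cadd_phred")) {
    sc[[cc]][runif(n) < 0.15] <- NA_real_
  }
  cod <- region == "coding_exonic"
  sc$is_missense[cod & D] <- runif(sum(cod & D)) < 0.9
  sc$is_lof[cod & D & !sc$is_missense] <- TRUE
  sc$is_synonymous[cod & !D] <- TRUE
  mis <- sc$is_missense
  # damaging missense: each of the 7 criteria met independently w.p. 0.85
  nmis <- sum(mis)
  if (nmis) {
    met <- matrix(runif(nmis * 7) < 0.85, nmis, 7)
    sc$phylop_mam[mis] <- ifelse(met[, 1], runif(nmis, 2.3, 5), runif(nmis, -1, 2.2))
    sc$phylop_vert100[mis] <- ifelse(met[, 2], runif(nmis, 4, 9), runif(nmis, -2, 3.9))
    sc$sift[mis] <- ifelse(met[, 3], runif(nmis, 0, 0.049), runif(nmis, 0.05, 1))
    sc$polyphen2[mis] <- ifelse(met[, 4], runif(nmis, 0.9, 1), runif(nmis, 0, 0.89))
    sc$mut_assessor[mis] <- ifelse(met[, 5], runif(nmis, 1.9, 4), runif(nmis, -1, 1.8))
    sc$mut_taster[mis] <- ifelse(met[, 6], runif(nmis, 0.5, 1), runif(nmis, 0, 0.49))
    sc$cadd_phred[mis] <- ifelse(met[, 7], runif(nmis, 15, 40), runif(nmis, 0, 14.9))
  }
  sc$is_lof[region == "splice_core"] <- TRUE
  spl <- region %in% c("splicing_site", "intronic") & D
  sc$dpsi[spl] <- runif(sum(spl), -10, -3.6)
  sc$dpsi[region == "splicing_site" & !D] <- runif(sum(region == "splicing_site" & !D), -3, 3)
  u3 <- region == "utr3"
  sc$phastcons[u3 & D] <- runif(sum(u3 & D), 0.05, 1)
  sc$phylop_mam[u3 & D] <- ifelse(runif(sum(u3 & D)) < 0.7,
                                  runif(sum(u3 & D), 1.5, 4),
                                  runif(sum(u3 & D), -1, 1.4))
  ng <- region == "nongenic"
  sc$deepbind_wt_pct[ng & D] <- runif(sum(ng & D), 99.9, 100)
  sc$deepbind_var_pct[ng & D] <- runif(sum(ng & D), 0, 99)
  sc$phastcons[ng & D] <- runif(sum(ng & D), 0.05, 1)
  sc$dhs_overlap[ng & D] <- runif(sum(ng & D)) < 0.6
  # benign nongenic never reaches the DeepBind wild-type cut (capped at 99)
  genic <- !region %in% "nongenic"
  gene <- ifelse(genic, sprintf("G%04d", sample.int(1500, n, TRUE)), NA_character_)
  list(region = region, scores = sc, gene = gene, damaging = D)
}

#' Simulate variant-level data for burden-test calibration
#'
#' Direct generator for the GC-confounded logistic burden design: each
#' variant has a 50 bp flanking GC value, a cohort label whose odds depend
#' on GC (the confounding path), and a tested-set membership whose odds
#' depend on both GC and cohort. The conditional (GC-adjusted) case/control
#' odds ratio for membership is exactly `damaging_or`; when
#' `gc_confounding > 0` a GC-free fit is biased away from it.
#'
#' @param n_variants Number of variants.
#' @param damaging_or True conditional odds ratio of membership for case vs
#'   control variants.
#' @param gc_confounding Log-odds effect (per SD of GC) of GC on both cohort
#'   and membership.
#' @param member_rate Baseline membership rate at mean GC in controls.
#' @param seed Integer seed.
#' @return data.frame with columns `cohort`, `gc`, `member`.
#' @export
simulate_burden_variants <- function(n_variants, damaging_or = 1,
                                     gc_confounding = 0,
                                     member_rate = 0.05, seed = 1L) {
  with_substream(seed, "burden_variants", {
    gc <- rbeta(n_variants, 9.5, 13.7)       # mean ~0.41, sd ~0.10
    z <- (gc - 0.41) / 0.10
    case <- runif(n_variants) < plogis(gc_confounding * z)
    eta <- qlogis(member_rate) + gc_confounding * z + log(damaging_or) * case
    member <- runif(n_variants) < plogis(eta)
    data.frame(cohort = ifelse(case, "case", "control"), gc = gc,
               member = member, stringsAsFactors = FALSE)
  })
}
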
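# Somatic/germline classification, clustered-DNM detection, parent-of-origin
# contrasts, paternal/maternal age models, and the CNV-proximity
# mutation-rate test.

#' Classify records as germline or somatic candidates by allelic fraction
#'
#' Post-zygotic (somatic/mosaic) mutations sit at lower allelic fractions
#' than the ~50% expected for constitutional heterozygotes. The fixed rule
#' flags records below 1/3 (two SDs below the cohort mean in the motivating
#' data); the adaptive rule recomputes the threshold as mean - 2*SD of the
#' cohort's SNV allelic-fraction distribution.
#'
#' @param records A [dnm_records] table.
#' @param mode "fixed" or "adaptive".
#' @param fixed_threshold Threshold for fixed mode (default 1/3).
#' @return List with `labels` ("germline"/"somatic_candidate" per record)
#'   and `threshold` (the threshold actually applied).
#' @export
classify_somatic <- function(records, mode = c("fixed", "adaptive"),
                             fixed_threshold = 1/3) {
  mode <- match.arg(mode)
  af <- allelic_fraction(records)
  thr <- if (mode == "fixed") {
    fixed_threshold
  } else {
    snv <- af[records$var_type == "SNV"]
    if (length(snv) < 30) {
      stop("adaptive mode needs >= 30 records (SD would be unstable)")
    }
    mean(snv) - 2 * sd(snv)
  }
  list(labels = ifelse(af < thr, "somatic_candidate", "germline"),
       threshold = thr)
}

#' Find clustered DNMs
#'
#' Two or more mutations of one individual within a 20 kb segment. With the
#' default `rule = "gap"`, same-sample same-chrom records are chained
#' transitively whenever consecutive sorted positions are at most `window`
#' apart (boundary inclusive: a gap of exactly `window` joins), and maximal
#' chains of size >= 2 are reported. `rule = "span"` instead cuts a chain
#' when its total span would exceed `window`.
#'
#' @param records A [dnm_records] table.
#' @param window Window in bp (default 20000).
#' @param rule "gap" (transitive chaining, order-independent) or "span".
#' @return List with `calls` (one row per cluster: cluster_id, sample_id,
#'   chrom, n_members, span, max_gap) and `members` (cluster_id, row index
#'   into `records`).
#' @export
find_clusters <- function(records, window = 20000, rule = c("gap", "span")) {
  rule <- match.arg(rule)
  empty <- list(
    calls = data.frame(cluster_id = integer(), sample_id = character(),
                       chrom = character(), n_members = integer(),
                       span = integer(), max_gap = integer(),
                       stringsAsFactors = FALSE),
    members = data.frame(cluster_id = integer(), row = integer())
  )
  if (nrow(records) < 2) return(empty)
  ord <- order(records$sample_id, records$chrom, records$pos)
  s <- records$sample_id[ord]; ch <- records$chrom[ord]; pos <- records$pos[ord]
  gap <- c(Inf, pos[-1] - pos[-length(pos)])
  newgrp <- c(TRUE, s[-1] != s[-length(s)] | ch[-1] != ch[-length(ch)])
  gap[newgrp] <- Inf
  if (rule == "gap") {
    grp <- cumsum(gap > window)
  } else {
    # greedy left-to-right: start a new cluster when the running span
    # from the current cluster anchor would exceed the window
    grp <- integer(length(pos)); g <- 0L; anchor <- -Inf
    for (i in seq_along(pos)) {
      if (is.infinite(gap[i]) || pos[i] - anchor > window) {
        g <- g + 1L; anchor <- pos[i]
      }
      grp[i] <- g
    }
  }
  tab <- tabulate(grp)
  keep <- which(tab[grp] >= 2L)
  if (!length(keep)) return(empty)
  grp_k <- grp[keep]
  ids <- match(grp_k, unique(grp_k))
  members <- data.frame(cluster_id = ids, row = ord[keep])
  sp <- vapply(split(pos[keep], ids), function(x) diff(range(x)), numeric(1))
  mg <- vapply(split(pos[keep], ids), function(x) max(diff(sort(x))), numeric(1))
  first <- !duplicated(ids)
  calls <- data.frame(
    cluster_id = ids[first],
    sample_id = s[keep][first], chrom = ch[keep][first],
    n_members = as.integer(table(ids)),
    span = as.integer(sp), max_gap = as.integer(mg),
    stringsAsFactors = FALSE
  )
  list(calls = calls, members = members)
}

#' Parent-of-origin contrast between clustered and unclustered DNMs
#'
#' Builds the 2x2 table (clustered/unclustered x paternal/maternal) over
#' germline records with known origin and applies the two-sided Fisher exact
#' test (minimum-likelihood enumeration convention). Records labelled
#' somatic candidates and unknown-origin records are excluded.
#'
#' @param records A [dnm_records] table.
#' @param clusters Output of [find_clusters] on the same records.
#' @param somatic_labels Optional per-record labels from [classify_somatic];
#'   records labelled "somatic_candidate" are dropped.
#' @return List: `table` (2x2), `odds_ratio` (conditional MLE), `p`,
#'   `maternal_fraction` (named, clustered/unclustered).
#' @export
origin_contrast <- function(records, clusters, somatic_labels = NULL) {
  keep <- records$origin %in% c("paternal", "maternal")
  if (!is.null(somatic_labels)) keep <- keep & somatic_labels != "somatic_candidate"
  clustered <- seq_len(nrow(records)) %in% clusters$members$row
  tab <- table(
    factor(ifelse(clustered[keep], "clustered", "unclustered"),
           c("clustered", "unclustered")),
    factor(records$origin[keep], c("paternal", "maternal"))
  )
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warning("a margin of the origin table is zero; p set to 1")
    return(list(table = tab, odds_ratio = NA_real_, p = 1,
                maternal_fraction = c(clustered = NA_real_,
                                      unclustered = NA_real_)))
  }
  ft <- fisher.test(tab)
  list(table = tab,
       odds_ratio = unname(ft$estimate),
       p = ft$p.value,
       maternal_fraction = c(
         clustered = tab["clustered", "maternal"] / sum(tab["clustered", ]),
         unclustered = tab["unclustered", "maternal"] / sum(tab["unclustered", ])
       ))
}

#' Maternal-fraction contrast by intra-cluster distance
#'
#' Each clustered DNM is assigned its nearest-neighbour distance within its
#' cluster; the 2x2 of (distance < cutoff vs >= cutoff) x (paternal vs
#' maternal) is tested with the two-sided Fisher exact test.
#'
#' @param records A [dnm_records] table.
#' @param clusters Output of [find_clusters].
#' @param cutoff Distance cutoff in bp (default 200).
#' @return List: `table`, `p`, `maternal_fraction` (named, under/over
#'   cutoff).
#' @export
distance_contrast <- function(records, clusters, cutoff = 200) {
  if (!nrow(clusters$members)) stop("no clusters to contrast")
  if (!is.finite(cutoff)) stop("cutoff must be finite (a single distance group is undefined)")
  m <- clusters$members
  nn <- unlist(lapply(split(m$row, m$cluster_id), function(rows) {
    p <- records$pos[rows]
    vapply(seq_along(p), function(i) min(abs(p[-i] - p[i])), numeric(1))
  }), use.names = FALSE)
  rows <- unlist(split(m$row, m$cluster_id), use.names = FALSE)
  ori <- records$origin[rows]
  known <- ori %in% c("paternal", "maternal")
  if (!any(known)) stop("no clustered records with known origin")
  grp <- factor(ifelse(nn[known] < cutoff, "under", "over"), c("under", "over"))
  tab <- table(grp, factor(ori[known], c("paternal", "maternal")))
  if (any(rowSums(tab) == 0)) {
    stop("one distance group is empty at cutoff ", cutoff)
  }
  ft <- fisher.test(tab)
  list(table = tab, p = ft$p.value,
       maternal_fraction = c(
         under = tab["under", "maternal"] / sum(tab["under", ]),
         over = tab["over", "maternal"] / sum(tab["over", ])
       ))
}

#' Mutation-rate elevation near de novo CNVs
#'
#' Windows are the union over CNVs of [start - flank, end + flank] (CNV body
#' included, clipped at contig bounds). The observed count is the number of
#' DNMs falling in windows and is compared with the genome-background
#' expectation by an upper-tail exact binomial test. With
#' `same_individual = TRUE` (default) only the CNV carrier's own DNMs and
#' windows count, and the per-trial background probability is the weighted
#' average of each carrier's own window fraction; with `FALSE` all DNMs are
#' tested against the pooled window union, probability
#' `window_bp / genome_bp`.
#'
#' @param records A [dnm_records] table.
#' @param cnvs A [cnv_events] table.
#' @param flank Flank in bp (default 1e5; must be >= 0).
#' @param genome_bp Total genome size in bp.
#' @param seqlens Optional named contig lengths for clipping.
#' @param same_individual Count only the carrier's own DNMs (default TRUE).
#' @return List of class `proximity_test`: observed, expected, window_bp,
#'   genome_bp, total_dnms, p.
#' @export
cnv_proximity_test <- function(records, cnvs, flank = 1e5, genome_bp,
                               seqlens = NULL, same_individual = TRUE) {
  if (flank < 0) stop("flank must be >= 0")
  if (!nrow(cnvs)) stop("no CNV events supplied")
  lo <- pmax(0, cnvs$start - flank)
  hi <- cnvs$end + flank
  if (!is.null(seqlens)) hi <- pmin(hi, seqlens[cnvs$chrom])
  # keep window rows aligned with cnvs rows (no sorting) for carrier matching
  win <- GenomicRanges::GRanges(cnvs$chrom, IRanges::IRanges(lo + 1L, hi))
  window_bp <- interval_union_length(win)
  if (genome_bp <= window_bp) stop("genome_bp must exceed the window union")
  sub <- if (same_individual) {
    records[records$sample_id %in% cnvs$sample_id, , drop = FALSE]
  } else records
  total <- nrow(sub)
  inwin <- logical(total)
  if (total) {
    gr <- GenomicRanges::GRanges(sub$chrom, IRanges::IRanges(sub$pos, sub$pos))
    ov <- GenomicRanges::findOverlaps(gr, win)
    hitrow <- S4Vectors::queryHits(ov)
    if (same_individual) {
      hitrow <- hitrow[sub$sample_id[hitrow] ==
                         cnvs$sample_id[S4Vectors::subjectHits(ov)]]
    }
    inwin[unique(hitrow)] <- TRUE
  }
  observed <- sum(inwin)
  pr <- if (same_individual && total) {
    # each carrier DNM can only fall in that carrier's own windows
    carrier_w <- vapply(unique(sub$sample_id), function(sid) {
      sel <- cnvs$sample_id == sid
      interval_union_length(interval_set(cnvs$chrom[sel], lo[sel], hi[sel]))
    }, numeric(1))
    n_i <- table(factor(sub$sample_id, names(carrier_w)))
    sum(as.numeric(n_i) * carrier_w) / (total * genome_bp)
  } else {
    window_bp / genome_bp
  }
  res <- list(observed = observed, expected = total * pr,
              window_bp = window_bp, genome_bp = genome_bp,
              total_dnms = total,
              p = pbinom(observed - 1L, total, pr, lower.tail = FALSE))
  class(res) <- "proximity_test"
  res
}

#' Per-trio phased DNM counts
#'
#' Counts of paternal- and maternal-phased germline SNVs and of total indels
#' per proband, the inputs to [age_models].
#'
#' @param records A [dnm_records] table (germline records).
#' @param trios A [trio_meta] table.
#' @return data.frame keyed by sample_id.
#' @export
per_trio_counts <- function(records, trios) {
  f <- factor(records$sample_id, levels = trios$sample_id)
  snv <- records$var_type == "SNV"
  data.frame(
    sample_id = trios$sample_id,
    paternal_snv = as.integer(table(f[snv & records$origin == "paternal"])),
    maternal_snv = as.integer(table(f[snv & records$origin == "maternal"])),
    indel_total = as.integer(table(f[records$var_type == "indel"])),
    stringsAsFactors = FALSE
  )
}

#' Parental-age models for DNM counts
#'
#' Pearson correlations between paternal age and paternal-phased SNV count
#' (and the maternal analogue), plus a joint Poisson log-link regression of
#' total indel count on paternal and maternal age with coefficient p-values
#' from the t distribution on n - 3 degrees of freedom.
#'
#' @param trios A [trio_meta] table (>= 10 rows).
#' @param counts Output of [per_trio_counts] aligned to `trios`.
#' @return List: pearson_r_paternal/p, pearson_r_maternal/p,
#'   poisson_beta_paternal/p, poisson_beta_maternal/p.
#' @export
age_models <- function(trios, counts) {
  stopifnot(nrow(trios) == nrow(counts))
  if (nrow(trios) < 10) stop("need >= 10 trios")
  if (sd(trios$paternal_age) == 0 || sd(trios$maternal_age) == 0) {
    stop("zero variance in parental ages")
  }
  safe_cor <- function(x, y) {
    if (sd(y) == 0) return(list(estimate = 0, p.value = 1))
    ct <- cor.test(x, y)
    list(estimate = unname(ct$estimate), p.value = ct$p.value)
  }
  cp <- safe_cor(trios$paternal_age, counts$paternal_snv)
  cm <- safe_cor(trios$maternal_age, counts$maternal_snv)
  fit <- glm(counts$indel_total ~ trios$paternal_age + trios$maternal_age,
             family = poisson())
  cf <- summary(fit)$coefficients
  df <- nrow(trios) - 3
  tp <- cf[2, 1] / cf[2, 2]; tm <- cf[3, 1] / cf[3, 2]
  list(
    pearson_r_paternal = cp$estimate, pearson_p_paternal = cp$p.value,
    pearson_r_maternal = cm$estimate, pearson_p_maternal = cm$p.value,
    poisson_beta_paternal = unname(cf[2, 1]),
    poisson_p_paternal = 2 * pt(-abs(tp), df),
    poisson_beta_maternal = unname(cf[3, 1]),
    poisson_p_maternal = 2 * pt(-abs(tm), df)
  )
}
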
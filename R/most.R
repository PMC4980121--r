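# Methylation Outlier Sample Test (MOST): probe filtering, scaled PCA with
# parallel-analysis component retention, covariate adjustment of PC scores,
# Grubbs outlier testing per component, and a dual FDR rule -- a sample is
# an outlier only when it passes Grubbs FDR < 0.1 on the same PC both
# before and after covariate correction.

#' Filter methylation probes
#'
#' Removes probes (1) on the sex chromosomes, (2) overlapping single
#' nucleotide polymorphisms, and (3) with a detection p-value above 0.05 in
#' any sample (strict: one failing sample removes the probe).
#'
#' @param beta samples x probes matrix of beta values in [0, 1] (column
#'   names are probe IDs).
#' @param annotation data.frame with columns probe, chrom, snp_overlap
#'   aligned to or matchable against `colnames(beta)`.
#' @param detection_p Matrix of detection p-values, same shape as `beta`.
#' @return List of class `beta_matrix`: `beta`, `annotation`,
#'   `removed` (named counts per rule: sex, snp, detection).
#' @export
filter_probes <- function(beta, annotation, detection_p) {
  stopifnot(ncol(beta) == nrow(annotation),
            all(dim(beta) == dim(detection_p)))
  ann <- annotation[match(colnames(beta), annotation$probe), , drop = FALSE]
  sex <- ann$chrom %in% c("chrX", "chrY", "X", "Y")
  snp <- ann$snp_overlap %in% TRUE
  detfail <- colSums(detection_p > 0.05) > 0
  drop <- sex | snp | detfail
  if (all(drop)) stop("no probes remain after filtering")
  out <- list(beta = beta[, !drop, drop = FALSE],
              annotation = ann[!drop, , drop = FALSE],
              removed = c(sex = sum(sex), snp = sum(snp),
                          detection = sum(detfail)))
  class(out) <- "beta_matrix"
  out
}

#' Scaled PCA with randomized-eigenvalue component retention
#'
#' Principal components of the per-probe centered, unit-variance-scaled
#' matrix. The eigenvalue null is built from `n_perm` randomized matrices
#' in which every probe column is independently permuted across samples
#' (parallel analysis); component k is retained when the observed k-th
#' eigenvalue exceeds the maximum k-th eigenvalue over the randomizations
#' (`perm_rule = "per_rank"`, default) or the global maximum across all
#' randomized eigenvalues (`perm_rule = "global"`). Retention is reported
#' as the contiguous run from component 1.
#'
#' @param beta A `beta_matrix` from [filter_probes] or a samples x probes
#'   matrix. Zero-variance probes are dropped with a warning.
#' @param n_pcs Number of components to report (default 20).
#' @param n_perm Number of randomized matrices (default 20).
#' @param seed Integer seed for the randomizations.
#' @param perm_rule "per_rank" or "global".
#' @return List of class `pca_retain`: `scores` (samples x n_pcs),
#'   `loadings` (probes x n_pcs), `eigenvalues`, `perm_max`, `retained_k`,
#'   `n_probes`.
#' @export
pca_retain <- function(beta, n_pcs = 20, n_perm = 20, seed = 1L,
                       perm_rule = c("per_rank", "global")) {
  perm_rule <- match.arg(perm_rule)
  x <- if (inherits(beta, "beta_matrix")) beta$beta else beta
  n <- nrow(x)
  if (n < n_pcs + 2) stop("need at least n_pcs + 2 samples")
  cm <- colMeans(x)
  xc <- x - rep(cm, each = n)
  sds <- sqrt(colSums(xc^2) / (n - 1))
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance probe(s) dropped before PCA")
    xc <- xc[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  x <- xc  # centered; only dims/colnames used below
  xs <- xc / rep(sds, each = n)
  ev_scores <- function(m, values_only = FALSE) {
    # sample-space Gram matrix: eigenvalues match prcomp's sdev^2
    g <- tcrossprod(m) / (nrow(m) - 1)
    e <- eigen(g, symmetric = TRUE, only.values = values_only)
    lam <- pmax(e$values, 0)
    if (values_only) return(list(values = lam))
    list(values = lam, vectors = e$vectors)
  }
  e <- ev_scores(xs)
  lam <- e$values[seq_len(n_pcs)]
  d <- sqrt(pmax(e$values * (n - 1), 0))
  scores <- e$vectors %*% diag(d, n, n)
  scores <- scores[, seq_len(n_pcs), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  rownames(scores) <- rownames(x)
  # loadings: V = X' U / d (unit-norm right singular vectors)
  u <- e$vectors[, seq_len(n_pcs), drop = FALSE]
  dd <- d[seq_len(n_pcs)]; dd[dd == 0] <- 1
  loadings <- crossprod(xs, u) %*% diag(1 / dd, n_pcs, n_pcs)
  dimnames(loadings) <- list(colnames(x), paste0("PC", seq_len(n_pcs)))
  perm_lam <- with_substream(seed, "pca_perm", {
    vapply(seq_len(n_perm), function(b) {
      ev_scores(permute_columns(xs), values_only = TRUE)$values[seq_len(n_pcs)]
    }, numeric(n_pcs))
  })
  perm_max <- if (perm_rule == "per_rank") {
    apply(perm_lam, 1, max)
  } else {
    rep(max(perm_lam), n_pcs)
  }
  above <- lam > perm_max
  retained_k <- if (above[1]) max(which(cumsum(!above) == 0)) else 0L
  out <- list(scores = scores, loadings = loadings, eigenvalues = lam,
              all_eigenvalues = e$values, perm_max = perm_max,
              retained_k = as.integer(retained_k), n_probes = ncol(x))
  class(out) <- "pca_retain"
  out
}

#' Adjust PC scores for sample covariates
#'
#' Per-component ordinary least-squares residuals against the covariate
#' design (categorical covariates expanded to indicators), re-centered.
#' A rank-deficient design is an error naming the aliased columns.
#'
#' @param scores samples x PCs matrix.
#' @param covariates data.frame of per-sample covariates (sex, ethnicity,
#'   age, cell fractions, batch, chip order, ...).
#' @return Matrix of adjusted scores, same shape as `scores`.
#' @export
adjust_covariates <- function(scores, covariates) {
  stopifnot(nrow(covariates) == nrow(scores))
  mm <- model.matrix(~ ., data = covariates)
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    aliased <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    stop("rank-deficient covariate design; aliased: ",
         paste(aliased, collapse = ", "))
  }
  res <- qr.resid(q, scores)
  sweep(res, 2, colMeans(res))
}

#' Grubbs test for a single outlier
#'
#' Two-sided Grubbs statistic G = max |x - mean| / SD with p-value from the
#' t-distribution relation p = min(1, 2n P(T_{n-2} > t*)),
#' t* = sqrt(n (n-2) G^2 / ((n-1)^2 - n G^2)).
#'
#' @param values Numeric vector, n >= 3, nonzero SD.
#' @return List: `index` (most extreme sample), `G`, `p`.
#' @export
grubbs_test <- function(values) {
  n <- length(values)
  if (n < 3) stop("Grubbs test needs n >= 3")
  s <- sd(values)
  if (s == 0) stop("zero standard deviation")
  dev <- abs(values - mean(values))
  i <- which.max(dev)
  G <- dev[i] / s
  num <- n * (n - 2) * G^2
  den <- (n - 1)^2 - n * G^2
  p <- if (den <= 0) 0 else {
    min(1, 2 * n * pt(sqrt(num / den), df = n - 2, lower.tail = FALSE))
  }
  list(index = i, G = G, p = p)
}

#' Methylation Outlier Sample Test
#'
#' Full pipeline: probe filtering (optional), scaled PCA with
#' parallel-analysis retention, Grubbs test per retained component on raw
#' scores and on covariate-adjusted scores, BH FDR across retained
#' components within each family, and the dual rule: a sample is an outlier
#' on a PC only when its Grubbs FDR is below `fdr` both before and after
#' adjustment. Per-PC Shapiro-Wilk normality diagnostics are reported, not
#' gated on.
#'
#' @param beta samples x probes beta matrix, or a `beta_matrix`.
#' @param covariates data.frame of per-sample covariates.
#' @param annotation,detection_p Optional; when both are given,
#'   [filter_probes] is applied first.
#' @param fdr Dual-rule FDR threshold (default 0.1).
#' @param n_pcs,n_perm,perm_rule Passed to [pca_retain].
#' @param seed Integer seed.
#' @return List of class `most_result`: `pca` (the [pca_retain] result),
#'   `grubbs_raw`, `grubbs_adjusted` (per-PC candidate tables with BH FDR),
#'   `outliers` (sample, pc rows passing the dual rule), `shapiro_p`,
#'   `scores_adjusted`.
#' @export
most_detect <- function(beta, covariates, annotation = NULL,
                        detection_p = NULL, fdr = 0.1, n_pcs = 20,
                        n_perm = 20, seed = 1L,
                        perm_rule = c("per_rank", "global")) {
  if (!is.null(annotation) && !is.null(detection_p)) {
    beta <- filter_probes(if (inherits(beta, "beta_matrix")) beta$beta else beta,
                          annotation, detection_p)
  }
  pca <- pca_retain(beta, n_pcs = n_pcs, n_perm = n_perm, seed = seed,
                    perm_rule = perm_rule)
  k <- pca$retained_k
  adj <- adjust_covariates(pca$scores, covariates)
  grub <- function(scores) {
    if (k == 0) {
      return(data.frame(pc = integer(), sample = character(),
                        G = numeric(), p = numeric(), fdr = numeric(),
                        stringsAsFactors = FALSE))
    }
    out <- do.call(rbind, lapply(seq_len(k), function(j) {
      g <- grubbs_test(scores[, j])
      data.frame(pc = j,
                 sample = (rownames(scores) %||% as.character(seq_len(nrow(scores))))[g$index],
                 G = g$G, p = g$p, stringsAsFactors = FALSE)
    }))
    out$fdr <- p.adjust(out$p, method = "BH")
    out
  }
  graw <- grub(pca$scores)
  gadj <- grub(adj)
  hits <- merge(graw[graw$fdr < fdr, c("pc", "sample", "fdr")],
                gadj[gadj$fdr < fdr, c("pc", "sample", "fdr")],
                by = c("pc", "sample"), suffixes = c("_raw", "_adjusted"))
  shapiro_p <- if (k > 0) {
    vapply(seq_len(k), function(j) shapiro.test(pca$scores[, j])$p.value,
           numeric(1))
  } else numeric(0)
  out <- list(pca = pca, grubbs_raw = graw, grubbs_adjusted = gadj,
              outliers = hits[order(hits$pc), , drop = FALSE],
              shapiro_p = shapiro_p, scores_adjusted = adj)
  class(out) <- "most_result"
  out
}

#' Gene-set enrichment of component loadings
#'
#' For one principal component, takes the top `top_fraction` of probes by
#' loading magnitude separately among positive- and negative-loading
#' probes, maps them to genes, and Fisher-tests each gene set against the
#' universe of genes mapped by that sign's probes, with BH FDR across sets
#' within each sign.
#'
#' @param loadings Named numeric vector (probe -> loading) for one PC.
#' @param probe_gene data.frame with columns probe, gene; must cover at
#'   least half the probes.
#' @param gene_sets Named list of gene vectors.
#' @param top_fraction Fraction of probes selected per sign (default 0.01).
#' @return data.frame: set, sign, overlap, selected, set_universe, p, fdr.
#' @export
loading_enrichment <- function(loadings, probe_gene, gene_sets,
                               top_fraction = 0.01) {
  map <- probe_gene[match(names(loadings), probe_gene$probe), "gene"]
  if (mean(!is.na(map)) < 0.5) {
    stop("probe-to-gene map covers less than half of the probes")
  }
  one_sign <- function(sgn) {
    sel <- if (sgn == "positive") loadings > 0 else loadings < 0
    sel <- sel & !is.na(map)
    if (!any(sel)) return(NULL)
    universe <- unique(map[sel])
    ntop <- max(1L, ceiling(top_fraction * sum(sel)))
    ord <- order(abs(loadings[sel]), decreasing = TRUE)
    top_genes <- unique(map[sel][ord[seq_len(min(ntop, sum(sel)))]])
    rows <- lapply(names(gene_sets), function(nm) {
      set <- intersect(gene_sets[[nm]], universe)
      if (!length(set)) return(NULL)
      a <- sum(top_genes %in% set)
      b <- length(top_genes) - a
      cc <- length(set) - a
      d <- length(universe) - length(set) - b
      p <- fisher.test(matrix(c(a, b, cc, d), 2))$p.value
      data.frame(set = nm, sign = sgn, overlap = a,
                 selected = length(top_genes), set_universe = length(set),
                 p = p, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (!is.null(out)) out$fdr <- p.adjust(out$p, method = "BH")
    out
  }
  res <- rbind(one_sign("positive"), one_sign("negative"))
  if (is.null(res)) stop("no testable gene set")
  rownames(res) <- NULL
  res[order(res$sign, res$p), , drop = FALSE]
}
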
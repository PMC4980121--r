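# Case-control burden testing: GC-corrected logistic regression (full model
# y = b1*GC + b2*membership + c against the GC-only model, likelihood-ratio
# tested) and gene-set Fisher burden with Benjamini-Hochberg FDR.

#' GC content of the flanking window around each record
#'
#' Fraction of G/C among the `2*flank + 1` bases centered at the variant,
#' truncated at contig ends (denominator adjusted). A window consisting
#' entirely of N is an error.
#'
#' @param records A [dnm_records] table.
#' @param reference `DNAStringSet`.
#' @param flank Flank in bp (default 50, the scale at which case/control GC
#'   bias is strongest in the motivating data).
#' @return Numeric vector in [0, 1].
#' @export
gc_content <- function(records, reference, flank = 50) {
  ci <- match(records$chrom, names(reference))
  if (anyNA(ci)) stop("record chrom not present in reference")
  len <- Biostrings::width(reference)
  gc <- numeric(nrow(records))
  for (i in unique(ci)) {
    sel <- ci == i
    v <- Biostrings::Views(reference[[i]],
                           start = pmax(1L, records$pos[sel] - flank),
                           end = pmin(len[i], records$pos[sel] + flank))
    lf <- Biostrings::letterFrequency(v, c("G", "C", "N"))
    denom <- BiocGenerics::width(v) - lf[, "N"]
    if (any(denom == 0)) stop("all-N window around a variant")
    gc[sel] <- (lf[, "G"] + lf[, "C"]) / denom
  }
  gc
}

#' GC-corrected logistic burden test
#'
#' Fits the full logistic model `case ~ GC + membership` and the GC-only
#' reduced model by IRLS (tolerance 1e-8, up to 100 iterations) and tests
#' the membership coefficient with a 1-df likelihood-ratio test (Wald p
#' reported alongside). GC is used on its natural scale.
#'
#' @param universe A [dnm_records] table containing both cohorts, or any
#'   data.frame with a `cohort` column (and optionally `gc`).
#' @param member Logical vector over `universe` rows: membership of the
#'   tested variant set. Must be non-constant.
#' @param reference `DNAStringSet`, required unless `gc` is supplied or
#'   `universe` carries a `gc` column.
#' @param gc Optional precomputed per-variant GC covariate.
#' @param flank Flank for [gc_content] when GC is computed here.
#' @return Object of class `burden_model`: beta1 (GC), beta2 (membership),
#'   intercept, or_ (= exp(beta2)), p (LRT), p_wald, n_case, n_control,
#'   converged.
#' @export
fit_burden <- function(universe, member, reference = NULL, gc = NULL,
                       flank = 50) {
  stopifnot(length(member) == nrow(universe))
  if (is.null(gc)) {
    gc <- if ("gc" %in% names(universe)) universe$gc
    else gc_content(universe, reference, flank)
  }
  y <- as.integer(universe$cohort == "case")
  if (length(unique(y)) < 2) stop("universe must contain both cohorts")
  x2 <- as.integer(member)
  if (length(unique(x2)) < 2) {
    stop("membership indicator is constant; burden is untestable")
  }
  ctrl <- stats::glm.control(epsilon = 1e-8, maxit = 100)
  full <- glm(y ~ gc + x2, family = binomial(), control = ctrl)
  red <- glm(y ~ gc, family = binomial(), control = ctrl)
  if (!full$converged) stop("IRLS did not converge for the full model")
  fv <- full$fitted.values
  if (any(fv < 1e-10 | fv > 1 - 1e-10) && abs(coef(full)["x2"]) > 15) {
    stop("perfect separation on the membership covariate")
  }
  cf <- summary(full)$coefficients
  lrt <- 2 * (as.numeric(logLik(full)) - as.numeric(logLik(red)))
  out <- list(
    beta1 = unname(coef(full)["gc"]),
    beta2 = unname(coef(full)["x2"]),
    intercept = unname(coef(full)["(Intercept)"]),
    or_ = exp(unname(coef(full)["x2"])),
    p = pchisq(max(lrt, 0), df = 1, lower.tail = FALSE),
    p_wald = cf["x2", 4],
    n_case = sum(y == 1), n_control = sum(y == 0),
    converged = full$converged && red$converged
  )
  class(out) <- "burden_model"
  out
}

#' Variant universes for the burden comparisons
#'
#' The genic universe is all DNMs in exonic coding, core-splice, splicing,
#' UTR and intronic regions. The non-genic universe is all DNMs except
#' exonic (coding + core splice) and predicted splicing-qualifying
#' mutations (tier rules `splicingNeg_*`).
#'
#' @param records A [dnm_records] table.
#' @param scope "genic" or "nongenic".
#' @param calls Optional tier calls from [classify_cohort]; required for the
#'   nongenic universe's splicing exclusion.
#' @return Logical vector over `records` rows.
#' @export
define_universe <- function(records, scope = c("genic", "nongenic"),
                            calls = NULL) {
  scope <- match.arg(scope)
  if (scope == "genic") {
    records$region_class %in% c("coding_exonic", "splice_core",
                                "splicing_site", "utr5", "utr3", "intronic")
  } else {
    out <- !records$region_class %in% c("coding_exonic", "splice_core")
    if (!is.null(calls)) {
      out <- out & !(calls$rule1 %in% c("splicingNeg_3p5") |
                       calls$rule2 %in% c("splicingNeg_5"))
    }
    out
  }
}

#' Gene-set burden by Fisher exact test with BH FDR
#'
#' For each gene set within the size bounds, builds the 2x2 contingency of
#' (cohort x damaging status) over variants in set genes (self-contained
#' test), applies the two-sided Fisher exact test, drops sets whose table
#' is all zeros, and computes Benjamini-Hochberg FDR across the tested
#' sets.
#'
#' @param records A [dnm_records] table with gene symbols.
#' @param gene_sets Named list of gene-symbol vectors (e.g. [read_gmt]).
#' @param damaging Logical vector over `records` rows.
#' @param min_size,max_size Gene-count bounds for eligible sets (defaults
#'   50 and 1200).
#' @return data.frame: set, n_genes, case_damaging, case_other,
#'   control_damaging, control_other, fisher_or, fisher_p, bh_fdr.
#' @export
geneset_burden <- function(records, gene_sets, damaging,
                           min_size = 50, max_size = 1200) {
  sizes <- lengths(gene_sets)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep)) {
    warning("no gene set within the size bounds")
    return(data.frame(set = character(), n_genes = integer(),
                      case_damaging = integer(), case_other = integer(),
                      control_damaging = integer(), control_other = integer(),
                      fisher_or = numeric(), fisher_p = numeric(),
                      bh_fdr = numeric(), stringsAsFactors = FALSE))
  }
  res <- lapply(names(gene_sets)[keep], function(nm) {
    ing <- records$gene %in% gene_sets[[nm]] & !is.na(records$gene)
    tab <- c(
      cd = sum(ing & damaging & records$cohort == "case"),
      co = sum(ing & !damaging & records$cohort == "case"),
      nd = sum(ing & damaging & records$cohort == "control"),
      no = sum(ing & !damaging & records$cohort == "control")
    )
    if (all(tab == 0)) return(NULL)
    ft <- fisher.test(matrix(tab, 2, byrow = TRUE))
    data.frame(set = nm, n_genes = length(gene_sets[[nm]]),
               case_damaging = tab["cd"], case_other = tab["co"],
               control_damaging = tab["nd"], control_other = tab["no"],
               fisher_or = unname(ft$estimate), fisher_p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(res)) {
    warning("all candidate gene sets had all-zero tables")
    return(data.frame(set = character(), fisher_p = numeric(),
                      bh_fdr = numeric(), stringsAsFactors = FALSE))
  }
  rownames(res) <- NULL
  res$bh_fdr <- p.adjust(res$fisher_p, method = "BH")
  res[order(res$fisher_p), , drop = FALSE]
}
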
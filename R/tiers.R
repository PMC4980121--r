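# The damaging-variant classification engine. Two independent rule sets
# (tier 1, the permissive odds-ratio>1.5 set; tier 2, the stricter set)
# over genic and non-genic variants. All threshold comparisons use the
# operators of the published rule list verbatim; an absent score never
# meets a criterion.

.genic_regions <- c("coding_exonic", "splice_core", "splicing_site",
                    "utr5", "utr3", "intronic", "lncRNA")

# TRUE where x is non-missing and cmp holds; absent = criterion not met.
.met <- function(x, op, thr) {
  out <- switch(op,
                "<"  = x < thr,
                ">"  = x > thr,
                ">=" = x >= thr,
                "<=" = x <= thr)
  out & !is.na(x)
}

# Vectorized core: one pass over a records table, producing tier calls.
.tier_core <- function(r) {
  n <- nrow(r)
  genic <- r$region_class %in% .genic_regions
  lof <- r$is_lof %in% TRUE
  mis <- r$is_missense %in% TRUE
  splneg1 <- genic & !lof & .met(r$dpsi, "<", -3.5)
  splneg2 <- genic & !lof & .met(r$dpsi, "<", -5)
  utr5 <- r$region_class == "utr5"
  utr3c <- r$region_class == "utr3" & .met(r$phastcons, ">", 0)
  utr3cp <- utr3c & .met(r$phylop_mam, ">=", 1.5)
  crit <- cbind(.met(r$phylop_mam, ">=", 2.30),
                .met(r$phylop_vert100, ">=", 4.0),
                .met(r$sift, "<", 0.05),
                .met(r$polyphen2, ">=", 0.90),
                .met(r$mut_assessor, ">=", 1.9),
                .met(r$mut_taster, ">=", 0.5),
                .met(r$cadd_phred, ">=", 15))
  mis5of7 <- mis & rowSums(crit) >= 5
  dbl <- .met(r$deepbind_wt_pct, ">=", 99.9) & .met(r$deepbind_var_pct, "<=", 99)
  ng <- r$region_class == "nongenic"
  ng1 <- ng & dbl & .met(r$phastcons, ">", 0)
  ng2 <- ng1 & r$dhs_overlap %in% TRUE

  pick <- function(...) {
    rules <- list(...)
    out <- rep("none", n)
    for (nm in rev(names(rules))) out[rules[[nm]]] <- nm
    out
  }
  rule1 <- pick(LOF = genic & lof, missense_all = genic & mis,
                splicingNeg_3p5 = splneg1, utr5 = genic & utr5,
                utr3_cons = genic & utr3c,
                deepbind_loss_pcons = ng1)
  rule2 <- pick(LOF = genic & lof, missense_5of7 = genic & mis5of7,
                splicingNeg_5 = splneg2, utr5 = genic & utr5,
                utr3_cons_phylop = genic & utr3cp,
                deepbind_loss_dhs = ng2)
  data.frame(
    genic = genic,
    tier1 = rule1 != "none",
    tier2 = rule2 != "none",
    rule1 = rule1, rule2 = rule2,
    stringsAsFactors = FALSE
  )
}

#' Classify genic variants under the tier-1 damaging rules
#'
#' Tier 1 genic: (1) all LOF (stop gain + core splice site); (2) all
#' missense; (3) predicted exon-skipping variants with dPSI < -3.5 (stop
#' gains excluded); (4) all 5'UTR variants; (5) 3'UTR variants with
#' phastCons > 0.
#'
#' @param records A [dnm_records] table of genic records.
#' @return data.frame of tier calls (`tier1` plus `rule1`, the first
#'   matching rule in the order above).
#' @export
classify_genic_tier1 <- function(records) {
  if (any(records$region_class == "nongenic")) {
    stop("classify_genic_tier1 expects genic records only")
  }
  .tier_core(records)[, c("genic", "tier1", "rule1")]
}

#' Classify genic variants under the tier-2 damaging rules
#'
#' Tier 2 genic: (1) all LOF; (2) missense with at least 5 of 7 predictors
#' meeting damaging criteria (mammalian PhyloP >= 2.30, vertebrate-100
#' PhyloP >= 4.0, SIFT < 0.05, PolyPhen2 >= 0.90, Mutation Assessor >= 1.9,
#' Mutation Taster >= 0.5, CADD phred >= 15); (3) exon-skipping with
#' dPSI < -5; (4) all 5'UTR; (5) 3'UTR with phastCons > 0 and mammalian
#' PhyloP >= 1.5. The dPSI thresholds nest, so every tier-2 splicing call is
#' also tier 1.
#'
#' @param records A [dnm_records] table of genic records.
#' @return data.frame of tier calls (`tier2` plus `rule2`).
#' @export
classify_genic_tier2 <- function(records) {
  if (any(records$region_class == "nongenic")) {
    stop("classify_genic_tier2 expects genic records only")
  }
  .tier_core(records)[, c("genic", "tier2", "rule2")]
}

#' Classify non-genic variants under the DeepBind-loss rules
#'
#' A DeepBind binding loss is a site whose wild-type binding score is at or
#' above the 99.9th percentile of the genome background while the variant
#' score falls to or below the 99th. Tier 1 additionally requires
#' phastCons > 0; tier 2 additionally requires overlap with a DNase I
#' hypersensitive region.
#'
#' @param records A [dnm_records] table of nongenic records.
#' @return data.frame with `tier1`, `tier2`, and rule columns.
#' @export
classify_nongenic <- function(records) {
  if (any(records$region_class != "nongenic")) {
    stop("classify_nongenic expects nongenic records only")
  }
  .tier_core(records)
}

#' Classify a whole cohort and summarise the damaging breakdown
#'
#' Runs the tier engine over all records and tabulates tier-1 (damaging)
#' calls by category -- coding (LOF/missense in exonic or core-splice
#' regions), genic non-coding (UTR, splicing, intronic qualifying) and
#' non-genic non-coding -- per cohort. Each variant is counted once even if
#' several rules fire; percentages of the damaging total are reported to
#' one decimal (half-up).
#'
#' @param records A [dnm_records] table.
#' @return List: `calls` (per-record tier calls), `summary` (category x
#'   cohort counts with percentages).
#' @export
classify_cohort <- function(records) {
  calls <- .tier_core(records)
  cat3 <- rep(NA_character_, nrow(records))
  damaging <- calls$tier1
  coding <- damaging & calls$rule1 %in% c("LOF", "missense_all") &
    records$region_class %in% c("coding_exonic", "splice_core")
  nongenic <- damaging & !calls$genic
  cat3[damaging] <- "genic_noncoding"
  cat3[coding] <- "coding"
  cat3[nongenic] <- "nongenic_noncoding"
  lv <- c("coding", "genic_noncoding", "nongenic_noncoding")
  if (nrow(records) == 0L) {
    return(list(calls = calls,
                summary = data.frame(cohort = character(), category = character(),
                                     n = integer(), pct = numeric(),
                                     stringsAsFactors = FALSE)))
  }
  out <- do.call(rbind, lapply(unique(records$cohort), function(co) {
    sel <- records$cohort == co & damaging
    k <- table(factor(cat3[sel], lv))
    data.frame(cohort = co, category = lv, n = as.integer(k),
               pct = round_half_up(100 * as.integer(k) / max(1, sum(k)), 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  list(calls = calls, summary = out)
}
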
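# Trinucleotide mutation spectra (96 pyrimidine-centered channels, COSMIC
# convention), Ti/Tv, and spectrum comparison between cohorts.

.subst_classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 trinucleotide channel labels
#'
#' Pyrimidine-centered classes (C>A ... T>G) crossed with the 5' and 3'
#' flanking bases, labelled like `"A[C>T]G"`.
#'
#' @return Character vector of length 96.
#' @export
spectrum_channels <- function() {
  out <- character(0)
  for (cl in .subst_classes) {
    ref <- substr(cl, 1, 1)
    for (p5 in c("A", "C", "G", "T")) for (p3 in c("A", "C", "G", "T")) {
      out <- c(out, paste0(p5, "[", cl, "]", p3))
    }
  }
  out
}

#' Build the 96-channel trinucleotide spectrum of a set of SNVs
#'
#' Each SNV contributes one count to the channel given by its substitution
#' class and flanking bases, with purine-centered substitutions
#' reverse-complemented into the pyrimidine frame. Indels are skipped and
#' tallied; SNVs whose trinucleotide context contains N are skipped and
#' tallied.
#'
#' @param records A [dnm_records] table.
#' @param reference `DNAStringSet` covering all record positions.
#' @return Object of class `spectrum96`: `counts` (named, length 96), `n`
#'   (total SNVs counted), `skipped_indel`, `skipped_n`.
#' @export
build_spectrum <- function(records, reference) {
  snv <- records[records$var_type == "SNV", , drop = FALSE]
  skipped_indel <- nrow(records) - nrow(snv)
  counts <- setNames(integer(96), spectrum_channels())
  skipped_n <- 0L
  if (nrow(snv)) {
    ci <- match(snv$chrom, names(reference))
    if (anyNA(ci)) stop("record chrom not present in reference")
    len <- Biostrings::width(reference)
    ctx <- character(nrow(snv))
    for (i in unique(ci)) {
      sel <- ci == i
      lo <- pmax(1L, snv$pos[sel] - 1L); hi <- pmin(len[i], snv$pos[sel] + 1L)
      ctx[sel] <- toupper(as.character(Biostrings::Views(reference[[i]], lo, hi)))
    }
    ok <- nchar(ctx) == 3L & !grepl("N", ctx, fixed = TRUE)
    skipped_n <- sum(!ok)
    ctx <- ctx[ok]; ref <- snv$ref[ok]; alt <- snv$alt[ok]
    pur <- ref %in% c("A", "G")
    comp <- function(x) chartr("ACGT", "TGCA", x)
    rc3 <- function(x) paste0(comp(substr(x, 3, 3)), comp(substr(x, 2, 2)),
                              comp(substr(x, 1, 1)))
    ref[pur] <- comp(ref[pur]); alt[pur] <- comp(alt[pur])
    ctx[pur] <- rc3(ctx[pur])
    chan <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
    tab <- table(factor(chan, levels = spectrum_channels()))
    counts <- setNames(as.integer(tab), spectrum_channels())
  }
  out <- list(counts = counts, n = sum(counts),
              skipped_indel = skipped_indel, skipped_n = skipped_n)
  class(out) <- "spectrum96"
  out
}

#' @rdname build_spectrum
#' @param x A `spectrum96`.
#' @return `spectrum_freq`: the 96 channel frequencies (sum to 1).
#' @export
spectrum_freq <- function(x) {
  stopifnot(inherits(x, "spectrum96"))
  if (x$n == 0) stop("empty spectrum has no frequencies")
  x$counts / x$n
}

#' Transition/transversion ratio
#'
#' Transitions are A<->G and C<->T substitutions; all other SNVs are
#' transversions. Undefined (error) when no transversion is present.
#'
#' @param records A [dnm_records] table (SNVs are used; indels ignored).
#' @return Single numeric Ti/Tv ratio.
#' @export
titv <- function(records) {
  snv <- records[records$var_type == "SNV", , drop = FALSE]
  if (!nrow(snv)) stop("no SNVs")
  ti <- (snv$ref %in% c("A", "G") & snv$alt %in% c("A", "G")) |
    (snv$ref %in% c("C", "T") & snv$alt %in% c("C", "T"))
  if (!any(!ti)) stop("zero transversions: Ti/Tv undefined")
  sum(ti) / sum(!ti)
}

#' Pearson comparison of two 96-channel spectra
#'
#' Correlates the channel frequencies (scale-free) of two spectra. The
#' default p-value uses the large-sample t transform on 94 degrees of
#' freedom; `method = "permutation"` instead permutes channel assignments.
#'
#' @param s1,s2 `spectrum96` objects with n > 0.
#' @param method "t" or "permutation".
#' @param n_perm Permutations when `method = "permutation"`.
#' @return List: `r`, `p`.
#' @export
spectrum_correlation <- function(s1, s2, method = c("t", "permutation"),
                                 n_perm = 10000) {
  method <- match.arg(method)
  f1 <- spectrum_freq(s1); f2 <- spectrum_freq(s2)
  if (sd(f1) == 0 || sd(f2) == 0) stop("zero-variance spectrum")
  r <- cor(f1, f2)
  p <- if (method == "t") {
    tt <- r * sqrt(94 / (1 - r^2))
    2 * pt(-abs(tt), df = 94)
  } else {
    null <- replicate(n_perm, cor(f1, sample(f2)))
    (1 + sum(abs(null) >= abs(r))) / (n_perm + 1)
  }
  list(r = r, p = p)
}
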
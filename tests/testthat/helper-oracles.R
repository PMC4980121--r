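# Independent oracles and small fixture builders used across the suite.

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration (minimum-likelihood convention): sum the probabilities of all
# tables with the observed margins whose probability does not exceed the
# observed table's (within a relative tolerance for ties).
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + cc; n <- a + b + cc + d
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  lp <- function(x) {
    lchoose(c1, x) + lchoose(n - c1, r1 - x) - lchoose(n, r1)
  }
  probs <- exp(lp(lo:hi))
  obs <- exp(lp(a))
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Upper-tail exact binomial P(X >= k) by direct log-term summation.
binom_tail_oracle <- function(k, n, p) {
  if (k <= 0) return(1)
  if (k > n) return(0)
  i <- k:n
  sum(exp(lchoose(n, i) + i * log(p) + (n - i) * log1p(-p)))
}

# Brute-force clustered-DNM oracle: all-pairs adjacency (same sample, same
# chrom, |pos difference| <= window) closed transitively via union-find;
# returns the partition of row indices into components of size >= 2, as a
# canonical sorted list of sorted integer vectors.
cluster_oracle <- function(df, window = 20000) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && df$sample_id[i] == df$sample_id[j] &&
        df$chrom[i] == df$chrom[j] &&
        abs(df$pos[i] - df$pos[j]) <= window) {
      parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  comps <- split(seq_len(n), roots)
  comps <- comps[lengths(comps) >= 2]
  unname(comps[order(vapply(comps, min, integer(1)))])
}

# Canonicalize find_clusters() output to the same representation.
cluster_partition <- function(cl) {
  comps <- split(cl$members$row, cl$members$cluster_id)
  comps <- lapply(comps, sort)
  unname(comps[order(vapply(comps, min, integer(1)))])
}

# Benjamini-Hochberg step-up reference implementation.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Minimal DNM record table builder with sensible defaults.
make_records <- function(n = 1, sample_id = "s1", cohort = "case",
                         chrom = "contig1", pos = seq_len(n) * 1000L,
                         ref = "A", alt = "G", ad_ref = 15L, ad_alt = 15L,
                         origin = "paternal", region_class = "nongenic",
                         ...) {
  df <- data.frame(sample_id = sample_id, cohort = cohort, chrom = chrom,
                   pos = pos, ref = ref, alt = alt, ad_ref = ad_ref,
                   ad_alt = ad_alt, origin = origin,
                   region_class = region_class, stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  dnm_records(df)
}

# Small shared reference (2 x 50 kb) for I/O and spectra tests.
test_ref <- simulate_reference(n_contigs = 2, contig_length = 5e4,
                               gc_target = 0.5, seed = 42)

# Larger cohort-scale reference, built once for the simulation-calibration
# and acceptance tests (8 x 12.5 Mb = 100 Mb).
cohort_ref <- NULL
get_cohort_ref <- function() {
  if (is.null(cohort_ref)) {
    cohort_ref <<- simulate_reference(n_contigs = 8, contig_length = 12.5e6,
                                      gc_target = 0.41, seed = 20160803)
  }
  cohort_ref
}
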
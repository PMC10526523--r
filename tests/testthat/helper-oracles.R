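# Brute-force reference implementations used as independent oracles, plus
# small fixture builders. These deliberately use naive loops / closed forms,
# never the package's own code paths.

# Gower dissimilarity by explicit double loop over the definition.
gower_oracle <- function(x) {
  n <- nrow(x)
  rng <- apply(x, 2, function(v) diff(range(v)))
  keep <- which(rng > 0)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- mean(vapply(keep, function(c)
      abs(x[i, c] - x[j, c]) / rng[c], numeric(1)))
  }
  d
}

# Length-weighted bin means by explicit per-bp interval arithmetic.
bin_oracle <- function(segments, bins, cn_col) {
  samples <- unique(segments$sample)
  m <- matrix(NA_real_, length(samples), nrow(bins),
              dimnames = list(samples, NULL))
  for (s in samples) {
    seg <- segments[segments$sample == s, ]
    for (b in seq_len(nrow(bins))) {
      num <- 0; den <- 0
      for (r in seq_len(nrow(seg))) {
        ov <- min(bins$end[b], seg$end[r]) - max(bins$start[b], seg$start[r]) + 1
        if (ov > 0) { num <- num + ov * seg[[cn_col]][r]; den <- den + ov }
      }
      if (den > 0) m[s, b] <- num / den
    }
  }
  m
}

# BH step-up by hand.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# Hypergeometric upper tail from binomial coefficients.
hyper_oracle <- function(overlap, n_region, n_universe, n_sig) {
  ks <- overlap:min(n_region, n_sig)
  sum(choose(n_region, ks) * choose(n_universe - n_region, n_sig - ks)) /
    choose(n_universe, n_sig)
}

# Gene-level beta aggregation by explicit loops.
gene_beta_oracle <- function(beta, mapping) {
  out <- matrix(NA_real_, length(mapping), ncol(beta),
                dimnames = list(names(mapping), colnames(beta)))
  for (g in names(mapping)) for (j in seq_len(ncol(beta))) {
    v <- beta[mapping[[g]], j]
    if (any(!is.na(v))) out[g, j] <- mean(v, na.rm = TRUE)
  }
  out
}

# Small cohort shared by several test files (generated once per run).
tiny_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(sim_config(n_samples = 60, seed = 42))
    cache
  }
})

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
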
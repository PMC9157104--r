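## Independent brute-force oracles. These deliberately re-derive results by
## direct enumeration / double loops, never calling the implementation path
## they check.

## sliding-window means by an explicit (window, SNP) double loop
oracle_windows <- function(snps, width, step, min_snps) {
  out <- list()
  for (ch in sort(unique(snps$chrom))) {
    s <- snps[snps$chrom == ch, ]
    starts <- seq(1L, max(s$pos), by = step)
    for (st in starts) {
      en <- st + width - 1L
      inside <- s$afd[s$pos >= st & s$pos <= en]
      if (length(inside) >= min_snps)
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = st, end = en, n_snps = length(inside),
          mean_afd = mean(inside))
    }
  }
  do.call(rbind, out)
}

## all-pairs gene-by-region interval overlap
oracle_overlap <- function(genes, regions) {
  hits <- list()
  for (i in seq_len(nrow(regions))) {
    for (j in seq_len(nrow(genes))) {
      if (genes$chrom[j] == regions$chrom[i] &&
          genes$start[j] <= regions$end[i] &&
          genes$end[j] >= regions$start[i])
        hits[[length(hits) + 1L]] <- data.frame(region = i,
                                                gene_id = genes$gene_id[j])
    }
  }
  do.call(rbind, hits)
}

## exact upper-tail exceedance probability of the HWE genotype deviance by
## complete enumeration of the trinomial over genotype-count triples
oracle_exact_hwe_p <- function(obs, p, n = sum(obs)) {
  expected <- c(p^2, 2 * p * (1 - p), (1 - p)^2)
  d_obs <- sum((obs / n - expected)^2)
  ptot <- 0
  for (a in 0:n) for (b in 0:(n - a)) {
    cc <- n - a - b
    d <- sum((c(a, b, cc) / n - expected)^2)
    if (d >= d_obs)
      ptot <- ptot + exp(lgamma(n + 1) - lgamma(a + 1) - lgamma(b + 1) -
                           lgamma(cc + 1) + a * log(expected[1]) +
                           b * log(expected[2]) +
                           ifelse(cc > 0, cc * log(expected[3]), 0))
  }
  ptot
}

## Kolmogorov-Smirnov distance of a sample from Uniform(0, 1)
ks_uniform <- function(x) {
  x <- sort(x)
  n <- length(x)
  max(max(seq_len(n) / n - x), max(x - (seq_len(n) - 1) / n))
}
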
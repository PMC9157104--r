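## Genome-wide differentiation mapping between two pools.
##
## Differentiation is quantified by the absolute allele frequency difference
## (AFD): half the L1 distance between the two pools' allele-frequency
## vectors, which reduces to |p1 - p2| at a biallelic site. AFD ranges from
## 0 (identical frequencies) to 1 (fixed for alternative alleles).

#' Absolute allele frequency difference (AFD)
#'
#' Computes AFD between two allele-frequency vectors as half their L1
#' distance, `0.5 * sum(|f1 - f2|)`. For biallelic sites this equals the
#' absolute difference of either allele's frequency and lies in \[0, 1\],
#' with 1 meaning the pools are fixed for alternative alleles.
#'
#' @param freqs_1,freqs_2 numeric allele-frequency vectors over the same
#'   alleles in the same order; each must sum to 1 (tolerance 1e-9).
#' @return AFD in \[0, 1\].
#' @export
#' @examples
#' compute_afd(c(1, 0), c(0, 1))        # 1: fixed difference
#' compute_afd(c(0.75, 0.25), c(0.25, 0.75))
compute_afd <- function(freqs_1, freqs_2) {
  if (length(freqs_1) != length(freqs_2))
    validation_error("frequency vectors differ in length")
  if (abs(sum(freqs_1) - 1) > 1e-9 || abs(sum(freqs_2) - 1) > 1e-9)
    validation_error("allele frequencies must sum to 1")
  0.5 * sum(abs(freqs_1 - freqs_2))
}

## Vectorised biallelic calling over a whole site table. Returns a
## data.table with one row per input site and NA rows for sites that do not
## yield a biallelic SNP (monomorphic, empty, or a third allele above the
## error floor). Deletion counts are never part of the allele math.
call_biallelic_all <- function(sites, pools = c(1, 2), error_floor = 0.01) {
  if (error_floor < 0 || error_floor > 0.05)
    config_error("error_floor must be in [0, 0.05]")
  c1 <- pool_counts(sites, pools[1])
  c2 <- pool_counts(sites, pools[2])
  comb <- c1 + c2
  n <- nrow(comb)
  tot <- rowSums(comb)
  ## rank bases by combined count; ties broken by A<C<G<T column order
  rows <- seq_len(n)
  maj_i <- max.col(comb, ties.method = "first")
  tmp <- comb
  tmp[cbind(rows, maj_i)] <- -1L
  min_i <- max.col(tmp, ties.method = "first")
  min_n <- tmp[cbind(rows, min_i)]
  tmp[cbind(rows, min_i)] <- -1L
  third_any <- pmax(tmp[cbind(rows, max.col(tmp, ties.method = "first"))], 0L)
  ok <- tot > 0 & min_n > 0 & third_any <= error_floor * tot
  im1 <- cbind(rows, maj_i); im2 <- cbind(rows, min_i)
  d1 <- c1[im1] + c1[im2]
  d2 <- c2[im1] + c2[im2]
  f1 <- ifelse(d1 > 0, c1[im2] / d1, NaN)
  f2 <- ifelse(d2 > 0, c2[im2] / d2, NaN)
  out <- data.table(chrom = sites$chrom, pos = sites$pos,
                    major = BASES[maj_i], minor = BASES[min_i],
                    depth_1 = as.integer(d1), depth_2 = as.integer(d2),
                    freq_1 = f1, freq_2 = f2,
                    afd = abs(f1 - f2))
  out[!ok, `:=`(major = NA_character_, minor = NA_character_,
                depth_1 = NA_integer_, depth_2 = NA_integer_,
                freq_1 = NA_real_, freq_2 = NA_real_, afd = NA_real_)]
  out[]
}

#' Call a biallelic SNP from one site's pool counts
#'
#' Sums counts across the two compared pools; the two highest-count bases
#' become the major and minor allele. A site is rejected (returns `NULL`)
#' when it is monomorphic or empty, or when any third base exceeds
#' `error_floor` of the combined depth (putative sequencing error or a true
#' multi-allelic site, for which AFD orientation is undefined). Counts at
#' non-retained bases are discarded: per-pool depths and minor-allele
#' frequencies use the two retained alleles only.
#'
#' @inheritParams n_pools
#' @param pools length-2 integer vector: the two pool indices to compare.
#' @param error_floor maximum tolerated third-allele proportion of combined
#'   depth, in \[0, 0.05\].
#' @return a one-row `data.table` (chrom, pos, major, minor, depth_1,
#'   depth_2, freq_1, freq_2, afd) or `NULL` if no biallelic SNP is called.
#' @export
call_biallelic <- function(sites, pools = c(1, 2), error_floor = 0.01) {
  if (nrow(sites) != 1L)
    validation_error("call_biallelic expects a single site; see run_scan")
  res <- call_biallelic_all(sites, pools, error_floor)
  if (is.na(res$major[1])) NULL else res
}

#' Depth and minor-allele-frequency SNP filters
#'
#' A SNP passes when its per-pool depth (reads at the two retained alleles)
#' lies within `[depth_min, depth_max]` in BOTH pools (bounds inclusive) and
#' the minor-allele frequency computed from the SUMMED counts of both pools
#' is at least `maf_min`. The depth bounds exclude poorly sequenced and
#' repeated regions; the MAF bound excludes sequencing errors and
#' uninformative near-monomorphic sites.
#'
#' @param snps SNP table from [call_biallelic()] / [run_scan()].
#' @param depth_min,depth_max inclusive per-pool depth bounds.
#' @param maf_min minimum pooled minor-allele frequency.
#' @return logical vector, one element per SNP.
#' @export
passes_filters <- function(snps, depth_min = 40, depth_max = 130,
                           maf_min = 0.2) {
  if (depth_min > depth_max)
    config_error("depth_min (%s) exceeds depth_max (%s)", depth_min, depth_max)
  ## freq * depth recovers the integer minor-allele read counts; round to
  ## keep the pooled MAF exact at filter boundaries
  minor_reads <- round(snps$freq_1 * snps$depth_1) +
    round(snps$freq_2 * snps$depth_2)
  pooled_maf <- minor_reads / (snps$depth_1 + snps$depth_2)
  ok <- snps$depth_1 >= depth_min & snps$depth_1 <= depth_max &
    snps$depth_2 >= depth_min & snps$depth_2 <= depth_max &
    pooled_maf >= maf_min
  ok & !is.na(ok)
}

## lower median: for an even number of values, the smaller of the two
## central order statistics (deterministic, stays on an observed value)
median_lower <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(NA_real_)
  sort(x)[ceiling(length(x) / 2)]
}

#' Run the per-SNP differentiation scan
#'
#' Applies [call_biallelic()] then [passes_filters()] to every site of a
#' sorted site-count table and computes per-SNP AFD between the two pools.
#'
#' @inheritParams call_biallelic
#' @inheritParams passes_filters
#' @param sites site-count table sorted by (chrom, pos).
#' @return an object of class `afd_scan`: a list with `snps` (the surviving
#'   SNP table), `median_afd` (genome-wide lower median of retained SNPs'
#'   AFD; `NA` if none survive), `n_snps`, and `params`.
#' @export
run_scan <- function(sites, pools = c(1, 2), depth_min = 40, depth_max = 130,
                     maf_min = 0.2, error_floor = 0.01) {
  o <- order(sites$chrom, sites$pos)
  if (is.unsorted(o)) {
    bad <- which(o != seq_along(o))[1]
    validation_error("input sites not sorted by (chrom, pos); first offender: %s:%d",
                     sites$chrom[bad], sites$pos[bad])
  }
  called <- call_biallelic_all(sites, pools, error_floor)
  called <- called[!is.na(major)]
  keep <- passes_filters(called, depth_min, depth_max, maf_min)
  snps <- called[keep]
  res <- structure(list(
    snps = snps[],
    median_afd = median_lower(snps$afd),
    n_snps = nrow(snps),
    params = list(pools = pools, depth_min = depth_min,
                  depth_max = depth_max, maf_min = maf_min,
                  error_floor = error_floor)),
    class = "afd_scan")
  res
}

#' @export
print.afd_scan <- function(x, ...) {
  cat(sprintf("AFD scan: %d SNPs retained; genome-wide median AFD = %s\n",
              x$n_snps,
              if (is.na(x$median_afd)) "NA" else format(x$median_afd)))
  invisible(x)
}

## accept either an afd_scan or a bare SNP table
as_snp_table <- function(snps) {
  if (inherits(snps, "afd_scan")) snps$snps else as.data.table(snps)
}

#' Sliding-window smoothing of per-SNP AFD
#'
#' Averages per-SNP AFD over overlapping windows tiling each chromosome from
#' position 1 (`[1, width]`, `[step + 1, step + width]`, ...). A SNP belongs
#' to a window when `start <= pos <= end`; windows containing fewer than
#' `min_snps` SNPs are omitted. The window mean is the unweighted arithmetic
#' mean of the contained SNPs' AFD.
#'
#' @param snps SNP table or `afd_scan` object.
#' @param width window width in bp (must be a multiple of `step`).
#' @param step window start spacing in bp (overlap is `width - step`).
#' @param min_snps minimum SNPs for a window to be reported.
#' @return `data.table` with columns `chrom`, `start`, `end`, `n_snps`,
#'   `mean_afd`, sorted by (chrom, start).
#' @export
smooth_windows <- function(snps, width = 40000, step = 20000, min_snps = 6) {
  if (width < step) config_error("window width (%s) < step (%s)", width, step)
  if (width %% step != 0)
    config_error("window width must be a multiple of step")
  snps <- as_snp_table(snps)
  if (nrow(snps) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), n_snps = integer(),
                      mean_afd = numeric()))
  k <- width %/% step
  ## window j (0-based) spans [j*step + 1, j*step + width]; a SNP at pos
  ## falls into windows floor((pos-1)/step) - (0..k-1), clipped at j >= 0
  expanded <- snps[, {
    base <- (pos - 1L) %/% as.integer(step)
    j <- rep(base, each = k) - rep.int(0:(k - 1L), length(pos))
    list(j = j, afd = rep(afd, each = k))
  }, by = chrom][j >= 0L]
  win <- expanded[, .(n_snps = .N, mean_afd = mean(afd)), by = .(chrom, j)]
  win <- win[n_snps >= min_snps]
  win[, `:=`(start = j * as.integer(step) + 1L,
             end = j * as.integer(step) + as.integer(width))]
  setorder(win, chrom, start)
  win[, .(chrom, start, end, n_snps, mean_afd)]
}

#' Top differentiated SNPs
#'
#' Returns the `k` SNPs with the highest AFD genome-wide, sorted by AFD
#' descending. Ties are broken by genomic order (chrom, pos ascending);
#' when the k-th value is tied beyond rank k, exactly `k` records are still
#' returned and a note is logged.
#'
#' @param snps SNP table or `afd_scan` object.
#' @param k number of SNPs to return.
#' @return `data.table` of `k` SNP records.
#' @export
top_snps <- function(snps, k = 10) {
  snps <- as_snp_table(snps)
  if (k <= 0) config_error("k must be positive")
  if (nrow(snps) == 0L) validation_error("top_snps: empty SNP table")
  if (k > nrow(snps)) {
    warning(sprintf("k = %d exceeds table size %d; returning all SNPs",
                    k, nrow(snps)))
    k <- nrow(snps)
  }
  o <- order(-snps$afd, snps$chrom, snps$pos)
  top <- snps[o[seq_len(k)]]
  if (k < nrow(snps) && snps$afd[o[k + 1L]] == top$afd[k])
    message(sprintf("top_snps: AFD tie at rank %d broken by genomic order", k))
  top[]
}

#' Candidate regions around top SNPs
#'
#' Builds the gene-annotation regions: anchors (top SNPs) on the same
#' chromosome within `cluster_gap` of each other are merged into one cluster
#' anchored at the midpoint of its outermost members; each region spans
#' `anchor +/- span/2`, clipped at position 1; overlapping regions on a
#' chromosome are merged.
#'
#' @param anchors SNP table (needs `chrom`, `pos`), sorted by position
#'   within chromosome or not — it is sorted internally.
#' @param span total region width in bp centred on the anchor.
#' @param cluster_gap maximum distance for two anchors to join one cluster.
#' @return `data.table` with columns `chrom`, `start`, `end`, `anchor_pos`.
#' @export
candidate_regions <- function(anchors, span = 180000, cluster_gap = 20000) {
  anchors <- as_snp_table(anchors)
  if (nrow(anchors) == 0L)
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), anchor_pos = integer()))
  a <- anchors[, .(chrom, pos)]
  setorder(a, chrom, pos)
  a[, cluster_id := cumsum(c(1L, diff(pos) > cluster_gap)), by = chrom]
  cl <- a[, .(anchor_pos = as.integer(floor((min(pos) + max(pos)) / 2))),
          by = .(chrom, cluster_id)]
  half <- floor(span / 2)
  cl[, `:=`(start = pmax(1L, anchor_pos - as.integer(half)),
            end = anchor_pos + as.integer(half))]
  setorder(cl, chrom, start)
  ## merge overlapping regions per chromosome
  cl[, region_id := cumsum(c(1L, tail(start, -1L) > head(cummax(end), -1L))),
     by = chrom]
  out <- cl[, .(start = min(start), end = max(end),
                anchor_pos = as.integer(floor((min(anchor_pos) +
                                                 max(anchor_pos)) / 2))),
            by = .(chrom, region_id)]
  out[, region_id := NULL]
  setorder(out, chrom, start)
  out[]
}
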
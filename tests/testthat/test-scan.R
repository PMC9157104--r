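test_that("compute_afd is half the L1 distance and symmetric", {
  expect_equal(compute_afd(c(1, 0), c(0, 1)), 1)      # fixed difference
  expect_equal(compute_afd(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(compute_afd(c(0.75, 0.25), c(0.25, 0.75)), 0.5)
  # general multi-allelic form, symmetry
  f1 <- c(0.5, 0.3, 0.2); f2 <- c(0.1, 0.4, 0.5)
  expect_equal(compute_afd(f1, f2), 0.5 * sum(abs(f1 - f2)))
  expect_equal(compute_afd(f1, f2), compute_afd(f2, f1))
  expect_error(compute_afd(c(0.5, 0.4), c(0.5, 0.5)),
               class = "poolscan_validation_error")
  expect_error(compute_afd(c(1, 0), c(1, 0, 0)),
               class = "poolscan_validation_error")
})

test_that("call_biallelic identifies the two top alleles and cleans counts", {
  # fixed difference: pool1 all A, pool2 all G
  snp <- call_biallelic(two_pool_site(c(A = 50), c(G = 50)))
  expect_equal(snp$major, "A")       # tie 50/50 broken by base order
  expect_equal(snp$minor, "G")
  expect_equal(snp$freq_1, 0)
  expect_equal(snp$freq_2, 1)
  expect_equal(snp$afd, 1)
  # monomorphic -> nothing
  expect_null(call_biallelic(two_pool_site(c(A = 40), c(A = 60))))
  # all-zero combined counts -> nothing, not an error
  expect_null(call_biallelic(two_pool_site(c(A = 0), c(A = 0))))
  # third allele above the error floor -> rejected
  expect_null(call_biallelic(two_pool_site(c(A = 60, G = 35), c(T = 5)),
                             error_floor = 0.01))
  # same counts but floor 0.05 tolerates the third base; its reads are
  # discarded from depth and frequency denominators
  snp <- call_biallelic(two_pool_site(c(A = 60, G = 35), c(T = 5)),
                        error_floor = 0.05)
  expect_equal(snp$major, "A")
  expect_equal(snp$depth_2, 0L)      # pool 2 has no A/G reads
  expect_true(is.nan(snp$freq_2))
  expect_error(call_biallelic(two_pool_site(c(A = 1), c(A = 1)),
                              error_floor = 0.2),
               class = "poolscan_config_error")
})

test_that("depth and MAF filters are inclusive and count-weighted", {
  mk_snp <- function(d1, d2, maf) {
    data.table::data.table(chrom = "c", pos = 1L, major = "A", minor = "G",
                           depth_1 = d1, depth_2 = d2,
                           freq_1 = maf, freq_2 = maf,
                           afd = 0)
  }
  expect_false(passes_filters(mk_snp(39, 80, 0.3), 40, 130, 0.2))
  expect_true(passes_filters(mk_snp(40, 130, 0.2), 40, 130, 0.2))
  expect_false(passes_filters(mk_snp(40, 131, 0.3), 40, 130, 0.2))
  # pooled MAF from SUMMED counts: (A=30,G=10) + (A=33,G=7) -> 17/80
  snp <- call_biallelic(two_pool_site(c(A = 30, G = 10), c(A = 33, G = 7)))
  minor_reads <- round(snp$freq_1 * snp$depth_1 + snp$freq_2 * snp$depth_2)
  expect_equal(minor_reads / (snp$depth_1 + snp$depth_2), 17 / 80)
  expect_true(passes_filters(snp, 20, 130, 0.2))     # 0.2125 >= 0.2
  expect_false(passes_filters(snp, 20, 130, 0.22))
  expect_error(passes_filters(snp, 130, 40, 0.2),
               class = "poolscan_config_error")
})

test_that("filter order invariance: depth-then-MAF equals MAF-then-depth", {
  set.seed(5)
  snps <- random_snp_table(150)
  snps[, depth_1 := sample(20:200, .N, TRUE)]
  snps[, depth_2 := sample(20:200, .N, TRUE)]
  depth_only <- passes_filters(snps, 40, 130, 0)
  maf_only <- passes_filters(snps, 0, 10000, 0.2)
  both <- passes_filters(snps, 40, 130, 0.2)
  expect_equal(both, depth_only & maf_only)
})

test_that("run_scan applies calling and filtering site by site", {
  # 10-site toy stream designed so exactly 4 sites survive
  specs <- list(
    list(c(A = 50), c(G = 50)),                 # survives, afd 1
    list(c(A = 40), c(A = 60)),                 # monomorphic
    list(c(A = 60, G = 35), c(T = 5)),          # triallelic, rejected
    list(c(A = 30, G = 30), c(A = 50, G = 10)), # survives
    list(c(A = 20, G = 19), c(A = 1)),          # depth_1 39 < 40
    list(c(A = 70, G = 30), c(A = 80, G = 51)), # depth_2 131 > 130
    list(c(A = 55, G = 15), c(A = 65, G = 15)), # survives, maf 30/150
    list(c(A = 66, G = 9), c(A = 70, G = 5)),   # maf 14/150 < 0.2
    list(c(A = 45, G = 45), c(A = 45, G = 45)), # survives, afd 0
    list(c(A = 2), c(G = 2)))                   # depth below 40
  sites <- two_pool_sites(specs)
  scan <- run_scan(sites, depth_min = 40, depth_max = 130, maf_min = 0.2)
  expect_s3_class(scan, "afd_scan")
  expect_equal(scan$n_snps, 4L)
  expect_equal(scan$snps$pos, c(100L, 400L, 700L, 900L))
  # per-site oracle: call + filter each site independently
  surviving <- Filter(Negate(is.null), lapply(seq_len(nrow(sites)),
    function(i) {
      s <- call_biallelic(sites[i])
      if (!is.null(s) && passes_filters(s, 40, 130, 0.2)) s else NULL
    }))
  expect_equal(scan$snps, data.table::rbindlist(surviving))
  # lower median of the 4 surviving AFD values
  expect_equal(scan$median_afd, sort(scan$snps$afd)[2])
})

test_that("run_scan handles empty and degenerate streams", {
  empty <- two_pool_sites(list(list(c(A = 1), c(A = 1))))[0]
  scan <- run_scan(empty)
  expect_equal(scan$n_snps, 0L)
  expect_true(is.na(scan$median_afd))
  mono <- two_pool_sites(list(list(c(A = 50), c(A = 50)),
                              list(c(C = 50), c(C = 50))))
  expect_equal(run_scan(mono)$n_snps, 0L)
  unsorted <- two_pool_sites(list(list(c(A = 50), c(G = 50)),
                                  list(c(A = 50), c(G = 50))),
                             pos = c(200L, 100L))
  expect_error(run_scan(unsorted), "not sorted",
               class = "poolscan_validation_error")
})

test_that("smooth_windows matches the brute-force double-loop oracle", {
  set.seed(7)
  snps <- random_snp_table(200)
  win <- smooth_windows(snps, width = 40000, step = 20000, min_snps = 6)
  oracle <- oracle_windows(snps, 40000L, 20000L, 6L)
  expect_equal(as.data.frame(win), oracle, ignore_attr = TRUE)
  # min_snps boundary: a window with 5 SNPs is absent
  five <- data.table::data.table(chrom = "c", pos = c(1e5 + (1:5) * 100),
                                 afd = 0.5)
  expect_false(any(smooth_windows(five, min_snps = 6)$n_snps == 5))
  six <- data.table::data.table(chrom = "c", pos = 20001L + (1:6) * 100L,
                                afd = 0.5)
  w6 <- smooth_windows(six, min_snps = 6)
  expect_true(all(w6$mean_afd == 0.5))
  expect_true(all(w6$n_snps == 6))
  expect_error(smooth_windows(six, width = 10000, step = 20000),
               class = "poolscan_config_error")
  expect_error(smooth_windows(six, width = 50000, step = 20000),
               class = "poolscan_config_error")
})

test_that("each interior SNP contributes to exactly width/step windows", {
  set.seed(8)
  snps <- random_snp_table(100, chroms = "chrA", max_pos = 150000L)
  snps <- snps[pos > 40000]               # away from the chromosome start
  win <- smooth_windows(snps, width = 40000, step = 20000, min_snps = 1)
  hits <- vapply(seq_len(nrow(snps)), function(i) {
    sum(win$start <= snps$pos[i] & win$end >= snps$pos[i])
  }, 0L)
  expect_true(all(hits == 2L))
})

test_that("top_snps ranks by AFD with genomic tie-breaking", {
  snps <- random_snp_table(50)
  snps[1:3, afd := c(0.541, 0.50, 0.49)]
  snps[4:nrow(snps), afd := runif(nrow(snps) - 3, 0, 0.4)]
  top <- top_snps(snps, k = 3)
  expect_equal(top$afd, c(0.541, 0.50, 0.49))
  expect_equal(top_snps(snps, k = 1)$afd, 0.541)
  # all equal -> first k in genomic order
  ties <- data.table::data.table(chrom = "c", pos = c(10L, 20L, 30L, 40L),
                                 afd = 0.3)
  expect_message(tk <- top_snps(ties, k = 2), "tie")
  expect_equal(tk$pos, c(10L, 20L))
  expect_error(top_snps(snps, k = 0), class = "poolscan_config_error")
  expect_warning(all_back <- top_snps(ties, k = 10), "exceeds")
  expect_equal(nrow(all_back), 4L)
})

test_that("candidate_regions centers, clips, clusters and merges", {
  one <- data.table::data.table(chrom = "chrA", pos = 500000L)
  r <- candidate_regions(one, span = 180000)
  expect_equal(r$start, 410000L)
  expect_equal(r$end, 590000L)
  expect_equal(r$anchor_pos, 500000L)
  # clipping at position 1
  low <- data.table::data.table(chrom = "chrA", pos = 50000L)
  rl <- candidate_regions(low, span = 180000)
  expect_equal(rl$start, 1L)
  expect_equal(rl$end, 140000L)
  # four anchors within 3 kb merge into one cluster at the midpoint
  cluster <- data.table::data.table(chrom = "chrXX",
                                    pos = c(700000L, 701000L, 702000L,
                                            703000L))
  rc <- candidate_regions(cluster, span = 180000, cluster_gap = 20000)
  expect_equal(nrow(rc), 1L)
  expect_equal(rc$anchor_pos, 701500L)
  # overlapping regions from distinct clusters merge
  pair <- data.table::data.table(chrom = "chrA", pos = c(100000L, 200000L))
  rp <- candidate_regions(pair, span = 180000, cluster_gap = 20000)
  expect_equal(nrow(rp), 1L)
  expect_equal(candidate_regions(one[0]), candidate_regions(one)[0])
})
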
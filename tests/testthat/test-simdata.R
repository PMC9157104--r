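small_cfg <- function(...) {
  args <- utils::modifyList(
    list(n_neutral_snps = 400, chrom_length = 200000,
         causal_positions = c(major = 100000, modifier = 100000)),
    list(...))
  do.call(sim_config, args)
}

test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(freq_major_low = 1.2),
               class = "poolscan_validation_error")
  expect_error(sim_config(penetrance = c(PP = 0.9, PC = 0.5, XX = 0.1)),
               class = "poolscan_validation_error")
  expect_error(sim_config(depth_per_pool = c(Complete_CC = 65)),
               class = "poolscan_validation_error")
  expect_error(sim_config(causal_positions = c(major = 0, modifier = 10)),
               class = "poolscan_validation_error")
})

test_that("morph assignment is deterministic for LL and CC", {
  ind <- simulate_individuals(sim_config(n_individuals = 2000), seed = 1)
  expect_true(all(ind[major_genotype == "LL", morph] == "low"))
  expect_true(all(ind[major_genotype == "CC", morph] == "complete"))
  expect_true(all(ind[morph == "low", major_genotype] == "LL"))
  expect_true(all(ind[morph == "partial", major_genotype] == "CL"))
  # degenerate penetrance: no partial individuals at all
  none <- simulate_individuals(
    sim_config(n_individuals = 500, penetrance = c(PP = 0, PC = 0, CC = 0)),
    seed = 2)
  expect_false(any(none$morph == "partial"))
  # fixed low allele: everyone LL and low-morph
  all_low <- simulate_individuals(
    sim_config(n_individuals = 200, freq_major_low = 1), seed = 3)
  expect_true(all(all_low$major_genotype == "LL"))
  expect_true(all(all_low$morph == "low"))
})

test_that("group labels combine morph with major-locus genotype", {
  expect_equal(assign_group("complete", "CC"), "Complete_CC")
  expect_equal(assign_group("low", "LL"), "Low_LL")
  expect_equal(assign_group(c("complete", "partial"), c("CL", "CL")),
               c("Complete_CL", "Partial_CL"))
  # contract case reachable only on user-supplied tables
  expect_equal(assign_group("complete", "LL"), "unassigned")
  expect_equal(assign_group("partial", "CC"), "unassigned")
})

test_that("partial fraction among heterozygotes matches the penetrance mixture", {
  cfg <- sim_config(n_individuals = 10000)
  ind <- simulate_individuals(cfg, seed = 11)
  cl <- ind[major_genotype == "CL"]
  h <- hwe_expected(cfg$freq_modifier_partial)
  expected_frac <- sum(h * cfg$penetrance[c("PP", "PC", "CC")])
  se <- sqrt(expected_frac * (1 - expected_frac) / nrow(cl))
  expect_lt(abs(mean(cl$morph == "partial") - expected_frac), 3 * se)
  # unlinked modifier genotypes conform to HWE at n = 10,000
  obs <- table(factor(ind$modifier_genotype, c("PP", "PC", "CC"))) / 10000
  expect_lt(max(abs(obs - h)), 3 * sqrt(max(h * (1 - h)) / 10000))
})

test_that("pool depths and causal frequencies are recovered", {
  cfg <- small_cfg()
  ind <- simulate_individuals(cfg, seed = 21)
  res <- simulate_pool_counts(ind, cfg, seed = 22)
  expect_equal(nrow(res$sites), cfg$n_neutral_snps + 2L)
  # empirical mean depth within 1% of the configured mean at this n
  for (g in seq_along(cfg$depth_per_pool)) {
    depth <- rowSums(pool_counts(res$sites, g))
    expect_lt(abs(mean(depth) / cfg$depth_per_pool[g] - 1), 0.02)
  }
  # truth frequencies at the causal sites equal the genotype tallies
  major <- res$truth[site_type == "major"]
  low_ll <- ind[group == "Low_LL"]
  expect_equal(major$freq_Low_LL, 1)
  cc <- ind[group == "Complete_CC"]
  expect_equal(major$freq_Complete_CC, 0)
  mod <- res$truth[site_type == "modifier"]
  pcl <- ind[group == "Partial_CL"]
  expect_equal(mod$freq_Partial_CL,
               sum((pcl$modifier_genotype == "PP") * 2 +
                     (pcl$modifier_genotype == "PC")) / (2 * nrow(pcl)))
  expect_error(simulate_pool_counts(ind[group == "Low_LL"], cfg),
               class = "poolscan_config_error")
})

test_that("ld decay L -> 0 leaves neutral sites at background noise", {
  cfg <- small_cfg(ld_length = 0, error_rate = 0)
  ind <- simulate_individuals(cfg, seed = 31)
  res <- simulate_pool_counts(ind, cfg, seed = 32)
  neutral <- res$truth[site_type == "neutral"]
  # group frequencies at neutral sites are independent draws around the
  # same background frequency: the mean contrast is ~0 and uncorrelated
  # with distance from the causal site
  contrast <- neutral$freq_Partial_CL - neutral$freq_Complete_CL
  expect_lt(abs(mean(contrast)), 3 * sd(contrast) / sqrt(nrow(neutral)))
  expect_lt(abs(cor(abs(contrast),
                    abs(neutral$pos - 100000))), 0.15)
})

test_that("truth-table modifier contrast matches the closed-form mixture", {
  cfg <- sim_config(n_individuals = 40000, n_neutral_snps = 0,
                    chrom_length = 1000,
                    causal_positions = c(major = 100, modifier = 100))
  ind <- simulate_individuals(cfg, seed = 41)
  res <- simulate_pool_counts(ind, cfg, seed = 42)
  mod <- res$truth[site_type == "modifier"]
  th <- expected_modifier_contrast(cfg$freq_modifier_partial,
                                   cfg$penetrance)
  obs_contrast <- mod$freq_Partial_CL - mod$freq_Complete_CL
  # binomial-scale standard error at ~2*9000 chromosomes per CL pool
  expect_lt(abs(obs_contrast - th$contrast), 0.02)
  expect_lt(abs(mod$freq_Partial_CL - th$freq_partial_pool), 0.02)
  expect_lt(abs(mod$freq_Complete_CL - th$freq_complete_pool), 0.02)
})

test_that("simulate_dataset is deterministic and round-trips through sync", {
  cfg <- small_cfg(n_neutral_snps = 50)
  pre1 <- tempfile(); pre2 <- tempfile()
  d1 <- simulate_dataset(cfg, seed = 7, out_prefix = pre1)
  d2 <- simulate_dataset(cfg, seed = 7, out_prefix = pre2)
  expect_identical(d1$sites, d2$sites)
  expect_identical(d1$truth, d2$truth)
  expect_identical(readLines(paste0(pre1, ".sync")),
                   readLines(paste0(pre2, ".sync")))
  d3 <- simulate_dataset(cfg, seed = 8)
  expect_false(identical(d1$sites, d3$sites))
  # the sync file reproduces the in-memory counts
  back <- read_sync(paste0(pre1, ".sync"))
  expect_equal(back, d1$sites, ignore_attr = TRUE)
  # n_neutral_snps = 0 leaves exactly the two causal sites
  d0 <- simulate_dataset(small_cfg(n_neutral_snps = 0), seed = 9)
  expect_equal(nrow(d0$sites), 2L)
  expect_equal(sort(d0$truth$site_type), c("major", "modifier"))
})
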
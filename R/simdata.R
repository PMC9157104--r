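## Forward simulation of the study design: individuals carrying a major
## biallelic plate locus (genotypes CC/CL/LL; the low allele L is fully
## recessive for the low morph) and a modifier locus whose genotype
## (PP/PC/CC; P = "partial" allele) sets the probability that a major-locus
## heterozygote expresses the partial rather than the complete morph.
## Individuals are assigned to four phenotype-by-genotype groups, pooled,
## and "sequenced": per-site read depths are Poisson, reads are drawn
## binomially at the pool's true allele frequency, and sequencing errors
## scatter uniformly over the three other bases.
##
## Linkage around each causal SNP uses an exponential-decay copying rule:
## a neutral site at distance d copies the causal allele state of a
## chromosome with probability r(d) = exp(-d / ld_length), and otherwise
## draws from a site-specific background frequency. Sites far from any
## causal SNP therefore decay to independent background noise.

GROUPS <- c("Complete_CC", "Low_LL", "Complete_CL", "Partial_CL")

#' Simulation configuration
#'
#' Builds the parameter set for the forward simulator, defaulting to the
#' emulated study design: 186 phenotyped individuals, a recessive major
#' locus at allele frequency 0.39, a modifier at frequency 0.583 with
#' penetrance 0.9/0.5/0.1 (probability that a major-locus heterozygote is
#' partial, for modifier genotypes PP/PC/CC), ~50,000 SNPs over two 1-Mb
#' chromosomes, group sequencing depths 65/71/118/100x, and per-base
#' sequencing error 0.003.
#'
#' @param n_individuals number of simulated fish.
#' @param freq_major_low population frequency of the major-locus low allele.
#' @param freq_modifier_partial population frequency of the modifier
#'   partial allele.
#' @param penetrance named triple (PP, PC, CC): probability that a
#'   major-locus heterozygote is partially plated given its modifier
#'   genotype.
#' @param n_neutral_snps number of non-causal SNPs (split over the two
#'   chromosomes).
#' @param ld_length decay length L (bp) of the allele-copying probability
#'   `r(d) = exp(-d / L)` around each causal SNP.
#' @param chrom_length length (bp) of each simulated chromosome.
#' @param causal_positions named pair (major, modifier): positions of the
#'   causal SNPs on their chromosomes.
#' @param depth_per_pool named vector of mean sequencing depths per group.
#' @param error_rate per-base sequencing error probability.
#' @param plate_medians named triple (complete, partial, low): Poisson means
#'   of the morph-conditional plate-count distributions.
#' @param background_freq_range range of the uniform site-specific
#'   background allele frequency at neutral sites.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 186,
                       freq_major_low = 0.39,
                       freq_modifier_partial = 0.583,
                       penetrance = c(PP = 0.9, PC = 0.5, CC = 0.1),
                       n_neutral_snps = 49998,
                       ld_length = 10000,
                       chrom_length = 1e6,
                       causal_positions = c(major = 500000, modifier = 500000),
                       depth_per_pool = c(Complete_CC = 65, Low_LL = 71,
                                          Complete_CL = 118, Partial_CL = 100),
                       error_rate = 0.003,
                       plate_medians = c(complete = 47, partial = 39, low = 2),
                       background_freq_range = c(0.05, 0.95)) {
  cfg <- list(n_individuals = as.integer(n_individuals),
              freq_major_low = freq_major_low,
              freq_modifier_partial = freq_modifier_partial,
              penetrance = penetrance, n_neutral_snps = as.integer(n_neutral_snps),
              ld_length = ld_length, chrom_length = as.integer(chrom_length),
              causal_positions = causal_positions,
              depth_per_pool = depth_per_pool, error_rate = error_rate,
              plate_medians = plate_medians,
              background_freq_range = background_freq_range)
  fr <- c(cfg$freq_major_low, cfg$freq_modifier_partial, cfg$penetrance,
          cfg$error_rate, cfg$background_freq_range)
  if (any(is.na(fr)) || any(fr < 0) || any(fr > 1))
    validation_error("frequencies, penetrance and error_rate must be in [0, 1]")
  if (cfg$n_individuals < 1) validation_error("n_individuals must be >= 1")
  if (!all(c("PP", "PC", "CC") %in% names(cfg$penetrance)))
    validation_error("penetrance must be named (PP, PC, CC)")
  if (!all(GROUPS %in% names(cfg$depth_per_pool)) ||
      any(cfg$depth_per_pool <= 0))
    validation_error("depth_per_pool must name all four groups with depths > 0")
  if (!all(c("major", "modifier") %in% names(cfg$causal_positions)) ||
      any(cfg$causal_positions < 1) ||
      any(cfg$causal_positions > cfg$chrom_length))
    validation_error("causal_positions must be (major, modifier) within the chromosome")
  if (cfg$n_neutral_snps < 0) validation_error("n_neutral_snps must be >= 0")
  if (cfg$ld_length < 0) validation_error("ld_length must be >= 0")
  structure(cfg, class = "sim_config")
}

## sample one multinomial genotype class per individual
sample_genotypes <- function(n, p_allele1, labels) {
  probs <- c(p_allele1^2, 2 * p_allele1 * (1 - p_allele1), (1 - p_allele1)^2)
  sample(labels, n, replace = TRUE, prob = probs)
}

#' Assign an individual to an experimental group
#'
#' Group construction combines the phenotypic plate morph with the
#' major-locus genotype: (complete, CC) -> `Complete_CC`; (low, LL) ->
#' `Low_LL`; (complete, CL) -> `Complete_CL`; (partial, CL) ->
#' `Partial_CL`; any other combination -> `unassigned`.
#'
#' @param morph character vector: `"complete"`, `"partial"` or `"low"`.
#' @param major_genotype character vector: `"CC"`, `"CL"` or `"LL"`.
#' @return character vector of group labels.
#' @export
assign_group <- function(morph, major_genotype) {
  out <- rep("unassigned", length(morph))
  out[morph == "complete" & major_genotype == "CC"] <- "Complete_CC"
  out[morph == "low" & major_genotype == "LL"] <- "Low_LL"
  out[morph == "complete" & major_genotype == "CL"] <- "Complete_CL"
  out[morph == "partial" & major_genotype == "CL"] <- "Partial_CL"
  out
}

#' Simulate individual fish
#'
#' Draws major- and modifier-locus genotypes from Hardy-Weinberg proportions
#' at the configured allele frequencies, assigns the plate morph (LL is
#' always low and CC always complete; a CL heterozygote is partial with
#' probability `penetrance[modifier genotype]`, else complete), draws a
#' morph-conditional Poisson plate count, and labels the experimental group.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed (RNG state is preserved).
#' @return `data.table` with columns `id`, `major_genotype`,
#'   `modifier_genotype`, `morph`, `plate_count`, `group`.
#' @export
simulate_individuals <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    n <- config$n_individuals
    maj <- sample_genotypes(n, config$freq_major_low, c("LL", "CL", "CC"))
    mod <- sample_genotypes(n, config$freq_modifier_partial,
                            c("PP", "PC", "CC"))
    morph <- rep("complete", n)
    morph[maj == "LL"] <- "low"
    cl <- maj == "CL"
    partial <- cl & runif(n) < config$penetrance[mod]
    morph[cl] <- "complete"
    morph[partial] <- "partial"
    plates <- rpois(n, config$plate_medians[morph])
    data.table(id = sprintf("ind%04d", seq_len(n)),
               major_genotype = maj, modifier_genotype = mod,
               morph = morph, plate_count = plates,
               group = assign_group(morph, maj))
  })
}

## number of copies of allele 1 carried by each genotype label
dose2 <- function(genotype, hom1) {
  het <- c(LL = "CL", PP = "PC")[[hom1]]
  2L * (genotype == hom1) + 1L * (genotype == het)
}

## split error reads uniformly over the three non-true bases
## (sequential binomial thinning; fully vectorised)
split_errors <- function(n_err) {
  e1 <- rbinom(length(n_err), n_err, 1 / 3)
  e2 <- rbinom(length(n_err), n_err - e1, 1 / 2)
  cbind(e1, e2, n_err - e1 - e2)
}

#' Simulate pooled sequencing read counts
#'
#' For each site and group pool, the true pool allele frequency is the
#' focal-allele count among the group's `2n` chromosomes. At the two causal
#' sites this count is determined by the group members' genotypes; at a
#' neutral site at distance `d` from its chromosome's causal SNP, each
#' chromosome copies the causal allele state with probability
#' `r = exp(-d / ld_length)` and otherwise carries the focal allele at a
#' site-specific uniform background frequency. Read depth per site and pool
#' is Poisson at the group mean; each read reports the true base with
#' probability `1 - error_rate`, otherwise one of the three other bases
#' uniformly.
#'
#' @param individuals table from [simulate_individuals()]; all four groups
#'   must be non-empty.
#' @inheritParams simulate_individuals
#' @return list with `sites` (a site-count table; pools ordered
#'   `Complete_CC`, `Low_LL`, `Complete_CL`, `Partial_CL`) and `truth`
#'   (per-site chrom, pos, ref, alt, `site_type` = major/modifier/neutral,
#'   and the true focal-allele frequency per group).
#' @export
simulate_pool_counts <- function(individuals, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sizes <- vapply(GROUPS, function(g) sum(individuals$group == g), 0L)
  if (any(sizes == 0L))
    config_error("empty experimental group(s): %s",
                 paste(GROUPS[sizes == 0L], collapse = ", "))
  with_seed(seed, {
    ## focal ("allele 1") counts per group at the causal loci:
    ## major locus focal allele = L, modifier focal allele = P
    m_major <- vapply(GROUPS, function(g) {
      sum(dose2(individuals$major_genotype[individuals$group == g], "LL"))
    }, 0L)
    m_mod <- vapply(GROUPS, function(g) {
      sum(dose2(individuals$modifier_genotype[individuals$group == g], "PP"))
    }, 0L)
    H <- 2L * sizes

    ## site map: one causal SNP per chromosome plus uniform neutral SNPs
    n_neu <- config$n_neutral_snps
    n1 <- n_neu %/% 2L
    chroms <- c(major = "chrIV", modifier = "chrXVI")
    mk_chrom <- function(chrom, causal_pos, n_sites, causal_type) {
      avail <- setdiff(seq_len(config$chrom_length), causal_pos)
      neu <- sort(sample(avail, min(n_sites, length(avail))))
      data.table(chrom = chrom,
                 pos = as.integer(sort(c(causal_pos, neu))),
                 site_type = "neutral")[pos == causal_pos,
                                        site_type := causal_type][]
    }
    sites <- rbind(
      mk_chrom(chroms["major"], config$causal_positions[["major"]], n1,
               "major"),
      mk_chrom(chroms["modifier"], config$causal_positions[["modifier"]],
               n_neu - n1, "modifier"))
    ns <- nrow(sites)

    ## per-site copying probability from the chromosome's causal SNP and
    ## background frequency
    causal_pos <- ifelse(sites$chrom == chroms["major"],
                         config$causal_positions[["major"]],
                         config$causal_positions[["modifier"]])
    d <- abs(sites$pos - causal_pos)
    r <- if (config$ld_length > 0) exp(-d / config$ld_length) else
      as.numeric(d == 0)
    q <- runif(ns, config$background_freq_range[1],
               config$background_freq_range[2])

    ## true focal-allele frequency per group
    freqs <- matrix(NA_real_, ns, length(GROUPS),
                    dimnames = list(NULL, GROUPS))
    is_major_chr <- sites$chrom == chroms["major"]
    for (g in seq_along(GROUPS)) {
      m1 <- ifelse(is_major_chr, m_major[g], m_mod[g])
      ## chromosomes carrying causal state 1 show the focal allele w.p.
      ## r + (1-r)q, the others w.p. (1-r)q
      cnt <- rbinom(ns, m1, r + (1 - r) * q) +
        rbinom(ns, H[g] - m1, (1 - r) * q)
      causal <- sites$site_type != "neutral"
      cnt[causal] <- m1[causal]
      freqs[, g] <- cnt / H[g]
    }

    ## base identities and read sampling
    ref <- sample(BASES, ns, replace = TRUE)
    alt_offset <- sample.int(3L, ns, replace = TRUE)
    ref_i <- match(ref, BASES)
    OTHERS <- rbind(c(2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 4L),
                    c(1L, 2L, 3L))
    alt_i <- OTHERS[cbind(ref_i, alt_offset)]
    alt <- BASES[alt_i]
    rows <- seq_len(ns)
    counts <- vector("list", length(GROUPS))
    for (g in seq_along(GROUPS)) {
      depth <- rpois(ns, config$depth_per_pool[[GROUPS[g]]])
      alt_reads <- rbinom(ns, depth, freqs[, g])
      ref_reads <- depth - alt_reads
      err_ref <- rbinom(ns, ref_reads, config$error_rate)
      err_alt <- rbinom(ns, alt_reads, config$error_rate)
      cm <- matrix(0L, ns, 5L)
      cm[cbind(rows, ref_i)] <- ref_reads - err_ref
      cm[cbind(rows, alt_i)] <- cm[cbind(rows, alt_i)] + alt_reads - err_alt
      for (spread in list(list(err_ref, ref_i), list(err_alt, alt_i))) {
        e3 <- split_errors(spread[[1]])
        tgt <- OTHERS[spread[[2]], , drop = FALSE]
        for (k in 1:3)
          cm[cbind(rows, tgt[, k])] <- cm[cbind(rows, tgt[, k])] + e3[, k]
      }
      counts[[g]] <- cm
    }
    truth <- data.table(chrom = sites$chrom, pos = sites$pos, ref = ref,
                        alt = alt, site_type = sites$site_type,
                        ld_r = r)
    for (g in GROUPS) truth[, paste0("freq_", g) := freqs[, g]]
    list(sites = site_counts(sites$chrom, sites$pos, ref, counts),
         truth = truth[])
  })
}

#' Simulate a complete dataset
#'
#' End-to-end wrapper: simulates individuals, groups them, simulates pooled
#' read counts, and optionally writes `<prefix>.sync`, `<prefix>.truth.tsv`
#' and `<prefix>.individuals.tsv`. Deterministic given `seed`.
#'
#' @inheritParams simulate_individuals
#' @param out_prefix optional path prefix for the output files.
#' @return list with `sites`, `truth`, `individuals` and (when written)
#'   `files`.
#' @export
simulate_dataset <- function(config = sim_config(), seed = NULL,
                             out_prefix = NULL) {
  res <- with_seed(seed, {
    ind <- simulate_individuals(config)
    pools <- simulate_pool_counts(ind, config)
    c(pools, list(individuals = ind))
  })
  if (!is.null(out_prefix)) {
    files <- c(sync = paste0(out_prefix, ".sync"),
               truth = paste0(out_prefix, ".truth.tsv"),
               individuals = paste0(out_prefix, ".individuals.tsv"))
    write_sync(res$sites, files["sync"])
    meta <- list(tool = "poolscan simulate",
                 seed = if (is.null(seed)) "none" else seed,
                 pools = paste(GROUPS, collapse = ","))
    write_result_tsv(res$truth, files["truth"], meta)
    write_result_tsv(res$individuals, files["individuals"], meta)
    res$files <- files
  }
  res
}

#' Expected modifier-allele contrast between the two heterozygote pools
#'
#' Closed-form expectation of the difference in partial-allele frequency at
#' the modifier SNP between the `Partial_CL` and `Complete_CL` pools,
#' obtained by enumerating the three modifier genotypes: with HWE genotype
#' probabilities `h(g)` at frequency `p`, penetrance `pi(g)`, and allele
#' dose `x(g)/2` in (1, 1/2, 0), the partial pool's expected frequency is
#' `sum(h pi x/2) / sum(h pi)` and the complete pool's is
#' `sum(h (1-pi) x/2) / sum(h (1-pi))`.
#'
#' @param p modifier partial-allele frequency.
#' @param penetrance named triple (PP, PC, CC), as in [sim_config()].
#' @return list with `freq_partial_pool`, `freq_complete_pool`, `contrast`.
#' @export
expected_modifier_contrast <- function(p, penetrance) {
  h <- hwe_expected(p)                      # (PP, PC, CC)
  pen <- penetrance[c("PP", "PC", "CC")]
  dose <- c(PP = 1, PC = 0.5, CC = 0)
  fp <- sum(h * pen * dose) / sum(h * pen)
  fc <- sum(h * (1 - pen) * dose) / sum(h * (1 - pen))
  list(freq_partial_pool = fp, freq_complete_pool = fc, contrast = fp - fc)
}
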
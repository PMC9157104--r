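## Cross-population allele panels: SNPs fixed between two groups, or
## high-AFD SNPs flanking a focal SNP; the focal ("reduced plating") allele
## is oriented by the pool representing the reduced-plating phenotype, and
## its frequency is then tabulated in any number of additional pools.

panel_template <- function() {
  data.table(chrom = character(), pos = integer(),
             focal_allele = character(), other_allele = character(),
             afd = numeric())
}

mk_panel <- function(dt, focal_definition, source_scan) {
  structure(dt, focal_definition = focal_definition,
            source_scan = source_scan)
}

## orient the focal allele towards the reduced-plating pool
reduced_freq <- function(snps, reduced_pool) {
  if (!reduced_pool %in% c(1L, 2L))
    config_error("reduced_pool must be 1 or 2 (scan pool index)")
  if (reduced_pool == 1L) snps$freq_1 else snps$freq_2
}

#' Panel of SNPs fixed between the two scanned groups
#'
#' Selects SNPs with AFD exactly 1 (after allele cleaning, the two pools
#' carry alternative alleles at frequencies 0 and 1). The focal allele at
#' each SNP is the allele at frequency 1 in the reduced-plating pool.
#'
#' @param snps SNP table or `afd_scan` object.
#' @param reduced_pool which scan pool (1 or 2) is the reduced-plating
#'   group.
#' @param region optional one-row region (`chrom`, `start`, `end`) to
#'   restrict the panel to.
#' @return panel `data.table` (`chrom`, `pos`, `focal_allele`,
#'   `other_allele`, `afd`) with attributes `focal_definition` and
#'   `source_scan`.
#' @export
fixed_snp_panel <- function(snps, reduced_pool, region = NULL) {
  snps <- as_snp_table(snps)
  fx <- snps[afd == 1]
  if (!is.null(region))
    fx <- fx[chrom == region$chrom[1] & pos >= region$start[1] &
               pos <= region$end[1]]
  if (nrow(fx) == 0L)
    return(mk_panel(panel_template(), "fixed", "afd_scan"))
  rf <- reduced_freq(fx, reduced_pool)
  ## freq_* is the minor-allele frequency: at a fixed SNP the reduced pool
  ## carries either the minor (rf == 1) or the major (rf == 0) allele
  out <- fx[, .(chrom, pos,
                focal_allele = ifelse(rf == 1, minor, major),
                other_allele = ifelse(rf == 1, major, minor),
                afd)]
  mk_panel(out,
           sprintf("allele fixed (frequency 1) in reduced-plating pool %d",
                   reduced_pool),
           "afd_scan")
}

#' Panel of high-AFD SNPs flanking a focal SNP
#'
#' Within a region, keeps the focal SNP plus every SNP with AFD at least
#' `afd_min`. The focal allele of each SNP is the allele more frequent in
#' the reduced-plating pool (at an exact 0.5/0.5 frequency in that pool the
#' minor allele is kept, deterministically).
#'
#' @inheritParams fixed_snp_panel
#' @param focal one-row SNP record (`chrom`, `pos`) inside `region`.
#' @param region one-row region (`chrom`, `start`, `end`).
#' @param afd_min minimum AFD for flanking SNPs.
#' @return panel `data.table`, focal SNP first then flanking SNPs by
#'   position.
#' @export
high_afd_panel <- function(snps, focal, region, afd_min = 0.35,
                           reduced_pool = 2) {
  snps <- as_snp_table(snps)
  if (focal$chrom[1] != region$chrom[1] || focal$pos[1] < region$start[1] ||
      focal$pos[1] > region$end[1])
    validation_error("focal SNP %s:%d lies outside the region",
                     focal$chrom[1], focal$pos[1])
  inreg <- snps[chrom == region$chrom[1] & pos >= region$start[1] &
                  pos <= region$end[1]]
  keep <- inreg[afd >= afd_min | pos == focal$pos[1]]
  setorder(keep, pos)
  is_focal <- keep$pos == focal$pos[1]
  keep <- rbind(keep[is_focal], keep[!is_focal])
  rf <- reduced_freq(keep, reduced_pool)
  out <- keep[, .(chrom, pos,
                  focal_allele = ifelse(rf > 0.5, minor, major),
                  other_allele = ifelse(rf > 0.5, major, minor),
                  afd)]
  mk_panel(out,
           sprintf("allele more frequent in reduced-plating pool %d",
                   reduced_pool),
           "afd_scan")
}

#' Focal-allele frequencies of a panel across population pools
#'
#' For every population and panel SNP, the reported frequency is
#' focal-allele reads divided by reads at the two panel alleles; reads at
#' any third base are ignored. A population missing a panel site yields a
#' missing value (logged); a population with zero coverage at every panel
#' site is an error.
#'
#' @param panel panel table from [fixed_snp_panel()] / [high_afd_panel()].
#' @param pools named list of site-count tables, one per population.
#' @param pool_index which pool column of each site-count table to use.
#' @return `data.table` with `population`, `chrom`, `pos`, `focal_allele`,
#'   `frequency`, `depth`.
#' @export
panel_frequencies <- function(panel, pools, pool_index = 1) {
  if (is.null(names(pools)) || any(!nzchar(names(pools))))
    validation_error("pools must be a named list of site-count tables")
  out <- lapply(names(pools), function(popname) {
    sites <- pools[[popname]]
    m <- sites[panel[, .(chrom, pos)], on = c("chrom", "pos")]
    cm <- pool_counts(m, pool_index)
    focal_n <- cm[cbind(seq_len(nrow(panel)), match(panel$focal_allele,
                                                    BASES))]
    other_n <- cm[cbind(seq_len(nrow(panel)), match(panel$other_allele,
                                                    BASES))]
    depth <- focal_n + other_n
    missing <- is.na(focal_n) | depth == 0
    if (all(missing))
      validation_error("population '%s' has no coverage at any panel site",
                       popname)
    if (any(missing))
      message(sprintf("panel_frequencies: %d site(s) missing in '%s'",
                      sum(missing), popname))
    data.table(population = popname, chrom = panel$chrom, pos = panel$pos,
               focal_allele = panel$focal_allele,
               frequency = ifelse(missing, NA_real_, focal_n / depth),
               depth = ifelse(missing, NA_integer_, as.integer(depth)))
  })
  rbindlist(out)
}
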
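## Intersect candidate regions with the gene annotation and flag genes whose
## name or attribute text matches functional keywords — the programmatic
## stand-in for a manual database screen of candidate genes.

DEFAULT_KEYWORDS <- c("bone", "ectoderm", "tumor necrosis factor", "wnt")

#' Genes overlapping a candidate region
#'
#' Returns the genes whose 1-based closed interval overlaps the region by at
#' least 1 bp (a gene straddling the region boundary counts), sorted by
#' start position.
#'
#' @param genes gene table from [read_gff_genes()].
#' @param region a one-row region (needs `chrom`, `start`, `end`), e.g. one
#'   row of [candidate_regions()] output.
#' @return subset of `genes`, sorted by `start`.
#' @export
genes_in_region <- function(genes, region) {
  hit <- genes$chrom == region$chrom[1] &
    genes$start <= region$end[1] & genes$end >= region$start[1]
  out <- as.data.table(genes)[hit]
  setorder(out, start)
  out[]
}

#' Flag genes matching functional keywords
#'
#' Case-insensitive substring matching of each keyword against the gene's
#' display name and its attribute text. Gene records are never altered; the
#' result lists, per gene, the matched keywords in the order given.
#'
#' @param genes gene table from [read_gff_genes()].
#' @param keywords non-empty character vector of search terms.
#' @return `data.table` with `gene_id` and `matched_keywords` (keywords
#'   joined by `","`; empty string when nothing matches).
#' @export
flag_keywords <- function(genes, keywords = DEFAULT_KEYWORDS) {
  if (length(keywords) == 0L || all(!nzchar(keywords)))
    validation_error("keywords must be non-empty")
  hay <- tolower(paste(genes$name, genes$attributes))
  matched <- vapply(seq_len(nrow(genes)), function(i) {
    hit <- vapply(tolower(keywords), grepl, NA, x = hay[i], fixed = TRUE)
    paste(keywords[hit], collapse = ",")
  }, "")
  data.table(gene_id = genes$gene_id, matched_keywords = matched)
}

#' Annotate candidate regions with overlapping genes and keyword flags
#'
#' @param regions region table from [candidate_regions()].
#' @param genes gene table from [read_gff_genes()].
#' @param keywords search terms for [flag_keywords()].
#' @return `data.table` with one row per (region, overlapping gene):
#'   `region_chrom`, `region_start`, `region_end`, `gene_id`, `name`,
#'   `strand`, `start`, `end`, `matched_keywords`. Regions without genes
#'   contribute a single row with `NA` gene fields.
#' @export
annotate_regions <- function(regions, genes, keywords = DEFAULT_KEYWORDS) {
  out <- lapply(seq_len(nrow(regions)), function(i) {
    reg <- regions[i]
    g <- genes_in_region(genes, reg)
    base <- data.table(region_chrom = reg$chrom, region_start = reg$start,
                       region_end = reg$end)
    if (nrow(g) == 0L)
      return(cbind(base, data.table(gene_id = NA_character_,
                                    name = NA_character_,
                                    strand = NA_character_,
                                    start = NA_integer_, end = NA_integer_,
                                    matched_keywords = NA_character_)))
    flags <- flag_keywords(g, keywords)
    cbind(base[rep(1L, nrow(g))],
          g[, .(gene_id, name, strand, start, end)],
          flags[, .(matched_keywords)])
  })
  rbindlist(out)
}
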
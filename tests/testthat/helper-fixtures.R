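library(data.table)

## build a two-pool site table from per-pool named count lists, e.g.
## two_pool_site(c(A = 50), c(G = 50))
two_pool_site <- function(p1, p2, chrom = "chrI", pos = 100L, ref = "A") {
  mk <- function(x) {
    m <- matrix(0L, 1L, 4L, dimnames = list(NULL, c("A", "C", "G", "T")))
    m[1L, names(x)] <- as.integer(x)
    m
  }
  site_counts(chrom, pos, ref, list(mk(p1), mk(p2)))
}

## stack several two-pool sites (list of list(p1, p2)) at increasing pos
two_pool_sites <- function(specs, chrom = "chrI",
                           pos = seq(100L, by = 100L,
                                     length.out = length(specs))) {
  dt <- rbindlist(lapply(seq_along(specs), function(i) {
    two_pool_site(specs[[i]][[1]], specs[[i]][[2]], chrom = chrom,
                  pos = pos[i])
  }))
  dt
}

## random SNP table for window/oracle tests
random_snp_table <- function(n, chroms = c("chrA", "chrB"),
                             max_pos = 200000L) {
  dt <- data.table(chrom = sample(chroms, n, replace = TRUE),
                   pos = sample.int(max_pos, n),
                   major = "A", minor = "G",
                   depth_1 = 80L, depth_2 = 80L,
                   freq_1 = runif(n), freq_2 = runif(n))
  dt[, afd := abs(freq_1 - freq_2)]
  setorder(dt, chrom, pos)
  unique(dt, by = c("chrom", "pos"))
}

## write a small GFF3 annotation and return its path
write_toy_gff <- function(path = tempfile(fileext = ".gff3")) {
  lines <- c(
    "##gff-version 3",
    "chrA\ttoy\tgene\t100\t200\t.\t+\t.\tID=g1;Name=edar;description=bone development receptor",
    "chrA\ttoy\tmRNA\t100\t200\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chrA\ttoy\texon\t100\t150\t.\t+\t.\tParent=g1.t1",
    "chrA\ttoy\tgene\t401\t500\t.\t-\t.\tID=g2;description=wnt/beta-catenin signaling",
    "chrB\ttoy\tgene\t50\t80\t.\t+\t.\tID=g3;Name=actb")
  writeLines(lines, path)
  path
}
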
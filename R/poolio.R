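## File formats touched by the pipeline: samtools mpileup text, popoolation2
## sync count tables, GFF3 gene annotation, and TSV result tables.
##
## All coordinates are 1-based throughout (positions and closed intervals),
## matching mpileup, sync and GFF3; no 0-based conversion happens anywhere.

BASES <- c("A", "C", "G", "T")

## sync files carry counts in A:T:C:G:N:del order; internally we use A,C,G,T
SYNC_ORDER <- c("A", "T", "C", "G")

#' Per-site nucleotide count table
#'
#' Builds the pipeline's central container: one row per genomic site with
#' A/C/G/T (and deletion) read counts for each pool. Columns are `chrom`,
#' `pos`, `ref`, then `A_i`, `C_i`, `G_i`, `T_i`, `del_i` for pool
#' `i = 1..n_pools`.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param ref reference base per site (A/C/G/T/N).
#' @param counts list with one element per pool, each an `n x 4` (or `n x 5`
#'   with deletions) matrix of non-negative integer counts in A,C,G,T order.
#' @return a `data.table` of site counts.
#' @export
site_counts <- function(chrom, pos, ref, counts) {
  n <- length(pos)
  if (length(chrom) != n || length(ref) != n)
    validation_error("chrom, pos and ref must have equal length")
  if (any(pos < 1L)) validation_error("positions must be >= 1")
  dt <- data.table(chrom = as.character(chrom), pos = as.integer(pos),
                   ref = as.character(ref))
  for (i in seq_along(counts)) {
    m <- counts[[i]]
    if (nrow(m) != n || !ncol(m) %in% c(4L, 5L))
      validation_error("count matrix for pool %d must be %d x 4 (or x 5)", i, n)
    if (any(m < 0)) validation_error("negative count in pool %d", i)
    dt[, paste0(BASES, "_", i) := as.data.table(m[, 1:4, drop = FALSE])]
    dt[, paste0("del_", i) := if (ncol(m) == 5L) as.integer(m[, 5L]) else 0L]
  }
  dt[]
}

#' Number of pools in a site-count table
#' @param sites a site-count `data.table` (see [site_counts()]).
#' @return integer number of pools.
#' @export
n_pools <- function(sites) {
  sum(grepl("^A_[0-9]+$", names(sites)))
}

#' Extract one pool's count matrix
#' @inheritParams n_pools
#' @param pool pool index (1-based).
#' @param del include the deletion column as a 5th column?
#' @return numeric matrix, sites x bases (A,C,G,T\[,del\]).
#' @export
pool_counts <- function(sites, pool, del = FALSE) {
  cols <- paste0(BASES, "_", pool)
  if (del) cols <- c(cols, paste0("del_", pool))
  if (!all(cols %in% names(sites)))
    validation_error("no such pool: %d", pool)
  m <- as.matrix(sites[, cols, with = FALSE])
  colnames(m) <- if (del) c(BASES, "del") else BASES
  m
}

## readLines through a connection so plain and gzip input both work
## (file() sniffs the gzip magic bytes on read).
read_text_lines <- function(path) {
  con <- file(path, open = "r")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read a popoolation2-style sync file
#'
#' Sync files are tab-separated: chromosome, position, reference base, then
#' one `A:T:C:G:N:del` count field per pool. Counts are reordered into the
#' internal A,C,G,T order; the N slot is ignored and deletions are kept in a
#' separate column.
#'
#' @param path path to a sync file (plain or gzip-compressed).
#' @return a site-count `data.table` (see [site_counts()]).
#' @export
read_sync <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    return(site_counts(character(), integer(), character(),
                       list(matrix(0L, 0, 4))))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L || nf[1] < 4L)
    format_error("sync: inconsistent field count (first bad line: %d)",
                 which(nf != nf[1])[1])
  np <- nf[1] - 3L
  m <- matrix(unlist(fields), ncol = nf[1], byrow = TRUE)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos))
    format_error("sync: non-integer position at line %d", which(is.na(pos))[1])
  counts <- vector("list", np)
  for (i in seq_len(np)) {
    cf <- strsplit(m[, 3L + i], ":", fixed = TRUE)
    if (any(lengths(cf) != 6L))
      format_error("sync: pool %d count field is not A:T:C:G:N:del at line %d",
                   i, which(lengths(cf) != 6L)[1])
    cm <- suppressWarnings(matrix(as.integer(unlist(cf)), ncol = 6L,
                                  byrow = TRUE))
    if (anyNA(cm))
      format_error("sync: non-integer count in pool %d at line %d",
                   i, which(rowSums(is.na(cm)) > 0)[1])
    ## A:T:C:G -> A,C,G,T; keep del (col 6), drop N (col 5)
    counts[[i]] <- cm[, c(1L, 3L, 4L, 2L, 6L), drop = FALSE]
  }
  site_counts(m[, 1], pos, m[, 3], counts)
}

#' Write a site-count table as a sync file
#'
#' Emits the popoolation2 dialect: chrom, pos, ref, then per pool
#' `A:T:C:G:N:del` with N always 0. Inverse of [read_sync()].
#'
#' @inheritParams n_pools
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_sync <- function(sites, path) {
  np <- n_pools(sites)
  cols <- lapply(seq_len(np), function(i) {
    cm <- pool_counts(sites, i, del = TRUE)
    sprintf("%d:%d:%d:%d:0:%d", cm[, "A"], cm[, "T"], cm[, "C"], cm[, "G"],
            cm[, "del"])
  })
  lines <- do.call(paste, c(list(sites$chrom, sites$pos, sites$ref), cols,
                            sep = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

## Decode one mpileup read-base string into A/C/G/T/del counts.
## Standard encoding: . and , are the reference base; ACGTacgt alternate
## bases; ^X marks a read start (X is mapping quality, consumed); $ a read
## end; +n<seq>/-n<seq> an indel whose sequence is skipped; * (or #) a
## deleted base; > and < reference skips and N are ignored.
decode_pileup_bases <- function(bases, ref) {
  out <- c(A = 0L, C = 0L, G = 0L, T = 0L, del = 0L)
  ref <- toupper(ref)
  chars <- strsplit(bases, "", fixed = TRUE)[[1]]
  i <- 1L
  len <- length(chars)
  while (i <= len) {
    ch <- chars[i]
    if (ch == "^") {
      i <- i + 2L                      # ^ consumes the mapping-quality char
    } else if (ch == "$") {
      i <- i + 1L
    } else if (ch == "." || ch == ",") {
      if (ref %in% BASES) out[ref] <- out[ref] + 1L
      i <- i + 1L
    } else if (ch %in% c("+", "-")) {
      j <- i + 1L
      while (j <= len && chars[j] %in% as.character(0:9)) j <- j + 1L
      nskip <- as.integer(paste0(chars[(i + 1L):(j - 1L)], collapse = ""))
      if (is.na(nskip))
        format_error("mpileup: indel without length after '%s'", ch)
      i <- j + nskip
    } else if (ch == "*" || ch == "#") {
      out["del"] <- out["del"] + 1L
      i <- i + 1L
    } else {
      up <- toupper(ch)
      if (up %in% BASES) {
        out[up] <- out[up] + 1L
      } else if (up %in% c("N", ">", "<")) {
        ## ambiguous base / reference skip: not a base call
      } else {
        format_error("mpileup: unknown base symbol '%s'", ch)
      }
      i <- i + 1L
    }
  }
  out
}

#' Read samtools mpileup text into site counts
#'
#' Parses plain `samtools mpileup` output (3 + 3 per-pool columns: depth,
#' read bases, base qualities) into per-pool nucleotide counts. Base and
#' mapping qualities are ignored; indel sequences are skipped rather than
#' counted as base calls; N and reference skips are ignored.
#'
#' @param path path to mpileup text (plain or gzip-compressed).
#' @param n_pools number of pools (samples) in the file.
#' @return a site-count `data.table` (see [site_counts()]).
#' @export
read_mpileup <- function(path, n_pools) {
  n_pools <- as.integer(n_pools)
  if (is.na(n_pools) || n_pools < 1L)
    config_error("n_pools must be a positive integer")
  lines <- read_text_lines(path)
  lines <- lines[nzchar(lines)]
  expected <- 3L + 3L * n_pools
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != expected)
  if (length(bad))
    format_error("mpileup: expected %d columns, got %d at line %d",
                 expected, lengths(fields)[bad[1]], bad[1])
  nsite <- length(lines)
  counts <- lapply(seq_len(n_pools), function(i) matrix(0L, nsite, 5L))
  chrom <- character(nsite); pos <- integer(nsite); ref <- character(nsite)
  for (s in seq_len(nsite)) {
    f <- fields[[s]]
    chrom[s] <- f[1]
    pos[s] <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos[s]))
      format_error("mpileup: non-integer position at line %d", s)
    ref[s] <- f[3]
    for (i in seq_len(n_pools)) {
      depth <- suppressWarnings(as.integer(f[3L * i + 1L]))
      if (is.na(depth))
        format_error("mpileup: non-integer depth at line %d", s)
      if (depth > 0L)
        counts[[i]][s, ] <- decode_pileup_bases(f[3L * i + 2L], ref[s])
    }
  }
  site_counts(chrom, pos, ref, counts)
}

#' Read gene records from a GFF3 annotation
#'
#' Extracts features of a given type (default `"gene"`) as a flat table with
#' 1-based closed coordinates. Attribute key/value pairs other than `ID` and
#' `Name` are collapsed into a single `attributes` string, which downstream
#' keyword flagging searches. Features lacking an `ID` attribute are skipped
#' with a warning.
#'
#' @param path path to a GFF3 file (plain or gzip-compressed).
#' @param feature_type feature type(s) to keep, matched against column 3.
#' @return a `data.table` with columns `gene_id`, `name`, `chrom`, `start`,
#'   `end`, `strand`, `attributes`.
#' @export
read_gff_genes <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)              # seqnames,start,end,strand + attributes
  df <- df[as.character(df$type) %in% feature_type, , drop = FALSE]
  id <- if ("ID" %in% names(df)) as.character(df$ID) else
    rep(NA_character_, nrow(df))
  keep <- !is.na(id) & nzchar(id)
  if (any(!keep))
    warning(sprintf("skipping %d feature(s) without an ID attribute",
                    sum(!keep)))
  df <- df[keep, , drop = FALSE]; id <- id[keep]
  nm <- if ("Name" %in% names(df)) as.character(df$Name) else
    rep("", nrow(df))
  nm[is.na(nm)] <- ""
  drop <- c("seqnames", "start", "end", "width", "strand",
            "source", "type", "score", "phase", "ID", "Name")
  extra <- setdiff(names(df), drop)
  attrs <- if (length(extra) && nrow(df)) {
    vapply(seq_len(nrow(df)), function(r) {
      vals <- vapply(extra, function(k) {
        paste(unlist(df[r, k]), collapse = ",")
      }, "")
      ok <- !is.na(vals) & nzchar(vals) & vals != "NA"
      paste(sprintf("%s=%s", extra[ok], vals[ok]), collapse = ";")
    }, "")
  } else rep("", nrow(df))
  data.table(gene_id = id, name = nm,
             chrom = as.character(df$seqnames),
             start = as.integer(df$start),
             end = as.integer(df$end),
             strand = as.character(df$strand),
             attributes = as.character(attrs))
}

## TSV result tables carry a commented provenance header.
write_result_tsv <- function(dt, path, meta = NULL) {
  con <- file(path, "w")
  if (!is.null(meta)) {
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, function(x) paste(x, collapse = ","), "")),
               con)
  }
  close(con)
  fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

## Read a result TSV back, skipping the provenance header.
read_result_tsv <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  fread(text = paste(lines, collapse = "\n"), sep = "\t")
}
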
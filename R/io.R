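# Readers/writers for the package's plain-text dialects.  All tables are TSV
# with a header; missing values are encoded "NA".  Region files are BED
# (chrom, start, end, id) with an optional companion BED of covered
# sub-intervals keyed by the id column.

#' Read regions from a BED file
#'
#' @param path BED file with columns chrom, start, end, id (no header).
#' @param covered_path Optional companion BED (chrom, start, end, id) whose
#'   rows are the covered sub-intervals of the regions, matched by id.
#' @return Named list of [region] objects.
#' @export
read_regions_bed <- function(path, covered_path = NULL) {
  bed <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("chrom", "start", "end", "id"),
                    colClasses = c("character", "numeric", "numeric", "character"))
  cov <- NULL
  if (!is.null(covered_path)) {
    cov <- read.table(covered_path, sep = "\t", header = FALSE,
                      col.names = c("chrom", "start", "end", "id"),
                      colClasses = c("character", "numeric", "numeric", "character"))
  }
  out <- lapply(seq_len(nrow(bed)), function(i) {
    cm <- NULL
    if (!is.null(cov)) {
      sub <- cov[cov$id == bed$id[i], , drop = FALSE]
      if (nrow(sub) > 0) cm <- as.matrix(sub[, c("start", "end")])
    }
    region(bed$id[i], bed$chrom[i], bed$start[i], bed$end[i], covered = cm)
  })
  names(out) <- bed$id
  out
}

#' Write regions (and their coverage masks) as BED
#' @param regions Named list of [region] objects.
#' @param path Output BED path.
#' @param covered_path Optional path for the covered-interval companion BED.
#' @export
write_regions_bed <- function(regions, path, covered_path = NULL) {
  bed <- do.call(rbind, lapply(regions, function(r) {
    data.frame(chrom = r$chrom, start = r$start, end = r$end, id = r$id)
  }))
  write.table(format_num_df(bed), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  if (!is.null(covered_path)) {
    cov <- do.call(rbind, lapply(regions, function(r) {
      data.frame(chrom = r$chrom, start = r$covered[, 1],
                 end = r$covered[, 2], id = r$id)
    }))
    write.table(format_num_df(cov), covered_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

format_num_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- format(df[[j]], scientific = FALSE, trim = TRUE)
  }
  df
}

#' Read/write segregating-site tables
#'
#' Columns: region_id, chrom, pos, ancestral, derived, k, n (and, if present,
#' klass).  `read_sites` recomputes `klass` with [classify_mutation] and
#' validates `1 <= k <= n-1`.
#'
#' @param path TSV path.
#' @return Data frame of sites.
#' @export
read_sites <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                   colClasses = list(region_id = "character",
                                     chrom = "character",
                                     ancestral = "character",
                                     derived = "character"))
  if (any(df$k < 1 | df$k > df$n - 1)) {
    stop("site table violates 1 <= k <= n-1")
  }
  df$klass <- classify_mutation(df$ancestral, df$derived)
  df
}

#' @rdname read_sites
#' @param sites Data frame of sites.
#' @export
write_sites <- function(sites, path) {
  keep <- intersect(c("region_id", "chrom", "pos", "ancestral", "derived",
                      "k", "n", "klass"), names(sites))
  write.table(sites[, keep, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read/write fixed-difference tables
#'
#' Columns: region_id, chrom, pos, human, chimp, ancestral.  The lineage and
#' mutation class are recomputed on read: the substitution is on the human
#' lineage iff the human allele differs from the ancestral allele, and the
#' class is that of the ancestral-to-non-ancestral change.
#'
#' @param path TSV path.
#' @return Data frame of fixed differences with `lineage` and `klass`.
#' @export
read_fixed <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, na.strings = "NA",
                   colClasses = list(region_id = "character",
                                     chrom = "character",
                                     human = "character", chimp = "character",
                                     ancestral = "character"))
  annotate_fixed(df)
}

annotate_fixed <- function(df) {
  if (any(df$human == df$chimp, na.rm = TRUE)) {
    stop("fixed differences require human != chimp")
  }
  anc <- toupper(df$ancestral)
  df$lineage <- ifelse(toupper(df$human) != anc, "human", "chimp")
  der <- ifelse(df$lineage == "human", df$human, df$chimp)
  df$klass <- classify_mutation(anc, der)
  df
}

#' @rdname read_fixed
#' @param fixed Data frame of fixed differences.
#' @export
write_fixed <- function(fixed, path) {
  keep <- intersect(c("region_id", "chrom", "pos", "human", "chimp",
                      "ancestral", "lineage", "klass"), names(fixed))
  write.table(fixed[, keep, drop = FALSE], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read/write site-frequency-spectrum files
#'
#' Two tab-separated columns, "frequency" and "count", preceded by a comment
#' line `# n=<int>`.
#'
#' @param path Spectrum file path.
#' @return A [daf_spectrum].
#' @export
read_spectrum <- function(path) {
  first <- readLines(path, n = 1L)
  m <- regmatches(first, regexec("n=([0-9]+)", first))[[1]]
  if (length(m) < 2) stop("spectrum file must start with a '# n=<int>' line")
  n <- as.integer(m[2])
  df <- read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                   col.names = c("frequency", "count"))
  counts <- numeric(n - 1L)
  counts[df$frequency] <- df$count
  daf_spectrum(counts, n)
}

#' @rdname read_spectrum
#' @param spec A [daf_spectrum].
#' @export
write_spectrum <- function(spec, path) {
  stopifnot(inherits(spec, "daf_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# n=%d", spec$n), con)
  write.table(data.frame(frequency = seq_along(spec$counts),
                         count = format(spec$counts, digits = 17, trim = TRUE,
                                        scientific = FALSE)),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Ingest biallelic SNVs from a VCF into the site-table dialect
#'
#' Reads biallelic SNVs, polarizes them by an ancestral-allele INFO tag, and
#' maps them to the segregating-site table columns.  Sites whose ancestral
#' allele is missing or matches neither REF nor ALT are dropped.  Requires
#' the vcfR package.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param aa_tag INFO tag holding the ancestral allele (default `"AA"`).
#' @param region_id Label to place in the region_id column.
#' @return Site data frame (pos, ancestral, derived, k, n, klass).
#' @export
read_sites_vcf <- function(path, aa_tag = "AA", region_id = NA_character_) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("read_sites_vcf requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  aa <- toupper(vcfR::extract.info(v, element = aa_tag))
  gt <- vcfR::extract.gt(v)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L & !grepl(",", fix$ALT)
  rows <- which(keep & !is.na(aa) & (aa == toupper(fix$REF) | aa == toupper(fix$ALT)))
  out <- lapply(rows, function(i) {
    alleles <- unlist(strsplit(gt[i, ], "[/|]"))
    alleles <- alleles[!is.na(alleles) & alleles != "."]
    n <- length(alleles)
    anc_is_ref <- aa[i] == toupper(fix$REF[i])
    derived <- if (anc_is_ref) toupper(fix$ALT[i]) else toupper(fix$REF[i])
    k <- if (anc_is_ref) sum(alleles == "1") else sum(alleles == "0")
    if (n < 2L || k < 1L || k > n - 1L) return(NULL)
    data.frame(region_id = region_id, chrom = fix$CHROM[i],
               pos = as.numeric(fix$POS[i]) - 1,  # VCF is 1-based
               ancestral = aa[i], derived = derived, k = k, n = n)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(region_id = character(), chrom = character(),
                      pos = numeric(), ancestral = character(),
                      derived = character(), k = integer(), n = integer())
  }
  out$klass <- if (nrow(out)) classify_mutation(out$ancestral, out$derived) else character()
  out
}
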
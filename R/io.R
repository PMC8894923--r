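#' Read a bismark-style per-cytosine report
#'
#' Parses the tab-separated per-cytosine output of a bisulfite mapper:
#' columns chrom, position (1-based), strand, methylated count, unmethylated
#' count, context (CG/CHG/CHH) and an optional trinucleotide column. Rows
#' with zero coverage are retained (they matter for the "no methylated CHG
#' in the control" eligibility rule); positions are converted to the package's
#' 0-based internal convention.
#'
#' @param path path to the report (plain text, tab-separated).
#' @param sample_id label for the library.
#' @param genome_id genome label (defaults to `"genome"`).
#' @return a [methylome()] with every input row, sorted by position.
#' @export
read_cytosine_report <- function(path, sample_id, genome_id = "genome") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(methylome(data.table(chrom = character(), pos = integer(),
                                strand = character(), count_m = integer(),
                                count_u = integer(), context = character()),
                     sample_id, genome_id))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 6L)
  if (length(bad)) {
    stop(sprintf("line %d: expected >= 6 tab-separated fields, found %d",
                 bad[1], nf[bad[1]]))
  }
  m <- matrix(unlist(lapply(parts, `[`, 1:6)), ncol = 6, byrow = TRUE)
  pos1 <- suppressWarnings(as.integer(m[, 2]))
  cm <- suppressWarnings(as.integer(m[, 4]))
  cu <- suppressWarnings(as.integer(m[, 5]))
  check_field <- function(vals, raw, what) {
    bad <- which(is.na(vals) | vals < 0L)
    if (length(bad)) {
      stop(sprintf("line %d: invalid %s '%s'", bad[1], what, raw[bad[1]]))
    }
  }
  check_field(pos1, m[, 2], "position")
  check_field(cm, m[, 4], "methylated count")
  check_field(cu, m[, 5], "unmethylated count")
  bad <- which(!m[, 3] %in% STRANDS)
  if (length(bad)) stop(sprintf("line %d: unknown strand '%s'", bad[1], m[bad[1], 3]))
  bad <- which(!m[, 6] %in% CONTEXTS)
  if (length(bad)) stop(sprintf("line %d: unknown context '%s'", bad[1], m[bad[1], 6]))
  dt <- data.table(chrom = m[, 1], pos = pos1 - 1L, strand = m[, 3],
                   count_m = cm, count_u = cu, context = m[, 6])
  methylome(dt, sample_id, genome_id)
}

#' Write a methylome as a per-cytosine report
#'
#' Inverse of [read_cytosine_report()]: emits the tab-separated 1-based
#' report format, including zero-coverage rows, so that a read/write
#' round-trip reproduces the table exactly.
#'
#' @param x a [methylome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(x, path) {
  out <- data.table(x$chrom, x$pos + 1L, x$strand, x$count_m, x$count_u,
                    x$context)
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read gene and transposable-element features from GFF3
#'
#' Imports a GFF3 annotation and classifies records into genes and
#' transposable elements according to their GFF3 `type`. 1-based inclusive
#' GFF3 coordinates are converted to the 0-based half-open internal
#' convention.
#'
#' @param path GFF3 file.
#' @param gene_types GFF3 type strings treated as genes.
#' @param te_types GFF3 type strings treated as transposable elements.
#' @return a [feature_set()]; types absent from the file yield empty classes.
#' @export
read_gff3_features <- function(path, gene_types = "gene",
                               te_types = c("transposable_element")) {
  if (!file.exists(path)) stop("no such file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c(gene_types, te_types)
  gr <- gr[keep]
  if (!length(gr)) {
    return(feature_set(data.table(chrom = character(), start = integer(),
                                  end = integer(), strand = character(),
                                  feature_class = character(),
                                  feature_id = character())))
  }
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else NA_character_
  ids[is.na(ids)] <- sprintf("feature_%06d", which(is.na(ids)))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "+"
  feature_set(data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = strand,
    feature_class = ifelse(as.character(gr$type) %in% gene_types,
                           "gene", "transposable_element"),
    feature_id = ids
  ))
}

#' Read a plain gene-identifier list
#'
#' One identifier per line; blank lines and `#` comments skipped; duplicate
#' identifiers collapsed.
#'
#' @param path input file.
#' @param label label for the resulting set (default: file base name).
#' @return a [gene_list()].
#' @export
read_gene_list <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  ids <- trimws(readLines(path))
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  gene_list(ids, label %||% sub("\\.[^.]*$", "", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write DMRs as BED6
#'
#' One line per DMR: chrom, start, end (0-based half-open), name
#' `context:direction`, score `round(1000 * |mean delta|)`, strand `.`.
#'
#' @param dmrs a DMR table as returned by [call_dmrs()].
#' @param path output path.
#' @param header write a `track` header line? Off by default.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path, header = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (header) writeLines("track name=dmrs", con)
  if (nrow(dmrs)) {
    writeLines(sprintf("%s\t%d\t%d\t%s:%s\t%d\t.",
                       dmrs$chrom, dmrs$start, dmrs$end, dmrs$context,
                       dmrs$direction, round(1000 * abs(dmrs$mean_delta))),
               con)
  }
  invisible(path)
}

#' Read a BED6 DMR file written by [write_dmr_bed()]
#'
#' @param path BED file.
#' @return data.table with chrom, start, end, context, direction, score.
#' @export
read_dmr_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track")]
  if (!length(lines)) {
    return(data.table(chrom = character(), start = integer(), end = integer(),
                      context = character(), direction = character(),
                      score = integer()))
  }
  parts <- tstrsplit(lines, "\t", fixed = TRUE)
  name <- tstrsplit(parts[[4]], ":", fixed = TRUE)
  data.table(chrom = parts[[1]], start = as.integer(parts[[2]]),
             end = as.integer(parts[[3]]), context = name[[1]],
             direction = name[[2]], score = as.integer(parts[[5]]))
}

#' Write binned methylation levels as bedGraph
#'
#' Emits one record per bin with a defined level (bins with no covered
#' cytosine are omitted), the level rounded to 4 decimals.
#'
#' @param bins a bin-level table from [bin_methylation()] (one sample,
#'   one context).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(bins, path) {
  def <- bins[!is.na(bins$level)]
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(def)) {
    writeLines(sprintf("%s\t%d\t%d\t%.4f", def$chrom, def$start, def$end,
                       def$level), con)
  }
  invisible(path)
}
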
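#' @import data.table
#' @importFrom stats rbinom rnorm rpois runif setNames dhyper
#' @importFrom utils head tail
NULL

CONTEXTS <- c("CG", "CHG", "CHH")
STRANDS <- c("+", "-")

#' Construct a methylome table
#'
#' A methylome table holds strand-resolved per-cytosine read counts for one
#' sequencing library (or a pool of libraries). Positions are stored 0-based
#' internally; the bismark-style report format is 1-based and converted on
#' read/write. Symmetric CG dinucleotides are *not* collapsed: each strand's
#' cytosine is an independent record.
#'
#' @param dt data.frame/data.table with columns `chrom`, `pos` (0-based
#'   integer), `strand` (`+`/`-`), `count_m`, `count_u` (non-negative integer
#'   read counts), `context` (`CG`, `CHG`, `CHH`).
#' @param sample_id label for the library.
#' @param genome_id label tying the table to a genome/annotation.
#' @param validate check invariants (sorted, no duplicate sites)?
#' @return A `methylome` object (a `data.table` with `sample_id` and
#'   `genome_id` attributes), sorted by (chrom, pos, strand).
#' @export
methylome <- function(dt, sample_id, genome_id = "genome", validate = TRUE) {
  dt <- as.data.table(dt)
  req <- c("chrom", "pos", "strand", "count_m", "count_u", "context")
  missing_cols <- setdiff(req, names(dt))
  if (length(missing_cols)) {
    stop("methylome table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  dt <- dt[, req, with = FALSE]
  dt[, chrom := as.character(chrom)]
  dt[, pos := as.integer(pos)]
  dt[, count_m := as.integer(count_m)]
  dt[, count_u := as.integer(count_u)]
  setorder(dt, chrom, pos, strand)
  if (validate) {
    if (any(is.na(dt$pos)) || any(dt$pos < 0)) {
      stop("positions must be non-negative integers")
    }
    bad_strand <- !dt$strand %in% STRANDS
    if (any(bad_strand)) {
      stop("unknown strand value: ", dt$strand[which(bad_strand)[1]])
    }
    bad_ctx <- !dt$context %in% CONTEXTS
    if (any(bad_ctx)) {
      stop("unknown context value: ", dt$context[which(bad_ctx)[1]])
    }
    if (any(is.na(dt$count_m)) || any(is.na(dt$count_u)) ||
        any(dt$count_m < 0) || any(dt$count_u < 0)) {
      stop("read counts must be non-negative integers")
    }
    if (anyDuplicated(dt, by = c("chrom", "pos", "strand"))) {
      d <- dt[duplicated(dt, by = c("chrom", "pos", "strand"))][1]
      stop(sprintf("duplicate site %s:%d:%s in sample '%s'",
                   d$chrom, d$pos + 1L, d$strand, sample_id))
    }
  }
  setattr(dt, "sample_id", sample_id)
  setattr(dt, "genome_id", genome_id)
  setattr(dt, "class", c("methylome", class(dt)))
  dt[]
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf("methylome '%s' (genome '%s'): %d cytosines on %d chromosome(s)\n",
              sample_id(x), genome_id(x), nrow(x),
              length(unique(x$chrom))))
  if (nrow(x)) {
    tab <- table(x$context)
    cat("  contexts:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = " "),
        "\n")
  }
  invisible(x)
}

#' Sample and genome identifiers of a methylome
#' @param x a `methylome`
#' @return a character scalar label.
#' @export
sample_id <- function(x) attr(x, "sample_id")

#' @rdname sample_id
#' @export
genome_id <- function(x) attr(x, "genome_id")

stopifnot_same_genome <- function(...) {
  ids <- vapply(list(...), genome_id, character(1))
  if (length(unique(ids)) > 1) {
    stop("methylomes come from different genomes: ",
         paste(unique(ids), collapse = " vs "))
  }
  invisible(ids[1])
}

#' Feature set constructor
#'
#' Gene and transposable-element intervals used for DMR annotation and
#' metaplots. Coordinates are 0-based half-open.
#'
#' @param dt data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `feature_class` (`gene` or `transposable_element`), `feature_id`.
#' @return a `feature_set` (data.table).
#' @export
feature_set <- function(dt) {
  dt <- as.data.table(dt)
  req <- c("chrom", "start", "end", "strand", "feature_class", "feature_id")
  missing_cols <- setdiff(req, names(dt))
  if (length(missing_cols)) {
    stop("feature set is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  dt <- dt[, req, with = FALSE]
  dt[, start := as.integer(start)]
  dt[, end := as.integer(end)]
  if (any(dt$start >= dt$end)) stop("feature intervals must satisfy start < end")
  bad <- !dt$feature_class %in% c("gene", "transposable_element")
  if (any(bad)) stop("unknown feature_class: ", dt$feature_class[which(bad)[1]])
  dup <- dt[, .N, by = .(feature_class, feature_id)][N > 1]
  if (nrow(dup)) {
    stop("duplicate feature_id within class: ", dup$feature_id[1])
  }
  setorder(dt, chrom, start, end)
  setattr(dt, "class", c("feature_set", class(dt)))
  dt[]
}

#' Gene list constructor
#'
#' A labelled set of gene identifiers (e.g. a differentially-expressed-gene
#' set produced upstream).
#'
#' @param gene_ids character vector of identifiers (deduplicated).
#' @param label free-text label for the set.
#' @return a `gene_list` object.
#' @export
gene_list <- function(gene_ids, label = "genes") {
  structure(list(gene_ids = unique(as.character(gene_ids)), label = label),
            class = "gene_list")
}

#' @export
print.gene_list <- function(x, ...) {
  cat(sprintf("gene_list '%s': %d ids\n", x$label, length(x$gene_ids)))
  invisible(x)
}

#' @export
length.gene_list <- function(x) length(x$gene_ids)

# Derived tables (bins, calls, DMRs) must not inherit the methylome class
# or its sample attributes from data.table subsetting.
as_plain_table <- function(x) {
  setattr(x, "class", c("data.table", "data.frame"))
  setattr(x, "sample_id", NULL)
  setattr(x, "genome_id", NULL)
  x
}

# GRanges helpers -------------------------------------------------------

# internal 0-based half-open -> GRanges (1-based closed)
intervals_to_granges <- function(dt, strand = NULL) {
  GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end),
    strand = if (is.null(strand)) "*" else strand
  )
}
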
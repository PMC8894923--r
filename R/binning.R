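# Replicate pooling, fixed-bin weighted methylation levels, and per-site
# differential calls.

#' Pool replicate methylomes by summing read counts
#'
#' Per-site methylated and unmethylated counts are summed across the input
#' tables; a site appears in the output if it appears in at least one input.
#' Pooling is order-invariant.
#'
#' @param tables list of [methylome()] objects sharing a `genome_id`.
#' @param sample_id label for the pooled table (default: joined inputs).
#' @return a pooled [methylome()].
#' @export
pool_replicates <- function(tables, sample_id = NULL) {
  stopifnot(length(tables) >= 1)
  do.call(stopifnot_same_genome, tables)
  if (is.null(sample_id)) {
    sample_id <- paste(vapply(tables, function(t) attr(t, "sample_id"),
                              character(1)), collapse = "+")
  }
  if (length(tables) == 1) {
    out <- copy(tables[[1]])
    setattr(out, "sample_id", sample_id)
    return(out)
  }
  all <- rbindlist(lapply(tables, function(t)
    t[, .(chrom, pos, strand, context, count_m, count_u)]))
  pooled <- all[, .(count_m = sum(count_m), count_u = sum(count_u)),
                by = .(chrom, pos, strand, context)]
  ctx <- pooled[, .N, by = .(chrom, pos, strand)][N > 1]
  if (nrow(ctx)) {
    stop(sprintf("site %s:%d:%s has conflicting contexts across replicates",
                 ctx$chrom[1], ctx$pos[1] + 1L, ctx$strand[1]))
  }
  methylome(pooled, sample_id, genome_id(tables[[1]]), validate = FALSE)
}

#' Weighted methylation levels in fixed genomic bins
#'
#' Tiles each chromosome in fixed-width bins anchored at position 0 and
#' computes, per bin, the weighted methylation level of the requested
#' context: the sum of methylated reads divided by the sum of total reads
#' over cytosines with coverage at least `min_cov`. Bins containing sites of
#' the context but no covered site get an `NA` (undefined) level.
#'
#' @param table a [methylome()].
#' @param context `CG`, `CHG` or `CHH`.
#' @param bin_size bin width in bp (default 100).
#' @param min_cov minimum per-site coverage for a cytosine to contribute.
#' @return data.table (chrom, start, end, n_sites, n_covered, sum_m, sum_t,
#'   level) with one row per bin containing at least one site of the context.
#' @export
bin_methylation <- function(table, context, bin_size = 100L, min_cov = 4L) {
  if (!context %in% CONTEXTS) stop("unknown context: ", context)
  sel <- table$context == context
  x <- table[sel, .(chrom, pos, cov = count_m + count_u, count_m)]
  if (!nrow(x)) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), n_sites = integer(),
                      n_covered = integer(), sum_m = integer(),
                      sum_t = integer(), level = numeric()))
  }
  x[, start := (pos %/% bin_size) * bin_size]
  bins <- x[, .(n_sites = .N,
                n_covered = sum(cov >= min_cov),
                sum_m = sum(count_m[cov >= min_cov]),
                sum_t = sum(cov[cov >= min_cov])),
            by = .(chrom, start)]
  bins[, end := start + bin_size]
  bins[, level := ifelse(n_covered > 0, sum_m / sum_t, NA_real_)]
  bins <- as_plain_table(bins)
  setorder(bins, chrom, start)
  setcolorder(bins, c("chrom", "start", "end", "n_sites", "n_covered",
                      "sum_m", "sum_t", "level"))
  bins[]
}

#' Per-cytosine differential methylation calls
#'
#' Emits one record per site covered at least `min_cov` in *both* samples,
#' with per-sample levels, their difference `delta = level_b - level_a`, and
#' a differential flag `is_dmc` true when `|delta| >= threshold`.
#'
#' @param table_a,table_b two [methylome()] objects on the same genome
#'   (conventionally a = control, b = treated).
#' @param context cytosine context to compare.
#' @param threshold absolute level difference required to flag a site.
#' @param min_cov minimum coverage in both samples.
#' @return data.table (chrom, pos, strand, level_a, level_b, delta, is_dmc,
#'   direction) where direction is the sign of delta.
#' @export
call_dmcs <- function(table_a, table_b, context, threshold, min_cov = 4L) {
  if (!context %in% CONTEXTS) stop("unknown context: ", context)
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  stopifnot_same_genome(table_a, table_b)
  sel_a <- table_a$context == context
  sel_b <- table_b$context == context
  a <- table_a[sel_a, .(chrom, pos, strand, m_a = count_m,
                        cov_a = count_m + count_u)]
  b <- table_b[sel_b, .(chrom, pos, strand, m_b = count_m,
                        cov_b = count_m + count_u)]
  j <- a[b, on = c("chrom", "pos", "strand"), nomatch = NULL]
  j <- j[cov_a >= min_cov & cov_b >= min_cov]
  j[, level_a := m_a / cov_a]
  j[, level_b := m_b / cov_b]
  j[, delta := level_b - level_a]
  j[, is_dmc := abs(delta) >= threshold]
  j[, direction := sign(delta)]
  setorder(j, chrom, pos, strand)
  as_plain_table(j[, .(chrom, pos, strand, level_a, level_b, delta, is_dmc,
                       direction)])
}
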
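# DMR calling: screen 100-bp bins on DMC count and bin-level difference,
# merge candidate bins within 200 bp, discard singletons; ectopic-CHG
# variant additionally requires an unmethylated control bin.

#' DMR-calling parameters
#'
#' Bundles the thresholds of the bin-based DMR definition. Context defaults:
#' CG requires >= 4 differential cytosines and an absolute bin difference of
#' at least 0.40; CHG requires >= 5 and 0.35; the ectopic-CHG variant
#' requires >= 3 and 0.15 plus an unmethylated control bin. Candidate bins
#' within `merge_gap` bp (edge-to-edge) are merged and clusters of a single
#' bin are discarded.
#'
#' @param context `CG` or `CHG`.
#' @param direction `hypo`, `hyper`, or `ectopic` (CHG gains over an
#'   unmethylated control).
#' @param min_dmc minimum number of differentially methylated cytosines in a
#'   bin, with sign matching `direction`.
#' @param min_diff minimum absolute bin-level difference; also used as the
#'   per-site differential threshold.
#' @param merge_gap maximum edge-to-edge gap (bp) between candidate bins
#'   that merge.
#' @param bin_size bin width in bp.
#' @param min_cov minimum per-site coverage.
#' @param control_max_level for `ectopic`: maximum weighted CHG level of the
#'   control bin to count as unmethylated.
#' @param control_max_m_reads for `ectopic`: maximum methylated reads allowed
#'   at any single control site in the bin.
#' @return a `dmr_params` list.
#' @export
dmr_params <- function(context = c("CG", "CHG"),
                       direction = c("hypo", "hyper", "ectopic"),
                       min_dmc = NULL, min_diff = NULL,
                       merge_gap = 200L, bin_size = 100L, min_cov = 4L,
                       control_max_level = 0.02, control_max_m_reads = 1L) {
  context <- match.arg(context)
  direction <- match.arg(direction)
  if (direction == "ectopic" && context != "CHG") {
    stop("ectopic calling is defined for the CHG context")
  }
  defaults <- list(CG = list(min_dmc = 4L, min_diff = 0.40),
                   CHG = list(min_dmc = 5L, min_diff = 0.35),
                   ectopic = list(min_dmc = 3L, min_diff = 0.15))
  d <- if (direction == "ectopic") defaults$ectopic else defaults[[context]]
  p <- list(context = context, direction = direction,
            min_dmc = as.integer(min_dmc %||% d$min_dmc),
            min_diff = min_diff %||% d$min_diff,
            merge_gap = as.integer(merge_gap),
            bin_size = as.integer(bin_size), min_cov = as.integer(min_cov),
            control_max_level = control_max_level,
            control_max_m_reads = as.integer(control_max_m_reads))
  if (p$min_dmc < 1) stop("min_dmc must be >= 1")
  if (p$min_diff <= 0 || p$min_diff > 1) stop("min_diff must lie in (0, 1]")
  if (p$merge_gap < 0) stop("merge_gap must be >= 0")
  structure(p, class = "dmr_params")
}

#' Screen bins for DMR candidacy
#'
#' A bin is a candidate iff (i) its level is defined in both samples,
#' (ii) the signed difference `treated - control` matches the requested
#' direction with magnitude at least `min_diff`, and (iii) the bin contains
#' at least `min_dmc` differential cytosines whose sign matches the bin's
#' direction. For ectopic calling an eligibility table of unmethylated
#' control bins gates candidacy additionally.
#'
#' @param bins_a,bins_b bin tables from [bin_methylation()] for control (a)
#'   and treated (b), on the same grid.
#' @param dmcs site calls from [call_dmcs()] for the same pair.
#' @param params a [dmr_params()].
#' @param eligible optional data.table (chrom, start) of bins allowed to be
#'   candidates (used by [call_ectopic_chg()]).
#' @return data.table of candidate bins (chrom, start, end, level_a,
#'   level_b, delta, n_dmc), sorted.
#' @export
screen_bins <- function(bins_a, bins_b, dmcs, params, eligible = NULL) {
  if (any(bins_a$start %% params$bin_size != 0L) ||
      any(bins_b$start %% params$bin_size != 0L)) {
    stop("bin tables are not on the ", params$bin_size, "-bp grid")
  }
  a <- bins_a[, .(chrom, start, end, level_a = level)]
  b <- bins_b[, .(chrom, start, level_b = level)]
  j <- a[b, on = c("chrom", "start"), nomatch = NULL]
  j <- j[!is.na(level_a) & !is.na(level_b)]
  j[, delta := level_b - level_a]
  want_sign <- if (params$direction == "hypo") -1 else 1
  j <- j[sign(delta) == want_sign & abs(delta) >= params$min_diff]
  d <- dmcs[dmcs$is_dmc & dmcs$direction == want_sign,
            .(chrom, start = (pos %/% params$bin_size) * params$bin_size)]
  cnt <- d[, .(n_dmc = .N), by = .(chrom, start)]
  j <- cnt[j, on = c("chrom", "start")]
  j[is.na(n_dmc), n_dmc := 0L]
  j <- j[n_dmc >= params$min_dmc]
  if (!is.null(eligible)) {
    j <- j[eligible[, .(chrom, start)], on = c("chrom", "start"),
           nomatch = NULL]
  }
  setorder(j, chrom, start)
  j[, .(chrom, start, end, level_a, level_b, delta, n_dmc)]
}

#' Merge candidate bins into DMRs
#'
#' Single-linkage merge of candidate bins whose edge-to-edge gap is at most
#' `merge_gap` bp; clusters consisting of a single bin are discarded (a bin
#' must merge at least once to be part of a DMR). The DMR interval spans the
#' first bin start to the last bin end; `mean_delta` is the unweighted mean
#' of member-bin deltas.
#'
#' @param candidates candidate-bin table from [screen_bins()].
#' @param params a [dmr_params()].
#' @return DMR data.table (chrom, start, end, context, direction, n_bins,
#'   mean_delta, member_bins list-column of bin starts), sorted.
#' @export
merge_candidates <- function(candidates, params) {
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), context = character(),
                      direction = character(), n_bins = integer(),
                      mean_delta = numeric(), member_bins = list())
  if (!nrow(candidates)) return(empty)
  x <- copy(candidates)
  setorder(x, chrom, start)
  x[, gap := start - shift(end), by = chrom]
  x[, new_cluster := is.na(gap) | gap > params$merge_gap]
  x[, cluster := cumsum(new_cluster)]
  dmrs <- x[, .(chrom = chrom[1], start = min(start), end = max(end),
                n_bins = .N, mean_delta = mean(delta),
                member_bins = list(start)),
            by = cluster]
  dmrs <- dmrs[n_bins >= 2L]
  if (!nrow(dmrs)) return(empty)
  dmrs[, cluster := NULL]
  dmrs[, context := params$context]
  dmrs[, direction := params$direction]
  setorder(dmrs, chrom, start)
  setcolorder(dmrs, c("chrom", "start", "end", "context", "direction",
                      "n_bins", "mean_delta", "member_bins"))
  dmrs[]
}

#' Call DMRs between a control and a treated methylome
#'
#' Composition of [bin_methylation()], [call_dmcs()], [screen_bins()] and
#' [merge_candidates()]: bins are screened on differential-cytosine count
#' and bin-level difference, candidates within 200 bp are merged, and
#' isolated candidate bins are dropped.
#'
#' @param control,treated [methylome()] objects on the same genome.
#' @param params a [dmr_params()] (defaults: CG hypo with the standard
#'   thresholds).
#' @return sorted DMR data.table; the parameters used are attached as the
#'   `params` attribute.
#' @export
call_dmrs <- function(control, treated, params = dmr_params("CG", "hypo")) {
  stopifnot_same_genome(control, treated)
  bins_a <- bin_methylation(control, params$context, params$bin_size,
                            params$min_cov)
  bins_b <- bin_methylation(treated, params$context, params$bin_size,
                            params$min_cov)
  dmcs <- call_dmcs(control, treated, params$context, params$min_diff,
                    params$min_cov)
  cand <- screen_bins(bins_a, bins_b, dmcs, params)
  dmrs <- merge_candidates(cand, params)
  setattr(dmrs, "params", params)
  dmrs
}

#' Call regions of ectopic CHG methylation
#'
#' CHG gains over bins that are unmethylated in the control: a candidate bin
#' must have control weighted CHG level at most `control_max_level` *and* no
#' single control site with more than `control_max_m_reads` methylated
#' reads, at least `min_dmc` sites gaining at least `min_diff`, and a bin
#' gain of at least `min_diff`. Merging and singleton discarding are as in
#' [call_dmrs()].
#'
#' @param control,treated [methylome()] objects on the same genome.
#' @param params a [dmr_params()] with `direction = "ectopic"`.
#' @return sorted DMR data.table (direction `ectopic`).
#' @export
call_ectopic_chg <- function(control, treated,
                             params = dmr_params("CHG", "ectopic")) {
  stopifnot_same_genome(control, treated)
  if (params$direction != "ectopic") {
    stop("call_ectopic_chg requires direction = 'ectopic'")
  }
  bins_a <- bin_methylation(control, "CHG", params$bin_size, params$min_cov)
  bins_b <- bin_methylation(treated, "CHG", params$bin_size, params$min_cov)
  # control eligibility over *all* CHG sites, irrespective of coverage
  ctl <- control[control$context == "CHG",
                 .(max_m = max(count_m)),
                 by = .(chrom, start = (pos %/% params$bin_size) *
                          params$bin_size)]
  elig <- bins_a[!is.na(level) & level <= params$control_max_level,
                 .(chrom, start)]
  elig <- elig[ctl[max_m <= params$control_max_m_reads, .(chrom, start)],
               on = c("chrom", "start"), nomatch = NULL]
  dmcs <- call_dmcs(control, treated, "CHG", params$min_diff, params$min_cov)
  cand <- screen_bins(bins_a, bins_b, dmcs, params, eligible = elig)
  dmrs <- merge_candidates(cand, params)
  setattr(dmrs, "params", params)
  dmrs
}
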
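# Gene-body metaplots, chromosome-scale ratio tracks, and DMR x sample
# level matrices.

#' Gene-body methylation metaplot
#'
#' Averages weighted methylation over genes in fixed 100-bp intervals laid
#' out strand-aware around each gene: `flank/100` upstream bins, `body/100`
#' bins walking in from the 5' end, `body/100` bins walking out to the 3'
#' end, and `flank/100` downstream bins. For genes shorter than twice the
#' body window only non-overlapping interval pairs contribute (pair index
#' `j` is kept iff `j * 100 <= length/2`). Per interval the profile value is
#' the unweighted mean over genes of each gene's weighted level there; genes
#' with no covered cytosine in an interval are skipped for that interval.
#'
#' @param table a [methylome()].
#' @param features a [feature_set()]; only `gene` features are profiled.
#' @param context cytosine context.
#' @param flank flank size in bp (multiple of 100; default 2000).
#' @param body_window bp profiled inward from each gene end (multiple of
#'   100; default 1500).
#' @param min_cov minimum site coverage.
#' @return data.table (slot, zone, offset, mean_level, n_genes) with one
#'   row per 100-bp interval in 5'-to-3' order; `offset` is the bp of the
#'   interval start relative to the nearest gene end (negative upstream).
#' @export
gene_metaplot <- function(table, features, context = "CG", flank = 2000L,
                          body_window = 1500L, min_cov = 4L) {
  if (flank %% 100L != 0L || body_window %% 100L != 0L) {
    stop("flank and body_window must be multiples of 100")
  }
  nf <- flank %/% 100L
  nb <- body_window %/% 100L
  slots <- data.table(
    slot = seq_len(2L * nf + 2L * nb),
    zone = rep(c("upstream", "body_5p", "body_3p", "downstream"),
               c(nf, nb, nb, nf)),
    j = c(seq_len(nf), seq_len(nb), seq_len(nb), seq_len(nf)))
  slots[, offset := c(-(nf:1) * 100L, (seq_len(nb) - 1L) * 100L,
                      -(nb:1) * 100L, (seq_len(nf) - 1L) * 100L)]
  genes <- features[features$feature_class == "gene", ]
  prof <- slots[, .(slot, zone, offset)]
  if (!nrow(genes)) {
    prof[, `:=`(mean_level = NA_real_, n_genes = 0L)]
    return(prof[])
  }
  g <- as.data.table(genes)[, .(chrom, gstart = start, gend = end, strand,
                                gene_id = feature_id, L = end - start)]
  g[, gi := .I]
  iv <- cbind(g[rep(seq_len(nrow(g)), each = nrow(slots))],
              slots[rep(seq_len(nrow(slots)), times = nrow(g))])
  iv[, istart := NA_integer_]
  iv[zone == "upstream",
     istart := ifelse(strand == "+", gstart - (nf - j + 1L) * 100L,
                      gend + (nf - j) * 100L)]
  iv[zone == "body_5p",
     istart := ifelse(strand == "+", gstart + (j - 1L) * 100L,
                      gend - j * 100L)]
  iv[zone == "body_3p",
     istart := ifelse(strand == "+", gend - (nb - j + 1L) * 100L,
                      gstart + (nb - j) * 100L)]
  iv[zone == "downstream",
     istart := ifelse(strand == "+", gend + (j - 1L) * 100L,
                      gstart - j * 100L)]
  # drop overlapping body pairs in short genes, and flanks past the origin
  iv[, keep := TRUE]
  iv[zone == "body_5p", keep := j * 100L <= L / 2]
  iv[zone == "body_3p", keep := (nb - j + 1L) * 100L <= L / 2]
  iv <- iv[keep == TRUE & istart >= 0L]
  iv[, iend := istart + 100L]

  sel <- table$context == context & table$count_m + table$count_u >= min_cov
  x <- table[sel, .(chrom, istart = pos, iend = pos + 1L, count_m,
                    cov = count_m + count_u)]
  setkey(iv, chrom, istart, iend)
  ov <- foverlaps(x, iv[, .(chrom, istart, iend, gi, slot)],
                  type = "within", nomatch = NULL)
  lv <- ov[, .(level = sum(count_m) / sum(cov)), by = .(gi, slot)]
  agg <- lv[, .(mean_level = mean(level), n_genes = .N), by = slot]
  prof <- agg[prof, on = "slot"]
  prof[is.na(n_genes), n_genes := 0L]
  setorder(prof, slot)
  as_plain_table(prof[, .(slot, zone, offset, mean_level, n_genes)])
}

#' Chromosome-scale methylation ratio track
#'
#' Computes weighted methylation levels in large bins (default 100 kb) for
#' two samples and their ratio numerator/denominator; bins where the
#' denominator level is below `floor` (or undefined) are left undefined.
#'
#' @param numerator,denominator [methylome()] objects on the same genome.
#' @param context cytosine context.
#' @param bin bin width in bp (default 100000).
#' @param floor minimum denominator level for a defined ratio.
#' @param min_cov minimum site coverage (default 1).
#' @return data.table (chrom, start, end, level_num, level_den, ratio).
#' @export
chromosome_ratio_profile <- function(numerator, denominator, context = "CG",
                                     bin = 100000L, floor = 0.01,
                                     min_cov = 1L) {
  stopifnot_same_genome(numerator, denominator)
  num <- bin_methylation(numerator, context, bin, min_cov)
  den <- bin_methylation(denominator, context, bin, min_cov)
  j <- merge(num[, .(chrom, start, end, level_num = level)],
             den[, .(chrom, start, level_den = level)],
             by = c("chrom", "start"), all = TRUE)
  j[, ratio := ifelse(!is.na(level_den) & level_den >= floor &
                        !is.na(level_num),
                      level_num / level_den, NA_real_)]
  setorder(j, chrom, start)
  as_plain_table(j)[]
}

#' DMR x sample methylation level matrix
#'
#' For each DMR interval and each sample, the weighted methylation level
#' over the DMR's covered cytosines of the requested context (read counts
#' pooled across sites); cells with no covered site are `NA`. This is the
#' input of DMR heatmaps.
#'
#' @param dmrs DMR table.
#' @param tables list of [methylome()] objects.
#' @param context cytosine context.
#' @param min_cov minimum site coverage.
#' @return numeric matrix, rows `chrom:start-end` per DMR (genomic order),
#'   columns sample ids.
#' @export
dmr_sample_matrix <- function(dmrs, tables, context = "CG", min_cov = 4L) {
  dmr_dt <- as.data.table(dmrs)[, .(chrom, istart = start, iend = end)]
  dmr_dt[, row := .I]
  rn <- sprintf("%s:%d-%d", dmr_dt$chrom, dmr_dt$istart, dmr_dt$iend)
  mat <- matrix(NA_real_, nrow = nrow(dmr_dt), ncol = length(tables),
                dimnames = list(rn, vapply(tables, sample_id, character(1))))
  if (!nrow(dmr_dt)) return(mat)
  setkey(dmr_dt, chrom, istart, iend)
  for (k in seq_along(tables)) {
    t <- tables[[k]]
    sel <- t$context == context & t$count_m + t$count_u >= min_cov
    x <- t[sel, .(chrom, istart = pos, iend = pos + 1L, count_m,
                  cov = count_m + count_u)]
    ov <- foverlaps(x, dmr_dt, type = "within", nomatch = NULL)
    lv <- ov[, .(level = sum(count_m) / sum(cov)), by = row]
    mat[lv$row, k] <- lv$level
  }
  mat
}
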
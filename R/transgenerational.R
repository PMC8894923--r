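# Per-DMR transgenerational restoration of methylation and epiallele
# segregation between sibling lines.

#' Fraction of lost methylation that was restored
#'
#' Linear interpolation between the progenitor (eM2) and control levels:
#' `r = (em3 - em2) / (control - em2)`, clipped to `[0, 1]`, so `r = 1`
#' means full restoration to the control level and `r = 0` no recovery.
#' Undefined (`NA`) when the control-eM2 loss is smaller than `min_loss`
#' (no meaningful loss to restore) or any level is missing.
#'
#' @param level_control,level_em2,level_em3 weighted methylation levels in
#'   `[0, 1]` (vectorised).
#' @param min_loss minimum `|control - em2|` for a defined fraction.
#' @return numeric vector of restoration fractions in `[0, 1]` or `NA`.
#' @export
restoration_fraction <- function(level_control, level_em2, level_em3,
                                 min_loss = 0.2) {
  loss <- level_control - level_em2
  r <- (level_em3 - level_em2) / loss
  r <- pmin(pmax(r, 0), 1)
  r[is.na(loss) | abs(loss) < min_loss | is.na(level_em3)] <- NA_real_
  r
}

#' Classify per-DMR methylation restoration across generations
#'
#' Computes weighted levels over each DMR interval in the control, eM2 and
#' eM3 methylomes, the restoration fraction, and a status: `restored`
#' (`r >= restore_threshold`), `unrestored` (`r <= 1 - restore_threshold`),
#' `partial` in between, or `undefined`.
#'
#' @param dmrs DMR table (any table with chrom/start/end works, e.g. a
#'   planted-region registry).
#' @param control,em2,em3 [methylome()] objects.
#' @param context cytosine context.
#' @param restore_threshold restoration fraction from which a DMR counts as
#'   restored (default 0.8).
#' @param min_loss minimum control-eM2 loss for a defined fraction.
#' @param min_cov minimum site coverage.
#' @return list with `records` (data.table: DMR interval, the three levels,
#'   `r`, `status`) and `summary` (fractions of restored / partial /
#'   unrestored among defined records, and `n_defined`).
#' @export
classify_restoration <- function(dmrs, control, em2, em3, context = "CG",
                                 restore_threshold = 0.8, min_loss = 0.2,
                                 min_cov = 4L) {
  mat <- dmr_sample_matrix(dmrs, list(control, em2, em3), context, min_cov)
  rec <- as.data.table(dmrs)[, .(chrom, start, end)]
  rec[, level_control := mat[, 1]]
  rec[, level_em2 := mat[, 2]]
  rec[, level_em3 := mat[, 3]]
  rec[, r := restoration_fraction(level_control, level_em2, level_em3,
                                  min_loss)]
  rec[, status := fifelse(is.na(r), "undefined",
                   fifelse(r >= restore_threshold, "restored",
                    fifelse(r <= 1 - restore_threshold, "unrestored",
                            "partial")))]
  def <- rec[status != "undefined"]
  summary <- list(
    n_defined = nrow(def),
    restored = if (nrow(def)) mean(def$status == "restored") else NA_real_,
    partial = if (nrow(def)) mean(def$status == "partial") else NA_real_,
    unrestored = if (nrow(def)) mean(def$status == "unrestored") else NA_real_)
  list(records = rec[], summary = summary)
}

#' Compare restoration between sibling lines
#'
#' Joins two restoration-record tables computed on the identical DMR list
#' and classifies each DMR's joint status: both restored, both unrestored
#' (including partial agreement on the same status), `segregating` when the
#' two siblings' defined statuses differ, or `undefined` when either is.
#'
#' @param records_a,records_b `records` tables from
#'   [classify_restoration()] on the same DMRs.
#' @return list with `joint` (per-DMR table with `status_a`, `status_b`,
#'   `joint_status`), `segregating` (the subset with differing statuses)
#'   and `segregating_fraction` (among DMRs defined in both siblings).
#' @export
compare_sibling_lines <- function(records_a, records_b) {
  key <- c("chrom", "start", "end")
  if (nrow(records_a) != nrow(records_b) ||
      !identical(records_a[, key, with = FALSE],
                 records_b[, key, with = FALSE])) {
    stop("sibling records are not keyed by the same DMRs")
  }
  joint <- records_a[, .(chrom, start, end, status_a = status,
                         r_a = r)]
  joint[, status_b := records_b$status]
  joint[, r_b := records_b$r]
  joint[, joint_status := fifelse(
    status_a == "undefined" | status_b == "undefined", "undefined",
    fifelse(status_a == status_b, paste0(status_a, "/", status_b),
            "segregating"))]
  def <- joint[joint_status != "undefined"]
  seg <- joint[joint_status == "segregating"]
  list(joint = joint[], segregating = seg[],
       segregating_fraction = if (nrow(def)) nrow(seg) / nrow(def)
                              else NA_real_)
}
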
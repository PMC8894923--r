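# DMR annotation against genomic features, DMR/DEG intersection, and the
# exact multi-set intersection test.

#' Classify DMRs against genomic features
#'
#' Computes, per DMR, the bp of overlap with genes and with transposable
#' elements and assigns one class by largest overlap (ties broken in favour
#' of genes); DMRs overlapping neither class are `intergenic`.
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param features a [feature_set()].
#' @return the DMR table with columns `bp_gene`, `bp_te`, `feature_class`
#'   and a comma-separated `feature_ids` column of overlapped features.
#' @export
classify_dmrs <- function(dmrs, features) {
  out <- copy(as.data.table(dmrs))
  if (!nrow(out)) {
    out[, `:=`(bp_gene = integer(), bp_te = integer(),
               feature_class = character(), feature_ids = character())]
    return(out[])
  }
  dgr <- intervals_to_granges(out)
  overlap_bp <- function(cls) {
    f <- features[features$feature_class == cls, ]
    bp <- integer(nrow(out))
    ids <- character(nrow(out))
    if (nrow(f)) {
      fgr <- intervals_to_granges(f)
      hits <- GenomicRanges::findOverlaps(dgr, fgr)
      if (length(hits)) {
        w <- GenomicRanges::width(IRanges::pintersect(
          dgr[S4Vectors::queryHits(hits)], fgr[S4Vectors::subjectHits(hits)]))
        agg <- data.table(q = S4Vectors::queryHits(hits), w = w,
                          id = f$feature_id[S4Vectors::subjectHits(hits)])
        s <- agg[, .(bp = sum(w), ids = paste(id, collapse = ",")), by = q]
        bp[s$q] <- s$bp
        ids[s$q] <- s$ids
      }
    }
    list(bp = bp, ids = ids)
  }
  g <- overlap_bp("gene")
  t <- overlap_bp("transposable_element")
  out[, bp_gene := g$bp]
  out[, bp_te := t$bp]
  out[, feature_class := ifelse(bp_gene == 0L & bp_te == 0L, "intergenic",
                                ifelse(bp_gene >= bp_te, "gene",
                                       "transposable_element"))]
  out[, feature_ids := ifelse(feature_class == "gene", g$ids,
                              ifelse(feature_class == "transposable_element",
                                     t$ids, ""))]
  out[]
}

#' Genes overlapping or near DMRs
#'
#' A gene is included iff the minimum genomic distance between its interval
#' and any DMR interval is at most `window` bp (overlap counts as distance
#' 0); strand is ignored.
#'
#' @param dmrs DMR table.
#' @param features a [feature_set()]; only `gene` features are considered.
#' @param window proximity window in bp (default 1000).
#' @return a [gene_list()] of qualifying gene identifiers.
#' @export
genes_near_dmrs <- function(dmrs, features, window = 1000L) {
  if (window < 0) stop("window must be >= 0")
  genes <- features[features$feature_class == "gene", ]
  if (!nrow(genes) || !nrow(dmrs)) {
    return(gene_list(character(), sprintf("genes_within_%dbp_of_dmrs", window)))
  }
  ggr <- intervals_to_granges(genes)
  dgr <- intervals_to_granges(dmrs)
  hits <- GenomicRanges::distanceToNearest(ggr, dgr, ignore.strand = TRUE)
  keep <- S4Vectors::queryHits(hits)[
    S4Vectors::mcols(hits)$distance <= window]
  gene_list(genes$feature_id[keep],
            sprintf("genes_within_%dbp_of_dmrs", window))
}

#' Intersect two gene lists
#'
#' @param list_a,list_b [gene_list()] objects.
#' @return a [gene_list()] of the common identifiers, labelled with both
#'   parents.
#' @export
intersect_gene_sets <- function(list_a, list_b) {
  gene_list(intersect(list_a$gene_ids, list_b$gene_ids),
            paste(list_a$label, list_b$label, sep = " & "))
}

# Exact pmf of the k-set intersection size under independent uniform draws
# without replacement: conditionally on |S1 ∩ ... ∩ Sj| = m, the overlap
# with the next set of size s is hypergeometric(m, n - m, s).
intersection_size_pmf <- function(sizes, n) {
  if (any(sizes > n)) stop("set size exceeds universe size")
  pmf <- c(rep(0, sizes[1]), 1)  # point mass at |S1|
  for (s in sizes[-1]) {
    m_max <- length(pmf) - 1L
    x_max <- min(m_max, s)
    # M[m+1, x+1] = P(overlap = x | current intersection = m)
    M <- outer(0:m_max, 0:x_max,
               function(m, x) dhyper(x, m, n - m, s))
    pmf <- as.numeric(pmf %*% M)
  }
  pmf
}

#' Exact multi-set intersection test
#'
#' Given k sets drawn from a universe of `universe_size` elements, computes
#' the expected size of their common intersection under independent uniform
#' sampling without replacement, the fold enrichment of the observed
#' intersection, and the exact upper-tail p-value
#' `P(X >= observed)`. For k = 2 the null distribution is hypergeometric;
#' for k > 2 it is obtained by exact convolution over successive
#' intersections. Above `exact_limit` (on the smallest running intersection
#' bound) a Monte-Carlo estimate over `mc_draws` hypergeometric chains is
#' used instead.
#'
#' @param sets list of [gene_list()] objects or character vectors (bin keys,
#'   gene ids, ...).
#' @param universe_size number of elements the sets are drawn from.
#' @param exact_limit largest min-set size for which the exact convolution
#'   is computed.
#' @param mc_draws Monte-Carlo sample size for the fallback.
#' @param seed seed for the Monte-Carlo fallback.
#' @return an `intersection_result` list: labels, sizes, universe_size,
#'   observed, expected, fold, p_value, method.
#' @export
multiset_exact_test <- function(sets, universe_size, exact_limit = 2000L,
                                mc_draws = 100000L, seed = 1L) {
  if (length(sets) < 2) stop("need at least two sets")
  ids <- lapply(sets, function(s) {
    if (inherits(s, "gene_list")) s$gene_ids else unique(as.character(s))
  })
  labels <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (inherits(s, "gene_list")) s$label else sprintf("set%d", i)
  }, character(1))
  sizes <- lengths(ids)
  n <- as.integer(universe_size)
  if (any(sizes > n)) stop("set size exceeds universe size")
  observed <- length(Reduce(intersect, ids))
  expected <- n * prod(sizes / n)
  if (min(sizes) <= exact_limit) {
    pmf <- intersection_size_pmf(sizes, n)
    if (observed == 0) {
      p <- 1
    } else {
      p <- sum(pmf[(observed + 1L):length(pmf)])
      p <- min(max(p, 0), 1)
    }
    method <- "exact"
  } else {
    p <- with_seed(seed, {
      x <- rep(sizes[1], mc_draws)
      for (s in sizes[-1]) x <- stats::rhyper(mc_draws, x, n - x, s)
      (sum(x >= observed) + 1) / (mc_draws + 1)
    })
    method <- "monte-carlo"
  }
  structure(list(labels = labels, sizes = as.integer(sizes),
                 universe_size = n, observed = observed,
                 expected = expected,
                 fold = if (expected > 0) observed / expected else NA_real_,
                 p_value = p, method = method),
            class = "intersection_result")
}

#' @export
print.intersection_result <- function(x, ...) {
  cat(sprintf(
    "%d-set intersection: observed %d, expected %.3f (fold %.2f), p = %.3g [%s]\n",
    length(x$sizes), x$observed, x$expected, x$fold, x$p_value, x$method))
  invisible(x)
}
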
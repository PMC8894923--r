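test_that("bin screening applies the count and difference gates", {
  params <- dmr_params("CG", "hypo")
  bins_a <- data.table(chrom = "Chr1", start = 0L, end = 100L, n_sites = 6L,
                       n_covered = 6L, sum_m = 49L, sum_t = 60L,
                       level = 0.82)
  bins_b <- copy(bins_a)[, level := 0.30]
  dmcs <- data.table(chrom = "Chr1", pos = 1:5, strand = "+",
                     level_a = 0.8, level_b = 0.2, delta = -0.6,
                     is_dmc = TRUE, direction = -1)
  cand <- screen_bins(bins_a, bins_b, dmcs, params)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$n_dmc, 5L)
  expect_equal(cand$delta, -0.52)

  # three DMCs fail the CG count gate
  cand3 <- screen_bins(bins_a, bins_b, dmcs[1:3], params)
  expect_equal(nrow(cand3), 0)

  # DMCs of the wrong sign do not count
  cand_w <- screen_bins(bins_a, bins_b,
                        copy(dmcs)[, `:=`(delta = 0.6, direction = 1)],
                        params)
  expect_equal(nrow(cand_w), 0)

  # grid mismatch is rejected
  off <- copy(bins_a)[, start := 13L]
  expect_error(screen_bins(off, bins_b, dmcs, params), "grid")
})

test_that("screening matches an exhaustive per-bin check on random bins", {
  set.seed(17)
  n <- 500L
  params <- dmr_params("CG", "hypo")
  bins_a <- data.table(chrom = sample(c("Chr1", "Chr2"), n, TRUE),
                       start = sample(seq(0L, 99900L, 100L), n))
  bins_a <- unique(bins_a, by = c("chrom", "start"))
  bins_a[, `:=`(end = start + 100L, n_sites = 6L, n_covered = 6L,
                sum_m = 0L, sum_t = 60L,
                level = ifelse(runif(.N) < 0.1, NA_real_, runif(.N)))]
  bins_b <- copy(bins_a)[, level := ifelse(runif(.N) < 0.1, NA_real_,
                                           runif(.N))]
  dmcs <- bins_a[rep(seq_len(.N), rpois(.N, 3))]
  dmcs <- dmcs[, .(chrom, pos = start + sample.int(100L, .N, TRUE) - 1L,
                   is_dmc = runif(.N) < 0.8,
                   direction = sample(c(-1, 1), .N, TRUE))]
  got <- screen_bins(bins_a, bins_b, dmcs, params)
  # brute force over every bin
  exp_rows <- 0L
  for (i in seq_len(nrow(bins_a))) {
    la <- bins_a$level[i]; lb <- bins_b$level[i]
    if (is.na(la) || is.na(lb)) next
    delta <- lb - la
    if (!(delta <= -params$min_diff)) next
    nd <- dmcs[chrom == bins_a$chrom[i] &
                 pos %/% 100L * 100L == bins_a$start[i] &
                 is_dmc & direction == -1, .N]
    if (nd < params$min_dmc) next
    exp_rows <- exp_rows + 1L
    row <- got[chrom == bins_a$chrom[i] & start == bins_a$start[i]]
    expect_equal(nrow(row), 1)
    expect_equal(row$n_dmc, nd)
  }
  expect_equal(nrow(got), exp_rows)
})

test_that("candidate merging follows the 200-bp edge-to-edge rule", {
  params <- dmr_params("CG", "hypo")
  mk_cand <- function(starts, chrom = "Chr1") {
    data.table(chrom = chrom, start = starts, end = starts + 100L,
               level_a = 0.8, level_b = 0.3, delta = -0.5, n_dmc = 5L)
  }
  # gap exactly 200 bp merges
  d <- merge_candidates(mk_cand(c(1000L, 1300L)), params)
  expect_equal(nrow(d), 1)
  expect_equal(c(d$start, d$end), c(1000L, 1400L))
  expect_equal(d$n_bins, 2L)
  # gap 300 bp -> two discarded singletons
  expect_equal(nrow(merge_candidates(mk_cand(c(1000L, 1400L)), params)), 0)
  # isolated candidate is never a DMR
  expect_equal(nrow(merge_candidates(mk_cand(1000L), params)), 0)
  # mean_delta is the unweighted mean of member deltas
  cand <- mk_cand(c(0L, 100L))
  cand$delta <- c(-0.4, -0.6)
  expect_equal(merge_candidates(cand, params)$mean_delta, -0.5)
})

test_that("merging equals an independent interval-merge oracle", {
  params <- dmr_params("CG", "hypo")
  for (rep in 1:50) {
    set.seed(rep)
    n <- sample(2:25, 1)
    cand <- data.table(chrom = sample(c("Chr1", "Chr2"), n, TRUE),
                       start = sample(seq(0L, 5000L, 100L), n))
    cand <- unique(cand, by = c("chrom", "start"))
    cand[, `:=`(end = start + 100L, level_a = 0.9, level_b = 0.3,
                delta = -0.6, n_dmc = 5L)]
    setorder(cand, chrom, start)
    got <- merge_candidates(cand, params)
    # oracle: GenomicRanges reduce with min.gapwidth = gap + 1, then drop
    # clusters that contain a single candidate bin
    gr <- GenomicRanges::GRanges(cand$chrom,
                                 IRanges::IRanges(cand$start + 1L, cand$end))
    red <- GenomicRanges::reduce(gr, min.gapwidth = params$merge_gap + 1L)
    nb <- GenomicRanges::countOverlaps(red, gr)
    red <- red[nb >= 2]
    expect_equal(nrow(got), length(red))
    if (length(red)) {
      expect_equal(got$start, GenomicRanges::start(red) - 1L)
      expect_equal(got$end, GenomicRanges::end(red))
      expect_equal(got$n_bins, unname(nb[nb >= 2]))
    }
  }
})

test_that("self-comparison yields zero DMRs in every context and direction", {
  sc <- small_scenario()
  for (ctx in c("CG", "CHG")) {
    for (dir in c("hypo", "hyper")) {
      expect_equal(nrow(call_dmrs(sc$control, sc$control,
                                  dmr_params(ctx, dir))), 0)
    }
  }
  expect_equal(nrow(call_ectopic_chg(sc$control, sc$control)), 0)
})

test_that("raising thresholds never enlarges the candidate set", {
  sc <- small_scenario()
  base <- dmr_params("CG", "hypo")
  bins_a <- bin_methylation(sc$control, "CG")
  bins_b <- bin_methylation(sc$treated, "CG")
  dmcs <- call_dmcs(sc$control, sc$treated, "CG", base$min_diff)
  cand <- screen_bins(bins_a, bins_b, dmcs, base)
  for (p2 in list(dmr_params("CG", "hypo", min_diff = 0.55),
                  dmr_params("CG", "hypo", min_dmc = 7L))) {
    dmcs2 <- call_dmcs(sc$control, sc$treated, "CG", p2$min_diff)
    cand2 <- screen_bins(bins_a, bins_b, dmcs2, p2)
    expect_true(all(paste(cand2$chrom, cand2$start) %in%
                      paste(cand$chrom, cand$start)))
  }
})

test_that("hypo DMRs of (A vs B) equal hyper DMRs of (B vs A)", {
  sc <- small_scenario()
  hypo <- call_dmrs(sc$control, sc$treated, dmr_params("CG", "hypo"))
  hyper <- call_dmrs(sc$treated, sc$control, dmr_params("CG", "hyper"))
  expect_equal(hypo[, .(chrom, start, end)], hyper[, .(chrom, start, end)])
  expect_equal(hypo$mean_delta, -hyper$mean_delta)
})

test_that("called DMRs are sorted and disjoint within context/direction", {
  sc <- small_scenario()
  dmrs <- call_dmrs(sc$control, sc$treated)
  expect_false(is.unsorted(order(dmrs$chrom, dmrs$start)))
  gaps <- dmrs[, start - shift(end), by = chrom]$V1
  expect_true(all(gaps > 0, na.rm = TRUE))
})

test_that("the composed caller equals running the four stages manually", {
  sc <- small_scenario()
  params <- dmr_params("CG", "hypo")
  dmrs <- call_dmrs(sc$control, sc$treated, params)
  bins_a <- bin_methylation(sc$control, "CG", params$bin_size, params$min_cov)
  bins_b <- bin_methylation(sc$treated, "CG", params$bin_size, params$min_cov)
  dmcs <- call_dmcs(sc$control, sc$treated, "CG", params$min_diff,
                    params$min_cov)
  manual <- merge_candidates(screen_bins(bins_a, bins_b, dmcs, params),
                             params)
  expect_equal(as.data.table(dmrs), as.data.table(manual),
               ignore_attr = "params")
})

test_that("ectopic CHG eligibility requires an unmethylated control bin", {
  mk <- function(ms, id) {
    n <- length(ms)
    mk_methylome(data.table(chrom = "Chr1", pos = seq(5L, by = 10L,
                                                      length.out = n),
                            strand = "+", count_m = as.integer(ms),
                            count_u = as.integer(20 - ms), context = "CHG"),
                 id)
  }
  params <- dmr_params("CHG", "ectopic")
  ctl0 <- mk(rep(0L, 8), "ctl")            # fully unmethylated control bin
  trt <- mk(rep(5L, 8), "trt")             # gains ~0.25 everywhere
  expect_equal(nrow(screen_bins(bin_methylation(ctl0, "CHG"),
                                bin_methylation(trt, "CHG"),
                                call_dmcs(ctl0, trt, "CHG", 0.15), params)),
               1)
  got <- call_ectopic_chg(ctl0, trt)  # single bin -> singleton discarded
  expect_equal(nrow(got), 0)

  # one control site with 3 methylated reads makes the bin ineligible even
  # though its weighted level (3/160) passes the 0.02 gate
  ctl3 <- mk(c(3L, rep(0L, 7)), "ctl")
  expect_lte(bin_methylation(ctl3, "CHG")$level, 0.02)
  expect_equal(nrow(screen_bins(bin_methylation(ctl3, "CHG"),
                                bin_methylation(trt, "CHG"),
                                call_dmcs(ctl3, trt, "CHG", 0.15), params)),
               1)
  expect_equal(nrow(call_ectopic_chg(ctl3, trt)), 0)
})

test_that("ectopic CHG gains are recovered against the registry", {
  sc <- fixture("ectopic_scenario", function() {
    cfg <- sim_config(n_chrom = 1L, chrom_length = 400000L, seed = 29L,
                      treatment_prob = 0.12,
                      base_levels = list(
                        CG = c(gene = 0.75, transposable_element = 0.85,
                               intergenic = 0.65),
                        CHG = c(gene = 0, transposable_element = 0,
                                intergenic = 0),
                        CHH = c(gene = 0.03, transposable_element = 0.1,
                                intergenic = 0.02)))
    ga <- generate_genome_annotation(cfg)
    truth <- generate_true_methylome(ga$genome, ga$features, cfg)
    gain <- apply_chg_gain(truth, cfg, delta = 0.30)
    list(control = simulate_wgbs_counts(truth, cfg, "c", seed = 31),
         treated = simulate_wgbs_counts(gain$truth, cfg, "t", seed = 32),
         registry = gain$registry)
  })
  ect <- call_ectopic_chg(sc$control, sc$treated)
  rec <- registry_recovery(ect, sc$registry, "CHG")
  expect_gte(rec$recall, 0.9)
  expect_gte(rec$precision, 0.9)
  expect_true(all(ect$direction == "ectopic"))
})
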
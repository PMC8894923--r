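mk_features <- function(df) feature_set(as.data.table(df))

test_that("DMRs are classified by largest feature overlap", {
  feats <- mk_features(data.table(
    chrom = "Chr1", start = c(500L, 3000L), end = c(2000L, 3500L),
    strand = "+", feature_class = c("gene", "transposable_element"),
    feature_id = c("g1", "t1")))
  dmrs <- data.table(chrom = "Chr1",
                     start = c(1000L, 5000L, 1900L),
                     end = c(1400L, 5400L, 3200L),
                     context = "CG", direction = "hypo", mean_delta = -0.5)
  ann <- classify_dmrs(dmrs, feats)
  expect_equal(ann$feature_class, c("gene", "intergenic", "transposable_element"))
  expect_equal(ann$bp_gene, c(400L, 0L, 100L))
  expect_equal(ann$bp_te, c(0L, 0L, 200L))
  expect_equal(ann$feature_ids[1], "g1")
  # tie-break favours genes
  tie <- classify_dmrs(data.table(chrom = "Chr1", start = 1900L, end = 3100L,
                                  context = "CG", direction = "hypo",
                                  mean_delta = -0.5), feats)
  expect_equal(tie$bp_gene, tie$bp_te)
  expect_equal(tie$feature_class, "gene")
})

test_that("classification partitions DMRs and matches an all-pairs oracle", {
  set.seed(23)
  feats <- data.table(
    chrom = sample(c("Chr1", "Chr2"), 50, TRUE),
    start = sample.int(50000L, 50))
  feats[, end := start + sample(200:3000, .N, TRUE)]
  feats[, `:=`(strand = "+",
               feature_class = sample(c("gene", "transposable_element"),
                                      .N, TRUE),
               feature_id = sprintf("f%02d", .I))]
  feats <- feature_set(feats)
  dmrs <- data.table(chrom = sample(c("Chr1", "Chr2"), 300, TRUE),
                     start = sample.int(52000L, 300))
  dmrs[, `:=`(end = start + sample(100:1500, .N, TRUE), context = "CG",
              direction = "hypo", mean_delta = -0.5)]
  ann <- classify_dmrs(dmrs, feats)
  expect_equal(nrow(ann), 300)
  expect_true(all(ann$feature_class %in%
                    c("gene", "transposable_element", "intergenic")))
  # brute force bp overlap
  fdt <- as.data.table(feats)
  for (i in sample.int(300, 40)) {
    ov <- function(cls) {
      f <- fdt[feature_class == cls & chrom == ann$chrom[i]]
      if (!nrow(f)) return(0L)
      sum(pmax(0L, pmin(f$end, ann$end[i]) - pmax(f$start, ann$start[i])))
    }
    bg <- ov("gene"); bt <- ov("transposable_element")
    expect_equal(ann$bp_gene[i], bg)
    expect_equal(ann$bp_te[i], bt)
    exp_cls <- if (bg == 0 && bt == 0) "intergenic"
               else if (bg >= bt) "gene" else "transposable_element"
    expect_equal(ann$feature_class[i], exp_cls)
  }
})

test_that("gene proximity uses closest-end distance with overlap as zero", {
  feats <- mk_features(data.table(
    chrom = "Chr1", start = c(5000L, 20000L), end = c(6000L, 21000L),
    strand = c("+", "-"), feature_class = "gene",
    feature_id = c("near", "far")))
  dmrs <- data.table(chrom = "Chr1", start = 6500L, end = 6600L,
                     context = "CG", direction = "hypo", mean_delta = -0.4)
  expect_equal(genes_near_dmrs(dmrs, feats, 1000L)$gene_ids, "near")
  # distance 500 included, 1500 excluded
  dmrs2 <- data.table(chrom = "Chr1", start = 7500L, end = 7600L,
                      context = "CG", direction = "hypo", mean_delta = -0.4)
  expect_equal(length(genes_near_dmrs(dmrs2, feats, 1000L)), 0)
  # window monotonicity and brute-force membership on a random instance
  set.seed(5)
  rf <- data.table(chrom = "Chr1", start = sample.int(100000L, 60))
  rf[, `:=`(end = start + sample(500:2000, .N, TRUE), strand = "+",
            feature_class = "gene", feature_id = sprintf("g%02d", .I))]
  rf <- feature_set(rf)
  rd <- data.table(chrom = "Chr1", start = sample.int(100000L, 30))
  rd[, `:=`(end = start + 200L, context = "CG", direction = "hypo",
            mean_delta = -0.5)]
  prev <- character()
  fdt <- as.data.table(rf)
  for (w in c(0L, 500L, 1000L, 5000L)) {
    got <- sort(genes_near_dmrs(rd, rf, w)$gene_ids)
    expect_true(all(prev %in% got))
    prev <- got
    expected <- fdt$feature_id[vapply(seq_len(nrow(fdt)), function(i) {
      d <- pmax(0L, pmax(rd$start - fdt$end[i], fdt$start[i] - rd$end))
      min(d) <= w
    }, logical(1))]
    expect_setequal(got, expected)
  }
})

test_that("gene-set intersection obeys set identities", {
  a <- gene_list(c("g1", "g2", "g3"), "A")
  b <- gene_list(c("g2", "g3", "g4"), "B")
  expect_setequal(intersect_gene_sets(a, b)$gene_ids, c("g2", "g3"))
  expect_equal(length(intersect_gene_sets(a, gene_list("x", "X"))), 0)
  set.seed(9)
  for (i in 1:10) {
    s1 <- gene_list(sample(letters, sample(5:20, 1)), "s1")
    s2 <- gene_list(sample(letters, sample(5:20, 1)), "s2")
    inter <- length(intersect_gene_sets(s1, s2))
    expect_equal(inter + length(setdiff(s1$gene_ids, s2$gene_ids)),
                 length(s1))
  }
})

test_that("two-set exact test equals the hypergeometric tail to 1e-10", {
  set.seed(41)
  for (rep in 1:30) {
    n <- sample(20:200, 1)
    sa <- sample(5:min(50, n), 1)
    sb <- sample(5:min(50, n), 1)
    universe <- sprintf("e%03d", seq_len(n))
    A <- sample(universe, sa)
    B <- sample(universe, sb)
    res <- multiset_exact_test(list(A, B), n)
    obs <- length(intersect(A, B))
    direct <- if (obs == 0) 1 else sum(dhyper(obs:min(sa, sb), sa, n - sa, sb))
    expect_equal(res$observed, obs)
    expect_lt(abs(res$p_value - direct), 1e-10)
    expect_equal(res$expected, n * (sa / n) * (sb / n))
  }
})

test_that("three-set null pmf equals exhaustive enumeration on a tiny universe", {
  # n = 6, three sets of size 3: enumerate all C(6,3)^3 draws directly
  n <- 6L; s <- 3L
  combs <- combn(n, s)
  nc <- ncol(combs)
  tallies <- numeric(s + 1)
  for (i in seq_len(nc)) for (j in seq_len(nc)) for (k in seq_len(nc)) {
    x <- length(Reduce(intersect, list(combs[, i], combs[, j], combs[, k])))
    tallies[x + 1] <- tallies[x + 1] + 1
  }
  enum <- tallies / nc^3
  # exercise the public tail through sets with each observed intersection
  for (obs in 0:3) {
    sets <- switch(obs + 1,
                   list(c("1", "2", "3"), c("4", "5", "6"), c("1", "2", "4")),
                   list(c("1", "2", "3"), c("1", "4", "5"), c("1", "2", "6")),
                   list(c("1", "2", "3"), c("1", "2", "4"), c("1", "2", "5")),
                   list(c("1", "2", "3"), c("1", "2", "3"), c("1", "2", "3")))
    res <- multiset_exact_test(sets, n)
    expect_equal(res$observed, obs)
    expect_equal(res$p_value, sum(enum[(obs + 1):(s + 1)]), tolerance = 1e-12)
  }
})

test_that("three-set exact tail agrees with Monte-Carlo simulation", {
  n <- 30L; sizes <- c(10L, 10L, 10L)
  # sets with a 3-element common intersection (a moderate-probability tail)
  A <- 1:10; B <- c(1:3, 11:17); C <- c(1:3, 18:24)
  res <- multiset_exact_test(list(as.character(A), as.character(B),
                                  as.character(C)), n)
  expect_equal(res$observed, 3)
  set.seed(77)
  draws <- 1e5
  x <- vapply(seq_len(draws), function(i) {
    length(Reduce(intersect, lapply(sizes, sample.int, n = n)))
  }, integer(1))
  mc_p <- mean(x >= 3)
  se <- sqrt(mc_p * (1 - mc_p) / draws)
  expect_lt(abs(res$p_value - mc_p), 3 * se)
  # pmf sanity: expected size matches the simulation mean
  expect_equal(res$expected, n * prod(sizes / n))
  expect_lt(abs(mean(x) - res$expected), 0.02)
})

test_that("exact-test tail identities hold", {
  res0 <- multiset_exact_test(list(c("a", "b"), c("c", "d")), 100)
  expect_equal(res0$observed, 0)
  expect_equal(res0$p_value, 1)
  # p decreases as observed grows, all sizes fixed
  ps <- vapply(1:5, function(k) {
    A <- sprintf("e%02d", 1:10)
    B <- c(sprintf("e%02d", 1:k), sprintf("x%02d", 1:(12 - k)))
    multiset_exact_test(list(A, B), 100)$p_value
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_error(multiset_exact_test(list(letters, letters), 10), "universe")
})

test_that("monte-carlo fallback approximates the exact tail", {
  A <- sprintf("e%04d", 1:300)
  B <- sprintf("e%04d", 100:500)
  exact <- multiset_exact_test(list(A, B), 5000)
  mc <- multiset_exact_test(list(A, B), 5000, exact_limit = 10L,
                            mc_draws = 50000L, seed = 3L)
  expect_equal(mc$method, "monte-carlo")
  expect_equal(exact$method, "exact")
  expect_lt(abs(mc$p_value - exact$p_value),
            3 * sqrt(exact$p_value * (1 - exact$p_value) / 50000) + 1e-4)
})
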
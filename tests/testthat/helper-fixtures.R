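library(data.table)

# Memoised fixtures: heavy simulations are built once per test run and
# shared across test files.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

# quick in-code methylome
mk_methylome <- function(df, id = "s", genome = "g") {
  methylome(as.data.table(df), id, genome)
}

# random well-formed site table over a few kb
random_methylome <- function(n = 500, span = 10000L, seed = 1, id = "r",
                             chroms = c("Chr1", "Chr2"), max_cov = 30L) {
  set.seed(seed)
  key <- unique(data.table(
    chrom = sample(chroms, n, TRUE),
    pos = sample.int(span, n, TRUE) - 1L,
    strand = sample(c("+", "-"), n, TRUE)))
  # context is a deterministic function of the site so that independently
  # generated replicates stay consistent at shared positions
  key[, context := c("CG", "CHG", "CHH")[
    (pos + (strand == "+")) %% 3L + 1L]]
  key[, cov := rpois(.N, max_cov / 2)]
  key[, count_m := rbinom(.N, cov, runif(.N))]
  key[, count_u := cov - count_m]
  mk_methylome(key[, .(chrom, pos, strand, count_m, count_u, context)], id)
}

# 200-kb single-chromosome scenario with planted CG losses
small_scenario <- function() {
  fixture("small_scenario", function() {
    cfg <- sim_config(n_chrom = 1L, chrom_length = 200000L, seed = 7L,
                      treatment_prob = 0.15)
    ga <- generate_genome_annotation(cfg)
    truth <- generate_true_methylome(ga$genome, ga$features, cfg)
    em2 <- apply_epimutagenesis(truth, cfg)
    list(cfg = cfg, genome = ga$genome, features = ga$features,
         truth = truth, em2 = em2$truth, registry = em2$registry,
         control = simulate_wgbs_counts(truth, cfg, "control", seed = 11,
                                        genome_id = "sim"),
         treated = simulate_wgbs_counts(em2$truth, cfg, "treated", seed = 12,
                                        genome_id = "sim"))
  })
}

# full 3-Mb benchmark scenario (defaults of sim_config)
bench_scenario <- function() {
  fixture("bench_scenario", function() {
    cfg <- sim_config(seed = 42L)
    ga <- generate_genome_annotation(cfg)
    truth <- generate_true_methylome(ga$genome, ga$features, cfg)
    em2 <- apply_epimutagenesis(truth, cfg)
    list(cfg = cfg, features = ga$features, truth = truth,
         em2 = em2$truth, registry = em2$registry,
         control = simulate_wgbs_counts(truth, cfg, "control", seed = 1,
                                        genome_id = "sim"),
         treated = simulate_wgbs_counts(em2$truth, cfg, "treated", seed = 2,
                                        genome_id = "sim"))
  })
}

# independent brute-force DMR caller: per-bin loop + union-find merge
brute_force_dmrs <- function(control, treated, params) {
  ctx <- params$context
  bs <- params$bin_size
  sites_a <- as.data.table(control)[context == ctx]
  sites_b <- as.data.table(treated)[context == ctx]
  setkey(sites_a, chrom, pos, strand)
  setkey(sites_b, chrom, pos, strand)
  want_sign <- if (params$direction == "hypo") -1 else 1
  all_bins <- unique(rbind(
    sites_a[, .(chrom, start = (pos %/% bs) * bs)],
    sites_b[, .(chrom, start = (pos %/% bs) * bs)]))
  setorder(all_bins, chrom, start)
  cand <- list()
  for (i in seq_len(nrow(all_bins))) {
    ch <- all_bins$chrom[i]; st <- all_bins$start[i]
    sa <- sites_a[chrom == ch & pos >= st & pos < st + bs]
    sb <- sites_b[chrom == ch & pos >= st & pos < st + bs]
    ca <- sa[count_m + count_u >= params$min_cov]
    cb <- sb[count_m + count_u >= params$min_cov]
    if (!nrow(ca) || !nrow(cb)) next
    la <- sum(ca$count_m) / sum(ca$count_m + ca$count_u)
    lb <- sum(cb$count_m) / sum(cb$count_m + cb$count_u)
    delta <- lb - la
    if (sign(delta) != want_sign || abs(delta) < params$min_diff) next
    j <- merge(sa, sb, by = c("chrom", "pos", "strand"))
    j <- j[count_m.x + count_u.x >= params$min_cov &
             count_m.y + count_u.y >= params$min_cov]
    sd <- j$count_m.y / (j$count_m.y + j$count_u.y) -
      j$count_m.x / (j$count_m.x + j$count_u.x)
    n_dmc <- sum(abs(sd) >= params$min_diff & sign(sd) == want_sign)
    if (n_dmc < params$min_dmc) next
    cand[[length(cand) + 1]] <- data.table(chrom = ch, start = st,
                                           end = st + bs, delta = delta)
  }
  cand <- rbindlist(cand)
  if (!nrow(cand)) return(data.table(chrom = character(), start = integer(),
                                     end = integer(), n_bins = integer(),
                                     member_bins = list()))
  # union-find over candidate bins
  parent <- seq_len(nrow(cand))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nrow(cand))) for (k in seq_len(nrow(cand))) {
    if (i == k) next
    if (cand$chrom[i] == cand$chrom[k]) {
      gap <- max(cand$start[i], cand$start[k]) -
        min(cand$end[i], cand$end[k])
      if (gap <= params$merge_gap) {
        ri <- find(i); rk <- find(k)
        if (ri != rk) parent[rk] <- ri
      }
    }
  }
  cand[, root := vapply(seq_len(.N), find, integer(1))]
  out <- cand[, .(chrom = chrom[1], start = min(start), end = max(end),
                  n_bins = .N, member_bins = list(sort(start)),
                  mean_delta = mean(delta)), by = root]
  out <- out[n_bins >= 2L][, root := NULL]
  setorder(out, chrom, start)
  out[]
}
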
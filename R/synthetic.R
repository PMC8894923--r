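# WGBS simulator: toy genome + annotation, ground-truth per-cytosine
# methylation probabilities, region-level epimutagenesis/restoration, and
# Poisson/binomial read-count sampling with a planted-region registry.

#' Simulation configuration
#'
#' Bundles and validates every knob of the WGBS simulator. Defaults describe
#' the benchmark scenario used throughout the package's validation: a 3-Mb
#' genome (two 1.5-Mb chromosomes), 1-kb demethylation events hitting 10% of
#' tiles with a CG effect size of -0.6, 20x Poisson coverage and a 0.5%
#' bisulfite conversion error.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param gc_content genome GC fraction.
#' @param gene_density,te_density features per 100 kb.
#' @param base_levels named list mapping context (`CG`, `CHG`, `CHH`) to a
#'   length-3 numeric vector of mean true methylation in
#'   (gene, transposable_element, intergenic) compartments.
#' @param region_size size in bp of the tiles on which demethylation and
#'   restoration events act.
#' @param treatment_prob per-tile probability of a demethylation event.
#' @param treatment_delta CG methylation change in affected tiles
#'   (in `[-1, 0]`; clipped at 0).
#' @param restoration_prob per-planted-region probability that the next
#'   generation reverts the region to control methylation.
#' @param mean_coverage mean reads per cytosine (Poisson).
#' @param conversion_error probability that a methylated read is read as
#'   unmethylated (applied as thinning of methylated reads).
#' @param false_methylation probability floor of spurious methylated calls at
#'   unmethylated sites (default 0).
#' @param jitter_sd relative (multiplicative) per-site jitter of true levels;
#'   a base level of 0 therefore stays exactly 0.
#' @param seed integer master seed; all stages derive their streams from it.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(n_chrom = 2L,
                       chrom_length = 1500000L,
                       gc_content = 0.36,
                       gene_density = 10,
                       te_density = 5,
                       base_levels = list(
                         CG  = c(gene = 0.75, transposable_element = 0.85,
                                 intergenic = 0.65),
                         CHG = c(gene = 0.05, transposable_element = 0.40,
                                 intergenic = 0.02),
                         CHH = c(gene = 0.03, transposable_element = 0.10,
                                 intergenic = 0.02)),
                       region_size = 1000L,
                       treatment_prob = 0.1,
                       treatment_delta = -0.6,
                       restoration_prob = 0.35,
                       mean_coverage = 20,
                       conversion_error = 0.005,
                       false_methylation = 0,
                       jitter_sd = 0.05,
                       seed = 1L) {
  cfg <- list(n_chrom = as.integer(n_chrom),
              chrom_length = as.integer(chrom_length),
              gc_content = gc_content, gene_density = gene_density,
              te_density = te_density, base_levels = base_levels,
              region_size = as.integer(region_size),
              treatment_prob = treatment_prob,
              treatment_delta = treatment_delta,
              restoration_prob = restoration_prob,
              mean_coverage = mean_coverage,
              conversion_error = conversion_error,
              false_methylation = false_methylation,
              jitter_sd = jitter_sd, seed = as.integer(seed))
  probs <- c(gc_content = gc_content, treatment_prob = treatment_prob,
             restoration_prob = restoration_prob,
             conversion_error = conversion_error,
             false_methylation = false_methylation)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad)) stop("probabilities must lie in [0,1]: ",
                        paste(bad, collapse = ", "))
  if (treatment_delta < -1 || treatment_delta > 0) {
    stop("treatment_delta must lie in [-1, 0]")
  }
  if (cfg$mean_coverage <= 0) stop("mean_coverage must be positive")
  if (cfg$chrom_length < 10L * 100L) stop("chrom_length too small")
  for (ctx in CONTEXTS) {
    lv <- base_levels[[ctx]]
    if (is.null(lv) || length(lv) != 3 || any(lv < 0) || any(lv > 1)) {
      stop("base_levels$", ctx,
           " must be 3 values (gene, TE, intergenic) in [0,1]")
    }
  }
  structure(cfg, class = "sim_config")
}

# Evaluate `code` under `seed`, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed %% .Machine$integer.max)
  code
}

#' Generate a toy genome and annotation
#'
#' Draws i.i.d. nucleotide sequences at the configured GC content and places
#' non-overlapping gene and transposable-element intervals at the configured
#' densities (genes 1.5-3.5 kb, TEs 0.5-2 kb, random strand). Deterministic
#' given the config seed.
#'
#' @param config a [sim_config()].
#' @return list with `genome` (named character vector of chromosome
#'   sequences) and `features` (a [feature_set()]).
#' @export
generate_genome_annotation <- function(config) {
  with_seed(config$seed, {
    genome <- character(config$n_chrom)
    names(genome) <- sprintf("Chr%d", seq_len(config$n_chrom))
    feats <- vector("list", config$n_chrom)
    p <- c((1 - config$gc_content) / 2, config$gc_content / 2,
           config$gc_content / 2, (1 - config$gc_content) / 2)
    for (i in seq_len(config$n_chrom)) {
      L <- config$chrom_length
      genome[i] <- paste(sample(c("A", "C", "G", "T"), L, TRUE, p),
                         collapse = "")
      n_gene <- round(config$gene_density * L / 1e5)
      n_te <- round(config$te_density * L / 1e5)
      lens <- c(as.integer(runif(n_gene, 1500, 3500)),
                as.integer(runif(n_te, 500, 2000)))
      cls <- rep(c("gene", "transposable_element"), c(n_gene, n_te))
      ord <- sample.int(length(lens))
      lens <- lens[ord]; cls <- cls[ord]
      free <- L - sum(lens)
      if (free < length(lens)) {
        stop("configuration error: feature densities leave no room for ",
             "overlap-free placement")
      }
      gaps <- sort(sample.int(free, length(lens)))
      starts <- gaps + cumsum(c(0L, head(lens, -1L)))
      feats[[i]] <- data.table(
        chrom = names(genome)[i], start = starts, end = starts + lens,
        strand = sample(STRANDS, length(lens), TRUE), feature_class = cls)
    }
    fdt <- rbindlist(feats)
    fdt[, feature_id := sprintf("%s%05d",
                                ifelse(feature_class == "gene", "G", "TE"),
                                seq_len(.N)), by = feature_class]
    list(genome = genome, features = feature_set(fdt))
  })
}

#' Scan a genome for cytosine positions and contexts
#'
#' Returns every cytosine on both strands with its CG/CHG/CHH trinucleotide
#' context. Sites whose trinucleotide would extend past the chromosome end
#' are dropped.
#'
#' @param genome named character vector of chromosome sequences.
#' @return data.table with chrom, pos (0-based), strand, context.
#' @export
scan_cytosines <- function(genome) {
  res <- lapply(names(genome), function(chrom) {
    v <- strsplit(genome[[chrom]], "", fixed = TRUE)[[1]]
    n <- length(v)
    ip <- which(v == "C")
    ip <- ip[ip <= n - 2L]
    ctx_p <- ifelse(v[ip + 1L] == "G", "CG",
                    ifelse(v[ip + 2L] == "G", "CHG", "CHH"))
    im <- which(v == "G")
    im <- im[im >= 3L]
    ctx_m <- ifelse(v[im - 1L] == "C", "CG",
                    ifelse(v[im - 2L] == "C", "CHG", "CHH"))
    data.table(chrom = chrom,
               pos = c(ip, im) - 1L,
               strand = rep(c("+", "-"), c(length(ip), length(im))),
               context = c(ctx_p, ctx_m))
  })
  out <- rbindlist(res)
  setorder(out, chrom, pos, strand)
  out[]
}

#' Generate ground-truth per-cytosine methylation probabilities
#'
#' Each cytosine receives a true methylation probability equal to the
#' configured mean for its (context, compartment) cell times a multiplicative
#' jitter `1 + N(0, jitter_sd)`, clipped to `[0, 1]`; a base level of 0 stays
#' exactly 0. Compartment is gene / transposable_element / intergenic by
#' feature overlap.
#'
#' @param genome,features output of [generate_genome_annotation()].
#' @param config a [sim_config()].
#' @return a `true_methylome`: data.table (chrom, pos, strand, context, p)
#'   with a `generation` attribute set to `"control"`.
#' @export
generate_true_methylome <- function(genome, features, config) {
  sites <- scan_cytosines(genome)
  sites[, compartment := "intergenic"]
  if (nrow(features)) {
    sgr <- GenomicRanges::GRanges(sites$chrom,
                                  IRanges::IRanges(sites$pos + 1L, width = 1L))
    for (cls in c("transposable_element", "gene")) {
      f <- features[features$feature_class == cls, ]
      if (!nrow(f)) next
      hit <- GenomicRanges::countOverlaps(sgr, intervals_to_granges(f)) > 0
      sites[hit, compartment := cls]
    }
  }
  with_seed(config$seed + 1L, {
    comp_idx <- match(sites$compartment,
                      c("gene", "transposable_element", "intergenic"))
    base <- numeric(nrow(sites))
    for (ctx in CONTEXTS) {
      sel <- sites$context == ctx
      base[sel] <- config$base_levels[[ctx]][comp_idx[sel]]
    }
    p <- pmin(pmax(base * (1 + rnorm(nrow(sites), 0, config$jitter_sd)), 0), 1)
    truth <- sites[, .(chrom, pos, strand, context)]
    truth[, p := p]
    setattr(truth, "generation", "control")
    truth[]
  })
}

plant_regions <- function(truth, config, context, delta, prob, generation,
                          seed) {
  rs <- config$region_size
  tiles <- truth[, .(start = seq(0L, max(pos), by = rs)), by = chrom]
  tiles[, end := start + rs]
  with_seed(seed, {
    tiles[, planted := runif(.N) < prob]
  })
  registry <- tiles[planted == TRUE,
                    .(chrom, start, end, context = context, delta = delta,
                      generation = generation)]
  out <- copy(truth)
  if (nrow(registry)) {
    out[, tile := (pos %/% rs) * rs]
    key <- paste(registry$chrom, registry$start)
    hit <- out$context == context & paste(out$chrom, out$tile) %in% key
    out[hit, p := pmin(pmax(p + delta, 0), 1)]
    out[, tile := NULL]
  }
  setattr(out, "generation", generation)
  list(truth = out[], registry = registry[])
}

#' Apply region-level epimutagenesis (CG demethylation)
#'
#' Tiles the genome into `region_size` tiles; each tile is independently hit
#' with probability `treatment_prob`, and CG methylation inside hit tiles is
#' shifted by `treatment_delta` (clipped at 0). Non-CG contexts are left
#' untouched. The returned registry of planted regions is the truth standard
#' for recall/precision.
#'
#' @param truth control `true_methylome`.
#' @param config a [sim_config()].
#' @param seed RNG seed for the event draws (default derived from config).
#' @return list with `truth` (eM2 generation) and `registry` (data.table of
#'   planted regions: chrom, start, end, context, delta, generation).
#' @export
apply_epimutagenesis <- function(truth, config, seed = config$seed + 2L) {
  plant_regions(truth, config, "CG", config$treatment_delta,
                config$treatment_prob, "eM2", seed)
}

#' Plant ectopic CHG methylation gains
#'
#' Counterpart of [apply_epimutagenesis()] for the CHG context: hit tiles
#' gain `delta` CHG methylation (clipped at 1), emulating ectopic CHG
#' methylation arising at loci unmethylated in the control.
#'
#' @param truth control `true_methylome`.
#' @param config a [sim_config()].
#' @param delta CHG gain applied inside hit tiles.
#' @param prob per-tile event probability (defaults to `treatment_prob`).
#' @param seed RNG seed.
#' @return list with `truth` and `registry` as in [apply_epimutagenesis()].
#' @export
apply_chg_gain <- function(truth, config, delta = 0.30,
                           prob = config$treatment_prob,
                           seed = config$seed + 3L) {
  plant_regions(truth, config, "CHG", delta, prob, "eM2", seed)
}

#' Apply transgenerational restoration
#'
#' Each planted region independently reverts to control methylation with
#' probability `restoration_prob`; unrestored regions keep their eM2 values
#' and unplanted positions are unchanged. Calling twice with different seeds
#' models sibling eM3 lines and yields segregating regions.
#'
#' @param em2_truth eM2 `true_methylome`.
#' @param control_truth control `true_methylome` (same site set).
#' @param registry planted-region registry from [apply_epimutagenesis()].
#' @param config a [sim_config()].
#' @param seed RNG seed for the restoration draws.
#' @return list with `truth` (eM3 generation) and `registry` augmented with a
#'   logical `restored` column.
#' @export
apply_restoration <- function(em2_truth, control_truth, registry, config,
                              seed = config$seed + 4L) {
  reg <- copy(registry)
  with_seed(seed, {
    reg[, restored := runif(.N) < config$restoration_prob]
  })
  out <- copy(em2_truth)
  res <- reg[restored == TRUE]
  if (nrow(res)) {
    rs <- config$region_size
    out[, tile := (pos %/% rs) * rs]
    key <- paste(res$chrom, res$start, res$context)
    hit <- paste(out$chrom, out$tile, out$context) %in% key
    out[hit, p := control_truth$p[hit]]
    out[, tile := NULL]
  }
  setattr(out, "generation", "eM3")
  list(truth = out[], registry = reg[])
}

#' Simulate WGBS read counts from a true methylome
#'
#' Per cytosine, coverage is Poisson with the configured mean and the
#' methylated count is binomial with success probability
#' `p * (1 - conversion_error) + false_methylation` (conversion error acts as
#' thinning of methylated reads).
#'
#' @param truth a `true_methylome`.
#' @param config a [sim_config()].
#' @param sample_id label for the simulated library.
#' @param seed RNG seed for the count draws.
#' @param genome_id genome label.
#' @return a [methylome()].
#' @export
simulate_wgbs_counts <- function(truth, config, sample_id,
                                 seed = config$seed + 10L,
                                 genome_id = "sim") {
  with_seed(seed, {
    n <- nrow(truth)
    cov <- rpois(n, config$mean_coverage)
    pe <- pmin(pmax(truth$p * (1 - config$conversion_error) +
                      config$false_methylation, 0), 1)
    cm <- rbinom(n, cov, pe)
    methylome(data.table(chrom = truth$chrom, pos = truth$pos,
                         strand = truth$strand, count_m = cm,
                         count_u = cov - cm, context = truth$context),
              sample_id, genome_id, validate = FALSE)
  })
}

#' Measure DMR recall and precision against a planted-region registry
#'
#' Recall is the fraction of planted regions (of the requested context)
#' overlapped by at least one called DMR; precision is the fraction of called
#' DMRs overlapping at least one planted region.
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param registry planted-region registry.
#' @param context restrict registry to this context (default: all).
#' @return list with `recall`, `precision`, `n_planted`, `n_called`.
#' @export
registry_recovery <- function(dmrs, registry, context = NULL) {
  reg <- registry
  if (!is.null(context)) {
    sel <- registry$context == context
    reg <- registry[sel, ]
  }
  if (!nrow(reg) || !nrow(dmrs)) {
    return(list(recall = if (nrow(reg)) 0 else NA_real_,
                precision = if (nrow(dmrs)) 0 else NA_real_,
                n_planted = nrow(reg), n_called = nrow(dmrs)))
  }
  rgr <- intervals_to_granges(reg)
  dgr <- intervals_to_granges(dmrs)
  list(recall = mean(GenomicRanges::countOverlaps(rgr, dgr) > 0),
       precision = mean(GenomicRanges::countOverlaps(dgr, rgr) > 0),
       n_planted = nrow(reg), n_called = nrow(dmrs))
}

#' Write a genome as FASTA
#' @param genome named character vector of sequences.
#' @param path output path.
#' @param width line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(genome)) {
    writeLines(paste0(">", chrom), con)
    s <- genome[[chrom]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write a feature set as GFF3
#' @param features a [feature_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    type <- ifelse(features$feature_class == "gene", "gene",
                   "transposable_element")
    writeLines(sprintf("%s\tbinmeth\t%s\t%d\t%d\t.\t%s\t.\tID=%s",
                       features$chrom, type, features$start + 1L,
                       features$end, features$strand, features$feature_id),
               con)
  }
  invisible(path)
}

#' Write a planted-region registry as BED and TSV
#' @param registry registry data.table.
#' @param base output path base; writes `<base>.bed` and `<base>.tsv`.
#' @return character vector of written paths, invisibly.
#' @export
write_registry <- function(registry, base) {
  bed <- paste0(base, ".bed"); tsv <- paste0(base, ".tsv")
  if (nrow(registry)) {
    writeLines(sprintf("%s\t%d\t%d\t%s:%+.2f", registry$chrom, registry$start,
                       registry$end, registry$context, registry$delta), bed)
  } else writeLines(character(), bed)
  fwrite(registry, tsv, sep = "\t")
  invisible(c(bed, tsv))
}

#' Simulate a full study-design dataset to disk
#'
#' Emulates the sample structure of the azacytidine epimutagenesis study:
#' an untreated control (2 replicates), a solvent (DMSO) control
#' (2 replicates), treated suppressor lines with strong genome-wide CG loss,
#' non-suppressor lines with near-control methylation, and two third-
#' generation (eM3) sibling lines with partial, partially segregating CG
#' restoration. Writes FASTA, GFF3, per-cytosine reports, and the planted
#' registry.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created).
#' @param n_suppressor,n_nonsuppressor numbers of treated lines.
#' @return list with file paths, the registry, and in-memory objects.
#' @export
simulate_dataset <- function(config, dir, n_suppressor = 2L,
                             n_nonsuppressor = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ga <- generate_genome_annotation(config)
  truth <- generate_true_methylome(ga$genome, ga$features, config)
  paths <- list(fasta = file.path(dir, "genome.fa"),
                gff3 = file.path(dir, "annotation.gff3"))
  write_fasta(ga$genome, paths$fasta)
  write_gff3(ga$features, paths$gff3)

  samples <- list()
  write_sample <- function(tr, id, seed) {
    tab <- simulate_wgbs_counts(tr, config, id, seed = seed)
    p <- file.path(dir, paste0(id, ".cov.txt"))
    write_cytosine_report(tab, p)
    samples[[id]] <<- p
    tab
  }
  for (i in 1:2) write_sample(truth, sprintf("control_rep%d", i),
                              config$seed + 100L + i)
  for (i in 1:2) write_sample(truth, sprintf("solvent_rep%d", i),
                              config$seed + 110L + i)

  em2 <- apply_epimutagenesis(truth, config)
  write_registry(em2$registry, file.path(dir, "registry"))
  for (i in seq_len(n_suppressor)) {
    write_sample(em2$truth, sprintf("suppressor_%d", i),
                 config$seed + 120L + i)
  }
  for (i in seq_len(n_nonsuppressor)) {
    write_sample(truth, sprintf("nonsuppressor_%d", i),
                 config$seed + 130L + i)
  }
  em3a <- apply_restoration(em2$truth, truth, em2$registry, config,
                            seed = config$seed + 140L)
  em3b <- apply_restoration(em2$truth, truth, em2$registry, config,
                            seed = config$seed + 141L)
  write_sample(em3a$truth, "em3_sibling_1", config$seed + 150L)
  write_sample(em3b$truth, "em3_sibling_2", config$seed + 151L)

  list(paths = paths, samples = samples, registry = em2$registry,
       features = ga$features, genome = ga$genome,
       truth = list(control = truth, em2 = em2$truth,
                    em3a = em3a$truth, em3b = em3b$truth),
       em3_registries = list(a = em3a$registry, b = em3b$registry))
}
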
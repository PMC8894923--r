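# End-to-end orchestration: declarative YAML config -> simulate/analyse run
# directory with BED/TSV reports, a manifest and a log.

PIPELINE_DEFAULTS <- list(
  bin_size = 100L, merge_gap = 200L, min_cov = 4L,
  cg_min_dmc = 4L, cg_min_diff = 0.40,
  chg_min_dmc = 5L, chg_min_diff = 0.35,
  ectopic_min_dmc = 3L, ectopic_min_diff = 0.15,
  near_gene_window = 1000L, restore_threshold = 0.8, min_loss = 0.2)

SAMPLE_ROLES <- c("control_untreated", "control_solvent", "treated_line",
                  "em3_line")

#' Validate and normalise a pipeline configuration
#'
#' Reads a YAML configuration (or takes an equivalent list), injects the
#' default caller parameters, and checks types and ranges. All violations
#' are collected and reported together, not fail-fast; unknown keys are
#' rejected. Normalisation is idempotent.
#'
#' @param config path to a YAML file, or a list.
#' @return the normalised config list (class `pipeline_config`), or an error
#'   listing every violation.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  errors <- character()
  note <- function(...) errors <<- c(errors, sprintf(...))

  known <- c("genome_id", "seed", "output_dir", "annotation", "samples",
             "deg_lists", "params")
  unknown <- setdiff(names(config), known)
  for (k in unknown) note("unknown key '%s'", k)

  config$genome_id <- config$genome_id %||% "genome"
  config$seed <- as.integer(config$seed %||% 1L)
  if (is.null(config$output_dir)) note("missing required key 'output_dir'")
  if (is.null(config$samples) || !length(config$samples)) {
    note("missing required key 'samples'")
    config$samples <- list()
  }
  for (i in seq_along(config$samples)) {
    s <- config$samples[[i]]
    for (f in c("id", "role", "path")) {
      if (is.null(s[[f]])) note("samples[%d]: missing field '%s'", i, f)
    }
    if (!is.null(s$role) && !s$role %in% SAMPLE_ROLES) {
      note("samples[%d]: unknown role '%s'", i, s$role)
    }
  }
  roles <- vapply(config$samples,
                  function(s) s$role %||% NA_character_, character(1))
  if (length(config$samples) &&
      !any(roles %in% c("control_untreated", "control_solvent"))) {
    note("configuration needs at least one control sample")
  }
  if (length(config$samples) && !any(roles == "treated_line")) {
    note("configuration needs at least one treated_line sample")
  }

  p <- config$params %||% list()
  unknown_p <- setdiff(names(p), names(PIPELINE_DEFAULTS))
  for (k in unknown_p) note("unknown params key '%s'", k)
  for (k in names(PIPELINE_DEFAULTS)) p[[k]] <- p[[k]] %||% PIPELINE_DEFAULTS[[k]]
  for (k in c("cg_min_diff", "chg_min_diff", "ectopic_min_diff",
              "restore_threshold", "min_loss")) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      note("params$%s must be a number in [0, 1], got %s", k,
           paste(format(v), collapse = ","))
    }
  }
  for (k in c("bin_size", "merge_gap", "min_cov", "cg_min_dmc",
              "chg_min_dmc", "ectopic_min_dmc", "near_gene_window")) {
    v <- p[[k]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v != round(v)) {
      note("params$%s must be a non-negative integer, got %s", k,
           paste(format(v), collapse = ","))
    } else p[[k]] <- as.integer(v)
  }
  if (is.numeric(p$bin_size) && p$bin_size < 1) note("params$bin_size must be >= 1")
  config$params <- p[order(names(p))]

  if (length(errors)) {
    stop("invalid pipeline configuration:\n  - ",
         paste(errors, collapse = "\n  - "), call. = FALSE)
  }
  structure(config[intersect(known, names(config))],
            class = "pipeline_config")
}

#' Run the full methylome analysis pipeline
#'
#' Reads every sample in the config, pools control replicates, calls CG
#' hypomethylated DMRs and ectopic-CHG regions per treated line, annotates
#' DMRs against the features, intersects DMR-proximal genes with the
#' configured DEG lists, computes metaplots, control-relative 100-kb ratio
#' tracks and the DMR x sample matrix, and (when eM3 lines are present)
#' restoration and sibling-segregation reports. All outputs, with stage
#' provenance, are listed in `manifest.json`; the run is deterministic
#' given config and inputs.
#'
#' @param config a path, list, or `pipeline_config`.
#' @return invisibly, the run directory path.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else validate_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$output_dir, "pipeline.log")
  logf <- function(stage, fmt, ...) {
    cat(sprintf("[%s] %s\n", stage, sprintf(fmt, ...)),
        file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  manifest <- list()
  emit <- function(path, stage) {
    manifest[[length(manifest) + 1]] <<- list(path = basename(path),
                                              stage = stage)
    path
  }
  p <- cfg$params

  roles <- vapply(cfg$samples, `[[`, character(1), "role")
  ids <- vapply(cfg$samples, `[[`, character(1), "id")
  tabs <- lapply(cfg$samples, function(s)
    read_cytosine_report(s$path, s$id, cfg$genome_id))
  names(tabs) <- ids
  logf("load", "read %d samples (%s)", length(tabs),
       paste(ids, collapse = ", "))

  ctl_roles <- if (any(roles == "control_untreated")) "control_untreated"
               else "control_solvent"
  control <- pool_replicates(tabs[roles == ctl_roles], sample_id = "control")
  logf("pool", "pooled %d %s replicates", sum(roles == ctl_roles), ctl_roles)

  features <- NULL
  if (!is.null(cfg$annotation)) features <- read_gff3_features(cfg$annotation)
  degs <- lapply(cfg$deg_lists %||% list(), function(d)
    read_gene_list(if (is.list(d)) d$path else d))

  cg_par <- dmr_params("CG", "hypo", min_dmc = p$cg_min_dmc,
                       min_diff = p$cg_min_diff, merge_gap = p$merge_gap,
                       bin_size = p$bin_size, min_cov = p$min_cov)
  ect_par <- dmr_params("CHG", "ectopic", min_dmc = p$ectopic_min_dmc,
                        min_diff = p$ectopic_min_diff,
                        merge_gap = p$merge_gap, bin_size = p$bin_size,
                        min_cov = p$min_cov)
  all_dmrs <- list()
  for (id in ids[roles == "treated_line"]) {
    dmrs <- call_dmrs(control, tabs[[id]], cg_par)
    all_dmrs[[id]] <- dmrs
    logf("call-dmrs", "%s: %d CG hypo DMRs", id, nrow(dmrs))
    write_dmr_bed(dmrs, emit(file.path(cfg$output_dir,
                                       paste0(id, ".cg_hypo.bed")),
                             "call-dmrs"))
    ect <- call_ectopic_chg(control, tabs[[id]], ect_par)
    logf("call-ectopic-chg", "%s: %d ectopic CHG regions", id, nrow(ect))
    write_dmr_bed(ect, emit(file.path(cfg$output_dir,
                                      paste0(id, ".ectopic_chg.bed")),
                            "call-ectopic-chg"))
    if (!is.null(features) && nrow(dmrs)) {
      ann <- classify_dmrs(dmrs, features)
      fwrite(ann[, !"member_bins"],
             emit(file.path(cfg$output_dir, paste0(id, ".dmr_annotation.tsv")),
                  "annotate"), sep = "\t")
      near <- genes_near_dmrs(dmrs, features, p$near_gene_window)
      writeLines(near$gene_ids,
                 emit(file.path(cfg$output_dir, paste0(id, ".near_genes.txt")),
                      "near-genes"))
      for (dg in degs) {
        both <- intersect_gene_sets(near, dg)
        logf("deg-intersect", "%s x %s: %d genes", id, dg$label, length(both))
        writeLines(both$gene_ids,
                   emit(file.path(cfg$output_dir,
                                  sprintf("%s.%s.intersect.txt", id, dg$label)),
                        "deg-intersect"))
      }
    }
  }

  if (!is.null(features)) {
    for (id in ids) {
      prof <- gene_metaplot(tabs[[id]], features, "CG",
                            min_cov = p$min_cov)
      fwrite(prof, emit(file.path(cfg$output_dir,
                                  paste0(id, ".metaplot.tsv")), "metaplot"),
             sep = "\t")
    }
  }
  for (id in ids[roles != ctl_roles]) {
    rt <- chromosome_ratio_profile(tabs[[id]], control, "CG")
    fwrite(rt, emit(file.path(cfg$output_dir, paste0(id, ".ratio100kb.tsv")),
                    "ratio-track"), sep = "\t")
  }

  treated_ids <- ids[roles == "treated_line"]
  em3_ids <- ids[roles == "em3_line"]
  if (length(treated_ids) && nrow(all_dmrs[[treated_ids[1]]])) {
    dmrs1 <- all_dmrs[[treated_ids[1]]]
    mat <- dmr_sample_matrix(dmrs1, tabs, "CG", p$min_cov)
    fwrite(as.data.table(mat, keep.rownames = "dmr"),
           emit(file.path(cfg$output_dir, "dmr_sample_matrix.tsv"), "matrix"),
           sep = "\t")
    if (length(em3_ids)) {
      recs <- lapply(em3_ids, function(id)
        classify_restoration(dmrs1, control, tabs[[treated_ids[1]]],
                             tabs[[id]], "CG", p$restore_threshold,
                             p$min_loss, p$min_cov))
      names(recs) <- em3_ids
      for (id in em3_ids) {
        fwrite(recs[[id]]$records,
               emit(file.path(cfg$output_dir,
                              paste0(id, ".restoration.tsv")), "transgen"),
               sep = "\t")
        logf("transgen", "%s: restored fraction %.3f (n=%d)", id,
             recs[[id]]$summary$restored, recs[[id]]$summary$n_defined)
      }
      if (length(em3_ids) >= 2) {
        sib <- compare_sibling_lines(recs[[1]]$records, recs[[2]]$records)
        write_dmr_bed(
          cbind(sib$segregating[, .(chrom, start, end)],
                context = "CG", direction = "hypo", mean_delta = 0),
          emit(file.path(cfg$output_dir, "segregating.bed"), "transgen"))
        logf("transgen", "siblings %s/%s: segregating fraction %.3f",
             em3_ids[1], em3_ids[2], sib$segregating_fraction)
      }
    }
  }

  yaml::write_yaml(unclass(cfg), file.path(cfg$output_dir, "config.echo.yaml"))
  manifest[[length(manifest) + 1]] <- list(path = "config.echo.yaml",
                                           stage = "provenance")
  jsonlite::write_json(list(params = cfg$params, files = manifest),
                       file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cfg$output_dir)
}
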
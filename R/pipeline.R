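#' Pipeline configuration
#'
#' Assembles the effective configuration for [run_pipeline()]. Every default
#' matches the package-wide convention: expression filter TPM >= 0.5, usage
#' |log2FC| >= 1.0, padj <= 0.05, 200 nt intron / 10 nt exon windows. When no
#' input paths are given the bundled simulator provides genome, annotation,
#' counts and a motif collection, making the demo self-contained.
#'
#' @param outdir output directory.
#' @param seed integer master seed; all pipeline randomness derives from it.
#' @param simulate list of [sim_config()] overrides (ignored when `paths`
#'   supplies real inputs).
#' @param paths optional named list: `genome`, `gtf`, `counts`,
#'   `sample_sheet`, `motifs`, `embryo_records`, `embryo_usage`. `NULL`
#'   entries fall back to simulation.
#' @param thresholds list of [analysis_thresholds()] overrides.
#' @param window list of [window_spec()] overrides.
#' @param tau asymmetry threshold for [classify_mode()].
#' @param n_decoys decoy motifs when simulating the motif collection.
#' @param enrichment_unit `"presence"` or `"hits"` (see [enrich_motifs()]).
#' @return A list of class `pipeline_config` with all defaults resolved.
#' @export
pipeline_config <- function(outdir = tempfile("posmap_run_"),
                            seed = 1L,
                            simulate = list(),
                            paths = list(),
                            thresholds = list(),
                            window = list(),
                            tau = 0.2,
                            n_decoys = 50L,
                            enrichment_unit = "presence") {
  sim_args <- utils::modifyList(list(seed = as.integer(seed)), simulate)
  cfg <- list(
    outdir = outdir,
    seed = as.integer(seed),
    simulate = sim_args,
    paths = paths,
    thresholds = do.call(analysis_thresholds, thresholds),
    window = do.call(window_spec, window),
    tau = tau,
    n_decoys = as.integer(n_decoys),
    enrichment_unit = match.arg(enrichment_unit, c("presence", "hits"))
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; omitted keys
#' keep their defaults.
#'
#' @param path YAML file.
#' @param ... overrides applied after the file (e.g. `seed`, `outdir`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  if (!file.exists(path)) config_error("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L) {
    config_error("unknown config key(s): %s", paste(bad, collapse = ", "))
  }
  args <- utils::modifyList(raw, list(...))
  do.call(pipeline_config, args)
}

pm_log <- function(fmt, ...) {
  message(sprintf("[posmap %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

# run one stage; on error, abort naming the stage and keep the files this
# stage already wrote under a .partial suffix
run_stage <- function(stage, written, code) {
  t0 <- Sys.time()
  pm_log("stage %s ...", stage)
  res <- tryCatch(code, error = function(e) {
    for (f in written()) {
      if (file.exists(f)) file.rename(f, paste0(f, ".partial"))
    }
    stop(pm_condition(
      sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
      "posmap_stage_error"))
  })
  pm_log("stage %s done (%.1fs)", stage,
         as.numeric(difftime(Sys.time(), t0, units = "secs")))
  res
}

write_tsv_out <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full positional motif-map pipeline
#'
#' Executes simulate (or load) -> usage test -> threshold/classify ->
#' background sampling -> proximal-region extraction -> motif scan and
#' enrichment -> positional profile -> mode call -> optional embryo/adult
#' comparison, writing every result as TSV into `config$outdir` plus a JSON
#' manifest with an MD5 hash per output file. Identical configuration and
#' seed give identical hashes. When no exon passes the thresholds the
#' motif stages are skipped and the manifest records the degenerate outcome.
#'
#' @param config a [pipeline_config()] or path to a YAML file for
#'   [read_pipeline_config()].
#' @return The manifest (list), invisibly; also written as `manifest.json`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  note <- function(path) {
    files <<- unique(c(files, path))
    path
  }
  written <- function() files

  eff <- unclass(config)
  eff$thresholds <- unclass(eff$thresholds)
  eff$window <- unclass(eff$window)
  yaml::write_yaml(eff, note(file.path(outdir, "config_effective.yaml")))

  p <- config$paths
  simulated <- is.null(p$genome) || is.null(p$gtf) || is.null(p$counts)

  ## ---- simulate / load ----
  inputs <- run_stage("simulate", written, {
    if (simulated) {
      ds <- simulate_dataset(do.call(sim_config, config$simulate))
      paths <- write_dataset(ds, outdir)
      for (f in paths) note(f)
      list(genome = ds$genome, models = ds$models, counts = ds$counts,
           groups = ds$groups, truth = ds$truth, plant_motif = ds$config$plant_motif)
    } else {
      for (f in unlist(p[c("genome", "gtf", "counts")])) {
        if (!file.exists(f)) config_error("input file not found: %s", f)
      }
      genome <- read_genome_fasta(p$genome)
      models <- read_gtf(p$gtf)
      counts <- read_counts(p$counts)
      sheet <- utils::read.delim(p$sample_sheet, stringsAsFactors = FALSE)
      groups <- sheet$group[match(colnames(counts), sheet$sample)]
      if (anyNA(groups)) format_error("sample sheet does not cover all count columns")
      list(genome = genome, models = models, counts = counts, groups = groups,
           truth = NULL, plant_motif = "ACUAAY")
    }
  })

  ## ---- motif collection ----
  motifs <- run_stage("motifs", written, {
    if (!is.null(p$motifs)) {
      if (!file.exists(p$motifs)) {
        config_error("motif file not found: %s", p$motifs)
      }
      parse_attract_table(p$motifs)
    } else {
      mc <- make_motif_collection(config$n_decoys, seed = config$seed,
                                  planted_iupac = inputs$plant_motif)
      write_attract_table(mc, note(file.path(outdir, "motifs.tsv")))
      mc
    }
  })

  ## ---- usage test + thresholds + classes ----
  records <- run_stage("usage", written, {
    rec <- exon_usage_test(inputs$counts, inputs$groups, models = inputs$models)
    write_usage_records(rec, note(file.path(outdir, "usage_records.tsv")))
    rec
  })
  classes <- run_stage("classify", written, {
    sig <- apply_thresholds(records, config$thresholds)
    cl <- classify_exons(sig)
    n_bg <- min(nrow(sig),
                sum(records$gene_tpm >= config$thresholds$min_tpm) - nrow(sig))
    bg <- if (n_bg > 0L) {
      sample_background(records, n_bg, seed = config$seed,
                        thresholds = config$thresholds)
    } else records[0L, , drop = FALSE]
    cs <- exon_class_set(cl$activated, cl$repressed, bg,
                         thresholds = config$thresholds, seed = config$seed)
    assign_df <- rbind(
      if (nrow(cl$activated)) data.frame(exon_key = cl$activated$exon_key,
                                         class = "activated"),
      if (nrow(cl$repressed)) data.frame(exon_key = cl$repressed$exon_key,
                                         class = "repressed"),
      if (nrow(bg)) data.frame(exon_key = bg$exon_key, class = "independent")
    )
    if (is.null(assign_df)) assign_df <- data.frame(exon_key = character(0),
                                                   class = character(0))
    write_tsv_out(assign_df, note(file.path(outdir, "exon_classes.tsv")))
    cs
  })

  n_sig <- nrow(classes$activated) + nrow(classes$repressed)
  manifest <- list(
    package = "posmap",
    seed = config$seed,
    outdir = outdir,
    n_exons_tested = nrow(records),
    n_significant = n_sig,
    n_activated = nrow(classes$activated),
    n_repressed = nrow(classes$repressed),
    status = if (n_sig == 0L) "no_differential_splicing" else "ok"
  )

  if (n_sig > 0L && nrow(classes$independent) > 0L) {
    ## ---- regions ----
    reg <- run_stage("extract", written, {
      fg_keys <- c(classes$activated$exon_key, classes$repressed$exon_key)
      bg_keys <- classes$independent$exon_key
      fg <- proximal_regions(inputs$models, inputs$genome, fg_keys,
                             config$window)
      bg <- proximal_regions(inputs$models, inputs$genome, bg_keys,
                             config$window)
      regions_to_bed(rbind(fg, bg), note(file.path(outdir, "regions.bed")))
      list(fg = fg, bg = bg)
    })
    ## ---- enrichment ----
    enr <- run_stage("enrich", written, {
      e <- enrich_motifs(reg$fg, reg$bg, motifs, unit = config$enrichment_unit)
      write_tsv_out(e, note(file.path(outdir, "enrichment.tsv")))
      e
    })
    ## ---- positional profile + mode ----
    prof <- run_stage("profile", written, {
      top <- motifs[motifs$motif_id == enr$motif_id[1L], , drop = FALSE]
      all_reg <- rbind(reg$fg, reg$bg)
      pr <- positional_profile(classes, all_reg, top)
      write_tsv_out(pr$summary, note(file.path(outdir, "profile.tsv")))
      write_tsv_out(pr$density, note(file.path(outdir, "profile_density.tsv")))
      pr
    })
    modes <- run_stage("mode", written, {
      m <- classify_mode(prof, tau = config$tau)
      write_tsv_out(m, note(file.path(outdir, "mode_calls.tsv")))
      m
    })
    manifest$top_motif <- enr$motif_id[1L]
    manifest$profiled_motif <- prof$motif
  }

  ## ---- optional embryo/adult comparison ----
  if (!is.null(p$embryo_records) && !is.null(p$embryo_usage)) {
    run_stage("compare", written, {
      emb_rec <- utils::read.delim(p$embryo_records, stringsAsFactors = FALSE)
      emb_use <- utils::read.delim(p$embryo_usage, stringsAsFactors = FALSE)
      embryo_wt <- stats::setNames(emb_use$usage, emb_use$exon_key)
      ov <- overlap_genes(apply_thresholds(records, config$thresholds)$gene_id,
                          apply_thresholds(emb_rec, config$thresholds)$gene_id)
      rev_ <- detect_reversion(records, embryo_wt, config$thresholds)
      write_tsv_out(rev_$events, note(file.path(outdir, "reversion_events.tsv")))
      write_tsv_out(
        data.frame(metric = c("n_overlap_genes", "fraction_b_in_a",
                              "fraction_a_in_b", "jaccard",
                              "n_reverted_genes"),
                   value = c(ov$n_intersect, ov$fraction_b_in_a,
                             ov$fraction_a_in_b, ov$jaccard,
                             rev_$n_reverted_genes)),
        note(file.path(outdir, "comparison_summary.tsv")))
      invisible(NULL)
    })
  }

  manifest$files <- lapply(sort(files), function(f) {
    list(path = basename(f), md5 = unname(tools::md5sum(f)))
  })
  names(manifest$files) <- vapply(manifest$files, `[[`, character(1), "path")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Summarize a pipeline run
#'
#' Reads the outputs named by a manifest and prints a human-readable summary:
#' significant/activated/repressed exon counts, the top enriched motifs, the
#' positional profile, the mode calls, and the reversion summary when the
#' comparison stage ran.
#'
#' @param manifest the list returned by [run_pipeline()] or the path to a
#'   `manifest.json`.
#' @return The summary as a list, invisibly.
#' @export
pipeline_report <- function(manifest) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  }
  need <- c("outdir", "n_significant", "status", "files")
  if (!all(need %in% names(manifest))) {
    data_error("incomplete manifest: missing %s",
               paste(setdiff(need, names(manifest)), collapse = ", "))
  }
  outdir <- manifest$outdir
  out <- list(
    n_exons_tested = manifest$n_exons_tested,
    n_significant = manifest$n_significant,
    n_activated = manifest$n_activated,
    n_repressed = manifest$n_repressed
  )
  cat(sprintf("posmap pipeline summary (seed %s)\n", manifest$seed))
  cat(sprintf("  exons tested: %d | significant: %d (activated %d, repressed %d)\n",
              out$n_exons_tested, out$n_significant, out$n_activated,
              out$n_repressed))
  if (identical(manifest$status, "no_differential_splicing")) {
    cat("  no differentially spliced exons\n")
    return(invisible(out))
  }
  enr_path <- file.path(outdir, "enrichment.tsv")
  if (file.exists(enr_path)) {
    enr <- utils::read.delim(enr_path, stringsAsFactors = FALSE)
    out$top_motifs <- utils::head(enr, 10L)
    cat("  top enriched motifs:\n")
    print(out$top_motifs[, c("rank", "rbp_name", "iupac", "odds_ratio",
                             "p_value", "padj")])
  }
  prof_path <- file.path(outdir, "profile.tsv")
  if (file.exists(prof_path)) {
    out$profile <- utils::read.delim(prof_path, stringsAsFactors = FALSE)
    cat("  positional profile (normalized motif counts):\n")
    print(out$profile)
  }
  mode_path <- file.path(outdir, "mode_calls.tsv")
  if (file.exists(mode_path)) {
    out$modes <- utils::read.delim(mode_path, stringsAsFactors = FALSE)
    cat("  positional mode calls:\n")
    print(out$modes)
  }
  cmp_path <- file.path(outdir, "comparison_summary.tsv")
  if (file.exists(cmp_path)) {
    out$comparison <- utils::read.delim(cmp_path, stringsAsFactors = FALSE)
    cat("  embryo/adult comparison:\n")
    print(out$comparison)
  }
  invisible(out)
}
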
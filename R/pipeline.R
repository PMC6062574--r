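log_msg <- function(stage, ...) {
  message("[", stage, "] ", ...)
}

write_stage_table <- function(dt, path, stage, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage=%s seed=%s umisense=%s", stage, seed,
                     as.character(utils::packageVersion("umisense"))), con)
  utils::write.table(dt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> qc -> downsample/saturation -> spike-in sensitivity
#' -> power simulation, as configured, writing every artifact under the
#' configured output directory together with the resolved configuration and
#' a machine-readable manifest (JSON with per-file MD5 checksums). A stage
#' failure halts the run with the stage name and persists the partial
#' manifest.
#'
#' @param config a `run_config` from [read_run_config()] (default: package
#'   defaults).
#' @param outdir overrides `config$outdir`.
#' @return path of the run directory, invisibly; the manifest is
#'   `manifest.json` inside it.
#' @export
run_pipeline <- function(config = read_run_config(), outdir = NULL) {
  if (!is.null(outdir)) config$outdir <- outdir
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character()
  manifest_path <- file.path(config$outdir, "manifest.json")
  add <- function(p) artifacts <<- c(artifacts, p)
  seed <- config$seed
  stage <- "config"
  result <- try({
    write_run_config(config, file.path(config$outdir, "config.yaml"))
    add(file.path(config$outdir, "config.yaml"))

    stage <- "simulate"
    log_msg(stage, "generating ", config$simdata$n_cells, " cells x ",
            config$simdata$n_genes, " genes (seed ", seed, ")")
    sc <- config$simdata
    cfg <- sim_config(
      n_cells = sc$n_cells,
      gene_means = rep(sc$mean_expression, sc$n_genes),
      gene_dispersions = rep(sc$dispersion, sc$n_genes),
      capture_efficiency = sc$capture_efficiency,
      pcr_cycles = sc$pcr_cycles,
      pcr_efficiency_alpha = sc$pcr_efficiency_alpha,
      pcr_efficiency_beta = sc$pcr_efficiency_beta,
      reads_per_cell = sc$reads_per_cell,
      doublet_rate = sc$doublet_rate,
      crosstalk_rate = sc$crosstalk_rate,
      seed = seed)
    ec <- config$ercc
    design <- spikein_ladder(ec$n_levels, ec$species_per_level,
                             ec$min_molecules, ec$max_molecules)
    exp <- simulate_experiment(cfg, design)
    write_matrix_bundle(exp$umi, file.path(config$outdir, "umi_matrix"))
    write_matrix_bundle(exp$reads, file.path(config$outdir, "read_matrix"))
    add(file.path(config$outdir, "umi_matrix",
                  c("matrix.mtx", "features.tsv", "barcodes.tsv")))
    add(file.path(config$outdir, "read_matrix",
                  c("matrix.mtx", "features.tsv", "barcodes.tsv")))
    mt_path <- file.path(config$outdir, "molecules.tsv.gz")
    write_molecule_table(exp$table, mt_path)
    add(mt_path)
    truth_path <- file.path(config$outdir, "truth_doublets.tsv")
    write_stage_table(
      data.table::data.table(cell = names(exp$truth$doublet_flags),
                             doublet = exp$truth$doublet_flags),
      truth_path, stage, seed)
    add(truth_path)

    stage <- "qc"
    log_msg(stage, "nearest-neighbor correlations and doublet flags")
    endo <- setdiff(rownames(exp$umi), design$spikein_id)
    nn <- nn_correlation(exp$umi[endo, , drop = FALSE])
    thr <- config$qc$nn_threshold
    if (!is.null(thr) && is.na(thr)) thr <- NULL
    lowq <- flag_low_quality(nn, thr)
    dbl <- flag_doublets_by_umi(colSums(exp$umi[endo, , drop = FALSE]),
                                config$qc$doublet_multiplier)
    qc_path <- file.path(config$outdir, "qc_cells.tsv")
    write_stage_table(
      data.table::data.table(cell = colnames(exp$umi),
                             nn_correlation = as.numeric(nn),
                             flag_low_correlation = as.logical(lowq),
                             flag_doublet_peak = as.logical(dbl),
                             nn_rule = attr(lowq, "rule"),
                             nn_cutoff = attr(lowq, "cutoff"),
                             doublet_cutoff = attr(dbl, "cutoff")),
      qc_path, stage, seed)
    add(qc_path)

    stage <- "depth"
    log_msg(stage, "saturation at depths ",
            paste(config$depth$depths, collapse = ","))
    sat <- saturation_curve(exp$table, config$depth$depths, seed = seed,
                            nested = config$depth$nested)
    sat_path <- file.path(config$outdir, "saturation.tsv")
    write_stage_table(sat, sat_path, stage, seed)
    add(sat_path)
    ev_path <- file.path(config$outdir, "amplification_evenness.tsv")
    write_stage_table(amplification_evenness(exp$table), ev_path, stage, seed)
    add(ev_path)

    stage <- "ercc"
    log_msg(stage, "per-cell detection fits")
    fits <- fit_detection_models(exp$umi, design, scale = ec$scale)
    fit_path <- file.path(config$outdir, "detection_fits.tsv")
    write_stage_table(fits, fit_path, stage, seed)
    add(fit_path)
    sens <- protocol_sensitivity(fits, "simulated")
    sens_path <- file.path(config$outdir, "sensitivity_summary.tsv")
    write_stage_table(sens, sens_path, stage, seed)
    add(sens_path)
    content <- estimate_mrna_content(exp$umi, design)
    con_path <- file.path(config$outdir, "mrna_content.tsv")
    write_stage_table(
      data.table::data.table(cell = names(content$per_cell),
                             molecules = content$per_cell),
      con_path, stage, seed)
    add(con_path)

    stage <- "power"
    pc <- config$power
    log_msg(stage, "power simulation, sizes ",
            paste(pc$sample_sizes, collapse = ","), " x ", pc$iterations,
            " iterations")
    params <- estimate_nb_params(exp$umi[endo, , drop = FALSE],
                                 pc$min_cells_detected)
    pw <- power_analysis(params, pc$sample_sizes, pc$iterations, seed,
                         pc$de_fraction, pc$lfc_sd, pc$alpha)
    pw_path <- file.path(config$outdir, "power_results.tsv")
    write_stage_table(pw$results, pw_path, stage, seed)
    add(pw_path)
    pws_path <- file.path(config$outdir, "power_summary.tsv")
    write_stage_table(pw$summary, pws_path, stage, seed)
    add(pws_path)
    NULL
  }, silent = TRUE)
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("umisense")),
    status = if (inherits(result, "try-error")) "failed" else "ok",
    failed_stage = if (inherits(result, "try-error")) stage else NULL,
    artifacts = lapply(artifacts, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  if (inherits(result, "try-error"))
    stop("pipeline failed in stage '", stage, "': ",
         attr(result, "condition")$message, call. = FALSE)
  invisible(config$outdir)
}
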
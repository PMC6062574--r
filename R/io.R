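#' Write a count matrix as a 10x-style MatrixMarket bundle
#'
#' Writes `matrix.mtx` (1-based coordinate MatrixMarket, integer values),
#' `features.tsv` (id, name, type in {endogenous, spikein}) and
#' `barcodes.tsv` into `dir`.
#'
#' @param mat features x cells integer matrix with dimnames.
#' @param dir output directory (created if needed).
#' @param feature_types optional character vector per row; default derives
#'   spike-ins from `spikein_prefix`.
#' @param spikein_prefix feature-id prefix marking spike-ins
#'   (default "ERCC-").
#' @return `dir`, invisibly.
#' @export
write_matrix_bundle <- function(mat, dir, feature_types = NULL,
                                spikein_prefix = "ERCC-") {
  stopifnot(!is.null(rownames(mat)), !is.null(colnames(mat)))
  if (anyDuplicated(rownames(mat)) || anyDuplicated(colnames(mat)))
    stop("duplicate feature ids or barcodes", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sp <- Matrix::Matrix(mat, sparse = TRUE)
  Matrix::writeMM(sp, file.path(dir, "matrix.mtx"))
  if (is.null(feature_types))
    feature_types <- ifelse(startsWith(rownames(mat), spikein_prefix),
                            "spikein", "endogenous")
  utils::write.table(
    data.frame(id = rownames(mat), name = rownames(mat),
               type = feature_types),
    file.path(dir, "features.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(colnames(mat), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a 10x-style MatrixMarket bundle
#'
#' Validates sidecar lengths against the matrix dimensions, rejects
#' duplicate ids/barcodes, and attaches the endogenous/spike-in partition
#' (from the features `type` column, falling back to `spikein_prefix`).
#'
#' @param dir directory containing matrix.mtx, features.tsv, barcodes.tsv.
#' @param spikein_prefix prefix fallback for the spike-in partition.
#' @return integer matrix with dimnames; attribute `"feature_type"`.
#' @export
read_matrix_bundle <- function(dir, spikein_prefix = "ERCC-") {
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("missing bundle file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  sp <- Matrix::readMM(paths[1L])
  feats <- utils::read.table(paths[2L], sep = "\t",
                             col.names = c("id", "name", "type"),
                             colClasses = "character")
  bcs <- readLines(paths[3L])
  if (nrow(feats) != nrow(sp))
    stop("features.tsv has ", nrow(feats), " rows but matrix declares ",
         nrow(sp), call. = FALSE)
  if (length(bcs) != ncol(sp))
    stop("barcodes.tsv has ", length(bcs), " rows but matrix declares ",
         ncol(sp), call. = FALSE)
  if (anyDuplicated(feats$id))
    stop("duplicate feature ids in features.tsv", call. = FALSE)
  if (anyDuplicated(bcs))
    stop("duplicate barcodes in barcodes.tsv", call. = FALSE)
  m <- as.matrix(sp)
  storage.mode(m) <- "integer"
  dimnames(m) <- list(feats$id, bcs)
  type <- feats$type
  if (all(type == "")) {
    type <- ifelse(startsWith(feats$id, spikein_prefix),
                   "spikein", "endogenous")
  }
  attr(m, "feature_type") <- stats::setNames(type, feats$id)
  m
}

#' Write a molecule table as (optionally gzipped) TSV
#'
#' Columns cell, feature, umi, reads with a header line.
#'
#' @param table a [molecule_table()].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_molecule_table <- function(table, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(data.table::as.data.table(table), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a molecule table
#'
#' Accepts plain or gzipped TSV with header (cell, feature, umi, reads).
#' Duplicate (cell, feature, umi) keys and reads < 1 are format errors
#' reported with their (1-based, header-inclusive) line numbers.
#'
#' @param path input path.
#' @return a [molecule_table()].
#' @export
read_molecule_table <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "r") else file(path, "r")
  on.exit(close(con))
  dt <- data.table::as.data.table(
    utils::read.table(con, sep = "\t", header = TRUE,
                      colClasses = c("character", "character", "character",
                                     "integer")))
  if (!identical(names(dt), c("cell", "feature", "umi", "reads")))
    stop("molecule table header must be cell, feature, umi, reads",
         call. = FALSE)
  if (nrow(dt) && any(dt$reads < 1L))
    stop("reads < 1 at line ", which(dt$reads < 1L)[1L] + 1L, call. = FALSE)
  dup <- which(duplicated(dt, by = c("cell", "feature", "umi")))
  if (length(dup))
    stop("duplicate molecule key at line ", dup[1L] + 1L, call. = FALSE)
  molecule_table(dt)
}

default_run_config <- function() {
  list(
    seed = 1L,
    outdir = "umisense_run",
    log_level = "info",
    simdata = list(n_cells = 96L, n_genes = 2000L, mean_expression = 10,
                   dispersion = 0.5, capture_efficiency = 0.1,
                   pcr_cycles = 14L, pcr_efficiency_alpha = 8,
                   pcr_efficiency_beta = 2, reads_per_cell = 20000L,
                   doublet_rate = 0, crosstalk_rate = 0),
    ercc = list(n_levels = 23L, species_per_level = 4L,
                min_molecules = 0.12, max_molecules = 10000,
                spikein_prefix = "ERCC-", scale = "log10"),
    qc = list(doublet_multiplier = 1.5, nn_threshold = NA),  # NA = MAD rule
    depth = list(depths = c(1000L, 5000L, 10000L, 20000L), nested = TRUE),
    power = list(sample_sizes = c(24L, 48L, 96L), iterations = 3L,
                 de_fraction = 0.10, lfc_sd = 1.5, alpha = 0.05,
                 min_cells_detected = 10L)
  )
}

merge_config <- function(base, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop("unknown config key: ", full, call. = FALSE)
    if (is.list(base[[key]]) && !is.null(user[[key]]))
      base[[key]] <- merge_config(base[[key]], as.list(user[[key]]), full)
    else base[[key]] <- user[[key]]
  }
  base
}

#' Read a pipeline run configuration (YAML)
#'
#' Unknown keys are rejected; omitted keys take package defaults. Pass
#' `path = NULL` for the pure defaults.
#'
#' @param path YAML file, or NULL.
#' @return nested list of class `run_config`.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- merge_config(cfg, user)
  }
  structure(cfg, class = "run_config")
}

#' Write the fully resolved run configuration
#' @param config a `run_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
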
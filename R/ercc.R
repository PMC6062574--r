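#' Spike-in design table
#'
#' The known number of input molecules per cell for each spike-in species,
#' the ground truth for detection-limit modeling. Molecules may be supplied
#' directly or derived from a concentration via [molecules_from_dilution()].
#'
#' @param spikein_id character vector of unique ids.
#' @param molecules_per_cell positive reals (fractional expected copies are
#'   allowed and retained in fitting).
#' @param attomoles_per_ul,dilution_factor,volume_ul alternative
#'   specification; used when `molecules_per_cell` is missing.
#' @return data.table of class `spikein_design` with columns `spikein_id`,
#'   `molecules_per_cell`.
#' @export
spikein_design <- function(spikein_id, molecules_per_cell = NULL,
                           attomoles_per_ul = NULL, dilution_factor = 1,
                           volume_ul = 1) {
  if (anyDuplicated(spikein_id))
    stop("spike-in ids must be unique", call. = FALSE)
  if (is.null(molecules_per_cell)) {
    if (is.null(attomoles_per_ul))
      stop("supply molecules_per_cell or attomoles_per_ul", call. = FALSE)
    molecules_per_cell <- molecules_from_dilution(attomoles_per_ul,
                                                  dilution_factor, volume_ul)
  }
  if (any(molecules_per_cell < 0))
    stop("molecules_per_cell must be non-negative", call. = FALSE)
  out <- data.table::data.table(spikein_id = as.character(spikein_id),
                                molecules_per_cell =
                                  as.numeric(molecules_per_cell))
  data.table::setattr(out, "class",
                      c("spikein_design", class(data.table::data.table())))
  out
}

as_spikein_design <- function(x) {
  if (inherits(x, "spikein_design")) return(x)
  spikein_design(x$spikein_id, x$molecules_per_cell)
}

#' ERCC-like geometric spike-in ladder
#'
#' A 92-species, 23-level geometric abundance ladder mirroring the layout of
#' ERCC Mix 1 (4 species per level). Default span is ~0.12 to 10,000 expected
#' molecules per cell (level ratio ~1.67, near 2-fold).
#'
#' @param n_levels number of abundance levels.
#' @param species_per_level species per level.
#' @param min_molecules,max_molecules molecules per cell at the lowest and
#'   highest level.
#' @return a [spikein_design()].
#' @export
spikein_ladder <- function(n_levels = 23L, species_per_level = 4L,
                           min_molecules = 0.12, max_molecules = 10000) {
  stopifnot(n_levels >= 2L, species_per_level >= 1L,
            min_molecules > 0, max_molecules > min_molecules)
  lv <- exp(seq(log(min_molecules), log(max_molecules), length.out = n_levels))
  mol <- rep(lv, each = species_per_level)
  spikein_design(sprintf("ERCC-%05d", seq_along(mol)), mol)
}

#' Molecules per cell from a dilution of a stock concentration
#'
#' molecules = attomoles_per_ul * volume_ul / dilution_factor * 6.02214076e5
#' (Avogadro's number gives 6.02214076e5 molecules per attomole).
#'
#' @param attomoles_per_ul stock concentration.
#' @param dilution_factor fold dilution (> 0), e.g. 80000 for 1:80,000.
#' @param volume_ul volume added per cell (> 0).
#' @return expected molecules per cell.
#' @examples
#' molecules_from_dilution(1, 80000, 0.1) # ~0.75 molecules
#' @export
molecules_from_dilution <- function(attomoles_per_ul, dilution_factor,
                                    volume_ul) {
  if (any(dilution_factor <= 0) || any(volume_ul <= 0))
    stop("dilution_factor and volume_ul must be positive", call. = FALSE)
  attomoles_per_ul * volume_ul / dilution_factor * 6.02214076e5
}

spikein_rows <- function(counts, design) {
  idx <- match(design$spikein_id, rownames(counts))
  if (anyNA(idx)) {
    warning(sum(is.na(idx)), " design id(s) absent from matrix; treated as ",
            "non-detected", call. = FALSE)
  }
  idx
}

#' Per-cell spike-in detection table
#'
#' One row per design entry: known input molecules and whether the species
#' was detected in that cell. A species is considered detected from 1 UMI.
#' Design ids absent from the matrix yield count 0 (absence = non-detection)
#' with a warning.
#'
#' @param umi_counts features x cells UMI count matrix (rownames contain the
#'   spike-in ids).
#' @param design a [spikein_design()].
#' @param cell barcode (column name) or column index.
#' @return data.table with columns `spikein_id`, `molecules`, `count`,
#'   `detected`.
#' @export
detection_table <- function(umi_counts, design, cell) {
  design <- as_spikein_design(design)
  idx <- spikein_rows(umi_counts, design)
  cnt <- ifelse(is.na(idx), 0L, umi_counts[ifelse(is.na(idx), 1L, idx), cell])
  data.table::data.table(spikein_id = design$spikein_id,
                         molecules = design$molecules_per_cell,
                         count = as.integer(cnt),
                         detected = as.integer(cnt >= 1L))
}

#' Fit the binomial logistic detection model for one cell
#'
#' Maximum-likelihood binomial regression of detection on spike-in input
#' abundance, logit P(detected) = b0 + b1 * log10(molecules) (or raw
#' molecules with `scale = "raw"`). Complete separation or an all-same
#' outcome yields `converged = FALSE` and an undefined m50, never an error.
#'
#' @param table output of [detection_table()] (columns `molecules`,
#'   `detected`).
#' @param scale covariate scale, `"log10"` (default; spike ladders are
#'   geometric) or `"raw"`.
#' @return object of class `detection_fit`: list(b0, b1, m50, converged,
#'   n_detected, n_total, scale).
#' @export
fit_detection_model <- function(table, scale = c("log10", "raw")) {
  scale <- match.arg(scale)
  tab <- data.table::as.data.table(table)
  if (length(unique(tab$molecules)) < 2L)
    stop("need >= 2 distinct molecule levels", call. = FALSE)
  res <- list(b0 = NA_real_, b1 = NA_real_, m50 = NA_real_,
              converged = FALSE, n_detected = sum(tab$detected),
              n_total = nrow(tab), scale = scale)
  class(res) <- "detection_fit"
  if (res$n_detected == 0L || res$n_detected == res$n_total)
    return(res)  # all-same outcome: flat likelihood direction, flagged
  x <- if (scale == "log10") log10(tab$molecules) else tab$molecules
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(tab$detected ~ x, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100L)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  res$b0 <- unname(stats::coef(fit)[1L])
  res$b1 <- unname(stats::coef(fit)[2L])
  res$converged <- fit$converged && !separated
  if (res$converged) res$m50 <- detection_limit(res)
  res
}

#' @export
print.detection_fit <- function(x, ...) {
  cat("detection_fit (", x$scale, "):", x$n_detected, "/", x$n_total,
      "detected; converged =", x$converged, "\n")
  if (x$converged)
    cat("  logit P =", signif(x$b0, 4), "+", signif(x$b1, 4),
        "* covariate; m50 =", signif(x$m50, 5), "molecules\n")
  invisible(x)
}

#' Molecules needed for 50% detection probability
#'
#' Inverts the fitted detection curve at P = 0.5: m50 = 10^(-b0/b1) on the
#' log10 scale (or -b0/b1 on the raw scale). Requires a converged fit with
#' positive slope; otherwise NA.
#'
#' @param fit a `detection_fit` (or list with b0, b1, scale).
#' @return m50 in molecules, or NA if undefined.
#' @export
detection_limit <- function(fit) {
  if (is.na(fit$b1) || fit$b1 <= 0) return(NA_real_)
  if (identical(fit$scale, "raw")) -fit$b0 / fit$b1 else 10^(-fit$b0 / fit$b1)
}

#' Closed-form detection limit of the binomial capture model
#'
#' Under per-molecule capture probability p, P(detect | m fixed input copies)
#' = 1 - (1-p)^m, so 50% detection needs ln(0.5)/ln(1-p) molecules. Serves as
#' the analytic oracle for GLM-derived m50 on data simulated with fixed-copy
#' (fractional) loading; Poisson loading shifts the curve to 1 - exp(-mp)
#' with m50 = ln(2)/p instead.
#'
#' @param p capture probability, strictly in (0, 1).
#' @return molecules needed for 50% detection.
#' @examples
#' closed_form_limit(0.5) # 1
#' closed_form_limit(0.1) # 6.5788...
#' @export
closed_form_limit <- function(p) {
  if (any(p <= 0) || any(p >= 1))
    stop("p must be strictly inside (0, 1)", call. = FALSE)
  log(0.5) / log1p(-p)
}

#' Fit detection models for many cells
#'
#' @param umi_counts features x cells UMI count matrix.
#' @param design a [spikein_design()].
#' @param cells barcodes to fit (default: all columns).
#' @param scale covariate scale, see [fit_detection_model()].
#' @return data.table: cell, b0, b1, m50, converged, n_detected, n_total.
#' @export
fit_detection_models <- function(umi_counts, design, cells = NULL,
                                 scale = "log10") {
  if (is.null(cells)) cells <- colnames(umi_counts)
  rows <- lapply(cells, function(cc) {
    f <- suppressWarnings(
      fit_detection_model(detection_table(umi_counts, design, cc), scale))
    data.table::data.table(cell = cc, b0 = f$b0, b1 = f$b1, m50 = f$m50,
                           converged = f$converged,
                           n_detected = f$n_detected, n_total = f$n_total)
  })
  data.table::rbindlist(rows)
}

#' Per-group median detection limit
#'
#' Summarizes per-cell m50 values by group (e.g. protocol). Non-converged
#' fits are excluded, with the exclusion count reported per group; a group
#' with zero converged fits is reported with an NA median, never dropped.
#'
#' @param fits data.table from [fit_detection_models()].
#' @param grouping group label per row of `fits` (recycled scalar allowed).
#' @return data.table: group, median_m50, n_cells, n_excluded.
#' @export
protocol_sensitivity <- function(fits, grouping = "all") {
  dt <- data.table::as.data.table(fits)
  dt[, "group" := rep_len(grouping, nrow(dt))]
  g <- dt[, list(
    median_m50 = if (any(converged & !is.na(m50)))
      stats::median(m50[converged & !is.na(m50)]) else NA_real_,
    n_cells = sum(converged & !is.na(m50)),
    n_excluded = sum(!converged | is.na(m50))
  ), by = "group"]
  excl <- sum(g$n_excluded)
  if (excl > 0L)
    message("protocol_sensitivity: excluded ", excl, " non-converged fit(s)")
  g[]
}

#' Spike-in detection efficiency of a cell
#'
#' Fraction of spiked molecules recovered as UMIs: sum of spike-in UMI counts
#' divided by the sum of design molecules (ratio of sums, not mean of
#' per-species ratios). Values above 1 are permitted but flagged as
#' anomalous.
#'
#' @param umi_counts features x cells UMI count matrix.
#' @param design a [spikein_design()].
#' @param cells barcodes (default all); vectorized.
#' @return named numeric vector of efficiencies.
#' @export
detection_efficiency <- function(umi_counts, design, cells = NULL) {
  design <- as_spikein_design(design)
  if (is.null(cells)) cells <- colnames(umi_counts)
  idx <- spikein_rows(umi_counts, design)
  tot <- sum(design$molecules_per_cell)
  sub <- umi_counts[idx[!is.na(idx)], cells, drop = FALSE]
  eff <- colSums(sub) / tot
  if (any(eff > 1))
    warning(sum(eff > 1), " cell(s) with detection efficiency > 1 (anomalous)",
            call. = FALSE)
  stats::setNames(as.numeric(eff), cells)
}

#' Estimate cellular mRNA content from spike-in efficiency
#'
#' Per cell: total endogenous UMIs divided by the spike-in detection
#' efficiency. Cells with zero efficiency are undefined (NA) and excluded
#' from the median with a message.
#'
#' @param umi_counts features x cells UMI count matrix (endogenous +
#'   spike-in rows).
#' @param design a [spikein_design()] identifying the spike-in rows.
#' @param cells barcodes (default all).
#' @return list: `per_cell` named vector of molecule estimates,
#'   `median` across defined cells, `n_undefined`.
#' @export
estimate_mrna_content <- function(umi_counts, design, cells = NULL) {
  design <- as_spikein_design(design)
  if (is.null(cells)) cells <- colnames(umi_counts)
  eff <- suppressWarnings(detection_efficiency(umi_counts, design, cells))
  endo <- setdiff(rownames(umi_counts), design$spikein_id)
  tot <- colSums(umi_counts[endo, cells, drop = FALSE])
  content <- ifelse(eff > 0, tot / eff, NA_real_)
  n_undef <- sum(is.na(content))
  if (n_undef > 0L)
    message("estimate_mrna_content: ", n_undef,
            " cell(s) with zero efficiency excluded")
  list(per_cell = stats::setNames(as.numeric(content), cells),
       median = stats::median(content, na.rm = TRUE),
       n_undefined = n_undef)
}
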
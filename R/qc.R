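#' Nearest-neighbor Spearman correlation per cell
#'
#' All-to-all Spearman rank correlations of expression values (raw counts;
#' ranks are invariant to any monotone per-cell transform), then per cell the
#' highest correlation against any other cell. Broken cells and failed
#' libraries show visibly lower nearest-neighbor correlations than average
#' cells.
#'
#' @param umi_counts features x cells count matrix (>= 2 cells).
#' @return named numeric vector, NA (flagged via attribute `"undefined"`)
#'   for constant-expression cells.
#' @export
nn_correlation <- function(umi_counts) {
  if (ncol(umi_counts) < 2L)
    stop("need >= 2 cells for nearest-neighbor correlations", call. = FALSE)
  m <- as.matrix(umi_counts)
  cc <- suppressWarnings(stats::cor(m, method = "spearman"))
  diag(cc) <- NA
  nn <- apply(cc, 2L, function(v) if (all(is.na(v))) NA_real_
              else max(v, na.rm = TRUE))
  undef <- apply(m, 2L, function(v) stats::sd(v) == 0)
  nn[undef] <- NA_real_
  out <- stats::setNames(as.numeric(nn), colnames(m))
  attr(out, "undefined") <- names(out)[undef]
  out
}

#' Flag low-quality cells from nearest-neighbor correlations
#'
#' Default rule: flag cells with nn < median(nn) - 3 * MAD(nn), a robust
#' stand-in for the visual call that low-quality libraries sit clearly below
#' the bulk of the distribution. When MAD = 0 only cells strictly below the
#' median are flagged. A fixed numeric `threshold` overrides the rule.
#' Undefined (NA) values are always flagged.
#'
#' @param nn_values numeric vector from [nn_correlation()].
#' @param threshold optional fixed cutoff; cells with nn < threshold are
#'   flagged.
#' @return logical vector; attributes `"rule"` and `"cutoff"` record the
#'   decision rule actually applied.
#' @export
flag_low_quality <- function(nn_values, threshold = NULL) {
  if (is.null(threshold)) {
    med <- stats::median(nn_values, na.rm = TRUE)
    cutoff <- med - 3 * stats::mad(nn_values, na.rm = TRUE)
    rule <- "median-3MAD"
  } else {
    cutoff <- threshold
    rule <- "fixed"
  }
  flags <- is.na(nn_values) | nn_values < cutoff
  names(flags) <- names(nn_values)
  attr(flags, "rule") <- rule
  attr(flags, "cutoff") <- cutoff
  flags
}

#' Flag doublets as multiples of the modal UMI total
#'
#' Doublets are identifiable as multiples of the major peak of the per-cell
#' UMI-total distribution. The major mode is located by Gaussian kernel
#' density with Silverman's bandwidth; cells with total > multiplier * mode
#' are flagged.
#'
#' @param umi_totals per-cell total UMI counts (>= 5 cells).
#' @param multiplier cutoff multiple of the mode (default 1.5).
#' @return logical vector; attributes `"mode"`, `"multiplier"`, `"cutoff"`.
#' @export
flag_doublets_by_umi <- function(umi_totals, multiplier = 1.5) {
  if (length(umi_totals) < 5L)
    stop("mode estimation unreliable with < 5 cells", call. = FALSE)
  if (stats::sd(umi_totals) == 0) {
    mode <- umi_totals[1L]
  } else {
    d <- stats::density(umi_totals, bw = "nrd0", kernel = "gaussian")
    mode <- d$x[which.max(d$y)]
  }
  flags <- umi_totals > multiplier * mode
  names(flags) <- names(umi_totals)
  attr(flags, "mode") <- mode
  attr(flags, "multiplier") <- multiplier
  attr(flags, "cutoff") <- multiplier * mode
  flags
}

#' Fixed-threshold cell filters
#'
#' Retains cells with at least `min_reads` raw reads AND a mapping rate
#' strictly above `min_maprate`; then excludes likely doublets that have
#' strictly more than `max_umis` UMIs AND strictly more than `max_genes`
#' genes (both conditions required). Defaults follow common practice for
#' plate-based libraries of a complex tissue.
#'
#' @param records data.frame with columns `cell_barcode`, `total_reads`,
#'   `mapping_rate`, `total_umis`, `genes_detected`.
#' @param min_reads,min_maprate,max_umis,max_genes thresholds.
#' @return list: `retained` barcodes, `excluded` data.table (cell, rule) and
#'   `tally` of exclusions per rule (a cell failing several read/maprate
#'   rules is tallied under each).
#' @export
filter_cells_threshold <- function(records, min_reads = 50000,
                                   min_maprate = 0.75, max_umis = 40000,
                                   max_genes = 5000) {
  dt <- data.table::as.data.table(records)
  low_reads <- dt$total_reads < min_reads
  low_map <- dt$mapping_rate <= min_maprate
  keep1 <- !low_reads & !low_map
  dbl <- keep1 & dt$total_umis > max_umis & dt$genes_detected > max_genes
  retained <- dt$cell_barcode[keep1 & !dbl]
  excl <- data.table::rbindlist(list(
    data.table::data.table(cell = dt$cell_barcode[low_reads],
                           rule = "low_reads"),
    data.table::data.table(cell = dt$cell_barcode[low_map],
                           rule = "low_maprate"),
    data.table::data.table(cell = dt$cell_barcode[dbl],
                           rule = "doublet_threshold")))
  list(retained = retained,
       excluded = excl,
       tally = c(low_reads = sum(low_reads), low_maprate = sum(low_map),
                 doublet_threshold = sum(dbl)))
}

#' Classify barcodes by species in a mixing experiment
#'
#' In a barnyard design the two species' cells are mixed, so cross-cell
#' contamination shows up as reads assigned to the wrong genome. Each barcode
#' is called for the genome with more uniquely aligned reads; the
#' wrong-species fraction is min(a, b) / (a + b).
#'
#' @param counts data.frame with columns `cell_barcode`, `reads_species_a`,
#'   `reads_species_b` (unique alignments only).
#' @return data.table: cell_barcode, reads_species_a, reads_species_b,
#'   call ("A", "B" or "ambiguous"), wrong_species_fraction (NA when a+b = 0).
#' @export
assign_species <- function(counts) {
  dt <- data.table::as.data.table(counts)
  a <- dt$reads_species_a
  b <- dt$reads_species_b
  call <- ifelse(a > b, "A", ifelse(b > a, "B", "ambiguous"))
  frac <- ifelse(a + b > 0, pmin(a, b) / (a + b), NA_real_)
  data.table::data.table(cell_barcode = dt$cell_barcode,
                         reads_species_a = a, reads_species_b = b,
                         call = call, wrong_species_fraction = frac)
}

#' Welch test comparing crosstalk between two groups
#'
#' Two-sided Welch two-sample t-test (Welch-Satterthwaite degrees of
#' freedom) on wrong-species fractions, e.g. comparing protocol variants.
#'
#' @param fractions_group1,fractions_group2 numeric vectors (length >= 2).
#' @return list: statistic, df, p.value, mean1, mean2.
#' @export
compare_crosstalk_groups <- function(fractions_group1, fractions_group2) {
  if (length(fractions_group1) < 2L || length(fractions_group2) < 2L)
    stop("each group needs >= 2 values", call. = FALSE)
  tt <- stats::t.test(fractions_group1, fractions_group2,
                      alternative = "two.sided", var.equal = FALSE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p.value = tt$p.value,
       mean1 = mean(fractions_group1), mean2 = mean(fractions_group2))
}
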
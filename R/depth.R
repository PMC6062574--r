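cell_stage_seed <- function(seed, i, extra = 0L) {
  as.integer((as.numeric(seed) + 100003 * i + extra) %% 2147483647)
}

#' Downsample a molecule table to a fixed read depth per cell
#'
#' For each cell, exactly min(target_depth, total reads) reads are drawn
#' without replacement from the cell's read multiset (a multivariate
#' hypergeometric draw over molecules); molecules left with zero reads are
#' removed. With `nested = TRUE` (default) the reads kept at a smaller depth
#' are a subset of those kept at any larger depth for the same seed, so
#' saturation curves are monotone per cell. Cells with fewer reads than the
#' target are kept at full depth and listed in attribute `"short_cells"`,
#' not dropped.
#'
#' @param table a [molecule_table()].
#' @param target_depth reads to retain per cell (>= 1).
#' @param seed integer seed.
#' @param nested logical; nested subset sampling (default) or independent
#'   draws per depth.
#' @return a downsampled `molecule_table`.
#' @export
downsample_reads <- function(table, target_depth, seed = 1L, nested = TRUE) {
  if (target_depth < 1) stop("target_depth must be >= 1", call. = FALSE)
  target_depth <- as.integer(target_depth)
  dt <- data.table::copy(data.table::as.data.table(table))
  data.table::setorder(dt, cell)  # stable: within-cell input order preserved
  totals <- dt[, list(tot = sum(reads)), by = "cell"]
  short <- totals$cell[totals$tot < target_depth]
  extra <- if (nested) 0L else target_depth
  # per-cell seed depends only on (seed, cell rank[, depth]): prefixes of one
  # shuffle give nested read subsets across depths for the same seed
  res <- dt[, {
    tot <- sum(reads)
    if (tot <= target_depth) {
      list(feature = feature, umi = umi, reads = reads)
    } else {
      molidx <- rep.int(seq_len(.N), reads)
      set.seed(cell_stage_seed(seed, .GRP, extra))
      kept <- tabulate(molidx[sample.int(tot)][seq_len(target_depth)],
                       nbins = .N)
      sel <- kept > 0L
      list(feature = feature[sel], umi = umi[sel], reads = kept[sel])
    }
  }, by = "cell"]
  res <- molecule_table(res)
  data.table::setattr(res, "short_cells", short)
  res
}

#' Saturation curve: complexity versus sequencing depth
#'
#' Downsamples the table to each requested depth and records per cell the
#' number of distinct UMIs and genes detected. With nested sampling the
#' curves are non-decreasing in depth for every cell and seed.
#'
#' @param table a [molecule_table()].
#' @param depths integer vector of read depths.
#' @param seed integer seed.
#' @param nested passed to [downsample_reads()].
#' @return data.table: cell, depth, reads_kept, umis_detected,
#'   genes_detected, umis_per_read.
#' @export
saturation_curve <- function(table, depths, seed = 1L, nested = TRUE) {
  depths <- sort(unique(as.integer(depths)))
  rows <- lapply(depths, function(d) {
    ds <- downsample_reads(table, d, seed = seed, nested = nested)
    dd <- data.table::as.data.table(ds)
    pt <- dd[, list(reads_kept = sum(reads), umis_detected = .N,
                    genes_detected = length(unique(feature))), by = "cell"]
    pt[, "depth" := d]
    pt[, "umis_per_read" := pt$umis_detected / pt$reads_kept]
    pt
  })
  out <- data.table::rbindlist(rows)
  data.table::setcolorder(out, c("cell", "depth", "reads_kept",
                                 "umis_detected", "genes_detected",
                                 "umis_per_read"))
  out[order(out$cell, out$depth)]
}

#' Amplification evenness statistics per cell
#'
#' Reads-per-UMI summaries computed exactly from the molecule table: mean,
#' coefficient of variation (population SD / mean) and UMIs per read. Uneven
#' amplification inflates the CV and wastes reads on overamplified
#' molecules, reducing recovered complexity at fixed depth. CV is undefined
#' (NA) for cells with fewer than 2 molecules.
#'
#' @param table a [molecule_table()].
#' @return data.table: cell, n_umis, total_reads, mean_reads_per_umi,
#'   cv_reads_per_umi, umis_per_read.
#' @export
amplification_evenness <- function(table) {
  dt <- data.table::as.data.table(table)
  dt[, list(
    n_umis = .N,
    total_reads = sum(reads),
    mean_reads_per_umi = mean(reads),
    cv_reads_per_umi = if (.N < 2L) NA_real_
      else sqrt(mean((reads - mean(reads))^2)) / mean(reads),
    umis_per_read = .N / sum(reads)
  ), by = "cell"][order(cell)]
}
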
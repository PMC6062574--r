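#' Simulation configuration for molecule-level scRNA-seq data
#'
#' Bundles the parameters of the generative model: negative-binomial (NB)
#' endogenous expression, per-molecule binomial capture, uneven PCR
#' amplification, fixed-depth read sampling, doublets and barcode crosstalk.
#'
#' The NB is parameterized by mean \eqn{\mu} and dispersion \eqn{\phi} with
#' \eqn{var = \mu + \phi \mu^2}; this maps to the base-R `size` parameter as
#' `size = 1/phi` (and \eqn{\phi = 0} degenerates to Poisson).
#'
#' @param n_cells number of cells (non-negative integer).
#' @param gene_means vector of positive reals: expected molecules per cell per
#'   gene.
#' @param gene_dispersions vector of non-negative reals, same length as
#'   `gene_means`: NB dispersion \eqn{\phi}.
#' @param capture_efficiency per-molecule probability in (0, 1] that an input
#'   molecule is converted to an observable UMI.
#' @param pcr_cycles non-negative integer number of PCR cycles.
#' @param pcr_efficiency_alpha,pcr_efficiency_beta positive shape parameters:
#'   per-molecule amplification efficiency is drawn Beta(alpha, beta).
#' @param reads_per_cell positive integer sequencing depth per cell.
#' @param doublet_rate fraction of cells merged into doublets, in [0, 0.5).
#' @param crosstalk_rate per-molecule probability of reassignment to another
#'   barcode, in [0, 0.2].
#' @param seed integer seed; expanded into per-stage child seeds (see
#'   [child_seeds()]).
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(n_cells = 10, gene_means = rep(2, 50))
#' @export
sim_config <- function(n_cells,
                       gene_means,
                       gene_dispersions = rep(0, length(gene_means)),
                       capture_efficiency = 0.1,
                       pcr_cycles = 14L,
                       pcr_efficiency_alpha = 8,
                       pcr_efficiency_beta = 2,
                       reads_per_cell = 10000L,
                       doublet_rate = 0,
                       crosstalk_rate = 0,
                       seed = 1L) {
  stopifnot(length(n_cells) == 1L, n_cells >= 0, n_cells == floor(n_cells))
  if (length(gene_means) != length(gene_dispersions))
    stop("gene_means and gene_dispersions must have equal length",
         call. = FALSE)
  if (any(gene_means <= 0)) stop("gene_means must be positive", call. = FALSE)
  if (any(gene_dispersions < 0))
    stop("gene_dispersions must be non-negative", call. = FALSE)
  if (capture_efficiency <= 0 || capture_efficiency > 1)
    stop("capture_efficiency must be in (0, 1]", call. = FALSE)
  stopifnot(pcr_cycles >= 0, pcr_cycles == floor(pcr_cycles),
            pcr_efficiency_alpha > 0, pcr_efficiency_beta > 0,
            reads_per_cell >= 1)
  if (doublet_rate < 0 || doublet_rate >= 0.5)
    stop("doublet_rate must be in [0, 0.5)", call. = FALSE)
  if (crosstalk_rate < 0 || crosstalk_rate > 0.2)
    stop("crosstalk_rate must be in [0, 0.2]", call. = FALSE)
  structure(list(
    n_cells = as.integer(n_cells),
    gene_means = as.numeric(gene_means),
    gene_dispersions = as.numeric(gene_dispersions),
    capture_efficiency = capture_efficiency,
    pcr_cycles = as.integer(pcr_cycles),
    pcr_efficiency_alpha = pcr_efficiency_alpha,
    pcr_efficiency_beta = pcr_efficiency_beta,
    reads_per_cell = as.integer(reads_per_cell),
    doublet_rate = doublet_rate,
    crosstalk_rate = crosstalk_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_cells, "cells,", length(x$gene_means), "genes\n")
  cat("  capture p =", x$capture_efficiency,
      "| PCR", x$pcr_cycles, "cycles, e ~ Beta(",
      x$pcr_efficiency_alpha, ",", x$pcr_efficiency_beta, ")\n")
  cat("  depth =", x$reads_per_cell, "reads/cell | doublets",
      x$doublet_rate, "| crosstalk", x$crosstalk_rate,
      "| seed", x$seed, "\n")
  invisible(x)
}

#' Expand a global seed into per-stage child seeds
#'
#' Fixed rule: `set.seed(seed)` then `sample.int(2^31 - 2, n)`. Each pipeline
#' stage consumes one child seed, so stages are independently reproducible.
#'
#' @param seed integer master seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`, all below 2^31.
#' @export
child_seeds <- function(seed, n) {
  stopifnot(n >= 1)
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(2147483646L, n)
}

barcode_names <- function(n) sprintf("BC%05d", seq_len(n))
gene_names <- function(n) sprintf("G%05d", seq_len(n))

#' Simulate endogenous expression (true molecule counts)
#'
#' Draws the features x cells matrix of true molecules per cell, entry (g, c)
#' ~ NB(mean mu_g, dispersion phi_g) as a gamma-Poisson mixture; phi_g = 0
#' gives Poisson(mu_g).
#'
#' @param config a [sim_config()].
#' @return integer matrix, genes in rows, cells in columns, with dimnames.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(child_seeds(config$seed, 8L)[1L])
  g <- length(config$gene_means)
  n <- config$n_cells
  m <- matrix(0L, nrow = g, ncol = n,
              dimnames = list(gene_names(g), barcode_names(n)))
  if (n == 0L) return(m)
  phi <- config$gene_dispersions
  mu <- config$gene_means
  pois <- phi == 0
  if (any(pois))
    m[pois, ] <- stats::rpois(sum(pois) * n, mu[pois])
  if (any(!pois))
    m[!pois, ] <- stats::rnbinom(sum(!pois) * n, mu = mu[!pois],
                                 size = 1 / phi[!pois])
  storage.mode(m) <- "integer"
  m
}

#' Binomial capture of molecules
#'
#' Each true molecule independently becomes an observable UMI with probability
#' `p`, so entrywise captured ~ Binomial(true, p). This implies the detection
#' law P(detect | m true molecules) = 1 - (1-p)^m.
#'
#' @param true_counts integer matrix of true molecules (features x cells).
#' @param p capture probability in [0, 1].
#' @param seed integer seed.
#' @return integer matrix with the dimensions and dimnames of `true_counts`.
#' @export
capture_molecules <- function(true_counts, p, seed = 1L) {
  if (p < 0 || p > 1) stop("capture probability must be in [0, 1]",
                           call. = FALSE)
  set.seed(as.integer(seed))
  out <- true_counts
  out[] <- stats::rbinom(length(true_counts), size = as.vector(true_counts),
                         prob = p)
  storage.mode(out) <- "integer"
  out
}

#' Simulate captured spike-in counts for a plate of cells
#'
#' Loading of each spike-in species into each cell is, by default, Poisson
#' around the design value (physical pipetting of a dilution, which is also
#' what makes fractional expected copies meaningful); captured counts are then
#' a binomial thinning with probability `p`. `loading = "fractional"` instead
#' loads floor(m) + Bernoulli(m - floor(m)) copies, the fixed-copy world in
#' which the detection law is exactly 1 - (1-p)^m (see [closed_form_limit()]).
#'
#' @param design a [spikein_design()] (or data.frame with `spikein_id`,
#'   `molecules_per_cell`).
#' @param p capture probability in [0, 1].
#' @param n_cells number of cells.
#' @param seed integer seed.
#' @param loading `"poisson"` (default) or `"fractional"`.
#' @return integer matrix, spike-in species x cells.
#' @export
spike_in_counts <- function(design, p, n_cells, seed = 1L,
                            loading = c("poisson", "fractional")) {
  loading <- match.arg(loading)
  design <- as_spikein_design(design)
  if (any(design$molecules_per_cell < 0))
    stop("design molecules must be non-negative", call. = FALSE)
  if (p < 0 || p > 1) stop("capture probability must be in [0, 1]",
                           call. = FALSE)
  set.seed(as.integer(seed))
  s <- nrow(design)
  mol <- design$molecules_per_cell
  loaded <- if (loading == "poisson") {
    matrix(stats::rpois(s * n_cells, rep(mol, n_cells)), nrow = s)
  } else {
    fl <- floor(mol)
    matrix(rep(fl, n_cells) +
             stats::rbinom(s * n_cells, 1L, rep(mol - fl, n_cells)),
           nrow = s)
  }
  cap <- matrix(stats::rbinom(s * n_cells, size = as.vector(loaded), prob = p),
                nrow = s,
                dimnames = list(design$spikein_id, barcode_names(n_cells)))
  storage.mode(cap) <- "integer"
  attr(cap, "loaded") <- loaded
  cap
}

#' Construct / validate a molecule table
#'
#' A molecule table records one row per sequenced molecule: cell barcode,
#' feature id, UMI id and number of reads supporting it.
#'
#' @param x data.frame with columns `cell`, `feature`, `umi`, `reads`.
#' @return a `molecule_table` (a data.table).
#' @export
molecule_table <- function(x) {
  dt <- data.table::as.data.table(x)
  need <- c("cell", "feature", "umi", "reads")
  if (!all(need %in% names(dt)))
    stop("molecule table needs columns cell, feature, umi, reads",
         call. = FALSE)
  dt <- dt[, need, with = FALSE]
  dt[, c("cell", "feature", "umi") := lapply(.SD, as.character),
     .SDcols = c("cell", "feature", "umi")]
  dt[, "reads" := as.integer(dt[["reads"]])]
  if (nrow(dt) && any(dt$reads < 1L))
    stop("molecule reads must be >= 1", call. = FALSE)
  if (anyDuplicated(dt, by = c("cell", "feature", "umi")))
    stop("duplicate (cell, feature, umi) keys", call. = FALSE)
  data.table::setattr(dt, "class",
                      c("molecule_table", class(data.table::data.table())))
  dt
}

#' PCR amplification and fixed-depth sequencing
#'
#' Each captured molecule i draws an amplification efficiency
#' e_i ~ Beta(alpha, beta) and gets weight w_i = (1 + e_i)^cycles. For each
#' cell, `reads_per_cell` reads are allocated over its molecules by a single
#' multinomial draw with probabilities proportional to w_i. Molecules with
#' zero reads are dropouts: absent from the returned table. Read totals per
#' non-empty cell equal `reads_per_cell` exactly.
#'
#' Deterministic per-molecule weights (rather than a branching process) are a
#' documented simplification: they reproduce reads-per-UMI dispersion at desk
#' scale.
#'
#' @param captured integer matrix of captured molecules (features x cells).
#' @param config a [sim_config()] supplying cycles, Beta shapes and depth.
#' @param seed integer seed (default: the amplify-stage child of
#'   `config$seed`).
#' @return a [molecule_table()]; attribute `"amplification"` holds the
#'   per-molecule weights (named list per cell).
#' @export
amplify_and_sequence <- function(captured, config,
                                 seed = child_seeds(config$seed, 8L)[4L]) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  cells <- colnames(captured)
  if (is.null(cells)) cells <- barcode_names(ncol(captured))
  feats <- rownames(captured)
  if (is.null(feats)) feats <- gene_names(nrow(captured))
  depth <- config$reads_per_cell
  out <- vector("list", ncol(captured))
  amp <- vector("list", ncol(captured))
  names(amp) <- cells
  for (j in seq_len(ncol(captured))) {
    cnt <- captured[, j]
    tot <- sum(cnt)
    if (tot == 0L) {
      warning("cell ", cells[j], " has zero captured molecules; emitting ",
              "empty cell", call. = FALSE)
      next
    }
    fidx <- rep.int(seq_along(cnt), cnt)
    e <- stats::rbeta(tot, config$pcr_efficiency_alpha,
                      config$pcr_efficiency_beta)
    w <- (1 + e)^config$pcr_cycles
    reads <- as.integer(stats::rmultinom(1L, depth, prob = w))
    keep <- reads > 0L
    # umi ids are synthetic: within-cell running index per molecule
    out[[j]] <- data.table::data.table(
      cell = cells[j],
      feature = feats[fidx[keep]],
      umi = sprintf("UMI%06d", which(keep)),
      reads = reads[keep])
    amp[[j]] <- w
  }
  tab <- molecule_table(data.table::rbindlist(out))
  data.table::setattr(tab, "amplification", amp)
  tab
}

#' Merge random barcode pairs into doublets
#'
#' floor(rate * n_cells) barcode pairs are merged: molecules of the second
#' barcode are relabeled to the first; UMI collisions on the same feature are
#' resolved by keeping the larger read count (so molecule totals are conserved
#' up to collisions).
#'
#' @param table a [molecule_table()].
#' @param rate doublet rate in [0, 0.5).
#' @param seed integer seed.
#' @return the merged `molecule_table`; attributes `"doublet_flags"` (named
#'   logical over surviving barcodes) and `"doublet_pairs"` record the truth.
#' @export
inject_doublets <- function(table, rate, seed = 1L) {
  if (rate < 0 || rate >= 0.5)
    stop("doublet rate must be in [0, 0.5)", call. = FALSE)
  cells <- sort(unique(table$cell))
  k <- floor(rate * length(cells))
  flags <- stats::setNames(rep(FALSE, length(cells)), cells)
  if (k == 0L) {
    out <- molecule_table(data.table::copy(table))
    data.table::setattr(out, "doublet_flags", flags)
    data.table::setattr(out, "doublet_pairs",
                        data.table::data.table(kept = character(),
                                               merged = character()))
    return(out)
  }
  set.seed(as.integer(seed))
  pick <- sample(cells, 2L * k)
  kept <- pick[seq_len(k)]
  merged <- pick[k + seq_len(k)]
  dt <- data.table::copy(data.table::as.data.table(table))
  map <- stats::setNames(kept, merged)
  hit <- dt$cell %in% merged
  dt[hit, "cell" := map[dt$cell[hit]]]
  # collision rule: same (cell, feature, umi) keeps the max read count
  dt <- dt[order(-dt$reads)]
  dt <- unique(dt, by = c("cell", "feature", "umi"))
  out <- molecule_table(dt[order(dt$cell, dt$feature, dt$umi)])
  flags <- flags[setdiff(cells, merged)]
  flags[kept] <- TRUE
  data.table::setattr(out, "doublet_flags", flags)
  data.table::setattr(out, "doublet_pairs",
                      data.table::data.table(kept = kept, merged = merged))
  out
}

#' Reassign molecules to random other barcodes (crosstalk)
#'
#' Each molecule is independently moved to a uniformly chosen other barcode
#' with probability `rate`. Molecule count is conserved exactly: a moved
#' molecule whose (cell, feature, umi) key would collide is given a fresh UMI
#' id suffix.
#'
#' @param table a [molecule_table()].
#' @param rate reassignment probability in [0, 0.2].
#' @param seed integer seed.
#' @return the perturbed `molecule_table`; attribute `"crosstalk_events"`
#'   counts reassigned molecules and `"crosstalk_origin"` records each moved
#'   molecule's source barcode.
#' @export
inject_crosstalk <- function(table, rate, seed = 1L) {
  if (rate < 0 || rate > 0.2)
    stop("crosstalk rate must be in [0, 0.2]", call. = FALSE)
  dt <- data.table::copy(data.table::as.data.table(table))
  cells <- sort(unique(dt$cell))
  if (rate == 0 || length(cells) < 2L) {
    out <- molecule_table(dt)
    data.table::setattr(out, "crosstalk_events", 0L)
    return(out)
  }
  set.seed(as.integer(seed))
  n <- nrow(dt)
  move <- stats::runif(n) < rate
  idx <- which(move)
  if (length(idx)) {
    origin <- dt$cell[idx]
    # uniform over the other barcodes: draw from all, bump collisions with self
    pos <- match(origin, cells)
    draw <- sample.int(length(cells) - 1L, length(idx), replace = TRUE)
    draw <- draw + (draw >= pos)
    dt[idx, "cell" := cells[draw]]
    dup <- which(duplicated(dt, by = c("cell", "feature", "umi")))
    if (length(dup))
      dt[dup, "umi" := paste0(dt$umi[dup], ".x", seq_along(dup))]
    out <- molecule_table(dt)
    data.table::setattr(out, "crosstalk_origin",
                        data.table::data.table(row = idx, origin = origin,
                                               target = cells[draw]))
  } else {
    out <- molecule_table(dt)
  }
  data.table::setattr(out, "crosstalk_events", length(idx))
  out
}

#' Tabulate a molecule table into UMI and read count matrices
#'
#' @param table a [molecule_table()].
#' @param features,cells optional vectors fixing row/column universe and
#'   order (defaults: sorted ids present in the table).
#' @return list with integer matrices `umi` (distinct molecules per
#'   feature/cell) and `reads` (read sums).
#' @export
count_matrices <- function(table, features = NULL, cells = NULL) {
  dt <- data.table::as.data.table(table)
  if (is.null(features)) features <- sort(unique(dt$feature))
  if (is.null(cells)) cells <- sort(unique(dt$cell))
  fi <- factor(dt$feature, levels = features)
  ci <- factor(dt$cell, levels = cells)
  umi <- unclass(as.matrix(table(fi, ci)))
  dimnames(umi) <- NULL
  dim(umi) <- c(length(features), length(cells))
  reads <- matrix(0L, length(features), length(cells),
                  dimnames = list(features, cells))
  agg <- dt[, list(r = sum(reads)), by = c("feature", "cell")]
  reads[cbind(match(agg$feature, features), match(agg$cell, cells))] <- agg$r
  dimnames(umi) <- list(features, cells)
  storage.mode(umi) <- "integer"
  storage.mode(reads) <- "integer"
  list(umi = umi, reads = reads)
}

#' Run the full generative model
#'
#' Composes expression simulation, binomial capture, spike-in loading, PCR
#' amplification + fixed-depth sequencing, doublet merging and crosstalk
#' injection, and tabulates the result. Stage seeds are children of
#' `config$seed` ([child_seeds()]), so the bundle is byte-identical across
#' runs with the same configuration.
#'
#' @param config a [sim_config()].
#' @param design optional [spikein_design()]; spike-in rows are appended to
#'   the matrices under their `spikein_id`s.
#' @param spikein_loading loading model passed to [spike_in_counts()].
#' @return list of class `sim_experiment`: `table` (molecule_table), `umi`
#'   and `reads` (count matrices over all simulated barcodes), `truth` (list:
#'   true_molecules, captured_molecules, doublet_flags, crosstalk_events,
#'   per_molecule_amplification), and `config`.
#' @export
simulate_experiment <- function(config, design = NULL,
                                spikein_loading = "poisson") {
  stopifnot(inherits(config, "sim_config"))
  seeds <- child_seeds(config$seed, 8L)
  true <- simulate_expression(config)
  captured <- capture_molecules(true, config$capture_efficiency, seeds[2L])
  if (!is.null(design)) {
    sp <- spike_in_counts(design, config$capture_efficiency, config$n_cells,
                          seeds[3L], loading = spikein_loading)
    loaded <- attr(sp, "loaded")
    attr(sp, "loaded") <- NULL
    true <- rbind(true, structure(loaded, dimnames = dimnames(sp)))
    captured <- rbind(captured, sp)
    storage.mode(true) <- "integer"
  }
  tab <- amplify_and_sequence(captured, config, seeds[4L])
  amp <- attr(tab, "amplification")
  tab <- inject_doublets(tab, config$doublet_rate, seeds[5L])
  dfl <- attr(tab, "doublet_flags")
  tab <- inject_crosstalk(tab, config$crosstalk_rate, seeds[6L])
  mats <- count_matrices(tab, features = rownames(captured),
                         cells = names(dfl))
  structure(list(
    table = tab,
    umi = mats$umi,
    reads = mats$reads,
    truth = list(true_molecules = true,
                 captured_molecules = captured,
                 doublet_flags = dfl,
                 crosstalk_events = attr(tab, "crosstalk_events"),
                 per_molecule_amplification = amp),
    config = config
  ), class = "sim_experiment")
}
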
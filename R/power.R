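#' Median-of-ratios size factors
#'
#' Per-cell scaling constants normalizing sequencing depth: each cell's
#' median ratio of counts to the per-gene geometric mean, computed over genes
#' with a nonzero geometric mean (i.e. expressed in every cell), rescaled to
#' mean 1. Falls back to library-size factors (with a warning) when no gene
#' is expressed in all cells.
#'
#' @param counts features x cells count matrix.
#' @return positive numeric vector of length ncol(counts), mean 1; attribute
#'   `"method"` records which rule applied.
#' @export
size_factors <- function(counts) {
  m <- as.matrix(counts)
  loggm <- rowMeans(log(m))
  use <- is.finite(loggm)
  if (!any(use)) {
    warning("no gene expressed in all cells; using library-size factors",
            call. = FALSE)
    sf <- colSums(m)
    sf <- sf / mean(sf)
    attr(sf, "method") <- "library_size"
    return(sf)
  }
  ratios <- m[use, , drop = FALSE] / exp(loggm[use])
  sf <- apply(ratios, 2L, stats::median)
  sf <- sf / mean(sf)
  attr(sf, "method") <- "median_of_ratios"
  sf
}

#' Method-of-moments negative-binomial parameter estimation
#'
#' Genes detected (count >= 1) in at least `min_cells_detected` cells are
#' retained; on size-factor-normalized counts, per-gene mean = sample mean
#' and dispersion phi = max(0, (var - mean) / mean^2) (var = mu + phi mu^2;
#' a sub-Poisson moment estimate clamps to phi = 0).
#'
#' @param counts features x cells count matrix.
#' @param min_cells_detected detection filter (default 10).
#' @param sf optional precomputed size factors.
#' @return data.table of class `nb_params`: gene, mean, dispersion.
#' @export
estimate_nb_params <- function(counts, min_cells_detected = 10L, sf = NULL) {
  m <- as.matrix(counts)
  keep <- rowSums(m >= 1L) >= min_cells_detected
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L) stop("no gene passes the detection filter", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(m, 2L, sf, "/")
  mu <- rowMeans(norm)
  v <- apply(norm, 1L, stats::var)
  phi <- pmax(0, (v - mu) / mu^2)
  out <- data.table::data.table(gene = rownames(m), mean = mu,
                                dispersion = phi)
  data.table::setattr(out, "class",
                      c("nb_params", class(data.table::data.table())))
  out
}

#' Plant log2 fold-changes for a two-group comparison
#'
#' floor(de_fraction * n_genes) genes are selected uniformly as truly
#' differentially expressed; their log2 fold-changes are drawn N(0, lfc_sd^2)
#' and all other genes get exactly 0.
#'
#' @param params an [estimate_nb_params()] table (or anything with a `gene`
#'   column).
#' @param de_fraction fraction of DE genes (default 0.10).
#' @param lfc_sd standard deviation of planted log2 fold-changes
#'   (default 1.5).
#' @param seed integer seed.
#' @return data.table: gene, lfc, is_de.
#' @export
plant_fold_changes <- function(params, de_fraction = 0.10, lfc_sd = 1.5,
                               seed = 1L) {
  stopifnot(de_fraction >= 0, de_fraction <= 1, lfc_sd >= 0)
  genes <- params$gene
  n <- length(genes)
  k <- floor(de_fraction * n)
  set.seed(as.integer(seed))
  de <- rep(FALSE, n)
  de[sample.int(n, k)] <- TRUE
  lfc <- numeric(n)
  lfc[de] <- stats::rnorm(k, 0, lfc_sd)
  data.table::data.table(gene = genes, lfc = lfc, is_de = de)
}

#' Simulate a two-group NB comparison with planted fold-changes
#'
#' Group means are mu * 2^(+lfc/2) and mu * 2^(-lfc/2) (symmetric split,
#' preserving overall mean expression); counts are NB(group mean, phi) per
#' gene and cell, with exactly `n_per_group` cells per group.
#'
#' @param params an [estimate_nb_params()] table.
#' @param lfcs log2 fold-change vector or [plant_fold_changes()] table.
#' @param n_per_group cells per group.
#' @param seed integer seed.
#' @param symmetric if FALSE, the full fold-change is applied to group 2
#'   only.
#' @return list: `counts` (genes x 2n matrix), `groups` (factor of "g1"/"g2").
#' @export
simulate_two_groups <- function(params, lfcs, n_per_group, seed = 1L,
                                symmetric = TRUE) {
  if (is.data.frame(lfcs)) lfcs <- lfcs$lfc
  stopifnot(length(lfcs) == nrow(params), n_per_group >= 1)
  set.seed(as.integer(seed))
  mu <- params$mean
  phi <- params$dispersion
  mu1 <- if (symmetric) mu * 2^(lfcs / 2) else mu
  mu2 <- if (symmetric) mu * 2^(-lfcs / 2) else mu * 2^(-lfcs)
  g <- nrow(params)
  draw <- function(muv) {
    m <- matrix(0L, g, n_per_group)
    pois <- phi == 0
    if (any(pois))
      m[pois, ] <- stats::rpois(sum(pois) * n_per_group, muv[pois])
    if (any(!pois))
      m[!pois, ] <- stats::rnbinom(sum(!pois) * n_per_group, mu = muv[!pois],
                                   size = 1 / phi[!pois])
    m
  }
  counts <- cbind(draw(mu1), draw(mu2))
  rownames(counts) <- params$gene
  colnames(counts) <- sprintf("C%04d", seq_len(2L * n_per_group))
  storage.mode(counts) <- "integer"
  list(counts = counts,
       groups = factor(rep(c("g1", "g2"), each = n_per_group)))
}

#' Per-gene Wilcoxon rank-sum differential-expression test
#'
#' Two-sided Wilcoxon rank-sum test per gene on size-factor-normalized
#' counts, using the normal approximation with mid-ranks, tie correction and
#' continuity correction. Genes with all-identical values get p = 1. This is
#' a deliberate, named stand-in for heavier DE machinery inside power
#' simulations (attribute `"test"` = "wilcoxon_rank_sum").
#'
#' @param counts genes x cells count matrix.
#' @param groups two-level factor over columns.
#' @param normalize compute [size_factors()] and divide (default TRUE).
#' @return numeric vector of two-sided p-values, one per gene.
#' @export
de_test <- function(counts, groups, normalize = TRUE) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2L, length(groups) == ncol(counts))
  m <- as.matrix(counts)
  if (normalize) {
    sf <- suppressWarnings(size_factors(m))
    m <- sweep(m, 2L, sf, "/")
  }
  g1 <- groups == levels(groups)[1L]
  n1 <- sum(g1)
  n2 <- sum(!g1)
  N <- n1 + n2
  p <- apply(m, 1L, function(x) {
    if (length(unique(x)) == 1L) return(1)
    r <- rank(x)
    U <- sum(r[g1]) - n1 * (n1 + 1) / 2
    ties <- rle(sort(x))$lengths
    tiecor <- sum(ties^3 - ties) / (N * (N - 1))
    s2 <- n1 * n2 / 12 * ((N + 1) - tiecor)
    if (s2 <= 0) return(1)
    z <- U - n1 * n2 / 2
    z <- (z - sign(z) * 0.5) / sqrt(s2)  # continuity correction
    2 * stats::pnorm(-abs(z))
  })
  out <- stats::setNames(unname(p), rownames(m))
  attr(out, "test") <- "wilcoxon_rank_sum"
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic BH: order p ascending, q_(i) = min over j >= i of p_(j) * m / j,
#' capped at 1, returned in input order.
#'
#' @param pvalues numeric vector in [0, 1] (NAs propagate).
#' @return adjusted q-values in input order.
#' @export
bh_adjust <- function(pvalues) {
  p <- as.numeric(pvalues)
  ok <- !is.na(p)
  m <- sum(ok)
  q <- rep(NA_real_, length(p))
  if (m > 0L) {
    o <- order(p[ok])
    ps <- p[ok][o]
    qs <- pmin(1, cummin(rev(ps * m / seq_len(m))))
    q[ok] <- replace(q[ok], o, rev(qs))
  }
  q
}

#' True-positive and false-discovery rates of DE calls
#'
#' Calls a gene DE iff q < alpha. TPR = true positives / number of truly DE
#' genes; FDR = false positives / max(number of calls, 1).
#'
#' @param qvalues adjusted p-values.
#' @param truth logical vector of true DE status.
#' @param alpha significance cutoff (default 0.05).
#' @return list: tpr, fdr, n_called, n_de_true.
#' @export
tpr_fdr <- function(qvalues, truth, alpha = 0.05) {
  stopifnot(length(qvalues) == length(truth))
  call <- !is.na(qvalues) & qvalues < alpha
  tp <- sum(call & truth)
  fp <- sum(call & !truth)
  list(tpr = if (sum(truth) > 0) tp / sum(truth) else NA_real_,
       fdr = fp / max(sum(call), 1L),
       n_called = sum(call), n_de_true = sum(truth))
}

#' Two-group NB power simulation across sample sizes
#'
#' Full factorial over sample sizes and iterations: per iteration, plant
#' fold-changes (fresh per iteration by default), simulate the two groups,
#' test per gene, BH-adjust, and record TPR/FDR at `alpha`. Child seeds are
#' derived from `seed`, so each (size, iteration) cell is reproducible.
#'
#' @param params an [estimate_nb_params()] table.
#' @param sample_sizes cells per group (default c(24, 48, 96, 192, 384)).
#' @param iterations simulation iterations per size (default 25).
#' @param seed integer master seed.
#' @param de_fraction,lfc_sd passed to [plant_fold_changes()].
#' @param alpha DE call cutoff on q-values (default 0.05).
#' @param fresh_lfc draw new fold-changes each iteration (default TRUE).
#' @return list of class `power_result`: `results` (n_per_group, iteration,
#'   tpr, fdr, n_called, n_de_true), `summary` (per-size mean and quartiles
#'   of TPR/FDR), `n80` (smallest size with mean TPR >= 0.8, NA if none),
#'   plus the substitution labels `test` and `normalization`.
#' @export
power_analysis <- function(params, sample_sizes = c(24L, 48L, 96L, 192L, 384L),
                           iterations = 25L, seed = 1L, de_fraction = 0.10,
                           lfc_sd = 1.5, alpha = 0.05, fresh_lfc = TRUE) {
  sample_sizes <- sort(as.integer(sample_sizes))
  seeds <- child_seeds(seed, length(sample_sizes) * iterations * 2L)
  rows <- list()
  k <- 0L
  fixed_lfc <- if (!fresh_lfc)
    plant_fold_changes(params, de_fraction, lfc_sd, seed)
  for (n in sample_sizes) {
    for (it in seq_len(iterations)) {
      k <- k + 1L
      lfc <- if (fresh_lfc)
        plant_fold_changes(params, de_fraction, lfc_sd, seeds[2L * k - 1L])
      else fixed_lfc
      sim <- simulate_two_groups(params, lfc, n, seeds[2L * k])
      pv <- de_test(sim$counts, sim$groups)
      res <- tpr_fdr(bh_adjust(pv), lfc$is_de, alpha)
      rows[[k]] <- data.table::data.table(
        n_per_group = n, iteration = it, tpr = res$tpr, fdr = res$fdr,
        n_called = res$n_called, n_de_true = res$n_de_true)
    }
  }
  results <- data.table::rbindlist(rows)
  summary <- results[, list(
    mean_tpr = mean(tpr), q1_tpr = stats::quantile(tpr, 0.25),
    median_tpr = stats::median(tpr), q3_tpr = stats::quantile(tpr, 0.75),
    mean_fdr = mean(fdr), median_fdr = stats::median(fdr)
  ), by = "n_per_group"]
  hit <- summary$n_per_group[summary$mean_tpr >= 0.8]
  structure(list(results = results, summary = summary,
                 n80 = if (length(hit)) min(hit) else NA_integer_,
                 alpha = alpha, test = "wilcoxon_rank_sum",
                 normalization = "median_of_ratios"),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat("power_result (test =", x$test, ", normalization =", x$normalization,
      ", alpha =", x$alpha, ")\n")
  print(x$summary)
  cat("smallest n/group with mean TPR >= 0.8:", x$n80, "\n")
  invisible(x)
}
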
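test_that("sim_config validates its invariants", {
  expect_error(sim_config(10, gene_means = c(1, 2), gene_dispersions = 0.1),
               "equal length")
  expect_error(sim_config(10, gene_means = 1, capture_efficiency = 0),
               "capture_efficiency")
  expect_error(sim_config(10, gene_means = 1, doublet_rate = 0.5),
               "doublet_rate")
  expect_error(sim_config(10, gene_means = 1, crosstalk_rate = 0.3),
               "crosstalk_rate")
  expect_error(sim_config(10, gene_means = c(1, -1)), "positive")
})

test_that("simulate_expression matches NB/Poisson moments", {
  # phi = 0: Poisson(5); 50,000 draws. SE(mean) = sqrt(5/n); for the sample
  # variance SE^2 ~ (mu4 - var^2)/n with Poisson mu4 = lambda + 3 lambda^2.
  n <- 50000L
  cfg <- sim_config(n_cells = n, gene_means = 5, gene_dispersions = 0,
                    seed = 42)
  x <- as.numeric(simulate_expression(cfg))
  expect_lt(abs(mean(x) - 5), 3 * sqrt(5 / n))
  se_var <- sqrt((5 + 2 * 25) / n)
  expect_lt(abs(var(x) - 5), 3 * se_var)

  # phi = 0.5: var = mu + phi mu^2 = 17.5; SE of S^2 from sample 4th moment
  cfg2 <- sim_config(n_cells = n, gene_means = 5, gene_dispersions = 0.5,
                     seed = 43)
  y <- as.numeric(simulate_expression(cfg2))
  se_var2 <- sqrt((mean((y - mean(y))^4) - var(y)^2) / n)
  expect_lt(abs(var(y) - 17.5), 3 * se_var2)
})

test_that("simulate_expression handles the empty case and is reproducible", {
  cfg <- sim_config(n_cells = 0, gene_means = rep(2, 7))
  m <- simulate_expression(cfg)
  expect_identical(dim(m), c(7L, 0L))
  cfg2 <- sim_config(n_cells = 5, gene_means = rep(2, 7), seed = 3)
  expect_identical(simulate_expression(cfg2), simulate_expression(cfg2))
})

test_that("capture_molecules is binomial thinning", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("a", "b"), c("x", "y", "z")))
  expect_identical(capture_molecules(m, 1, 1), {
    mm <- m; storage.mode(mm) <- "integer"; mm
  })
  expect_true(all(capture_molecules(m, 0, 1) == 0L))
  expect_error(capture_molecules(m, 1.2), "\\[0, 1\\]")

  # detection closed form: m = 5 copies, p = 0.1, 1e5 trials
  tr <- matrix(5L, 1, 100000)
  dimnames(tr) <- list("g", paste0("c", 1:100000))
  cap <- capture_molecules(tr, 0.1, seed = 7)
  frac <- mean(cap >= 1L)
  p0 <- 1 - 0.9^5
  expect_lt(abs(frac - p0), 3 * sqrt(p0 * (1 - p0) / 100000))
})

test_that("detection probability follows 1 - (1-p)^m across m and p", {
  for (p in c(0.05, 0.1, 0.5)) {
    for (m in c(1L, 2L, 4L, 8L, 16L)) {
      n <- 20000L
      tr <- matrix(m, 1, n)
      dimnames(tr) <- list("g", paste0("c", seq_len(n)))
      det <- mean(capture_molecules(tr, p, seed = m * 100 + p * 1000) >= 1L)
      p0 <- 1 - (1 - p)^m
      tol <- 3.5 * sqrt(p0 * (1 - p0) / n) + 1e-9
      expect_lt(abs(det - p0), tol)
    }
  }
})

test_that("spike_in_counts loads and thins correctly", {
  d0 <- spikein_design(c("ERCC-1", "ERCC-2"), c(0, 0))
  expect_true(all(spike_in_counts(d0, 0.5, 50) == 0L))
  expect_error(spikein_design("ERCC-1", -1), "non-negative")

  d <- spikein_design("ERCC-1", 1000)
  cap <- spike_in_counts(d, 0.5, 10000, seed = 5)
  # thinned Poisson: mean 500, var 500
  expect_lt(abs(mean(cap) - 500), 3 * sqrt(500 / 10000))

  # p = 1, large design value: captured ~ Poisson(design) (two-sample KS,
  # ties make the test conservative)
  cap1 <- as.numeric(spike_in_counts(d, 1, 5000, seed = 6))
  set.seed(61)
  ref <- rpois(5000, 1000)
  ks <- suppressWarnings(ks.test(cap1, ref))
  expect_gt(ks$p.value, 0.01)
})

test_that("fractional loading realizes the fixed-copy detection law", {
  d <- spikein_design("ERCC-1", 1.0)
  cap <- spike_in_counts(d, 0.5, 40000, seed = 8, loading = "fractional")
  # exactly 1 copy loaded -> detection probability exactly p
  det <- mean(cap >= 1L)
  expect_lt(abs(det - 0.5), 3 * sqrt(0.25 / 40000))
  ld <- attr(cap, "loaded")
  expect_true(all(ld == 1L))
})

test_that("amplify_and_sequence conserves reads and handles edge cases", {
  cfg <- sim_config(n_cells = 4, gene_means = rep(3, 30),
                    capture_efficiency = 0.9, reads_per_cell = 500, seed = 9)
  cap <- capture_molecules(simulate_expression(cfg), 0.9, 2)
  tab <- amplify_and_sequence(cap, cfg)
  rd <- data.table::as.data.table(tab)[, sum(reads), by = cell]
  expect_true(all(rd$V1 == 500L))

  # cycles = 0 -> all weights exactly 1
  cfg0 <- sim_config(n_cells = 2, gene_means = rep(3, 10), pcr_cycles = 0,
                     reads_per_cell = 100, seed = 10)
  cap0 <- capture_molecules(simulate_expression(cfg0), 1, 3)
  tab0 <- amplify_and_sequence(cap0, cfg0)
  expect_true(all(unlist(attr(tab0, "amplification")) == 1))

  # a cell with zero captured molecules warns but does not fail
  capz <- cap0
  capz[, 1] <- 0L
  expect_warning(tz <- amplify_and_sequence(capz, cfg0), "zero captured")
  expect_false(colnames(capz)[1] %in% tz$cell)
})

test_that("near-constant efficiency gives a symmetric multinomial", {
  # alpha, beta huge at fixed mean: weights effectively equal
  cfg <- sim_config(n_cells = 1, gene_means = rep(5, 40),
                    pcr_efficiency_alpha = 1e7, pcr_efficiency_beta = 1e7,
                    pcr_cycles = 10, reads_per_cell = 20000, seed = 12)
  cap <- matrix(1L, 40, 1, dimnames = list(gene_names <- sprintf("G%02d", 1:40),
                                           "BC1"))
  tab <- amplify_and_sequence(cap, cfg, seed = 13)
  obs <- data.table::as.data.table(tab)$reads
  expect_equal(sum(obs), 20000L)
  chi <- chisq.test(obs, p = rep(1 / length(obs), length(obs)))
  expect_gt(chi$p.value, 0.01)
})

test_that("beta-efficiency variance orders reads-per-UMI CV", {
  # smaller alpha+beta at fixed mean 0.8 -> more amplification noise -> CV up
  shapes <- list(c(80, 20), c(8, 2), c(2, 0.5))
  cvs <- sapply(seq_along(shapes), function(i) {
    cfg <- sim_config(n_cells = 6, gene_means = rep(10, 100),
                      pcr_efficiency_alpha = shapes[[i]][1],
                      pcr_efficiency_beta = shapes[[i]][2],
                      pcr_cycles = 12, reads_per_cell = 30000,
                      capture_efficiency = 0.9, seed = 20 + i)
    cap <- capture_molecules(simulate_expression(cfg), 0.9, 30 + i)
    ev <- amplification_evenness(amplify_and_sequence(cap, cfg, seed = 40 + i))
    mean(ev$cv_reads_per_umi)
  })
  expect_true(all(diff(cvs) > 0))
})

test_that("inject_doublets merges the configured number of barcodes", {
  tab <- toy_table()
  t0 <- inject_doublets(tab, 0, 1)
  expect_equal(data.table::as.data.table(t0), data.table::as.data.table(tab),
               ignore_attr = TRUE)
  expect_error(inject_doublets(tab, 0.5, 1), "\\[0, 0.5\\)")

  # disjoint features: merged UMI total = sum of parts (any pair merging
  # three fully disjoint cells leaves all 3 molecules)
  disj <- molecule_table(data.frame(cell = c("A", "B", "C"),
                                    feature = c("G1", "G2", "G3"),
                                    umi = c("u1", "u2", "u3"),
                                    reads = c(1L, 2L, 3L)))
  td <- inject_doublets(disj, 0.34, seed = 2)  # floor(0.34 * 3) = 1 merge
  expect_equal(length(unique(td$cell)), 2L)
  expect_equal(nrow(td), 3L)
  expect_equal(sum(td$reads), 6L)

  # identical keys: collision resolved by keeping the max read count
  coll <- molecule_table(data.frame(cell = c("A", "B", "C"), feature = "G1",
                                    umi = "u1", reads = c(1L, 2L, 3L)))
  tc <- inject_doublets(coll, 0.34, seed = 2)
  merged_cell <- attr(tc, "doublet_pairs")$kept
  merged_src <- attr(tc, "doublet_pairs")$merged
  pair_max <- max(coll$reads[coll$cell %in% c(merged_cell, merged_src)])
  expect_equal(nrow(tc), 2L)
  expect_equal(tc[cell == merged_cell]$reads, pair_max)

  # rate = 0.1, 100 cells -> exactly 10 merges, 90 barcodes remain
  big <- molecule_table(data.frame(
    cell = rep(sprintf("BC%03d", 1:100), each = 3),
    feature = rep(c("G1", "G2", "G3"), 100),
    umi = paste0("u", rep(1:3, 100), ".", rep(1:100, each = 3)),
    reads = 1L))
  bd <- inject_doublets(big, 0.1, seed = 4)
  expect_equal(length(unique(bd$cell)), 90L)
  expect_equal(sum(attr(bd, "doublet_flags")), 10L)
})

test_that("inject_crosstalk conserves molecules and matches its rate", {
  tab <- toy_table()
  t0 <- inject_crosstalk(tab, 0, 1)
  expect_equal(data.table::as.data.table(t0), data.table::as.data.table(tab),
               ignore_attr = TRUE)
  expect_identical(attr(t0, "crosstalk_events"), 0L)

  n <- 100000L
  big <- molecule_table(data.frame(
    cell = rep(sprintf("BC%02d", 1:50), length.out = n),
    feature = "G1",
    umi = paste0("u", seq_len(n)),
    reads = 1L))
  bc <- inject_crosstalk(big, 0.01, seed = 3)
  expect_equal(nrow(bc), n)  # conservation
  ev <- attr(bc, "crosstalk_events")
  expect_lt(abs(ev - 1000), 3 * sqrt(n * 0.01 * 0.99))
  # reassignment goes to a *different* barcode
  org <- attr(bc, "crosstalk_origin")
  expect_true(all(org$origin != org$target))
})

test_that("simulate_experiment is consistent and deterministic", {
  cfg <- sim_config(n_cells = 8, gene_means = rep(4, 60),
                    gene_dispersions = rep(0.2, 60),
                    capture_efficiency = 0.3, reads_per_cell = 2000,
                    doublet_rate = 0.2, crosstalk_rate = 0.05, seed = 77)
  des <- spikein_ladder(n_levels = 6, species_per_level = 2,
                        min_molecules = 1, max_molecules = 100)
  ex <- simulate_experiment(cfg, des)
  expect_equal(sum(ex$umi), nrow(ex$table))
  expect_equal(sum(ex$reads), sum(ex$table$reads))
  expect_true(all(colnames(ex$umi) == names(ex$truth$doublet_flags)))
  expect_equal(sum(ex$truth$doublet_flags), 1L)  # floor(0.2 * 8)
  # captured <= true elementwise (pre-crosstalk truth record)
  expect_true(all(ex$truth$captured_molecules <= ex$truth$true_molecules))
  ex2 <- simulate_experiment(cfg, des)
  expect_identical(ex$umi, ex2$umi)
  expect_equal(data.table::as.data.table(ex$table),
               data.table::as.data.table(ex2$table))
})
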
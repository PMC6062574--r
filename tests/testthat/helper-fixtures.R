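# Small in-code fixtures shared across test files.

# a tiny deterministic molecule table: 2 cells, known reads
toy_table <- function() {
  molecule_table(data.frame(
    cell = c("A", "A", "A", "B", "B"),
    feature = c("G1", "G1", "G2", "G1", "G3"),
    umi = c("u1", "u2", "u3", "u1", "u2"),
    reads = c(3L, 1L, 2L, 4L, 6L)))
}

# small simulated experiment used by several modules
small_experiment <- function(seed = 11, n_cells = 12, n_genes = 150,
                             capture = 0.2, depth = 4000, doublet_rate = 0,
                             crosstalk_rate = 0) {
  cfg <- sim_config(n_cells = n_cells,
                    gene_means = rep(6, n_genes),
                    gene_dispersions = rep(0.4, n_genes),
                    capture_efficiency = capture,
                    reads_per_cell = depth,
                    doublet_rate = doublet_rate,
                    crosstalk_rate = crosstalk_rate,
                    seed = seed)
  simulate_experiment(cfg, spikein_ladder())
}

# hypergeometric survival probability, closed form (independent of package)
hyper_survival <- function(r, D) {
  T <- sum(r)
  1 - choose(T - r, D) / choose(T, D)
}

# brute-force enumeration of all C(T, D) draws (oracle for downsampling)
enum_survival <- function(r, D) {
  T <- sum(r)
  molidx <- rep.int(seq_along(r), r)
  draws <- utils::combn(T, D)
  rowMeans(apply(draws, 2L, function(s)
    tabulate(molidx[s], nbins = length(r)) > 0))
}
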
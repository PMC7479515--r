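# Shared fixtures: all synthetic, built in code at test time.

# A small random TPM matrix (columns sum to 1e6).
random_tpm <- function(n_genes = 200, n_cells = 20, seed = 1) {
  set.seed(seed)
  x <- matrix(rgamma(n_genes * n_cells, shape = 0.5, rate = 0.01),
              n_genes, n_cells,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("c%03d", seq_len(n_cells))))
  x <- sweep(x, 2, colSums(x), "/") * 1e6
  expression_matrix(x, "tpm")
}

# Small genome + one-sample cohort with strong CNAs, reused by several
# module tests.
small_cohort <- function(seed = 7) {
  g <- make_genome(n_genes = 2000, n_chromosomes = 8, seed = 11)
  design <- list(sample_design(
    "s1", "PF",
    malignant = c(NSC = 40, ependymal = 40),
    normal = c(microglia = 10, oligodendrocyte = 10),
    cna = data.frame(arm = c("chr1q", "chr2p"), multiplier = c(1.5, 0.5)),
    cycling_frac = 0.15
  ))
  sim <- simulate_cells(g, design, fold_up = 4, seed = seed)
  list(genome = g, sim = sim)
}

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

# re-tag a centered matrix as log scale (for idempotence checks)
restamp_log <- function(er) expression_matrix(unclass(er), "log")
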
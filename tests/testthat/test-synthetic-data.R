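test_that("genome layout is a deterministic partition with disjoint modules", {
  g1 <- make_genome(3000, 10, seed = 1)
  g2 <- make_genome(3000, 10, seed = 1)
  expect_identical(g1, g2)
  # gene -> chromosome assignment partitions the universe
  expect_equal(nrow(g1$genes), 3000)
  expect_false(anyDuplicated(g1$genes$gene_id) > 0)
  expect_true(all(table(g1$genes$chrom) >= 1))
  # positions strictly increase within each chromosome
  by_chr <- split(g1$genes$start, g1$genes$chrom)
  expect_true(all(vapply(by_chr, function(s) all(diff(s) > 0), logical(1))))
  # modules are pairwise disjoint subsets of the universe
  mods <- g1$modules
  expect_true(all(unlist(mods) %in% g1$genes$gene_id))
  expect_false(anyDuplicated(unlist(mods)) > 0)
  # oversized modules are rejected
  expect_error(make_genome(100, 2, module_sizes = c(a = 101), seed = 1),
               "exceed")
})

test_that("simulated cells are TPM-normalized with planted truth attached", {
  fx <- small_cohort(seed = 3)
  sim <- fx$sim
  expect_equal(colSums(unclass(sim$expr)), rep(1e6, ncol(sim$expr)),
               tolerance = 1e-6, ignore_attr = TRUE)
  # normal cells never carry CNA events; cycling implies malignant
  normals <- sim$cells[sim$cells$class == "normal", ]
  expect_true(all(vapply(normals$cna, nrow, integer(1)) == 0))
  expect_true(all(is.na(normals$program)))
  expect_false(any(normals$cycling))
  # determinism for a fixed seed
  sim2 <- simulate_cells(fx$genome, list(sample_design(
    "s1", "PF", malignant = c(NSC = 40, ependymal = 40),
    normal = c(microglia = 10, oligodendrocyte = 10),
    cna = data.frame(arm = c("chr1q", "chr2p"), multiplier = c(1.5, 0.5)),
    cycling_frac = 0.15)), fold_up = 4, seed = 3)
  expect_equal(unclass(sim$expr), unclass(sim2$expr))
  expect_error(simulate_cells(fx$genome, list()), "empty")
  expect_error(sample_design("s", cna = data.frame(arm = "chr1q",
                                                   multiplier = -1)),
               "positive")
})

test_that("a planted arm gain raises malignant window means over that arm", {
  fx <- small_cohort(seed = 5)
  sim <- fx$sim
  er <- center_expression(log_transform(sim$expr))
  # brute-force window means over chr1q genes only
  ann <- fx$genome$genes
  arm_genes <- ann$gene_id[ann$chrom == "chr1" & ann$arm == "q"]
  vals <- pmin(pmax(unclass(er)[arm_genes, ], -3), 3)
  arm_mean <- colMeans(vals)
  mal <- sim$cells$class == "malignant"
  expect_gt(mean(arm_mean[mal]), mean(arm_mean[!mal]))
  # and the profile machinery sees the same contrast
  prof <- compute_cna_profile(er, ann)
  on_arm <- prof$window_info$chrom == "chr1" &
    prof$window_info$from > sum(ann$chrom == "chr1") * 0.4
  wm <- colMeans(prof$windows[on_arm, , drop = FALSE])
  expect_gt(mean(wm[mal]), mean(wm[!mal]))
})

test_that("null configuration gives equal malignant and normal mean profiles", {
  g <- make_genome(600, 4, seed = 2)
  # fold-up 1 (no module signal), no CNA, Poisson counts
  design <- list(sample_design("s1", "PF",
    malignant = c(NSC = 60), normal = c(microglia = 60),
    cna = NULL, cycling_frac = 0))
  sim <- simulate_cells(g, design, fold_up = 1,
                        noise = list(dispersion = 0, sample_sdlog = 0),
                        seed = 9)
  mal <- sim$cells$class == "malignant"
  pm <- rowMeans(unclass(sim$expr)[, mal])
  pn <- rowMeans(unclass(sim$expr)[, !mal])
  # relative difference of mean profiles stays at sampling noise level
  expect_lt(median(abs(pm - pn) / (pm + pn + 1)), 0.05)
  expect_error(simulate_cells(g, design, fold_up = 0.5), "fold_up")
})

test_that("regulon simulation respects its activation design", {
  cells <- tibble::tibble(cell_id = sprintf("c%03d", 1:500),
                          program = rep(c("NSC", "ependymal"), each = 250))
  des <- tibble::tibble(regulon = c("rA", "rB"),
                        program = c("NSC", "ependymal"),
                        p_on = c(1, 0.8))
  act <- simulate_regulons(cells, des, seed = 3)
  expect_true(all(act %in% 0:1))
  expect_equal(mean(act[cells$program == "NSC", "rA"]), 1)
  expect_equal(mean(act[cells$program == "NSC", "rB"]), 0)
  # empirical proportion within 3 binomial SEs of p_on
  p_hat <- mean(act[cells$program == "ependymal", "rB"])
  expect_lt(abs(p_hat - 0.8), 3 * sqrt(0.8 * 0.2 / 250))
  # all-off design
  des0 <- dplyr::mutate(des, p_on = 0)
  expect_true(all(simulate_regulons(cells, des0, seed = 1) == 0))
  expect_error(simulate_regulons(cells, dplyr::mutate(des, p_on = 1.2)),
               "p_on")
  # reproducible
  expect_identical(simulate_regulons(cells, des, seed = 3), act)
})

test_that("bulk cohort compositions sum to one and carry survival truth", {
  g <- make_genome(800, 5, seed = 4)
  bk <- simulate_bulk_cohort(g, n_samples = 50, beta = log(3), seed = 6)
  comp <- as.matrix(bk$samples[c("NSC", "ependymal", "neuronal")])
  expect_equal(rowSums(comp), rep(1, 50), tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(comp >= 0 & comp <= 1))
  expect_true(all(bk$samples$time > 0))
  expect_true(all(bk$samples$event %in% 0:1))
  expect_equal(colSums(unclass(bk$expr)), rep(1e6, 50),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_warning(
    simulate_bulk_cohort(g, 10, composition_prior = c(NSC = 1, ependymal = 0,
                                                      neuronal = 0),
                         seed = 1),
    "degenerate")
  expect_error(simulate_bulk_cohort(g, 1), "samples")
})
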
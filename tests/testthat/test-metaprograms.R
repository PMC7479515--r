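test_that("overdispersed-gene selection favors planted variable modules", {
  g <- make_genome(1500, 6, seed = 41)
  sim <- simulate_cells(g, list(sample_design(
    "s1", "PF", malignant = c(NSC = 50, ependymal = 50), normal = NULL,
    cna = NULL, cycling_frac = 0)), fold_up = 4, seed = 42)
  e <- log_transform(sim$expr)
  top <- overdispersed_genes(e, n = 200)
  planted <- c(g$modules$NSC, g$modules$ependymal)
  expect_gte(mean(planted %in% top), 0.8)
  # n >= gene count returns everything
  expect_equal(sort(overdispersed_genes(e, n = 1e6)), sort(rownames(e)))
  expect_error(overdispersed_genes(e, n = 0), "at least 1")
  # a constant gene is never preferred over variable ones
  x <- unclass(e)
  x[1, ] <- 1
  expect_false(rownames(x)[1] %in%
                 overdispersed_genes(expression_matrix(x, "log"), n = 100))
})

test_that("NMF is deterministic, monotone, and recovers planted rank-2 structure", {
  set.seed(50)
  # two disjoint modules on disjoint cell groups
  w_true <- cbind(c(rep(4, 20), rep(0, 40)), c(rep(0, 40), rep(4, 20)))
  h_true <- rbind(c(rep(1, 15), rep(0, 15)), c(rep(0, 15), rep(1, 15)))
  v <- w_true %*% h_true + matrix(runif(60 * 30, 0, 0.05), 60)
  dimnames(v) <- list(sprintf("g%02d", 1:60), sprintf("c%02d", 1:30))
  fit <- run_nmf(v, k = 2)
  expect_true(all(diff(fit$loss) <= 1e-9 * max(fit$loss[1], 1)))
  expect_identical(fit$w, run_nmf(v, k = 2)$w) # deterministic
  pr <- nmf_programs(fit, n_top = 20)
  mods <- list(sprintf("g%02d", 1:20), sprintf("g%02d", 41:60))
  j <- vapply(unique(pr$factor), function(f) {
    top <- pr$gene_id[pr$factor == f]
    max(vapply(mods, jaccard, numeric(1), a = top))
  }, numeric(1))
  expect_true(all(j >= 0.8))
  # k = 1 approximates a scaled mean profile
  fit1 <- run_nmf(v, k = 1)
  expect_gt(cor(fit1$w[, 1], rowMeans(v)), 0.99)
  expect_error(run_nmf(v, k = 100), "k exceeds")
  expect_error(run_nmf(v - 10, k = 2), "non-negative")
})

test_that("program clustering retains correlated sets and drops singletons", {
  set.seed(60)
  base <- rnorm(200)
  scores <- tibble::tibble(
    cell_id = paste0("c", 1:200),
    p1 = base + rnorm(200, 0, 0.3),
    p2 = base + rnorm(200, 0, 0.3),
    p3 = base + rnorm(200, 0, 0.3),
    q1 = rnorm(200),
    q2 = rnorm(200)
  )
  cl <- cluster_programs(scores)
  trio <- cl$cluster[match(c("p1", "p2", "p3"), cl$program)]
  expect_equal(length(unique(trio)), 1L)
  expect_true(all(cl$retained[match(c("p1", "p2", "p3"), cl$program)]))
  expect_false(any(cl$retained[match(c("q1", "q2"), cl$program)]))
  # whitelisted singleton survives
  cl_w <- cluster_programs(scores, whitelist = "q1")
  expect_true(cl_w$retained[match("q1", cl_w$program)])
  # duplicated program: one cluster with r = 1
  dup <- scores[c("cell_id", "p1")]
  dup$p1_copy <- dup$p1
  cl_d <- cluster_programs(dup)
  expect_equal(cl_d$cluster[1], cl_d$cluster[2])
  expect_equal(cl_d$mean_corr[1], 1)
  # orthogonal programs: nothing retained
  ortho <- scores[c("cell_id", "q1", "q2")]
  ortho$q3 <- rnorm(200)
  expect_false(any(cluster_programs(ortho)$retained))
  # invariant to input column order
  perm <- scores[c("cell_id", "q2", "p2", "q1", "p1", "p3")]
  cl_p <- cluster_programs(perm)
  expect_equal(cl_p$retained[match(cl$program, cl_p$program)], cl$retained)
  expect_error(cluster_programs(scores[c("cell_id", "p1")]), "at least 2")
})

test_that("metaprogram merging averages weights with a deterministic tie-break", {
  set.seed(70)
  w <- matrix(runif(50 * 3), 50, 3,
              dimnames = list(sprintf("g%02d", 1:50), c("a", "b", "c")))
  mp <- merge_to_metaprogram(w, c("a", "b"), n_top = 10)
  avg <- rowMeans(w[, c("a", "b")])
  oracle <- names(sort(avg, decreasing = TRUE))[1:10]
  expect_equal(sort(mp$genes$gene_id), sort(oracle))
  expect_equal(mp$genes$mean_weight, sort(avg, decreasing = TRUE)[1:10],
               ignore_attr = TRUE)
  # single member: its own top genes
  mp1 <- merge_to_metaprogram(w, "c", n_top = 5)
  expect_equal(mp1$genes$gene_id,
               names(sort(w[, "c"], decreasing = TRUE))[1:5])
  # identical members agree with either one alone
  w2 <- cbind(a = w[, "a"], a2 = w[, "a"])
  expect_equal(merge_to_metaprogram(w2, c("a", "a2"), n_top = 5)$genes$gene_id,
               names(sort(w[, "a"], decreasing = TRUE))[1:5])
  expect_error(merge_to_metaprogram(w, character()), "empty")
})

test_that("the vectorized rank-sum p equals wilcox.test's normal approximation", {
  set.seed(80)
  x <- matrix(c(rnorm(8 * 12), round(rnorm(4 * 12), 1)), 12, byrow = FALSE)
  x <- matrix(rnorm(12 * 20), 12, 20)
  x[3, ] <- round(x[3, ]) # force ties
  in_pop <- rep(c(TRUE, FALSE), c(8, 12))
  p <- scstates:::rowwise_ranksum_p(x, in_pop)
  oracle <- apply(x, 1, function(v) {
    stats::wilcox.test(v[in_pop], v[!in_pop], exact = FALSE)$p.value
  })
  expect_equal(p, oracle, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("signature genes pass the p, fold-change and detection rules", {
  set.seed(90)
  n_cells <- 60
  state <- rep(c("A", "B"), each = 30)
  x <- matrix(abs(rnorm(40 * n_cells, 2, 0.3)), 40, n_cells,
              dimnames = list(sprintf("g%02d", 1:40),
                              sprintf("c%02d", 1:n_cells)))
  x["g01", state == "A"] <- x["g01", state == "A"] + 2 # clean signature gene
  # g02: strong difference but detected in only 49% of A hidden below
  x["g02", ] <- 0
  up <- which(state == "A")[1:14] # 14/30 < 0.5
  x["g02", up] <- 6
  m <- expression_matrix(x, "log")
  assign <- tibble::tibble(cell_id = colnames(x), state = state)
  sig <- signature_genes(m, assign)
  a_genes <- sig$gene_id[sig$state == "A"]
  expect_true("g01" %in% a_genes)
  expect_false("g02" %in% a_genes) # fails the half-of-cells rule
  # identical populations yield no signatures
  x0 <- matrix(rnorm(40 * n_cells, 2, 0.3), 40, n_cells,
               dimnames = dimnames(x))
  expect_equal(nrow(signature_genes(expression_matrix(x0, "log"), assign)), 0)
  # tiny population skipped with a warning
  assign_small <- assign
  assign_small$state[1:2] <- "C"
  assign_small$state[3:n_cells] <- "A"
  expect_warning(signature_genes(m, assign_small), "fewer than")
})

test_that("planted modules are recovered as signature genes of their state", {
  g <- make_genome(1200, 6, seed = 91)
  sim <- simulate_cells(g, list(sample_design(
    "s1", "PF", malignant = c(NSC = 40, ependymal = 40), normal = NULL,
    cna = NULL, cycling_frac = 0)), fold_up = 4, seed = 92)
  e <- log_transform(sim$expr)
  assign <- tibble::tibble(cell_id = sim$cells$cell_id,
                           state = sim$cells$program)
  sig <- signature_genes(e, assign)
  nsc_sig <- sig$gene_id[sig$state == "NSC"]
  expect_gte(mean(g$modules$NSC %in% nsc_sig), 0.8)
})
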
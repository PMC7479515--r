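test_that("bulk scoring matches the single-cell scorer code path", {
  g <- make_genome(800, 5, seed = 121)
  bk <- simulate_bulk_cohort(g, n_samples = 40, seed = 122)
  sig <- g$modules$ependymal
  sc <- score_bulk(bk$expr, sig)
  # samples treated as cells through the single-cell path
  ea <- aggregate_expression(bk$expr)
  er <- center_expression(log_transform(bk$expr),
                          group = rep("all", ncol(bk$expr)))
  oracle <- score_cells(er, sig, ea = ea)
  expect_equal(sc$score, oracle$score, tolerance = 1e-12)
  # identical samples score zero (centering removes everything)
  same <- unclass(bk$expr)[, rep(1, 6)]
  colnames(same) <- paste0("s", 1:6)
  sc0 <- score_bulk(expression_matrix(same, "tpm"), sig)
  expect_equal(sc0$score, rep(0, 6), tolerance = 1e-10)
  expect_error(score_bulk(bk$expr, paste0("missing", 1:10)), "signature")
})

test_that("bulk scores track the planted program fraction", {
  g <- make_genome(800, 5, seed = 123)
  bk <- simulate_bulk_cohort(g, n_samples = 60, seed = 124)
  sc <- score_bulk(bk$expr, g$modules$ependymal)
  rho <- stats::cor(sc$score, bk$samples$frac_target, method = "spearman")
  expect_gte(rho, 0.8)
})

test_that("dichotomization splits bimodal scores and ignores constant shifts", {
  set.seed(130)
  scores <- tibble::tibble(sample_id = paste0("s", 1:20),
                           score = c(rnorm(10, -2, 0.1), rnorm(10, 2, 0.1)))
  d <- dichotomize(scores)
  expect_equal(as.character(d$group), rep(c("low", "high"), each = 10))
  # invariant to adding a constant
  d2 <- dichotomize(dplyr::mutate(scores, score = score + 100))
  expect_equal(d$group, d2$group)
  # planted two-component mixture recovered with >= 90% accuracy
  truth <- rep(c("low", "high"), each = 50)
  s <- c(rnorm(50, -1, 0.5), rnorm(50, 1, 0.5))
  d3 <- dichotomize(tibble::tibble(sample_id = paste0("x", 1:100), score = s))
  expect_gte(mean(as.character(d3$group) == truth), 0.9)
  # median fallback
  dm <- dichotomize(scores, method = "median")
  expect_equal(sum(dm$group == "high"), 10)
  expect_error(dichotomize(scores[1:3, ]), "at least 4")
  expect_error(dichotomize(dplyr::mutate(scores, score = 1)), "identical")
})

test_that("the log-rank statistic matches a hand-computed oracle", {
  # independent observed-minus-expected / hypergeometric-variance form
  logrank_oracle <- function(time, event, group) {
    g1 <- levels(factor(group))[1]
    o_minus_e <- 0
    v <- 0
    for (t in sort(unique(time[event == 1]))) {
      at_risk <- time >= t
      n <- sum(at_risk)
      n1 <- sum(at_risk & group == g1)
      d <- sum(time == t & event == 1)
      d1 <- sum(time == t & event == 1 & group == g1)
      o_minus_e <- o_minus_e + d1 - d * n1 / n
      if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    o_minus_e^2 / v
  }
  cohort <- tibble::tibble(
    time = c(2, 4, 5, 7, 9, 12),
    event = c(1, 1, 0, 1, 1, 0),
    group = factor(c("low", "high", "low", "high", "low", "high"))
  )
  res <- km_logrank(cohort)
  expect_equal(res$chisq,
               logrank_oracle(cohort$time, cohort$event, cohort$group),
               tolerance = 1e-10)
  # identical groups: statistic 0, p = 1
  same <- tibble::tibble(time = rep(c(1, 3, 6), 2),
                         event = rep(c(1, 1, 0), 2),
                         group = rep(c("low", "high"), each = 3))
  res0 <- km_logrank(same)
  expect_equal(res0$chisq, 0, tolerance = 1e-12)
  expect_equal(res0$p_value, 1, tolerance = 1e-12)
  # p invariant under label swap
  swap <- dplyr::mutate(cohort,
                        group = factor(ifelse(group == "low", "high", "low")))
  expect_equal(km_logrank(swap)$p_value, res$p_value, tolerance = 1e-12)
  expect_error(km_logrank(dplyr::mutate(cohort, event = 0)), "event")
})

test_that("KM estimates are proper step functions", {
  cohort <- tibble::tibble(time = c(1, 2, 3, 4, 5, 6, 7, 8),
                           event = c(1, 1, 1, 1, 0, 0, 0, 0),
                           group = rep(c("a", "b"), 4))
  td <- tidy(km_logrank(cohort))
  for (g in c("a", "b")) {
    est <- td$estimate[td$group == g]
    expect_true(all(diff(est) <= 1e-12))
    expect_lte(max(est), 1)
  }
  # no events: survival constant at 1
  none <- tibble::tibble(time = 1:8,
                         event = c(rep(0, 7), 1),
                         group = rep(c("a", "b"), 4))
  td2 <- tidy(km_logrank(none))
  expect_true(all(td2$estimate[td2$group == "a"] == 1))
})

test_that("stratification recovers a planted survival effect end to end", {
  g <- make_genome(800, 5, seed = 140)
  bk <- simulate_bulk_cohort(g, n_samples = 200, beta = log(3), seed = 141)
  sc <- score_bulk(bk$expr, g$modules$ependymal)
  d <- dichotomize(sc)
  cohort <- dplyr::inner_join(d, bk$samples[c("sample_id", "time", "event")],
                              by = "sample_id")
  res <- km_logrank(cohort)
  expect_lt(res$p_value, 0.05)
  # high-score group fares worse: lower survival at the median time
  km <- tidy(res)
  med <- stats::median(cohort$time)
  surv_at <- function(grp) {
    d <- km[km$group == grp & km$time <= med, ]
    if (nrow(d) == 0) 1 else min(d$estimate)
  }
  expect_lt(surv_at("high"), surv_at("low"))
})
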
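# Correlation inference is validated two ways: against a hand-rolled
# covariance/sd oracle, and against stats::cor.test as an independent
# reference implementation.

test_that("pearson r matches the brute-force moment oracle and cor.test", {
  set.seed(31L)
  for (i in 1:20) {
    n <- 50L
    x <- rnorm(n); y <- 0.4 * x + rnorm(n)
    res <- correlate(x, y, "pearson")
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(res$r, r_oracle, tolerance = 1e-12)
    ct <- cor.test(x, y)
    expect_equal(res$p, ct$p.value, tolerance = 1e-12)
    expect_equal(c(res$ci_lo, res$ci_hi), as.numeric(ct$conf.int),
                 tolerance = 1e-9)
  }
})

test_that("perfect linearity gives r = 1 and pairwise-complete n is honoured", {
  res <- correlate(c(1, 2, 3), c(2, 4, 6))
  expect_identical(res$r, 1)
  expect_identical(res$n, 3L)

  x <- c(1, 2, NA, 4, 5); y <- c(2, NA, 3, 8, 10)
  expect_identical(correlate(x, y)$n, 3L)
})

test_that("spearman is invariant under strictly monotone transforms", {
  set.seed(77L)
  x <- rnorm(30L); y <- 0.5 * x + rnorm(30L)
  base <- correlate(x, y, "spearman")
  for (f in list(exp, function(v) v^3, function(v) 5 * v - 2)) {
    expect_equal(correlate(f(x), y, "spearman")$r, base$r,
                 tolerance = 1e-12)
  }
  expect_equal(base$r, unname(cor.test(x, y, method = "spearman")$estimate),
               tolerance = 1e-12)
})

test_that("degenerate inputs yield flagged undefined results, not NaN", {
  res <- correlate(c(1, 2), c(3, 4))
  expect_true(res$undefined)
  expect_true(is.na(res$r) && is.na(res$p))

  res2 <- correlate(rep(1, 10), rnorm(10))
  expect_true(res2$undefined)
  expect_identical(res2$reason, "zero variance")
})

test_that("exact spearman permutation p agrees with the t approximation in rank order", {
  set.seed(13L)
  x <- rnorm(6L); y <- rnorm(6L)
  ex <- correlate(x, y, "spearman", exact = TRUE)
  ap <- correlate(x, y, "spearman", exact = FALSE)
  expect_identical(ex$r, ap$r)
  expect_gt(ex$p, 0); expect_lte(ex$p, 1)
  # exact p is a permutation fraction over 6! orderings
  expect_equal(ex$p * factorial(6), round(ex$p * factorial(6)),
               tolerance = 1e-8)
})

test_that("blood-brain correlations carry per-cell pairwise-complete n", {
  sim <- simulate_cohort(quick_sim(seed = 5L))
  sc <- scored_cohort(sim)
  bb <- blood_brain_correlations(sc$scores, sim$sheet, "smoking")
  expect_identical(bb$n[bb$tissue_y == "BA35"], 13L)
  expect_true(all(bb$n[bb$tissue_y != "BA35"] == 14L))
  # blood correlated with itself is exactly 1
  wide <- measure_wide(sc$scores, sim$sheet, "smoking")
  expect_identical(correlate(wide[, "blood"], wide[, "blood"])$r, 1)
})

test_that("a zero-coupling region shows |r| < 0.05 at n = 2000", {
  # BA17 decoupled, the remaining regions at 0.5
  rho <- c(BA17 = 0, "BA20/21" = 0.5, BA24 = 0.5, BA35 = 0.5, BA46 = 0.5)
  sim <- simulate_cohort(quick_sim(seed = 2024L, n_individuals = 2000L,
                                   rho = rho, sigma_cpg = 0,
                                   missing_ba35 = FALSE))
  sc <- scored_cohort(sim)
  bb <- blood_brain_correlations(sc$scores, sim$sheet, "smoking")
  expect_lt(abs(bb$r[bb$tissue_y == "BA17"]), 0.05)
  expect_true(all(abs(bb$r[bb$tissue_y != "BA17"] - 0.5) < 0.05))
})

test_that("score-trait correlations restrict pack-years analyses to complete cases", {
  sim <- simulate_cohort(quick_sim(seed = 6L))
  sc <- scored_cohort(sim)
  phenos <- add_pack_years(sim$phenotypes)
  expect_identical(sum(!is.na(phenos$pack_years)), 9L)   # 5 of 14 lack cpd
  tc <- score_trait_correlations(sc$scores, sim$sheet, phenos)
  py <- tc[tc$trait == "pack_years" & tc$tissue != "BA35", ]
  expect_true(all(py$n == 9L))

  # constant phenotype -> undefined flag
  phenos$hdl <- 1.5
  sim2 <- simulate_cohort(quick_sim(seed = 6L, traits = "HDL"))
  sc2 <- scored_cohort(sim2)
  tc2 <- score_trait_correlations(sc2$scores, sim2$sheet, phenos,
                                  pairs = list(HDL = "hdl"))
  expect_true(all(tc2$undefined))
})

test_that("inter-region matrices are symmetric with unit diagonal", {
  sim <- simulate_cohort(quick_sim(seed = 7L))
  sc <- scored_cohort(sim)
  cm <- interregion_matrix(sc$scores, sim$sheet, "smoking")
  expect_identical(dim(cm$r), c(5L, 5L))
  expect_identical(unname(diag(cm$r)), rep(1, 5L))
  expect_identical(cm$r, t(cm$r))
  expect_identical(cm$method, "spearman")

  # identical score vectors in two regions -> off-diagonal r = 1
  sc1 <- sc$scores
  w17 <- sc1$sample_id[grepl("_BA17$", sc1$sample_id)]
  w46 <- sc1$sample_id[grepl("_BA46$", sc1$sample_id)]
  sc1$score[match(w46, sc1$sample_id)] <-
    sc1$score[match(w17, sc1$sample_id)]
  cm1 <- interregion_matrix(sc1, sim$sheet, "smoking")
  expect_equal(cm1$r["BA17", "BA46"], 1)
})

test_that("exchangeable regions recover their pairwise coupling at n = 2000", {
  # blood coupling rho per region implies inter-region correlation rho^2;
  # sqrt(0.5) everywhere targets pairwise 0.5. Checked on the Pearson
  # matrix, the scale on which the coupling is specified (rank-based
  # Spearman values sit ~0.02 lower for Gaussian scores).
  sim <- simulate_cohort(quick_sim(seed = 314L, n_individuals = 2000L,
                                   rho = sqrt(0.5), sigma_cpg = 0,
                                   missing_ba35 = FALSE))
  sc <- scored_cohort(sim)
  cm <- interregion_matrix(sc$scores, sim$sheet, "smoking",
                           method = "pearson")
  off <- cm$r[upper.tri(cm$r)]
  expect_true(all(abs(off - 0.5) < 0.05))
})

test_that("sensitivity comparison ranks, flags top agreement and sees robustness", {
  set.seed(55L)
  n <- 2000L
  x <- rnorm(n); y <- 0.6 * x + 0.8 * rnorm(n)
  rp <- correlate(x, y, "pearson")$r
  rs <- correlate(x, y, "spearman")$r
  expect_lt(abs(rp - rs), 0.05)              # near-equality for Gaussian data

  # one gross outlier perturbs spearman less than pearson
  x2 <- c(rnorm(20L)); y2 <- 0.6 * x2 + 0.8 * rnorm(20L)
  x2o <- c(x2, 50); y2o <- c(y2, -50)
  d_p <- abs(correlate(x2o, y2o, "pearson")$r -
               correlate(x2, y2, "pearson")$r)
  d_s <- abs(correlate(x2o, y2o, "spearman")$r -
               correlate(x2, y2, "spearman")$r)
  expect_lt(d_s, d_p)

  sim <- simulate_cohort(quick_sim(seed = 8L))
  sc <- scored_cohort(sim)
  pe <- blood_brain_correlations(sc$scores, sim$sheet, "smoking", "pearson")
  sp <- blood_brain_correlations(sc$scores, sim$sheet, "smoking", "spearman")
  cmp <- sensitivity_compare(pe, sp)
  expect_identical(nrow(cmp), nrow(pe))
  expect_true(all(c("rank_pearson", "rank_spearman") %in% names(cmp)))
  # identical inputs to both -> identical ranks
  same <- sensitivity_compare(pe, pe)
  expect_identical(same$rank_pearson, same$rank_spearman)
})

test_that("fisher CI covers r and has near-nominal coverage", {
  res <- correlate(rnorm(20L), rnorm(20L))
  expect_true(res$ci_lo <= res$r && res$r <= res$ci_hi)
  ci <- fisher_ci(0.5, 14)
  expect_equal(ci, tanh(atanh(0.5) + c(-1, 1) * qnorm(0.975) / sqrt(11)),
               tolerance = 1e-12)
})

test_that("power estimator is calibrated, cross-validated and monotone", {
  null <- correlation_power(20L, 0, n_sims = 1500L, seed = 41L)
  expect_lt(abs(null$power - 0.05), 2 * sqrt(0.05 * 0.95 / 1500))

  est <- correlation_power(14L, 0.5, n_sims = 1500L, seed = 42L)
  expect_lt(abs(est$power - est$power_fisher), 3 * est$se)

  pw <- vapply(c(10L, 20L, 40L, 80L), function(n) {
    correlation_power(n, 0.4, n_sims = 800L, seed = 43L)$power
  }, numeric(1L))
  expect_true(all(diff(pw) > 0))
})
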
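test_that("the default design yields 69 brain samples plus 14 blood samples", {
  sim <- simulate_cohort(sim_config(seed = 1L))
  n_brain <- sum(vapply(sim$betas[BRAIN_REGIONS],
                        function(b) ncol(b$values), 1L))
  expect_identical(n_brain, 69L)                   # 14 x 5 - 1 missing BA35
  expect_identical(ncol(sim$betas$blood$values), 14L)
  expect_identical(nrow(as.data.frame(sim$sheet)), 83L)

  mi <- sim$truth$missing_ba35_individual
  expect_true(mi %in% sim$sheet$individual_id)
  ba35 <- sim$sheet$individual_id[sim$sheet$tissue == "BA35"]
  expect_false(mi %in% ba35)
  expect_identical(length(ba35), 13L)
})

test_that("simulation is deterministic in the seed and varies across seeds", {
  a <- simulate_cohort(quick_sim(seed = 9L, n_individuals = 5L))
  b <- simulate_cohort(quick_sim(seed = 9L, n_individuals = 5L))
  c <- simulate_cohort(quick_sim(seed = 10L, n_individuals = 5L))
  expect_identical(a$betas$blood$values, b$betas$blood$values)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_false(identical(a$betas$blood$values, c$betas$blood$values))
})

test_that("weight fixtures are reproducible, trait-disjoint and AHRR-anchored", {
  w1 <- make_weight_fixture("smoking", 10L, seed = 7L)
  w2 <- make_weight_fixture("smoking", 10L, seed = 7L)
  expect_identical(w1$weights, w2$weights)
  expect_length(w1, 10L)
  expect_identical(anyDuplicated(names(w1$weights)), 0L)

  expect_true(AHRR_PROBE %in% names(w1$weights))
  expect_lt(w1$weights[[AHRR_PROBE]], 0)

  w3 <- make_weight_fixture("smoking", 10L, seed = 8L)
  expect_false(setequal(names(w1$weights), names(w3$weights)))

  w_hdl <- make_weight_fixture("HDL", 50L, seed = 7L)
  expect_length(intersect(names(w1$weights), names(w_hdl$weights)), 0L)
})

test_that("the degenerate noiseless limit gives r = 1 between blood and brain", {
  sim <- simulate_cohort(quick_sim(seed = 12L, rho = 1, sigma_cpg = 0,
                                   lambda_trait = 1, missing_ba35 = FALSE))
  sc <- scored_cohort(sim)
  bb <- blood_brain_correlations(sc$scores, sim$sheet, "smoking")
  expect_equal(bb$r, rep(1, 5L), tolerance = 1e-9)
})

test_that("betas stay in [0.001, 0.999] and the logit/expit map round-trips", {
  sim <- simulate_cohort(quick_sim(seed = 13L, sigma_cpg = 3))
  for (b in sim$betas) {
    expect_true(all(b$values >= 0.001 & b$values <= 0.999))
  }
  x <- c(0.001, 0.2, 0.5, 0.77, 0.999)
  expect_equal(methbridge:::.expit2(methbridge:::.logit2(x)), x,
               tolerance = 1e-12)
})

test_that("planted QC failures are recovered exactly, with no false removals", {
  cfg <- quick_sim(seed = 99L, n_cpgs = 100L,
                   qc_failures = list(n_detp_samples = 1L, n_detp_probes = 2L,
                                      n_beadcount_probes = 2L))
  sim <- simulate_cohort(cfg)
  brain <- cbind_beta(sim$betas[BRAIN_REGIONS], platform = "EPIC")
  out <- filter_brain_qc(brain)
  planted <- sim$truth$planted
  expect_setequal(removed_ids(out$report, "sample"), planted$detp_samples)
  expect_setequal(removed_ids(out$report, "probe"),
                  c(planted$detp_probes, planted$beadcount_probes))
  rep <- as.data.frame(out$report)
  expect_setequal(rep$id[rep$reason == "beadcount"],
                  planted$beadcount_probes)
  expect_setequal(rep$id[rep$reason == "detp"], planted$detp_probes)
  expect_setequal(rep$id[rep$reason == "high_detp_fraction"],
                  planted$detp_samples)

  clean <- filter_brain_qc(cbind_beta(
    simulate_cohort(quick_sim(seed = 100L))$betas[BRAIN_REGIONS],
    platform = "EPIC"))
  expect_identical(nrow(clean$report), 0L)
})

test_that("planted sex mislabels are recovered by the sex check", {
  cfg <- quick_sim(seed = 101L,
                   qc_failures = list(n_sex_mislabels = 1L))
  sim <- simulate_cohort(cfg)
  rep <- check_sex(sim$betas$blood, sim$sheet, sim$truth$x_probes)
  flagged <- removed_ids(rep, "sample")
  expect_identical(sub("_blood$", "", flagged),
                   sim$truth$mislabelled_individuals)
})

test_that("config invariants are enforced", {
  expect_error(sim_config(), "seed")
  bad_rho <- matrix(0.5, 1L, 2L,
                    dimnames = list("smoking", c("BA17", "nope")))
  expect_error(sim_config(traits = "smoking", regions = c("BA17", "BA24"),
                          rho_region = bad_rho, seed = 1L),
               "rho_region")
  ok_rho <- matrix(2, 1L, 1L, dimnames = list("smoking", "BA17"))
  expect_error(sim_config(traits = "smoking", regions = "BA17",
                          rho_region = ok_rho, seed = 1L),
               "\\[-1, 1\\]")
})

test_that("phenotypes track the latent traits with the configured structure", {
  sim <- simulate_cohort(sim_config(seed = 3L))
  ph <- sim$phenotypes
  expect_identical(sum(ph$smoking_status == 0L), 2L)
  expect_identical(sum(ph$smoking_status == 2L), 5L)
  expect_identical(sum(ph$smoking_status == 1L), 7L)
  # latent smoking trait orders the status classes by construction
  Ts <- sim$truth$T[, "smoking"]
  expect_true(max(Ts[ph$smoking_status == 0L]) <
                min(Ts[ph$smoking_status == 2L]))
  # at large n the phenotype correlates with its latent trait
  big <- simulate_cohort(sim_config(n_individuals = 1000L, seed = 4L))
  r_hdl <- cor(big$truth$T[, "HDL"], big$phenotypes$hdl)
  expect_gt(r_hdl, 0.5)
})
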
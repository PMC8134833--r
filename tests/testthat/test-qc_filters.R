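# QC fixtures are built by planting failures into otherwise-clean matrices,
# then asserting that exactly the planted ids are removed, with the right
# reason code, and that clean content is untouched.

clean_qc_matrix <- function(n_probes, n_samples, seed = 1L) {
  v <- toy_values(n_probes, n_samples, seed)
  dp <- matrix(1e-6, n_probes, n_samples, dimnames = dimnames(v))
  bc <- matrix(8L, n_probes, n_samples, dimnames = dimnames(v))
  beta_matrix(v, dp, bc)
}

test_that("brain QC removes a sample with >1% failing probes, reason high_detp_fraction", {
  m <- clean_qc_matrix(100L, 10L)
  m$detection_p[1:2, "S03"] <- 0.2           # 2% of probes fail in S03
  out <- filter_brain_qc(m)
  expect_identical(removed_ids(out$report, "sample"), "S03")
  expect_identical(out$report$reason[out$report$axis == "sample"],
                   "high_detp_fraction")
  expect_identical(sample_ids(out$matrix), setdiff(sample_ids(m), "S03"))
  expect_identical(probe_ids(out$matrix), probe_ids(m))
})

test_that("brain QC removes a probe with beadcount <3 in >5% of samples", {
  m <- clean_qc_matrix(100L, 50L)
  m$beadcount["cg0000007", 1:3] <- 2L        # 6% of samples below 3 beads
  out <- filter_brain_qc(m)
  expect_identical(removed_ids(out$report, "probe"), "cg0000007")
  expect_identical(out$report$reason, "beadcount")
})

test_that("brain QC removes a probe failing detection p in >1% of samples", {
  # 200 probes so the 1 failing probe stays under the 1% per-sample rule
  m <- clean_qc_matrix(200L, 100L)
  m$detection_p["cg0000003", 1:2] <- 0.9     # 2% of samples fail
  out <- filter_brain_qc(m)
  expect_identical(removed_ids(out$report, "probe"), "cg0000003")
  expect_identical(out$report$reason, "detp")
})

test_that("a clean matrix passes brain QC untouched with an empty report", {
  m <- clean_qc_matrix(100L, 10L)
  out <- filter_brain_qc(m)
  expect_identical(out$matrix$values, m$values)
  expect_identical(nrow(out$report), 0L)
})

test_that("brain QC applies samples before probes; the order matters", {
  # S01 fails 2% of probes; cg0000001 fails ONLY in S01. Sample-first:
  # S01 goes, cg0000001 then fails 0% of the remaining samples and stays.
  # Probe-first would have removed it (1/10 = 10% > 1%).
  m <- clean_qc_matrix(100L, 10L)
  m$detection_p[1:2, "S01"] <- 0.5
  probe_first_frac <- rowMeans(m$detection_p > 0.05)["cg0000001"]
  expect_gt(probe_first_frac, 0.01)          # the orders genuinely diverge
  out <- filter_brain_qc(m)
  expect_identical(removed_ids(out$report, "sample"), "S01")
  expect_true("cg0000001" %in% probe_ids(out$matrix))
})

test_that("brain and blood filters are idempotent and counts reconcile", {
  m <- clean_qc_matrix(100L, 50L)
  m$detection_p[1:2, "S05"] <- 0.5
  m$beadcount["cg0000009", 1:4] <- 2L
  m$detection_p["cg0000011", c("S20", "S21")] <- 0.8
  once <- filter_brain_qc(m)
  twice <- filter_brain_qc(once$matrix)
  expect_identical(twice$matrix$values, once$matrix$values)
  expect_identical(nrow(twice$report), 0L)
  for (res in list(once)) {
    rep <- res$report
    b <- attr(rep, "before"); a <- attr(rep, "after")
    expect_identical(b[["probes"]] - a[["probes"]],
                     length(removed_ids(rep, "probe")))
    expect_identical(b[["samples"]] - a[["samples"]],
                     length(removed_ids(rep, "sample")))
  }
})

test_that("blood QC rescales the absolute call-rate threshold to fixture size", {
  # 1000 probes, 20 samples; S01 misses 100 probes. Scaled threshold is
  # 1000 * 450000/485512 ~ 926.9, so 900 detected probes fails. The missed
  # probes are detected in 19/20 = 95% of samples, which meets the 95%
  # probe rule, so only the sample is removed.
  m <- clean_qc_matrix(1000L, 20L)
  m$detection_p[1:100, "S01"] <- 0.5
  out <- suppressMessages(filter_blood_qc(m))
  expect_identical(removed_ids(out$report, "sample"), "S01")
  expect_identical(out$report$reason[out$report$axis == "sample"],
                   "low_call_rate")
  expect_identical(length(removed_ids(out$report, "probe")), 0L)
  smp <- out$report[out$report$axis == "sample", ]
  expect_equal(smp$rule_value, 900)
  expect_equal(smp$threshold, 1000 * 450000 / 485512, tolerance = 1e-10)
})

test_that("blood QC removes probes detected in <95% of samples", {
  m <- clean_qc_matrix(100L, 50L)
  m$detection_p["cg0000042", 1:3] <- 0.5     # detected in 94% of samples
  out <- suppressMessages(filter_blood_qc(m))
  expect_identical(removed_ids(out$report, "probe"), "cg0000042")
  expect_identical(out$report$reason, "low_detection_rate")

  clean <- suppressMessages(filter_blood_qc(clean_qc_matrix(100L, 10L)))
  expect_identical(nrow(clean$report), 0L)
})

test_that("rules with absent side-matrices are skipped with a warning", {
  m <- toy_beta(20L, 5L, seed = 2L)          # no detp, no beadcount
  w <- testthat::capture_warnings(out <- filter_brain_qc(m))
  expect_match(w, "absent", all = TRUE)
  expect_length(w, 2L)                       # det-p rules and beadcount rule
  expect_identical(out$matrix$values, m$values)
  expect_warning(out2 <- filter_blood_qc(m), "blood QC skipped")
  expect_identical(out2$matrix$values, m$values)
})

sex_fixture <- function(true_sex, recorded = true_sex, seed = 5L) {
  set.seed(seed)
  n <- length(true_sex)
  ids <- sprintf("S%02d", seq_len(n))
  xp <- sprintf("cgX%04d", 1:10)
  mu <- ifelse(true_sex == "F", 0.45, 0.25)
  v <- matrix(rep(mu, each = 10L), 10L, n, dimnames = list(xp, ids)) +
    matrix(rnorm(10L * n, 0, 0.01), 10L)
  m <- beta_matrix(pmin(pmax(v, 0), 1))
  sheet <- toy_sheet(ids, paste0("I", seq_len(n)), rep("blood", n), recorded)
  list(m = m, sheet = sheet, xp = xp)
}

test_that("sex check flags exactly the mislabelled sample", {
  truth <- rep(c("M", "F"), each = 5L)
  recorded <- truth
  recorded[3L] <- "F"                        # true M recorded as F
  fx <- sex_fixture(truth, recorded)
  rep <- check_sex(fx$m, fx$sheet, fx$xp)
  expect_identical(removed_ids(rep, "sample"), "S03")
  expect_identical(rep$reason, "sex_mismatch")
})

test_that("sex check guards against single-sex cohorts and unknowns", {
  fx <- sex_fixture(rep("M", 8L))
  expect_warning(rep <- check_sex(fx$m, fx$sheet, fx$xp), "separation")
  expect_identical(nrow(rep), 0L)

  truth <- rep(c("M", "F"), each = 5L)
  recorded <- truth
  recorded[3L] <- "unknown"                  # unknown is exempt
  fx2 <- sex_fixture(truth, recorded)
  rep2 <- check_sex(fx2$m, fx2$sheet, fx2$xp)
  expect_identical(nrow(rep2), 0L)

  one <- fx$m[, "S01"]
  expect_warning(check_sex(one, fx$sheet[1L, ], fx$xp), "fewer than 2")
})

test_that("blacklist removal handles present, empty and absent ids", {
  m <- toy_beta(10L, 3L, seed = 9L)
  bl <- probe_ids(m)[1:5]
  out <- apply_blacklist(m, bl)
  expect_identical(nrow(out$matrix$values), 5L)
  expect_setequal(removed_ids(out$report, "probe"), bl)
  expect_true(all(out$report$reason == "blacklist"))

  ident <- apply_blacklist(m, character())
  expect_identical(ident$matrix$values, m$values)

  expect_warning(out2 <- apply_blacklist(m, c("cgZZZ1", "cgZZZ2")),
                 "2 blacklisted")
  expect_identical(out2$matrix$values, m$values)
})

test_that("thresholds outside their invariants are rejected", {
  expect_error(qc_thresholds(probe_fail_sample_frac = 1.2), "fraction")
  expect_error(qc_thresholds(beadcount_min = -1), "beadcount_min")
})
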
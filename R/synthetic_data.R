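# Synthetic paired blood/brain methylation cohorts with known ground truth.
#
# Generative model (all effects on the M-value scale, outputs as betas):
#   latent trait        T_ik  ~ N(0, 1)           (individual i, trait k)
#   blood factor        S_ik  = lambda_k T_ik + sqrt(1 - lambda_k^2) e
#   region factor       S_ikr = rho_kr S_ik + sqrt(1 - rho_kr^2) e
#   CpG M-value         m_ijr = mu_j + c w_j S_ikr + sigma_cpg e
#   beta                b     = 2^m / (2^m + 1), clamped to [0.001, 0.999]
# CpG loadings are proportional to the fixture weights w_j, so the projected
# episcore is (to first order) the sufficient statistic of the latent factor
# and the blood-brain score correlation converges to rho_kr as n grows.
# Region coupling is therefore specified directly at the score level — the
# quantity the concordance analyses measure.

.expit2 <- function(m) 2^m / (2^m + 1)
.logit2 <- function(b) log2(b / (1 - b))
.clamp_beta <- function(b) pmin(pmax(b, 0.001), 0.999)

# run expr under a temporary seed, restoring the caller's RNG stream
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Default blood-brain score coupling per trait and region
#'
#' Region-specific target correlations between the blood score and each
#' brain-region score, chosen to mirror the regionally variable coupling
#' observed in matched blood/brain cohorts: strong smoking coupling in the
#' dorsolateral prefrontal cortex (BA46), negative BMI coupling in BA46,
#' moderate HDL coupling in BA20/21, and weak (0.2) coupling elsewhere.
#'
#' @param traits trait names (rows).
#' @param regions region names (columns).
#' @return Numeric matrix traits x regions with values in `[-1, 1]`.
#' @export
default_rho_region <- function(traits = TRAITS, regions = BRAIN_REGIONS) {
  rho <- matrix(0.2, length(traits), length(regions),
                dimnames = list(traits, regions))
  set_if <- function(tr, rg, v) {
    if (tr %in% traits && rg %in% regions) rho[tr, rg] <<- v
  }
  set_if("smoking", "BA46", 0.5)
  set_if("smoking", "BA24", 0.29)
  set_if("smoking", "BA35", 0.36)
  set_if("HDL", "BA20/21", 0.55)
  set_if("HDL", "BA24", 0.38)
  set_if("HDL", "BA35", -0.32)
  set_if("BMI", "BA46", -0.72)
  set_if("BMI", "BA35", -0.46)
  set_if("alcohol", "BA24", 0.35)
  set_if("alcohol", "BA46", 0.25)
  rho
}

#' Simulation configuration
#'
#' Defaults encode the study design the generator emulates: 14 individuals,
#' one blood sample plus five Brodmann-area brain regions each, one
#' hippocampal (BA35) specimen unavailable, four lifestyle traits, and a
#' phenotype model matched to the cohort's summary statistics (5 current /
#' 7 former / 2 never smokers; 5 of 14 missing cigarettes-per-day so pack
#' years is analysable in 9; HDL 1.49 (0.4) mmol/l, BMI 25.5 (5.1) kg/m^2,
#' alcohol 14 (15) units/week, assessment age 77.9 (1.7), start age 16 (2)).
#' QC-failure counts default to zero: the emulated dataset corresponds to
#' the post-QC state of the real cohort; failures are planted explicitly
#' when exercising the QC filters.
#'
#' @param n_individuals number of individuals, default 14.
#' @param regions brain region labels, default [BRAIN_REGIONS].
#' @param traits trait names, default [TRAITS].
#' @param n_cpgs_per_trait CpGs per predictor fixture, default 100.
#' @param n_x_probes X-linked probes for the sex check, default 20.
#' @param n_platform_only_probes probes private to each platform (EPIC-only
#'   in brain, 450K-only in blood) exercising harmonization, default 5.
#' @param rho_region traits x regions matrix of target blood-brain score
#'   correlations, default [default_rho_region()].
#' @param lambda_trait loading of the latent trait on the blood epigenetic
#'   factor, per trait (recycled), default 0.7.
#' @param sigma_cpg per-CpG noise SD on the M-value scale, default 0.5.
#' @param effect_size scale `c` of the CpG loadings `c * w_j`, default 0.2
#'   M-units (keeps betas inside the near-linear range of the logistic).
#' @param missing_ba35 omit one random individual's BA35 sample, default
#'   TRUE.
#' @param pheno_model named list overriding phenotype-model parameters (see
#'   Details in the package vignette).
#' @param qc_failures named list of planted QC failures:
#'   `n_detp_samples` (brain samples failing the detection-p sample rule),
#'   `n_detp_probes`, `n_beadcount_probes`, `n_sex_mislabels`. All default
#'   0.
#' @param seed integer seed; mandatory, all randomness flows from it.
#' @return A list of class `SimulationConfig`.
#' @export
sim_config <- function(n_individuals = 14L, regions = BRAIN_REGIONS,
                       traits = TRAITS, n_cpgs_per_trait = 100L,
                       n_x_probes = 20L, n_platform_only_probes = 5L,
                       rho_region = default_rho_region(traits, regions),
                       lambda_trait = 0.7, sigma_cpg = 0.5,
                       effect_size = 0.2, missing_ba35 = TRUE,
                       pheno_model = list(), qc_failures = list(), seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("an explicit integer seed is mandatory", call. = FALSE)
  }
  traits <- match.arg(traits, TRAITS, several.ok = TRUE)
  if (!is.matrix(rho_region) ||
      !identical(sort(rownames(rho_region)), sort(traits)) ||
      !identical(sort(colnames(rho_region)), sort(regions))) {
    stop("rho_region must be a traits x regions matrix matching the ",
         "configured region list", call. = FALSE)
  }
  if (any(abs(rho_region) > 1)) stop("rho values must lie in [-1, 1]",
                                     call. = FALSE)
  if (n_cpgs_per_trait < 1L) stop("n_cpgs_per_trait must be >= 1",
                                  call. = FALSE)
  lambda_trait <- rep_len(lambda_trait, length(traits))
  if (any(abs(lambda_trait) > 1)) stop("lambda must lie in [-1, 1]",
                                       call. = FALSE)
  pm <- utils::modifyList(list(
    frac_never = 2 / 14, frac_current = 5 / 14, frac_missing_cpd = 5 / 14,
    missing_start_age = TRUE,
    assess_age_mean = 77.9, assess_age_sd = 1.7,
    start_age_mean = 16, start_age_sd = 2,
    cpd_mean = 20, cpd_slope = 12, cpd_sd = 5,
    hdl_mean = 1.49, hdl_sd = 0.4,
    bmi_mean = 25.5, bmi_sd = 5.1,
    alcohol_mean = 14, alcohol_sd = 15,
    pheno_loading = 0.7), pheno_model)
  qf <- utils::modifyList(list(n_detp_samples = 0L, n_detp_probes = 0L,
                               n_beadcount_probes = 0L,
                               n_sex_mislabels = 0L), qc_failures)
  structure(list(n_individuals = as.integer(n_individuals),
                 regions = regions, traits = traits,
                 n_cpgs_per_trait = as.integer(n_cpgs_per_trait),
                 n_x_probes = as.integer(n_x_probes),
                 n_platform_only_probes = as.integer(n_platform_only_probes),
                 rho_region = rho_region[traits, regions, drop = FALSE],
                 lambda_trait = stats::setNames(lambda_trait, traits),
                 sigma_cpg = sigma_cpg, effect_size = effect_size,
                 missing_ba35 = missing_ba35, pheno_model = pm,
                 qc_failures = qf, seed = as.integer(seed)),
            class = "SimulationConfig")
}

#' Reproducible predictor weight fixture
#'
#' Builds a trait weight table with `n_cpgs` unique probes: a sign-balanced
#' mixture of large (|w| ~ 0.5) and small (|w| ~ 0.05) coefficients, the
#' shape of LASSO-trained predictors. Probe id pools are disjoint across
#' traits. The smoking fixture always contains cg05575921 with a large
#' negative weight (the AHRR probe is hypomethylated in smokers).
#'
#' @param trait trait name.
#' @param n_cpgs number of CpGs, default 100.
#' @param seed integer seed; the caller's RNG stream is left untouched.
#' @return A [weight_table()].
#' @export
make_weight_fixture <- function(trait, n_cpgs = 100L, seed) {
  trait <- match.arg(trait, TRAITS)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  .with_seed(seed, {
    offset <- match(trait, TRAITS) * 10000000L
    ids <- sprintf("cg%08d", offset + sample.int(9999999L, n_cpgs))
    n_large <- ceiling(n_cpgs / 2)
    mags <- c(abs(stats::rnorm(n_large, 0.5, 0.15)),
              abs(stats::rnorm(n_cpgs - n_large, 0.05, 0.02)))
    signs <- sample(rep_len(c(-1, 1), n_cpgs))
    w <- stats::setNames(signs * mags, ids)
    if (trait == "smoking") {
      names(w)[1L] <- AHRR_PROBE
      w[1L] <- -1.0
    }
    weight_table(trait, w, intercept = 0)
  })
}

.sanitize_tissue <- function(t) gsub("/", "_", t, fixed = TRUE)

#' Simulate a matched blood/brain methylation cohort
#'
#' Draws a full synthetic dataset from the factor model described in the
#' package vignette: beta matrices (with detection-p and beadcount
#' side-matrices) for blood and each brain region, predictor weight
#' fixtures, a sample sheet, a phenotype table, and the ground truth
#' (latent traits, tissue factors, true coupling, planted failures, true
#' sex). With the default design (14 individuals, 5 regions, one BA35
#' sample unavailable) the brain matrices hold 69 samples in total.
#'
#' @param cfg a [sim_config()].
#' @return A list with elements `betas` (named list of `BetaMatrix`: blood
#'   plus one per region), `weights` (named list of `WeightTable`), `sheet`
#'   (a `SampleSheet`), `phenotypes` (a `PhenotypeTable`, raw fields; derive
#'   pack years with [add_pack_years()]), and `truth` (a `GroundTruth`
#'   list).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  K <- length(cfg$traits)
  ind <- sprintf("I%03d", seq_len(n))

  weights <- stats::setNames(
    lapply(seq_len(K), function(k) {
      make_weight_fixture(cfg$traits[k], cfg$n_cpgs_per_trait,
                          seed = (cfg$seed %% 100000L) * 10L + k)
    }), cfg$traits)

  true_sex <- ifelse(stats::runif(n) < 9 / 14, "M", "F")
  T_mat <- matrix(stats::rnorm(n * K), n, K,
                  dimnames = list(ind, cfg$traits))
  lam <- cfg$lambda_trait
  S_blood <- sweep(T_mat, 2L, lam, `*`) +
    sweep(matrix(stats::rnorm(n * K), n, K), 2L, sqrt(1 - lam^2), `*`)
  dimnames(S_blood) <- dimnames(T_mat)
  S_region <- stats::setNames(lapply(cfg$regions, function(rg) {
    rho <- cfg$rho_region[, rg]
    S <- sweep(S_blood, 2L, rho, `*`) +
      sweep(matrix(stats::rnorm(n * K), n, K), 2L, sqrt(1 - rho^2), `*`)
    dimnames(S) <- dimnames(T_mat)
    S
  }), cfg$regions)

  # probe layout: trait CpGs + X probes + platform-private noise probes
  w_all <- unlist(lapply(weights, `[[`, "weights"))
  names(w_all) <- unlist(lapply(weights, function(w) names(w$weights)))
  trait_of <- rep(cfg$traits, vapply(weights, length, 1L))
  p_trait <- names(w_all)
  p_x <- sprintf("cgX%06d", seq_len(cfg$n_x_probes))
  npo <- cfg$n_platform_only_probes
  p_epic <- if (npo) sprintf("cgE%06d", seq_len(npo)) else character()
  p_450k <- if (npo) sprintf("cgK%06d", seq_len(npo)) else character()

  bimodal_mu <- function(k) sample(c(-1, 1), k, replace = TRUE) *
    stats::runif(k, 1, 3)
  mu_trait <- stats::setNames(bimodal_mu(length(p_trait)), p_trait)
  mu_epic <- stats::setNames(bimodal_mu(length(p_epic)), p_epic)
  mu_450k <- stats::setNames(bimodal_mu(length(p_450k)), p_450k)
  # X probes: mean beta ~0.45 in females (X-inactivation intermediate
  # methylation), ~0.25 in males
  mu_x_sex <- c(F = .logit2(0.45), M = .logit2(0.25))

  trait_idx <- match(trait_of, cfg$traits)
  make_tissue <- function(S, sample_suffix, extra_ids, extra_mu) {
    m_sig <- mu_trait + cfg$effect_size * w_all *
      t(S[, trait_idx, drop = FALSE])          # probes x individuals
    m_sig <- m_sig +
      matrix(stats::rnorm(length(m_sig), 0, cfg$sigma_cpg), nrow(m_sig))
    m_x <- matrix(rep(mu_x_sex[true_sex], each = cfg$n_x_probes),
                  cfg$n_x_probes, n) +
      matrix(stats::rnorm(cfg$n_x_probes * n, 0, 0.15), cfg$n_x_probes)
    m_extra <- if (length(extra_ids)) {
      matrix(extra_mu, length(extra_ids), n) +
        matrix(stats::rnorm(length(extra_ids) * n, 0, cfg$sigma_cpg),
               length(extra_ids))
    } else matrix(numeric(), 0L, n)
    m <- rbind(m_sig, m_x, m_extra)
    rownames(m) <- c(p_trait, p_x, extra_ids)
    colnames(m) <- paste(ind, sample_suffix, sep = "_")
    .clamp_beta(.expit2(m))
  }

  betas <- vector("list", length(cfg$regions) + 1L)
  names(betas) <- c("blood", cfg$regions)
  b_blood <- make_tissue(S_blood, "blood", p_450k, mu_450k)
  region_vals <- lapply(cfg$regions, function(rg) {
    make_tissue(S_region[[rg]], .sanitize_tissue(rg), p_epic, mu_epic)
  })
  names(region_vals) <- cfg$regions

  # one hippocampal (BA35) specimen unavailable
  missing_ind <- NA_character_
  if (cfg$missing_ba35 && "BA35" %in% cfg$regions) {
    missing_ind <- ind[sample.int(n, 1L)]
    keep <- colnames(region_vals[["BA35"]]) != paste0(missing_ind, "_BA35")
    region_vals[["BA35"]] <- region_vals[["BA35"]][, keep, drop = FALSE]
  }

  # QC side matrices with optional planted failures
  qf <- cfg$qc_failures
  brain_samples <- unlist(lapply(region_vals, colnames), use.names = FALSE)
  plant <- list(detp_samples = character(), detp_probes = character(),
                beadcount_probes = character())
  if (qf$n_detp_samples > 0L) {
    plant$detp_samples <- sample(brain_samples, qf$n_detp_samples)
  }
  all_brain_probes <- rownames(region_vals[[1L]])
  if (qf$n_detp_probes > 0L) {
    plant$detp_probes <- sample(all_brain_probes, qf$n_detp_probes)
  }
  if (qf$n_beadcount_probes > 0L) {
    plant$beadcount_probes <- sample(setdiff(all_brain_probes,
                                             plant$detp_probes),
                                     qf$n_beadcount_probes)
  }
  # Each planted probe fails in its own (disjoint) 10% of the clean brain
  # samples: the affected samples then carry at most one failing planted
  # probe each, so the >1%-of-probes sample rule cannot fire collaterally.
  ok_brain <- setdiff(brain_samples, plant$detp_samples)
  frac_hit <- max(1L, ceiling(0.10 * length(ok_brain)))
  assign_fail <- function(probes) {
    if (!length(probes)) return(list())
    pool <- sample(ok_brain)
    stats::setNames(lapply(seq_along(probes), function(q) {
      idx <- ((q - 1L) * frac_hit + seq_len(frac_hit) - 1L) %%
        length(pool) + 1L
      pool[idx]
    }), probes)
  }
  detp_fail_in <- assign_fail(plant$detp_probes)
  bead_fail_in <- assign_fail(plant$beadcount_probes)

  side_matrices <- function(vals, brain) {
    np <- nrow(vals); ns <- ncol(vals)
    dp <- matrix(stats::runif(np * ns, 0, 1e-4), np, ns,
                 dimnames = dimnames(vals))
    bc <- matrix(5L + stats::rpois(np * ns, 2), np, ns,
                 dimnames = dimnames(vals))
    if (brain) {
      for (s in intersect(plant$detp_samples, colnames(vals))) {
        hit <- sample.int(np, max(1L, ceiling(0.05 * np)))
        dp[hit, s] <- stats::runif(length(hit), 0.05, 1)
      }
      for (pr in names(detp_fail_in)) {
        cols <- intersect(detp_fail_in[[pr]], colnames(vals))
        if (length(cols)) dp[pr, cols] <- stats::runif(length(cols), 0.05, 1)
      }
      for (pr in names(bead_fail_in)) {
        cols <- intersect(bead_fail_in[[pr]], colnames(vals))
        if (length(cols)) bc[pr, cols] <- 2L
      }
    }
    list(dp = dp, bc = bc)
  }

  sb <- side_matrices(b_blood, brain = FALSE)
  betas[["blood"]] <- beta_matrix(b_blood, sb$dp, sb$bc, platform = "450K")
  for (rg in cfg$regions) {
    sr <- side_matrices(region_vals[[rg]], brain = TRUE)
    betas[[rg]] <- beta_matrix(region_vals[[rg]], sr$dp, sr$bc,
                               platform = "EPIC")
  }

  # sample sheet (recorded sex carries any planted mislabels)
  recorded_sex <- true_sex
  mislabelled <- character()
  if (qf$n_sex_mislabels > 0L) {
    flip <- sample.int(n, qf$n_sex_mislabels)
    recorded_sex[flip] <- ifelse(true_sex[flip] == "M", "F", "M")
    mislabelled <- ind[flip]
  }
  sheet_rows <- do.call(rbind, lapply(names(betas), function(ts) {
    sids <- colnames(betas[[ts]]$values)
    iid <- sub(paste0("_", .sanitize_tissue(ts), "$"), "", sids)
    data.frame(sample_id = sids, individual_id = iid, tissue = ts,
               recorded_sex = recorded_sex[match(iid, ind)],
               stringsAsFactors = FALSE)
  }))
  sheet <- sample_sheet(sheet_rows)

  phenos <- .simulate_phenotypes(ind, T_mat, cfg)

  truth <- structure(list(
    T = T_mat, S_blood = S_blood, S_region = S_region,
    rho_region = cfg$rho_region, lambda_trait = cfg$lambda_trait,
    true_sex = stats::setNames(true_sex, ind),
    mislabelled_individuals = mislabelled,
    missing_ba35_individual = missing_ind,
    planted = plant, x_probes = p_x, seed = cfg$seed),
    class = "GroundTruth")

  list(betas = betas, weights = weights, sheet = sheet,
       phenotypes = phenos, truth = truth, config = cfg)
}

.simulate_phenotypes <- function(ind, T_mat, cfg) {
  pm <- cfg$pheno_model
  n <- length(ind)
  loading <- pm$pheno_loading
  mix <- function(Tk) loading * Tk + sqrt(1 - loading^2) * stats::rnorm(n)
  col_or_zero <- function(tr) {
    if (tr %in% colnames(T_mat)) T_mat[, tr] else rep(0, n)
  }

  # smoking status by latent-trait quantile: heaviest exposure = current
  Ts <- col_or_zero("smoking")
  n_never <- round(pm$frac_never * n)
  n_current <- round(pm$frac_current * n)
  ord <- order(Ts)
  status <- integer(n)
  status[ord] <- c(rep(0L, n_never), rep(1L, n - n_never - n_current),
                   rep(2L, n_current))

  assess_age <- stats::rnorm(n, pm$assess_age_mean, pm$assess_age_sd)
  start_age <- pmax(10, round(stats::rnorm(n, pm$start_age_mean,
                                           pm$start_age_sd)))
  start_age[status == 0L] <- NA_real_
  ever <- which(status > 0L)
  if (pm$missing_start_age && length(ever)) {
    start_age[sample(ever, 1L)] <- NA_real_
  }
  stop_age <- rep(NA_real_, n)
  stop_age[status == 2L] <- assess_age[status == 2L]
  former <- which(status == 1L)
  if (length(former)) {
    lo <- ifelse(is.na(start_age[former]), pm$start_age_mean,
                 start_age[former]) + 5
    stop_age[former] <- stats::runif(length(former), lo,
                                     pmax(lo + 1, assess_age[former]))
  }
  cpd <- pmax(1, pm$cpd_mean + pm$cpd_slope * Ts + stats::rnorm(n, 0, pm$cpd_sd))
  cpd[status == 0L] <- NA_real_
  n_miss <- min(round(pm$frac_missing_cpd * n), length(ever))
  if (n_miss > 0L) cpd[sample(ever, n_miss)] <- NA_real_

  phenos <- data.frame(
    individual_id = ind,
    smoking_status = status,
    cigarettes_per_day = cpd,
    age_started_smoking = start_age,
    age_stopped_or_current = stop_age,
    alcohol_units_week = pmax(0, pm$alcohol_mean +
                                pm$alcohol_sd * mix(col_or_zero("alcohol"))),
    bmi = pmax(12, pm$bmi_mean + pm$bmi_sd * mix(col_or_zero("BMI"))),
    hdl = pmax(0.3, pm$hdl_mean + pm$hdl_sd * mix(col_or_zero("HDL"))),
    stringsAsFactors = FALSE)
  phenotype_table(phenos)
}

#' Write a simulated cohort to a directory of plain-text artifacts
#'
#' Emits per-tissue beta/detection-p/beadcount TSVs, the weight tables, the
#' sample sheet, the phenotype table and a ground-truth YAML.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance_header(extra = c(seed = sim$config$seed))
  for (ts in names(sim$betas)) {
    write_beta_matrix(sim$betas[[ts]],
                      file.path(dir, paste0("beta_", .sanitize_tissue(ts),
                                            ".tsv")), header = hdr)
  }
  for (tr in names(sim$weights)) {
    write_weight_table(sim$weights[[tr]],
                       file.path(dir, paste0("weights_", tr, ".tsv")),
                       header = hdr)
  }
  write_sample_sheet(sim$sheet, file.path(dir, "sample_sheet.tsv"),
                     header = hdr)
  write_phenotype_table(sim$phenotypes, file.path(dir, "phenotypes.tsv"),
                        header = hdr)
  truth <- sim$truth
  yaml::write_yaml(list(
    seed = sim$config$seed,
    rho_region = as.list(as.data.frame(truth$rho_region)),
    lambda_trait = as.list(truth$lambda_trait),
    true_sex = as.list(truth$true_sex),
    missing_ba35_individual = truth$missing_ba35_individual,
    mislabelled_individuals = truth$mislabelled_individuals,
    planted = truth$planted), file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}
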
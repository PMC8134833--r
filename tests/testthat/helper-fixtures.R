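# Shared fixture builders. Everything is generated in code at test time;
# no binary or stored data.

toy_values <- function(n_probes = 3L, n_samples = 2L, seed = 1L) {
  set.seed(seed)
  matrix(runif(n_probes * n_samples, 0.05, 0.95), n_probes, n_samples,
         dimnames = list(sprintf("cg%07d", seq_len(n_probes)),
                         sprintf("S%02d", seq_len(n_samples))))
}

toy_beta <- function(n_probes = 3L, n_samples = 2L, seed = 1L,
                     detp = FALSE, bead = FALSE) {
  v <- toy_values(n_probes, n_samples, seed)
  dp <- if (detp) matrix(1e-6, n_probes, n_samples, dimnames = dimnames(v))
  bc <- if (bead) matrix(8L, n_probes, n_samples, dimnames = dimnames(v))
  beta_matrix(v, dp, bc)
}

toy_sheet <- function(sample_id, individual_id, tissue,
                      recorded_sex = "unknown") {
  sample_sheet(data.frame(sample_id = sample_id,
                          individual_id = individual_id, tissue = tissue,
                          recorded_sex = recorded_sex,
                          stringsAsFactors = FALSE))
}

# small cohort simulation used across tests (1 trait keeps it fast)
quick_sim <- function(seed, n_individuals = 14L, traits = "smoking",
                      n_cpgs = 30L, rho = NULL, sigma_cpg = 0.5, ...) {
  regions <- BRAIN_REGIONS
  rho_m <- matrix(if (is.null(rho)) 0.5 else rho, length(traits),
                  length(regions), dimnames = list(traits, regions))
  sim_config(n_individuals = n_individuals, traits = traits,
             n_cpgs_per_trait = n_cpgs, n_x_probes = 5L,
             n_platform_only_probes = 0L, rho_region = rho_m,
             sigma_cpg = sigma_cpg, seed = seed, ...)
}

# combined post-harmonization matrix + scores for a simulated cohort
scored_cohort <- function(sim) {
  brain <- cbind_beta(sim$betas[setdiff(names(sim$betas), "blood")],
                      platform = "EPIC")
  harm <- suppressMessages(harmonize_platforms(list(sim$betas$blood, brain)))
  comb <- cbind_beta(harm)
  scores <- suppressWarnings(project_scores_multi(comb, sim$weights))
  list(combined = comb, scores = scores)
}
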
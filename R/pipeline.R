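# Pipeline orchestration: QC -> harmonize -> score -> phenotypes ->
# concordance, from a single YAML (or list) config, writing a report
# directory whose files all carry a provenance header. Reruns with the same
# config and seed are byte-identical.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(structure(class = c("methbridge_stage_error", "error", "condition"),
                   list(message = sprintf("[stage %s] %s", name,
                                          conditionMessage(e)),
                        call = NULL, stage = name)))
  })
}

.default_config <- function() {
  list(simulate = NULL, inputs = NULL, blacklist = NULL, restrict_to = NULL,
       x_probes = NULL, min_coverage = 0.95, cohort_mean_start_age = 16,
       thresholds = list(), include_blood_interregion = FALSE)
}

#' Run the full blood-brain concordance pipeline
#'
#' Stages, in order: `load` (read the configured inputs, or simulate a
#' cohort when `config$simulate` is given), `qc` (brain rules on the pooled
#' brain samples, blood rules on blood, probe blacklist, methylation sex
#' check with flagged samples removed), `harmonize` (probe intersection,
#' optionally restricted to a 450K probe list), `score` (episcore projection
#' for every weight table plus cg05575921 extraction), `phenotypes` (pack
#' years derivation), `correlate` (blood-brain, score-trait and inter-region
#' correlations, Pearson plus Spearman sensitivity), `report` (TSV outputs
#' plus a run log). Any stage error aborts with a condition of class
#' `methbridge_stage_error` carrying the stage name.
#'
#' @param config a list, or path to a YAML file, with keys `simulate` (named
#'   arguments to [sim_config()], at least `seed`) or `inputs` (paths:
#'   `beta`/`detection_p`/`beadcount` named per tissue, `sample_sheet`,
#'   `phenotypes`, `weights` named per trait), plus optional `blacklist`,
#'   `restrict_to`, `x_probes` (paths to probe-id lists), `thresholds`
#'   (overrides for [qc_thresholds()]), `min_coverage`,
#'   `cohort_mean_start_age`, `include_blood_interregion`.
#' @param out_dir report directory, created if needed.
#' @return Invisibly, a list with the in-memory artifacts (`scores`,
#'   `phenotypes`, `qc_report`, `blood_brain`, `trait_correlations`,
#'   `interregion`, `sensitivity`, `sheet`) and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(.default_config(), config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  loaded <- .stage("load", .load_stage(cfg))
  hdr <- provenance_header(inputs = loaded$input_files,
                           extra = c(seed = as.character(loaded$seed)))

  thr <- .stage("qc", do.call(qc_thresholds, cfg$thresholds))
  qc <- .stage("qc", .qc_stage(loaded, thr, cfg))
  harm <- .stage("harmonize", .harmonize_stage(qc, cfg))

  scores <- .stage("score", {
    if (!length(loaded$weights)) stop("no weight tables configured")
    project_scores_multi(harm$combined, loaded$weights,
                         min_coverage = cfg$min_coverage)
  })
  cpg <- .stage("score", extract_cpg(harm$combined))

  phenos <- .stage("phenotypes",
                   add_pack_years(loaded$phenotypes,
                                  cfg$cohort_mean_start_age))

  corr <- .stage("correlate",
                 .correlate_stage(scores, cpg, loaded$sheet, phenos, cfg))

  .stage("report", .report_stage(out_dir, hdr, qc, scores, phenos, corr,
                                 loaded))
  invisible(c(list(out_dir = out_dir, scores = scores, phenotypes = phenos,
                   qc_report = qc$report, sheet = loaded$sheet), corr))
}

.load_stage <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (is.null(sim_args$seed)) stop("simulate config requires a seed")
    sim <- simulate_cohort(do.call(sim_config, sim_args))
    brain <- cbind_beta(sim$betas[setdiff(names(sim$betas), "blood")],
                        platform = "EPIC")
    list(blood = sim$betas$blood, brain = brain, sheet = sim$sheet,
         phenotypes = sim$phenotypes, weights = sim$weights,
         x_probes = sim$truth$x_probes, seed = sim$config$seed,
         input_files = character())
  } else if (!is.null(cfg$inputs)) {
    inp <- cfg$inputs
    rd <- function(ts, platform) {
      read_beta_matrix(inp$beta[[ts]], platform = platform,
                       detection_p_path = inp$detection_p[[ts]],
                       beadcount_path = inp$beadcount[[ts]])
    }
    tissues <- names(inp$beta)
    if (!"blood" %in% tissues) stop("inputs$beta must include 'blood'")
    regions <- setdiff(tissues, "blood")
    brain_list <- lapply(regions, rd, platform = "EPIC")
    brain <- cbind_beta(harmonize_platforms(brain_list))
    weights <- stats::setNames(
      lapply(names(inp$weights), function(tr) {
        read_weight_table(inp$weights[[tr]], trait = tr)
      }), names(inp$weights))
    x_probes <- if (!is.null(cfg$x_probes)) read_blacklist(cfg$x_probes)
    list(blood = rd("blood", "450K"), brain = brain,
         sheet = read_sample_sheet(inp$sample_sheet),
         phenotypes = read_phenotype_table(inp$phenotypes),
         weights = weights, x_probes = x_probes, seed = NA_character_,
         input_files = unlist(inp, use.names = FALSE))
  } else {
    stop("config needs either 'simulate' or 'inputs'")
  }
}

.qc_stage <- function(loaded, thr, cfg) {
  brain_qc <- filter_brain_qc(loaded$brain, thr)
  blood_qc <- filter_blood_qc(loaded$blood, thr)
  report <- rbind(as.data.frame(brain_qc$report),
                  as.data.frame(blood_qc$report))
  brain <- brain_qc$matrix
  blood <- blood_qc$matrix
  if (!is.null(cfg$blacklist)) {
    bl <- read_blacklist(cfg$blacklist)
    brain_bl <- apply_blacklist(brain, bl)
    blood_bl <- apply_blacklist(blood, bl)
    brain <- brain_bl$matrix; blood <- blood_bl$matrix
    report <- rbind(report, as.data.frame(brain_bl$report))
  }
  list(blood = blood, brain = brain, report = report,
       sheet = loaded$sheet, x_probes = loaded$x_probes)
}

.harmonize_stage <- function(qc, cfg) {
  restrict <- if (!is.null(cfg$restrict_to)) read_blacklist(cfg$restrict_to)
  harm <- harmonize_platforms(list(qc$blood, qc$brain), restrict)
  combined <- cbind_beta(harm, platform = "custom")
  if (!is.null(qc$x_probes) &&
      length(intersect(qc$x_probes, probe_ids(combined)))) {
    sex <- check_sex(combined, qc$sheet, qc$x_probes)
    bad <- removed_ids(sex, "sample")
    if (length(bad)) {
      combined <- combined[, setdiff(sample_ids(combined), bad)]
    }
    qc$report <- rbind(qc$report, as.data.frame(sex))
  } else {
    warning("no X-linked probes configured/present: sex check skipped",
            call. = FALSE)
  }
  list(combined = combined, report = qc$report)
}

.correlate_stage <- function(scores, cpg, sheet, phenos, cfg) {
  measures <- unique(scores$trait)
  has_cpg <- nrow(cpg) > 0L
  bb <- function(method) {
    rows <- lapply(measures, function(ms) {
      blood_brain_correlations(scores, sheet, ms, method = method)
    })
    if (has_cpg) {
      rows <- c(rows, list(blood_brain_correlations(cpg, sheet, AHRR_PROBE,
                                                    method = method)))
    }
    do.call(rbind, rows)
  }
  tc <- function(method) {
    rbind(score_trait_correlations(scores, sheet, phenos, method = method),
          if (has_cpg) score_trait_correlations(cpg, sheet, phenos,
                                                method = method))
  }
  bb_p <- bb("pearson"); bb_s <- bb("spearman")
  tc_p <- tc("pearson"); tc_s <- tc("spearman")
  inter <- lapply(stats::setNames(nm = c(measures,
                                         if (has_cpg) AHRR_PROBE)),
                  function(ms) {
    interregion_matrix(if (ms %in% measures) scores else cpg, sheet, ms,
                       include_blood = isTRUE(cfg$include_blood_interregion))
  })
  list(blood_brain = bb_p, blood_brain_spearman = bb_s,
       trait_correlations = tc_p, trait_correlations_spearman = tc_s,
       interregion = inter,
       sensitivity = list(blood_brain = sensitivity_compare(bb_p, bb_s),
                          trait = sensitivity_compare(tc_p, tc_s)))
}

.report_stage <- function(out_dir, hdr, qc, scores, phenos, corr, loaded) {
  out <- function(f) file.path(out_dir, f)
  write_qc_report(qc_report(qc$report), out("qc_report.tsv"), header = hdr)
  write_score_table(scores, out("score_table.tsv"), header = hdr)
  write_phenotype_table(phenos, out("phenotypes_derived.tsv"), header = hdr)
  write_correlation_report(
    rbind(corr$blood_brain, corr$blood_brain_spearman),
    out("correlations_blood_brain.tsv"), header = hdr)
  write_correlation_report(
    rbind(corr$trait_correlations, corr$trait_correlations_spearman),
    out("correlations_trait.tsv"), header = hdr)
  inter_long <- do.call(rbind, lapply(names(corr$interregion), function(ms) {
    cm <- corr$interregion[[ms]]
    idx <- which(upper.tri(cm$r), arr.ind = TRUE)
    data.frame(measure = ms, method = cm$method,
               tissue_x = rownames(cm$r)[idx[, 1L]],
               tissue_y = colnames(cm$r)[idx[, 2L]],
               r = cm$r[idx], n = cm$n[idx], p = cm$p[idx],
               stringsAsFactors = FALSE)
  }))
  write_correlation_report(inter_long, out("correlations_interregion.tsv"),
                           header = hdr)
  n_tests <- nrow(corr$blood_brain) + nrow(corr$trait_correlations) +
    nrow(inter_long) / 2L
  log_lines <- c(hdr,
                 sprintf("samples scored: %d", length(unique(scores$sample_id))),
                 sprintf("traits: %s", paste(unique(scores$trait),
                                             collapse = ", ")),
                 sprintf("qc removals/flags: %d", nrow(qc$report)),
                 sprintf("correlations computed (per method): %d", n_tests),
                 "p-values are unadjusted; the count above annotates multiplicity")
  writeLines(log_lines, out("run_log.txt"))
  invisible(out_dir)
}
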
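# Probe- and sample-level QC. Filters are pure: (BetaMatrix, thresholds) ->
# (BetaMatrix, QcReport). Rule order is documented per filter and the
# inequalities are applied exactly as stated (strict where stated strict).

#' QC thresholds
#'
#' Defaults encode the standard array QC rules used for the brain (EPIC) and
#' blood (450K) matrices:
#' * brain: drop samples in which >1% of probes have detection p > 0.05;
#'   drop probes with beadcount < 3 in >5% of samples; drop probes with
#'   detection p > 0.05 in >1% of samples.
#' * blood: drop probes with detection rate < 95% at p < 0.01; drop samples
#'   detecting fewer than 450,000 probes at p < 0.01 (an absolute count tied
#'   to the 485,512-probe 450K array, rescaled proportionally for smaller
#'   matrices; see [filter_blood_qc()]).
#'
#' @param probe_detection_p_max detection p above which a measurement counts
#'   as failed (brain rules). Default 0.05.
#' @param probe_fail_sample_frac probe removed when failed in more than this
#'   fraction of samples. Default 0.01.
#' @param sample_fail_probe_frac sample removed when more than this fraction
#'   of its probes failed. Default 0.01.
#' @param beadcount_min minimum acceptable beadcount. Default 3.
#' @param beadcount_fail_sample_frac probe removed when beadcount is below
#'   `beadcount_min` in more than this fraction of samples. Default 0.05.
#' @param blood_detection_p detection p threshold for the blood rules.
#'   Default 0.01.
#' @param blood_probe_call_rate_min minimum fraction of samples in which a
#'   blood probe must be detected. Default 0.95.
#' @param blood_sample_min_probes minimum detected-probe count per blood
#'   sample, on a full 450K array. Default 450000.
#' @param blood_array_size probe count of the full array the sample threshold
#'   refers to. Default 485512.
#' @return A list of class `QcThresholds`.
#' @export
qc_thresholds <- function(probe_detection_p_max = 0.05,
                          probe_fail_sample_frac = 0.01,
                          sample_fail_probe_frac = 0.01,
                          beadcount_min = 3L,
                          beadcount_fail_sample_frac = 0.05,
                          blood_detection_p = 0.01,
                          blood_probe_call_rate_min = 0.95,
                          blood_sample_min_probes = 450000L,
                          blood_array_size = 485512L) {
  t <- list(probe_detection_p_max = probe_detection_p_max,
            probe_fail_sample_frac = probe_fail_sample_frac,
            sample_fail_probe_frac = sample_fail_probe_frac,
            beadcount_min = beadcount_min,
            beadcount_fail_sample_frac = beadcount_fail_sample_frac,
            blood_detection_p = blood_detection_p,
            blood_probe_call_rate_min = blood_probe_call_rate_min,
            blood_sample_min_probes = blood_sample_min_probes,
            blood_array_size = blood_array_size)
  fracs <- c("probe_detection_p_max", "probe_fail_sample_frac",
             "sample_fail_probe_frac", "beadcount_fail_sample_frac",
             "blood_detection_p", "blood_probe_call_rate_min")
  for (f in fracs) {
    if (!is.numeric(t[[f]]) || length(t[[f]]) != 1L || is.na(t[[f]]) ||
        t[[f]] < 0 || t[[f]] > 1) {
      stop("threshold '", f, "' must be a fraction in [0, 1]", call. = FALSE)
    }
  }
  if (t$beadcount_min < 0) stop("beadcount_min must be >= 0", call. = FALSE)
  if (t$blood_sample_min_probes < 0 || t$blood_array_size <= 0) {
    stop("blood sample thresholds must be positive", call. = FALSE)
  }
  class(t) <- "QcThresholds"
  t
}

# ---- QcReport ---------------------------------------------------------------

.qc_row <- function(axis, id, reason, rule_value, threshold) {
  data.frame(axis = axis, id = id, reason = reason,
             rule_value = rule_value, threshold = threshold,
             stringsAsFactors = FALSE)
}

.empty_qc <- function() {
  .qc_row(character(), character(), character(), numeric(), numeric())
}

#' Assemble a QcReport
#'
#' A `QcReport` is a data frame with one row per removal or flag —
#' columns `axis` (`"probe"`/`"sample"`), `id`, `reason`, `rule_value` (the
#' observed statistic), `threshold` — plus `counts` attributes recording
#' probe/sample counts before and after so that removed + retained always
#' reconciles with the input.
#'
#' @param rows removal rows (internal layout, see above).
#' @param before,after named integer vectors `c(probes=, samples=)`.
#' @return A data frame of class `QcReport`.
#' @export
qc_report <- function(rows = .empty_qc(), before = c(probes = 0L, samples = 0L),
                      after = before) {
  structure(rows, class = c("QcReport", "data.frame"),
            before = before, after = after)
}

#' @export
print.QcReport <- function(x, ...) {
  b <- attr(x, "before"); a <- attr(x, "after")
  cat(sprintf("QcReport: probes %d -> %d, samples %d -> %d (%d removals/flags)\n",
              b[["probes"]], a[["probes"]], b[["samples"]], a[["samples"]],
              nrow(x)))
  if (nrow(x)) print(as.data.frame(x), ...)
  invisible(x)
}

#' Removed identifiers from a QcReport
#' @param report a `QcReport`.
#' @param axis `"probe"` or `"sample"`.
#' @return Character vector of removed ids.
#' @export
removed_ids <- function(report, axis) report$id[report$axis == axis]

#' @rdname write_correlation_report
#' @param report a `QcReport`.
#' @export
write_qc_report <- function(report, path, sep = "tab",
                            header = provenance_header()) {
  .write_delim_table(as.data.frame(report), path, .delim(sep), header)
}

# ---- brain QC ---------------------------------------------------------------

#' Brain (EPIC) probe/sample QC
#'
#' Rules applied in order:
#' 1. remove samples in which more than `sample_fail_probe_frac` (>1%) of
#'    probes have detection p > `probe_detection_p_max` (0.05) — reason
#'    `high_detp_fraction`;
#' 2. remove probes with beadcount < `beadcount_min` (3) in more than
#'    `beadcount_fail_sample_frac` (>5%) of the *remaining* samples —
#'    reason `beadcount`;
#' 3. remove probes with detection p > 0.05 in more than
#'    `probe_fail_sample_frac` (>1%) of the remaining samples — reason
#'    `detp`.
#'
#' The ordering matters (a failing sample cannot fail probes it no longer
#' belongs to) and every removal carries the first rule that fired. A rule
#' whose side-matrix is absent is skipped with a warning. Missing cells in a
#' side-matrix are treated as non-failing. Filters are idempotent.
#'
#' @param m a `BetaMatrix` with `detection_p` and `beadcount`.
#' @param thresholds a [qc_thresholds()].
#' @return `list(matrix = filtered BetaMatrix, report = QcReport)`.
#' @export
filter_brain_qc <- function(m, thresholds = qc_thresholds()) {
  stopifnot(inherits(m, "BetaMatrix"), inherits(thresholds, "QcThresholds"))
  before <- c(probes = nrow(m$values), samples = ncol(m$values))
  rows <- .empty_qc()
  keep_s <- sample_ids(m)

  # (1) sample rule on detection p
  if (is.null(m$detection_p)) {
    warning("detection_p absent: detection-p QC rules skipped", call. = FALSE)
  } else {
    fail <- m$detection_p > thresholds$probe_detection_p_max
    fail[is.na(fail)] <- FALSE
    frac_s <- colMeans(fail)
    bad <- frac_s > thresholds$sample_fail_probe_frac
    if (any(bad)) {
      rows <- rbind(rows, .qc_row("sample", names(frac_s)[bad],
                                  "high_detp_fraction", frac_s[bad],
                                  thresholds$sample_fail_probe_frac))
      keep_s <- setdiff(keep_s, names(frac_s)[bad])
    }
  }
  m2 <- m[, keep_s]
  keep_p <- probe_ids(m2)

  # (2) probe rule on beadcount, over remaining samples
  if (is.null(m2$beadcount)) {
    warning("beadcount absent: beadcount QC rule skipped", call. = FALSE)
  } else {
    low <- m2$beadcount < thresholds$beadcount_min
    low[is.na(low)] <- FALSE
    frac_p <- rowMeans(low)
    bad <- frac_p > thresholds$beadcount_fail_sample_frac
    if (any(bad)) {
      rows <- rbind(rows, .qc_row("probe", names(frac_p)[bad], "beadcount",
                                  frac_p[bad],
                                  thresholds$beadcount_fail_sample_frac))
      keep_p <- setdiff(keep_p, names(frac_p)[bad])
    }
  }

  # (3) probe rule on detection p, over remaining samples, first-rule-wins
  if (!is.null(m2$detection_p)) {
    fail <- m2$detection_p > thresholds$probe_detection_p_max
    fail[is.na(fail)] <- FALSE
    frac_p <- rowMeans(fail)
    bad <- names(frac_p)[frac_p > thresholds$probe_fail_sample_frac]
    bad <- intersect(bad, keep_p)
    if (length(bad)) {
      rows <- rbind(rows, .qc_row("probe", bad, "detp", frac_p[bad],
                                  thresholds$probe_fail_sample_frac))
      keep_p <- setdiff(keep_p, bad)
    }
  }

  out <- m2[keep_p, ]
  after <- c(probes = nrow(out$values), samples = ncol(out$values))
  list(matrix = out, report = qc_report(rows, before, after))
}

# ---- blood QC ---------------------------------------------------------------

#' Blood (450K) probe/sample QC
#'
#' Rules applied in order:
#' 1. remove probes detected (p < `blood_detection_p`, 0.01) in fewer than
#'    `blood_probe_call_rate_min` (95%) of samples — reason
#'    `low_detection_rate`;
#' 2. remove samples detecting fewer probes than the call-rate threshold —
#'    reason `low_call_rate`. The published threshold (450,000 probes) is an
#'    absolute count on a `blood_array_size` = 485,512-probe array; when the
#'    matrix has fewer probes the threshold is rescaled proportionally
#'    (`n_probes * 450000/485512`) and the scaling factor logged via
#'    [message()], so the rule stays meaningful on desk-scale fixtures.
#'    The rescaling uses the probe count remaining after rule 1.
#'
#' @param m a `BetaMatrix` with `detection_p`.
#' @param thresholds a [qc_thresholds()].
#' @return `list(matrix = filtered BetaMatrix, report = QcReport)`.
#' @export
filter_blood_qc <- function(m, thresholds = qc_thresholds()) {
  stopifnot(inherits(m, "BetaMatrix"), inherits(thresholds, "QcThresholds"))
  before <- c(probes = nrow(m$values), samples = ncol(m$values))
  rows <- .empty_qc()
  if (is.null(m$detection_p)) {
    warning("detection_p absent: blood QC skipped", call. = FALSE)
    return(list(matrix = m, report = qc_report(rows, before)))
  }
  det <- m$detection_p < thresholds$blood_detection_p
  det[is.na(det)] <- FALSE

  rate <- rowMeans(det)
  bad_p <- rate < thresholds$blood_probe_call_rate_min
  if (any(bad_p)) {
    rows <- rbind(rows, .qc_row("probe", names(rate)[bad_p],
                                "low_detection_rate", rate[bad_p],
                                thresholds$blood_probe_call_rate_min))
  }
  keep_p <- names(rate)[!bad_p]

  n_probes <- length(keep_p)
  scale <- n_probes / thresholds$blood_array_size
  min_detected <- thresholds$blood_sample_min_probes * scale
  if (scale < 1) {
    message(sprintf(
      "blood sample call-rate threshold rescaled by %.6g (%d probes): >= %.1f detected probes required",
      scale, n_probes, min_detected))
  }
  n_det <- colSums(det[keep_p, , drop = FALSE])
  bad_s <- n_det < min_detected
  if (any(bad_s)) {
    rows <- rbind(rows, .qc_row("sample", names(n_det)[bad_s],
                                "low_call_rate", n_det[bad_s], min_detected))
  }
  out <- m[keep_p, names(n_det)[!bad_s]]
  after <- c(probes = nrow(out$values), samples = ncol(out$values))
  list(matrix = out, report = qc_report(rows, before, after))
}

# ---- sex check --------------------------------------------------------------

#' Flag samples whose methylation-predicted sex disagrees with the record
#'
#' Sex is predicted from the per-sample mean beta over X-linked probes:
#' X-inactivation leaves females with intermediate methylation on the
#' inactive X, so their mean X beta is higher than males'. Samples are split
#' by deterministic 2-means (centres initialised at the observed min and
#' max); the higher-centre cluster is called female. Samples with
#' `recorded_sex == "unknown"` are exempt. If the two cluster centres are
#' closer than `min_separation` (single-sex cohorts), or fewer than 2
#' samples are available, prediction is skipped with a warning and nothing
#' is flagged.
#'
#' @param m a `BetaMatrix`.
#' @param sheet a [sample_sheet()] covering the samples of `m`.
#' @param x_probe_ids character vector of X-chromosome probe ids present in
#'   `m`.
#' @param min_separation minimum mean-beta distance between cluster centres
#'   for a call, default 0.05.
#' @return A `QcReport` fragment whose rows flag mismatched samples with
#'   reason `sex_mismatch` (`rule_value` is the sample's mean X beta,
#'   `threshold` the cluster-centre midpoint). Samples are flagged, not
#'   removed; pass `removed_ids(rep, "sample")` to a subset if removal is
#'   wanted.
#' @export
check_sex <- function(m, sheet, x_probe_ids, min_separation = 0.05) {
  stopifnot(inherits(m, "BetaMatrix"))
  sheet <- sample_sheet(as.data.frame(sheet))
  x_probe_ids <- intersect(x_probe_ids, probe_ids(m))
  n <- c(probes = nrow(m$values), samples = ncol(m$values))
  if (!length(x_probe_ids)) {
    stop("no X-linked probes present in the matrix", call. = FALSE)
  }
  if (ncol(m$values) < 2L) {
    warning("fewer than 2 samples: sex prediction skipped", call. = FALSE)
    return(qc_report(before = n))
  }
  xb <- colMeans(m$values[x_probe_ids, , drop = FALSE], na.rm = TRUE)
  centres <- range(xb)
  if (diff(centres) < .Machine$double.eps) {
    warning("X-probe means are constant: sex prediction skipped",
            call. = FALSE)
    return(qc_report(before = n))
  }
  km <- stats::kmeans(xb, centers = matrix(centres, ncol = 1L))
  ord <- order(km$centers[, 1L])                 # low = male, high = female
  if (diff(km$centers[ord, 1L]) < min_separation) {
    warning(sprintf(
      "X cluster separation %.3f < %.3f mean-beta units: single-sex cohort assumed, sex check skipped",
      diff(km$centers[ord, 1L]), min_separation), call. = FALSE)
    return(qc_report(before = n))
  }
  predicted <- ifelse(km$cluster == ord[2L], "F", "M")
  midpoint <- mean(km$centers[, 1L])
  rec <- sheet$recorded_sex[match(names(xb), sheet$sample_id)]
  flag <- !is.na(rec) & rec != "unknown" & rec != predicted
  rows <- if (any(flag)) {
    .qc_row("sample", names(xb)[flag], "sex_mismatch", xb[flag], midpoint)
  } else .empty_qc()
  qc_report(rows, before = n)
}

# ---- blacklist --------------------------------------------------------------

#' Remove blacklisted probes (SNP-overlapping, cross-hybridising X/Y probes)
#'
#' @param m a `BetaMatrix`.
#' @param blacklist character vector of probe ids to drop. Ids absent from
#'   the matrix are ignored with a warning reporting their count.
#' @return `list(matrix, report)` as for the other filters; removals carry
#'   reason `blacklist`.
#' @export
apply_blacklist <- function(m, blacklist) {
  stopifnot(inherits(m, "BetaMatrix"))
  before <- c(probes = nrow(m$values), samples = ncol(m$values))
  blacklist <- unique(as.character(blacklist))
  present <- intersect(blacklist, probe_ids(m))
  absent <- setdiff(blacklist, present)
  if (length(absent)) {
    warning(length(absent), " blacklisted probe(s) not present in matrix",
            call. = FALSE)
  }
  rows <- if (length(present)) {
    .qc_row("probe", present, "blacklist", NA_real_, NA_real_)
  } else .empty_qc()
  out <- m[setdiff(probe_ids(m), present), ]
  after <- c(probes = nrow(out$values), samples = ncol(out$values))
  list(matrix = out, report = qc_report(rows, before, after))
}
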
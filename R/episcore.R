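# Episcore projection: apply blood-trained CpG weights to any beta matrix.
# The score is a plain weighted sum over the available CpGs — terms for
# missing CpGs are dropped WITHOUT rescaling, because rescaling would change
# the score's units relative to the published predictors; per-sample
# coverage is reported instead so users can judge completeness.

#' Harmonize beta matrices to a common probe set
#'
#' Subsets every matrix to the intersection of all probe sets, optionally
#' further intersected with `restrict_to` (e.g. the 450K probe list, so EPIC
#' brain data and 450K blood data are compared on common content). The
#' resulting probe order is the first matrix's order; the intersection size
#' is logged via [message()].
#'
#' @param matrices list of `BetaMatrix` objects (length >= 1).
#' @param restrict_to optional character vector of probe ids.
#' @return List of `BetaMatrix` objects over the identical probe set/order.
#' @export
harmonize_platforms <- function(matrices, restrict_to = NULL) {
  stopifnot(length(matrices) >= 1L,
            all(vapply(matrices, inherits, TRUE, "BetaMatrix")))
  common <- Reduce(intersect, lapply(matrices, probe_ids))
  if (!is.null(restrict_to)) common <- intersect(common, restrict_to)
  if (!length(common)) {
    stop("no probes shared by all matrices",
         if (!is.null(restrict_to)) " after restriction", call. = FALSE)
  }
  common <- probe_ids(matrices[[1L]])[probe_ids(matrices[[1L]]) %in% common]
  message(sprintf("harmonized %d matrices to %d common probes",
                  length(matrices), length(common)))
  lapply(matrices, function(m) m[common, ])
}

#' Project predictor weights onto a beta matrix
#'
#' Computes, for every sample `i`,
#' `score_i = intercept + sum_j w_j * beta_ij`
#' over the weight-table CpGs that are present in the matrix and non-missing
#' for that sample. Per-sample missing cells are handled like absent probes:
#' the term is dropped and the sample's coverage reduced. Coverage is
#' `n_cpgs_used / n_cpgs_in_weight_table`; samples below `min_coverage` are
#' flagged with a warning but never dropped.
#'
#' @param m a `BetaMatrix` (normally post-QC and harmonized).
#' @param w a [weight_table()].
#' @param min_coverage warning threshold on coverage, default 0.95 (the
#'   published predictors retain >95% of their CpGs on both platforms).
#' @return A data frame of class `ScoreTable` with columns `sample_id`,
#'   `trait`, `score`, `n_cpgs_used`, `coverage`.
#' @export
project_scores <- function(m, w, min_coverage = 0.95) {
  stopifnot(inherits(m, "BetaMatrix"), inherits(w, "WeightTable"))
  hit <- names(w$weights)[names(w$weights) %in% probe_ids(m)]
  if (!length(hit)) {
    stop("no weight-table CpGs overlap the matrix for trait '", w$trait, "'",
         call. = FALSE)
  }
  b <- m$values[hit, , drop = FALSE]
  ww <- w$weights[hit]
  contrib <- b * ww                       # rows recycle ww across samples
  score <- w$intercept + colSums(contrib, na.rm = TRUE)
  n_used <- as.integer(colSums(!is.na(b)))
  coverage <- n_used / length(w$weights)
  low <- coverage < min_coverage
  if (any(low)) {
    warning(sprintf(
      "%d sample(s) below %.0f%% CpG coverage for trait '%s' (min %.3f); scores retained",
      sum(low), 100 * min_coverage, w$trait, min(coverage)), call. = FALSE)
  }
  out <- data.frame(sample_id = colnames(b), trait = w$trait,
                    score = unname(score), n_cpgs_used = unname(n_used),
                    coverage = unname(coverage), stringsAsFactors = FALSE)
  class(out) <- c("ScoreTable", "data.frame")
  out
}

#' Project several weight tables at once
#'
#' @param m a `BetaMatrix`.
#' @param weight_list list of [weight_table()]s (one per trait).
#' @param min_coverage as in [project_scores()].
#' @return A combined `ScoreTable` (rows keyed by sample x trait).
#' @export
project_scores_multi <- function(m, weight_list, min_coverage = 0.95) {
  out <- do.call(rbind, lapply(weight_list, project_scores, m = m,
                               min_coverage = min_coverage))
  rownames(out) <- NULL
  class(out) <- c("ScoreTable", "data.frame")
  out
}

#' Extract a single CpG's betas across samples
#'
#' Defaults to cg05575921 (AHRR), the strongest single blood DNAm correlate
#' of smoking, hypomethylated in smokers. Samples with a missing cell at the
#' probe are omitted; a probe absent from the matrix yields an empty table
#' with a warning.
#'
#' @param m a `BetaMatrix`.
#' @param probe_id CpG id, default [AHRR_PROBE].
#' @return A data frame of class `SingleCpgTable` with columns `sample_id`,
#'   `probe_id`, `beta`.
#' @export
extract_cpg <- function(m, probe_id = AHRR_PROBE) {
  stopifnot(inherits(m, "BetaMatrix"), length(probe_id) == 1L)
  if (!probe_id %in% probe_ids(m)) {
    warning("probe ", probe_id, " absent from matrix; empty table returned",
            call. = FALSE)
    out <- data.frame(sample_id = character(), probe_id = character(),
                      beta = numeric(), stringsAsFactors = FALSE)
  } else {
    b <- m$values[probe_id, ]
    keep <- !is.na(b)
    out <- data.frame(sample_id = names(b)[keep], probe_id = probe_id,
                      beta = unname(b[keep]), stringsAsFactors = FALSE)
  }
  class(out) <- c("SingleCpgTable", "data.frame")
  out
}
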
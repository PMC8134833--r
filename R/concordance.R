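# Correlation inference for blood-brain concordance analyses.
#
# Every correlation is reported as (r, n, p, 95% CI): pairwise-complete n,
# two-sided p from t = r*sqrt(n-2)/sqrt(1-r^2) with df = n-2, and a
# Fisher-z interval tanh(atanh(r) +/- 1.96/sqrt(n-3)). Spearman is Pearson
# on average-ranked data with the same t approximation (adequate at n >= 9;
# an exact permutation p is available for tiny n). Degenerate inputs
# (n < 3, zero variance) yield a result flagged `undefined` rather than
# propagating NaN.

#' Two-sided p-value from a correlation coefficient and sample size
#'
#' Computes `t = r * sqrt(n - 2) / sqrt(1 - r^2)` and the two-sided tail
#' probability on `n - 2` degrees of freedom — the analytic recomputation
#' used to check any printed (r, n, P) triple.
#'
#' @param r correlation coefficient(s), `|r| < 1`.
#' @param n pairwise-complete sample size(s), `n >= 3`.
#' @return Numeric vector of two-sided p-values.
#' @export
cor_p <- function(r, n) {
  stopifnot(all(abs(r) < 1), all(n >= 3))
  t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

#' Fisher-z 95% confidence interval for a correlation
#'
#' @param r correlation coefficient.
#' @param n sample size (`n > 3` for a finite interval).
#' @param level confidence level, default 0.95.
#' @return `c(lo, hi)`; `c(NA, NA)` when `n <= 3`.
#' @export
fisher_ci <- function(r, n, level = 0.95) {
  if (n <= 3) return(c(NA_real_, NA_real_))
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(c(z - q * se, z + q * se))
}

.avg_rank <- function(x) rank(x, ties.method = "average")

.undefined_result <- function(var_x, var_y, method, n, why) {
  structure(list(var_x = var_x, var_y = var_y, method = method,
                 r = NA_real_, n = n, t_stat = NA_real_, df = n - 2L,
                 p = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                 undefined = TRUE, reason = why),
            class = "CorrelationResult")
}

#' Correlate two vectors with full inference
#'
#' Pairwise-complete observations are used. Pearson is the product-moment
#' coefficient; Spearman is Pearson applied to average ranks. The two-sided
#' p-value uses the t approximation with `df = n - 2`; for Spearman with
#' `exact = TRUE` and `n <= 8` an exact permutation p over all `n!` orderings
#' is computed instead.
#'
#' @param x,y numeric vectors of equal length.
#' @param method `"pearson"` or `"spearman"`.
#' @param labels length-2 character vector naming x and y in the result.
#' @param exact use the exact Spearman permutation p for `n <= 8`.
#' @return A `CorrelationResult`: list with `var_x`, `var_y`, `method`, `r`,
#'   `n`, `t_stat`, `df`, `p`, `ci_lo`, `ci_hi`, `undefined`. When fewer
#'   than 3 complete pairs remain or either vector is constant, the result
#'   has `undefined = TRUE` and `NA` statistics.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman"),
                      labels = c("x", "y"), exact = FALSE) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  if (n < 3L) {
    return(.undefined_result(labels[1L], labels[2L], method, n, "n < 3"))
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(.undefined_result(labels[1L], labels[2L], method, n,
                             "zero variance"))
  }
  xs <- if (method == "spearman") .avg_rank(x) else x
  ys <- if (method == "spearman") .avg_rank(y) else y
  r <- stats::cor(xs, ys)
  r <- max(-1, min(1, r))
  if (abs(r) < 1) {
    t_stat <- r * sqrt(n - 2) / sqrt(1 - r^2)
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  } else {
    t_stat <- sign(r) * Inf
    p <- .Machine$double.xmin        # perfectly monotone: p ~ 0, kept in (0,1]
  }
  if (method == "spearman" && exact && n <= 8L) {
    p <- .spearman_exact_p(xs, ys, r)
  }
  ci <- if (abs(r) < 1) fisher_ci(r, n) else c(r, r)
  structure(list(var_x = labels[1L], var_y = labels[2L], method = method,
                 r = r, n = n, t_stat = t_stat, df = n - 2L, p = p,
                 ci_lo = ci[1L], ci_hi = ci[2L], undefined = FALSE,
                 reason = NA_character_),
            class = "CorrelationResult")
}

# exhaustive permutation null for Spearman at tiny n (n! <= 40320)
.spearman_exact_p <- function(rx, ry, r_obs) {
  n <- length(rx)
  perms <- .permutations(n)
  r_null <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
  mean(abs(r_null) >= abs(r_obs) - 1e-12)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' @export
print.CorrelationResult <- function(x, ...) {
  if (x$undefined) {
    cat(sprintf("correlation %s ~ %s [%s]: undefined (%s), n = %d\n",
                x$var_x, x$var_y, x$method, x$reason, x$n))
  } else {
    cat(sprintf(
      "correlation %s ~ %s [%s]: r = %.3f, n = %d, p = %.3g, 95%% CI [%.3f, %.3f]\n",
      x$var_x, x$var_y, x$method, x$r, x$n, x$p, x$ci_lo, x$ci_hi))
  }
  invisible(x)
}

#' @export
as.data.frame.CorrelationResult <- function(x, ...) {
  data.frame(var_x = x$var_x, var_y = x$var_y, method = x$method, r = x$r,
             n = x$n, p = x$p, ci_lo = x$ci_lo, ci_hi = x$ci_hi,
             undefined = x$undefined, stringsAsFactors = FALSE)
}

# ---- measure layout helpers -------------------------------------------------

#' Pivot per-sample measures to an individuals x tissues matrix
#'
#' Accepts a `ScoreTable` (uses `score`, filtered to `measure` as a trait)
#' or a `SingleCpgTable` (uses `beta`; `measure` is the probe id). Cells
#' with no sample (e.g. a missing BA35 specimen) are `NA`.
#'
#' @param tab a `ScoreTable` or `SingleCpgTable`.
#' @param sheet a [sample_sheet()] mapping samples to individuals/tissues.
#' @param measure trait name or probe id selecting rows of `tab`.
#' @return Numeric matrix, individuals x tissues.
#' @export
measure_wide <- function(tab, sheet, measure) {
  sheet <- sample_sheet(as.data.frame(sheet))
  if ("score" %in% names(tab)) {
    tab <- tab[tab$trait == measure, , drop = FALSE]
    val <- tab$score
  } else if ("beta" %in% names(tab)) {
    tab <- tab[tab$probe_id == measure, , drop = FALSE]
    val <- tab$beta
  } else {
    stop("expected a ScoreTable or SingleCpgTable", call. = FALSE)
  }
  if (!nrow(tab)) stop("no rows for measure '", measure, "'", call. = FALSE)
  idx <- match(tab$sample_id, sheet$sample_id)
  if (anyNA(idx)) stop("sample(s) missing from sample sheet: ",
                       tab$sample_id[is.na(idx)][1L], call. = FALSE)
  ind <- sort(unique(sheet$individual_id))
  tis <- intersect(TISSUES, unique(sheet$tissue[idx]))
  wide <- matrix(NA_real_, length(ind), length(tis),
                 dimnames = list(ind, tis))
  wide[cbind(match(sheet$individual_id[idx], ind),
             match(sheet$tissue[idx], tis))] <- val
  wide
}

#' Blood-vs-brain correlations for one measure
#'
#' Correlates each brain region's per-individual measure against the blood
#' measure, pairwise-complete (so a region with one missing specimen reports
#' n one lower).
#'
#' @param tab a `ScoreTable` or `SingleCpgTable` covering blood and brain
#'   samples.
#' @param sheet a [sample_sheet()].
#' @param measure trait name or probe id.
#' @param method `"pearson"` (primary) or `"spearman"` (sensitivity).
#' @return Data frame with one row per region: `measure`, `tissue_x`
#'   (`"blood"`), `tissue_y`, `method`, `r`, `n`, `p`, `ci_lo`, `ci_hi`,
#'   `undefined`.
#' @export
blood_brain_correlations <- function(tab, sheet, measure,
                                     method = "pearson") {
  wide <- measure_wide(tab, sheet, measure)
  if (!"blood" %in% colnames(wide)) {
    stop("no blood samples found for measure '", measure, "'", call. = FALSE)
  }
  regions <- setdiff(colnames(wide), "blood")
  rows <- lapply(regions, function(rg) {
    res <- correlate(wide[, "blood"], wide[, rg], method = method,
                     labels = c("blood", rg))
    cbind(measure = measure, tissue_x = "blood", tissue_y = rg,
          as.data.frame(res)[-(1:2)])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default measure-to-trait correlation map
#'
#' Smoking score and cg05575921 are tested against pack years and smoking
#' status; the HDL, alcohol and BMI scores against their clinical/self-report
#' fields.
#'
#' @return Named list: measure -> character vector of phenotype columns.
#' @export
default_trait_map <- function() {
  stats::setNames(
    list(c("pack_years", "smoking_status"), c("pack_years", "smoking_status"),
         "hdl", "alcohol_units_week", "bmi"),
    c("smoking", AHRR_PROBE, "HDL", "alcohol", "BMI"))
}

#' Correlate tissue measures with lifestyle phenotypes
#'
#' For each measure and each tissue in which it was assayed, correlates the
#' per-individual measure with the mapped phenotype field(s),
#' pairwise-complete (individuals missing the phenotype — e.g. missing pack
#' years — drop out of that correlation only).
#'
#' @param tab a `ScoreTable` or `SingleCpgTable`.
#' @param sheet a [sample_sheet()].
#' @param phenos a [phenotype_table()] (with `pack_years` already derived).
#' @param pairs measure-to-phenotype map, default [default_trait_map()];
#'   measures absent from `tab` are skipped.
#' @param method `"pearson"` or `"spearman"`.
#' @return Data frame: `measure`, `tissue`, `trait`, `method`, `r`, `n`,
#'   `p`, `ci_lo`, `ci_hi`, `undefined`.
#' @export
score_trait_correlations <- function(tab, sheet, phenos,
                                     pairs = default_trait_map(),
                                     method = "pearson") {
  phenos <- phenotype_table(as.data.frame(phenos))
  avail <- if ("score" %in% names(tab)) unique(tab$trait)
           else unique(tab$probe_id)
  rows <- list()
  for (measure in intersect(names(pairs), avail)) {
    wide <- measure_wide(tab, sheet, measure)
    for (trait in pairs[[measure]]) {
      if (!trait %in% names(phenos)) next
      ph <- phenos[[trait]][match(rownames(wide), phenos$individual_id)]
      for (tis in colnames(wide)) {
        res <- correlate(wide[, tis], ph, method = method,
                         labels = c(tis, trait))
        rows[[length(rows) + 1L]] <-
          cbind(measure = measure, tissue = tis, trait = trait,
                as.data.frame(res)[-(1:2)])
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Inter-region correlation matrix for one measure
#'
#' Symmetric matrix of correlations of a measure between every pair of
#' brain regions (optionally including blood), Spearman by default.
#' Diagonal r is exactly 1.
#'
#' @param tab a `ScoreTable` or `SingleCpgTable`.
#' @param sheet a [sample_sheet()].
#' @param measure trait name or probe id.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param include_blood include blood as a sixth axis.
#' @return A list of class `CorrelationMatrix` with symmetric matrices `r`,
#'   `n`, `p` and the `measure`/`method` labels.
#' @export
interregion_matrix <- function(tab, sheet, measure, method = "spearman",
                               include_blood = FALSE) {
  wide <- measure_wide(tab, sheet, measure)
  axes <- intersect(c(if (include_blood) "blood", BRAIN_REGIONS),
                    colnames(wide))
  if (length(axes) < 2L) stop("need at least 2 regions", call. = FALSE)
  k <- length(axes)
  r <- n <- p <- matrix(NA_real_, k, k, dimnames = list(axes, axes))
  diag(r) <- 1
  diag(n) <- colSums(!is.na(wide[, axes, drop = FALSE]))
  diag(p) <- NA_real_
  for (i in seq_len(k - 1L)) {
    for (j in seq((i + 1L), k)) {
      res <- correlate(wide[, axes[i]], wide[, axes[j]], method = method,
                       labels = axes[c(i, j)])
      r[i, j] <- r[j, i] <- res$r
      n[i, j] <- n[j, i] <- res$n
      p[i, j] <- p[j, i] <- res$p
    }
  }
  structure(list(measure = measure, method = method, r = r, n = n, p = p),
            class = "CorrelationMatrix")
}

#' @export
print.CorrelationMatrix <- function(x, ...) {
  cat(sprintf("CorrelationMatrix [%s, %s]:\n", x$measure, x$method))
  print(round(x$r, 3))
  invisible(x)
}

#' Pearson/Spearman sensitivity comparison
#'
#' Pairs each Pearson correlation with its Spearman counterpart (matched on
#' all shared label columns), ranks associations by `|r|` under each method
#' (within measure), and flags whether the top association per measure
#' agrees across methods — the operational check that the strongest
#' correlations are method-consistent.
#'
#' @param pearson,spearman data frames as returned by
#'   [blood_brain_correlations()] or [score_trait_correlations()], computed
#'   with the respective method on the same data.
#' @return Data frame with `r_pearson`, `r_spearman`, `rank_pearson`,
#'   `rank_spearman` per association and attribute `top_agreement`: a named
#'   logical per measure, TRUE when both methods rank the same association
#'   first.
#' @export
sensitivity_compare <- function(pearson, spearman) {
  keys <- setdiff(intersect(names(pearson), names(spearman)),
                  c("method", "r", "n", "p", "ci_lo", "ci_hi", "undefined"))
  if (!length(keys)) stop("no shared key columns", call. = FALSE)
  pe <- pearson[c(keys, "r", "n")]
  sp <- spearman[c(keys, "r")]
  names(pe)[names(pe) == "r"] <- "r_pearson"
  names(sp)[names(sp) == "r"] <- "r_spearman"
  out <- merge(pe, sp, by = keys, sort = FALSE)
  if (nrow(out) != nrow(pearson)) {
    stop("pearson and spearman sets do not pair one-to-one", call. = FALSE)
  }
  grp <- if ("measure" %in% keys) out$measure else rep("all", nrow(out))
  rk <- function(v) stats::ave(-abs(v), grp, FUN = rank)
  out$rank_pearson <- rk(out$r_pearson)
  out$rank_spearman <- rk(out$r_spearman)
  top <- vapply(split(out, grp), function(d) {
    which.max(abs(d$r_pearson)) == which.max(abs(d$r_spearman))
  }, TRUE)
  attr(out, "top_agreement") <- top
  out
}

# ---- power ------------------------------------------------------------------

#' Power of the two-sided Pearson correlation test
#'
#' Monte-Carlo estimate: `n_sims` bivariate-normal samples of size `n` at
#' true correlation `rho`, fraction with `p < alpha`. A closed-form
#' Fisher-z approximation (`power = P(|Z| > z_{alpha/2})` with
#' `Z ~ N(atanh(rho) * sqrt(n - 3), 1)`) is returned alongside as a
#' cross-check. Used to quantify why regression modelling is not attempted
#' at very small n.
#'
#' @param n sample size per simulated dataset (`n >= 4`).
#' @param rho true correlation in `[-1, 1]`.
#' @param alpha two-sided significance level, default 0.05.
#' @param n_sims Monte-Carlo replicates, default 2000.
#' @param seed integer seed (required for reproducibility).
#' @return A list of class `PowerEstimate`: `power` (Monte-Carlo), `se`
#'   (binomial MC standard error), `power_fisher` (closed form), plus the
#'   inputs.
#' @export
correlation_power <- function(n, rho, alpha = 0.05, n_sims = 2000, seed) {
  stopifnot(n >= 4, abs(rho) <= 1, alpha > 0, alpha < 1, n_sims >= 1)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  set.seed(seed)
  hits <- vapply(seq_len(n_sims), function(i) {
    x <- stats::rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
    correlate(x, y, "pearson")$p < alpha
  }, TRUE)
  mc <- mean(hits)
  za <- stats::qnorm(1 - alpha / 2)
  mu <- atanh(rho) * sqrt(n - 3)
  fisher <- stats::pnorm(-za + mu) + stats::pnorm(-za - mu)
  structure(list(power = mc, se = sqrt(mc * (1 - mc) / n_sims),
                 power_fisher = fisher, n = n, rho = rho, alpha = alpha,
                 n_sims = n_sims),
            class = "PowerEstimate")
}

#' @export
print.PowerEstimate <- function(x, ...) {
  cat(sprintf(
    "power(n = %d, rho = %.2f, alpha = %.3g): MC %.3f (se %.3f), Fisher-z %.3f\n",
    x$n, x$rho, x$alpha, x$power, x$se, x$power_fisher))
  invisible(x)
}
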
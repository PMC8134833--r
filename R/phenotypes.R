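# Lifestyle phenotype coding and derivation. Smoking status uses the cohort
# convention 0 = never, 1 = former, 2 = current. Pack years is
# cigarettes/day * years smoked / 20 (20 cigarettes per pack): the usual
# statement "packs per day * years / 20" double-converts if read literally,
# so the cigarettes-based form is implemented and documented here.

#' Validate a phenotype table
#'
#' Required columns: `individual_id`, `smoking_status` (0 never / 1 former /
#' 2 current). Recognised optional columns: `cigarettes_per_day`,
#' `age_started_smoking`, `age_stopped_or_current` (stop age for former
#' smokers, age at assessment for current smokers), `pack_years`,
#' `alcohol_units_week`, `bmi` (kg/m^2), `hdl` (mmol/l). Missing values are
#' `NA`.
#'
#' @param df data frame.
#' @return The validated data frame, classed `PhenotypeTable`.
#' @export
phenotype_table <- function(df) {
  need <- c("individual_id", "smoking_status")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$individual_id)) {
    stop("duplicate individual_id in phenotype table", call. = FALSE)
  }
  st <- df$smoking_status
  if (any(!is.na(st) & !st %in% 0:2)) {
    stop("smoking_status must be 0 (never), 1 (former) or 2 (current)",
         call. = FALSE)
  }
  nonneg <- intersect(c("cigarettes_per_day", "age_started_smoking",
                        "age_stopped_or_current", "pack_years",
                        "alcohol_units_week", "bmi", "hdl"), names(df))
  for (f in nonneg) {
    if (any(df[[f]] < 0, na.rm = TRUE)) {
      stop("negative values in '", f, "'", call. = FALSE)
    }
  }
  if ("pack_years" %in% names(df)) {
    bad <- !is.na(st) & st == 0 & !is.na(df$pack_years) & df$pack_years != 0
    if (any(bad)) stop("never-smokers must have pack_years 0", call. = FALSE)
  }
  class(df) <- c("PhenotypeTable", "data.frame")
  df
}

#' @rdname phenotype_table
#' @param path file path.
#' @param sep `"tab"` or `"comma"`.
#' @export
read_phenotype_table <- function(path, sep = "tab") {
  phenotype_table(.read_delim_table(path, .delim(sep)))
}

#' @rdname phenotype_table
#' @param phenos a `PhenotypeTable` to write.
#' @param header provenance header line.
#' @export
write_phenotype_table <- function(phenos, path, sep = "tab",
                                  header = provenance_header()) {
  .write_delim_table(as.data.frame(phenos), path, .delim(sep), header)
}

#' Derive smoking pack years
#'
#' `pack_years = cigarettes_per_day * years_smoked / 20`, with:
#' * never-smokers (`smoking_status == 0`) recorded as 0 regardless of other
#'   fields;
#' * a missing start age imputed with `cohort_mean_start_age` (the cohort
#'   convention is the group mean, 16 years);
#' * missing `cigarettes_per_day` left missing — such individuals are
#'   excluded from pack-years analyses, not imputed;
#' * years smoked = `age_stopped_or_current - age_started_smoking` (for
#'   current smokers the "stop" field holds the age at assessment); a former
#'   smoker without a stop age stays missing.
#'
#' All arguments are vectorized and recycled to a common length.
#'
#' @param smoking_status integer 0/1/2 (never/former/current).
#' @param cigarettes_per_day cigarettes smoked per day, or `NA`.
#' @param age_started_smoking start age in years, or `NA` (imputed).
#' @param age_stopped_or_current stop age (former) or assessment age
#'   (current), or `NA`.
#' @param cohort_mean_start_age imputation value for missing start ages,
#'   default 16.
#' @return Numeric vector of pack years (`NA` where underivable), with
#'   attribute `n_excluded` counting ever-smokers lost to missing
#'   `cigarettes_per_day`.
#' @export
derive_pack_years <- function(smoking_status, cigarettes_per_day = NA_real_,
                              age_started_smoking = NA_real_,
                              age_stopped_or_current = NA_real_,
                              cohort_mean_start_age = 16) {
  n <- max(length(smoking_status), length(cigarettes_per_day),
           length(age_started_smoking), length(age_stopped_or_current))
  st <- rep_len(as.numeric(smoking_status), n)
  cpd <- rep_len(as.numeric(cigarettes_per_day), n)
  a0 <- rep_len(as.numeric(age_started_smoking), n)
  a1 <- rep_len(as.numeric(age_stopped_or_current), n)
  if (any(!is.na(st) & !st %in% 0:2)) {
    stop("smoking_status must be 0, 1 or 2", call. = FALSE)
  }
  for (v in list(cpd, a0, a1)) {
    if (any(v < 0, na.rm = TRUE)) {
      stop("smoking inputs must be non-negative", call. = FALSE)
    }
  }
  a0 <- ifelse(is.na(a0) & !is.na(st) & st > 0, cohort_mean_start_age, a0)
  years <- a1 - a0
  if (any(years < 0, na.rm = TRUE)) {
    stop("negative smoking duration (stop age before start age)",
         call. = FALSE)
  }
  py <- cpd * years / 20
  py[!is.na(st) & st == 0] <- 0
  excluded <- !is.na(st) & st > 0 & is.na(cpd)
  structure(py, n_excluded = sum(excluded))
}

#' Add a derived `pack_years` column to a phenotype table
#'
#' @param phenos a [phenotype_table()].
#' @param cohort_mean_start_age see [derive_pack_years()].
#' @return The table with `pack_years` filled in; attribute
#'   `n_excluded_pack_years` records ever-smokers missing
#'   `cigarettes_per_day`.
#' @export
add_pack_years <- function(phenos, cohort_mean_start_age = 16) {
  phenos <- phenotype_table(as.data.frame(phenos))
  col <- function(f) if (f %in% names(phenos)) phenos[[f]] else NA_real_
  py <- derive_pack_years(phenos$smoking_status, col("cigarettes_per_day"),
                          col("age_started_smoking"),
                          col("age_stopped_or_current"),
                          cohort_mean_start_age)
  phenos$pack_years <- as.numeric(py)
  attr(phenos, "n_excluded_pack_years") <- attr(py, "n_excluded")
  class(phenos) <- c("PhenotypeTable", "data.frame")
  phenos
}

#' Summarize a phenotype cohort
#'
#' Per-field n (%), mean (SD) and unknown counts, in the layout of a cohort
#' characteristics table: smoking status split into current/former/never
#' with counts and percentages; pack years, alcohol units/week, BMI and HDL
#' as mean (SD) with unknown counts. SD is reported missing for n = 1.
#'
#' @param phenos a [phenotype_table()].
#' @return Data frame with columns `characteristic`, `n`, `percent`, `mean`,
#'   `sd`, `unknown`.
#' @export
summarize_cohort <- function(phenos) {
  phenos <- phenotype_table(as.data.frame(phenos))
  if (!nrow(phenos)) stop("need at least one record", call. = FALSE)
  N <- nrow(phenos)
  rows <- list()
  st <- phenos$smoking_status
  for (lab in c(current = 2, former = 1, never = 0)) {
    k <- sum(!is.na(st) & st == lab)
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = paste0("smoking_", names(which(c(current = 2,
                                                        former = 1,
                                                        never = 0) == lab))),
      n = k, percent = 100 * k / N, mean = NA_real_, sd = NA_real_,
      unknown = NA_integer_, stringsAsFactors = FALSE)
  }
  num_fields <- c(pack_years = "pack_years",
                  alcohol_units_week = "alcohol_units_week",
                  bmi = "bmi", hdl = "hdl")
  for (f in num_fields) {
    if (!f %in% names(phenos)) next
    x <- phenos[[f]]
    k <- sum(!is.na(x))
    rows[[length(rows) + 1L]] <- data.frame(
      characteristic = f, n = k, percent = NA_real_,
      mean = if (k) mean(x, na.rm = TRUE) else NA_real_,
      sd = if (k > 1L) stats::sd(x, na.rm = TRUE) else NA_real_,
      unknown = sum(is.na(x)), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
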
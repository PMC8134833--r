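#' @keywords internal
"_PACKAGE"

#' Recognised tissue labels
#'
#' Blood plus the five Brodmann-area brain regions handled by the pipeline:
#' BA17 (primary visual cortex), BA20/21 (inferior temporal cortex), BA24
#' (anterior cingulate cortex), BA35 (hippocampus) and BA46 (dorsolateral
#' prefrontal cortex).
#'
#' @format Character vectors.
#' @export
TISSUES <- c("blood", "BA17", "BA20/21", "BA24", "BA35", "BA46")

#' @rdname TISSUES
#' @export
BRAIN_REGIONS <- c("BA17", "BA20/21", "BA24", "BA35", "BA46")

#' Lifestyle traits with published blood-derived DNAm predictors
#' @export
TRAITS <- c("smoking", "HDL", "BMI", "alcohol")

#' The AHRR smoking probe, the strongest single blood DNAm correlate of smoking
#' @export
AHRR_PROBE <- "cg05575921"

PLATFORMS <- c("450K", "EPIC", "custom")

# ---- BetaMatrix -------------------------------------------------------------

#' Construct a validated BetaMatrix
#'
#' A `BetaMatrix` bundles a probes x samples matrix of methylation beta
#' values (fractions in `[0, 1]`, `NA` allowed) with optional same-shape
#' detection p-value and beadcount side-matrices used by the QC filters.
#' Probe identifiers are the rownames, sample identifiers the colnames; both
#' must be unique, and side-matrices must share the exact probe/sample
#' ordering of `values`.
#'
#' @param values numeric matrix, probes x samples, values in `[0, 1]` or `NA`.
#' @param detection_p optional numeric matrix of detection p-values in
#'   `[0, 1]`, same dimnames as `values`.
#' @param beadcount optional matrix of non-negative integer bead counts,
#'   same dimnames as `values`.
#' @param platform array platform label, one of `"450K"`, `"EPIC"`,
#'   `"custom"`. Metadata only: probe content, not the label, drives
#'   platform harmonization.
#' @return An object of class `BetaMatrix`.
#' @export
beta_matrix <- function(values, detection_p = NULL, beadcount = NULL,
                        platform = "custom") {
  platform <- match.arg(platform, PLATFORMS)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must carry probe rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    dup <- rownames(values)[duplicated(rownames(values))][1L]
    stop("duplicate probe id: ", dup, call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- colnames(values)[duplicated(colnames(values))][1L]
    stop("duplicate sample id: ", dup, call. = FALSE)
  }
  .check_unit_interval(values, "beta value")
  for (side in c("detection_p", "beadcount")) {
    sm <- get(side)
    if (is.null(sm)) next
    if (!is.matrix(sm) || !identical(dim(sm), dim(values)) ||
        !identical(dimnames(sm), dimnames(values))) {
      stop("'", side, "' must share the exact probe/sample ordering of ",
           "'values'", call. = FALSE)
    }
  }
  if (!is.null(detection_p)) .check_unit_interval(detection_p, "detection p")
  if (!is.null(beadcount) && any(beadcount < 0, na.rm = TRUE)) {
    stop("beadcount values must be non-negative", call. = FALSE)
  }
  structure(
    list(values = values, detection_p = detection_p, beadcount = beadcount,
         platform = platform),
    class = "BetaMatrix"
  )
}

# error names the offending probe/sample cell, as the QC trail requires
.check_unit_interval <- function(m, what) {
  bad <- which(m < 0 | m > 1)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(m))
    stop(sprintf("%s %.6g outside [0, 1] at probe '%s', sample '%s'",
                 what, m[bad[1L]], rownames(m)[i[1L]], colnames(m)[i[2L]]),
         call. = FALSE)
  }
  invisible(m)
}

#' @export
print.BetaMatrix <- function(x, ...) {
  cat(sprintf("BetaMatrix: %d probes x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$platform))
  cat(sprintf("  detection_p: %s | beadcount: %s\n",
              if (is.null(x$detection_p)) "absent" else "present",
              if (is.null(x$beadcount)) "absent" else "present"))
  invisible(x)
}

#' @export
dim.BetaMatrix <- function(x) dim(x$values)

#' Probe and sample identifiers of a BetaMatrix
#' @param m a `BetaMatrix`.
#' @return Character vector of identifiers.
#' @export
probe_ids <- function(m) rownames(m$values)

#' @rdname probe_ids
#' @export
sample_ids <- function(m) colnames(m$values)

#' Subset a BetaMatrix, keeping side-matrices aligned
#'
#' @param x a `BetaMatrix`.
#' @param i probe index (character, logical or integer).
#' @param j sample index.
#' @param ... ignored.
#' @export
`[.BetaMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  sub <- function(m) if (is.null(m)) NULL else m[i, j, drop = FALSE]
  beta_matrix(x$values[i, j, drop = FALSE], sub(x$detection_p),
              sub(x$beadcount), x$platform)
}

#' Combine BetaMatrix objects sample-wise
#'
#' Binds the samples of several matrices sharing an identical probe set into
#' one `BetaMatrix` (used e.g. to QC all brain regions jointly). Side
#' matrices are combined when present in every input, dropped otherwise.
#'
#' @param mats list of `BetaMatrix` objects with identical probe sets.
#' @param platform platform label of the result.
#' @return A single `BetaMatrix`.
#' @export
cbind_beta <- function(mats, platform = mats[[1L]]$platform) {
  stopifnot(length(mats) >= 1L, all(vapply(mats, inherits, TRUE, "BetaMatrix")))
  ref <- probe_ids(mats[[1L]])
  for (m in mats) {
    if (!identical(probe_ids(m), ref)) {
      stop("all matrices must share an identical probe set/order ",
           "(harmonize first)", call. = FALSE)
    }
  }
  bind <- function(field) {
    parts <- lapply(mats, `[[`, field)
    if (any(vapply(parts, is.null, TRUE))) return(NULL)
    do.call(cbind, parts)
  }
  beta_matrix(do.call(cbind, lapply(mats, `[[`, "values")),
              bind("detection_p"), bind("beadcount"), platform)
}

# ---- delimited I/O ----------------------------------------------------------

.delim <- function(sep = c("tab", "comma")) {
  switch(match.arg(sep), tab = "\t", comma = ",")
}

#' Provenance header for written artifacts
#'
#' Every file the package writes opens with one `#`-prefixed line recording
#' the tool version and the md5 of each input file, so a report can be traced
#' to its inputs. No timestamp is included: reruns with identical inputs and
#' seed must be byte-identical.
#'
#' @param inputs character vector of input file paths to hash (optional).
#' @param extra named character vector of extra key=value fields (e.g. seed).
#' @return A single `"# ..."` string.
#' @export
provenance_header <- function(inputs = character(), extra = character()) {
  ver <- as.character(utils::packageVersion("methbridge"))
  fields <- c(sprintf("methbridge=%s", ver))
  if (length(inputs)) {
    h <- tools::md5sum(inputs)
    fields <- c(fields, sprintf("md5(%s)=%s", basename(names(h)), unname(h)))
  }
  if (length(extra)) {
    fields <- c(fields, sprintf("%s=%s", names(extra), extra))
  }
  paste0("# ", paste(fields, collapse = " | "))
}

.read_delim_table <- function(path, sep) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), quote = "")
  if (!nrow(df) || !ncol(df)) stop("empty file: ", path, call. = FALSE)
  df
}

.write_delim_table <- function(df, path, sep, header = provenance_header(),
                               digits = 15L) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA_character_, format(x, digits = digits, trim = TRUE,
                                           scientific = NA))
  })
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = sep, quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

.matrix_to_df <- function(m, id_col = "probe_id") {
  cbind(stats::setNames(data.frame(rownames(m), stringsAsFactors = FALSE),
                        id_col),
        as.data.frame(m, check.names = FALSE))
}

.df_to_matrix <- function(df, what = "probe") {
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicate ", what, " id: ", ids[duplicated(ids)][1L], call. = FALSE)
  }
  body <- df[-1L]
  bad_col <- !vapply(body, function(x) is.numeric(x) || all(is.na(x)), TRUE)
  if (any(bad_col)) {
    stop("non-numeric values in column '", names(body)[bad_col][1L], "'",
         call. = FALSE)
  }
  m <- as.matrix(as.data.frame(lapply(body, as.numeric),
                               check.names = FALSE))
  dimnames(m) <- list(ids, names(body))
  m
}

#' Read a beta matrix (and optional QC side-matrices) from delimited text
#'
#' The expected layout is a header row of sample ids, a first column of CpG
#' probe ids, and beta values in `[0, 1]`. Empty cells and `NA` are parsed as
#' missing (never as 0: a beta of 0 is a meaningful measurement). Lines
#' starting `#` are provenance comments and are skipped.
#'
#' @param path path to the beta value file.
#' @param platform platform label (`"450K"`, `"EPIC"`, `"custom"`); metadata
#'   only.
#' @param detection_p_path,beadcount_path optional paths to same-shaped
#'   detection p-value / beadcount matrices.
#' @param sep `"tab"` (canonical) or `"comma"`.
#' @return A validated [beta_matrix()].
#' @export
read_beta_matrix <- function(path, platform = "custom",
                             detection_p_path = NULL, beadcount_path = NULL,
                             sep = "tab") {
  sc <- .delim(sep)
  vals <- .df_to_matrix(.read_delim_table(path, sc))
  rd_side <- function(p) {
    if (is.null(p)) return(NULL)
    m <- .df_to_matrix(.read_delim_table(p, sc))
    m[rownames(vals), colnames(vals), drop = FALSE]
  }
  beta_matrix(vals, rd_side(detection_p_path), rd_side(beadcount_path),
              platform)
}

#' Write a BetaMatrix to delimited text
#'
#' Values are written with 15 significant digits so a write/read round trip
#' preserves them beyond 10 significant digits. Side matrices, when present,
#' are written next to `path` with `.detp`/`.beadcount` inserted before the
#' extension.
#'
#' @param m a `BetaMatrix`.
#' @param path output path for the beta values.
#' @param sep `"tab"` or `"comma"`.
#' @param header provenance header line.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(m, path, sep = "tab",
                              header = provenance_header()) {
  stopifnot(inherits(m, "BetaMatrix"))
  sc <- .delim(sep)
  .write_delim_table(.matrix_to_df(m$values), path, sc, header)
  side_path <- function(tag) {
    sub("(\\.[^.]+)$", paste0(".", tag, "\\1"), path)
  }
  if (!is.null(m$detection_p)) {
    .write_delim_table(.matrix_to_df(m$detection_p), side_path("detp"), sc,
                       header)
  }
  if (!is.null(m$beadcount)) {
    .write_delim_table(.matrix_to_df(m$beadcount), side_path("beadcount"),
                       sc, header, digits = 8L)
  }
  invisible(path)
}

# ---- WeightTable ------------------------------------------------------------

#' Construct a predictor weight table
#'
#' A `WeightTable` holds the linear predictor for one lifestyle trait: a set
#' of CpG probes with signed coefficients (as produced by LASSO training in
#' an external blood cohort) plus an optional intercept. The per-sample
#' episcore is `intercept + sum_j w_j * beta_ij`.
#'
#' @param trait one of `"smoking"`, `"HDL"`, `"BMI"`, `"alcohol"`.
#' @param weights named numeric vector, names are CpG probe ids.
#' @param intercept numeric intercept, default 0.
#' @return An object of class `WeightTable`.
#' @export
weight_table <- function(trait, weights, intercept = 0) {
  trait <- match.arg(trait, TRAITS)
  if (!length(weights)) stop("weight table needs at least 1 entry",
                             call. = FALSE)
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("weights must be named by probe id", call. = FALSE)
  }
  if (anyDuplicated(names(weights))) {
    stop("duplicate probe id in weight table: ",
         names(weights)[duplicated(names(weights))][1L], call. = FALSE)
  }
  if (!all(is.finite(weights))) stop("weights must be finite", call. = FALSE)
  if (!is.finite(intercept)) stop("intercept must be finite", call. = FALSE)
  structure(list(trait = trait, weights = weights,
                 intercept = as.numeric(intercept)),
            class = "WeightTable")
}

#' @export
print.WeightTable <- function(x, ...) {
  cat(sprintf("WeightTable[%s]: %d CpGs, intercept %.4g\n",
              x$trait, length(x$weights), x$intercept))
  invisible(x)
}

#' @export
length.WeightTable <- function(x) length(x$weights)

#' Read a two-column (probe, coefficient) predictor weight file
#'
#' An optional intercept is recognised as a row whose probe id is
#' `"(Intercept)"` or `"intercept"` (case-insensitive). The entry count is
#' reported via [message()].
#'
#' @param path delimited file with columns probe id, coefficient (header
#'   optional but canonical files carry `probe_id<sep>weight`).
#' @param trait trait label for the resulting table.
#' @param sep `"tab"` or `"comma"`.
#' @return A [weight_table()].
#' @export
read_weight_table <- function(path, trait, sep = "tab") {
  df <- .read_delim_table(path, .delim(sep))
  if (ncol(df) < 2L) stop("weight file needs two columns (probe, weight)",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  w <- df[[2L]]
  if (!is.numeric(w)) stop("non-numeric coefficient in ", path, call. = FALSE)
  is_int <- tolower(ids) %in% c("(intercept)", "intercept")
  intercept <- if (any(is_int)) sum(w[is_int]) else 0
  w <- w[!is_int]
  names(w) <- ids[!is_int]
  wt <- weight_table(trait, w, intercept)
  message(sprintf("read %d weight entries for trait '%s' from %s",
                  length(w), trait, basename(path)))
  wt
}

#' @rdname read_weight_table
#' @param wt a `WeightTable` to write.
#' @param header provenance header line.
#' @export
write_weight_table <- function(wt, path, sep = "tab",
                               header = provenance_header()) {
  stopifnot(inherits(wt, "WeightTable"))
  df <- data.frame(probe_id = names(wt$weights), weight = unname(wt$weights),
                   stringsAsFactors = FALSE)
  if (wt$intercept != 0) {
    df <- rbind(df, data.frame(probe_id = "(Intercept)",
                               weight = wt$intercept))
  }
  .write_delim_table(df, path, .delim(sep), header)
}

# ---- SampleSheet ------------------------------------------------------------

#' Validate a sample sheet
#'
#' Columns: `sample_id`, `individual_id`, `tissue` (one of [TISSUES]),
#' `recorded_sex` (`"F"`, `"M"`, `"unknown"`). Each individual contributes at
#' most one sample per tissue.
#'
#' @param df data frame with the columns above.
#' @return The validated data frame, classed `SampleSheet`.
#' @export
sample_sheet <- function(df) {
  need <- c("sample_id", "individual_id", "tissue", "recorded_sex")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df[need] <- lapply(df[need], as.character)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  bad <- setdiff(unique(df$tissue), TISSUES)
  if (length(bad)) stop("unknown tissue label(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  bad_sex <- setdiff(unique(df$recorded_sex), c("F", "M", "unknown"))
  if (length(bad_sex)) stop("recorded_sex must be F, M or unknown",
                            call. = FALSE)
  key <- paste(df$individual_id, df$tissue)
  if (anyDuplicated(key)) {
    stop("duplicate (individual_id, tissue) pair: ", key[duplicated(key)][1L],
         call. = FALSE)
  }
  class(df) <- c("SampleSheet", "data.frame")
  df
}

#' @rdname sample_sheet
#' @param path file path.
#' @param sep `"tab"` or `"comma"`.
#' @export
read_sample_sheet <- function(path, sep = "tab") {
  sample_sheet(.read_delim_table(path, .delim(sep)))
}

#' @rdname sample_sheet
#' @param sheet a `SampleSheet` to write.
#' @param header provenance header line.
#' @export
write_sample_sheet <- function(sheet, path, sep = "tab",
                               header = provenance_header()) {
  .write_delim_table(as.data.frame(sheet), path, .delim(sep), header)
}

# ---- score / report tables --------------------------------------------------

#' Read or write a ScoreTable
#'
#' Columns: `sample_id`, `trait`, `score`, `n_cpgs_used`, `coverage`.
#'
#' @param scores a `ScoreTable` data frame (from [project_scores()]).
#' @param path file path.
#' @param sep `"tab"` or `"comma"`.
#' @param header provenance header line.
#' @export
write_score_table <- function(scores, path, sep = "tab",
                              header = provenance_header()) {
  .write_delim_table(as.data.frame(scores), path, .delim(sep), header)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path, sep = "tab") {
  df <- .read_delim_table(path, .delim(sep))
  need <- c("sample_id", "trait", "score", "n_cpgs_used", "coverage")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("score table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  class(df) <- c("ScoreTable", "data.frame")
  df
}

#' Write a correlation report
#'
#' One row per correlation: `measure`, `tissue_x`, `tissue_y` (or trait),
#' `method`, `r`, `n`, `p`, `ci_lo`, `ci_hi`.
#'
#' @param report data frame of correlation rows.
#' @param path file path.
#' @param sep `"tab"` or `"comma"`.
#' @param header provenance header line.
#' @export
write_correlation_report <- function(report, path, sep = "tab",
                                     header = provenance_header()) {
  .write_delim_table(as.data.frame(report), path, .delim(sep), header)
}

#' Read a plain-text probe blacklist (one probe id per line)
#'
#' @param path text file; `#` lines are comments.
#' @return Character vector of probe ids.
#' @export
read_blacklist <- function(path) {
  x <- readLines(path)
  x <- trimws(x[!startsWith(trimws(x), "#")])
  unique(x[nzchar(x)])
}
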
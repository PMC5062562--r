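#' Column dialect for feature tables
#'
#' Real feature-extraction exports carry dozens of columns under vendor
#' names; `quadarray` reads a minimal canonical set and a dialect maps the
#' canonical names onto whatever the file's header uses, so genuine exports
#' can be adapted without rewriting them.
#'
#' @param probe_id,replicate_index,gps,manual_flag,outlier_flag,pixel_cv,is_control
#'   Column names in the file for, respectively: the probe identifier, the
#'   on-chip replicate index (1-4), the processed signal (gProcessedSignal,
#'   RU), the manual flag (0/1), the software outlier flag (0/1), the
#'   per-feature pixel-intensity coefficient of variation, and the control
#'   status (0/1).
#' @return An object of class `feature_dialect`.
#' @examples
#' feature_dialect()
#' @export
feature_dialect <- function(probe_id = "ProbeName",
                            replicate_index = "ReplicateIndex",
                            gps = "gProcessedSignal",
                            manual_flag = "IsManualFlag",
                            outlier_flag = "IsOutlier",
                            pixel_cv = "PixelCV",
                            is_control = "IsControl") {
  d <- list(probe_id = probe_id, replicate_index = replicate_index,
            gps = gps, manual_flag = manual_flag,
            outlier_flag = outlier_flag, pixel_cv = pixel_cv,
            is_control = is_control)
  stopifnot(vapply(d, function(x) is.character(x) && length(x) == 1L,
                   logical(1)))
  structure(d, class = "feature_dialect")
}

#' Construct a per-sample array table
#'
#' One `array_table` holds the metadata and all physical features of a
#' single scanned array. Non-control probes may occur at most once per
#' replicate index (at most four features per probe); control features are
#' not required to carry replicate structure.
#'
#' @param sample_id Sample identifier (unique within a dataset).
#' @param strain Mouse strain label, one of `"BALBC"`, `"B6"`.
#' @param subset Cell-subset label, one of `"iNKT1"`, `"iNKT2"`, `"iNKT17"`,
#'   `"CD4neg_iNKT1"`, `"CD4pos_iNKT1"`, `"other"`.
#' @param experiment_id Biological-replicate identifier (e.g. `"Exp1"`).
#' @param features `data.frame` with columns `probe_id`, `replicate_index`,
#'   `gps`, `manual_flag`, `outlier_flag`, `pixel_cv`, `is_control`.
#' @return A validated object of class `array_table`.
#' @export
array_table <- function(sample_id, strain, subset, experiment_id, features) {
  x <- structure(list(sample_id = as.character(sample_id),
                      strain = as.character(strain),
                      subset = as.character(subset),
                      experiment_id = as.character(experiment_id),
                      features = features),
                 class = "array_table")
  validate_array_table(x)
}

.strain_levels <- c("BALBC", "B6")
.subset_levels <- c("iNKT1", "iNKT2", "iNKT17",
                    "CD4neg_iNKT1", "CD4pos_iNKT1", "other")
.feature_cols <- c("probe_id", "replicate_index", "gps",
                   "manual_flag", "outlier_flag", "pixel_cv", "is_control")

#' Validate an array table
#'
#' Checks metadata levels and the feature invariants: non-negative signal
#' and pixel CV, replicate indices in 1..4, each non-control probe printed
#' at most four times with distinct replicate indices, and at least one
#' non-control feature present.
#'
#' @param x An `array_table`.
#' @return `x`, invisibly unchanged, or an error describing the violation.
#' @export
validate_array_table <- function(x) {
  if (!inherits(x, "array_table")) stop("not an array_table")
  if (!x$strain %in% .strain_levels)
    stop("unknown strain '", x$strain, "' (expected ",
         paste(.strain_levels, collapse = ", "), ")")
  if (!x$subset %in% .subset_levels)
    stop("unknown subset '", x$subset, "' (expected ",
         paste(.subset_levels, collapse = ", "), ")")
  f <- x$features
  if (!is.data.frame(f)) stop("features must be a data.frame")
  miss <- setdiff(.feature_cols, names(f))
  if (length(miss))
    stop("features table lacks column(s): ", paste(miss, collapse = ", "))
  if (!is.numeric(f$gps) || anyNA(f$gps))
    stop("gps must be numeric and non-missing")
  bad <- which(f$gps < 0)
  if (length(bad))
    stop("negative gps in feature row ", bad[1L])
  bad <- which(f$pixel_cv < 0 | is.na(f$pixel_cv))
  if (length(bad))
    stop("invalid pixel_cv in feature row ", bad[1L])
  ri <- f$replicate_index
  bad <- which(is.na(ri) | ri != as.integer(ri) | ri < 1L | ri > 4L)
  if (length(bad))
    stop("replicate_index outside 1..4 in feature row ", bad[1L])
  for (col in c("manual_flag", "outlier_flag", "is_control"))
    if (!is.logical(f[[col]]) || anyNA(f[[col]]))
      stop(col, " must be logical and non-missing")
  nc <- f[!f$is_control, , drop = FALSE]
  if (nrow(nc) == 0L)
    stop("no non-control features present")
  key <- paste(nc$probe_id, nc$replicate_index, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    stop("duplicate (probe_id, replicate_index): ",
         sub("\r", " / replicate ", d, fixed = TRUE))
  }
  cnt <- table(nc$probe_id)
  if (any(cnt > 4L))
    stop("probe '", names(cnt)[which(cnt > 4L)[1L]],
         "' occurs more than 4 times among non-control features")
  invisible(x)
}

#' @export
print.array_table <- function(x, ...) {
  cat("array_table:", x$sample_id,
      sprintf("(%s %s %s)", x$strain, x$subset, x$experiment_id), "\n")
  f <- x$features
  cat(sprintf("  %d features (%d non-control probes, %d control features)\n",
              nrow(f), length(unique(f$probe_id[!f$is_control])),
              sum(f$is_control)))
  invisible(x)
}

#' Read a tab-delimited feature table
#'
#' Reads one array's feature table (one row per physical feature) into a
#' validated [array_table()]. Rows violating the invariants abort the read
#' with an error naming the offense; nothing is silently dropped.
#'
#' @param path Path to the TSV file.
#' @param dialect A [feature_dialect()] mapping canonical column roles to
#'   file column names.
#' @param sample_id,strain,subset,experiment_id Sample metadata (normally
#'   supplied by the sidecar metadata table, see [read_sample_metadata()]).
#' @return An `array_table`.
#' @export
read_feature_table <- function(path, dialect = feature_dialect(),
                               sample_id = basename(path),
                               strain = "BALBC", subset = "other",
                               experiment_id = "Exp1") {
  if (!file.exists(path)) stop("feature table not found: ", path)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = "NA", colClasses = NA)
  missing_cols <- setdiff(unlist(dialect), names(raw))
  if (length(missing_cols))
    stop("feature table format error: missing required column(s) ",
         paste(missing_cols, collapse = ", "), " in ", path)
  to_flag <- function(v, name) {
    if (is.logical(v)) return(v)
    v <- suppressWarnings(as.numeric(v))
    if (anyNA(v) || !all(v %in% c(0, 1)))
      stop("column ", name, " must be 0/1")
    v == 1
  }
  f <- data.frame(
    probe_id = as.character(raw[[dialect$probe_id]]),
    replicate_index = as.integer(raw[[dialect$replicate_index]]),
    gps = as.numeric(raw[[dialect$gps]]),
    manual_flag = to_flag(raw[[dialect$manual_flag]], dialect$manual_flag),
    outlier_flag = to_flag(raw[[dialect$outlier_flag]], dialect$outlier_flag),
    pixel_cv = as.numeric(raw[[dialect$pixel_cv]]),
    is_control = to_flag(raw[[dialect$is_control]], dialect$is_control),
    stringsAsFactors = FALSE
  )
  array_table(sample_id, strain, subset, experiment_id, f)
}

#' Write a feature table
#'
#' Inverse of [read_feature_table()]: writes the canonical tab-separated
#' feature table (flags encoded 0/1) so that a read-back round trip
#' reproduces the features.
#'
#' @param table An `array_table`.
#' @param path Output path.
#' @param dialect Column dialect used for the header.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, dialect = feature_dialect()) {
  validate_array_table(table)
  f <- table$features
  out <- data.frame(
    a = f$probe_id, b = f$replicate_index,
    c = sprintf("%.17g", f$gps),
    d = as.integer(f$manual_flag), e = as.integer(f$outlier_flag),
    f = sprintf("%.17g", f$pixel_cv), g = as.integer(f$is_control),
    stringsAsFactors = FALSE
  )
  names(out) <- unlist(dialect)[c("probe_id", "replicate_index", "gps",
                                  "manual_flag", "outlier_flag",
                                  "pixel_cv", "is_control")]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read the sample metadata sidecar table
#'
#' @param path TSV with required columns `SampleID`, `Strain`, `Subset`,
#'   `ExperimentID`, `FeatureFile` (feature-table path, relative paths are
#'   resolved against the metadata file's directory).
#' @return A `data.frame`, one row per sample.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  m <- utils::read.delim(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  req <- c("SampleID", "Strain", "Subset", "ExperimentID", "FeatureFile")
  miss <- setdiff(req, names(m))
  if (length(miss))
    stop("metadata format error: missing required column(s) ",
         paste(miss, collapse = ", "))
  if (nrow(m) == 0L) stop("metadata file lists no samples")
  if (anyDuplicated(m$SampleID))
    stop("duplicate SampleID in metadata: ",
         m$SampleID[duplicated(m$SampleID)][1L])
  m
}

#' Read a full set of arrays described by a metadata table
#'
#' @param metadata_path Path to the sidecar metadata TSV.
#' @param dialect Column dialect for the feature tables.
#' @return Named list of `array_table`s (names are sample ids).
#' @export
read_array_set <- function(metadata_path, dialect = feature_dialect()) {
  meta <- read_sample_metadata(metadata_path)
  base <- dirname(metadata_path)
  out <- vector("list", nrow(meta))
  names(out) <- meta$SampleID
  for (i in seq_len(nrow(meta))) {
    fp <- meta$FeatureFile[i]
    if (!file.exists(fp)) fp <- file.path(base, meta$FeatureFile[i])
    out[[i]] <- read_feature_table(fp, dialect,
                                   sample_id = meta$SampleID[i],
                                   strain = meta$Strain[i],
                                   subset = meta$Subset[i],
                                   experiment_id = meta$ExperimentID[i])
  }
  out
}

.validate_expression_matrix <- function(mat, floor = NULL) {
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("expression matrix must be a numeric matrix")
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix must carry probe and sample names")
  if (anyDuplicated(rownames(mat))) stop("duplicated probe_ids")
  if (anyDuplicated(colnames(mat))) stop("duplicated sample_ids")
  v <- mat[!is.na(mat)]
  if (any(v <= 0)) stop("expression values must be positive")
  if (!is.null(floor) && length(v) && min(v) < floor)
    stop("expression value below the surrogate floor of ", floor)
  invisible(mat)
}

#' Write an expression matrix to TSV
#'
#' Probes as rows, samples as columns, `NA` for missing values, full
#' (17 significant digit) precision so that [read_expression_matrix()]
#' reproduces the matrix bit-exactly.
#'
#' @param mat Numeric matrix with probe rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(mat, path) {
  .validate_expression_matrix(mat)
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) stop("cannot write to ", path, ": ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste(c("ProbeID", colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1L, function(r)
    paste(ifelse(is.na(r), "NA", sprintf("%.17g", r)), collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Read an expression matrix written by [write_expression_matrix()]
#'
#' @param path TSV path.
#' @return Numeric matrix, probes x samples.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression matrix not found: ", path)
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE,
                         na.strings = "NA")
  if (names(d)[1L] != "ProbeID")
    stop("expression matrix format error: first column must be ProbeID")
  mat <- as.matrix(d[, -1L, drop = FALSE])
  rownames(mat) <- d$ProbeID
  storage.mode(mat) <- "double"
  .validate_expression_matrix(mat)
  mat
}
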
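#' Preprocessing configuration
#'
#' Houses the constants of the feature-level processing procedure: the
#' reference 75th-percentile value the whole series is scaled to (1500 RU),
#' the surrogate intensity floor (20 RU), the interquartile-range fence
#' multiplier for replicate-outlier exclusion (1.42), and the maximal
#' tolerated pixel-intensity coefficient of variation (0.5).
#'
#' @param reference_percentile_value Reference value the chosen percentile
#'   of every array is scaled to. Default 1500 RU.
#' @param percentile Percentile (in percent) used for global linear
#'   scaling. Default 75.
#' @param surrogate_floor Lower intensity threshold; collapsed values below
#'   it are substituted by it. Default 20 RU.
#' @param iqr_multiplier Fence width, in interquartile ranges, of the
#'   within-quadruplicate outlier rule. Default 1.42.
#' @param pixel_cv_max Maximal pixel-intensity coefficient of variation per
#'   feature. Default 0.5.
#' @param quantile_convention `"linear_interpolation"` (interpolation
#'   between order statistics; `stats::quantile` type 7) or
#'   `"nearest_rank"` (type 1). Applied uniformly to the scaling percentile
#'   and to the quartiles of the fence rule.
#' @param fence_convention `"quartile_fences"` for the Tukey-style interval
#'   `[Q1 - k*IQR, Q3 + k*IQR]`, or `"median_centered"` for
#'   `[median - k*IQR, median + k*IQR]`.
#' @param floor_stage `"post_collapse"` (floor the collapsed per-probe
#'   value; default) or `"pre_collapse"` (floor each surviving replicate
#'   before averaging; provided for sensitivity analysis).
#' @return An object of class `pipeline_config`.
#' @examples
#' pipeline_config()
#' @export
pipeline_config <- function(reference_percentile_value = 1500,
                            percentile = 75,
                            surrogate_floor = 20,
                            iqr_multiplier = 1.42,
                            pixel_cv_max = 0.5,
                            quantile_convention = c("linear_interpolation",
                                                    "nearest_rank"),
                            fence_convention = c("quartile_fences",
                                                 "median_centered"),
                            floor_stage = c("post_collapse",
                                            "pre_collapse")) {
  quantile_convention <- match.arg(quantile_convention)
  fence_convention <- match.arg(fence_convention)
  floor_stage <- match.arg(floor_stage)
  num <- c(reference_percentile_value = reference_percentile_value,
           surrogate_floor = surrogate_floor,
           iqr_multiplier = iqr_multiplier,
           pixel_cv_max = pixel_cv_max)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all thresholds must be strictly positive")
  if (!is.finite(percentile) || percentile <= 0 || percentile >= 100)
    stop("percentile must lie in (0, 100)")
  structure(list(reference_percentile_value = reference_percentile_value,
                 percentile = percentile,
                 surrogate_floor = surrogate_floor,
                 iqr_multiplier = iqr_multiplier,
                 pixel_cv_max = pixel_cv_max,
                 quantile_convention = quantile_convention,
                 fence_convention = fence_convention,
                 floor_stage = floor_stage),
            class = "pipeline_config")
}

#' Quantile under the configured convention
#'
#' All percentile and quartile computations of the pipeline go through this
#' one function so the convention is applied consistently.
#'
#' @param x Numeric vector.
#' @param probs Probabilities in `[0, 1]`.
#' @param config A [pipeline_config()].
#' @return Quantiles, unnamed.
#' @export
qa_quantile <- function(x, probs, config = pipeline_config()) {
  type <- switch(config$quantile_convention,
                 linear_interpolation = 7L,
                 nearest_rank = 1L)
  stats::quantile(x, probs = probs, type = type, names = FALSE)
}

#' Array-specific global linear scaling factor
#'
#' The factor is the reference percentile value divided by the observed
#' percentile (default: 75th) of the array's raw non-control processed
#' signals; multiplying every signal by it places all arrays of a series on
#' a common intensity scale.
#'
#' @param raw_gps_values Raw processed-signal values of one array (all
#'   non-control on-chip replicates, before any exclusion).
#' @param config A [pipeline_config()].
#' @return The positive scaling factor.
#' @examples
#' x <- c(10, 20, 1500, 1500, 1500)   # P75 = 1500
#' compute_scaling_factor(x)          # 1
#' @export
compute_scaling_factor <- function(raw_gps_values, config = pipeline_config()) {
  x <- raw_gps_values[!is.na(raw_gps_values)]
  if (!length(x)) stop("no signal values supplied")
  if (any(x < 0)) stop("raw gps values must be non-negative")
  if (!any(x > 0)) stop("degenerate array: all signal values are zero")
  p <- qa_quantile(x, config$percentile / 100, config)
  if (p <= 0)
    stop("degenerate array: the ", config$percentile,
         "th percentile of the signal is not positive")
  config$reference_percentile_value / p
}

#' Apply a scaling factor to an array table
#'
#' Multiplies every feature's processed signal (controls included) by the
#' factor; flags, pixel CVs and feature order are untouched.
#'
#' @param table An `array_table`.
#' @param factor Positive scaling factor.
#' @return The scaled `array_table`.
#' @export
apply_normalization <- function(table, factor) {
  if (!is.numeric(factor) || length(factor) != 1L || !is.finite(factor) ||
      factor <= 0)
    stop("scaling factor must be a single positive number")
  table$features$gps <- table$features$gps * factor
  table
}

#' Exclude unreliable members of an on-chip replicate group
#'
#' Applies the four exclusion rules in order, first match wins:
#' (i) manually flagged; (ii) flagged as outlier by the extraction
#' software; (iii) normalized value outside the interquartile-range fences
#' of the replicate group (quartiles over the members surviving rules i-ii,
#' candidate included); (iv) pixel-intensity coefficient of variation above
#' the cutoff.
#'
#' @param gps Normalized signal values of the group members (1-4 values).
#' @param manual_flag,outlier_flag Logical vectors, recycled if length 1.
#' @param pixel_cv Numeric vector of pixel CVs, recycled if length 1.
#' @param config A [pipeline_config()].
#' @return A list with `keep` (logical), `reason` (character, `NA` for
#'   survivors, otherwise one of `"manual_flag"`, `"software_outlier"`,
#'   `"iqr_fence"`, `"pixel_cv"`), and the fence `bounds` used (or `NULL`
#'   when no member reached rule iii).
#' @export
exclude_replicates <- function(gps, manual_flag = FALSE, outlier_flag = FALSE,
                               pixel_cv = 0, config = pipeline_config()) {
  n <- length(gps)
  if (n < 1L) stop("replicate group is empty")
  if (n > 4L) stop("replicate group has more than 4 members")
  manual_flag <- rep_len(as.logical(manual_flag), n)
  outlier_flag <- rep_len(as.logical(outlier_flag), n)
  pixel_cv <- rep_len(as.numeric(pixel_cv), n)
  if (anyNA(gps) || any(gps < 0)) stop("invalid normalized gps values")
  reason <- rep(NA_character_, n)
  reason[manual_flag] <- "manual_flag"
  reason[is.na(reason) & outlier_flag] <- "software_outlier"
  bounds <- NULL
  cand <- is.na(reason)
  if (any(cand)) {
    v <- gps[cand]
    q <- qa_quantile(v, c(0.25, 0.5, 0.75), config)
    iqr <- q[3L] - q[1L]
    bounds <- switch(config$fence_convention,
                     quartile_fences = c(q[1L] - config$iqr_multiplier * iqr,
                                         q[3L] + config$iqr_multiplier * iqr),
                     median_centered = c(q[2L] - config$iqr_multiplier * iqr,
                                         q[2L] + config$iqr_multiplier * iqr))
    out <- cand & (gps < bounds[1L] | gps > bounds[2L])
    reason[out] <- "iqr_fence"
  }
  cv_bad <- is.na(reason) & pixel_cv > config$pixel_cv_max
  reason[cv_bad] <- "pixel_cv"
  list(keep = is.na(reason), reason = reason, bounds = bounds)
}

#' Geometric-mean collapse of surviving replicate values
#'
#' @param surviving_values Positive normalized values of the surviving
#'   members; may be empty.
#' @return The geometric mean, or `NA` for an empty set.
#' @examples
#' collapse_replicates(c(10, 1000))   # 100
#' @export
collapse_replicates <- function(surviving_values) {
  if (!length(surviving_values)) return(NA_real_)
  if (anyNA(surviving_values) || any(surviving_values <= 0))
    stop("geometric mean undefined: values must be strictly positive")
  exp(mean(log(surviving_values)))
}

#' Substitute the surrogate intensity floor
#'
#' Values below the lower intensity threshold are replaced by it; missing
#' values stay missing (the floor is a threshold, not an imputation).
#'
#' @param value Numeric vector of collapsed values (may contain `NA`).
#' @param config A [pipeline_config()].
#' @return Floored values.
#' @examples
#' apply_floor(c(5, 20, 1500, NA))   # 20 20 1500 NA
#' @export
apply_floor <- function(value, config = pipeline_config()) {
  pmax(value, config$surrogate_floor)
}

#' Preprocess a single array
#'
#' Runs the full per-sample procedure: compute the scaling factor from all
#' raw non-control signals, scale the array, apply the four exclusion rules
#' within each probe's on-chip replicate group, collapse survivors by
#' geometric mean, and floor the result. Deterministic; an audit trail of
#' every exclusion is returned.
#'
#' @param table An `array_table`.
#' @param config A [pipeline_config()].
#' @return A list with `sample_id`, `values` (named numeric vector, one
#'   entry per non-control probe in order of first appearance, `NA` when
#'   every member was excluded), `normalization` (sample id, observed
#'   percentile, scaling factor), `exclusions` (data.frame: probe_id,
#'   replicate_index, reason, value), and `counts`.
#' @export
preprocess_sample <- function(table, config = pipeline_config()) {
  validate_array_table(table)
  f <- table$features
  nc <- f[!f$is_control, , drop = FALSE]
  observed <- qa_quantile(nc$gps, config$percentile / 100, config)
  factor <- compute_scaling_factor(nc$gps, config)
  norm_gps <- nc$gps * factor
  probes <- unique(nc$probe_id)
  idx <- split(seq_len(nrow(nc)), factor(nc$probe_id, levels = probes))
  values <- rep(NA_real_, length(probes))
  names(values) <- probes
  exc_probe <- character(0); exc_rep <- integer(0)
  exc_reason <- character(0); exc_value <- numeric(0)
  pre_floor <- identical(config$floor_stage, "pre_collapse")
  for (k in seq_along(idx)) {
    i <- idx[[k]]
    ex <- exclude_replicates(norm_gps[i], nc$manual_flag[i],
                             nc$outlier_flag[i], nc$pixel_cv[i], config)
    if (!all(ex$keep)) {
      j <- which(!ex$keep)
      exc_probe <- c(exc_probe, rep(probes[k], length(j)))
      exc_rep <- c(exc_rep, nc$replicate_index[i][j])
      exc_reason <- c(exc_reason, ex$reason[j])
      exc_value <- c(exc_value, norm_gps[i][j])
    }
    surv <- norm_gps[i][ex$keep]
    if (pre_floor && length(surv)) surv <- apply_floor(surv, config)
    values[k] <- collapse_replicates(surv)
  }
  values <- apply_floor(values, config)
  exclusions <- data.frame(probe_id = exc_probe, replicate_index = exc_rep,
                           reason = exc_reason, value = exc_value,
                           stringsAsFactors = FALSE)
  counts <- c(features_read = nrow(f),
              noncontrol_features = nrow(nc),
              excluded_manual = sum(exc_reason == "manual_flag"),
              excluded_software = sum(exc_reason == "software_outlier"),
              excluded_iqr = sum(exc_reason == "iqr_fence"),
              excluded_cv = sum(exc_reason == "pixel_cv"),
              surviving_features = nrow(nc) - length(exc_reason),
              probes_collapsed = sum(!is.na(values)),
              probes_missing = sum(is.na(values)),
              probes_floored = sum(!is.na(values) &
                                     values == config$surrogate_floor))
  list(sample_id = table$sample_id,
       values = values,
       normalization = list(sample_id = table$sample_id,
                            observed_percentile = observed,
                            scaling_factor = factor),
       exclusions = exclusions,
       counts = counts)
}

#' Preprocess a set of arrays into an expression matrix
#'
#' Applies [preprocess_sample()] to every array and assembles the collapsed
#' per-probe values into a probes x samples matrix (probe order taken from
#' the union of the arrays in order of first appearance).
#'
#' @param tables Named list of `array_table`s.
#' @param config A [pipeline_config()].
#' @return A list with `expression` (matrix), `normalization` (data.frame
#'   with observed percentile and scaling factor per sample), `exclusions`
#'   (data.frame with a `sample_id` column), and `counts` (matrix,
#'   samples x counters).
#' @export
preprocess_dataset <- function(tables, config = pipeline_config()) {
  if (!length(tables)) stop("no arrays supplied")
  res <- lapply(tables, preprocess_sample, config = config)
  ids <- vapply(res, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("duplicate sample ids across arrays")
  probes <- unique(unlist(lapply(res, function(r) names(r$values)),
                          use.names = FALSE))
  mat <- matrix(NA_real_, nrow = length(probes), ncol = length(res),
                dimnames = list(probes, ids))
  for (j in seq_along(res))
    mat[names(res[[j]]$values), j] <- res[[j]]$values
  norm <- do.call(rbind, lapply(res, function(r)
    data.frame(sample_id = r$normalization$sample_id,
               observed_percentile = r$normalization$observed_percentile,
               scaling_factor = r$normalization$scaling_factor,
               stringsAsFactors = FALSE)))
  rownames(norm) <- NULL
  exc <- do.call(rbind, lapply(seq_along(res), function(j) {
    e <- res[[j]]$exclusions
    e <- cbind(sample_id = rep(ids[j], nrow(e)), e,
               stringsAsFactors = FALSE)
    e
  }))
  rownames(exc) <- NULL
  counts <- do.call(rbind, lapply(res, `[[`, "counts"))
  rownames(counts) <- ids
  list(expression = mat, normalization = norm,
       exclusions = exc, counts = counts)
}

#' Write / read a flat key-value pipeline configuration (YAML)
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `path` invisibly for the writer; a `pipeline_config` for the
#'   reader. Unknown keys in the file are rejected.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(vals), c(known, "expression_floor",
                                  "fold_threshold"))
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  do.call(pipeline_config, vals[intersect(names(vals), known)])
}
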
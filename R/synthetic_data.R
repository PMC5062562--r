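#' Parameters of the synthetic array generator
#'
#' The generator emulates the structure of a one-color series with on-chip
#' quadruplicate features across strains, cell subsets and independent
#' experiments: log-normal expression, planted subset-specific probes at a
#' fixed fold, planted negligible and sub-floor probes, multiplicative
#' replicate noise, planted value outliers, manual/software flags, high
#' pixel-CV members, and per-array global scale differences that the
#' normalization step must undo.
#'
#' @param n_probes Number of non-control probes. Default 2000 (desk scale;
#'   the emulated design carries roughly 32000).
#' @param n_control_probes Control features per array (single copies).
#' @param replicates_per_probe On-chip replicates per non-control probe.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of the
#'   expressed ("shared") probe baseline, clipped into an expressed band
#'   away from the classification floor.
#' @param frac_unique_per_pair Fraction of probes planted as specific to
#'   each subset (applied once per subset).
#' @param planted_fold Fold elevation of a subset-specific probe in its
#'   subset. Default 4.
#' @param frac_negligible Fraction of probes planted below the 500 RU
#'   expression floor in every subset.
#' @param frac_subfloor Fraction of probes planted below the 20 RU
#'   surrogate floor (values drawn uniformly in (1, 15)) in every subset.
#' @param replicate_noise_log_sd s.d. of the log-normal replicate noise.
#' @param outlier_rate Per-feature probability of a planted value outlier.
#' @param outlier_magnitude Multiplicative magnitude of planted outliers
#'   (applied up or down at random).
#' @param flag_rate Per-feature probability of a planted manual flag, and
#'   independently of a planted software outlier flag.
#' @param high_cv_rate Per-feature probability of a planted pixel CV above
#'   the 0.5 cutoff.
#' @param strains,subsets,experiments Sample-design labels; one array is
#'   generated per combination.
#' @param array_scale_log_sd s.d. of the log-normal per-array raw scale
#'   factor (makes the raw 75th percentiles differ between arrays).
#' @param seed Integer seed; the full output is reproducible from it.
#' @return An object of class `generator_params`.
#' @export
generator_params <- function(n_probes = 2000L,
                             n_control_probes = 100L,
                             replicates_per_probe = 4L,
                             baseline_log_mean = log(1600),
                             baseline_log_sd = 1,
                             frac_unique_per_pair = 0.015,
                             planted_fold = 4,
                             frac_negligible = 0.55,
                             frac_subfloor = 0.03,
                             replicate_noise_log_sd = 0.05,
                             outlier_rate = 0.01,
                             outlier_magnitude = 8,
                             flag_rate = 0.005,
                             high_cv_rate = 0.005,
                             strains = c("BALBC", "B6"),
                             subsets = c("iNKT1", "iNKT2", "iNKT17"),
                             experiments = c("Exp1", "Exp2"),
                             array_scale_log_sd = 0.25,
                             seed = 1L) {
  p <- list(n_probes = as.integer(n_probes),
            n_control_probes = as.integer(n_control_probes),
            replicates_per_probe = as.integer(replicates_per_probe),
            baseline_log_mean = baseline_log_mean,
            baseline_log_sd = baseline_log_sd,
            frac_unique_per_pair = frac_unique_per_pair,
            planted_fold = planted_fold,
            frac_negligible = frac_negligible,
            frac_subfloor = frac_subfloor,
            replicate_noise_log_sd = replicate_noise_log_sd,
            outlier_rate = outlier_rate,
            outlier_magnitude = outlier_magnitude,
            flag_rate = flag_rate,
            high_cv_rate = high_cv_rate,
            strains = strains, subsets = subsets,
            experiments = experiments,
            array_scale_log_sd = array_scale_log_sd,
            seed = as.integer(seed))
  if (p$n_probes < 1L) stop("n_probes must be positive")
  if (p$replicates_per_probe < 1L || p$replicates_per_probe > 4L)
    stop("replicates_per_probe must lie in 1..4")
  if (p$planted_fold <= 1) stop("planted_fold must exceed 1")
  fr <- c(p$frac_unique_per_pair, p$frac_negligible, p$frac_subfloor,
          p$outlier_rate, p$flag_rate, p$high_cv_rate)
  if (any(fr < 0) || any(fr > 1)) stop("fractions must lie in [0, 1]")
  if (p$frac_unique_per_pair * length(p$subsets) + p$frac_negligible +
      p$frac_subfloor > 1)
    stop("infeasible fractions: planted classes exceed the probe set")
  if (p$replicate_noise_log_sd < 0 || p$array_scale_log_sd < 0)
    stop("noise s.d. must be non-negative")
  if (length(p$subsets) < 2L) stop("need at least 2 subsets")
  structure(p, class = "generator_params")
}

# The planted class bands keep multiplicative margins around the 20 RU
# surrogate floor and the 500 RU classification floor: sub-floor in (1, 15),
# negligible in (25, 350), expressed shared clipped to [700, 40000], unique
# bases in [2000, 8000]. With the default fractions the noiseless 75th
# percentile of a column sits near the 1500 RU reference, so normalization
# leaves planted values close to their planted scale and the margins absorb
# both the residual scaling and the replicate noise.

# deterministic per-probe substream: adding probes never shifts the draws
# of existing probes
.probe_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 1103515245 * as.numeric(i)) %% 2147483647)
}

#' Generate a synthetic array set with planted ground truth
#'
#' One array is produced per strain x subset x experiment combination. The
#' planted per-probe expression mean is identical across strains and
#' experiments; replicate-level noise, outliers, flags and per-array scale
#' factors differ. Ground truth records the planted class of every probe,
#' its noiseless expression mean per subset, the pairwise category implied
#' by those means under the default classification rule, and the position
#' of every planted artifact.
#'
#' @param params A [generator_params()].
#' @return A list with `arrays` (named list of `array_table`s), `metadata`
#'   (data.frame as read by [read_sample_metadata()], `FeatureFile` left
#'   `NA` until written), and `truth` (planted classes, means, pairwise
#'   categories, artifact positions, sub-floor probes, per-array scale
#'   factors, and the `params` used).
#' @export
generate_dataset <- function(params = generator_params()) {
  stopifnot(inherits(params, "generator_params"))
  p <- params
  design <- expand.grid(strain = p$strains, subset = p$subsets,
                        experiment = p$experiments,
                        stringsAsFactors = FALSE)
  design <- design[order(design$strain, design$experiment, design$subset), ]
  rownames(design) <- NULL
  design$sample_id <- paste(design$strain, design$subset,
                            design$experiment, sep = "_")
  n_samples <- nrow(design)
  n_sub <- length(p$subsets)
  reps <- p$replicates_per_probe

  # array-level draws from the base stream
  set.seed(p$seed)
  array_scale <- exp(stats::rnorm(n_samples, 0, p$array_scale_log_sd))
  names(array_scale) <- design$sample_id
  control_vals <- NULL
  if (p$n_control_probes > 0L)
    control_vals <- matrix(exp(stats::runif(p$n_control_probes * n_samples,
                                            log(20), log(8000))),
                           nrow = p$n_control_probes)

  probe_ids <- sprintf("P_%05d", seq_len(p$n_probes))
  class_breaks <- cumsum(c(p$frac_subfloor, p$frac_negligible,
                           rep(p$frac_unique_per_pair, n_sub)))
  expr_lo <- 4 * 500            # expressed band for planted unique probes
  expr_hi <- 8000

  means <- matrix(NA_real_, nrow = p$n_probes, ncol = n_sub,
                  dimnames = list(probe_ids, p$subsets))
  classes <- character(p$n_probes)
  unique_subset <- rep(NA_character_, p$n_probes)
  noise <- matrix(1, nrow = n_samples * reps, ncol = p$n_probes)
  out_mult <- matrix(1, nrow = n_samples * reps, ncol = p$n_probes)
  man_flag <- matrix(FALSE, nrow = n_samples * reps, ncol = p$n_probes)
  sw_flag <- matrix(FALSE, nrow = n_samples * reps, ncol = p$n_probes)
  cv <- matrix(NA_real_, nrow = n_samples * reps, ncol = p$n_probes)

  ndraw <- n_samples * reps
  for (i in seq_len(p$n_probes)) {
    set.seed(.probe_seed(p$seed, i))
    u <- stats::runif(1)
    k <- findInterval(u, class_breaks) + 1L   # 1 subfloor, 2 negligible,
    if (k == 1L) {                            # 2+j unique to subset j, else shared
      classes[i] <- "subfloor"
      means[i, ] <- stats::runif(1, 1, 15)
    } else if (k == 2L) {
      classes[i] <- "negligible"
      means[i, ] <- exp(stats::runif(1, log(25), log(350)))
    } else if (k <= 2L + n_sub) {
      j <- k - 2L
      classes[i] <- "unique"
      unique_subset[i] <- p$subsets[j]
      base <- exp(stats::runif(1, log(expr_lo), log(expr_hi)))
      means[i, ] <- base
      means[i, j] <- base * p$planted_fold
    } else {
      classes[i] <- "shared"
      base <- exp(pmin(pmax(stats::rnorm(1, p$baseline_log_mean,
                                         p$baseline_log_sd),
                            log(700)), log(40000)))
      means[i, ] <- base
    }
    if (p$replicate_noise_log_sd > 0)
      noise[, i] <- exp(stats::rnorm(ndraw, 0, p$replicate_noise_log_sd))
    if (p$outlier_rate > 0) {
      hit <- stats::runif(ndraw) < p$outlier_rate
      if (any(hit))
        out_mult[hit, i] <- p$outlier_magnitude ^
          (sign(stats::runif(sum(hit)) - 0.5))
    }
    if (p$flag_rate > 0) {
      man_flag[, i] <- stats::runif(ndraw) < p$flag_rate
      sw_flag[, i] <- stats::runif(ndraw) < p$flag_rate
    }
    cv[, i] <- stats::runif(ndraw, 0.01, 0.3)
    if (p$high_cv_rate > 0) {
      hit <- stats::runif(ndraw) < p$high_cv_rate
      cv[hit, i] <- stats::runif(sum(hit), 0.55, 1.2)
    }
  }

  arrays <- vector("list", n_samples)
  names(arrays) <- design$sample_id
  positions <- list()
  for (s in seq_len(n_samples)) {
    rows <- (s - 1L) * reps + seq_len(reps)
    subset_col <- match(design$subset[s], p$subsets)
    value <- means[, subset_col][col(noise[rows, , drop = FALSE])] *
      noise[rows, , drop = FALSE] * out_mult[rows, , drop = FALSE]
    raw <- as.vector(value) * array_scale[s]   # column-major: reps fastest
    f <- data.frame(
      probe_id = rep(probe_ids, each = reps),
      replicate_index = rep(seq_len(reps), times = p$n_probes),
      gps = raw,
      manual_flag = as.vector(man_flag[rows, , drop = FALSE]),
      outlier_flag = as.vector(sw_flag[rows, , drop = FALSE]),
      pixel_cv = as.vector(cv[rows, , drop = FALSE]),
      is_control = FALSE,
      stringsAsFactors = FALSE
    )
    if (p$n_control_probes > 0L) {
      f <- rbind(f, data.frame(
        probe_id = sprintf("CTRL_%04d", seq_len(p$n_control_probes)),
        replicate_index = 1L,
        gps = control_vals[, s] * array_scale[s],
        manual_flag = FALSE, outlier_flag = FALSE,
        pixel_cv = 0.1, is_control = TRUE,
        stringsAsFactors = FALSE))
    }
    arrays[[s]] <- array_table(design$sample_id[s], design$strain[s],
                               design$subset[s], design$experiment[s], f)
    art <- data.frame(
      probe_id = rep(probe_ids, each = reps),
      replicate_index = rep(seq_len(reps), times = p$n_probes),
      value_outlier = as.vector(out_mult[rows, , drop = FALSE]) != 1,
      manual_flag = as.vector(man_flag[rows, , drop = FALSE]),
      software_flag = as.vector(sw_flag[rows, , drop = FALSE]),
      high_cv = as.vector(cv[rows, , drop = FALSE]) > 0.5,
      stringsAsFactors = FALSE)
    art <- art[art$value_outlier | art$manual_flag | art$software_flag |
                 art$high_cv, , drop = FALSE]
    if (nrow(art)) {
      rownames(art) <- NULL
      positions[[design$sample_id[s]]] <-
        cbind(sample_id = rep(design$sample_id[s], nrow(art)), art,
              stringsAsFactors = FALSE)
    }
  }
  positions <- if (length(positions)) {
    out <- do.call(rbind, positions); rownames(out) <- NULL; out
  } else NULL

  cc <- classify_config()
  pairs <- utils::combn(p$subsets, 2L, simplify = FALSE)
  pair_truth <- do.call(rbind, lapply(pairs, function(pr) {
    calls <- classify_gene_pair(means[, pr[1L]], means[, pr[2L]], cc)
    data.frame(probe_id = probe_ids,
               pair = paste(pr, collapse = ":"),
               category = calls$category, stringsAsFactors = FALSE)
  }))

  metadata <- data.frame(SampleID = design$sample_id,
                         Strain = design$strain,
                         Subset = design$subset,
                         ExperimentID = design$experiment,
                         FeatureFile = NA_character_,
                         stringsAsFactors = FALSE)
  truth <- list(params = p,
                classes = data.frame(probe_id = probe_ids, class = classes,
                                     unique_subset = unique_subset,
                                     stringsAsFactors = FALSE),
                means = means,
                pair_truth = pair_truth,
                positions = positions,
                subfloor_probes = probe_ids[classes == "subfloor"],
                array_scale = array_scale)
  list(arrays = arrays, metadata = metadata, truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Emits one feature TSV per array, the sidecar metadata TSV, the planted
#' truth tables, and the generator parameters (YAML), in the formats the
#' reading functions consume.
#'
#' @param dataset Output of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @param dialect Feature-table column dialect.
#' @return The metadata file path, invisibly.
#' @export
write_dataset <- function(dataset, dir, dialect = feature_dialect()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meta <- dataset$metadata
  meta$FeatureFile <- paste0("features_", meta$SampleID, ".tsv")
  for (i in seq_len(nrow(meta)))
    write_feature_table(dataset$arrays[[meta$SampleID[i]]],
                        file.path(dir, meta$FeatureFile[i]), dialect)
  meta_path <- file.path(dir, "metadata.tsv")
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(dataset$truth$classes,
                     file.path(dir, "truth_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth$pair_truth,
                     file.path(dir, "truth_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  yaml::write_yaml(unclass(dataset$truth$params),
                   file.path(dir, "generator_params.yaml"))
  invisible(meta_path)
}

#' Generate two seeded groups for decision-tree calibration
#'
#' @param effect_size Location shift of group B, in units of the
#'   distribution's s.d. (0 gives exchangeable null groups).
#' @param n_a,n_b Group sizes (>= 2).
#' @param distribution `"normal"`, `"exponential"` (unit rate), or
#'   `"lognormal"` (sdlog 1).
#' @param seed Integer seed.
#' @return List with `group_a`, `group_b`.
#' @export
generate_group_samples <- function(effect_size = 0, n_a, n_b,
                                   distribution = c("normal", "exponential",
                                                    "lognormal"),
                                   seed = 1L) {
  distribution <- match.arg(distribution)
  if (n_a < 2L || n_b < 2L) stop("group sizes must be at least 2")
  set.seed(as.integer(seed))
  draw <- switch(distribution,
                 normal = function(n) stats::rnorm(n),
                 exponential = function(n) stats::rexp(n),
                 lognormal = function(n) stats::rlnorm(n))
  sd1 <- switch(distribution, normal = 1, exponential = 1,
                lognormal = sqrt((exp(1) - 1) * exp(1)))
  list(group_a = draw(n_a), group_b = draw(n_b) + effect_size * sd1)
}
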
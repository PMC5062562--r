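.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full pipeline on a described array set
#'
#' Reads the arrays listed in a metadata table, preprocesses them into an
#' expression matrix (scaling, exclusion, collapse, floor), classifies all
#' subset pairs per strain and experiment, aggregates Venn counts across
#' experiments, and writes the matrix, reports, audit log and a JSON run
#' manifest to `out_dir`. Deterministic: re-running on identical inputs
#' reproduces byte-identical matrices and reports.
#'
#' @param metadata_path Sidecar metadata TSV (see [read_sample_metadata()]).
#' @param out_dir Output directory, created if needed.
#' @param config A [pipeline_config()], or `NULL` to read `config_path`.
#' @param config_path Optional YAML config file; flat keys for
#'   [pipeline_config()] plus optional `expression_floor` /
#'   `fold_threshold` for the classification step.
#' @param classify_cfg A [classify_config()] (overridden by config-file
#'   keys when present).
#' @param dialect Feature-table column dialect.
#' @param pairs Optional list of length-2 subset vectors to classify;
#'   default: all pairs of subsets present within each strain.
#' @return Invisibly, a list with `expression`, `normalization`,
#'   `exclusions`, `counts`, `summaries` (venn_summary objects), `venn`
#'   (aggregated data.frame), `manifest`, and the output `paths`.
#' @export
run_pipeline <- function(metadata_path, out_dir,
                         config = pipeline_config(), config_path = NULL,
                         classify_cfg = classify_config(),
                         dialect = feature_dialect(), pairs = NULL) {
  if (!is.null(config_path)) {
    config <- .stage("config", read_pipeline_config(config_path))
    extra <- yaml::read_yaml(config_path)
    if (!is.null(extra$expression_floor) || !is.null(extra$fold_threshold))
      classify_cfg <- classify_config(
        expression_floor = extra$expression_floor %||%
          classify_cfg$expression_floor,
        fold_threshold = extra$fold_threshold %||%
          classify_cfg$fold_threshold)
  }
  meta <- .stage("read_metadata", read_sample_metadata(metadata_path))
  arrays <- .stage("read_features", read_array_set(metadata_path, dialect))
  pre <- .stage("preprocess", preprocess_dataset(arrays, config))

  summaries <- .stage("classify", {
    out <- list()
    for (strain in unique(meta$Strain)) {
      sub_meta <- meta[meta$Strain == strain, , drop = FALSE]
      subs <- unique(sub_meta$Subset)
      prs <- pairs %||% (if (length(subs) >= 2L)
        utils::combn(subs, 2L, simplify = FALSE) else list())
      for (pr in prs)
        for (exp_id in unique(sub_meta$ExperimentID)) {
          if (!all(pr %in% sub_meta$Subset[sub_meta$ExperimentID == exp_id]))
            next
          key <- paste(strain, paste(pr, collapse = ":"), exp_id, sep = "|")
          out[[key]] <- venn_summary(pre$expression, sub_meta, pr, exp_id,
                                     strain = strain, config = classify_cfg)
        }
    }
    out
  })

  venn <- .stage("aggregate", {
    if (!length(summaries)) NULL else {
      grp <- vapply(summaries, function(s)
        paste(s$strain, paste(s$pair, collapse = ":"), sep = "|"),
        character(1))
      rows <- lapply(split(summaries, grp), function(ss) {
        agg <- summarize_across_experiments(unname(ss))
        cbind(strain = ss[[1L]]$strain,
              pair = paste(ss[[1L]]$pair, collapse = ":"),
              agg, stringsAsFactors = FALSE)
      })
      out <- do.call(rbind, rows[order(names(rows))])
      rownames(out) <- NULL
      out
    }
  })

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    expression = file.path(out_dir, "expression_matrix.tsv"),
    normalization = file.path(out_dir, "normalization.tsv"),
    audit = file.path(out_dir, "exclusion_audit.tsv"),
    classification = file.path(out_dir, "classification_report.tsv"),
    venn = file.path(out_dir, "venn_report.tsv"),
    manifest = file.path(out_dir, "run_manifest.json"))
  .stage("write_outputs", {
    write_expression_matrix(pre$expression, paths$expression)
    norm <- pre$normalization
    norm$observed_percentile <- sprintf("%.17g", norm$observed_percentile)
    norm$scaling_factor <- sprintf("%.17g", norm$scaling_factor)
    utils::write.table(norm, paths$normalization, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    exc <- pre$exclusions
    if (nrow(exc)) exc$value <- sprintf("%.17g", exc$value)
    utils::write.table(exc, paths$audit, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    if (length(summaries))
      write_classification_report(summaries, paths$classification)
    if (!is.null(venn)) {
      v <- venn
      v$mean <- sprintf("%.17g", v$mean)
      v$sd <- sprintf("%.17g", v$sd)
      utils::write.table(v, paths$venn, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  })

  manifest <- .stage("manifest", {
    feature_files <- vapply(seq_len(nrow(meta)), function(i) {
      fp <- meta$FeatureFile[i]
      if (!file.exists(fp)) fp <- file.path(dirname(metadata_path),
                                            meta$FeatureFile[i])
      fp
    }, character(1))
    digests <- as.list(tools::md5sum(c(metadata_path, feature_files)))
    counts <- pre$counts
    m <- list(
      package = "quadarray",
      version = as.character(utils::packageVersion("quadarray")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      config = unclass(config),
      classify_config = unclass(classify_cfg),
      inputs = digests,
      samples = rownames(counts),
      stage_counts = as.list(as.data.frame(counts)),
      totals = as.list(colSums(counts)),
      n_probes_classified = if (length(summaries))
        sum(vapply(summaries, `[[`, numeric(1), "total")) else 0
    )
    jsonlite::write_json(m, paths$manifest, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    m
  })

  invisible(list(expression = pre$expression,
                 normalization = pre$normalization,
                 exclusions = pre$exclusions,
                 counts = pre$counts,
                 summaries = summaries,
                 venn = venn,
                 manifest = manifest,
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
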
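#' Classification configuration
#'
#' @param expression_floor Expression level (RU) below which a probe is
#'   considered negligibly expressed in a pairwise comparison. Default 500.
#' @param fold_threshold Fold-change (max/min ratio) above which a probe
#'   expressed in at least one subset of a pair is called subset-specific.
#'   Default 2 ("more than twofold", strict).
#' @return An object of class `classify_config`.
#' @export
classify_config <- function(expression_floor = 500, fold_threshold = 2) {
  if (!is.finite(expression_floor) || expression_floor <= 0)
    stop("expression_floor must be positive")
  if (!is.finite(fold_threshold) || fold_threshold <= 1)
    stop("fold_threshold must exceed 1")
  structure(list(expression_floor = expression_floor,
                 fold_threshold = fold_threshold),
            class = "classify_config")
}

#' Pairwise subtype-specificity call for one probe (vectorized)
#'
#' A probe compared between subsets A and B is `negligible` when both
#' values lie below the expression floor, `unique_A`/`unique_B` when at
#' least one value reaches the floor and the max/min fold exceeds the
#' threshold (the higher side names the subset), and `shared` otherwise
#' (expressed, less than threshold-fold apart). Values exactly at the floor
#' count as expressed; a fold exactly at the threshold is shared.
#'
#' @param value_a,value_b Positive expression values (RU); vectors of equal
#'   length are classified elementwise.
#' @param config A [classify_config()].
#' @return A data.frame with `value_a`, `value_b`, `fold`, `category`.
#' @examples
#' classify_gene_pair(c(100, 600, 1200), c(300, 400, 400))
#' @export
classify_gene_pair <- function(value_a, value_b, config = classify_config()) {
  if (length(value_a) != length(value_b))
    stop("value_a and value_b must have equal length")
  if (anyNA(value_a) || anyNA(value_b) ||
      any(value_a <= 0) || any(value_b <= 0))
    stop("expression values must be positive and non-missing")
  fl <- config$expression_floor
  fold <- pmax(value_a, value_b) / pmin(value_a, value_b)
  category <- ifelse(value_a < fl & value_b < fl, "negligible",
                     ifelse(fold > config$fold_threshold,
                            ifelse(value_a > value_b, "unique_A", "unique_B"),
                            "shared"))
  data.frame(value_a = unname(value_a), value_b = unname(value_b),
             fold = unname(fold), category = unname(category),
             stringsAsFactors = FALSE)
}

.find_sample <- function(metadata, subset, experiment, strain) {
  hit <- metadata$Subset == subset & metadata$ExperimentID == experiment
  if (!is.null(strain)) hit <- hit & metadata$Strain == strain
  ids <- metadata$SampleID[hit]
  if (length(ids) == 0L)
    stop("missing sample: no array for subset ", subset,
         ", experiment ", experiment,
         if (!is.null(strain)) paste0(", strain ", strain))
  if (length(ids) > 1L)
    stop("ambiguous sample lookup for subset ", subset, ", experiment ",
         experiment, "; supply strain")
  ids
}

#' Pairwise Venn summary for one experiment
#'
#' Classifies every probe of the expression matrix for one ordered subset
#' pair within one experiment (and optionally one strain) and counts the
#' categories. Probes missing in either sample are excluded from the total
#' and reported separately as `n_unclassifiable`.
#'
#' @param mat Expression matrix (probes x samples).
#' @param metadata Sample metadata data.frame (columns `SampleID`,
#'   `Strain`, `Subset`, `ExperimentID`).
#' @param pair Character vector of two subset labels `(A, B)`.
#' @param experiment Experiment (biological replicate) identifier.
#' @param strain Optional strain label to disambiguate the lookup.
#' @param config A [classify_config()].
#' @return An object of class `venn_summary`: pair, experiment, strain,
#'   counts (`n_negligible`, `n_shared`, `n_unique_a`, `n_unique_b`,
#'   `n_unclassifiable`, `total`) and the per-probe `calls` data.frame.
#' @export
venn_summary <- function(mat, metadata, pair, experiment, strain = NULL,
                         config = classify_config()) {
  stopifnot(length(pair) == 2L)
  id_a <- .find_sample(metadata, pair[1L], experiment, strain)
  id_b <- .find_sample(metadata, pair[2L], experiment, strain)
  for (id in c(id_a, id_b))
    if (!id %in% colnames(mat))
      stop("missing sample: ", id, " not present in the expression matrix")
  a <- mat[, id_a]; b <- mat[, id_b]
  ok <- !is.na(a) & !is.na(b)
  calls <- classify_gene_pair(a[ok], b[ok], config)
  calls <- cbind(probe_id = rownames(mat)[ok], calls,
                 stringsAsFactors = FALSE)
  tab <- table(factor(calls$category,
                      levels = c("negligible", "shared",
                                 "unique_A", "unique_B")))
  structure(list(pair = pair, experiment = experiment, strain = strain,
                 sample_a = id_a, sample_b = id_b,
                 n_negligible = unname(tab[["negligible"]]),
                 n_shared = unname(tab[["shared"]]),
                 n_unique_a = unname(tab[["unique_A"]]),
                 n_unique_b = unname(tab[["unique_B"]]),
                 n_unclassifiable = sum(!ok),
                 total = sum(ok),
                 calls = calls),
            class = "venn_summary")
}

#' @export
print.venn_summary <- function(x, ...) {
  cat(sprintf("venn_summary %s vs %s (%s%s)\n", x$pair[1L], x$pair[2L],
              x$experiment,
              if (is.null(x$strain)) "" else paste0(", ", x$strain)))
  cat(sprintf("  negligible %d | shared %d | unique %s %d | unique %s %d | unclassifiable %d\n",
              x$n_negligible, x$n_shared, x$pair[1L], x$n_unique_a,
              x$pair[2L], x$n_unique_b, x$n_unclassifiable))
  invisible(x)
}

#' Mean and s.d. of Venn counts across independent experiments
#'
#' @param summaries List of `venn_summary` objects for the same subset
#'   pair (one per experiment).
#' @return data.frame with `category`, `mean`, `sd` (sample s.d., n-1
#'   denominator; 0 when a single experiment is supplied), `n_experiments`.
#' @export
summarize_across_experiments <- function(summaries) {
  if (!length(summaries)) stop("no summaries supplied")
  stopifnot(all(vapply(summaries, inherits, logical(1), "venn_summary")))
  pairs <- vapply(summaries, function(s) paste(s$pair, collapse = "|"),
                  character(1))
  if (length(unique(pairs)) != 1L)
    stop("summaries mix different subset pairs: ",
         paste(unique(pairs), collapse = " vs "))
  cats <- c(negligible = "n_negligible", shared = "n_shared",
            unique_A = "n_unique_a", unique_B = "n_unique_b")
  vals <- vapply(summaries, function(s) unlist(s[cats]),
                 numeric(length(cats)))
  vals <- matrix(vals, nrow = length(cats))
  m <- rowMeans(vals)
  s <- if (ncol(vals) > 1L) apply(vals, 1L, stats::sd) else rep(0, length(m))
  data.frame(category = names(cats), mean = m, sd = s,
             n_experiments = length(summaries),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export a (optionally row-standardized) submatrix for heat-map rendering
#'
#' Plain matrix export replacing interactive heat-map tooling: selects
#' probes and samples and optionally log2-transforms and z-scores each row
#' (mean 0, s.d. 1; zero-variance rows are emitted as all zero).
#'
#' @param mat Expression matrix.
#' @param probes,samples Row / column selections (must exist).
#' @param row_scaling `"none"` or `"log2_zscore"`.
#' @param path Optional TSV output path.
#' @return The (scaled) submatrix, invisibly when `path` is given.
#' @export
export_heatmap_matrix <- function(mat, probes = rownames(mat),
                                  samples = colnames(mat),
                                  row_scaling = c("none", "log2_zscore"),
                                  path = NULL) {
  row_scaling <- match.arg(row_scaling)
  bad <- setdiff(probes, rownames(mat))
  if (length(bad)) stop("unknown probe(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(samples, colnames(mat))
  if (length(bad)) stop("unknown sample(s): ", paste(bad, collapse = ", "))
  sub <- mat[probes, samples, drop = FALSE]
  if (row_scaling == "log2_zscore") {
    l <- log2(sub)
    mu <- rowMeans(l, na.rm = TRUE)
    sd <- apply(l, 1L, stats::sd, na.rm = TRUE)
    z <- (l - mu) / sd
    z[sd == 0 | is.na(sd), ] <- 0
    sub <- z
  }
  if (!is.null(path)) {
    write_expression_matrix_raw(sub, path)
    return(invisible(sub))
  }
  sub
}

# like write_expression_matrix but without the positivity validation
# (z-scored rows are signed)
write_expression_matrix_raw <- function(mat, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste(c("ProbeID", colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1L, function(r)
    paste(ifelse(is.na(r), "NA", sprintf("%.17g", r)), collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Write the per-probe classification report
#'
#' @param summaries List of `venn_summary` objects.
#' @param path TSV output path (columns probe_id, pair, strain, experiment,
#'   value_a, value_b, fold, category).
#' @return `path`, invisibly.
#' @export
write_classification_report <- function(summaries, path) {
  rows <- lapply(summaries, function(s)
    data.frame(probe_id = s$calls$probe_id,
               pair = paste(s$pair, collapse = ":"),
               strain = if (is.null(s$strain)) NA_character_ else s$strain,
               experiment = s$experiment,
               value_a = sprintf("%.17g", s$calls$value_a),
               value_b = sprintf("%.17g", s$calls$value_b),
               fold = sprintf("%.17g", s$calls$fold),
               category = s$calls$category,
               stringsAsFactors = FALSE))
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
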
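#' Configuration of the two-group testing decision tree
#'
#' @param alpha_normality Significance level of the normality gate.
#'   Default 0.05.
#' @param normality_test `"lilliefors"` (Kolmogorov-Smirnov against a
#'   normal with estimated mean and s.d., Lilliefors-corrected p; default)
#'   or `"ks"` (plain Kolmogorov-Smirnov with estimated parameters).
#' @param t_variant `"student"` (classic unpaired equal-variance t-test;
#'   default) or `"welch"`.
#' @return An object of class `stats_config`.
#' @export
stats_config <- function(alpha_normality = 0.05,
                         normality_test = c("lilliefors", "ks"),
                         t_variant = c("student", "welch")) {
  if (!is.finite(alpha_normality) || alpha_normality <= 0 ||
      alpha_normality >= 1)
    stop("alpha_normality must lie in (0, 1)")
  structure(list(alpha_normality = alpha_normality,
                 normality_test = match.arg(normality_test),
                 t_variant = match.arg(t_variant)),
            class = "stats_config")
}

.normality_p <- function(x, config) {
  if (stats::sd(x) == 0) return(0)       # degenerate: treat as non-normal
  if (config$normality_test == "lilliefors")
    nortest::lillie.test(x)$p.value
  else
    suppressWarnings(stats::ks.test(x, "pnorm", mean(x),
                                    stats::sd(x))$p.value)
}

#' Select the two-group test
#'
#' The sample-size gate comes first: with 4 or fewer values in either
#' group the Mann-Whitney U test is used regardless of the data. With more
#' than 4 per group, both groups are checked for normality; only if both
#' pass at `alpha_normality` is the unpaired t-test chosen, otherwise
#' Mann-Whitney.
#'
#' @param group_a,group_b Numeric vectors (each of length >= 2).
#' @param config A [stats_config()].
#' @return `"mann_whitney"` or `"t_test"`.
#' @export
select_test <- function(group_a, group_b, config = stats_config()) {
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 values")
  if (min(length(group_a), length(group_b)) <= 4L) return("mann_whitney")
  pa <- .normality_p(group_a, config)
  pb <- .normality_p(group_b, config)
  if (pa > config$alpha_normality && pb > config$alpha_normality)
    "t_test" else "mann_whitney"
}

#' Significance tier for a p-value
#'
#' Star convention: `NS` for p > 0.05, `*` for p < 0.05, `**` for
#' p < 0.01, `***` for p < 0.001 (a p of exactly 0.05 is NS).
#'
#' @param p p-value in `[0, 1]`.
#' @return Character tier.
#' @export
significance_tier <- function(p) {
  ifelse(p < 0.001, "***",
         ifelse(p < 0.01, "**",
                ifelse(p < 0.05, "*", "NS")))
}

#' Run the gated two-group comparison
#'
#' Applies [select_test()] and computes the two-tailed p-value of the
#' selected test. The Mann-Whitney test is exact when both groups have at
#' most 8 values and there are no ties, and uses the tie- and
#' continuity-corrected normal approximation otherwise. Fully tied data
#' (every value identical) short-circuits to p = 1 with a degenerate flag.
#'
#' @param group_a,group_b Numeric vectors (each of length >= 2).
#' @param config A [stats_config()].
#' @return An object of class `test_result`: `test_used`,
#'   `normality_checked`, `normality_p` (length-2 vector or `NULL`),
#'   `p_value`, `n_a`, `n_b`, `tier`, `degenerate`.
#' @examples
#' run_comparison(c(1, 2, 3), c(10, 11, 12))   # exact Mann-Whitney, p = 0.1
#' @export
run_comparison <- function(group_a, group_b, config = stats_config()) {
  n_a <- length(group_a); n_b <- length(group_b)
  if (n_a < 2L || n_b < 2L)
    stop("each group needs at least 2 values")
  gated <- min(n_a, n_b) <= 4L
  norm_p <- NULL
  if (gated) {
    test <- "mann_whitney"
  } else {
    norm_p <- c(a = .normality_p(group_a, config),
                b = .normality_p(group_b, config))
    test <- if (all(norm_p > config$alpha_normality)) "t_test"
            else "mann_whitney"
  }
  degenerate <- length(unique(c(group_a, group_b))) == 1L
  if (degenerate) {
    p <- 1
    warning("all values tied across both groups; reporting p = 1")
  } else if (test == "t_test") {
    p <- stats::t.test(group_a, group_b,
                       var.equal = config$t_variant == "student")$p.value
  } else {
    ties <- anyDuplicated(c(group_a, group_b)) > 0L
    exact <- !ties && n_a <= 8L && n_b <= 8L
    p <- suppressWarnings(
      stats::wilcox.test(group_a, group_b, exact = exact,
                         correct = TRUE)$p.value)
  }
  structure(list(test_used = test,
                 normality_checked = !gated,
                 normality_p = norm_p,
                 p_value = p,
                 n_a = n_a, n_b = n_b,
                 tier = significance_tier(p),
                 degenerate = degenerate),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  lab <- c(mann_whitney = "two-tailed Mann-Whitney U",
           t_test = "unpaired two-tailed t-test")[x$test_used]
  cat(sprintf("%s (n = %d vs %d): P = %.4g  %s\n",
              lab, x$n_a, x$n_b, x$p_value, x$tier))
  if (x$normality_checked)
    cat(sprintf("  normality p: %.3g / %.3g\n",
                x$normality_p[1L], x$normality_p[2L]))
  if (x$degenerate)
    cat("  (degenerate: all values tied)\n")
  invisible(x)
}

#' Compare two groups read from a two-column TSV
#'
#' @param path TSV with columns `group` (exactly two labels) and `value`.
#' @param config A [stats_config()].
#' @return A `test_result` with an added `groups` attribute (the two
#'   labels, in order of first appearance; the first is `group_a`).
#' @export
run_comparison_file <- function(path, config = stats_config()) {
  d <- utils::read.delim(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("group", "value") %in% names(d)))
    stop("group table must have columns 'group' and 'value'")
  labs <- unique(d$group)
  if (length(labs) != 2L)
    stop("group table must contain exactly 2 group labels, found ",
         length(labs))
  res <- run_comparison(d$value[d$group == labs[1L]],
                        d$value[d$group == labs[2L]], config)
  attr(res, "groups") <- labs
  res
}
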
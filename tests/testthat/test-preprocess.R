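test_that("scaling factor equals reference over the observed percentile", {
  cfg <- pipeline_config()
  x <- c(10, 20, 1500, 1500, 1500)       # P75 = 1500
  expect_equal(compute_scaling_factor(x, cfg), 1)
  expect_equal(compute_scaling_factor(x / 2, cfg), 2)  # P75 = 750
  y <- seq(10, 1000, by = 10)
  expect_equal(compute_scaling_factor(y, cfg),
               1500 / oracle_quantile7(y, 0.75))
  # nearest-rank convention goes through the matching oracle
  cfg1 <- pipeline_config(quantile_convention = "nearest_rank")
  expect_equal(compute_scaling_factor(y, cfg1),
               1500 / oracle_quantile1(y, 0.75))
  expect_error(compute_scaling_factor(rep(0, 10), cfg), "degenerate")
  expect_error(compute_scaling_factor(numeric(0), cfg), "no signal")
})

test_that("normalization scales signals and nothing else", {
  tab <- make_array(list(A = c(100, 200, 150, 180)), cv = list(A = 0.2))
  expect_equal(apply_normalization(tab, 1), tab)
  out <- apply_normalization(tab, 2)
  expect_equal(out$features$gps, c(200, 400, 300, 360))
  expect_equal(out$features$pixel_cv, tab$features$pixel_cv)
  expect_error(apply_normalization(tab, 0), "positive")
})

test_that("normalization is equivariant to a global raw rescale", {
  cfg <- pipeline_config()
  set.seed(3)
  x <- exp(rnorm(500, 6, 1.5))
  for (c_mult in c(0.01, 3, 1e4)) {
    f1 <- compute_scaling_factor(x, cfg)
    f2 <- compute_scaling_factor(c_mult * x, cfg)
    expect_equal(c_mult * x * f2, x * f1, tolerance = 1e-12)
  }
})

test_that("exclusion rules fire in order with one reason per member", {
  cfg <- pipeline_config()
  clean <- exclude_replicates(c(100, 110, 120, 115), config = cfg)
  expect_true(all(clean$keep))

  # pixel CV above 0.5 excludes exactly that member
  ex <- exclude_replicates(c(100, 100, 100, 100),
                           pixel_cv = c(0.1, 0.6, 0.1, 0.1), config = cfg)
  expect_equal(which(!ex$keep), 2L)
  expect_equal(ex$reason[2], "pixel_cv")
  # 0.5 itself is tolerated (rule is "exceeded 0.5")
  ex <- exclude_replicates(c(100, 100), pixel_cv = c(0.5, 0.5), config = cfg)
  expect_true(all(ex$keep))

  # manual flag wins over every later rule
  ex <- exclude_replicates(c(10, 10, 10, 1e6),
                           manual_flag = c(FALSE, FALSE, FALSE, TRUE),
                           outlier_flag = c(FALSE, FALSE, FALSE, TRUE),
                           pixel_cv = c(0.1, 0.1, 0.1, 0.9), config = cfg)
  expect_equal(ex$reason[4], "manual_flag")
  ex <- exclude_replicates(c(10, 10, 10, 1e6),
                           outlier_flag = c(FALSE, FALSE, FALSE, TRUE),
                           pixel_cv = c(0.1, 0.1, 0.1, 0.9), config = cfg)
  expect_equal(ex$reason[4], "software_outlier")

  # fence decision for a gross value outlier matches the explicit oracle
  ex <- exclude_replicates(c(10, 10, 10, 1000), config = cfg)
  expect_equal(ex$reason,
               oracle_exclusion(c(10, 10, 10, 1000), rep(FALSE, 4),
                                rep(FALSE, 4), rep(0.1, 4)))
  expect_equal(ex$reason[4], "iqr_fence")
  expect_error(exclude_replicates(numeric(0)), "empty")
})

test_that("exclusion decisions match the brute-force oracle on random groups", {
  cfg <- pipeline_config()
  cfg_m <- pipeline_config(fence_convention = "median_centered")
  set.seed(2024)
  for (i in 1:1000) {
    q <- random_quad()
    got <- exclude_replicates(q$gps, q$manual, q$software, q$cv, cfg)
    expect_identical(got$reason,
                     oracle_exclusion(q$gps, q$manual, q$software, q$cv))
    got_m <- exclude_replicates(q$gps, q$manual, q$software, q$cv, cfg_m)
    expect_identical(got_m$reason,
                     oracle_exclusion(q$gps, q$manual, q$software, q$cv,
                                      fence = "median_centered"))
  }
})

test_that("raising the pixel-CV cutoff never excludes a retained member", {
  set.seed(77)
  cuts <- c(0.2, 0.35, 0.5, 0.8)
  for (i in 1:200) {
    q <- random_quad()
    kept_prev <- NULL
    for (cut in cuts) {
      cfg <- pipeline_config(pixel_cv_max = cut)
      keep <- exclude_replicates(q$gps, q$manual, q$software, q$cv, cfg)$keep
      if (!is.null(kept_prev)) expect_true(all(keep[kept_prev]))
      kept_prev <- keep
    }
  }
})

test_that("geometric-mean collapse agrees with the product formula", {
  expect_equal(collapse_replicates(rep(100, 4)), 100)
  expect_equal(collapse_replicates(c(10, 1000)), 100)
  v <- c(37, 210, 95)
  expect_equal(collapse_replicates(v), prod(v)^(1 / length(v)))
  expect_true(is.na(collapse_replicates(numeric(0))))
  expect_error(collapse_replicates(c(1, 0)), "positive")
  # collapse lies within the surviving range
  set.seed(5)
  for (i in 1:100) {
    v <- exp(runif(sample(1:4, 1), 0, 10))
    g <- collapse_replicates(v)
    expect_gte(g, min(v) * (1 - 1e-12))
    expect_lte(g, max(v) * (1 + 1e-12))
  }
})

test_that("surrogate floor substitutes low values and propagates NA", {
  cfg <- pipeline_config()
  expect_equal(apply_floor(c(5, 20, 1500, NA), cfg), c(20, 20, 1500, NA))
})

test_that("per-sample pipeline restores the reference percentile and floors", {
  cfg <- pipeline_config()
  tab <- make_clean_array(1000, seed = 9)
  res <- preprocess_sample(tab, cfg)
  expect_equal(sum(!is.na(res$values)), 1000L)
  # post-normalization percentile invariant
  expect_equal(res$normalization$observed_percentile *
                 res$normalization$scaling_factor, 1500,
               tolerance = 1e-9)
  norm_gps <- tab$features$gps * res$normalization$scaling_factor
  expect_equal(qa_quantile(norm_gps, 0.75, cfg), 1500, tolerance = 1e-9)
  expect_gte(min(res$values, na.rm = TRUE), 20)
})

test_that("a fully flagged probe is reported missing, not imputed", {
  tab <- make_array(list(A = c(100, 110, 120, 115),
                         B = c(200, 210, 220, 215)),
                    manual = list(A = rep(TRUE, 4)))
  res <- preprocess_sample(tab)
  expect_true(is.na(res$values[["A"]]))
  expect_false(is.na(res$values[["B"]]))
  expect_equal(nrow(res$exclusions), 4L)
  expect_equal(unique(res$exclusions$reason), "manual_flag")
})

test_that("the final column is invariant to a global raw rescale", {
  tab <- make_clean_array(300, seed = 21)
  tab_scaled <- tab
  tab_scaled$features$gps <- tab$features$gps * 37.5
  v1 <- preprocess_sample(tab)$values
  v2 <- preprocess_sample(tab_scaled)$values
  expect_equal(v1, v2, tolerance = 1e-9)
})

test_that("floor stage placement changes the result as documented", {
  # filler probe B pins the raw P75 at 1500 so the scaling factor is 1
  tab <- make_array(list(A = c(4, 100), B = c(1500, 1500)))
  cfg <- pipeline_config()
  expect_equal(compute_scaling_factor(tab$features$gps, cfg), 1)
  # post-collapse (default): gm(4, 100) = 20 exactly at the floor
  post <- preprocess_sample(tab, cfg)$values[["A"]]
  pre <- preprocess_sample(tab,
    pipeline_config(floor_stage = "pre_collapse"))$values[["A"]]
  expect_equal(post, 20)
  expect_equal(pre, sqrt(20 * 100), tolerance = 1e-9)
})

test_that("controls are excluded from scaling and from the matrix", {
  tab <- make_array(list(A = c(100, 100, 100, 100)))
  ctrl <- quad_features("CTRL_1", c(1e6), control = TRUE)
  tab$features <- rbind(tab$features, ctrl)
  tab <- validate_array_table(tab)
  res <- preprocess_sample(tab)
  expect_false("CTRL_1" %in% names(res$values))
  # scaling factor computed on non-control values only
  expect_equal(res$normalization$observed_percentile, 100)
})

test_that("configuration validates and round-trips through YAML", {
  expect_error(pipeline_config(surrogate_floor = -1), "positive")
  expect_error(pipeline_config(percentile = 100), "percentile")
  cfg <- pipeline_config(iqr_multiplier = 2.5,
                         fence_convention = "median_centered")
  p <- withr::local_tempfile(fileext = ".yaml")
  write_pipeline_config(cfg, p)
  expect_equal(read_pipeline_config(p), cfg)
  writeLines("nonsense_key: 1", p)
  expect_error(read_pipeline_config(p), "unknown config key")
})
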
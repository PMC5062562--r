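test_that("pairwise categories follow the floor and fold rules", {
  cc <- classify_config()
  expect_equal(classify_gene_pair(100, 300, cc)$category, "negligible")
  r <- classify_gene_pair(600, 400, cc)
  expect_equal(r$category, "shared")
  expect_equal(r$fold, 1.5)
  r <- classify_gene_pair(1200, 400, cc)
  expect_equal(r$category, "unique_A")
  expect_equal(r$fold, 3)
  expect_equal(classify_gene_pair(400, 1200, cc)$category, "unique_B")
  # boundary conventions: 500 counts as expressed, fold exactly 2 is shared
  expect_equal(classify_gene_pair(500, 100, cc)$category, "unique_A")
  expect_equal(classify_gene_pair(1000, 500, cc)$category, "shared")
  expect_error(classify_gene_pair(0, 5), "positive")
  expect_error(classify_gene_pair(c(1, 2), 5), "equal length")
})

test_that("equal values are never unique and calls are symmetric", {
  cc <- classify_config()
  set.seed(8)
  x <- exp(runif(200, log(21), log(50000)))
  same <- classify_gene_pair(x, x, cc)$category
  expect_true(all(same %in% c("negligible", "shared")))
  a <- exp(runif(500, log(21), log(50000)))
  b <- exp(runif(500, log(21), log(50000)))
  ab <- classify_gene_pair(a, b, cc)$category
  ba <- classify_gene_pair(b, a, cc)$category
  flip <- c(negligible = "negligible", shared = "shared",
            unique_A = "unique_B", unique_B = "unique_A")
  expect_equal(unname(flip[ab]), ba)
})

test_that("increasing the higher value never demotes a unique call", {
  cc <- classify_config()
  b <- 800
  grid <- seq(801, 20000, length.out = 400)
  cats <- classify_gene_pair(grid, rep(b, length(grid)), cc)$category
  first_unique <- match("unique_A", cats)
  expect_false(any(cats[seq(first_unique, length(cats))] != "unique_A"))
})

test_that("venn counts are exhaustive, exclusive and orientation-symmetric", {
  mat <- matrix(c(100, 100, 600, 500, 2000, 100), nrow = 3, byrow = TRUE,
                dimnames = list(c("p1", "p2", "p3"), c("sA", "sB")))
  meta <- data.frame(SampleID = c("sA", "sB"), Strain = "BALBC",
                     Subset = c("iNKT1", "iNKT2"), ExperimentID = "Exp1",
                     stringsAsFactors = FALSE)
  vs <- venn_summary(mat, meta, c("iNKT1", "iNKT2"), "Exp1")
  expect_equal(c(vs$n_negligible, vs$n_shared, vs$n_unique_a, vs$n_unique_b),
               c(1, 1, 1, 0))
  expect_equal(vs$n_negligible + vs$n_shared + vs$n_unique_a + vs$n_unique_b,
               vs$total)
  sw <- venn_summary(mat, meta, c("iNKT2", "iNKT1"), "Exp1")
  expect_equal(sw$n_unique_a, vs$n_unique_b)
  expect_equal(sw$n_unique_b, vs$n_unique_a)
  expect_equal(sw$n_negligible, vs$n_negligible)

  # a probe missing in either sample is unclassifiable, not counted
  mat[2, 1] <- NA
  vs2 <- venn_summary(mat, meta, c("iNKT1", "iNKT2"), "Exp1")
  expect_equal(vs2$n_unclassifiable, 1L)
  expect_equal(vs2$total, 2L)
  expect_error(venn_summary(mat, meta, c("iNKT1", "iNKT17"), "Exp1"),
               "missing sample")
})

test_that("across-experiment aggregation reports mean and sample s.d.", {
  mk <- function(nA) {
    mat <- matrix(rep(c(3000, 100), each = nA), ncol = 2,
                  dimnames = list(sprintf("p%d", seq_len(nA)), c("a", "b")))
    meta <- data.frame(SampleID = c("a", "b"), Strain = "B6",
                       Subset = c("iNKT1", "iNKT2"), ExperimentID = "E",
                       stringsAsFactors = FALSE)
    venn_summary(mat, meta, c("iNKT1", "iNKT2"), "E")
  }
  s1 <- mk(400); s2 <- mk(600)
  agg <- summarize_across_experiments(list(s1, s2))
  ua <- agg[agg$category == "unique_A", ]
  expect_equal(ua$mean, 500)
  expect_equal(ua$sd, sd(c(400, 600)), tolerance = 1e-12)
  expect_equal(ua$sd, 141.42, tolerance = 1e-4)
  same <- summarize_across_experiments(list(s1, s1))
  expect_true(all(same$sd == 0))
  one <- summarize_across_experiments(list(s2))
  expect_equal(one$mean[one$category == "unique_A"], 600)
  expect_true(all(one$sd == 0))
  bad <- mk(10); bad$pair <- c("iNKT1", "iNKT17")
  expect_error(summarize_across_experiments(list(s1, bad)), "pairs")
})

test_that("heat-map export scales rows as documented", {
  mat <- matrix(c(20, 20, 20, 100, 400, 200), nrow = 2, byrow = TRUE,
                dimnames = list(c("flat", "var"), c("s1", "s2", "s3")))
  z <- export_heatmap_matrix(mat, row_scaling = "log2_zscore")
  expect_equal(unname(z["flat", ]), c(0, 0, 0))
  two <- export_heatmap_matrix(mat[, 1:2], probes = "var",
                               row_scaling = "log2_zscore")
  expect_equal(unname(two[1, ]), c(-1, 1) / sqrt(2), tolerance = 1e-9)
  pass <- export_heatmap_matrix(mat, row_scaling = "none")
  expect_identical(pass, mat)
  expect_error(export_heatmap_matrix(mat, probes = "nope"), "unknown probe")
  expect_error(export_heatmap_matrix(mat, samples = "nope"), "unknown sample")
})

test_that("classifier recovers planted categories under mild noise", {
  # planted margins: unique fold 4, shared fold <= 1.3, both >= 4x floor
  set.seed(99)
  n <- 1000
  truth <- sample(c("unique_A", "shared"), n, replace = TRUE)
  base <- exp(runif(n, log(2000), log(8000)))
  a <- ifelse(truth == "unique_A", base * 4,
              base * exp(runif(n, 0, log(1.3)) * sign(runif(n) - 0.5)))
  b <- base
  noisy <- function(x) x * exp(rnorm(n, 0, 0.1))
  got <- classify_gene_pair(noisy(a), noisy(b))$category
  expect_gte(mean(got == truth), 0.99)
})
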
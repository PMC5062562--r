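# Programmatic fixtures: arrays are always built in code, never stored.

# features data.frame for one quadruplicate probe
quad_features <- function(probe_id, gps, manual = FALSE, software = FALSE,
                          cv = 0.1, control = FALSE) {
  n <- length(gps)
  data.frame(probe_id = probe_id,
             replicate_index = seq_len(n),
             gps = gps,
             manual_flag = rep_len(manual, n),
             outlier_flag = rep_len(software, n),
             pixel_cv = rep_len(cv, n),
             is_control = rep_len(control, n),
             stringsAsFactors = FALSE)
}

# array_table from a named list of per-probe replicate-value vectors
make_array <- function(probe_values, sample_id = "S1", strain = "BALBC",
                       subset = "other", experiment = "Exp1",
                       manual = NULL, software = NULL, cv = NULL) {
  f <- do.call(rbind, lapply(names(probe_values), function(p)
    quad_features(p, probe_values[[p]],
                  manual = if (is.null(manual[[p]])) FALSE else manual[[p]],
                  software = if (is.null(software[[p]])) FALSE
                             else software[[p]],
                  cv = if (is.null(cv[[p]])) 0.1 else cv[[p]])))
  array_table(sample_id, strain, subset, experiment, f)
}

# clean array: n probes, constant replicate values drawn once per probe
make_clean_array <- function(n_probes, sample_id = "S1", seed = 1,
                             subset = "other", experiment = "Exp1",
                             scale = 1) {
  set.seed(seed)
  vals <- exp(runif(n_probes, log(30), log(20000))) * scale
  f <- do.call(rbind, lapply(seq_len(n_probes), function(i)
    quad_features(sprintf("P%04d", i), rep(vals[i], 4))))
  array_table(sample_id, "BALBC", subset, experiment, f)
}

# random quadruplicate with random flags/CVs, for oracle-equivalence runs
random_quad <- function() {
  n <- sample(1:4, 1)
  list(gps = exp(runif(n, log(5), log(30000))),
       manual = runif(n) < 0.15,
       software = runif(n) < 0.15,
       cv = ifelse(runif(n) < 0.2, runif(n, 0.5, 1.2), runif(n, 0, 0.5)))
}

# planted pairwise truth oriented to a requested (A, B) pair order
oriented_truth <- function(pair_truth, pair) {
  key <- paste(pair, collapse = ":")
  if (key %in% pair_truth$pair)
    return(pair_truth[pair_truth$pair == key, ])
  tr <- pair_truth[pair_truth$pair == paste(rev(pair), collapse = ":"), ]
  flip <- c(negligible = "negligible", shared = "shared",
            unique_A = "unique_B", unique_B = "unique_A")
  tr$category <- unname(flip[tr$category])
  tr$pair <- key
  tr
}

# smallest v (to tol) for which pred(v) becomes TRUE on [lo, hi];
# pred must be monotone (FALSE then TRUE)
bisect_threshold <- function(pred, lo, hi, tol = 1e-9, iter = 200) {
  stopifnot(!pred(lo), pred(hi))
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    if (pred(mid)) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  hi
}
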
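test_that("spearman_rho handles monotone profiles and ties", {
  x <- c(1, 3, 7, 9, 12)
  expect_equal(spearman_rho(x, exp(x)), 1)
  expect_equal(spearman_rho(x, -x^3), -1)
  # tie-handling oracle: Pearson correlation of average ranks
  xt <- c(1, 2, 2, 4); yt <- c(10, 20, 30, 40)
  expect_equal(spearman_rho(xt, yt),
               cor(rank(xt, ties.method = "average"),
                   rank(yt, ties.method = "average")))
  expect_true(is.na(spearman_rho(rep(1, 5), 1:5)))
  expect_error(spearman_rho(1:4, 1:5), "length mismatch")
  expect_error(spearman_rho(1:2, 1:2), ">= 3")
})

test_that("bootstrap conserves the pair universe and is deterministic", {
  cfg <- small_cfg()
  b <- generate_dataset(cfg)
  act <- b$truth$true_activity
  r1 <- bootstrap_correlations(act, b$metabolome, n_samples = 20,
                               subsample_size = 15, seed = 9)
  expect_equal(nrow(r1$pairs), nrow(act) * nrow(b$metabolome$values))
  r2 <- bootstrap_correlations(act, b$metabolome, n_samples = 20,
                               subsample_size = 15, seed = 9)
  expect_identical(r1$samples, r2$samples)
  expect_identical(r1$mean_correlation, r2$mean_correlation)
  expect_error(bootstrap_correlations(act, b$metabolome, n_samples = 2,
                                      subsample_size = 999),
               "exceeds shared conditions")
})

test_that("subsampling all conditions degenerates to a single-pass rho", {
  cfg <- small_cfg()
  b <- generate_dataset(cfg)
  act <- b$truth$true_activity
  res <- bootstrap_correlations(act, b$metabolome, n_samples = 5,
                                subsample_size = ncol(act), seed = 4)
  expect_true(all(apply(res$samples, 2, function(col)
    length(unique(col)) == 1)))
  i <- 25
  expect_equal(res$mean_correlation[i],
               spearman_rho(act[res$pairs$tf[i], ],
                            b$metabolome$values[res$pairs$metabolite[i], ]))
})

test_that("planted activating pairs correlate strongly", {
  cfg <- generator_config(seed = 7)
  b <- generate_dataset(cfg)
  res <- bootstrap_correlations(b$truth$true_activity, b$metabolome,
                                n_samples = 100, seed = 7)
  key <- paste(res$pairs$tf, res$pairs$metabolite)
  pl <- b$truth$planted
  idx <- match(paste(pl$tf, pl$metabolite), key)
  expect_true(all(res$mean_correlation[idx] > 0.8))
})

test_that("ROC handles perfect separation and matches the U statistic", {
  pairs <- data.frame(tf = "T", metabolite = sprintf("m%d", 1:10))
  known <- known_interactions(data.frame(tf = "T", metabolite = c("m1", "m2"),
                                         effect = "activating"))
  sep <- c(0.9, 0.8, seq(0.5, -0.9, length.out = 8))
  expect_equal(roc_for_sample(sep, pairs, known, "activating")$auc, 1)
  worst <- c(-0.9, -0.95, seq(0.5, 0.1, length.out = 8))
  expect_equal(roc_for_sample(worst, pairs, known, "activating")$auc, 0)

  # tie-corrected Mann-Whitney oracle over 100 seeded random score sets
  for (s in 1:100) {
    set.seed(s)
    scores <- round(runif(10, -1, 1), 1)  # coarse grid forces ties
    roc <- roc_for_sample(scores, pairs, known, "activating")
    pos <- scores[1:2]; neg <- scores[3:10]
    U <- sum(vapply(pos, function(p)
      sum(p > neg) + 0.5 * sum(p == neg), numeric(1)))
    expect_equal(roc$auc, U / (length(pos) * length(neg)),
                 label = sprintf("seed %d", s))
  }
})

test_that("ROC against pROC on a seeded example", {
  skip_if_not_installed("pROC")
  set.seed(55)
  pairs <- data.frame(tf = "T", metabolite = sprintf("m%d", 1:60))
  known <- known_interactions(data.frame(tf = "T",
                                         metabolite = sprintf("m%d", 1:10),
                                         effect = "activating"))
  scores <- c(rnorm(10, 0.5, 0.4), rnorm(50, 0, 0.4))
  got <- roc_for_sample(scores, pairs, known, "activating")$auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 10), rep(0, 50)), predictor = scores,
    direction = "<", quiet = TRUE)))
  expect_equal(got, ref)
})

test_that("random labels give a null AUC near 0.5", {
  set.seed(56)
  pairs <- data.frame(tf = "T", metabolite = sprintf("m%d", 1:100))
  aucs <- replicate(100, {
    scores <- rnorm(100)
    kn <- known_interactions(data.frame(
      tf = "T", metabolite = sample(pairs$metabolite, 10),
      effect = "activating"))
    roc_for_sample(scores, pairs, kn, "activating")$auc
  })
  expect_lt(abs(median(aucs) - 0.5), 0.05)
})

test_that("median ROC threshold matches per-sample brute force", {
  cfg <- small_cfg()
  b <- generate_dataset(cfg)
  res <- bootstrap_correlations(b$truth$true_activity, b$metabolome,
                                n_samples = 20, subsample_size = 15,
                                seed = 10)
  out <- median_roc_threshold(res, b$known, "activating", target_fpr = 0.1)
  labels <- paste(res$pairs$tf, res$pairs$metabolite) %in%
    paste(b$known$tf, b$known$metabolite)
  brute <- vapply(seq_len(res$n_samples), function(s) {
    sc <- res$samples[s, ]
    ok <- !is.na(sc)
    cand <- sort(unique(sc[ok]))
    fpr <- vapply(cand, function(t)
      mean(sc[ok & !labels] > t), numeric(1))
    min(cand[fpr <= 0.1])
  }, numeric(1))
  expect_equal(out$threshold, median(brute))
  expect_true(all(diff(out$median_curve$tpr) >= 0))

  # degenerate bootstrap: identical samples give the single-sample threshold
  res2 <- bootstrap_correlations(b$truth$true_activity, b$metabolome,
                                 n_samples = 4,
                                 subsample_size = cfg$n_conditions, seed = 2)
  out2 <- median_roc_threshold(res2, b$known, "activating")
  expect_equal(out2$threshold, out2$per_sample_thresholds[1])
})

test_that("stability is the proportion of samples above threshold", {
  res <- structure(list(
    pairs = data.frame(tf = "T", metabolite = c("m1", "m2", "m3")),
    samples = cbind(rep(0.9, 1000),
                    rep(-0.5, 1000),
                    c(rep(0.9, 128), rep(0, 872))),
    n_samples = 1000), class = "bootstrap_result")
  st <- stability_scores(res, threshold = 0.5, effect = "activating")
  expect_equal(st$pairs$stability, c(1, 0, 0.128))
})

test_that("stability cutoff selection maximizes known retention", {
  pairs <- data.frame(tf = "T", metabolite = sprintf("m%d", 1:50))
  set.seed(57)
  stab <- c(rep(1, 5), runif(45, 0, 0.95))
  st <- structure(list(pairs = cbind(pairs, stability = stab),
                       threshold = 0.3, effect = "activating"),
                  class = "stability_scores")
  kn <- known_interactions(data.frame(tf = "T",
                                      metabolite = sprintf("m%d", 1:5),
                                      effect = "activating"))
  cut <- select_stability_threshold(st, kn, "activating")
  expect_equal(cut, 1)  # retains exactly the known set

  # brute-force argmax oracle
  cand <- sort(unique(stab))
  ratio <- vapply(cand, function(ct)
    sum(stab[1:5] >= ct) / sum(stab >= ct), numeric(1))
  expect_equal(cut, max(cand[ratio == max(ratio)]))

  flat <- st; flat$pairs$stability <- rep(0.4, 50)
  expect_equal(select_stability_threshold(flat, kn, "activating"), 0.4)
})

test_that("rho, ROC and stability are invariant to monotone transforms", {
  cfg <- small_cfg()
  b <- generate_dataset(cfg)
  act <- b$truth$true_activity
  met <- b$metabolome
  met2 <- metabolite_matrix(exp(2 * log(met$values) + 1))  # strictly increasing
  r1 <- bootstrap_correlations(act, met, n_samples = 10,
                               subsample_size = 15, seed = 12)
  r2 <- bootstrap_correlations(act, met2, n_samples = 10,
                               subsample_size = 15, seed = 12)
  expect_equal(r1$samples, r2$samples)
  expect_equal(r1$mean_correlation, r2$mean_correlation)
  roc1 <- median_roc_threshold(r1, b$known, "activating")
  roc2 <- median_roc_threshold(r2, b$known, "activating")
  expect_equal(roc1$threshold, roc2$threshold)
  s1 <- stability_scores(r1, roc1$threshold)
  s2 <- stability_scores(r2, roc2$threshold)
  expect_equal(s1$pairs$stability, s2$pairs$stability)
})

test_that("inactivating orientation flips the score", {
  pairs <- data.frame(tf = "T", metabolite = sprintf("m%d", 1:6))
  kn <- known_interactions(data.frame(tf = "T", metabolite = "m1",
                                      effect = "inactivating"))
  scores <- c(-0.9, 0.5, 0.4, 0.1, -0.2, 0.3)
  roc <- roc_for_sample(scores, pairs, kn, "inactivating")
  expect_equal(roc$auc, 1)  # most negative rho ranks first once flipped
})
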
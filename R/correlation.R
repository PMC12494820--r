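# Bootstrap Spearman correlation between TF activities and metabolite
# abundances, ROC-based correlation thresholding at a target false positive
# rate, and per-pair stability scores.

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values; tolerant of ties. Returns
#' `NA` when either profile is constant (ranks undefined for correlation).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return rho in [-1, 1], or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need >= 3 paired observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
  cor(x, y, method = "spearman")
}

#' Bootstrap-averaged Spearman correlations for all TF-metabolite pairs
#'
#' Per bootstrap sample, `subsample_size` shared conditions are drawn without
#' replacement and Spearman's rho is computed for every (TF, metabolite)
#' pair over them. The reported correlation score of a pair is the arithmetic
#' mean over samples, ignoring samples where the pair's rho is undefined.
#' The pair universe is always the full n_tfs x n_metabolites grid.
#'
#' @param act a `tf_activity` or TF x condition activity matrix.
#' @param met a [metabolite_matrix()] or metabolite x condition matrix.
#' @param n_samples number of bootstrap samples (default 1000).
#' @param subsample_size conditions per sample (default 30).
#' @param seed integer seed.
#' @param retain_samples keep the n_samples x n_pairs matrix of per-sample
#'   correlations (required for thresholding and stability; default TRUE).
#' @return object of class `bootstrap_result`: `pairs` (data.frame `tf`,
#'   `metabolite`), `mean_correlation`, `samples` (matrix or NULL),
#'   `n_samples`, `subsample_size`, `seed`, `subsample_index` (list of
#'   condition index sets).
#' @export
bootstrap_correlations <- function(act, met, n_samples = 1000,
                                   subsample_size = 30, seed = NULL,
                                   retain_samples = TRUE) {
  A <- if (inherits(act, "tf_activity")) act$activities else act
  M <- if (inherits(met, "metabolite_matrix")) met$values else met
  shared <- intersect(colnames(A), colnames(M))
  if (length(shared) < subsample_size)
    stop(sprintf("subsample_size (%d) exceeds shared conditions (%d)",
                 subsample_size, length(shared)), call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  A <- A[, shared, drop = FALSE]
  M <- M[, shared, drop = FALSE]
  tfs <- rownames(A); mets <- rownames(M)
  n_pairs <- length(tfs) * length(mets)
  pairs <- data.frame(tf = rep(tfs, times = length(mets)),
                      metabolite = rep(mets, each = length(tfs)),
                      stringsAsFactors = FALSE)
  samples <- if (retain_samples)
    matrix(NA_real_, nrow = n_samples, ncol = n_pairs) else NULL
  acc <- numeric(n_pairs)
  cnt <- numeric(n_pairs)
  idx_sets <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    idx <- sort(sample(length(shared), subsample_size))
    idx_sets[[s]] <- idx
    rho <- suppressWarnings(
      cor(t(A[, idx, drop = FALSE]), t(M[, idx, drop = FALSE]),
          method = "spearman"))
    v <- as.vector(rho)
    if (retain_samples) samples[s, ] <- v
    ok <- !is.na(v)
    acc[ok] <- acc[ok] + v[ok]
    cnt <- cnt + ok
  }
  mean_corr <- ifelse(cnt > 0, acc / cnt, NA_real_)
  structure(list(pairs = pairs, mean_correlation = mean_corr,
                 samples = samples, n_samples = n_samples,
                 subsample_size = subsample_size, seed = seed,
                 subsample_index = idx_sets, conditions = shared),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %d pairs, %d samples of %d conditions\n",
              nrow(x$pairs), x$n_samples, x$subsample_size))
  invisible(x)
}

# orient scores so that "high = predicted interaction of the given effect"
.orient <- function(rho, effect) {
  if (effect == "activating") rho else -rho
}

.known_mask <- function(pairs, known, effect = NULL) {
  kn <- as.data.frame(known)
  if (!is.null(effect)) kn <- kn[kn$effect == effect, , drop = FALSE]
  paste(pairs$tf, pairs$metabolite, sep = "\r") %in%
    paste(kn$tf, kn$metabolite, sep = "\r")
}

#' ROC curve for one vector of per-pair correlations
#'
#' Scores are rho for activating effect and -rho for inactivating; positives
#' are the known pairs with the requested effect, negatives all other
#' measured pairs (including known pairs of the other effect). Pairs with
#' missing rho are excluded. The area under the curve uses trapezoidal
#' integration with tie grouping, equal to the tie-corrected
#' Mann-Whitney U / (P*N).
#'
#' @param correlations numeric per-pair rho, aligned with `pairs`.
#' @param pairs data.frame with `tf`, `metabolite` columns.
#' @param known a [known_interactions()].
#' @param effect `"activating"` or `"inactivating"`.
#' @return object of class `roc_curve`: data.frame `curve` (`fpr`, `tpr`,
#'   `threshold`), scalar `auc`.
#' @export
roc_for_sample <- function(correlations, pairs, known,
                           effect = c("activating", "inactivating")) {
  effect <- match.arg(effect)
  scores <- .orient(correlations, effect)
  labels <- .known_mask(pairs, known, effect)
  ok <- !is.na(scores)
  scores <- scores[ok]; labels <- labels[ok]
  if (!any(labels)) stop("no known pairs of the requested effect measured",
                         call. = FALSE)
  if (all(labels)) stop("no negative pairs available", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  P <- sum(l); N <- sum(!l)
  tp <- cumsum(l); fp <- cumsum(!l)
  last <- !duplicated(s, fromLast = TRUE)
  curve <- data.frame(fpr = c(0, fp[last] / N), tpr = c(0, tp[last] / P),
                      threshold = c(Inf, s[last]))
  auc <- sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
  structure(list(curve = curve, auc = auc), class = "roc_curve")
}

# smallest score threshold t with FPR(t) = #(negatives > t)/N <= target
.fpr_threshold <- function(scores, labels, target_fpr) {
  ok <- !is.na(scores)
  scores <- scores[ok]; labels <- labels[ok]
  negs <- sort(scores[!labels])
  N <- length(negs)
  u <- sort(unique(scores), decreasing = TRUE)
  fpr <- (N - findInterval(u, negs)) / N
  min(u[fpr <= target_fpr])
}

#' Correlation threshold from median per-sample ROC at a target FPR
#'
#' Per bootstrap sample, the smallest score threshold whose false positive
#' rate is at most `target_fpr` is found; the returned correlation threshold
#' is the median of these per-sample thresholds. A median ROC curve (median
#' TPR at 101 evenly spaced FPR grid points across samples) is returned for
#' reporting. Samples without measured positives are skipped.
#'
#' @param result a [bootstrap_correlations()] result with retained samples.
#' @param known a [known_interactions()].
#' @param effect `"activating"` or `"inactivating"`.
#' @param target_fpr target false positive rate (default 0.1).
#' @return list with `threshold`, `median_curve` (data.frame `fpr`, `tpr`),
#'   `per_sample_thresholds`, `auc` (median per-sample AUC), `effect`,
#'   `target_fpr`.
#' @export
median_roc_threshold <- function(result, known,
                                 effect = c("activating", "inactivating"),
                                 target_fpr = 0.1) {
  effect <- match.arg(effect)
  stopifnot(inherits(result, "bootstrap_result"))
  if (is.null(result$samples))
    stop("per-sample correlations were not retained", call. = FALSE)
  labels <- .known_mask(result$pairs, known, effect)
  if (!any(labels)) stop("no known pairs of the requested effect measured",
                         call. = FALSE)
  grid <- seq(0, 1, length.out = 101)
  thr <- rep(NA_real_, result$n_samples)
  aucs <- rep(NA_real_, result$n_samples)
  tpr_grid <- matrix(NA_real_, nrow = result$n_samples, ncol = length(grid))
  for (s in seq_len(result$n_samples)) {
    sc <- .orient(result$samples[s, ], effect)
    ok <- !is.na(sc)
    if (!any(labels & ok)) next
    roc <- roc_for_sample(result$samples[s, ], result$pairs, known, effect)
    thr[s] <- .fpr_threshold(sc, labels, target_fpr)
    aucs[s] <- roc$auc
    # step interpolation of TPR at the FPR grid
    tpr_grid[s, ] <- vapply(grid, function(g) {
      max(roc$curve$tpr[roc$curve$fpr <= g])
    }, numeric(1))
  }
  if (all(is.na(thr)))
    stop("no bootstrap sample had measured positives", call. = FALSE)
  list(threshold = median(thr, na.rm = TRUE),
       median_curve = data.frame(fpr = grid,
                                 tpr = apply(tpr_grid, 2, median,
                                             na.rm = TRUE)),
       per_sample_thresholds = thr,
       auc = median(aucs, na.rm = TRUE),
       effect = effect, target_fpr = target_fpr)
}

#' Per-pair stability scores
#'
#' Proportion of bootstrap samples in which a pair's correlation strictly
#' exceeds the threshold (in the orientation of the requested effect).
#' Samples where the pair's correlation is undefined count as not above;
#' proportions are over all `n_samples`.
#'
#' @param result a [bootstrap_correlations()] result with retained samples.
#' @param threshold correlation threshold (see [median_roc_threshold()]).
#' @param effect `"activating"` or `"inactivating"`.
#' @return object of class `stability_scores`: data.frame `pairs` with
#'   `tf`, `metabolite`, `stability`; scalar `threshold`, `effect`.
#' @export
stability_scores <- function(result, threshold,
                             effect = c("activating", "inactivating")) {
  effect <- match.arg(effect)
  stopifnot(inherits(result, "bootstrap_result"))
  if (is.null(result$samples))
    stop("per-sample correlations were not retained", call. = FALSE)
  sc <- .orient(result$samples, effect)
  above <- sc > threshold
  above[is.na(above)] <- FALSE
  prop <- colSums(above) / result$n_samples
  pairs <- result$pairs
  pairs$stability <- prop
  structure(list(pairs = pairs, threshold = threshold, effect = effect),
            class = "stability_scores")
}

#' Select the stability cutoff maximizing known-interaction retention
#'
#' Scans all observed stability values as candidate cutoffs (pairs are
#' retained when stability >= cutoff) and returns the cutoff maximizing the
#' proportion of retained pairs that are known interactions of the requested
#' effect; ties break toward the larger cutoff.
#'
#' @param scores a [stability_scores()] result.
#' @param known a [known_interactions()].
#' @param effect `"activating"` or `"inactivating"`.
#' @return the selected cutoff.
#' @export
select_stability_threshold <- function(scores, known,
                                       effect = c("activating",
                                                  "inactivating")) {
  effect <- match.arg(effect)
  stopifnot(inherits(scores, "stability_scores"))
  labels <- .known_mask(scores$pairs, known, effect)
  if (!any(labels)) stop("no known pairs with a stability score",
                         call. = FALSE)
  st <- scores$pairs$stability
  cand <- sort(unique(st))
  best <- -Inf; best_cut <- cand[1]
  for (cut in cand) {
    keep <- st >= cut
    if (!any(keep)) next
    ratio <- sum(labels[keep]) / sum(keep)
    if (ratio >= best) { best <- ratio; best_cut <- cut }
  }
  best_cut
}
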
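# TF activity inference by signed regulon enrichment on a rank/normal-score
# signature, with regulatory-network subsampling, plus the knockout benchmark
# and the dynamic chi-squared threshold used to filter TFs.

#' Z-score expression signature
#'
#' Per gene, expression values are standardized across conditions (mean 0,
#' sample sd 1); zero-variance genes get an all-zero signature row.
#'
#' @param expr an [expression_matrix()] with at least 3 conditions.
#' @return numeric gene x condition signature matrix.
#' @export
build_signature <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  v <- expr$values
  if (ncol(v) < 3) stop("signature needs >= 3 conditions", call. = FALSE)
  mu <- rowMeans(v)
  sdv <- apply(v, 1, sd)
  sig <- (v - mu) / ifelse(sdv > 0, sdv, 1)
  sig[sdv == 0, ] <- 0
  sig
}

# Per-condition normal-score transform: within each condition, signature
# values are ranked across genes (average ranks for ties) and mapped to
# standard-normal quantiles rank/(n+1).
normal_scores <- function(signature) {
  n <- nrow(signature)
  apply(signature, 2, function(col) qnorm(rank(col, ties.method = "average") /
                                            (n + 1)))
}

#' Raw regulon enrichment score
#'
#' Signed, size-normalized enrichment of one TF's regulon in one condition's
#' signature: `sum(sign_g * ns_g) / sqrt(n_used)`, where `ns` is the
#' per-condition normal-score transform of the signature and `n_used` counts
#' targets with nonzero sign that are present in the signature. Dual (sign-0)
#' edges are excluded. Flipping all regulon signs negates the score.
#'
#' @param signature gene x condition signature matrix (see
#'   [build_signature()]).
#' @param regulon data.frame of `target`, `sign` rows (see [regulon()]).
#' @param condition condition identifier (column of `signature`); if `NULL`,
#'   scores for all conditions are returned.
#' @return numeric score (or vector of per-condition scores).
#' @export
enrich_regulon <- function(signature, regulon, condition = NULL) {
  ns <- normal_scores(signature)
  keep <- regulon$sign != 0L & regulon$target %in% rownames(ns)
  if (!any(keep)) {
    warning("regulon has no usable (nonzero-sign) targets; score undefined",
            call. = FALSE)
    return(NA_real_)
  }
  reg <- regulon[keep, , drop = FALSE]
  sc <- colSums(reg$sign * ns[reg$target, , drop = FALSE]) /
    sqrt(nrow(reg))
  if (is.null(condition)) sc else unname(sc[condition])
}

# raw scores for every eligible TF at once (normal scores computed once)
.raw_scores <- function(ns, net, tfs) {
  out <- matrix(NA_real_, nrow = length(tfs), ncol = ncol(ns),
                dimnames = list(tfs, colnames(ns)))
  for (tf in tfs) {
    reg <- net[net$tf == tf & net$sign != 0L &
                 net$target %in% rownames(ns), , drop = FALSE]
    out[tf, ] <- colSums(reg$sign * ns[reg$target, , drop = FALSE]) /
      sqrt(nrow(reg))
  }
  out
}

#' Infer TF activities with regulatory-network subsampling
#'
#' For every TF with a regulon of at least `min_regulon` usable targets, raw
#' enrichment scores are computed on the normal-score signature; to buffer
#' the inference against uneven regulon sizes and network incompleteness,
#' each TF is scored within `n_subnets` subnetworks consisting of the TF plus
#' `extra_tfs` randomly drawn other TFs (without replacement; all others if
#' fewer exist). Within each subnetwork and condition, scores are
#' standardized across member TFs, and the final activity is the median of
#' the TF's standardized scores over the subnetworks. Per-subnetwork scores
#' are retained for the knockout benchmark.
#'
#' @param expr an [expression_matrix()].
#' @param net a [regulatory_network()].
#' @param n_subnets number of subnetworks per TF (default 10).
#' @param extra_tfs number of additional TFs per subnetwork (default 40).
#' @param seed integer seed for the subnetwork draws.
#' @param min_regulon minimum number of usable targets (default 3).
#' @return object of class `tf_activity`: `activities` (TF x condition
#'   matrix), `subnet_scores` (per TF, a subnets x conditions matrix),
#'   `n_subnets`.
#' @export
infer_activities <- function(expr, net, n_subnets = 10, extra_tfs = 40,
                             seed = NULL, min_regulon = 3) {
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(net, "regulatory_network"))
  if (!is.null(seed)) set.seed(seed)
  sig <- build_signature(expr)
  ns <- normal_scores(sig)
  usable <- net[net$sign != 0L & net$target %in% rownames(ns), , drop = FALSE]
  sizes <- table(usable$tf)
  tfs <- names(sizes)[sizes >= min_regulon]
  if (!length(tfs))
    stop("no TF has a regulon of the required size", call. = FALSE)
  tfs <- tfs[order(match(tfs, unique(net$tf)))]
  raw <- .raw_scores(ns, net, tfs)

  if (length(tfs) == 1L) {
    warning("single eligible TF: subnetwork standardization skipped, raw scores used",
            call. = FALSE)
    sub <- matrix(raw[1, ], nrow = n_subnets, ncol = ncol(raw),
                  byrow = TRUE, dimnames = list(NULL, colnames(raw)))
    return(structure(list(activities = raw,
                          subnet_scores = setNames(list(sub), tfs),
                          n_subnets = n_subnets, conditions = colnames(raw)),
                     class = "tf_activity"))
  }

  act <- matrix(NA_real_, nrow = length(tfs), ncol = ncol(raw),
                dimnames = dimnames(raw))
  subnet_scores <- vector("list", length(tfs))
  names(subnet_scores) <- tfs
  for (tf in tfs) {
    others <- setdiff(tfs, tf)
    k <- min(extra_tfs, length(others))
    sc <- matrix(NA_real_, nrow = n_subnets, ncol = ncol(raw),
                 dimnames = list(NULL, colnames(raw)))
    for (s in seq_len(n_subnets)) {
      members <- c(tf, sample(others, k))
      block <- raw[members, , drop = FALSE]
      mu <- colMeans(block)
      sg <- apply(block, 2, sd)
      z <- (raw[tf, ] - mu) / ifelse(sg > 0, sg, 1)
      z[sg == 0] <- 0
      sc[s, ] <- z
    }
    subnet_scores[[tf]] <- sc
    act[tf, ] <- apply(sc, 2, median)
  }
  structure(list(activities = act, subnet_scores = subnet_scores,
                 n_subnets = n_subnets, conditions = colnames(raw)),
            class = "tf_activity")
}

#' @export
print.tf_activity <- function(x, ...) {
  cat(sprintf("<tf_activity> %d TFs x %d conditions (%d subnetworks)\n",
              nrow(x$activities), ncol(x$activities), x$n_subnets))
  invisible(x)
}

#' Knockout direction benchmark
#'
#' For every condition whose metadata names a knocked-out gene that is also a
#' scored TF and a paired control condition, checks the expected direction
#' (activity lower in the knockout than in the control), reports the
#' per-pair accuracy as the proportion of subnetwork replicates satisfying
#' it, and the rank percentile of the knockout condition's activity among all
#' conditions for that TF (low = good).
#'
#' @param act a `tf_activity` from [infer_activities()].
#' @param meta condition metadata data.frame (see [expression_matrix()]).
#' @return object of class `benchmark_result`: data.frame `pairs` with
#'   columns `tf`, `ko_condition`, `control`, `direction_correct`,
#'   `accuracy`, `rank_percentile`; scalars `n_correct`, `n_total`.
#' @export
ko_direction_benchmark <- function(act, meta) {
  stopifnot(inherits(act, "tf_activity"))
  A <- act$activities
  ko <- meta[!is.na(meta$knocked_out_gene) & meta$knocked_out_gene != "" &
               meta$knocked_out_gene %in% rownames(A), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(ko))) {
    tf <- ko$knocked_out_gene[i]
    cond <- ko$condition[i]
    ctl <- ko$control_condition_id[i]
    if (is.na(ctl) || ctl == "" || !(ctl %in% colnames(A))) {
      warning(sprintf("knockout condition '%s' has no control; skipped", cond),
              call. = FALSE)
      next
    }
    sub <- act$subnet_scores[[tf]]
    accuracy <- mean(sub[, cond] < sub[, ctl])
    rk <- rank(A[tf, ], ties.method = "average")[cond] / ncol(A)
    rows[[length(rows) + 1L]] <- data.frame(
      tf = tf, ko_condition = cond, control = ctl,
      direction_correct = A[tf, cond] < A[tf, ctl],
      accuracy = accuracy, rank_percentile = unname(rk),
      stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows)) do.call(rbind, rows)
           else data.frame(tf = character(0), ko_condition = character(0),
                           control = character(0),
                           direction_correct = logical(0),
                           accuracy = numeric(0),
                           rank_percentile = numeric(0))
  structure(list(pairs = pairs, n_correct = sum(pairs$direction_correct),
                 n_total = nrow(pairs)),
            class = "benchmark_result")
}

#' Dynamic chi-squared threshold
#'
#' Scans every midpoint between consecutive sorted metric values as a
#' candidate cutoff; for each, forms the 2x2 table (above/below cutoff x
#' correct/incorrect) and computes the chi-squared test p-value (no
#' continuity correction). Returns the cutoff minimizing the p-value among
#' cutoffs where the above-cutoff group has the higher proportion correct;
#' ties break toward the smaller cutoff (retaining more TFs). Candidate
#' tables with an empty margin are skipped; if no valid cutoff exists,
#' `-Inf` (no filtering) is returned with a warning.
#'
#' @param values numeric per-TF metric.
#' @param correct logical per-TF success flag.
#' @return the selected cutoff.
#' @export
dynamic_chi2_threshold <- function(values, correct) {
  stopifnot(length(values) == length(correct))
  if (length(unique(values)) < 2 || length(unique(correct)) < 2) {
    warning("metric or flags carry no contrast; returning -Inf (no filter)",
            call. = FALSE)
    return(-Inf)
  }
  sv <- sort(unique(values))
  cand <- (sv[-1] + sv[-length(sv)]) / 2
  best_p <- Inf
  best_cut <- NA_real_
  for (cut in cand) {
    above <- values > cut
    if (!any(above) || all(above)) next
    tab <- table(factor(above, levels = c(FALSE, TRUE)),
                 factor(correct, levels = c(FALSE, TRUE)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p_above <- mean(correct[above])
    p_below <- mean(correct[!above])
    if (!(p_above > p_below)) next
    p <- suppressWarnings(chisq.test(tab, correct = FALSE)$p.value)
    if (is.na(p)) next
    if (p < best_p - 1e-15) { best_p <- p; best_cut <- cut }
  }
  if (is.na(best_cut)) {
    warning("no cutoff improves the correct proportion; returning -Inf",
            call. = FALSE)
    return(-Inf)
  }
  best_cut
}

#' Per-TF activity range and its retention on a condition subset
#'
#' Range = max - min activity per TF; retention = range over the subset
#' divided by range over all conditions (1 when the full range is 0).
#'
#' @param act a `tf_activity` or a TF x condition matrix.
#' @param subset character vector of condition ids.
#' @return data.frame with columns `tf`, `range_full`, `range_subset`,
#'   `retention`.
#' @export
activity_range <- function(act, subset) {
  A <- if (inherits(act, "tf_activity")) act$activities else act
  if (!length(subset)) stop("empty condition subset", call. = FALSE)
  if (!all(subset %in% colnames(A)))
    stop("subset conditions missing from activity matrix", call. = FALSE)
  rf <- apply(A, 1, max) - apply(A, 1, min)
  rs <- apply(A[, subset, drop = FALSE], 1, max) -
    apply(A[, subset, drop = FALSE], 1, min)
  retention <- ifelse(rf > 0, rs / rf, 1)
  data.frame(tf = rownames(A), range_full = rf, range_subset = rs,
             retention = retention, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Filter TFs on basal maximum activity and activity range
#'
#' Drops TFs whose maximum activity falls below `basal_max_cutoff` or whose
#' activity range (max - min) falls below `range_cutoff`. The shipped default
#' cutoffs (-0.752 and 0.166) are reference values derived from a specific
#' benchmark dataset via [dynamic_chi2_threshold()]; recompute them for new
#' data.
#'
#' @param act a `tf_activity`.
#' @param basal_max_cutoff minimum allowed per-TF maximum activity.
#' @param range_cutoff minimum allowed per-TF activity range.
#' @return the filtered `tf_activity`.
#' @export
apply_activity_filter <- function(act, basal_max_cutoff = -0.752,
                                  range_cutoff = 0.166) {
  stopifnot(inherits(act, "tf_activity"))
  A <- act$activities
  keep <- apply(A, 1, max) >= basal_max_cutoff &
    (apply(A, 1, max) - apply(A, 1, min)) >= range_cutoff
  act$activities <- A[keep, , drop = FALSE]
  act$subnet_scores <- act$subnet_scores[rownames(act$activities)]
  act
}
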
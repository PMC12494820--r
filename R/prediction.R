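# The three-filter candidate cascade (correlation, stability, metabolic
# distance) and the end-to-end workflow drivers.

#' Filter configuration for the candidate cascade
#'
#' @param target_fpr false positive rate for the correlation threshold
#'   (default 0.1).
#' @param correlation_threshold correlation cutoff; if `NULL`, derived via
#'   [median_roc_threshold()].
#' @param stability_cutoff stability cutoff; if `NULL`, selected via
#'   [select_stability_threshold()] (the reference value derived on the
#'   original benchmark data was 0.128).
#' @param distance_cutoff maximum metabolic distance (default 0: the
#'   metabolite must be a direct substrate or product of a TF-regulated
#'   reaction).
#' @param effect interaction orientation analyzed (default `"activating"`).
#' @return an object of class `filter_config`.
#' @export
filter_config <- function(target_fpr = 0.1, correlation_threshold = NULL,
                          stability_cutoff = NULL, distance_cutoff = 0,
                          effect = c("activating", "inactivating")) {
  effect <- match.arg(effect)
  if (target_fpr <= 0 || target_fpr >= 1)
    stop("target_fpr must be in (0, 1)", call. = FALSE)
  if (!is.null(stability_cutoff) &&
      (stability_cutoff < 0 || stability_cutoff > 1))
    stop("stability_cutoff must be in [0, 1]", call. = FALSE)
  if (distance_cutoff < 0)
    stop("distance_cutoff must be >= 0", call. = FALSE)
  structure(list(target_fpr = target_fpr,
                 correlation_threshold = correlation_threshold,
                 stability_cutoff = stability_cutoff,
                 distance_cutoff = distance_cutoff, effect = effect),
            class = "filter_config")
}

#' Apply the three-filter cascade to produce candidate pairs
#'
#' Retains pairs with mean correlation strictly above the correlation
#' threshold (oriented per effect), stability at least the stability cutoff
#' (`>=`, so the observed score value that defines the cutoff retains its
#' pairs), and metabolic distance at most the distance cutoff. Pairs whose
#' TF regulates no reaction at all are excluded, restricting the search to
#' TFs with at least one regulated enzyme. Retained pairs are annotated with
#' the position class and the known flag.
#'
#' @param boot a [bootstrap_correlations()] result.
#' @param stab a [stability_scores()] result.
#' @param dist distance records from [compute_distances()].
#' @param cfg a [filter_config()] with concrete
#'   `correlation_threshold` and `stability_cutoff` values.
#' @param known a [known_interactions()].
#' @return data.frame of candidate pairs (`tf`, `metabolite`,
#'   `correlation_score`, `stability`, `distance`, `position`, `known`).
#' @export
filter_candidates <- function(boot, stab, dist, cfg, known) {
  stopifnot(inherits(boot, "bootstrap_result"),
            inherits(stab, "stability_scores"),
            inherits(cfg, "filter_config"))
  if (is.null(cfg$correlation_threshold) || is.null(cfg$stability_cutoff))
    stop("filter_config must carry concrete correlation and stability cutoffs",
         call. = FALSE)
  key <- function(df) paste(df$tf, df$metabolite, sep = "\r")
  universe <- key(boot$pairs)
  for (nm in list(stability = stab$pairs, distance = dist)) {
    missing <- setdiff(universe, key(nm))
    if (length(missing))
      stop(sprintf("score sets cover different pair universes; %d missing (first: %s)",
                   length(missing), gsub("\r", "/", missing[1])),
           call. = FALSE)
  }
  df <- boot$pairs
  df$correlation_score <- .orient(boot$mean_correlation, cfg$effect)
  df$stability <- stab$pairs$stability[match(universe, key(stab$pairs))]
  di <- match(universe, key(dist))
  df$distance <- dist$distance[di]
  df$position <- dist$position[di]
  df$tf_has_regulated <- dist$tf_has_regulated[di]

  keep <- !is.na(df$correlation_score) &
    df$correlation_score > cfg$correlation_threshold &
    df$stability >= cfg$stability_cutoff &
    df$tf_has_regulated &
    df$distance <= cfg$distance_cutoff
  out <- df[keep, c("tf", "metabolite", "correlation_score", "stability",
                    "distance", "position"), drop = FALSE]
  # report the correlation on its natural signed scale
  out$correlation_score <- .orient(out$correlation_score, cfg$effect)
  out$known <- .known_mask(out, known, cfg$effect)
  rownames(out) <- NULL
  out
}

#' Summarize a candidate list
#'
#' Per-TF candidate counts, position-class proportions over classified
#' candidates, and recovery of known interactions under both
#' interpretations: a TF counts as recovered if any of its candidates
#' matches a known interaction (`any` rule), or only if its top-correlated
#' candidate does (`top` rule).
#'
#' @param pairs candidate data.frame from [filter_candidates()].
#' @param known a [known_interactions()].
#' @param effect orientation used for the known comparison.
#' @return object of class `prediction_summary`: `per_tf` counts,
#'   `position_proportions`, `n_candidates`, `known_recovered_any`,
#'   `known_recovered_top`, `known_total_measured`.
#' @export
summarize_predictions <- function(pairs, known,
                                  effect = c("activating", "inactivating")) {
  effect <- match.arg(effect)
  per_tf <- if (nrow(pairs)) as.data.frame(table(tf = pairs$tf),
                                           stringsAsFactors = FALSE)
            else data.frame(tf = character(0), Freq = integer(0))
  names(per_tf)[2] <- "n_candidates"
  classified <- pairs$position[pairs$position != "unclassified"]
  pos_prop <- if (length(classified))
    prop.table(table(factor(classified,
                            levels = c("upstream", "within", "downstream"))))
  else table(factor(character(0),
                    levels = c("upstream", "within", "downstream")))
  kn <- as.data.frame(known)
  kn <- kn[kn$effect == effect, , drop = FALSE]
  measured_tfs <- unique(kn$tf)
  rec_any <- 0L; rec_top <- 0L
  for (tf in measured_tfs) {
    cand <- pairs[pairs$tf == tf, , drop = FALSE]
    if (!nrow(cand)) next
    hits <- cand$metabolite %in% kn$metabolite[kn$tf == tf]
    if (any(hits)) rec_any <- rec_any + 1L
    if (hits[which.max(cand$correlation_score)]) rec_top <- rec_top + 1L
  }
  structure(list(per_tf = per_tf,
                 position_proportions = pos_prop,
                 n_candidates = nrow(pairs),
                 known_recovered_any = rec_any,
                 known_recovered_top = rec_top,
                 known_total_measured = length(measured_tfs)),
            class = "prediction_summary")
}

#' @export
print.prediction_summary <- function(x, ...) {
  cat(sprintf("<prediction_summary> %d candidates for %d TFs\n",
              x$n_candidates, nrow(x$per_tf)))
  cat(sprintf("  known TFs recovered: %d/%d (any candidate), %d/%d (top candidate)\n",
              x$known_recovered_any, x$known_total_measured,
              x$known_recovered_top, x$known_total_measured))
  pp <- round(100 * as.numeric(x$position_proportions))
  cat(sprintf("  positions: upstream %d%%, within %d%%, downstream %d%%\n",
              pp[1], pp[2], pp[3]))
  invisible(x)
}

#' Run the full prediction workflow on prepared inputs
#'
#' Chains activity inference, bootstrap correlation, ROC thresholding,
#' stability scoring, metabolic-distance computation and the candidate
#' cascade.
#'
#' @param expr an [expression_matrix()].
#' @param net a [regulatory_network()].
#' @param metabolome a [metabolite_matrix()].
#' @param model a [metabolic_model()].
#' @param known a [known_interactions()].
#' @param cfg a [filter_config()]; `NULL` cutoffs are derived from the data.
#' @param n_subnets,extra_tfs activity-inference subsampling parameters.
#' @param n_samples,subsample_size bootstrap parameters.
#' @param hub_cutoff,cofactors metabolic-graph filtering parameters.
#' @param seed master seed; activity inference uses `seed` and the bootstrap
#'   `seed + 1`.
#' @return list with elements `activities`, `benchmark`, `bootstrap`,
#'   `roc`, `stability`, `graph`, `distances`, `config` (cutoffs actually
#'   used), `candidates`, `summary`.
#' @export
run_workflow <- function(expr, net, metabolome, model, known,
                         cfg = filter_config(),
                         n_subnets = 10, extra_tfs = 40,
                         n_samples = 1000, subsample_size = 30,
                         hub_cutoff = 50, cofactors = default_cofactors(),
                         seed = 1) {
  act <- infer_activities(expr, net, n_subnets = n_subnets,
                          extra_tfs = extra_tfs, seed = seed)
  bench <- ko_direction_benchmark(act, expr$meta)
  boot <- bootstrap_correlations(act, metabolome, n_samples = n_samples,
                                 subsample_size = subsample_size,
                                 seed = seed + 1L)
  roc <- median_roc_threshold(boot, known, effect = cfg$effect,
                              target_fpr = cfg$target_fpr)
  if (is.null(cfg$correlation_threshold))
    cfg$correlation_threshold <- roc$threshold
  stab <- stability_scores(boot, cfg$correlation_threshold,
                           effect = cfg$effect)
  if (is.null(cfg$stability_cutoff))
    cfg$stability_cutoff <- select_stability_threshold(stab, known,
                                                       effect = cfg$effect)
  graph <- build_graph(model, net, hub_cutoff = hub_cutoff,
                       cofactors = cofactors)
  dist <- compute_distances(graph, rownames(act$activities),
                            rownames(metabolome$values))
  cands <- filter_candidates(boot, stab, dist, cfg, known)
  summ <- summarize_predictions(cands, known, effect = cfg$effect)
  list(activities = act, benchmark = bench, bootstrap = boot, roc = roc,
       stability = stab, graph = graph, distances = dist, config = cfg,
       candidates = cands, summary = summ)
}

#' Generate a synthetic study and run the full workflow on it
#'
#' End-to-end driver: generates the synthetic bundle for `cfg`, runs
#' [run_workflow()] with the bundle's seed, and optionally writes the
#' candidate list (and the inactivating-orientation secondary list) to
#' `outdir`.
#'
#' @param cfg a [generator_config()].
#' @param outdir optional output directory for `candidates.tsv`.
#' @param n_samples,subsample_size bootstrap parameters.
#' @param ... further arguments passed to [run_workflow()].
#' @return the [run_workflow()] result, plus elements `bundle` and
#'   `candidate_file` (when written).
#' @export
run_synthetic_study <- function(cfg = generator_config(), outdir = NULL,
                                n_samples = 1000, subsample_size = 30, ...) {
  bundle <- generate_dataset(cfg)
  res <- run_workflow(bundle$expr, bundle$net, bundle$metabolome,
                      bundle$model, bundle$known,
                      n_samples = n_samples,
                      subsample_size = subsample_size,
                      seed = cfg$seed, ...)
  res$bundle <- bundle
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    res$candidate_file <- file.path(outdir, "candidates.tsv")
    write_candidates(res$candidates, res$candidate_file)
  }
  res
}
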
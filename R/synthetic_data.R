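# Synthetic study generator: coupled expression, metabolome, regulatory
# network, toy metabolic model and known-interaction fixtures with planted
# ground truth. One top-level seed drives every sub-generator through fixed
# offsets (truth +0, expression +1, metabolome +2, model +3, ion table +4) so
# components are reproducible both inside generate_dataset() and when called
# on their own.

#' Configuration for the synthetic study generator
#'
#' Defaults define the package's reference study conditions: 30 TFs with
#' disjoint 8-gene regulons over 300 genes, 40 conditions of which 8 are
#' single-TF knockouts, 60 metabolites with 10 planted activating couplings at
#' strength 1, and Gaussian noise of sd 0.1 on (log-scale) expression and
#' metabolite abundances.
#'
#' @param n_tfs number of transcription factors.
#' @param n_genes number of (non-TF) genes in the expression matrix.
#' @param n_conditions number of experimental conditions.
#' @param n_metabolites number of measured metabolites.
#' @param targets_per_tf regulon size per TF (>= 3, mirroring the minimum
#'   regulon size required for activity inference).
#' @param noise_sd_expression sd of additive Gaussian noise on expression.
#' @param noise_sd_metabolite sd of Gaussian noise on log abundances.
#' @param n_planted number of planted TF-metabolite couplings.
#' @param prop_inactivating proportion of planted couplings with inactivating
#'   effect (the rest are activating).
#' @param coupling_strength strength in (0, 1] of each planted coupling.
#' @param n_ko_conditions number of knockout conditions (each knocks out one
#'   distinct TF; the first condition serves as their wild-type control).
#' @param known_fraction fraction of planted couplings disclosed as "known"
#'   interactions (the rest are novel pairs the pipeline should discover).
#' @param seed integer seed controlling the whole bundle.
#' @return an object of class `generator_config`.
#' @export
generator_config <- function(n_tfs = 30, n_genes = 300, n_conditions = 40,
                             n_metabolites = 60, targets_per_tf = 8,
                             noise_sd_expression = 0.1,
                             noise_sd_metabolite = 0.1,
                             n_planted = 10, prop_inactivating = 0,
                             coupling_strength = 1, n_ko_conditions = 8,
                             known_fraction = 0.5, seed = 7) {
  cfg <- list(n_tfs = n_tfs, n_genes = n_genes, n_conditions = n_conditions,
              n_metabolites = n_metabolites, targets_per_tf = targets_per_tf,
              noise_sd_expression = noise_sd_expression,
              noise_sd_metabolite = noise_sd_metabolite,
              n_planted = n_planted, prop_inactivating = prop_inactivating,
              coupling_strength = coupling_strength,
              n_ko_conditions = n_ko_conditions,
              known_fraction = known_fraction, seed = seed)
  counts <- c("n_tfs", "n_genes", "n_conditions", "n_metabolites",
              "targets_per_tf")
  for (nm in counts)
    if (cfg[[nm]] < 1) stop(sprintf("config: %s must be positive", nm))
  if (cfg$targets_per_tf < 3)
    stop("config: targets_per_tf must be >= 3")
  if (cfg$n_genes < cfg$targets_per_tf)
    stop("config: n_genes must be >= targets_per_tf")
  if (cfg$noise_sd_expression < 0 || cfg$noise_sd_metabolite < 0)
    stop("config: noise sds must be >= 0")
  if (cfg$coupling_strength <= 0 || cfg$coupling_strength > 1)
    stop("config: coupling_strength must be in (0, 1]")
  if (cfg$n_planted > min(cfg$n_tfs, cfg$n_metabolites))
    stop("config: n_planted cannot exceed n_tfs or n_metabolites")
  if (cfg$n_ko_conditions >= cfg$n_conditions)
    stop("config: need at least one non-knockout condition")
  if (cfg$n_ko_conditions > cfg$n_tfs)
    stop("config: cannot knock out more TFs than exist")
  structure(cfg, class = "generator_config")
}

.sd_id <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

# Intended distance/position layout for the planted couplings: the last two
# couplings (when >= 3 are planted) sit at metabolic distances 1 and 2 from
# the TF-regulated reactions; all others are direct (distance 0) with
# positions cycling upstream -> within -> downstream.
.planted_layout <- function(n_planted) {
  dist <- rep(0L, n_planted)
  pos <- rep(c("upstream", "within", "downstream"), length.out = n_planted)
  if (n_planted >= 3) {
    dist[n_planted - 1L] <- 1L
    dist[n_planted] <- 2L
    pos[c(n_planted - 1L, n_planted)] <- "unclassified"
  }
  data.frame(distance = dist, position = pos, stringsAsFactors = FALSE)
}

#' Generate the planted ground truth and regulatory network
#'
#' True TF activities are i.i.d. standard normal per (TF, condition); in each
#' knockout condition the knocked-out TF's activity is forced to its row
#' minimum minus 2, guaranteeing the expected direction of the knockout
#' benchmark. Each TF receives `targets_per_tf` distinct target genes with
#' signs +/-1 (at least one of each); regulons are disjoint whenever
#' `n_tfs * targets_per_tf <= n_genes`.
#'
#' @param cfg a [generator_config()].
#' @return list with elements `truth` (class `synthetic_truth`: `true_activity`
#'   matrix, `planted` couplings, `ko_map`, `planted_distances`) and `net`
#'   (a [regulatory_network()]).
#' @export
generate_truth <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  tfs <- .sd_id("tf", cfg$n_tfs)
  genes <- .sd_id("g", cfg$n_genes)
  conds <- .sd_id("cond", cfg$n_conditions)
  mets <- .sd_id("met", cfg$n_metabolites)

  act <- matrix(rnorm(cfg$n_tfs * cfg$n_conditions), nrow = cfg$n_tfs,
                dimnames = list(tfs, conds))

  # knockout conditions occupy the tail of the condition list; condition 1 is
  # their paired wild-type control
  ko_map <- data.frame(condition = character(0), tf = character(0),
                       control = character(0), stringsAsFactors = FALSE)
  if (cfg$n_ko_conditions > 0) {
    ko_conds <- conds[(cfg$n_conditions - cfg$n_ko_conditions + 1L):
                        cfg$n_conditions]
    ko_tfs <- tfs[seq_len(cfg$n_ko_conditions)]
    for (i in seq_along(ko_conds))
      act[ko_tfs[i], ko_conds[i]] <- min(act[ko_tfs[i], ]) - 2
    ko_map <- data.frame(condition = ko_conds, tf = ko_tfs,
                         control = conds[1], stringsAsFactors = FALSE)
  }

  disjoint <- cfg$n_tfs * cfg$targets_per_tf <= cfg$n_genes
  pool <- if (disjoint) sample(genes) else genes
  edges <- vector("list", cfg$n_tfs)
  for (i in seq_len(cfg$n_tfs)) {
    k <- cfg$targets_per_tf
    tg <- if (disjoint) pool[((i - 1L) * k + 1L):(i * k)]
          else sample(genes, k)
    signs <- c(1L, -1L, sample(c(1L, -1L), k - 2L, replace = TRUE))[sample(k)]
    edges[[i]] <- data.frame(tf = tfs[i], target = tg, sign = signs,
                             stringsAsFactors = FALSE)
  }
  net <- regulatory_network(do.call(rbind, edges))

  effects <- rep("activating", cfg$n_planted)
  n_inact <- round(cfg$prop_inactivating * cfg$n_planted)
  if (n_inact > 0) effects[sample(cfg$n_planted, n_inact)] <- "inactivating"
  planted <- data.frame(tf = tfs[seq_len(cfg$n_planted)],
                        metabolite = mets[seq_len(cfg$n_planted)],
                        effect = effects,
                        strength = rep(cfg$coupling_strength, cfg$n_planted),
                        stringsAsFactors = FALSE)
  layout <- .planted_layout(cfg$n_planted)
  planted_distances <- cbind(planted[, c("tf", "metabolite")], layout)

  truth <- structure(list(true_activity = act, planted = planted,
                          ko_map = ko_map,
                          planted_distances = planted_distances,
                          genes = genes, metabolites = mets),
                     class = "synthetic_truth")
  list(truth = truth, net = net)
}

#' Generate the expression matrix from planted activities
#'
#' Each regulated gene's expression is the signed sum of its regulators'
#' activities plus Gaussian noise; unregulated genes (including the TF genes
#' themselves, carried as rows so knockout metadata can reference them) are
#' pure noise.
#'
#' @param truth `synthetic_truth` from [generate_truth()].
#' @param net the matching [regulatory_network()].
#' @param cfg the [generator_config()].
#' @return an [expression_matrix()] with knockout metadata filled in.
#' @export
generate_expression <- function(truth, net, cfg) {
  set.seed(cfg$seed + 1L)
  act <- truth$true_activity
  tfs <- rownames(act); conds <- colnames(act)
  genes <- truth$genes
  W <- matrix(0, nrow = length(genes), ncol = length(tfs),
              dimnames = list(genes, tfs))
  W[cbind(match(net$target, genes), match(net$tf, tfs))] <- net$sign
  X <- W %*% act +
    matrix(rnorm(length(genes) * length(conds), sd = cfg$noise_sd_expression),
           nrow = length(genes))
  tf_rows <- matrix(rnorm(length(tfs) * length(conds),
                          sd = max(cfg$noise_sd_expression, 1e-8)),
                    nrow = length(tfs), dimnames = list(tfs, conds))
  vals <- rbind(X, tf_rows)
  meta <- data.frame(condition = conds, strain = "synthetic",
                     perturbation = "none",
                     knocked_out_gene = NA_character_,
                     control_condition_id = NA_character_,
                     stringsAsFactors = FALSE)
  if (nrow(truth$ko_map)) {
    idx <- match(truth$ko_map$condition, meta$condition)
    meta$perturbation[idx] <- "knockout"
    meta$knocked_out_gene[idx] <- truth$ko_map$tf
    meta$control_condition_id[idx] <- truth$ko_map$control
  }
  expression_matrix(vals, meta)
}

#' Generate metabolite abundances coupled to planted TF activities
#'
#' A planted activating coupling of strength s gives
#' abundance = exp(s * activity + eps); inactivating couplings use the negated
#' activity. Noise acts on the log scale so abundances stay positive and the
#' zero-noise Spearman correlation with the TF activity is exactly +1 (or -1).
#' Uncoupled metabolites are log-normal noise.
#'
#' @param truth `synthetic_truth` from [generate_truth()].
#' @param cfg the [generator_config()].
#' @return a [metabolite_matrix()] (metabolites x conditions).
#' @export
generate_metabolome <- function(truth, cfg) {
  set.seed(cfg$seed + 2L)
  act <- truth$true_activity
  conds <- colnames(act)
  mets <- truth$metabolites
  M <- matrix(exp(rnorm(length(mets) * length(conds))),
              nrow = length(mets), dimnames = list(mets, conds))
  for (i in seq_len(nrow(truth$planted))) {
    p <- truth$planted[i, ]
    eff <- if (p$effect == "activating") 1 else -1
    M[p$metabolite, ] <- exp(eff * p$strength * act[p$tf, ] +
                               rnorm(length(conds),
                                     sd = cfg$noise_sd_metabolite))
  }
  metabolite_matrix(M)
}

#' Generate a toy metabolic model realizing the planted distances
#'
#' For each planted coupling the model contains a short linear pathway whose
#' reactions are catalyzed by genes from the planted TF's regulon (for the
#' regulated steps) or by orphan genes (for the unregulated linker steps that
#' realize distances 1 and 2). Distance-0 metabolites are placed as substrate
#' only (upstream), intermediate of a regulated chain (within), or product
#' only (downstream). The model additionally carries one hub metabolite
#' participating in 51 reactions, a cofactor pair (`cofA`/`cofB`) attached to
#' every pathway reaction, and a purely extracellular reaction, to exercise
#' the graph filtering rules.
#'
#' @param truth `synthetic_truth` from [generate_truth()].
#' @param net the matching [regulatory_network()].
#' @param cfg the [generator_config()].
#' @return a [metabolic_model()].
#' @export
generate_toy_metabolic_model <- function(truth, net, cfg) {
  set.seed(cfg$seed + 3L)
  rxns <- list()
  species <- character()
  add_sp <- function(ids) species <<- union(species, ids)
  add_rxn <- function(id, subs, prods, genes, reversible = FALSE,
                      cof = TRUE) {
    if (cof) { subs <- c(subs, "cofA"); prods <- c(prods, "cofB") }
    add_sp(c(subs, prods))
    rxns[[id]] <<- list(id = id, substrates = subs, products = prods,
                        reversible = reversible, genes = genes)
  }

  pd <- truth$planted_distances
  for (i in seq_len(nrow(pd))) {
    tf <- pd$tf[i]; m <- pd$metabolite[i]
    reg_genes <- regulon(net, tf)$target
    aux <- function(j) sprintf("aux_%02d_%d", i, j)
    orph <- function(j) sprintf("orph_%02d_%d", i, j)
    rid <- function(j) sprintf("R_%02d_%d", i, j)
    if (pd$distance[i] == 0L) {
      switch(pd$position[i],
        upstream = add_rxn(rid(1), m, aux(1), reg_genes[1]),
        downstream = add_rxn(rid(1), aux(1), m, reg_genes[1]),
        within = {
          add_rxn(rid(1), aux(1), m, reg_genes[1])
          add_rxn(rid(2), m, aux(2), reg_genes[2])
        })
    } else if (pd$distance[i] == 1L) {
      add_rxn(rid(1), m, aux(1), orph(1))
      add_rxn(rid(2), aux(1), aux(2), reg_genes[1])
    } else {
      add_rxn(rid(1), m, aux(1), orph(1))
      add_rxn(rid(2), aux(1), aux(2), orph(2))
      add_rxn(rid(3), aux(2), aux(3), reg_genes[1])
    }
  }

  # uncoupled metabolites enter the model through unregulated filler
  # reactions so that absence from the candidate list is driven by the
  # correlation/stability filters, not merely by absence from the graph
  uncoupled <- setdiff(truth$metabolites, pd$metabolite)
  for (j in seq_along(uncoupled))
    add_rxn(sprintf("R_fill_%02d", j), uncoupled[j],
            sprintf("aux_fill_%02d", j), sprintf("orph_fill_%02d", j))

  for (j in 1:51)
    add_rxn(sprintf("R_hub_%02d", j), "hub", sprintf("hubsink_%02d", j),
            sprintf("orph_hub_%02d", j), cof = FALSE)

  add_rxn("R_ext", "xmet_a", "xmet_b", "orph_ext", cof = FALSE)

  sp <- data.frame(id = species,
                   compartment = ifelse(grepl("^xmet_", species), "e", "c"),
                   stringsAsFactors = FALSE)
  metabolic_model(rxns, sp)
}

#' Derive a replicated ion table and compound reference from a metabolome
#'
#' Emulates negative-mode flow-injection MS: each metabolite is assigned a
#' distinct synthetic monoisotopic mass and observed as the [M-H]- ion (m/z =
#' mass - 1.007276) across biological triplicates and technical duplicates,
#' with multiplicative log-normal replicate noise (sd 0.02, well inside the
#' 15 percent CV filter).
#'
#' @param met a [metabolite_matrix()].
#' @param cfg the [generator_config()].
#' @return list with elements `ions` (an [ion_table()]) and `reference`
#'   (compound reference data.frame).
#' @export
generate_ion_table <- function(met, cfg) {
  set.seed(cfg$seed + 4L)
  mets <- rownames(met$values); conds <- colnames(met$values)
  mass <- 100 + seq_along(mets) * 1.01
  ref <- data.frame(compound_id = mets, monoisotopic_mass = mass,
                    stringsAsFactors = FALSE)
  ions <- data.frame(ion_id = sprintf("ion%03d", seq_along(mets)),
                     mz = mass - 1.007276, stringsAsFactors = FALSE)
  grid <- expand.grid(ion_idx = seq_along(mets), condition = conds,
                      bio_rep = 1:3, tech_rep = 1:2,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  base <- met$values[cbind(grid$ion_idx, match(grid$condition, conds))]
  grid$intensity <- base * exp(rnorm(nrow(grid), sd = 0.02))
  data <- data.frame(ion_id = ions$ion_id[grid$ion_idx],
                     condition = grid$condition, bio_rep = grid$bio_rep,
                     tech_rep = grid$tech_rep, intensity = grid$intensity,
                     stringsAsFactors = FALSE)
  list(ions = ion_table(ions, data, level = "tech"), reference = ref)
}

#' Generate a complete, internally consistent synthetic study bundle
#'
#' Chains [generate_truth()], [generate_expression()],
#' [generate_metabolome()], [generate_toy_metabolic_model()] and
#' [generate_ion_table()], and discloses a `known_fraction` subset of the
#' planted couplings as the known-interaction set (the remainder are the
#' novel pairs the pipeline should discover).
#'
#' @param cfg a [generator_config()].
#' @return list of class `synthetic_bundle` with elements `truth`, `net`,
#'   `expr`, `metabolome`, `ion_table`, `reference`, `model`, `known`, `cfg`.
#' @export
generate_dataset <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  tr <- generate_truth(cfg)
  expr <- generate_expression(tr$truth, tr$net, cfg)
  met <- generate_metabolome(tr$truth, cfg)
  model <- generate_toy_metabolic_model(tr$truth, tr$net, cfg)
  ion <- generate_ion_table(met, cfg)
  n_known <- max(1L, round(cfg$known_fraction * nrow(tr$truth$planted)))
  kn <- tr$truth$planted[seq_len(min(n_known, nrow(tr$truth$planted))), ]
  known <- known_interactions(kn[, c("tf", "metabolite", "effect")])
  structure(list(truth = tr$truth, net = tr$net, expr = expr,
                 metabolome = met, ion_table = ion$ions,
                 reference = ion$reference, model = model, known = known,
                 cfg = cfg),
            class = "synthetic_bundle")
}

#' Serialize a synthetic bundle to a directory of plain-text files
#'
#' Writes expression matrix + metadata, regulatory network, metabolome,
#' ion table, compound reference, SBML model, known interactions and the
#' planted-truth tables as TSV/SBML under `dir`.
#'
#' @param bundle a `synthetic_bundle` from [generate_dataset()].
#' @param dir output directory (created if absent).
#' @return invisibly, the vector of file paths written.
#' @export
write_dataset <- function(bundle, dir) {
  stopifnot(inherits(bundle, "synthetic_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression_matrix(bundle$expr, p("expression.tsv"),
                          p("conditions.tsv"))
  write_regulatory_network(bundle$net, p("network.tsv"))
  write_metabolite_matrix(bundle$metabolome, p("metabolome.tsv"))
  write_ion_table(bundle$ion_table, p("ions.tsv"))
  write_compound_reference(bundle$reference, p("reference.tsv"))
  write_metabolic_model(bundle$model, p("model.xml"))
  write_known_interactions(bundle$known, p("known.tsv"))
  act <- bundle$truth$true_activity
  adf <- data.frame(tf = rownames(act), stringsAsFactors = FALSE)
  for (j in colnames(act)) adf[[j]] <- .fmt_num(act[, j])
  .write_tsv(adf, p("true_activity.tsv"))
  .write_tsv(bundle$truth$planted, p("planted.tsv"))
  .write_tsv(bundle$truth$planted_distances, p("planted_distances.tsv"))
  files <- c("expression.tsv", "conditions.tsv", "network.tsv",
             "metabolome.tsv", "ions.tsv", "reference.tsv", "model.xml",
             "known.tsv", "true_activity.tsv", "planted.tsv",
             "planted_distances.tsv")
  invisible(file.path(dir, files))
}
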
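# Shared fixtures: a small, fast generator configuration and a random toy
# metabolic model builder used by the distance oracle tests.

small_cfg <- function(...) {
  generator_config(n_tfs = 8, n_genes = 60, n_conditions = 20,
                   n_metabolites = 15, targets_per_tf = 4,
                   n_planted = 4, n_ko_conditions = 3, seed = 42, ...)
}

# random reaction-list model over <= n_mets metabolites with genes drawn from
# a tiny regulatory network; returns list(model, net)
random_model <- function(seed, n_mets = 12, n_rxns = 15, n_tfs = 3) {
  set.seed(seed)
  mets <- sprintf("m%02d", seq_len(n_mets))
  genes <- sprintf("gene%02d", 1:12)
  rxns <- lapply(seq_len(n_rxns), function(i) {
    k <- sample(2:3, 1)
    part <- sample(mets, k)
    ns <- sample(seq_len(k - 1), 1)
    list(id = sprintf("rx%02d", i),
         substrates = part[seq_len(ns)],
         products = part[(ns + 1):k],
         reversible = runif(1) < 0.3,
         genes = sample(genes, sample(0:2, 1)))
  })
  model <- metabolic_model(rxns, data.frame(id = mets, compartment = "c",
                                            stringsAsFactors = FALSE))
  tfs <- sprintf("TF%d", seq_len(n_tfs))
  net <- regulatory_network(data.frame(
    tf = rep(tfs, each = 4),
    target = unlist(lapply(seq_len(n_tfs), function(i) sample(genes, 4))),
    sign = 1L, stringsAsFactors = FALSE))
  list(model = model, net = net)
}

# independent distance oracle: exhaustive enumeration of simple
# metabolite/reaction alternating paths on the adjacency defined by the
# graph's role table, never using igraph's shortest-path machinery
brute_force_distance <- function(graph, tf, metabolite) {
  regs <- graph$regulated[[tf]]
  if (!length(regs) || !(metabolite %in% graph$metabolites)) return(Inf)
  rxns_of_met <- split(graph$roles$reaction, graph$roles$metabolite)
  mets_of_rxn <- split(graph$roles$metabolite, graph$roles$reaction)
  best <- Inf
  recurse <- function(met, seen_rxn, n_rxn) {
    for (r in rxns_of_met[[met]]) {
      if (r %in% seen_rxn) next
      if (n_rxn + 1 >= best + 1) next  # bound: cannot improve
      if (r %in% regs) { best <<- min(best, n_rxn); next }
      for (m2 in mets_of_rxn[[r]])
        if (m2 != met) recurse(m2, c(seen_rxn, r), n_rxn + 1)
    }
  }
  recurse(metabolite, character(0), 0)
  best
}
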
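test_that("graph filtering removes hubs, cofactors and extracellular species", {
  cfg <- small_cfg()
  b <- generate_dataset(cfg)
  g <- build_graph(b$model, b$net)
  expect_false("hub" %in% g$metabolites)
  expect_false(any(c("cofA", "cofB") %in% g$metabolites))
  expect_false(any(grepl("^xmet_", g$metabolites)))
  expect_true("hub" %in% g$removed_metabolites)
  # bipartite: every edge joins one metabolite and one reaction vertex
  ends <- igraph::as_edgelist(g$graph)
  expect_true(all(xor(grepl("^m:", ends[, 1]), grepl("^m:", ends[, 2]))))
})

test_that("the hub cutoff is a strict inequality", {
  mets <- c("busy", sprintf("s%02d", 1:50), "other", "x")
  rxns <- c(lapply(1:50, function(i)
    list(id = sprintf("r%02d", i), substrates = "busy",
         products = sprintf("s%02d", i), reversible = FALSE,
         genes = "gA")),
    list(list(id = "r51", substrates = "other", products = "x",
              reversible = FALSE, genes = "gA")))
  model <- metabolic_model(rxns, data.frame(id = mets, compartment = "c"))
  net <- regulatory_network(data.frame(tf = "T", target = "gA", sign = 1L))
  g50 <- build_graph(model, net, hub_cutoff = 50, cofactors = character(0))
  expect_true("busy" %in% g50$metabolites)   # exactly 50 reactions: retained
  g49 <- build_graph(model, net, hub_cutoff = 49, cofactors = character(0))
  expect_false("busy" %in% g49$metabolites)  # 50 > 49: removed
})

test_that("every graph edge corresponds to a substrate/product role", {
  cfg <- small_cfg()
  b <- generate_dataset(cfg)
  g <- build_graph(b$model, b$net)
  ends <- igraph::as_edgelist(g$graph)
  mcol <- ifelse(grepl("^m:", ends[, 1]), ends[, 1], ends[, 2])
  rcol <- ifelse(grepl("^r:", ends[, 1]), ends[, 1], ends[, 2])
  edge_key <- paste(sub("^m:", "", mcol), sub("^r:", "", rcol))
  role_key <- paste(g$roles$metabolite, g$roles$reaction)
  expect_setequal(unique(edge_key), unique(role_key))
})

test_that("distance follows the linked-reaction count", {
  # chain: m1 -r1-> m2 -r2-> m3, only r2 regulated
  model <- metabolic_model(
    list(list(id = "r1", substrates = "m1", products = "m2",
              reversible = FALSE, genes = "gX"),
         list(id = "r2", substrates = "m2", products = "m3",
              reversible = FALSE, genes = "gR")),
    data.frame(id = c("m1", "m2", "m3"), compartment = "c"))
  net <- regulatory_network(data.frame(tf = "T", target = "gR", sign = 1L))
  g <- build_graph(model, net, cofactors = character(0))
  expect_equal(tf_metabolite_distance(g, "T", "m2")$distance, 0)
  expect_equal(tf_metabolite_distance(g, "T", "m1")$distance, 1)
  expect_equal(tf_metabolite_distance(g, "T", "m3")$distance, 0)
  expect_error(tf_metabolite_distance(g, "NoSuchTF", "m1"), "unknown TF")
})

test_that("infinite distances arise for absent metabolites and unregulated TFs", {
  model <- metabolic_model(
    list(list(id = "r1", substrates = "a", products = "b",
              reversible = FALSE, genes = "g1"),
         list(id = "r2", substrates = "c", products = "d",
              reversible = FALSE, genes = "g2")),
    data.frame(id = c("a", "b", "c", "d"), compartment = "c"))
  net <- regulatory_network(data.frame(tf = c("T1", "T2"),
                                       target = c("g1", "gZ"),
                                       sign = 1L))
  g <- build_graph(model, net, cofactors = character(0))
  expect_equal(tf_metabolite_distance(g, "T1", "nope")$distance, Inf)
  expect_equal(tf_metabolite_distance(g, "T2", "a")$distance, Inf)
  # disconnected component: no path from c/d to r1
  expect_equal(tf_metabolite_distance(g, "T1", "c")$distance, Inf)
})

test_that("position classification follows stated reaction directions", {
  model <- metabolic_model(
    list(list(id = "r1", substrates = "sub", products = "mid",
              reversible = FALSE, genes = "gR"),
         list(id = "r2", substrates = "mid", products = "prod",
              reversible = FALSE, genes = "gR"),
         list(id = "r3", substrates = "rev_m", products = "other",
              reversible = TRUE, genes = "gR")),
    data.frame(id = c("sub", "mid", "prod", "rev_m", "other"),
               compartment = "c"))
  net <- regulatory_network(data.frame(tf = "T", target = "gR", sign = 1L))
  g <- build_graph(model, net, cofactors = character(0))
  expect_equal(classify_position(g, "T", "sub"), "upstream")
  expect_equal(classify_position(g, "T", "mid"), "within")
  expect_equal(classify_position(g, "T", "prod"), "downstream")
  # reversible regulated reaction counts both roles
  expect_equal(classify_position(g, "T", "rev_m"), "within")
  expect_equal(classify_position(g, "T", "absent"), "unclassified")
})

test_that("isobaric annotation sets take the minimum member distance", {
  model <- metabolic_model(
    list(list(id = "r1", substrates = "near", products = "z",
              reversible = FALSE, genes = "gR"),
         list(id = "r2", substrates = "far0", products = "far1",
              reversible = FALSE, genes = "gX"),
         list(id = "r3", substrates = "far1", products = "far2",
              reversible = FALSE, genes = "gR")),
    data.frame(id = c("near", "z", "far0", "far1", "far2"),
               compartment = "c"))
  net <- regulatory_network(data.frame(tf = "T", target = "gR", sign = 1L))
  g <- build_graph(model, net, cofactors = character(0))
  rec <- tf_metabolite_distance(g, "T", "far0;near")
  expect_equal(rec$distance, 0)
  expect_equal(rec$position, "upstream")  # taken from the arg-min compound
})

test_that("distance equals exhaustive simple-path enumeration on random models", {
  for (s in 1:20) {
    rm <- random_model(seed = 100 + s)
    g <- build_graph(rm$model, rm$net, cofactors = character(0))
    for (tf in unique(rm$net$tf)) {
      for (m in g$metabolites) {
        got <- tf_metabolite_distance(g, tf, m)$distance
        expect_equal(got, brute_force_distance(g, tf, m),
                     label = sprintf("seed %d tf %s met %s", s, tf, m))
      }
    }
  }
})

test_that("removing a metabolite never decreases any distance", {
  rm <- random_model(seed = 321, n_mets = 15, n_rxns = 20)
  g0 <- build_graph(rm$model, rm$net, cofactors = character(0))
  victim <- g0$metabolites[3]
  g1 <- build_graph(rm$model, rm$net, cofactors = victim)
  for (tf in unique(rm$net$tf))
    for (m in setdiff(g0$metabolites, victim)) {
      d0 <- tf_metabolite_distance(g0, tf, m)$distance
      d1 <- tf_metabolite_distance(g1, tf, m)$distance
      expect_gte(d1, d0)
    }
})

test_that("compute_distances matches the per-pair function and flags TFs", {
  cfg <- small_cfg()
  b <- generate_dataset(cfg)
  g <- build_graph(b$model, b$net)
  tfs <- unique(b$net$tf)[1:4]
  mets <- rownames(b$metabolome$values)[1:6]
  grid <- compute_distances(g, tfs, mets)
  expect_equal(nrow(grid), length(tfs) * length(mets))
  for (i in seq_len(nrow(grid))) {
    rec <- tf_metabolite_distance(g, grid$tf[i], grid$metabolite[i])
    expect_equal(grid$distance[i], rec$distance)
    expect_equal(grid$position[i], rec$position)
  }
  expect_equal(unname(grid$tf_has_regulated),
               unname(vapply(g$regulated[grid$tf], length, integer(1)) > 0))
})
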
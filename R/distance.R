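# Bipartite metabolite-reaction graph, TF-to-metabolite shortest-path
# distances (Dijkstra with unit edge weights, i.e. breadth-first search), and
# upstream/within/downstream classification of direct (distance-0) pairs.

# strip a trailing compartment suffix ("_c", "_e", ...) from a species id
.strip_compartment <- function(id, compartment) {
  suf <- paste0("_", compartment)
  ifelse(substring(id, nchar(id) - nchar(suf) + 1L) == suf,
         substring(id, 1L, nchar(id) - nchar(suf)), id)
}

#' Build the filtered bipartite metabolite-reaction graph
#'
#' Drops species outside the intracellular compartments and reactions whose
#' participants are all dropped; removes hub metabolites participating in
#' more than `hub_cutoff` reactions and every listed cofactor; annotates, per
#' TF, the reactions whose gene set intersects the TF's regulon. Metabolite
#' identifiers are compartment-stripped base ids. Edges are undirected for
#' distance computation; substrate/product roles are retained for position
#' classification.
#'
#' @param model a [metabolic_model()].
#' @param net a [regulatory_network()].
#' @param hub_cutoff metabolites in strictly more than this many reactions
#'   are removed (default 50).
#' @param cofactors character vector of cofactor/currency metabolite base ids
#'   to remove (default [default_cofactors()]).
#' @param intracellular compartment labels considered intracellular
#'   (default `"c"`).
#' @return object of class `metabolic_graph`: igraph `graph`, data.frame
#'   `roles` (`reaction`, `metabolite`, `role`), `reversible` (named
#'   logical), `regulated` (per-TF list of reaction ids),
#'   `removed_metabolites`, `metabolites`, `reactions`, `tfs`.
#' @export
build_graph <- function(model, net, hub_cutoff = 50,
                        cofactors = default_cofactors(),
                        intracellular = "c") {
  stopifnot(inherits(model, "metabolic_model"),
            inherits(net, "regulatory_network"))
  sp <- model$species
  keep_sp <- sp$id[sp$compartment %in% intracellular]
  comp <- setNames(sp$compartment, sp$id)
  base_id <- setNames(.strip_compartment(keep_sp, comp[keep_sp]), keep_sp)

  roles <- list()
  reversible <- logical(0)
  genes_by_rxn <- list()
  for (r in model$reactions) {
    subs <- intersect(r$substrates, keep_sp)
    prods <- intersect(r$products, keep_sp)
    if (!length(subs) && !length(prods)) next  # purely extracellular
    rows <- rbind(
      if (length(subs)) data.frame(reaction = r$id,
                                   metabolite = unname(base_id[subs]),
                                   role = "substrate",
                                   stringsAsFactors = FALSE),
      if (length(prods)) data.frame(reaction = r$id,
                                    metabolite = unname(base_id[prods]),
                                    role = "product",
                                    stringsAsFactors = FALSE))
    roles[[r$id]] <- rows
    reversible[r$id] <- isTRUE(r$reversible)
    genes_by_rxn[[r$id]] <- r$genes
  }
  roles <- do.call(rbind, c(roles, list(make.row.names = FALSE)))
  if (is.null(roles))
    stop("model has no intracellular reactions", call. = FALSE)

  # hub removal: reaction participation count per metabolite
  n_rxn <- tapply(roles$reaction, roles$metabolite,
                  function(r) length(unique(r)))
  hubs <- names(n_rxn)[n_rxn > hub_cutoff]
  removed <- union(hubs, cofactors)
  roles <- roles[!roles$metabolite %in% removed, , drop = FALSE]

  mets <- unique(roles$metabolite)
  rxns <- unique(roles$reaction)
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("m:", roles$metabolite),
               to = paste0("r:", roles$reaction),
               stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = c(paste0("m:", mets), paste0("r:", rxns)))

  tfs <- unique(net$tf)
  regulated <- lapply(tfs, function(tf) {
    targets <- regulon(net, tf)$target
    rxns[vapply(rxns, function(r)
      length(intersect(genes_by_rxn[[r]], targets)) > 0, logical(1))]
  })
  names(regulated) <- tfs

  structure(list(graph = g, roles = roles,
                 reversible = reversible[rxns],
                 regulated = regulated,
                 removed_metabolites = intersect(removed, names(n_rxn)),
                 metabolites = mets, reactions = rxns, tfs = tfs),
            class = "metabolic_graph")
}

#' @export
print.metabolic_graph <- function(x, ...) {
  cat(sprintf("<metabolic_graph> %d metabolites, %d reactions (%d removed)\n",
              length(x$metabolites), length(x$reactions),
              length(x$removed_metabolites)))
  invisible(x)
}

#' Default cofactor / currency metabolite list
#'
#' Common cofactors removed from the metabolic graph before distance
#' computation, to avoid biologically meaningless shortcuts. Fully
#' overridable via the `cofactors` argument of [build_graph()].
#'
#' @return character vector of base metabolite ids.
#' @export
default_cofactors <- function() {
  c("atp", "adp", "amp", "nad", "nadh", "nadp", "nadph", "coa",
    "pi", "ppi", "h2o", "h", "co2",
    "cofA", "cofB")
}

.distance_one <- function(graph, tf, metabolite) {
  regs <- graph$regulated[[tf]]
  mv <- paste0("m:", metabolite)
  if (!length(regs) || !(mv %in% igraph::V(graph$graph)$name))
    return(Inf)
  d <- igraph::distances(graph$graph, v = mv, to = paste0("r:", regs))
  best <- min(d)
  if (is.infinite(best)) Inf else (best - 1) / 2
}

#' Shortest-path distance from a TF's regulated reactions to a metabolite
#'
#' Distance = number of reactions on the shortest metabolite-to-regulated-
#' reaction path in the undirected bipartite graph, minus one: 0 when the
#' metabolite is a substrate or product of a regulated reaction, +1 per
#' additional linking reaction, infinite when the metabolite is absent from
#' the graph (removed, unannotated or extracellular), the TF regulates no
#' reaction, or no path exists. A `;`-joined isobaric annotation set scores
#' the minimum over its member compounds.
#'
#' @param graph a [build_graph()] result.
#' @param tf TF identifier (must exist in the regulatory network).
#' @param metabolite metabolite base id, or `;`-joined set of ids.
#' @return data.frame (one row) with `tf`, `metabolite`, `distance`,
#'   `position`.
#' @export
tf_metabolite_distance <- function(graph, tf, metabolite) {
  stopifnot(inherits(graph, "metabolic_graph"))
  if (!tf %in% graph$tfs)
    stop(sprintf("unknown TF id: '%s'", tf), call. = FALSE)
  members <- strsplit(metabolite, ";", fixed = TRUE)[[1]]
  dists <- vapply(members, function(m) .distance_one(graph, tf, m),
                  numeric(1))
  if (all(is.infinite(dists))) {
    d <- Inf
    pos <- "unclassified"
  } else {
    best <- which.min(dists)
    d <- unname(dists[best])
    pos <- if (d == 0) .classify_one(graph, tf, members[best])
           else "unclassified"
  }
  data.frame(tf = tf, metabolite = metabolite, distance = d,
             position = pos, stringsAsFactors = FALSE)
}

.classify_one <- function(graph, tf, metabolite) {
  regs <- graph$regulated[[tf]]
  rr <- graph$roles[graph$roles$metabolite == metabolite &
                      graph$roles$reaction %in% regs, , drop = FALSE]
  if (!nrow(rr)) return("unclassified")
  rev <- graph$reversible[rr$reaction]
  is_sub <- any(rr$role == "substrate" | rev)
  is_prod <- any(rr$role == "product" | rev)
  if (is_sub && is_prod) "within"
  else if (is_sub) "upstream"
  else if (is_prod) "downstream"
  else "unclassified"
}

#' Classify a direct metabolite as upstream / within / downstream
#'
#' Uses the stated reaction directions among the TF's regulated reactions:
#' substrate of at least one and product of none = upstream (feedforward
#' sensing of a pathway input); product only = downstream (end-product
#' feedback); both roles = within (pathway intermediate). A reversible
#' regulated reaction counts the metabolite in both roles. Metabolites that
#' do not participate directly in a regulated reaction (distance != 0) are
#' `"unclassified"`.
#'
#' @param graph a [build_graph()] result.
#' @param tf TF identifier.
#' @param metabolite metabolite base id.
#' @return one of `"upstream"`, `"within"`, `"downstream"`, `"unclassified"`.
#' @export
classify_position <- function(graph, tf, metabolite) {
  stopifnot(inherits(graph, "metabolic_graph"))
  if (!tf %in% graph$tfs)
    stop(sprintf("unknown TF id: '%s'", tf), call. = FALSE)
  .classify_one(graph, tf, metabolite)
}

#' Distance records for a grid of TFs and metabolites
#'
#' Vectorized wrapper over [tf_metabolite_distance()] annotating, per TF,
#' whether the TF regulates any reaction at all (TFs without enzymatic
#' targets yield infinite distances and are excluded by the candidate
#' cascade).
#'
#' @param graph a [build_graph()] result.
#' @param tfs character vector of TF identifiers.
#' @param metabolites character vector of metabolite ids (annotation sets
#'   allowed).
#' @return data.frame with `tf`, `metabolite`, `distance`, `position`,
#'   `tf_has_regulated`.
#' @export
compute_distances <- function(graph, tfs, metabolites) {
  stopifnot(inherits(graph, "metabolic_graph"))
  unknown <- setdiff(tfs, graph$tfs)
  if (length(unknown))
    stop(sprintf("unknown TF id: '%s'", unknown[1]), call. = FALSE)
  member_list <- strsplit(metabolites, ";", fixed = TRUE)
  all_members <- unique(unlist(member_list))
  vn <- igraph::V(graph$graph)$name
  present <- all_members[paste0("m:", all_members) %in% vn]

  res <- data.frame(tf = rep(tfs, times = length(metabolites)),
                    metabolite = rep(metabolites, each = length(tfs)),
                    distance = Inf, position = "unclassified",
                    stringsAsFactors = FALSE)
  for (ti in seq_along(tfs)) {
    tf <- tfs[ti]
    regs <- graph$regulated[[tf]]
    if (length(regs) && length(present)) {
      D <- igraph::distances(graph$graph, v = paste0("m:", present),
                             to = paste0("r:", regs))
      dmin <- apply(D, 1, min)
      dmap <- setNames(ifelse(is.finite(dmin), (dmin - 1) / 2, Inf), present)
    } else {
      dmap <- setNames(rep(Inf, length(present)), present)
    }
    for (mi in seq_along(metabolites)) {
      mem <- member_list[[mi]]
      dv <- rep(Inf, length(mem))
      hit <- mem %in% present
      dv[hit] <- dmap[mem[hit]]
      row <- (mi - 1L) * length(tfs) + ti
      if (all(is.infinite(dv))) next
      best <- which.min(dv)
      res$distance[row] <- dv[best]
      if (dv[best] == 0)
        res$position[row] <- .classify_one(graph, tf, mem[best])
    }
  }
  has_reg <- vapply(graph$regulated, length, integer(1)) > 0
  res$tf_has_regulated <- unname(has_reg[res$tf])
  res
}
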
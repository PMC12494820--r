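#' @importFrom stats median sd cor qnorm rnorm runif chisq.test setNames
#' @importFrom utils read.delim write.table head
NULL

# Numbers are serialized with 17 significant digits so that write -> read is
# an exact round trip at double precision.
.fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.infinite(x) & x > 0] <- "inf"
  out[is.infinite(x) & x < 0] <- "-inf"
  out[is.na(x)] <- "NA"
  trimws(out)
}

.parse_num <- function(x) {
  x <- trimws(as.character(x))
  out <- suppressWarnings(as.numeric(x))
  out[tolower(x) %in% c("inf", "+inf", "infinity")] <- Inf
  out[tolower(x) %in% c("-inf", "-infinity")] <- -Inf
  out
}

.read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, colClasses = "character", ...)
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, fileEncoding = "UTF-8")
}

.stop_format <- function(...) stop(sprintf(...), call. = FALSE)


# ---- ExpressionMatrix -------------------------------------------------------

#' Construct a validated expression matrix
#'
#' Container for a genes x conditions matrix of (log-scale) expression values
#' together with per-condition metadata. The metadata may name, per condition,
#' the knocked-out gene and the paired control condition used by the knockout
#' benchmark of the activity-inference step.
#'
#' @param values numeric matrix, rows = genes, columns = conditions, with
#'   unique finite dimnames.
#' @param meta optional data.frame with a `condition` column and optionally
#'   `strain`, `perturbation`, `knocked_out_gene`, `control_condition_id`.
#' @return an object of class `expression_matrix` with elements `values` and
#'   `meta`.
#' @export
expression_matrix <- function(values, meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    .stop_format("expression values must be a numeric matrix")
  genes <- rownames(values); conds <- colnames(values)
  if (is.null(genes) || is.null(conds))
    .stop_format("expression matrix must carry gene and condition names")
  if (anyDuplicated(genes))
    .stop_format("duplicate gene identifier: %s", genes[duplicated(genes)][1])
  if (anyDuplicated(conds))
    .stop_format("duplicate condition identifier: %s",
                 conds[duplicated(conds)][1])
  if (any(!is.finite(values)))
    .stop_format("expression values must be finite")
  if (is.null(meta)) {
    meta <- data.frame(condition = conds, strain = NA_character_,
                       perturbation = NA_character_,
                       knocked_out_gene = NA_character_,
                       control_condition_id = NA_character_,
                       stringsAsFactors = FALSE)
  } else {
    meta <- as.data.frame(meta, stringsAsFactors = FALSE)
    if (!"condition" %in% names(meta))
      .stop_format("condition metadata must have a 'condition' column")
    for (col in c("strain", "perturbation", "knocked_out_gene",
                  "control_condition_id"))
      if (!col %in% names(meta)) meta[[col]] <- NA_character_
    missing <- setdiff(meta$condition, conds)
    if (length(missing))
      .stop_format("metadata condition absent from matrix: %s", missing[1])
    ko <- meta$knocked_out_gene
    bad <- ko[!is.na(ko) & ko != "" & !(ko %in% genes)]
    if (length(bad))
      .stop_format("knocked_out_gene not present in genes: %s", bad[1])
    ctl <- meta$control_condition_id
    badc <- ctl[!is.na(ctl) & ctl != "" & !(ctl %in% conds)]
    if (length(badc))
      .stop_format("control_condition_id not present in conditions: %s",
                   badc[1])
    meta <- meta[match(conds, meta$condition), , drop = FALSE]
    meta$condition <- conds
    rownames(meta) <- NULL
  }
  structure(list(values = values, meta = meta), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d conditions\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read an expression matrix (and optional condition metadata) from TSV
#'
#' First column holds gene identifiers, remaining columns one condition each.
#' Row and column order are preserved from the file.
#'
#' @param path path to the matrix TSV.
#' @param meta_path optional path to a condition metadata TSV keyed by a
#'   `condition` column.
#' @return an [expression_matrix()].
#' @export
read_expression_matrix <- function(path, meta_path = NULL) {
  df <- .read_tsv(path)
  if (ncol(df) < 2) .stop_format("expression file needs >=1 condition column")
  genes <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- apply(vals, 2, .parse_num)
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(vals),
                                     dimnames = dimnames(vals))
  bad <- which(is.na(num) & vals != "NA", arr.ind = TRUE)
  if (nrow(bad))
    .stop_format("non-numeric expression value at gene '%s', condition '%s'",
                 genes[bad[1, 1]], colnames(vals)[bad[1, 2]])
  rownames(num) <- genes
  meta <- if (!is.null(meta_path)) .read_tsv(meta_path) else NULL
  expression_matrix(num, meta)
}

#' Write an expression matrix (and its condition metadata) to TSV
#'
#' @param x an [expression_matrix()].
#' @param path output path for the matrix.
#' @param meta_path optional output path for the metadata table.
#' @return invisibly, `x`.
#' @export
write_expression_matrix <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(gene = rownames(x$values), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (j in colnames(x$values)) df[[j]] <- .fmt_num(x$values[, j])
  .write_tsv(df, path)
  if (!is.null(meta_path)) .write_tsv(x$meta, meta_path)
  invisible(x)
}


# ---- RegulatoryNetwork ------------------------------------------------------

#' Construct a signed TF-to-gene regulatory network
#'
#' Edges carry a regulation sign: +1 (activation), -1 (repression) or 0
#' (dual/unknown mode). Duplicate (tf, target) rows with conflicting signs are
#' collapsed to sign 0.
#'
#' @param edges data.frame with columns `tf`, `target`, `sign` (+1/-1/0).
#' @return an object of class `regulatory_network` (a validated data.frame).
#' @export
regulatory_network <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  stopifnot(all(c("tf", "target", "sign") %in% names(edges)))
  edges$sign <- as.integer(edges$sign)
  if (any(!edges$sign %in% c(-1L, 0L, 1L)))
    .stop_format("edge sign must be one of -1, 0, +1")
  key <- paste(edges$tf, edges$target, sep = "\r")
  if (anyDuplicated(key)) {
    sg <- tapply(edges$sign, key, function(s)
      if (length(unique(s)) == 1L) s[1] else 0L)
    first <- edges[!duplicated(key), c("tf", "target")]
    first$sign <- as.integer(sg[paste(first$tf, first$target, sep = "\r")])
    edges <- first
  }
  rownames(edges) <- NULL
  structure(edges[, c("tf", "target", "sign")],
            class = c("regulatory_network", "data.frame"))
}

#' Regulon of one TF
#'
#' @param net a [regulatory_network()].
#' @param tf TF identifier.
#' @return data.frame of `target` and `sign` rows for that TF.
#' @export
regulon <- function(net, tf) {
  net[net$tf == tf, c("target", "sign"), drop = FALSE]
}

.effect_to_sign <- function(effect) {
  map <- c(activator = 1L, activation = 1L, "+" = 1L,
           repressor = -1L, repression = -1L, "-" = -1L,
           dual = 0L, "+-" = 0L, "-+" = 0L, unknown = 0L, "?" = 0L)
  s <- map[tolower(trimws(effect))]
  if (any(is.na(s)))
    .stop_format("unknown regulation effect token: '%s'",
                 effect[is.na(s)][1])
  unname(s)
}

#' Read a regulatory network from a three-column TSV
#'
#' Columns: tf, target, effect. Effect tokens `activator`/`repressor`/`dual`
#' (or `+`/`-`/`+-`) map to signs +1/-1/0.
#'
#' @param path path to the TSV.
#' @return a [regulatory_network()].
#' @export
read_regulatory_network <- function(path) {
  df <- .read_tsv(path)
  if (ncol(df) < 3) .stop_format("network file needs columns tf, target, effect")
  names(df)[1:3] <- c("tf", "target", "effect")
  regulatory_network(data.frame(tf = df$tf, target = df$target,
                                sign = .effect_to_sign(df$effect),
                                stringsAsFactors = FALSE))
}

#' Write a regulatory network to TSV
#'
#' @param net a [regulatory_network()].
#' @param path output path.
#' @return invisibly, `net`.
#' @export
write_regulatory_network <- function(net, path) {
  eff <- c("repressor", "dual", "activator")[net$sign + 2L]
  .write_tsv(data.frame(tf = net$tf, target = net$target, effect = eff,
                        stringsAsFactors = FALSE), path)
  invisible(net)
}


# ---- MetabolicModel ---------------------------------------------------------

#' Construct a metabolic model
#'
#' A reaction-list model: each reaction has substrate and product metabolite
#' ids, a reversibility flag and a (possibly empty) set of catalyzing gene
#' identifiers flattened from its gene-association rule.
#'
#' @param reactions list of reaction records, each a list with elements `id`,
#'   `substrates` (character), `products` (character), `reversible` (logical)
#'   and `genes` (character).
#' @param species data.frame with columns `id` and `compartment` covering every
#'   metabolite referenced by the reactions.
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(reactions, species) {
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "compartment") %in% names(species)))
  if (anyDuplicated(species$id))
    .stop_format("duplicate species id: %s",
                 species$id[duplicated(species$id)][1])
  ids <- vapply(reactions, function(r) r$id, character(1))
  if (anyDuplicated(ids))
    .stop_format("duplicate reaction id: %s", ids[duplicated(ids)][1])
  for (r in reactions) {
    if (length(r$substrates) == 0 || length(r$products) == 0)
      .stop_format("reaction '%s' must have >=1 substrate and >=1 product",
                   r$id)
    unk <- setdiff(c(r$substrates, r$products), species$id)
    if (length(unk))
      .stop_format("reaction '%s' references unknown species '%s'",
                   r$id, unk[1])
  }
  names(reactions) <- ids
  structure(list(reactions = reactions, species = species),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("<metabolic_model> %d reactions, %d species\n",
              length(x$reactions), nrow(x$species)))
  invisible(x)
}

# Flatten a boolean gene-association rule ("(b001 and b002) or b003") to the
# set of gene identifiers it mentions. Unparseable rules yield an empty set
# with a warning rather than an error.
.flatten_gene_rule <- function(rule, rxn_id = "?") {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(character())
  toks <- strsplit(gsub("[()]", " ", rule), "[[:space:]]+")[[1]]
  toks <- toks[nzchar(toks)]
  genes <- toks[!tolower(toks) %in% c("and", "or")]
  if (!length(genes)) {
    warning(sprintf("unparseable gene rule for reaction '%s'; empty gene set",
                    rxn_id), call. = FALSE)
    return(character())
  }
  unique(genes)
}

#' Read a metabolic model from SBML or JSON
#'
#' Dispatches on file extension: `.json` is parsed as a COBRA-style reaction
#' list (objects with a `metabolites` stoichiometry map and a
#' `gene_reaction_rule` string), anything else as SBML Level 3 with
#' COBRA-convention `GENE_ASSOCIATION` notes. Species with negative
#' stoichiometry become substrates, positive become products; the reversible
#' flag is taken from the reaction attribute or, for JSON, from
#' `lower_bound < 0` when no flag is present.
#'
#' @param path model file path.
#' @return a [metabolic_model()].
#' @export
read_metabolic_model <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE))
    .read_model_json(path)
  else
    .read_model_sbml(path)
}

.read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  sp <- do.call(rbind, lapply(obj$metabolites, function(m)
    data.frame(id = m$id,
               compartment = if (is.null(m$compartment)) "c" else m$compartment,
               stringsAsFactors = FALSE)))
  rxns <- lapply(obj$reactions, function(r) {
    st <- unlist(r$metabolites)
    rev <- if (!is.null(r$reversible)) isTRUE(r$reversible)
           else !is.null(r$lower_bound) && r$lower_bound < 0
    list(id = r$id,
         substrates = names(st)[st < 0],
         products = names(st)[st > 0],
         reversible = rev,
         genes = .flatten_gene_rule(r$gene_reaction_rule, r$id))
  })
  metabolic_model(rxns, sp)
}

.read_model_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  sp_nodes <- xml2::xml_find_all(doc, ".//listOfSpecies/species")
  sp <- data.frame(id = xml2::xml_attr(sp_nodes, "id"),
                   compartment = xml2::xml_attr(sp_nodes, "compartment"),
                   stringsAsFactors = FALSE)
  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  rxns <- lapply(rx_nodes, function(node) {
    id <- xml2::xml_attr(node, "id")
    subs <- xml2::xml_attr(
      xml2::xml_find_all(node, "./listOfReactants/speciesReference"), "species")
    prods <- xml2::xml_attr(
      xml2::xml_find_all(node, "./listOfProducts/speciesReference"), "species")
    rev <- identical(xml2::xml_attr(node, "reversible"), "true")
    notes <- xml2::xml_text(xml2::xml_find_all(node, "./notes//p"))
    rule_line <- notes[grepl("GENE_ASSOCIATION", notes)]
    rule <- if (length(rule_line))
      sub(".*GENE_ASSOCIATION:\\s*", "", rule_line[1]) else ""
    list(id = id, substrates = subs, products = prods, reversible = rev,
         genes = .flatten_gene_rule(rule, id))
  })
  metabolic_model(rxns, sp)
}

#' Write a metabolic model to SBML Level 3 or JSON
#'
#' @param model a [metabolic_model()].
#' @param path output path; `.json` selects the JSON reaction-list dialect.
#' @return invisibly, `model`.
#' @export
write_metabolic_model <- function(model, path) {
  stopifnot(inherits(model, "metabolic_model"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- list(
      metabolites = lapply(seq_len(nrow(model$species)), function(i)
        list(id = model$species$id[i],
             compartment = model$species$compartment[i])),
      reactions = lapply(unname(model$reactions), function(r) {
        st <- c(setNames(rep(-1, length(r$substrates)), r$substrates),
                setNames(rep(1, length(r$products)), r$products))
        list(id = r$id, metabolites = as.list(st),
             reversible = isTRUE(r$reversible),
             gene_reaction_rule = paste(r$genes, collapse = " or "))
      }))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    doc <- xml2::xml_new_root("sbml",
      xmlns = "http://www.sbml.org/sbml/level3/version1/core",
      level = "3", version = "1")
    mdl <- xml2::xml_add_child(doc, "model", id = "model")
    los <- xml2::xml_add_child(mdl, "listOfSpecies")
    for (i in seq_len(nrow(model$species)))
      xml2::xml_add_child(los, "species", id = model$species$id[i],
                          compartment = model$species$compartment[i])
    lor <- xml2::xml_add_child(mdl, "listOfReactions")
    for (r in model$reactions) {
      rn <- xml2::xml_add_child(lor, "reaction", id = r$id,
                                reversible = tolower(isTRUE(r$reversible)))
      if (length(r$genes)) {
        nt <- xml2::xml_add_child(rn, "notes")
        bd <- xml2::xml_add_child(nt, "body",
          xmlns = "http://www.w3.org/1999/xhtml")
        xml2::xml_add_child(bd, "p", paste0("GENE_ASSOCIATION: ",
                                            paste(r$genes, collapse = " or ")))
      }
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (s in r$substrates)
        xml2::xml_add_child(lre, "speciesReference", species = s,
                            stoichiometry = "1")
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (p in r$products)
        xml2::xml_add_child(lpr, "speciesReference", species = p,
                            stoichiometry = "1")
    }
    xml2::write_xml(doc, path)
  }
  invisible(model)
}


# ---- IonTable ---------------------------------------------------------------

#' Construct an ion-intensity table
#'
#' Long-format container for flow-injection MS ion intensities across
#' conditions and replicates. Depending on the preprocessing stage the data
#' carry technical replicates (`level = "tech"`), only biological replicates
#' (`"bio"`), or one value per condition (`"condition"`).
#'
#' @param ions data.frame with columns `ion_id` and `mz` (observed m/z in Da).
#' @param data data.frame with columns `ion_id`, `condition`, `intensity` and,
#'   depending on `level`, `bio_rep` and `tech_rep`.
#' @param level replicate level of `data`.
#' @return an object of class `ion_table`.
#' @export
ion_table <- function(ions, data, level = c("tech", "bio", "condition")) {
  level <- match.arg(level)
  ions <- as.data.frame(ions, stringsAsFactors = FALSE)
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  stopifnot(all(c("ion_id", "mz") %in% names(ions)))
  need <- switch(level,
                 tech = c("ion_id", "condition", "bio_rep", "tech_rep",
                          "intensity"),
                 bio = c("ion_id", "condition", "bio_rep", "intensity"),
                 condition = c("ion_id", "condition", "intensity"))
  if (!all(need %in% names(data)))
    .stop_format("ion table at level '%s' needs columns: %s", level,
                 paste(need, collapse = ", "))
  ions$mz <- .parse_num(ions$mz)
  if (any(!is.finite(ions$mz)) || any(ions$mz <= 0))
    .stop_format("ion m/z values must be positive")
  if (anyDuplicated(ions$ion_id))
    .stop_format("duplicate ion id: %s",
                 ions$ion_id[duplicated(ions$ion_id)][1])
  data$intensity <- .parse_num(data$intensity)
  if (any(is.na(data$intensity)) || any(data$intensity < 0))
    .stop_format("ion intensities must be nonnegative numbers")
  unk <- setdiff(data$ion_id, ions$ion_id)
  if (length(unk)) .stop_format("intensity row for unknown ion '%s'", unk[1])
  structure(list(ions = ions, data = data[, need], level = level),
            class = "ion_table")
}

#' @export
print.ion_table <- function(x, ...) {
  cat(sprintf("<ion_table> %d ions, %d rows (level: %s)\n",
              nrow(x$ions), nrow(x$data), x$level))
  invisible(x)
}

#' Read an ion table from TSV
#'
#' Expected columns: ion_id, mz, condition, bio_rep, tech_rep, intensity
#' (replicate columns may be absent for partially collapsed tables).
#'
#' @param path path to the TSV.
#' @return an [ion_table()].
#' @export
read_ion_table <- function(path) {
  df <- .read_tsv(path)
  level <- if ("tech_rep" %in% names(df)) "tech"
           else if ("bio_rep" %in% names(df)) "bio" else "condition"
  ions <- unique(df[, c("ion_id", "mz")])
  ion_table(ions, df[, setdiff(names(df), "mz")], level = level)
}

#' Write an ion table to TSV
#'
#' @param x an [ion_table()].
#' @param path output path.
#' @return invisibly, `x`.
#' @export
write_ion_table <- function(x, path) {
  stopifnot(inherits(x, "ion_table"))
  df <- x$data
  df$mz <- .fmt_num(x$ions$mz[match(df$ion_id, x$ions$ion_id)])
  df$intensity <- .fmt_num(.parse_num(df$intensity))
  first <- c("ion_id", "mz")
  .write_tsv(df[, c(first, setdiff(names(df), first))], path)
  invisible(x)
}

#' Read a compound reference list (compound_id, monoisotopic_mass) from TSV
#'
#' @param path path to the TSV.
#' @return data.frame with columns `compound_id` and `monoisotopic_mass`.
#' @export
read_compound_reference <- function(path) {
  df <- .read_tsv(path)
  stopifnot(all(c("compound_id", "monoisotopic_mass") %in% names(df)))
  df$monoisotopic_mass <- .parse_num(df$monoisotopic_mass)
  if (anyDuplicated(df$compound_id))
    .stop_format("duplicate compound id: %s",
                 df$compound_id[duplicated(df$compound_id)][1])
  if (any(!is.finite(df$monoisotopic_mass)) || any(df$monoisotopic_mass <= 0))
    .stop_format("monoisotopic masses must be positive")
  df
}

#' Write a compound reference list to TSV
#'
#' @param ref data.frame with `compound_id`, `monoisotopic_mass`.
#' @param path output path.
#' @return invisibly, `ref`.
#' @export
write_compound_reference <- function(ref, path) {
  ref$monoisotopic_mass <- .fmt_num(ref$monoisotopic_mass)
  .write_tsv(ref, path)
  invisible(ref)
}


# ---- KnownInteractionSet ----------------------------------------------------

#' Construct a set of known TF-metabolite interactions
#'
#' @param entries data.frame with columns `tf`, `metabolite`, `effect`
#'   (`"activating"` or `"inactivating"`).
#' @return an object of class `known_interactions` (a validated data.frame).
#' @export
known_interactions <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  stopifnot(all(c("tf", "metabolite", "effect") %in% names(entries)))
  if (any(!entries$effect %in% c("activating", "inactivating")))
    .stop_format("interaction effect must be 'activating' or 'inactivating'")
  key <- paste(entries$tf, entries$metabolite, sep = "\r")
  if (anyDuplicated(key))
    .stop_format("duplicate known interaction: %s / %s",
                 entries$tf[duplicated(key)][1],
                 entries$metabolite[duplicated(key)][1])
  rownames(entries) <- NULL
  structure(entries[, c("tf", "metabolite", "effect")],
            class = c("known_interactions", "data.frame"))
}

#' Read known TF-metabolite interactions from TSV
#'
#' @param path path to a TSV with columns tf, metabolite, effect.
#' @return a [known_interactions()].
#' @export
read_known_interactions <- function(path) known_interactions(.read_tsv(path))

#' Write known TF-metabolite interactions to TSV
#'
#' @param known a [known_interactions()].
#' @param path output path.
#' @return invisibly, `known`.
#' @export
write_known_interactions <- function(known, path) {
  .write_tsv(as.data.frame(known), path)
  invisible(known)
}


# ---- CandidatePair ----------------------------------------------------------

.validate_candidates <- function(pairs) {
  pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
  need <- c("tf", "metabolite", "correlation_score", "stability", "distance",
            "position", "known")
  if (!all(need %in% names(pairs)))
    .stop_format("candidate table needs columns: %s",
                 paste(need, collapse = ", "))
  if (nrow(pairs)) {
    if (any(abs(pairs$correlation_score) > 1 + 1e-12))
      .stop_format("correlation_score outside [-1, 1]")
    if (any(pairs$stability < 0 | pairs$stability > 1))
      .stop_format("stability outside [0, 1]")
    if (any(pairs$distance < 0, na.rm = TRUE))
      .stop_format("distance must be >= 0 or infinite")
  }
  pairs[, need]
}

#' Write candidate TF-metabolite pairs to TSV
#'
#' Rows are sorted by TF and, within a TF, by descending correlation score.
#' Infinite distances are serialized as the literal `inf`.
#'
#' @param pairs data.frame of candidate pairs (`tf`, `metabolite`,
#'   `correlation_score`, `stability`, `distance`, `position`, `known`).
#' @param path output path.
#' @return invisibly, the sorted candidate table.
#' @export
write_candidates <- function(pairs, path) {
  pairs <- .validate_candidates(pairs)
  if (nrow(pairs))
    pairs <- pairs[order(pairs$tf, -pairs$correlation_score,
                         pairs$metabolite), , drop = FALSE]
  out <- pairs
  out$correlation_score <- .fmt_num(pairs$correlation_score)
  out$stability <- .fmt_num(pairs$stability)
  out$distance <- .fmt_num(pairs$distance)
  out$known <- ifelse(pairs$known, "true", "false")
  .write_tsv(out, path)
  invisible(pairs)
}

#' Read candidate TF-metabolite pairs from TSV
#'
#' @param path path written by [write_candidates()].
#' @return data.frame of candidate pairs.
#' @export
read_candidates <- function(path) {
  df <- .read_tsv(path)
  df$correlation_score <- .parse_num(df$correlation_score)
  df$stability <- .parse_num(df$stability)
  df$distance <- .parse_num(df$distance)
  df$known <- tolower(df$known) %in% c("true", "1", "yes")
  .validate_candidates(df)
}
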
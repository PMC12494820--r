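# Metabolomics preprocessing: technical-replicate merging, total ion count
# normalization, coefficient-of-variation filtering and exact-mass annotation,
# turning a replicated ion table into a metabolite x condition matrix.

#' Construct a metabolite abundance matrix
#'
#' @param values nonnegative numeric matrix, rows = metabolites (annotation
#'   keys, possibly `;`-joined sets of isobaric compounds), columns =
#'   conditions.
#' @param annotation optional data.frame of row provenance with columns
#'   `metabolite`, `compounds`, `ion_id`, `mz`.
#' @return an object of class `metabolite_matrix`.
#' @export
metabolite_matrix <- function(values, annotation = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    .stop_format("metabolite values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    .stop_format("metabolite matrix must carry metabolite and condition names")
  if (anyDuplicated(rownames(values)))
    .stop_format("duplicate metabolite row: %s",
                 rownames(values)[duplicated(rownames(values))][1])
  if (any(values < 0))
    .stop_format("metabolite abundances must be nonnegative")
  if (is.null(annotation))
    annotation <- data.frame(metabolite = rownames(values),
                             compounds = rownames(values),
                             ion_id = NA_character_, mz = NA_real_,
                             stringsAsFactors = FALSE)
  structure(list(values = values, annotation = annotation),
            class = "metabolite_matrix")
}

#' @export
print.metabolite_matrix <- function(x, ...) {
  cat(sprintf("<metabolite_matrix> %d metabolites x %d conditions\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Read a metabolite abundance matrix from TSV
#'
#' @param path TSV with first column metabolite ids, one column per condition.
#' @return a [metabolite_matrix()].
#' @export
read_metabolite_matrix <- function(path) {
  df <- .read_tsv(path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- apply(vals, 2, .parse_num)
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(vals),
                                     dimnames = dimnames(vals))
  rownames(num) <- df[[1]]
  metabolite_matrix(num)
}

#' Write a metabolite abundance matrix to TSV
#'
#' @param x a [metabolite_matrix()].
#' @param path output path.
#' @return invisibly, `x`.
#' @export
write_metabolite_matrix <- function(x, path) {
  stopifnot(inherits(x, "metabolite_matrix"))
  df <- data.frame(metabolite = rownames(x$values), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (j in colnames(x$values)) df[[j]] <- .fmt_num(x$values[, j])
  .write_tsv(df, path)
  invisible(x)
}

# replicate-column key at the current level of an ion table
.rep_key <- function(data, level) {
  switch(level,
         tech = paste(data$condition, data$bio_rep, data$tech_rep, sep = "\r"),
         bio = paste(data$condition, data$bio_rep, sep = "\r"),
         condition = data$condition)
}

#' Total ion count normalization
#'
#' Divides every intensity by the total intensity of its
#' (condition, replicate) column, so each column sums to 1 while relative ion
#' proportions are preserved. Idempotent.
#'
#' @param table an [ion_table()].
#' @return the normalized [ion_table()].
#' @export
tic_normalize <- function(table) {
  stopifnot(inherits(table, "ion_table"))
  key <- .rep_key(table$data, table$level)
  tot <- tapply(table$data$intensity, key, sum)
  if (any(tot <= 0))
    .stop_format("all-zero intensity column: %s",
                 gsub("\r", "/", names(tot)[tot <= 0][1]))
  table$data$intensity <- table$data$intensity / as.numeric(tot[key])
  table
}

#' Average technical replicates
#'
#' Collapses technical replicates (repeated injections of the same biological
#' sample) to their arithmetic mean per ion, leaving one value per
#' (condition, biological replicate).
#'
#' @param table an [ion_table()] at technical-replicate level.
#' @return an [ion_table()] at biological-replicate level.
#' @export
merge_replicates <- function(table) {
  stopifnot(inherits(table, "ion_table"))
  if (table$level != "tech") return(table)
  d <- table$data
  key <- paste(d$ion_id, d$condition, d$bio_rep, sep = "\r")
  agg <- tapply(d$intensity, key, mean)
  first <- d[!duplicated(key), c("ion_id", "condition", "bio_rep")]
  first$intensity <- as.numeric(
    agg[paste(first$ion_id, first$condition, first$bio_rep, sep = "\r")])
  rownames(first) <- NULL
  ion_table(table$ions, first, level = "bio")
}

#' Coefficient-of-variation filter
#'
#' For every ion x condition, the CV (sd/mean) across biological replicates is
#' computed; an ion whose CV reaches `max_cv` in any condition is dropped
#' entirely (whole-profile removal, so every retained ion has a complete
#' condition profile for correlation). Retained cells are collapsed to the
#' replicate mean. A cell with mean 0 and nonzero sd counts as failing.
#'
#' @param table an [ion_table()] at biological-replicate level.
#' @param max_cv CV threshold (default 0.15, i.e. 15 percent).
#' @return an [ion_table()] at condition level containing only retained ions.
#' @export
cv_filter <- function(table, max_cv = 0.15) {
  stopifnot(inherits(table, "ion_table"))
  if (table$level == "tech") table <- merge_replicates(table)
  if (table$level != "bio")
    .stop_format("cv_filter needs biological replicates")
  d <- table$data
  key <- paste(d$ion_id, d$condition, sep = "\r")
  n_rep <- tapply(d$intensity, key, length)
  if (any(n_rep < 2))
    .stop_format("cv_filter needs >=2 biological replicates per condition")
  mu <- tapply(d$intensity, key, mean)
  sg <- tapply(d$intensity, key, sd)
  cv <- ifelse(mu > 0, sg / mu, ifelse(sg > 0, Inf, 0))
  fail_key <- names(cv)[cv >= max_cv]
  fail_ions <- unique(vapply(strsplit(fail_key, "\r"), `[`, character(1), 1))
  cells <- data.frame(do.call(rbind, strsplit(names(mu), "\r")),
                      stringsAsFactors = FALSE)
  names(cells) <- c("ion_id", "condition")
  cells$intensity <- as.numeric(mu)
  keep <- !cells$ion_id %in% fail_ions
  cells <- cells[keep, , drop = FALSE]
  ord <- order(match(cells$ion_id, table$ions$ion_id),
               match(cells$condition, unique(d$condition)))
  cells <- cells[ord, , drop = FALSE]
  rownames(cells) <- NULL
  ions <- table$ions[table$ions$ion_id %in% cells$ion_id, , drop = FALSE]
  ion_table(ions, cells, level = "condition")
}

#' Annotate ions against a compound reference by exact mass
#'
#' Assumes negative-mode [M-H]- ions: the expected m/z of a compound is its
#' neutral monoisotopic mass minus the proton mass (1.007276 Da). An ion is
#' annotated with every compound whose expected m/z lies within `tol`;
#' compounds sharing a (6-decimal rounded) reference mass collapse into a
#' single matrix row keyed by the `;`-joined annotation set, since isobaric
#' compounds cannot be distinguished by MS1. Unmatched ions are dropped; ions
#' mapping to the same annotation set are averaged.
#'
#' @param table an [ion_table()] at condition level (see [cv_filter()]).
#' @param ref compound reference data.frame (`compound_id`,
#'   `monoisotopic_mass`).
#' @param tol mass tolerance in Da (default 0.001).
#' @param adduct_mass mass offset of the assumed adduct (default -1.007276,
#'   the [M-H]- deprotonation).
#' @return a [metabolite_matrix()].
#' @export
annotate_ions <- function(table, ref, tol = 0.001, adduct_mass = -1.007276) {
  stopifnot(inherits(table, "ion_table"))
  if (table$level != "condition")
    .stop_format("annotate_ions expects a condition-level table")
  if (is.null(ref) || nrow(ref) == 0)
    .stop_format("empty compound reference")
  ref <- ref[order(ref$monoisotopic_mass, ref$compound_id), , drop = FALSE]
  exp_mz <- ref$monoisotopic_mass + adduct_mass
  # isobaric grouping key: reference mass rounded to 6 decimals
  grp <- as.character(round(ref$monoisotopic_mass, 6))
  grp_label <- vapply(split(ref$compound_id, grp), paste,
                      character(1), collapse = ";")

  conds <- unique(table$data$condition)
  rows <- list()
  for (i in seq_len(nrow(table$ions))) {
    mz <- table$ions$mz[i]
    hit <- which(abs(exp_mz - mz) <= tol)
    if (!length(hit)) next
    sets <- unique(grp[hit])
    for (s in sets) {
      lbl <- grp_label[[s]]
      d <- table$data[table$data$ion_id == table$ions$ion_id[i], ]
      v <- setNames(d$intensity[match(conds, d$condition)], conds)
      rows[[length(rows) + 1L]] <-
        list(metabolite = lbl, ion_id = table$ions$ion_id[i], mz = mz,
             values = v)
    }
  }
  if (!length(rows))
    return(metabolite_matrix(
      matrix(numeric(0), nrow = 0, ncol = length(conds),
             dimnames = list(character(0), conds))))
  labels <- vapply(rows, `[[`, character(1), "metabolite")
  uniq <- unique(labels)
  vals <- matrix(0, nrow = length(uniq), ncol = length(conds),
                 dimnames = list(uniq, conds))
  ann <- data.frame(metabolite = uniq, compounds = uniq,
                    ion_id = NA_character_, mz = NA_real_,
                    stringsAsFactors = FALSE)
  for (u in uniq) {
    sel <- rows[labels == u]
    vm <- do.call(rbind, lapply(sel, `[[`, "values"))
    vals[u, ] <- colMeans(vm)
    ann$ion_id[ann$metabolite == u] <-
      paste(vapply(sel, `[[`, character(1), "ion_id"), collapse = ";")
    ann$mz[ann$metabolite == u] <- sel[[1]]$mz
  }
  metabolite_matrix(vals, ann)
}

#' Maximum abundance fold change per metabolite
#'
#' Ratio of the highest to the lowest condition-level abundance of each
#' metabolite; always >= 1. A zero minimum yields an infinite ratio with a
#' warning.
#'
#' @param matrix a [metabolite_matrix()].
#' @return named numeric vector of fold changes.
#' @export
max_fold_change <- function(matrix) {
  stopifnot(inherits(matrix, "metabolite_matrix"))
  lo <- apply(matrix$values, 1, min)
  hi <- apply(matrix$values, 1, max)
  out <- hi / lo
  out[hi == 0 & lo == 0] <- 1
  if (any(is.infinite(out)))
    warning(sprintf("%d metabolite(s) with zero minimum abundance: infinite fold change",
                    sum(is.infinite(out))), call. = FALSE)
  out
}

#' Full metabolomics preprocessing chain
#'
#' Fixed order: [merge_replicates()] (technical duplicates),
#' [tic_normalize()], [cv_filter()], [annotate_ions()].
#'
#' @param table an [ion_table()] at technical-replicate level.
#' @param ref compound reference data.frame.
#' @param max_cv CV threshold for [cv_filter()].
#' @param tol mass tolerance for [annotate_ions()].
#' @return a [metabolite_matrix()].
#' @export
preprocess_ions <- function(table, ref, max_cv = 0.15, tol = 0.001) {
  annotate_ions(cv_filter(tic_normalize(merge_replicates(table)),
                          max_cv = max_cv),
                ref, tol = tol)
}
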
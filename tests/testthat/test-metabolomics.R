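make_ion_table <- function(intensity_by_col) {
  # intensity_by_col: list of condition -> matrix ions x (bio, tech) values
  rows <- list()
  ions <- sprintf("i%d", seq_len(nrow(intensity_by_col[[1]])))
  for (cond in names(intensity_by_col)) {
    m <- intensity_by_col[[cond]]
    for (b in seq_len(dim(m)[2]))
      for (tr in seq_len(dim(m)[3]))
        rows[[length(rows) + 1L]] <-
          data.frame(ion_id = ions, condition = cond, bio_rep = b,
                     tech_rep = tr, intensity = m[, b, tr],
                     stringsAsFactors = FALSE)
  }
  ion_table(data.frame(ion_id = ions, mz = 100 + seq_along(ions)),
            do.call(rbind, rows), level = "tech")
}

test_that("tic_normalize rescales columns to unit sum and is idempotent", {
  arr <- array(c(2, 3, 5), dim = c(3, 1, 1))
  tab <- make_ion_table(list(c1 = arr))
  norm <- tic_normalize(tab)
  expect_equal(norm$data$intensity, c(0.2, 0.3, 0.5))
  again <- tic_normalize(norm)
  expect_equal(again$data$intensity, norm$data$intensity)

  set.seed(4)
  arr2 <- array(runif(20 * 3 * 2, 0.1, 10), dim = c(20, 3, 2))
  tab2 <- tic_normalize(make_ion_table(list(a = arr2, b = arr2 * 2)))
  key <- paste(tab2$data$condition, tab2$data$bio_rep, tab2$data$tech_rep)
  sums <- tapply(tab2$data$intensity, key, sum)
  expect_true(all(abs(sums - 1) < 1e-12))

  zero <- make_ion_table(list(c1 = array(0, dim = c(3, 1, 1))))
  expect_error(tic_normalize(zero), "all-zero.*c1")
})

test_that("merge_replicates averages technical duplicates", {
  arr <- array(c(4, 1, 6, 3), dim = c(2, 1, 2))  # ion1: 4,6; ion2: 1,3
  merged <- merge_replicates(make_ion_table(list(c1 = arr)))
  expect_equal(merged$level, "bio")
  expect_equal(merged$data$intensity, c(5, 2))

  single <- array(c(4, 1), dim = c(2, 1, 1))
  m2 <- merge_replicates(make_ion_table(list(c1 = single)))
  expect_equal(m2$data$intensity, c(4, 1))

  set.seed(41)
  arr3 <- array(runif(5 * 2 * 3), dim = c(5, 2, 3))
  m3 <- merge_replicates(make_ion_table(list(c1 = arr3)))
  for (i in 1:5)
    for (b in 1:2) {
      v <- m3$data$intensity[m3$data$ion_id == sprintf("i%d", i) &
                               m3$data$bio_rep == b]
      expect_gte(v, min(arr3[i, b, ])); expect_lte(v, max(arr3[i, b, ]))
    }
})

test_that("cv_filter drops whole ion profiles that fail in any condition", {
  # ion1 constant (CV 0); ion2 mean 10 sd 2 in c2 (CV 0.2 >= 0.15)
  c1 <- array(rep(c(10, 5), 3), dim = c(2, 3, 1))
  c2 <- array(c(10, 8, 10, 10, 10, 12), dim = c(2, 3, 1))
  tab <- make_ion_table(list(c1 = c1, c2 = c2))
  filt <- cv_filter(tab)
  expect_equal(unique(filt$data$ion_id), "i1")
  expect_equal(filt$level, "condition")
  expect_equal(filt$data$intensity, c(10, 10))

  set.seed(43)
  arr <- array(rlnorm(10 * 3 * 1, sdlog = 0.2), dim = c(10, 3, 1))
  tab2 <- make_ion_table(list(a = arr, b = arr[, c(2, 3, 1), , drop = FALSE]))
  filt2 <- cv_filter(tab2, max_cv = 0.15)
  # brute-force recheck: every retained ion has CV < 0.15 in every condition
  for (ion in unique(filt2$data$ion_id)) {
    i <- as.integer(sub("i", "", ion))
    for (m in list(arr[i, , 1], arr[i, c(2, 3, 1), 1]))
      expect_lt(sd(m) / mean(m), 0.15)
  }
  dropped <- setdiff(sprintf("i%d", 1:10), unique(filt2$data$ion_id))
  for (ion in dropped) {
    i <- as.integer(sub("i", "", ion))
    cvs <- c(sd(arr[i, , 1]) / mean(arr[i, , 1]))
    expect_true(any(cvs >= 0.15))
  }
})

test_that("annotate_ions matches by [M-H]- mass within tolerance", {
  ref <- data.frame(compound_id = c("glc", "fru", "far"),
                    monoisotopic_mass = c(180.0634, 180.0634, 250.1),
                    stringsAsFactors = FALSE)
  ions <- data.frame(ion_id = c("i1", "i2"),
                     mz = c(180.0634 - 1.007276, 250.1 - 1.007276 + 0.002))
  data <- expand.grid(ion_id = ions$ion_id, condition = c("a", "b"),
                      stringsAsFactors = FALSE)
  data$intensity <- c(1, 2, 3, 4)
  tab <- ion_table(ions, data, level = "condition")
  mat <- annotate_ions(tab, ref, tol = 0.001)
  # isobaric pair collapses to one row with both annotations; far is 0.002
  # Da away and dropped
  expect_equal(nrow(mat$values), 1L)
  expect_setequal(strsplit(rownames(mat$values), ";")[[1]], c("glc", "fru"))
  expect_equal(unname(mat$values[1, c("a", "b")]), c(1, 3))
  expect_error(annotate_ions(tab, ref[0, ]), "empty.*reference")
})

test_that("max_fold_change is the max/min condition ratio", {
  m <- metabolite_matrix(matrix(c(2, 4, 6.68, 5, 5, 5), nrow = 2,
                                byrow = TRUE,
                                dimnames = list(c("a", "b"),
                                                c("x", "y", "z"))))
  fc <- max_fold_change(m)
  expect_equal(unname(fc["a"]), 3.34)
  expect_equal(unname(fc["b"]), 1)

  set.seed(44)
  v <- matrix(rlnorm(60), nrow = 6,
              dimnames = list(sprintf("m%d", 1:6), sprintf("c%d", 1:10)))
  fc2 <- max_fold_change(metabolite_matrix(v))
  for (i in 1:6)
    expect_equal(unname(fc2[i]), max(v[i, ]) / min(v[i, ]))
})

test_that("preprocessing output is invariant to ion row order", {
  cfg <- small_cfg()
  b <- generate_dataset(cfg)
  tab <- b$ion_table
  out1 <- preprocess_ions(tab, b$reference)
  set.seed(5)
  perm <- sample(nrow(tab$data))
  tab2 <- ion_table(tab$ions[sample(nrow(tab$ions)), ], tab$data[perm, ],
                    level = "tech")
  out2 <- preprocess_ions(tab2, b$reference)
  expect_setequal(rownames(out2$values), rownames(out1$values))
  expect_equal(out2$values[rownames(out1$values), colnames(out1$values)],
               out1$values)
})

test_that("preprocessing recovers the planted metabolome ranks", {
  cfg <- small_cfg()
  b <- generate_dataset(cfg)
  mat <- preprocess_ions(b$ion_table, b$reference)
  # TIC normalization rescales conditions, but within-condition relative
  # intensities must match the generated metabolome
  common <- intersect(rownames(mat$values), rownames(b$metabolome$values))
  expect_gt(length(common), 0)
  for (cond in colnames(mat$values)[1:3]) {
    r <- cor(mat$values[common, cond], b$metabolome$values[common, cond],
             method = "spearman")
    expect_gt(r, 0.98)
  }
})
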
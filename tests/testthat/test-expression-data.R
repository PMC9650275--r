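# expression_data: merging by mature sequence, replicate averaging,
# binarization against the 1%-of-pool threshold.

make_source <- function(values, labels, names, seqs, hairpin = FALSE,
                        dataset = NA_character_) {
  mir_matrix(values,
             data.frame(sample = paste0("s", seq_len(nrow(values))),
                        label = labels, dataset = dataset,
                        stringsAsFactors = FALSE),
             data.frame(name = names, sequence = seqs,
                        is_hairpin = rep_len(hairpin, length(names)),
                        stringsAsFactors = FALSE),
             units = "copies_per_cell")
}

test_that("merge unifies identical mature sequences across names and sources", {
  seq_shared <- "UAAGUGCUUCCAUGUUUUAGUAG"
  d1 <- make_source(matrix(c(10, 20), 2, 1), c("positive", "negative"),
                    "miR-A", seq_shared)
  d2 <- make_source(matrix(c(5, 7), 2, 1), c("positive", "negative"),
                    "miR-B-renamed", seq_shared)
  m <- merge_datasets(list(a = d1, b = d2))
  expect_equal(ncol(m$values), 1)
  expect_equal(nrow(m$values), 4)
  # U -> T normalization happened on the stored sequence
  expect_equal(m$mirnas$sequence, gsub("U", "T", seq_shared))
  prov <- attr(m, "provenance")
  expect_setequal(vapply(prov[[1]], `[[`, "", "name"),
                  c("miR-A", "miR-B-renamed"))
})

test_that("same-sequence records within one dataset are summed per sample", {
  seqs <- c("UAAGUGCUUCCAUGUUUUAGUAG", "UAAGUGCUUCCAUGUUUUAGUAG")
  d <- make_source(matrix(c(10, 1, 30, 2), 2, 2), c("positive", "negative"),
                   c("miR-A", "miR-A-dup"), seqs)
  m <- merge_datasets(list(x = d))
  expect_equal(ncol(m$values), 1)
  expect_equal(unname(m$values[, 1]), c(40, 3))
})

test_that("hairpin records are eliminated, by flag or by sequence list", {
  d <- make_source(matrix(c(1, 1, 2, 2), 2, 2), c("positive", "negative"),
                   c("mature", "hairpin-rec"),
                   c(strrep("AC", 11), strrep("AG", 30)),
                   hairpin = c(FALSE, TRUE))
  m <- merge_datasets(list(x = d))
  expect_equal(m$mirnas$name, "mature")

  d2 <- make_source(matrix(c(1, 1, 2, 2), 2, 2), c("positive", "negative"),
                    c("mature", "looks-mature"),
                    c(strrep("AC", 11), strrep("AG", 30)))
  m2 <- merge_datasets(list(x = d2), hairpin_sequences = strrep("AG", 30))
  expect_equal(m2$mirnas$name, "mature")
  expect_error(merge_datasets(list(x = d), hairpin_sequences = strrep("AC", 11)),
               "no usable miRNAs")
})

test_that("merged column count equals the union of distinct sequences", {
  src <- generate_expression_sources(
    expression_spec(n_background_mirnas = 30, seed = 11), n_sources = 3,
    shared_fraction = 0.4)
  m <- merge_datasets(src$datasets)
  # brute-force set union over the generator's ground-truth sequence lists
  union_seqs <- unique(unlist(lapply(src$datasets, function(d)
    d$mirnas$sequence)))
  expect_setequal(m$mirnas$sequence, union_seqs)
  expect_equal(ncol(m$values), length(src$union_sequences))
  # miRNAs absent from a source are zero-filled, and sample ids prefixed
  expect_true(all(startsWith(m$samples$sample, "src")))
  expect_equal(nrow(m$values),
               sum(vapply(src$datasets, function(d) nrow(d$values), 0L)))
})

test_that("merge errors on duplicate sample ids after prefixing", {
  d1 <- make_source(matrix(1, 1, 1), "positive", "m1", strrep("AC", 11))
  d2 <- make_source(matrix(1, 1, 1), "negative", "m2", strrep("AG", 11))
  expect_error(merge_datasets(list(x = d1, x = d2)), "duplicate sample id")
})

test_that("merge is idempotent in columns: re-merging doubles samples only", {
  src <- generate_expression_sources(
    expression_spec(n_background_mirnas = 10, seed = 3), n_sources = 2)
  m <- merge_datasets(src$datasets)
  m2 <- merge_datasets(list(copy1 = m, copy2 = m))
  expect_equal(ncol(m2$values), ncol(m$values))
  expect_equal(nrow(m2$values), 2 * nrow(m$values))
})

test_that("average_replicates takes arithmetic means and keeps singletons", {
  mat <- mir_matrix(matrix(c(2, 4, 7), 3, 1),
                    data.frame(sample = c("a1", "a2", "b"),
                               label = c("positive", "positive", "negative"),
                               replicate_group = c("A", "A", NA)),
                    data.frame(name = "m1", sequence = strrep("AC", 11)),
                    units = "copies_per_cell")
  avg <- average_replicates(mat)
  expect_equal(nrow(avg$values), 2)
  expect_equal(unname(avg$values[avg$samples$sample == "A", 1]), 3)
  expect_equal(unname(avg$values[avg$samples$sample == "b", 1]), 7)
})

test_that("average_replicates rejects conflicting labels within a group", {
  mat <- mir_matrix(matrix(c(2, 4), 2, 1),
                    data.frame(sample = c("a1", "a2"),
                               label = c("positive", "negative"),
                               replicate_group = c("A", "A")),
                    data.frame(name = "m1", sequence = strrep("AC", 11)),
                    units = "copies_per_cell")
  expect_error(average_replicates(mat), "conflicting labels")
})

test_that("replicate means match an independent second summation order", {
  gen <- generate_expression(expression_spec(n_positive = 3, n_negative = 4,
                                             n_background_mirnas = 8,
                                             n_replicates = 3, seed = 21))
  avg <- average_replicates(gen$matrix)
  grp <- gen$matrix$samples$replicate_group
  for (g in unique(grp)) {
    # oracle: sum columns one value at a time, in reverse row order
    rows <- rev(which(grp == g))
    manual <- rep(0, ncol(gen$matrix$values))
    for (r in rows) manual <- manual + gen$matrix$values[r, ]
    manual <- manual / length(rows)
    expect_equal(unname(avg$values[avg$samples$sample == g, ]),
                 unname(manual), tolerance = 1e-12)
  }
  # balanced groups preserve the per-miRNA grand mean
  expect_equal(colMeans(avg$values), colMeans(gen$matrix$values),
               tolerance = 1e-12)
})

test_that("binarize computes per-sample pool-fraction ratios", {
  # one miRNA at 2% of the pool, one at exactly 1%, t_fraction = 0.01
  mat <- tiny_matrix(matrix(c(2, 1, 97), 1, 3), "positive")
  mat$samples$label <- "positive" # single sample: scoring not used here
  b <- binarize(mat, 0.01)
  expect_equal(unname(b$ratio_over_t[1, 1]), 2)
  expect_equal(unname(b$ratio_over_t[1, 2]), 1)

  # closed form on known fractions
  gen <- generate_expression(expression_spec(seed = 5))
  b2 <- binarize(gen$matrix, 0.01)
  frac <- gen$matrix$values / rowSums(gen$matrix$values)
  expect_equal(b2$ratio_over_t, frac / 0.01, tolerance = 1e-12)
})

test_that("binarize is invariant to per-sample rescaling and names zero samples", {
  gen <- generate_expression(expression_spec(seed = 6))
  scaled <- gen$matrix
  scaled$values[3, ] <- scaled$values[3, ] * 17
  expect_equal(binarize(scaled)$ratio_over_t[3, ],
               binarize(gen$matrix)$ratio_over_t[3, ], tolerance = 1e-12)

  zero <- gen$matrix
  zero$values[2, ] <- 0
  expect_error(binarize(zero), zero$samples$sample[2], fixed = TRUE)
})

test_that("csv round trip preserves the matrix", {
  gen <- generate_expression(expression_spec(n_background_mirnas = 5, seed = 9))
  dir <- withr::local_tempdir()
  mcsv <- file.path(dir, "m.csv")
  write_expression_csv(gen$matrix, mcsv, file.path(dir, "prov.json"))
  scsv <- file.path(dir, "seq.csv")
  sheet <- file.path(dir, "samples.csv")
  utils::write.csv(gen$matrix$mirnas, scsv, row.names = FALSE)
  utils::write.csv(gen$matrix$samples, sheet, row.names = FALSE)
  back <- read_expression_csv(mcsv, scsv, sheet)
  expect_equal(back$values, gen$matrix$values, tolerance = 1e-9)
})
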
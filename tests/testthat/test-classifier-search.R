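# classifier_search: per-sample output prediction, cMargin/AUC/truth
# scoring, exhaustive enumeration under constraints, bootstrap pruning.

test_that("empty topology gives every sample the same unrepressed output", {
  mat <- tiny_matrix(matrix(runif(12, 0, 5000), 4, 3),
                     c("positive", "positive", "negative", "negative"))
  out <- predict_outputs(circuit_topology(), mat)
  expect_equal(length(unique(out)), 1)
  # pure miR_low architecture: FF4 = 0, Act2 unrepressed
  p <- model_parameters()
  expect_equal(unname(out[1]),
               p$OutMAX * p$Act2MAX / (p$KD2 + p$Act2MAX), tolerance = 1e-12)
})

test_that("a high_gate miRNA at zero yields the fully repressed Off output", {
  mat <- tiny_matrix(matrix(c(3000, 0, 10, 10), 2, 2),
                     c("positive", "negative"))
  out <- predict_outputs(circuit_topology(high_gate = "miR-1"), mat)
  expect_equal(unname(out["s2"]), steady_state(0)$Out, tolerance = 1e-12)
  expect_equal(unname(out["s1"]), steady_state(3000)$Out, tolerance = 1e-12)
})

test_that("predicted outputs match the composition oracle per sample", {
  vals <- matrix(c(3000, 2500, 0, 5,     # miR-h
                   0, 10, 2000, 0,       # miR-l1
                   0, 0, 40, 1500),      # miR-l2
                 4, 3)
  mat <- tiny_matrix(vals, c("positive", "positive", "negative", "negative"),
                     c("h", "l1", "l2"))
  topo <- circuit_topology(high_gate = "h", low_sensors = c("l1", "l2"))
  out <- predict_outputs(topo, mat)
  p <- model_parameters()
  for (i in 1:4) {
    oracle <- fp_steady_state(vals[i, 1], p, vals[i, 2:3])
    expect_equal(unname(out[i]), oracle$Out, tolerance = 1e-10)
  }
  expect_error(predict_outputs(circuit_topology(high_gate = "nope"), mat),
               "unknown miRNA")
  counts <- mat
  counts$units <- "counts"
  expect_error(predict_outputs(topo, counts), "copies_per_cell")
})

test_that("the worked margin example matches the brute-force oracle", {
  # positives {100, 100}, negatives {10, 5}
  oracle <- cmargin_bruteforce(c(100, 100), c(10, 5))
  expect_equal(oracle$avg_margin, 1.1505, tolerance = 1e-4)
  expect_equal(oracle$worst_margin, 1)
  expect_equal(oracle$cmargin, 1.0753, tolerance = 1e-4)
  s <- mircircuit:::score_outputs(c(100, 100, 10, 5),
                                  c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(s$avg_margin, oracle$avg_margin, tolerance = 1e-12)
  expect_equal(s$worst_margin, oracle$worst_margin, tolerance = 1e-12)
  expect_equal(s$cmargin, oracle$cmargin, tolerance = 1e-12)
  expect_equal(s$auc, 1)
})

test_that("degenerate scorings: identical outputs and perfect separation", {
  s <- mircircuit:::score_outputs(rep(42, 5), c(TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(s$avg_margin, 0)
  expect_equal(s$worst_margin, 0)
  expect_equal(s$cmargin, 0)
  expect_equal(s$auc, 0.5)
  expect_equal(s$truth, rep(1L, 5)) # at the midpoint counts as true
  expect_equal(mircircuit:::score_outputs(c(3, 4, 1, 2),
                                          c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
})

test_that("AUC equals the brute-force pairwise count on random score sets", {
  set.seed(33)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    labels <- c(TRUE, FALSE, runif(n - 2) > 0.5)
    scores <- sample(round(runif(n, 0, 10) * 2) / 2) # with ties
    expect_equal(auc_score(scores, labels), auc_bruteforce(scores, labels))
  }
})

test_that("cMargin is invariant to a positive output rescaling and lies
           between its two component margins", {
  set.seed(12)
  for (i in 1:20) {
    n_pos <- sample(2:5, 1)
    n_neg <- sample(2:6, 1)
    out <- runif(n_pos + n_neg, 0.01, 1000)
    positive <- rep(c(TRUE, FALSE), c(n_pos, n_neg))
    s1 <- mircircuit:::score_outputs(out, positive)
    s2 <- mircircuit:::score_outputs(out * 137.5, positive)
    expect_equal(s1$cmargin, s2$cmargin, tolerance = 1e-10)
    expect_gte(s1$cmargin, min(s1$avg_margin, s1$worst_margin) - 1e-12)
    expect_lte(s1$cmargin, max(s1$avg_margin, s1$worst_margin) + 1e-12)
  }
})

test_that("zero outputs are floored at epsilon with a warning", {
  expect_warning(
    s <- mircircuit:::score_outputs(c(10, 0), c(TRUE, FALSE), epsilon = 1e-6),
    "floored")
  expect_equal(s$worst_margin, log10(10 / 1e-6), tolerance = 1e-12)
  expect_true(is.finite(s$cmargin))
})

test_that("log10 margin convention: cMargin 1.16 is a 14.4-fold change", {
  expect_equal(cmargin_fold_change(1.16), 14.45, tolerance = 1e-3)
  expect_lt(abs(cmargin_fold_change(1.16) - 14.4), 0.1)
})

test_that("search recovers planted perfect markers as the top circuit", {
  gen <- generate_expression(expression_spec(
    n_background_mirnas = 20,
    planted_high = list(list(id = "mark-pos", pos_level = 3000, neg_level = 0)),
    planted_low = list(list(id = "mark-neg", pos_level = 0, neg_level = 3000,
                            prop_negative = 1)),
    replicate_cv = 0.1, seed = 77))
  rk <- enumerate_and_search(gen$matrix,
                             config = search_config(max_total_inputs = 2,
                                                    max_inputs_per_gate = 1))
  top <- top_circuit(rk)
  expect_equal(top$topology$high_gate, "mark-pos")
  expect_equal(top$topology$low_sensors, "mark-neg")
  # brute-force confirmation: no scored circuit beats the planted one
  expect_true(all(as.data.frame(rk)$cmargin <= top$cmargin + 1e-12))
  expect_equal(unname(top$truth[gen$matrix$samples$label == "positive"]),
               rep(1L, 4))

  # under a single-input budget the most discriminative singleton wins
  rk1 <- enumerate_and_search(gen$matrix,
                              config = search_config(max_total_inputs = 1))
  singles <- as.data.frame(rk1)
  expect_true(all(singles$n_inputs == 1))
  best_manual <- max(singles$cmargin)
  expect_equal(top_circuit(rk1)$cmargin, best_manual)
})

test_that("label shuffling destroys the margin", {
  gen <- generate_expression(expression_spec(n_background_mirnas = 10,
                                             seed = 55))
  set.seed(99)
  tops <- replicate(10, {
    m <- gen$matrix
    m$samples$label <- sample(m$samples$label)
    r <- try(enumerate_and_search(
      m, config = search_config(max_total_inputs = 2)), silent = TRUE)
    if (inherits(r, "try-error")) NA_real_ else top_circuit(r)$cmargin
  })
  planted <- gen$manifest$planted_cmargin
  # shuffled-label margins collapse relative to the planted signal
  expect_lt(stats::median(tops, na.rm = TRUE), planted / 2)
})

test_that("pruning removes an uninformative input and is deterministic", {
  gen <- generate_expression(expression_spec(
    n_background_mirnas = 10,
    planted_high = list(list(id = "mark-pos", pos_level = 3000, neg_level = 0)),
    planted_low = list(
      list(id = "mark-neg", pos_level = 0, neg_level = 3000, prop_negative = 1),
      list(id = "dead-weight", pos_level = 0, neg_level = 0,
           prop_negative = 1)),
    replicate_cv = 0, seed = 13))
  topo <- circuit_topology(high_gate = "mark-pos",
                           low_sensors = c("mark-neg", "dead-weight"))
  scored <- score_circuit(topo, gen$matrix)
  cfg <- search_config(prune = TRUE, bootstrap_reps = 100, seed = 42)
  pruned <- prune_circuit(scored, gen$matrix, config = cfg)
  # constant-expression input contributes nothing and is pruned
  expect_false("dead-weight" %in% pruned$topology$low_sensors)
  expect_true("mark-neg" %in% pruned$topology$low_sensors)
  expect_equal(pruned$topology$high_gate, "mark-pos")
  # determinism under a fixed seed
  pruned2 <- prune_circuit(scored, gen$matrix, config = cfg)
  expect_identical(pruned$topology, pruned2$topology)
  expect_identical(pruned$cmargin, pruned2$cmargin)

  # strongly contributing planted markers survive pruning untouched
  strong <- score_circuit(circuit_topology("mark-pos", "mark-neg"), gen$matrix)
  kept <- prune_circuit(strong, gen$matrix, config = cfg)
  expect_identical(kept$topology, strong$topology)
})

test_that("ranking artifacts can be written to disk", {
  gen <- generate_expression(expression_spec(n_background_mirnas = 5, seed = 2))
  rk <- enumerate_and_search(gen$matrix,
                             config = search_config(max_total_inputs = 2))
  dir <- withr::local_tempdir()
  paths <- write_ranking(rk, file.path(dir, "circuits.csv"),
                         file.path(dir, "pred.csv"),
                         file.path(dir, "top.json"))
  expect_true(all(file.exists(paths)))
  rep <- jsonlite::read_json(file.path(dir, "top.json"))
  expect_equal(rep$cmargin, top_circuit(rk)$cmargin, tolerance = 1e-9)
})
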
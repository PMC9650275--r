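# Classifier-circuit search: enumerate candidate input sets under count
# constraints, predict per-sample circuit output with the steady-state model,
# and score circuits by cMargin (log10 classification margin), ROC AUC and
# per-sample truth values; optional bootstrap pruning of weak inputs.

#' Circuit topology
#'
#' Which miRNAs feed the miR_high OR-gate (output requires them HIGH) and
#' which act as individual miR_low sensors (output requires them LOW). The
#' implied logic is `(miR_h1 OR miR_h2 ...) AND NOT miR_l1 AND NOT miR_l2 ...`.
#'
#' @param high_gate character vector of miRNA ids on the OR-gate (may be
#'   empty for a pure miR_low circuit).
#' @param low_sensors character vector of miR_low miRNA ids.
#' @return an object of class `circuit_topology`.
#' @export
circuit_topology <- function(high_gate = character(), low_sensors = character()) {
  high_gate <- sort(unique(as.character(high_gate)))
  low_sensors <- sort(unique(as.character(low_sensors)))
  if (length(intersect(high_gate, low_sensors)))
    stop("a miRNA cannot be both a miR_high and a miR_low input")
  structure(list(high_gate = high_gate, low_sensors = low_sensors),
            class = "circuit_topology")
}

#' @export
format.circuit_topology <- function(x, ...) {
  h <- if (length(x$high_gate)) paste(x$high_gate, collapse = " | ") else "-"
  l <- if (length(x$low_sensors)) paste(x$low_sensors, collapse = ", ") else "-"
  sprintf("high:{%s} low:{%s}", h, l)
}

#' @export
print.circuit_topology <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

n_inputs <- function(topology)
  length(topology$high_gate) + length(topology$low_sensors)

#' Search configuration
#'
#' @param max_total_inputs maximal number of miRNA inputs overall.
#' @param max_inputs_per_gate maximal number of miRNAs on the OR-gate.
#' @param t_fraction binarization threshold fraction for the candidate
#'   prefilter.
#' @param prune run bootstrap pruning on the top circuit?
#' @param bootstrap_reps bootstrap replicates for pruning.
#' @param prune_alpha removal threshold on the one-sided bootstrap fraction
#'   of non-positive cMargin contributions.
#' @param seed RNG seed (mandatory when `prune = TRUE`).
#' @param aggregate how the average margin aggregates group outputs:
#'   geometric (default, consistent with log10 margins) or arithmetic means.
#' @param topology_cap hard cap on the number of enumerated topologies.
#' @param epsilon floor applied to zero outputs before taking ratios.
#' @return an object of class `search_config`.
#' @export
search_config <- function(max_total_inputs = 3, max_inputs_per_gate = 3,
                          t_fraction = 0.01, prune = FALSE,
                          bootstrap_reps = 200, prune_alpha = 0.05,
                          seed = NULL, aggregate = c("geometric", "arithmetic"),
                          topology_cap = 2e5, epsilon = 1e-6) {
  aggregate <- match.arg(aggregate)
  stopifnot(max_total_inputs >= 1, max_inputs_per_gate >= 0,
            t_fraction > 0, t_fraction < 1,
            bootstrap_reps >= 1, prune_alpha > 0, prune_alpha < 1)
  if (prune && is.null(seed)) stop("pruning requires an explicit seed")
  structure(list(max_total_inputs = max_total_inputs,
                 max_inputs_per_gate = max_inputs_per_gate,
                 t_fraction = t_fraction, prune = prune,
                 bootstrap_reps = bootstrap_reps, prune_alpha = prune_alpha,
                 seed = seed, aggregate = aggregate,
                 topology_cap = topology_cap, epsilon = epsilon),
            class = "search_config")
}

#' Predict per-sample circuit outputs
#'
#' For every sample, the OR-gate input is the sum of the high_gate miRNA
#' abundances and each low_sensors miRNA represses Act2 individually; the
#' steady-state output is returned. An empty high_gate bypasses the
#' double-inversion branch (FF4 = 0).
#'
#' @param topology a [circuit_topology()].
#' @param matrix a [mir_matrix] in copies per cell.
#' @param params a [model_parameters()] object.
#' @return named numeric vector of outputs (molecules/cell) per sample.
#' @export
predict_outputs <- function(topology, matrix, params = model_parameters()) {
  stopifnot(inherits(topology, "circuit_topology"),
            inherits(matrix, "mir_matrix"))
  if (matrix$units != "copies_per_cell")
    stop("classifier search requires abundances in copies_per_cell, got ",
         matrix$units)
  ids <- c(topology$high_gate, topology$low_sensors)
  missing <- setdiff(ids, colnames(matrix$values))
  if (length(missing))
    stop("topology references unknown miRNA(s): ",
         paste(missing, collapse = ", "))
  has_high <- length(topology$high_gate) > 0
  vapply(seq_len(nrow(matrix$values)), function(i) {
    m_high <- if (has_high)
      sum(matrix$values[i, topology$high_gate]) else 0
    lows <- matrix$values[i, topology$low_sensors]
    steady_state(m_high, lows, params, high_sensor = has_high)$Out
  }, 0, USE.NAMES = FALSE) |>
    stats::setNames(matrix$samples$sample)
}

#' ROC AUC of scores against binary labels
#'
#' Area under the ROC curve via the rank (Mann-Whitney) identity, with ties
#' counted as half.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param positive logical vector, TRUE for positive-class observations.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, positive) {
  stopifnot(length(scores) == length(positive), is.logical(positive))
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# core scoring on a plain output vector + positivity mask
score_outputs <- function(outputs, positive, aggregate = "geometric",
                          epsilon = 1e-6, warn_floor = TRUE) {
  if (any(outputs <= 0)) {
    if (warn_floor)
      warning("output(s) at zero floored to epsilon = ", epsilon)
    outputs <- pmax(outputs, epsilon)
  }
  pos <- outputs[positive]
  neg <- outputs[!positive]
  gm_pos <- geomean(pos)
  gm_neg <- geomean(neg)
  avg_margin <- if (aggregate == "geometric") log10(gm_pos / gm_neg)
                else log10(mean(pos) / mean(neg))
  worst_margin <- log10(min(pos) / max(neg))
  cmargin <- (avg_margin + worst_margin) / 2
  midpoint <- sqrt(gm_pos * gm_neg)
  # compare on the log scale with a float-tolerance so outputs exactly at
  # the midpoint count as true
  truth <- as.integer(log10(outputs) >= log10(midpoint) - 1e-9)
  list(avg_margin = avg_margin, worst_margin = worst_margin,
       cmargin = cmargin, auc = auc_score(outputs, positive),
       truth = truth, midpoint = midpoint)
}

#' Score a circuit on a labeled expression matrix
#'
#' The average margin is the log10 ratio of (by default geometric) mean
#' outputs in the positive vs negative sample sets; the worst margin is the
#' log10 of the smallest output ratio over all positive/negative pairs;
#' cMargin is their mean. AUC treats outputs as scores for the positive
#' class. Truth marks samples whose output is at or above the geometric
#' midpoint of the two group geometric means.
#'
#' @param topology a [circuit_topology()].
#' @param matrix a labeled [mir_matrix] in copies per cell.
#' @param params a [model_parameters()] object.
#' @param config a [search_config()] (aggregate and epsilon are used).
#' @return an object of class `scored_circuit`: topology, per-sample outputs,
#'   `avg_margin`, `worst_margin`, `cmargin` (log10 units), `auc`, `truth`.
#' @export
score_circuit <- function(topology, matrix, params = model_parameters(),
                          config = search_config()) {
  positive <- matrix$samples$label == "positive"
  if (!any(positive) || all(positive))
    stop("scoring requires at least one positive and one negative sample")
  outputs <- predict_outputs(topology, matrix, params)
  s <- score_outputs(outputs, positive, config$aggregate, config$epsilon)
  structure(list(topology = topology, per_sample_output = outputs,
                 avg_margin = s$avg_margin, worst_margin = s$worst_margin,
                 cmargin = s$cmargin, auc = s$auc,
                 truth = stats::setNames(s$truth, names(outputs))),
            class = "scored_circuit")
}

#' @export
print.scored_circuit <- function(x, ...) {
  cat(sprintf("scored_circuit %s\n  cMargin %.4f (avg %.4f, worst %.4f), AUC %.3f\n",
              format(x$topology), x$cmargin, x$avg_margin, x$worst_margin, x$auc))
  invisible(x)
}

#' Fold change implied by a cMargin
#'
#' cMargin is carried in log10 units, so `10^cmargin` is the corresponding
#' output fold change between the positive and negative groups.
#'
#' @param cmargin classification margin, log10 units.
#' @return fold change.
#' @export
cmargin_fold_change <- function(cmargin) 10^cmargin

#' Candidate miRNA prefilter
#'
#' Role-based pool reduction on the binarized matrix: miR_high candidates
#' must exceed the threshold t in all positive samples but not in all
#' negative samples; miR_low candidates must exceed t in at least one
#' negative sample and in no positive sample. A soft variant relaxes the
#' "all positives" / "no positives" requirements to fractions.
#'
#' @param binarized a [binarize()] result.
#' @param high_pos_frac minimal fraction of positive samples a miR_high
#'   candidate must exceed t in (1 = all).
#' @param low_pos_frac maximal fraction of positive samples a miR_low
#'   candidate may exceed t in (0 = none).
#' @return list with character vectors `high` and `low`.
#' @export
prefilter_candidates <- function(binarized, high_pos_frac = 1,
                                 low_pos_frac = 0) {
  stopifnot(inherits(binarized, "mir_binarized"))
  over <- binarized$ratio_over_t > 1
  positive <- binarized$samples$label == "positive"
  pos_frac <- colMeans(over[positive, , drop = FALSE])
  neg_frac <- colMeans(over[!positive, , drop = FALSE])
  high <- colnames(over)[pos_frac >= high_pos_frac & neg_frac < 1]
  low <- colnames(over)[neg_frac > 0 & pos_frac <= low_pos_frac]
  list(high = high, low = setdiff(low, high))
}

# all subsets of `ids` of size 0..k, as a list of character vectors
subsets_up_to <- function(ids, k) {
  out <- list(character(0))
  for (size in seq_len(min(k, length(ids)))) {
    cmb <- utils::combn(ids, size, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Exhaustive classifier-circuit search
#'
#' Prefilters the candidate pool by miR_high/miR_low role, enumerates every
#' admissible topology within the input-count constraints, scores each with
#' the steady-state model, and ranks by cMargin (descending), breaking ties
#' by fewer total inputs, then smaller OR-gate (preferring designs without
#' miR_high sensors), then lexicographic miRNA ids. Optionally prunes the
#' top circuit by bootstrap.
#'
#' @param matrix labeled [mir_matrix] in copies per cell.
#' @param params a [model_parameters()] object.
#' @param config a [search_config()].
#' @return object of class `circuit_ranking`: a data.frame summary (one row
#'   per circuit: high_gate, low_sensors, n_inputs, cmargin, avg_margin,
#'   worst_margin, auc) with the full `scored_circuit` list in attribute
#'   `scored` and, when pruning is on, the pruned top circuit in attribute
#'   `pruned_top`.
#' @export
enumerate_and_search <- function(matrix, params = model_parameters(),
                                 config = search_config()) {
  stopifnot(inherits(matrix, "mir_matrix"), inherits(config, "search_config"))
  cand <- prefilter_candidates(binarize(matrix, config$t_fraction))
  if (length(cand$high) + length(cand$low) == 0)
    stop("candidate pool empty after prefilter")

  high_sets <- subsets_up_to(cand$high,
                             min(config$max_inputs_per_gate,
                                 config$max_total_inputs))
  topologies <- list()
  for (h in high_sets) {
    room <- config$max_total_inputs - length(h)
    for (l in subsets_up_to(cand$low, room)) {
      if (length(h) + length(l) == 0) next
      topologies[[length(topologies) + 1L]] <- circuit_topology(h, l)
    }
  }
  if (length(topologies) == 0) stop("no admissible topology under constraints")
  if (length(topologies) > config$topology_cap)
    stop(length(topologies), " topologies exceed the cap (",
         config$topology_cap, "); tighten the prefilter or constraints")

  scored <- lapply(topologies, score_circuit, matrix = matrix,
                   params = params, config = config)
  df <- data.frame(
    high_gate = vapply(scored, function(s)
      paste(s$topology$high_gate, collapse = "|"), ""),
    low_sensors = vapply(scored, function(s)
      paste(s$topology$low_sensors, collapse = "|"), ""),
    n_inputs = vapply(scored, function(s) n_inputs(s$topology), 0L),
    n_high = vapply(scored, function(s) length(s$topology$high_gate), 0L),
    cmargin = vapply(scored, `[[`, 0, "cmargin"),
    avg_margin = vapply(scored, `[[`, 0, "avg_margin"),
    worst_margin = vapply(scored, `[[`, 0, "worst_margin"),
    auc = vapply(scored, `[[`, 0, "auc"),
    stringsAsFactors = FALSE)
  key <- paste(df$high_gate, df$low_sensors)
  ord <- order(-df$cmargin, df$n_inputs, df$n_high, key)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  scored <- scored[ord]

  res <- structure(df, scored = scored, class = c("circuit_ranking", "data.frame"))
  if (config$prune)
    attr(res, "pruned_top") <- prune_circuit(scored[[1]], matrix, params, config)
  res
}

#' Top circuit of a ranking
#'
#' @param ranking an [enumerate_and_search()] result.
#' @param pruned return the pruned top circuit when available?
#' @return a `scored_circuit`.
#' @export
top_circuit <- function(ranking, pruned = TRUE) {
  stopifnot(inherits(ranking, "circuit_ranking"))
  p <- attr(ranking, "pruned_top")
  if (pruned && !is.null(p)) p else attr(ranking, "scored")[[1]]
}

#' Bootstrap pruning of weak circuit inputs
#'
#' Iteratively removes the input miRNA whose contribution to cMargin is
#' least significant under class-stratified bootstrap resampling of the
#' samples: for each input, the cMargin difference with vs without it is
#' computed on each resample, and the input with the largest one-sided
#' fraction of non-positive differences is removed when that fraction
#' exceeds `prune_alpha`. Stops when no input qualifies or removal would
#' empty the topology; the final topology is rescored on the full data.
#'
#' @param scored a [score_circuit()] result (or `scored_circuit` from a
#'   ranking).
#' @param matrix labeled [mir_matrix] used for scoring.
#' @param params a [model_parameters()] object.
#' @param config a [search_config()] with `seed` set.
#' @return the pruned, rescored `scored_circuit`.
#' @export
prune_circuit <- function(scored, matrix, params = model_parameters(),
                          config = search_config(prune = TRUE, seed = 1)) {
  stopifnot(inherits(scored, "scored_circuit"))
  if (is.null(config$seed)) stop("pruning requires config$seed")
  topo <- scored$topology
  positive <- matrix$samples$label == "positive"
  pos_idx <- which(positive)
  neg_idx <- which(!positive)

  # per-sample outputs for a topology, with resampling indices applied later
  outputs_for <- function(t) predict_outputs(t, matrix, params)

  drop_one <- function(t, id) {
    circuit_topology(setdiff(t$high_gate, id), setdiff(t$low_sensors, id))
  }

  with_rng(config$seed, {
    repeat {
      ids <- c(topo$high_gate, topo$low_sensors)
      if (length(ids) <= 1) break
      full_out <- outputs_for(topo)
      reduced_out <- lapply(ids, function(id) outputs_for(drop_one(topo, id)))
      # stratified bootstrap indices, shared across candidate inputs
      boots <- replicate(config$bootstrap_reps, c(
        sample(pos_idx, length(pos_idx), replace = TRUE),
        sample(neg_idx, length(neg_idx), replace = TRUE)), simplify = FALSE)
      frac_nonpos <- vapply(seq_along(ids), function(k) {
        delta <- vapply(boots, function(b) {
          pb <- positive[b]
          score_outputs(full_out[b], pb, config$aggregate, config$epsilon,
                        warn_floor = FALSE)$cmargin -
            score_outputs(reduced_out[[k]][b], pb, config$aggregate,
                          config$epsilon, warn_floor = FALSE)$cmargin
        }, 0)
        mean(delta <= 0)
      }, 0)
      worst <- which.max(frac_nonpos)
      if (frac_nonpos[worst] <= config$prune_alpha) break
      candidate <- drop_one(topo, ids[worst])
      if (n_inputs(candidate) == 0) {
        warning("pruning would empty the topology; keeping last non-empty circuit")
        break
      }
      topo <- candidate
    }
  })
  score_circuit(topo, matrix, params, config)
}

#' Write a circuit ranking and per-sample predictions to CSV/JSON
#'
#' @param ranking an [enumerate_and_search()] result.
#' @param circuits_csv path for the ranked-circuits CSV.
#' @param predictions_csv optional path for the top circuit's per-sample
#'   outputs and truth values.
#' @param report_json optional path for a top-circuit JSON report.
#' @return invisibly, the paths written.
#' @export
write_ranking <- function(ranking, circuits_csv, predictions_csv = NULL,
                          report_json = NULL) {
  stopifnot(inherits(ranking, "circuit_ranking"))
  utils::write.csv(as.data.frame(ranking), circuits_csv, row.names = FALSE)
  top <- top_circuit(ranking)
  if (!is.null(predictions_csv))
    utils::write.csv(data.frame(sample = names(top$per_sample_output),
                                output = unname(top$per_sample_output),
                                truth = unname(top$truth)),
                     predictions_csv, row.names = FALSE)
  if (!is.null(report_json))
    jsonlite::write_json(list(high_gate = top$topology$high_gate,
                              low_sensors = top$topology$low_sensors,
                              cmargin = top$cmargin,
                              avg_margin = top$avg_margin,
                              worst_margin = top$worst_margin,
                              auc = top$auc,
                              fold_change = cmargin_fold_change(top$cmargin)),
                         report_json, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  invisible(c(circuits_csv, predictions_csv, report_json))
}
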
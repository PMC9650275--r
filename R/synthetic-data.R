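# Seeded synthetic-data generators with ground-truth manifests. They emulate
# the structure of the pipeline's real inputs — multi-source miRNA expression
# matrices with planted positive/negative marker miRNAs, flow-cytometry event
# mixtures, and micropatterned-colony point clouds — so every module can be
# tested without external data. Each generator is a pure function of its spec
# (same seed, identical output) and does not disturb the caller's RNG state.

#' Specification for a synthetic labeled expression matrix
#'
#' Defaults mirror the structure of the real application: 4 pluripotent
#' (positive) samples vs 15 differentiated (negative) cell states; one
#' planted positive marker at the high physiological level of 3,000
#' copies/cell (absent in negatives) and two planted negative markers, each
#' expressed in a complementary subset of negatives; log-normal background
#' miRNAs whose median sits well below the 1%-of-pool relevance threshold.
#'
#' @param n_positive,n_negative sample counts per class.
#' @param n_background_mirnas number of unplanted background miRNAs.
#' @param planted_high list of planted positive markers; each a list with
#'   `id`, `pos_level`, `neg_level` (copies/cell).
#' @param planted_low list of planted negative markers; each a list with
#'   `id`, `pos_level`, `neg_level` and either `prop_negative` (the fraction
#'   of negative samples expressing it, chosen at random) or
#'   `negative_samples` (explicit negative sample names, e.g. `"neg_03"`).
#' @param background_meanlog,background_sdlog log-normal background
#'   parameters on copies/cell.
#' @param replicate_cv multiplicative (log-normal) noise coefficient of
#'   variation applied per measurement; 0 for a deterministic matrix.
#' @param n_replicates replicates per biological sample (rows get a shared
#'   `replicate_group`).
#' @param seed mandatory RNG seed.
#' @return an object of class `expression_spec`.
#' @export
expression_spec <- function(n_positive = 4, n_negative = 15,
                            n_background_mirnas = 50,
                            planted_high = list(list(id = "syn-miR-pos-1",
                                                     pos_level = 3000,
                                                     neg_level = 0)),
                            planted_low = list(
                              list(id = "syn-miR-neg-1", pos_level = 0,
                                   neg_level = 3000, prop_negative = 0.5),
                              list(id = "syn-miR-neg-2", pos_level = 0,
                                   neg_level = 3000, prop_negative = 0.5)),
                            background_meanlog = log(5),
                            background_sdlog = 1,
                            replicate_cv = 0.2, n_replicates = 1, seed) {
  stopifnot(n_positive >= 1, n_negative >= 1, n_background_mirnas >= 0,
            replicate_cv >= 0, n_replicates >= 1)
  if (missing(seed)) stop("an explicit seed is mandatory")
  ok_marker <- function(m) all(c("id", "pos_level", "neg_level") %in% names(m)) &&
    m$pos_level >= 0 && m$neg_level >= 0
  stopifnot(all(vapply(planted_high, ok_marker, TRUE)),
            all(vapply(planted_low, ok_marker, TRUE)))
  structure(list(n_positive = n_positive, n_negative = n_negative,
                 n_background_mirnas = n_background_mirnas,
                 planted_high = planted_high, planted_low = planted_low,
                 background_meanlog = background_meanlog,
                 background_sdlog = background_sdlog,
                 replicate_cv = replicate_cv, n_replicates = n_replicates,
                 seed = as.integer(seed)),
            class = "expression_spec")
}

random_sequences <- function(n, length = 22) {
  if (n == 0) return(character(0))
  seqs <- character(0)
  while (length(seqs) < n) {
    more <- vapply(seq_len(n - length(seqs)), function(i)
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = ""), "")
    seqs <- unique(c(seqs, more))
  }
  seqs
}

# multiplicative log-normal noise with a given CV, mean 1
cv_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic labeled miRNA expression matrix
#'
#' Plants the spec's positive and negative marker miRNAs at their stated
#' copies/cell levels on top of log-normal background, with optional
#' replicate structure and multiplicative noise. The ground-truth manifest
#' records the planted topology and its cMargin under the default model
#' parameters, scored with [score_circuit()] on the generated matrix.
#'
#' @param spec an [expression_spec()].
#' @return list with `matrix` (a [mir_matrix]) and `manifest` (planted
#'   topology, per-marker levels, the scored planted cMargin, seed).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "expression_spec"))
  planted_ids <- vapply(c(spec$planted_high, spec$planted_low), `[[`, "", "id")
  if (anyDuplicated(planted_ids)) stop("duplicate planted miRNA ids")
  bg_ids <- if (spec$n_background_mirnas > 0)
    sprintf("syn-miR-bg-%03d", seq_len(spec$n_background_mirnas)) else character(0)
  if (length(intersect(planted_ids, bg_ids)))
    stop("planted ids collide with background ids")

  n_bio <- spec$n_positive + spec$n_negative
  bio_names <- c(sprintf("pos_%02d", seq_len(spec$n_positive)),
                 sprintf("neg_%02d", seq_len(spec$n_negative)))
  labels <- rep(c("positive", "negative"), c(spec$n_positive, spec$n_negative))
  ids <- c(planted_ids, bg_ids)

  with_rng(spec$seed, {
    seqs <- random_sequences(length(ids))
    # per-biological-sample expected levels
    base <- matrix(0, n_bio, length(ids), dimnames = list(bio_names, ids))
    for (m in spec$planted_high)
      base[, m$id] <- ifelse(labels == "positive", m$pos_level, m$neg_level)
    low_expressing <- list()
    neg_rows <- which(labels == "negative")
    for (m in spec$planted_low) {
      base[, m$id] <- m$pos_level
      rows <- if (!is.null(m$negative_samples)) {
        idx <- match(m$negative_samples, bio_names)
        if (anyNA(idx)) stop("unknown negative sample(s) for ", m$id)
        idx
      } else {
        k <- max(1, round((m$prop_negative %||% 0.5) * length(neg_rows)))
        sort(sample(neg_rows, k))
      }
      base[rows, m$id] <- m$neg_level
      low_expressing[[m$id]] <- bio_names[rows]
    }
    if (length(bg_ids))
      base[, bg_ids] <- matrix(
        stats::rlnorm(n_bio * length(bg_ids), spec$background_meanlog,
                      spec$background_sdlog), n_bio)

    # expand replicates with multiplicative noise
    rep_idx <- rep(seq_len(n_bio), each = spec$n_replicates)
    values <- base[rep_idx, , drop = FALSE] *
      matrix(cv_noise(length(rep_idx) * length(ids), spec$replicate_cv),
             length(rep_idx))
    has_reps <- spec$n_replicates > 1
    sheet <- data.frame(
      sample = if (has_reps)
        paste0(bio_names[rep_idx], "_r", rep(seq_len(spec$n_replicates), n_bio))
      else bio_names,
      label = labels[rep_idx],
      cell_state = bio_names[rep_idx],
      replicate_group = if (has_reps) bio_names[rep_idx] else NA_character_,
      dataset = NA_character_, stringsAsFactors = FALSE)
    mat <- mir_matrix(values, sheet,
                      data.frame(name = ids, sequence = seqs,
                                 is_hairpin = FALSE,
                                 source_dataset = "synthetic",
                                 stringsAsFactors = FALSE),
                      units = "copies_per_cell")
  })

  topo <- circuit_topology(
    high_gate = vapply(spec$planted_high, `[[`, "", "id"),
    low_sensors = vapply(spec$planted_low, `[[`, "", "id"))
  scored <- suppressWarnings(score_circuit(topo, mat))
  list(matrix = mat,
       manifest = list(planted_topology = topo,
                       planted_cmargin = scored$cmargin,
                       planted_auc = scored$auc,
                       low_expressing_samples = low_expressing,
                       seed = spec$seed))
}

#' Split a synthetic panel into partially overlapping source datasets
#'
#' Emulates merging miRNA-seq studies: the generated samples are distributed
#' across `n_sources` datasets; planted markers and a `shared_fraction` of
#' the background panel appear in every source (under source-specific alias
#' names, exercising sequence-based unification) while the remaining
#' background miRNAs are private to one source.
#'
#' @param spec an [expression_spec()].
#' @param n_sources number of source datasets (>= 2).
#' @param shared_fraction fraction of background miRNAs shared by all
#'   sources.
#' @return list with `datasets` (named list of [mir_matrix]), and the
#'   ground-truth `union_sequences` (distinct mature sequences across
#'   sources) and `truth` manifest from [generate_expression()].
#' @export
generate_expression_sources <- function(spec, n_sources = 3,
                                        shared_fraction = 0.5) {
  stopifnot(n_sources >= 2, shared_fraction >= 0, shared_fraction <= 1)
  gen <- generate_expression(spec)
  mat <- gen$matrix
  planted <- vapply(c(spec$planted_high, spec$planted_low), `[[`, "", "id")
  bg <- setdiff(mat$mirnas$name, planted)

  with_rng(spec$seed + 1L, {
    n_shared <- round(shared_fraction * length(bg))
    shared_bg <- sample(bg, n_shared)
    private_bg <- setdiff(bg, shared_bg)
    private_owner <- if (length(private_bg))
      sample(rep_len(seq_len(n_sources), length(private_bg))) else integer(0)
    # samples round-robin across sources, keeping replicate groups together
    grp <- ifelse(is.na(mat$samples$replicate_group),
                  mat$samples$sample, mat$samples$replicate_group)
    groups <- unique(grp)
    owner_grp <- rep_len(seq_len(n_sources), length(groups))
    datasets <- lapply(seq_len(n_sources), function(s) {
      rows <- which(grp %in% groups[owner_grp == s])
      cols <- c(planted, shared_bg, private_bg[private_owner == s])
      mir <- mat$mirnas[match(cols, mat$mirnas$name), , drop = FALSE]
      # source-specific alias names for shared columns
      mir$name <- paste0(mir$name, ".src", s)
      mir$source_dataset <- paste0("src", s)
      mir_matrix(mat$values[rows, cols, drop = FALSE],
                 transform(mat$samples[rows, , drop = FALSE],
                           dataset = paste0("src", s)),
                 mir, units = mat$units)
    })
    names(datasets) <- paste0("src", seq_len(n_sources))
  })
  list(datasets = datasets,
       union_sequences = unique(mat$mirnas$sequence),
       truth = gen$manifest)
}

#' Synthetic stand-in for the merged multi-study pluripotency dataset
#'
#' A labeled synthetic emulation of the real application's input: three
#' miRNA-seq sources with partially overlapping panels and replicates,
#' covering 4 pluripotent lines (positives) and 15 differentiated states
#' (negatives); a planted pluripotency marker (expressed at 3,000
#' copies/cell only in positives, playing the role miR-302a plays in the
#' real data) and two planted differentiation markers, each expressed in a
#' complementary subset of negatives (the miR-375/miR-489 roles). One source
#' additionally carries a hairpin record that merging must eliminate. This
#' is NOT the real dataset; it only reproduces its structure.
#'
#' @param seed RNG seed.
#' @return as [generate_expression_sources()], plus `hairpin_sequences`.
#' @export
synthetic_ev1_like <- function(seed) {
  spec <- expression_spec(
    n_positive = 4, n_negative = 15, n_background_mirnas = 40,
    planted_high = list(list(id = "syn-miR-302a-like", pos_level = 3000,
                             neg_level = 0)),
    # the two differentiation markers cover complementary negative subsets,
    # so together they flag every differentiated state
    planted_low = list(
      list(id = "syn-miR-375-like", pos_level = 0, neg_level = 2500,
           negative_samples = sprintf("neg_%02d", 1:8)),
      list(id = "syn-miR-489-like", pos_level = 0, neg_level = 2500,
           negative_samples = sprintf("neg_%02d", 9:15))),
    replicate_cv = 0.15, n_replicates = 2, seed = seed)
  src <- generate_expression_sources(spec, n_sources = 3,
                                     shared_fraction = 0.5)
  hairpin_seq <- with_rng(seed + 2L, random_sequences(1, 60))
  d1 <- src$datasets[[1]]
  hp_values <- cbind(d1$values,
                     `syn-hairpin-1` = rep(1000, nrow(d1$values)))
  hp_mirnas <- rbind(d1$mirnas,
                     data.frame(name = "syn-hairpin-1", sequence = hairpin_seq,
                                is_hairpin = TRUE, source_dataset = "src1",
                                stringsAsFactors = FALSE))
  src$datasets[[1]] <- mir_matrix(hp_values, d1$samples, hp_mirnas,
                                  units = d1$units)
  src$hairpin_sequences <- hairpin_seq
  src
}

#' Specification for a synthetic flow-cytometry event table
#'
#' Two-population log-normal mixtures per channel: transfected events draw
#' from the positive population, untransfected from the negative one.
#'
#' @param n_events number of events.
#' @param transfected_fraction fraction of transfected (channel-positive)
#'   events.
#' @param channels named list; each element a list with `pos_meanlog`,
#'   `pos_sdlog`, `neg_meanlog`, `neg_sdlog`.
#' @param dead_fraction fraction of dead-stain-positive events.
#' @param scatter_live_fraction fraction of events inside the scatter
#'   "live" gate.
#' @param seed mandatory RNG seed.
#' @return an object of class `cytometry_spec`.
#' @export
cytometry_spec <- function(n_events = 10000, transfected_fraction = 0.5,
                           channels = list(
                             reporter = list(pos_meanlog = log(1000),
                                             pos_sdlog = 0.5,
                                             neg_meanlog = log(10),
                                             neg_sdlog = 0.5),
                             marker = list(pos_meanlog = log(2000),
                                           pos_sdlog = 0.5,
                                           neg_meanlog = log(10),
                                           neg_sdlog = 0.5)),
                           dead_fraction = 0.05,
                           scatter_live_fraction = 0.9, seed) {
  if (missing(seed)) stop("an explicit seed is mandatory")
  stopifnot(n_events >= 1, transfected_fraction >= 0, transfected_fraction <= 1,
            dead_fraction >= 0, dead_fraction <= 1,
            scatter_live_fraction >= 0, scatter_live_fraction <= 1,
            length(channels) >= 1, !is.null(names(channels)))
  structure(list(n_events = n_events,
                 transfected_fraction = transfected_fraction,
                 channels = channels, dead_fraction = dead_fraction,
                 scatter_live_fraction = scatter_live_fraction,
                 seed = as.integer(seed)),
            class = "cytometry_spec")
}

#' Generate a synthetic flow-cytometry event table
#'
#' @param spec a [cytometry_spec()].
#' @return list with `events` (data.frame: one intensity column per channel,
#'   `dead_stain`, logical `scatter_live`, and the hidden truth column
#'   `transfected`) and `manifest` (the spec's mixture parameters).
#' @export
generate_cytometry <- function(spec) {
  stopifnot(inherits(spec, "cytometry_spec"))
  with_rng(spec$seed, {
    transfected <- stats::runif(spec$n_events) < spec$transfected_fraction
    events <- data.frame(row.names = seq_len(spec$n_events))
    for (ch in names(spec$channels)) {
      p <- spec$channels[[ch]]
      events[[ch]] <- ifelse(
        transfected,
        stats::rlnorm(spec$n_events, p$pos_meanlog, p$pos_sdlog),
        stats::rlnorm(spec$n_events, p$neg_meanlog, p$neg_sdlog))
    }
    dead <- stats::runif(spec$n_events) < spec$dead_fraction
    events$dead_stain <- ifelse(dead,
                                stats::rlnorm(spec$n_events, log(5000), 0.3),
                                stats::rlnorm(spec$n_events, log(20), 0.5))
    events$scatter_live <- stats::runif(spec$n_events) < spec$scatter_live_fraction
    events$transfected <- transfected
  })
  list(events = events,
       manifest = list(channels = spec$channels,
                       transfected_fraction = spec$transfected_fraction,
                       dead_fraction = spec$dead_fraction,
                       scatter_live_fraction = spec$scatter_live_fraction,
                       seed = spec$seed))
}

# lognormal partial expectation E[X; X > g]
lnorm_partial_mean <- function(g, meanlog, sdlog) {
  exp(meanlog + sdlog^2 / 2) *
    stats::pnorm((meanlog + sdlog^2 - log(g)) / sdlog)
}

#' Analytic rel.U. implied by a cytometry spec at given gates
#'
#' Closed-form expectation of the total reporter and marker signals under
#' the spec's log-normal mixtures, used as an independent oracle for
#' [relative_units()] on generated fixtures.
#'
#' @param spec a [cytometry_spec()].
#' @param gates named thresholds for the spec's channels.
#' @param reporter,marker channel names.
#' @return the expected rel.U. value.
#' @export
implied_relative_units <- function(spec, gates, reporter, marker) {
  total <- function(ch) {
    p <- spec$channels[[ch]]
    g <- gates[[ch]]
    w <- spec$transfected_fraction
    w * lnorm_partial_mean(g, p$pos_meanlog, p$pos_sdlog) +
      (1 - w) * lnorm_partial_mean(g, p$neg_meanlog, p$neg_sdlog)
  }
  total(reporter) / total(marker)
}

#' Specification for a synthetic micropatterned colony
#'
#' Cells uniform over the colony disc; each marker's intensity follows a
#' named radial profile shape plus Gaussian noise. Shapes (of normalized
#' radius r in [0, 1]): `flat`, `edge_high` (increasing), `center_high`
#' (decreasing), `ring` (Gaussian bump at r = 0.6).
#'
#' @param n_cells number of cells (>= 10).
#' @param colony_radius colony radius, micrometers.
#' @param markers named list; each a list with `shape`, `amplitude`,
#'   `baseline`.
#' @param noise_sd Gaussian intensity noise SD.
#' @param seed mandatory RNG seed.
#' @return an object of class `colony_spec`.
#' @export
colony_spec <- function(n_cells = 2000, colony_radius = 250,
                        markers = list(
                          Sox2 = list(shape = "center_high", amplitude = 1,
                                      baseline = 0.1),
                          TBXT = list(shape = "ring", amplitude = 1,
                                      baseline = 0.1),
                          Sox17 = list(shape = "edge_high", amplitude = 1,
                                       baseline = 0.1)),
                        noise_sd = 0.05, seed) {
  if (missing(seed)) stop("an explicit seed is mandatory")
  stopifnot(n_cells >= 10, colony_radius > 0, noise_sd >= 0,
            length(markers) >= 1, !is.null(names(markers)))
  structure(list(n_cells = n_cells, colony_radius = colony_radius,
                 markers = markers, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "colony_spec")
}

radial_shape_fun <- function(shape, amplitude, baseline) {
  switch(shape,
         flat = function(r) baseline + amplitude + 0 * r,
         edge_high = function(r) baseline + amplitude * r,
         center_high = function(r) baseline + amplitude * (1 - r),
         ring = function(r) baseline +
           amplitude * exp(-(r - 0.6)^2 / (2 * 0.15^2)),
         stop("unknown radial shape: ", shape))
}

#' Generate a synthetic colony point cloud
#'
#' @param spec a [colony_spec()].
#' @return list with `cells` (data.frame: `x`, `y` in micrometers relative to
#'   the colony center, one intensity column per marker), `radius`, and
#'   `manifest` holding the true radial functions.
#' @export
generate_colony <- function(spec) {
  stopifnot(inherits(spec, "colony_spec"))
  funs <- lapply(spec$markers, function(m)
    radial_shape_fun(m$shape, m$amplitude, m$baseline))
  with_rng(spec$seed, {
    r <- spec$colony_radius * sqrt(stats::runif(spec$n_cells))
    theta <- 2 * pi * stats::runif(spec$n_cells)
    cells <- data.frame(x = r * cos(theta), y = r * sin(theta))
    for (m in names(spec$markers))
      cells[[m]] <- funs[[m]](r / spec$colony_radius) +
        stats::rnorm(spec$n_cells, 0, spec$noise_sd)
  })
  list(cells = cells, radius = spec$colony_radius,
       manifest = list(radial_functions = funs, markers = spec$markers,
                       noise_sd = spec$noise_sd, seed = spec$seed))
}
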
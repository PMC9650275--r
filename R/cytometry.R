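# Flow-cytometry quantification: percentile gating against single-color
# controls, reporter signal in relative and absolute units, and viability.
# Compensation and scatter gating are accepted as pre-applied input; the
# canonical event table is a per-event CSV.

#' Gate threshold from a negative single-color control
#'
#' The positivity threshold for a channel is set on a fluorophore-negative
#' control so that 99.9% of control events fall outside (at or below) the
#' gate; events strictly above the threshold count as positive.
#'
#' @param control data.frame of control events (one row per event).
#' @param channel channel (column) name.
#' @param quantile_level percentile of the control used as threshold
#'   (default 0.999).
#' @return scalar intensity threshold.
#' @export
gate_threshold <- function(control, channel, quantile_level = 0.999) {
  if (!is.data.frame(control) || nrow(control) == 0)
    stop("empty control table")
  if (!channel %in% names(control)) stop("unknown channel: ", channel)
  x <- control[[channel]]
  if (any(!is.finite(x))) stop("non-finite intensities in control")
  if (nrow(control) < 1000)
    warning("control has fewer than 1,000 events (", nrow(control),
            "); threshold estimate may be unstable")
  unname(stats::quantile(x, quantile_level, type = 7))
}

#' Build a gate set from per-channel control tables
#'
#' @param controls named list mapping channel name to its negative-control
#'   event table.
#' @param quantile_level percentile rule (default 99.9%).
#' @return named numeric vector of thresholds with a `provenance` attribute.
#' @export
gate_set <- function(controls, quantile_level = 0.999) {
  thr <- vapply(names(controls), function(ch)
    gate_threshold(controls[[ch]], ch, quantile_level), 0)
  attr(thr, "provenance") <- paste0(names(controls), ": ", quantile_level * 100,
                                    "th percentile of supplied control")
  thr
}

positive_mask <- function(events, gates, channel) {
  if (!channel %in% names(events)) stop("unknown channel: ", channel)
  if (!channel %in% names(gates)) stop("no gate for channel: ", channel)
  events[[channel]] > gates[[channel]]
}

# mean(channel in positive cells) x frequency(positive cells); 0 when no
# event is positive. Frequencies are relative to the events passed in
# (live/single pre-gating is the caller's responsibility).
total_signal <- function(events, gates, channel) {
  pos <- positive_mask(events, gates, channel)
  if (!any(pos)) return(0)
  mean(events[[channel]][pos]) * mean(pos)
}

#' Reporter intensity in relative units (rel.U.)
#'
#' `[mean(reporter in reporter+ cells) x freq(reporter+)] /
#'  [mean(marker in marker+ cells) x freq(marker+)]` — the total reporter
#' signal normalized by the total transfection-marker signal to counter
#' transfection variation. Events are assumed pre-gated to live singlets.
#'
#' @param sample data.frame of events.
#' @param gates named thresholds from [gate_set()] (or a named numeric).
#' @param reporter,marker channel names.
#' @return scalar rel.U. value.
#' @export
relative_units <- function(sample, gates, reporter, marker) {
  denom <- total_signal(sample, gates, marker)
  if (denom == 0)
    stop("no transfection-marker-positive events; rel.U. undefined")
  total_signal(sample, gates, reporter) / denom
}

#' Reporter intensity in absolute units (a.u.)
#'
#' `mean(reporter in reporter+ cells) x freq(reporter+)`, without marker
#' normalization.
#'
#' @inheritParams relative_units
#' @return scalar a.u. value.
#' @export
absolute_units <- function(sample, gates, reporter) {
  total_signal(sample, gates, reporter)
}

#' Viability of a sample
#'
#' Product of the fraction of scatter-"live" cells and the fraction of cells
#' negative for the dead stain, both computed on the full event set.
#'
#' @param sample data.frame of events with a logical `scatter_live` column
#'   and a dead-stain intensity column.
#' @param dead_channel dead-stain channel name.
#' @param dead_threshold stain positivity threshold (events at or below it
#'   are stain-negative); typically from [gate_threshold()] on an unstained
#'   control.
#' @param scatter_col name of the logical scatter-live flag column.
#' @return viability fraction in [0, 1].
#' @export
viability <- function(sample, dead_channel = "dead_stain", dead_threshold,
                      scatter_col = "scatter_live") {
  stopifnot(scatter_col %in% names(sample), dead_channel %in% names(sample))
  live <- sample[[scatter_col]]
  if (!is.logical(live)) stop(scatter_col, " must be logical")
  mean(live) * mean(sample[[dead_channel]] <= dead_threshold)
}

#' Per-sample cytometry metrics table
#'
#' Convenience wrapper computing rel.U., a.u., positive fractions and
#' viability for one sample.
#'
#' @inheritParams relative_units
#' @inheritParams viability
#' @return one-row data.frame of metrics.
#' @export
cytometry_metrics <- function(sample, gates, reporter, marker,
                              dead_channel = "dead_stain",
                              dead_threshold = NULL,
                              scatter_col = "scatter_live") {
  data.frame(
    rel_units = relative_units(sample, gates, reporter, marker),
    abs_units = absolute_units(sample, gates, reporter),
    reporter_pos_frac = mean(positive_mask(sample, gates, reporter)),
    marker_pos_frac = mean(positive_mask(sample, gates, marker)),
    viability = if (is.null(dead_threshold)) NA_real_
                else viability(sample, dead_channel, dead_threshold, scatter_col))
}
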
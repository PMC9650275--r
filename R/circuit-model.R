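# Steady-state bow-tie circuit model: a miR_high sensor (double inversion,
# miRNA -| Act1 -> miR-FF4 -| Act2) and direct miR_low repression converge on
# the central activator Act2, which drives the output. All relationships are
# non-cooperative Hill functions; the cascade has no feedback, so the steady
# state is obtained by closed-form sequential substitution.

#' Circuit model parameters
#'
#' The eight constants of the steady-state model, all in molecules/cell.
#' Defaults are the optimized set used throughout: IC50s of 20, dissociation
#' constants of 10,251, maximal activator levels of 9,755, maximal miR-FF4 of
#' 3,000 and maximal output of 30,000 molecules/cell.
#'
#' @param IC50miR endogenous-miRNA concentration for half knockdown.
#' @param IC50FF4 miR-FF4 concentration for half repression of Act2.
#' @param KD1,KD2 dissociation constants of Act1/Act2 from their promoters.
#' @param Act1MAX,Act2MAX maximal constitutive activator concentrations.
#' @param FF4MAX maximal miR-FF4 expression under full activation.
#' @param OutMAX maximal output under Act2 saturation.
#' @return an object of class `circuit_params` (named numeric list).
#' @export
model_parameters <- function(IC50miR = 20, IC50FF4 = 20,
                             KD1 = 10251, KD2 = 10251,
                             Act1MAX = 9755, Act2MAX = 9755,
                             FF4MAX = 3000, OutMAX = 30000) {
  p <- list(IC50miR = IC50miR, IC50FF4 = IC50FF4, KD1 = KD1, KD2 = KD2,
            Act1MAX = Act1MAX, Act2MAX = Act2MAX, FF4MAX = FF4MAX,
            OutMAX = OutMAX)
  ok_scalar <- function(v) is.numeric(v) && length(v) == 1 && is.finite(v)
  bad <- !vapply(p, ok_scalar, TRUE)
  # IC50s and dissociation constants appear in denominators and must be
  # strictly positive; MAX levels may be zero (disconnected branch limits)
  strict <- c("IC50miR", "IC50FF4", "KD1", "KD2")
  bad <- bad |
    vapply(names(p), function(nm)
      ok_scalar(p[[nm]]) &&
        (if (nm %in% strict) p[[nm]] <= 0 else p[[nm]] < 0), TRUE)
  if (any(bad))
    stop("invalid parameter value(s): ",
         paste(names(p)[bad], collapse = ", "))
  structure(p, class = "circuit_params")
}

#' Load model parameters from a JSON file
#'
#' @param path JSON file mapping parameter names to values; missing names
#'   fall back to the optimized defaults.
#' @return a `circuit_params` object.
#' @export
read_parameters <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(model_parameters))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  do.call(model_parameters, as.list(vals))
}

# survival fraction of a Hill-repressed node: 1 - m/(ic50 + m)
hill_repression <- function(m, ic50) ic50 / (ic50 + m)

#' Steady state of the bow-tie circuit
#'
#' Sequential closed-form evaluation: Act1 is repressed by the summed
#' miR_high input, Act1 drives miR-FF4, miR-FF4 represses Act2, and each
#' miR_low input further represses Act2 multiplicatively (shared IC50miR);
#' Act2 drives the output. With `high_sensor = FALSE` the double-inversion
#' branch is absent (FF4 = 0, Act1 reported as NA) for pure miR_low circuits.
#'
#' @param miR_high_total combined miR_high input, molecules/cell (>= 0).
#' @param miR_low_levels named or unnamed numeric vector of miR_low input
#'   concentrations, molecules/cell (>= 0); may be empty.
#' @param params a [model_parameters()] object.
#' @param high_sensor logical; is the miR_high sensor part of the circuit?
#' @return object of class `steady_state`: list with `Act1`, `FF4`, `Act2`,
#'   `Out` in molecules/cell.
#' @export
steady_state <- function(miR_high_total = 0, miR_low_levels = numeric(0),
                         params = model_parameters(), high_sensor = TRUE) {
  stopifnot(inherits(params, "circuit_params"))
  if (!is.numeric(miR_high_total) || length(miR_high_total) != 1 ||
      is.na(miR_high_total) || miR_high_total < 0)
    stop("miR_high_total must be a single non-negative number")
  if (length(miR_low_levels) && any(!is.finite(miR_low_levels) | miR_low_levels < 0))
    stop("miR_low levels must be finite and non-negative")

  if (high_sensor) {
    Act1 <- params$Act1MAX * hill_repression(miR_high_total, params$IC50miR)
    FF4 <- params$FF4MAX * Act1 / (params$KD1 + Act1)
  } else {
    Act1 <- NA_real_
    FF4 <- 0
  }
  low_factor <- prod(hill_repression(miR_low_levels, params$IC50miR))
  Act2 <- params$Act2MAX * hill_repression(FF4, params$IC50FF4) * low_factor
  Out <- params$OutMAX * Act2 / (params$KD2 + Act2)
  structure(list(Act1 = Act1, FF4 = FF4, Act2 = Act2, Out = Out),
            class = "steady_state")
}

#' On/Off ratio (dynamic range) of the miR_high sensor
#'
#' Ratio of steady-state outputs at the On and Off miR_high input levels,
#' with no miR_low inputs. Defaults follow the simulated states: On at 3,000
#' molecules/cell (high physiological), Off at 0.
#'
#' @param params a [model_parameters()] object.
#' @param m_on,m_off miR_high input in the On/Off state, molecules/cell.
#' @return scalar ratio; `Inf` (with a warning) when the Off output is zero.
#' @export
on_off_ratio <- function(params = model_parameters(), m_on = 3000, m_off = 0) {
  out_on <- steady_state(m_on, params = params)$Out
  out_off <- steady_state(m_off, params = params)$Out
  if (out_off == 0) {
    warning("Off-state output is zero; On/Off ratio reported as +Inf")
    return(Inf)
  }
  out_on / out_off
}

#' Single-parameter screen of the On/Off ratio
#'
#' Dose-response of the dynamic range as one model parameter sweeps a grid
#' with all others fixed.
#'
#' @param params baseline [model_parameters()].
#' @param name parameter to vary (one of the eight names).
#' @param grid strictly positive, sorted numeric grid.
#' @param m_on,m_off On/Off miR_high inputs.
#' @return a `screen_result` data.frame with columns `value`, `on`, `off`,
#'   `ratio`; the varied parameter name is in attribute `varied`.
#' @export
parameter_screen <- function(params, name, grid, m_on = 3000, m_off = 0) {
  stopifnot(inherits(params, "circuit_params"))
  if (!name %in% names(params)) stop("unknown parameter: ", name)
  if (any(grid <= 0) || is.unsorted(grid))
    stop("grid must be strictly positive and sorted")
  res <- vapply(grid, function(v) {
    p <- params
    p[[name]] <- v
    c(on = steady_state(m_on, params = p)$Out,
      off = steady_state(m_off, params = p)$Out)
  }, c(on = 0, off = 0))
  out <- data.frame(value = grid, on = res["on", ], off = res["off", ])
  out$ratio <- ifelse(out$off > 0, out$on / out$off, Inf)
  if (any(out$off == 0)) warning("zero Off output at some grid points (+Inf ratio)")
  structure(out, varied = name, class = c("screen_result", "data.frame"))
}

#' Combinatorial Act1MAX x Act2MAX screen
#'
#' FF4 and output levels at the On and Off states over every pair on the two
#' grids, plus the FF4 Off/On and output On/Off ratios. FF4 depends only on
#' the Act1 branch, so its grids are constant along the Act2MAX axis.
#'
#' @param act1_grid,act2_grid positive grids of Act1MAX / Act2MAX values.
#' @param params fixed remaining parameters.
#' @param m_on,m_off On/Off miR_high inputs.
#' @return list of matrices (rows = Act1MAX, cols = Act2MAX): `ff4_on`,
#'   `ff4_off`, `out_on`, `out_off`, `ff4_off_on`, `out_on_off`.
#' @export
combinatorial_screen <- function(act1_grid, act2_grid,
                                 params = model_parameters(),
                                 m_on = 3000, m_off = 0) {
  stopifnot(all(act1_grid > 0), all(act2_grid > 0))
  dn <- list(Act1MAX = as.character(act1_grid), Act2MAX = as.character(act2_grid))
  mk <- function() matrix(NA_real_, length(act1_grid), length(act2_grid),
                          dimnames = dn)
  out <- list(ff4_on = mk(), ff4_off = mk(), out_on = mk(), out_off = mk())
  for (i in seq_along(act1_grid)) for (j in seq_along(act2_grid)) {
    p <- params
    p$Act1MAX <- act1_grid[i]
    p$Act2MAX <- act2_grid[j]
    on <- steady_state(m_on, params = p)
    off <- steady_state(m_off, params = p)
    out$ff4_on[i, j] <- on$FF4
    out$ff4_off[i, j] <- off$FF4
    out$out_on[i, j] <- on$Out
    out$out_off[i, j] <- off$Out
  }
  out$ff4_off_on <- out$ff4_off / out$ff4_on
  out$out_on_off <- out$out_on / out$out_off
  out
}

#' Attenuate an output through a miSFIT tuner variant
#'
#' miSFITs (mutated miRNA target-site variants) confer graded, pre-selected
#' repression of an output; they are consumed here as multiplicative
#' repression factors in [0, 1], not predicted from sequence.
#'
#' @param out output level(s), molecules/cell.
#' @param repression_factor scalar factor in [0, 1], or a variant name to be
#'   looked up in `variant_table`.
#' @param variant_table optional named numeric vector or list mapping variant
#'   names to factors (e.g. from [read_misfit_table()]).
#' @return attenuated output(s).
#' @export
misfit_attenuate <- function(out, repression_factor, variant_table = NULL) {
  if (is.character(repression_factor)) {
    if (is.null(variant_table) || !repression_factor %in% names(variant_table))
      stop("unknown miSFIT variant: ", repression_factor)
    repression_factor <- as.numeric(variant_table[[repression_factor]])
  }
  if (!is.numeric(repression_factor) || any(repression_factor < 0) ||
      any(repression_factor > 1))
    stop("repression factor must lie in [0, 1]")
  out * repression_factor
}

#' Read a miSFIT variant table (variant, factor) from CSV
#'
#' @param path CSV with columns `variant` and `factor` (factors in [0, 1]).
#' @return named numeric vector of repression factors.
#' @export
read_misfit_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("variant", "factor") %in% names(tab)))
  if (any(tab$factor < 0 | tab$factor > 1))
    stop("miSFIT factors must lie in [0, 1]")
  stats::setNames(tab$factor, tab$variant)
}
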
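# Micropatterned-colony spatial quantification: radial (annular-bin) mean
# intensity profiles with standard errors, max-normalization, area under the
# radial curve above the minimum-intensity baseline, and marker-positive
# composition fractions. Colony membership and cell coordinates relative to
# the colony center are accepted as input (segmentation/clustering is out of
# scope).

#' Radial intensity profile of a colony
#'
#' Cells are assigned a normalized radius `r = sqrt(x^2 + y^2) / radius`
#' (clipped to [0, 1]; 0 = colony center, 1 = edge) and grouped into
#' equal-width annular bins; per bin the arithmetic mean intensity, its
#' standard error and the cell count are reported. Bins are cell-weighted
#' (no annulus-area correction). SE is NA for bins with fewer than 2 cells.
#'
#' @param cells data.frame with columns `x`, `y` (micrometers, relative to
#'   the colony center) and one intensity column per marker.
#' @param marker intensity column to profile.
#' @param radius colony radius in micrometers (> 0). Cells farther than
#'   1.2x the radius are rejected as mis-assigned.
#' @param n_bins number of annular bins (>= 2), default 20.
#' @return a `radial_profile` data.frame with columns `bin_lo`, `bin_hi`,
#'   `bin_mid`, `n`, `mean`, `se`; the marker name is kept in attribute
#'   `marker`.
#' @export
radial_profile <- function(cells, marker, radius, n_bins = 20) {
  stopifnot(is.data.frame(cells), n_bins >= 2, radius > 0)
  if (nrow(cells) == 0) stop("empty colony")
  if (!marker %in% names(cells)) stop("unknown marker: ", marker)
  r <- sqrt(cells$x^2 + cells$y^2) / radius
  if (any(r > 1.2))
    stop("cell(s) beyond 1.2x the colony radius; check colony assignment")
  r <- pmin(r, 1)
  edges <- seq(0, 1, length.out = n_bins + 1)
  bin <- pmin(findInterval(r, edges, rightmost.closed = TRUE), n_bins)
  v <- cells[[marker]]
  prof <- data.frame(
    bin_lo = edges[-(n_bins + 1)],
    bin_hi = edges[-1],
    bin_mid = (edges[-1] + edges[-(n_bins + 1)]) / 2,
    n = vapply(seq_len(n_bins), function(b) sum(bin == b), 0L))
  prof$mean <- vapply(seq_len(n_bins), function(b)
    if (prof$n[b] > 0) mean(v[bin == b]) else NA_real_, 0)
  prof$se <- vapply(seq_len(n_bins), function(b)
    if (prof$n[b] >= 2) stats::sd(v[bin == b]) / sqrt(prof$n[b]) else NA_real_, 0)
  structure(prof, marker = marker, normalized = FALSE,
            class = c("radial_profile", "data.frame"))
}

#' Normalize a radial profile to its peak
#'
#' Divides all bin means (and SEs) by the highest radial mean intensity, so
#' the peak bin equals 1. Idempotent on an already-normalized profile.
#'
#' @param profile a [radial_profile()].
#' @return the normalized `radial_profile`.
#' @export
normalize_profile <- function(profile) {
  stopifnot(inherits(profile, "radial_profile"))
  top <- max(profile$mean, na.rm = TRUE)
  if (!is.finite(top) || top <= 0)
    stop("cannot normalize: maximal radial intensity is not positive")
  profile$mean <- profile$mean / top
  profile$se <- profile$se / top
  attr(profile, "normalized") <- TRUE
  profile
}

#' Area under a radial profile above its minimum baseline
#'
#' Trapezoidal area of `mean - min(mean)` over the normalized radius (bin
#' midpoints), so each profile carries its own baseline; the associated
#' standard error is propagated in quadrature with the trapezoid weights.
#' Empty bins are dropped from the curve; bins with undefined SE contribute
#' zero to the error term (flagged by `se_complete`).
#'
#' @param profile a [radial_profile()] (typically normalized first).
#' @return list with `auc`, `se`, and `se_complete` (FALSE when some bins
#'   lacked an SE).
#' @export
profile_auc <- function(profile) {
  stopifnot(inherits(profile, "radial_profile"))
  keep <- profile$n > 0
  x <- profile$bin_mid[keep]
  y <- profile$mean[keep]
  se <- profile$se[keep]
  if (length(x) < 2) stop("need at least two populated bins")
  y0 <- y - min(y)
  k <- length(x)
  # trapezoid weights: auc = sum(w_i * y0_i)
  w <- numeric(k)
  w[1] <- (x[2] - x[1]) / 2
  w[k] <- (x[k] - x[k - 1]) / 2
  if (k > 2) w[2:(k - 1)] <- (x[3:k] - x[1:(k - 2)]) / 2
  se_complete <- !anyNA(se)
  se_use <- ifelse(is.na(se), 0, se)
  list(auc = sum(w * y0),
       se = sqrt(sum((w * se_use)^2)),
       se_complete = se_complete)
}

#' Marker-positive composition fractions of a colony
#'
#' Per marker, the fraction of cells with intensity strictly above the
#' supplied threshold (from negative-control clouds, same 99.9% percentile
#' rule as cytometry gating). Markers are not mutually exclusive, so
#' fractions need not sum to 1.
#'
#' @param cells per-cell data.frame with one intensity column per marker.
#' @param thresholds named numeric vector mapping marker to threshold.
#' @return named numeric vector of fractions in [0, 1].
#' @export
composition_fractions <- function(cells, thresholds) {
  stopifnot(is.data.frame(cells), length(thresholds) >= 1,
            !is.null(names(thresholds)))
  missing <- setdiff(names(thresholds), names(cells))
  if (length(missing)) stop("unknown marker(s): ", paste(missing, collapse = ", "))
  vapply(names(thresholds), function(m)
    mean(cells[[m]] > thresholds[[m]]), 0)
}

#' Radial profiles and AUCs for several markers at once
#'
#' @param cells per-cell data.frame (`x`, `y`, marker columns).
#' @param markers character vector of marker columns.
#' @param radius colony radius, micrometers.
#' @param n_bins number of annular bins.
#' @return list with `profiles` (long data.frame: marker, bin_mid, mean, se,
#'   n) and `auc` (data.frame: marker, auc, se), computed on max-normalized
#'   profiles.
#' @export
colony_summary <- function(cells, markers, radius, n_bins = 20) {
  profs <- lapply(markers, function(m)
    normalize_profile(radial_profile(cells, m, radius, n_bins)))
  long <- do.call(rbind, lapply(seq_along(markers), function(i)
    data.frame(marker = markers[i], profs[[i]][, c("bin_mid", "mean", "se", "n")])))
  aucs <- do.call(rbind, lapply(seq_along(markers), function(i) {
    a <- profile_auc(profs[[i]])
    data.frame(marker = markers[i], auc = a$auc, se = a$se)
  }))
  list(profiles = long, auc = aucs)
}
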
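# miRNA expression matrices: construction, I/O, merging, replicate
# averaging, and binarization against the 1%-of-pool relevance threshold.

#' miRNA expression matrix
#'
#' Container for a samples x miRNAs abundance table together with the sample
#' sheet (class labels, cell states, replicate groups, source dataset) and the
#' miRNA annotation (mature sequence, hairpin flag, source). This is the
#' canonical input of the classifier search.
#'
#' @param values numeric matrix, rows = samples, columns = miRNAs, all values
#'   >= 0. Row and column names are taken from `samples$sample` and
#'   `mirnas$name` when absent.
#' @param samples data.frame with columns `sample`, `label` (one of
#'   `"positive"`/`"negative"`), and optionally `cell_state`,
#'   `replicate_group`, `dataset`.
#' @param mirnas data.frame with columns `name`, `sequence` (mature sequence
#'   over A/C/G/U/T, normalized to uppercase DNA on construction), and
#'   optionally `is_hairpin`, `source_dataset`.
#' @param units abundance units: `"copies_per_cell"`, `"counts"` or
#'   `"fraction"`. The classifier search requires copies per cell.
#' @return an object of class `mir_matrix`.
#' @export
mir_matrix <- function(values, samples, mirnas,
                       units = c("copies_per_cell", "counts", "fraction")) {
  units <- match.arg(units)
  values <- as.matrix(values)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  mirnas <- as.data.frame(mirnas, stringsAsFactors = FALSE)
  stopifnot(is.numeric(values),
            all(c("sample", "label") %in% names(samples)),
            all(c("name", "sequence") %in% names(mirnas)))
  if (nrow(values) != nrow(samples) || ncol(values) != nrow(mirnas))
    stop("values must be samples x mirnas (",
         nrow(samples), " x ", nrow(mirnas), ")")
  if (any(values < 0) || any(!is.finite(values)))
    stop("abundances must be finite and >= 0")
  if (!all(samples$label %in% c("positive", "negative")))
    stop("sample labels must be 'positive' or 'negative'")
  if (anyDuplicated(samples$sample))
    stop("duplicate sample ids: ",
         paste(unique(samples$sample[duplicated(samples$sample)]), collapse = ", "))
  if (is.null(mirnas$is_hairpin)) mirnas$is_hairpin <- FALSE
  if (is.null(mirnas$source_dataset)) mirnas$source_dataset <- NA_character_
  if (is.null(samples$cell_state)) samples$cell_state <- NA_character_
  if (is.null(samples$replicate_group)) samples$replicate_group <- NA_character_
  if (is.null(samples$dataset)) samples$dataset <- NA_character_
  if (anyDuplicated(paste(mirnas$source_dataset, mirnas$name)))
    stop("duplicate miRNA name within a source dataset")
  mirnas$sequence <- normalize_sequence(mirnas$sequence)
  rownames(values) <- samples$sample
  colnames(values) <- mirnas$name
  structure(list(values = values, samples = samples, mirnas = mirnas,
                 units = units),
            class = "mir_matrix")
}

#' @export
print.mir_matrix <- function(x, ...) {
  cat(sprintf("mir_matrix: %d samples x %d miRNAs [%s]\n",
              nrow(x$values), ncol(x$values), x$units))
  cat(sprintf("  positives: %d, negatives: %d\n",
              sum(x$samples$label == "positive"),
              sum(x$samples$label == "negative")))
  invisible(x)
}

#' @export
dim.mir_matrix <- function(x) dim(x$values)

#' Merge multi-source miRNA expression datasets by mature sequence
#'
#' Hairpin records (flagged per record or matching a supplied hairpin sequence
#' list) are eliminated; records with an identical mature sequence — after
#' uppercasing and U->T normalization — are unified into one column, summing
#' abundances within a sample; miRNAs absent from a source are zero-filled.
#' Sample ids are prefixed with the dataset tag.
#'
#' @param datasets named list of [mir_matrix] objects; names are used as the
#'   sample-id prefix (falling back to each sample sheet's `dataset`, then
#'   `ds<i>`).
#' @param hairpin_sequences optional character vector of hairpin sequences; a
#'   record whose mature sequence exactly matches one (after normalization) is
#'   eliminated.
#' @return a [mir_matrix] covering the union of distinct mature sequences,
#'   with a `provenance` attribute mapping each merged column to the source
#'   (dataset, name) pairs unified into it.
#' @export
merge_datasets <- function(datasets, hairpin_sequences = NULL) {
  stopifnot(is.list(datasets), length(datasets) >= 1)
  lapply(datasets, function(d)
    if (!inherits(d, "mir_matrix")) stop("all datasets must be mir_matrix"))
  units <- unique(vapply(datasets, `[[`, "", "units"))
  if (length(units) != 1)
    stop("datasets carry different units: ", paste(units, collapse = ", "))
  hp <- if (length(hairpin_sequences)) normalize_sequence(hairpin_sequences)
        else character(0)

  tags <- names(datasets)
  if (is.null(tags)) tags <- rep(NA_character_, length(datasets))
  tags <- vapply(seq_along(datasets), function(i) {
    if (!is.na(tags[i]) && nzchar(tags[i])) return(tags[i])
    ds <- unique(datasets[[i]]$samples$dataset)
    if (length(ds) == 1 && !is.na(ds)) ds else paste0("ds", i)
  }, "")

  kept <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    drop <- d$mirnas$is_hairpin | d$mirnas$sequence %in% hp
    list(values = d$values[, !drop, drop = FALSE],
         mirnas = d$mirnas[!drop, , drop = FALSE],
         samples = transform(d$samples,
                             sample = paste0(tags[i], ":", sample),
                             dataset = tags[i]))
  })

  seqs <- unique(unlist(lapply(kept, function(k) k$mirnas$sequence)))
  if (length(seqs) == 0)
    stop("no usable miRNAs after hairpin elimination")
  all_samples <- do.call(rbind, lapply(kept, `[[`, "samples"))
  if (anyDuplicated(all_samples$sample))
    stop("duplicate sample id after dataset prefixing: ",
         paste(unique(all_samples$sample[duplicated(all_samples$sample)]),
               collapse = ", "))

  merged <- matrix(0, nrow(all_samples), length(seqs),
                   dimnames = list(all_samples$sample, NULL))
  provenance <- stats::setNames(vector("list", length(seqs)), seqs)
  canonical <- character(length(seqs))
  row0 <- 0
  for (k in kept) {
    idx <- match(k$mirnas$sequence, seqs)
    rows <- row0 + seq_len(nrow(k$values))
    for (j in seq_along(idx)) {
      merged[rows, idx[j]] <- merged[rows, idx[j]] + k$values[, j]
      provenance[[idx[j]]] <- c(provenance[[idx[j]]],
                                list(list(dataset = k$samples$dataset[1],
                                          name = k$mirnas$name[j])))
      if (!nzchar(canonical[idx[j]])) canonical[idx[j]] <- k$mirnas$name[j]
    }
    row0 <- row0 + nrow(k$values)
  }
  # resolve canonical-name collisions across sequences by suffixing
  canonical <- make.unique(canonical, sep = "/")

  out <- mir_matrix(merged, all_samples,
                    data.frame(name = canonical, sequence = seqs,
                               is_hairpin = FALSE,
                               source_dataset = "merged",
                               stringsAsFactors = FALSE),
                    units = units)
  names(provenance) <- canonical
  attr(out, "provenance") <- provenance
  out
}

#' Average replicate samples
#'
#' Collapses samples sharing a `replicate_group` to their arithmetic mean.
#' Samples without a group are kept unchanged. Labels (and cell states) must
#' agree within a group.
#'
#' @param matrix a [mir_matrix] with `replicate_group` populated for at least
#'   one group.
#' @return a [mir_matrix] with one row per replicate group.
#' @export
average_replicates <- function(matrix) {
  stopifnot(inherits(matrix, "mir_matrix"))
  grp <- matrix$samples$replicate_group
  if (all(is.na(grp))) stop("no replicate_group populated")
  key <- ifelse(is.na(grp), paste0(".single.", matrix$samples$sample), grp)
  keys <- unique(key)
  vals <- matrix(0, length(keys), ncol(matrix$values))
  sheet <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    rows <- which(key == keys[i])
    lab <- unique(matrix$samples$label[rows])
    if (length(lab) != 1)
      stop("conflicting labels within replicate group '", keys[i], "'")
    vals[i, ] <- colMeans(matrix$values[rows, , drop = FALSE])
    sheet[[i]] <- data.frame(
      sample = if (is.na(grp[rows[1]])) matrix$samples$sample[rows[1]] else keys[i],
      label = lab,
      cell_state = matrix$samples$cell_state[rows[1]],
      replicate_group = NA_character_,
      dataset = matrix$samples$dataset[rows[1]],
      stringsAsFactors = FALSE)
  }
  mir_matrix(vals, do.call(rbind, sheet), matrix$mirnas, units = matrix$units)
}

#' Binarize an expression matrix against the pool-fraction threshold t
#'
#' Per sample, the relevance threshold is `t = t_fraction x (total abundance
#' of the sample)`; the returned ratios are `abundance / t`, so a value > 1
#' means the miRNA exceeds the threshold (is "biologically relevant") in that
#' sample. The default `t_fraction = 0.01` is 1% of the total miRNA pool.
#'
#' @param matrix a [mir_matrix].
#' @param t_fraction fraction of the per-sample total pool, in (0, 1).
#' @return an object of class `mir_binarized` with elements `ratio_over_t`
#'   (samples x miRNAs), `t_fraction`, `samples`, `mirnas`.
#' @export
binarize <- function(matrix, t_fraction = 0.01) {
  stopifnot(inherits(matrix, "mir_matrix"),
            is.numeric(t_fraction), length(t_fraction) == 1,
            t_fraction > 0, t_fraction < 1)
  totals <- rowSums(matrix$values)
  if (any(totals <= 0))
    stop("sample(s) with zero total abundance: ",
         paste(matrix$samples$sample[totals <= 0], collapse = ", "))
  ratio <- matrix$values / (t_fraction * totals)
  structure(list(ratio_over_t = ratio, t_fraction = t_fraction,
                 samples = matrix$samples, mirnas = matrix$mirnas),
            class = "mir_binarized")
}

#' Read an expression dataset from its three CSV tables
#'
#' The wide matrix CSV has rows = miRNAs (first column `name`) and columns =
#' samples; the sequence table has columns `name`, `sequence`, optionally
#' `is_hairpin`; the sample sheet has columns `sample`, `label`, optionally
#' `cell_state`, `replicate_group`, `dataset`.
#'
#' @param matrix_csv,sequences_csv,samples_csv file paths.
#' @param units abundance units tag.
#' @return a [mir_matrix].
#' @export
read_expression_csv <- function(matrix_csv, sequences_csv, samples_csv,
                                units = "copies_per_cell") {
  wide <- utils::read.csv(matrix_csv, check.names = FALSE)
  seqs <- utils::read.csv(sequences_csv, stringsAsFactors = FALSE)
  sheet <- utils::read.csv(samples_csv, stringsAsFactors = FALSE)
  rownames(wide) <- wide[[1]]
  wide <- as.matrix(wide[, -1, drop = FALSE])
  idx <- match(rownames(wide), seqs$name)
  if (anyNA(idx)) stop("miRNAs missing from sequence table: ",
                       paste(rownames(wide)[is.na(idx)], collapse = ", "))
  sidx <- match(colnames(wide), sheet$sample)
  if (anyNA(sidx)) stop("samples missing from sample sheet: ",
                        paste(colnames(wide)[is.na(sidx)], collapse = ", "))
  mir_matrix(t(wide), sheet[sidx, , drop = FALSE],
             seqs[idx, , drop = FALSE], units = units)
}

#' Write a merged matrix as CSV plus a provenance JSON
#'
#' @param matrix a [mir_matrix] (typically from [merge_datasets()]).
#' @param matrix_csv path for the wide CSV (rows = miRNAs, columns = samples).
#' @param provenance_json optional path for the unification provenance.
#' @return invisibly, the paths written.
#' @export
write_expression_csv <- function(matrix, matrix_csv, provenance_json = NULL) {
  stopifnot(inherits(matrix, "mir_matrix"))
  wide <- data.frame(name = matrix$mirnas$name, t(matrix$values),
                     check.names = FALSE)
  utils::write.csv(wide, matrix_csv, row.names = FALSE)
  if (!is.null(provenance_json)) {
    prov <- attr(matrix, "provenance") %||%
      stats::setNames(as.list(matrix$mirnas$sequence), matrix$mirnas$name)
    jsonlite::write_json(prov, provenance_json, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(c(matrix_csv, provenance_json))
}
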
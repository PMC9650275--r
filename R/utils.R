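# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Geometric mean
#'
#' Geometric mean of a strictly positive vector, computed on the log scale
#' for numerical stability.
#'
#' @param x numeric vector, all values > 0.
#' @return scalar geometric mean.
#' @export
geomean <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 1)
  if (any(x <= 0)) stop("geomean() requires strictly positive values")
  exp(mean(log(x)))
}

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. Generators must not leak RNG state.
with_rng <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("a single integer seed is required")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Normalize a mature miRNA sequence: uppercase, U -> T, alphabet-checked.
normalize_sequence <- function(seq) {
  seq <- toupper(as.character(seq))
  seq <- gsub("U", "T", seq, fixed = TRUE)
  bad <- grepl("[^ACGT]", seq) | !nzchar(seq)
  if (any(bad))
    stop("invalid mature sequence(s): ",
         paste(utils::head(seq[bad], 3), collapse = ", "))
  seq
}
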
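# Independent oracles and small fixture builders shared across tests.
# Oracles deliberately avoid the code paths they check.

# fixed-point iteration of the four steady-state equations (independent of
# the package's closed-form sequential substitution)
fp_steady_state <- function(m, p, lows = numeric(0), tol = 1e-12) {
  x <- c(0, 0, 0, 0) # Act1, FF4, Act2, Out
  low_factor <- prod(vapply(lows, function(l) 1 - l / (p$IC50miR + l), 0))
  if (length(lows) == 0) low_factor <- 1
  repeat {
    new <- c(p$Act1MAX * (1 - m / (p$IC50miR + m)),
             p$FF4MAX * x[1] / (p$KD1 + x[1]),
             p$Act2MAX * (1 - x[2] / (p$IC50FF4 + x[2])) * low_factor,
             p$OutMAX * x[3] / (p$KD2 + x[3]))
    if (max(abs(new - x)) < tol) return(
      list(Act1 = new[1], FF4 = new[2], Act2 = new[3], Out = new[4]))
    x <- new
  }
}

# brute-force pairwise ROC AUC (Mann-Whitney count)
auc_bruteforce <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# brute-force margins from explicit pairs and geometric means
cmargin_bruteforce <- function(pos, neg) {
  gm <- function(x) exp(mean(log(x)))
  avg <- log10(gm(pos) / gm(neg))
  worst <- log10(min(outer(pos, neg, `/`)))
  list(avg_margin = avg, worst_margin = worst, cmargin = (avg + worst) / 2)
}

# deterministic distinct 22-mers: a 20-base stem plus an index-specific tail
fixed_sequences <- function(n) {
  tails <- c(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0))
  stopifnot(n <= length(tails))
  paste0(strrep("AC", 10), tails[seq_len(n)])
}

# a tiny hand-built labeled matrix in copies/cell
tiny_matrix <- function(values, labels,
                        mirna_names = paste0("miR-", seq_len(ncol(values)))) {
  values <- as.matrix(values)
  mir_matrix(values,
             data.frame(sample = paste0("s", seq_len(nrow(values))),
                        label = labels, stringsAsFactors = FALSE),
             data.frame(name = mirna_names,
                        sequence = fixed_sequences(ncol(values)),
                        stringsAsFactors = FALSE),
             units = "copies_per_cell")
}
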
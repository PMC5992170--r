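# Independent oracles used across the suite. These deliberately avoid
# the code paths they check.

# One-sided enrichment p-value by direct enumeration of the
# hypergeometric distribution with choose().
enumerate_enrichment_p <- function(count_sel, total_sel, count_bg,
                                   total_bg) {
  K <- count_sel + count_bg          # occurrences over both pools
  N <- total_sel + total_bg
  ks <- max(0, total_sel - (N - K)):min(total_sel, K)
  probs <- choose(K, ks) * choose(N - K, total_sel - ks) /
    choose(N, total_sel)
  sum(probs[ks >= count_sel])
}

# Mismatch count by explicit character loop (no wildcard handling needed
# for the oracle cases that use it).
loop_hamming <- function(a, b) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- 0L
  for (i in seq_along(av)) if (av[i] != bv[i]) n <- n + 1L
  n
}

# Exhaustive window scan by substring extraction.
brute_scan <- function(spec, sequence, max_mm) {
  L <- nchar(spec)
  hits <- list()
  for (o in 0:(nchar(sequence) - L)) {
    w <- substr(sequence, o + 1, o + L)
    mm <- loop_hamming(spec, w)
    if (mm <= max_mm) hits[[length(hits) + 1]] <- c(offset = o, mm = mm)
  }
  hits
}

# All-pairs N/O distance scan over a structure model data frame.
brute_hbonds <- function(model, cutoff = 3.5, min_dist = 2.2) {
  at <- model[model$element %in% c("N", "O") &
                model$polymer != "water", , drop = FALSE]
  n <- 0L
  if (nrow(at) < 2) return(0L)
  for (i in seq_len(nrow(at) - 1)) {
    for (j in (i + 1):nrow(at)) {
      if (at$chain[i] == at$chain[j] && at$resno[i] == at$resno[j]) next
      d <- sqrt((at$x[i] - at$x[j])^2 + (at$y[i] - at$y[j])^2 +
                  (at$z[i] - at$z[j])^2)
      if (d > min_dist && d <= cutoff) n <- n + 1L
    }
  }
  n
}

random_target <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
        collapse = "")
}
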
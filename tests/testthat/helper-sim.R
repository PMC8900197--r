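# Shared small-genome objects: built once per test run. The 10%-scale
# genome (~312 bins, chr21 = 5 bins) keeps module tests fast; acceptance
# tests build the full-scale genome themselves.
small_genome <- build_genome(bin_width = 1e6, scale = 0.1)

quiet <- function(expr) suppressMessages(expr)

small_panel_for <- function(genome, n_ref = 10, seed = 42,
                            profile = source_profile("SCM")) {
  pan <- simulate_reference_panel(n_ref, profile, genome, seed = seed)
  quiet(build_panel_from_counts(pan$samples, genome, sexes = pan$sexes))
}
small_panel <- small_panel_for(small_genome)

# Full-scale genome + 20-sample SCM reference panel, built lazily once
# and shared by the tests that need realistic problem sizes.
full_env <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      genome <- build_genome(bin_width = 1e6, scale = 1)
      pan <- simulate_reference_panel(20, source_profile("SCM"), genome,
                                      seed = 101)
      panel <- quiet(build_panel_from_counts(pan$samples, genome,
                                             sexes = pan$sexes))
      cache <<- list(genome = genome, panel = panel)
    }
    cache
  }
})

# Brute-force oracle for the maximal circular-arc t statistic:
# enumerates every non-wrapping arc (i, j) and computes the two-sample
# pooled t directly from the two groups. Canonical arc representation
# folds the duplicated whole-prefix/whole-suffix partitions.
oracle_max_t <- function(x) {
  n <- length(x)
  best <- -1; bi <- 0; bj <- n
  for (i in 0:(n - 1)) {
    for (j in (i + 1):n) {
      if (j - i >= n) next
      arc <- x[(i + 1):j]
      comp <- x[setdiff(seq_len(n), (i + 1):j)]
      sp2 <- (sum((arc - mean(arc))^2) + sum((comp - mean(comp))^2)) /
        (n - 2)
      tt <- if (sp2 <= 0) {
        if (mean(arc) == mean(comp)) 0 else Inf
      } else {
        abs(mean(arc) - mean(comp)) /
          sqrt(sp2 * (1 / length(arc) + 1 / length(comp)))
      }
      if (tt > best + 1e-12) {
        best <- tt; bi <- i; bj <- j
      }
    }
  }
  list(i = bi, j = bj, stat = best)
}

canonical_arc <- function(i, j, n) {
  # a prefix arc (0, j) and its complement (j, n) are the same circular
  # partition; represent both as the prefix
  if (i == 0) c(0L, j) else if (j == n) c(0L, i) else c(i, j)
}
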
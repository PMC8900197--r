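#' Maximal circular-arc t statistic
#'
#' The core statistic of circular binary segmentation: the vector is
#' treated as a circle, and for every arc the two-sample pooled-variance
#' t statistic between the arc and its complement is computed; the arc
#' maximizing |T| is returned. Boundaries are 0-based half-open: the arc
#' `(i, j)` is `x[(i+1):j]`. Ties keep the smallest `i`, then smallest
#' `j`. A zero-variance input returns `T = 0` with arc `(0, length(x))`.
#'
#' @param x Numeric vector (length >= 4).
#' @param min_width Minimum bins in the arc and in each non-empty flank
#'   (1 = unconstrained, the exported contract).
#' @return List with `i`, `j` (boundaries) and `stat` (signed T; the sign
#'   is that of the arc-minus-complement mean difference).
#' @export
max_t_arc <- function(x, min_width = 1L) {
  stopifnot(is.numeric(x))
  if (length(x) < 4) stop("need at least 4 observations")
  if (anyNA(x)) stop("x must not contain NA")
  cbs_max_arc(as.numeric(x), as.integer(min_width))
}

#' Permutation p-value for the maximal arc statistic
#'
#' Permutes the bins within the vector (preserving the per-chromosome
#' noise scale), recomputes the maximal |T| for each permutation, and
#' returns `p = (1 + #{max |T*| >= |T_obs|}) / (n_perm + 1)`.
#'
#' @param x Numeric vector.
#' @param t_obs Observed statistic (e.g. from [max_t_arc()]).
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed.
#' @param min_width Passed through to the arc search.
#' @return Permutation p-value.
#' @export
permutation_pvalue <- function(x, t_obs, n_perm = 1000L, seed = 1L,
                               min_width = 1L) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  res <- .perm_test(x, t_obs, n_perm, seed, min_width, early_alpha = NULL)
  res$p
}

# Shared permutation machinery; early_alpha != NULL allows stopping as
# soon as the p-value provably exceeds it (decision-only use).
.perm_test <- function(x, t_obs, n_perm, seed, min_width,
                       early_alpha = NULL) {
  n <- length(x)
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  perms <- matrix(0L, nrow = n_perm, ncol = n)
  for (p in seq_len(n_perm)) perms[p, ] <- sample.int(n)
  stop_after <- if (is.null(early_alpha)) -1L
  else as.integer(ceiling(early_alpha * (n_perm + 1)))
  res <- cbs_perm_count(as.numeric(x), perms, t_obs,
                        as.integer(min_width), stop_after)
  complete <- res$used == n_perm
  p <- (1 + res$exceed) / (res$used + 1)
  sig <- if (is.null(early_alpha)) NA else complete && p < early_alpha
  list(p = p, complete = complete, significant = sig)
}

#' Segment one chromosome's copy-ratio vector
#'
#' Recursive circular binary segmentation: find the maximal arc, test it
#' by permutation, and if significant (`p < alpha`) split the vector at
#' the arc boundaries and recurse into each piece. No segment shorter
#' than `min_width` bins is ever produced. Inputs shorter than
#' `max(min_width, 4)` are returned as a single unsplit segment.
#'
#' @param x Numeric ratio vector for the chromosome's valid bins.
#' @param alpha Split significance level (default 0.01).
#' @param n_perm Permutations per test (default 1000).
#' @param min_width Minimum segment width in bins (default 3).
#' @param seed Integer seed.
#' @return Data frame with `start`, `end` (0-based half-open indices into
#'   `x`), `n_bins`, `mean`, `p` (split p-value; 1 for unsplit pieces).
#' @export
segment_chromosome <- function(x, alpha = 0.01, n_perm = 1000L,
                               min_width = 3L, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, min_width >= 2)
  n <- length(x)
  if (n == 0L)
    return(data.frame(start = integer(), end = integer(),
                      n_bins = integer(), mean = numeric(), p = numeric()))
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max %/% 2L, 1024L)
  seed_i <- 0L
  next_seed <- function() {
    seed_i <<- seed_i + 1L
    if (seed_i > length(seeds)) seed_i <<- 1L
    seeds[seed_i]
  }

  recurse <- function(lo, hi) { # 0-based half-open slice of x
    len <- hi - lo
    piece <- x[(lo + 1):hi]
    if (len < max(min_width * 2L, 4L))
      return(data.frame(start = lo, end = hi, n_bins = len,
                        mean = mean(piece), p = 1))
    arc <- cbs_max_arc(piece, as.integer(min_width))
    if (arc$stat == 0 || (arc$i == 0 && arc$j == len))
      return(data.frame(start = lo, end = hi, n_bins = len,
                        mean = mean(piece), p = 1))
    test <- .perm_test(piece, arc$stat, n_perm, next_seed(), min_width,
                       early_alpha = alpha)
    if (!test$significant)
      return(data.frame(start = lo, end = hi, n_bins = len,
                        mean = mean(piece), p = 1))
    cuts <- unique(c(lo, lo + arc$i, lo + arc$j, hi))
    out <- do.call(rbind, lapply(seq_len(length(cuts) - 1L), function(k) {
      recurse(cuts[k], cuts[k + 1L])
    }))
    # pieces left unsplit deeper down carry the p of the test that
    # created them
    out$p[out$p == 1] <- test$p
    out
  }
  res <- recurse(0L, n)
  rownames(res) <- NULL
  res
}

#' Merge adjacent segments with similar means
#'
#' Canonical CBS pruning: adjacent segments whose means differ by less
#' than `merge_threshold` (ratio units) are merged; the merged mean is
#' the bin-count-weighted mean.
#'
#' @param segments Data frame as returned by [segment_chromosome()].
#' @param merge_threshold Mean-difference threshold (default 0.1).
#' @return Merged segment data frame.
#' @export
merge_segments <- function(segments, merge_threshold = 0.1) {
  if (nrow(segments) <= 1L) return(segments)
  segs <- segments[order(segments$start), , drop = FALSE]
  repeat {
    if (nrow(segs) <= 1L) break
    diffs <- abs(diff(segs$mean))
    k <- which.min(diffs)
    if (diffs[k] >= merge_threshold) break
    n1 <- segs$n_bins[k]; n2 <- segs$n_bins[k + 1L]
    segs$end[k] <- segs$end[k + 1L]
    segs$n_bins[k] <- n1 + n2
    segs$mean[k] <- (n1 * segs$mean[k] + n2 * segs$mean[k + 1L]) / (n1 + n2)
    segs$p[k] <- min(segs$p[k], segs$p[k + 1L])
    segs <- segs[-(k + 1L), , drop = FALSE]
  }
  rownames(segs) <- NULL
  segs
}

#' Segment a whole copy-ratio profile
#'
#' Applies [segment_chromosome()] then [merge_segments()] to every
#' chromosome's valid bins. Bin indices in the result refer to positions
#' within each chromosome's valid-bin vector; `genome_start`/`genome_end`
#' give the corresponding genome bin rows.
#'
#' @param profile A `copy_ratio_profile`.
#' @param alpha,n_perm,min_width,merge_threshold CBS parameters.
#' @param seed Integer seed.
#' @return Data frame of segments with columns `chrom`, `start`, `end`,
#'   `n_bins`, `mean`, `p`, `genome_start`, `genome_end`.
#' @export
segment_genome <- function(profile, alpha = 0.01, n_perm = 1000L,
                           min_width = 3L, merge_threshold = 0.1,
                           seed = 1L) {
  stopifnot(inherits(profile, "copy_ratio_profile"))
  g <- profile$genome
  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)
  chrom_seeds <- sample.int(.Machine$integer.max %/% 2L,
                            length(chromosome_names()))
  out <- list()
  for (ci in seq_along(chromosome_names())) {
    ch <- chromosome_names()[ci]
    idx <- which(g$chrom == ch & profile$valid)
    if (length(idx) == 0L) next
    x <- profile$ratio[idx]
    segs <- segment_chromosome(x, alpha = alpha, n_perm = n_perm,
                               min_width = min_width,
                               seed = chrom_seeds[ci])
    segs <- merge_segments(segs, merge_threshold)
    segs$chrom <- ch
    segs$genome_start <- idx[segs$start + 1L] - 1L
    segs$genome_end <- idx[segs$end]
    out[[length(out) + 1L]] <- segs
  }
  res <- do.call(rbind, out)
  res <- res[, c("chrom", "start", "end", "n_bins", "mean", "p",
                 "genome_start", "genome_end")]
  rownames(res) <- NULL
  res
}
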
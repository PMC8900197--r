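#' Simulate one sample's per-bin read counts
#'
#' The expected read weight of bin `b` is
#' `[(1 - c) * cn_embryo(b)/2 + c * cn_XX(b)/2] * gcbias(gc_b) * usable_b`,
#' where `c` is the profile's 46,XX contamination fraction and mosaic
#' events contribute the effective copy number `2 + m * (cn - 2)`. This
#' encodes the linear dosage model of shallow-WGS CNV detection: a gain
#' from two to three copies raises expected counts by 50%, a loss to one
#' copy lowers them by 50%. Counts are drawn by gamma-multinomial
#' sampling: per-bin gamma factors with variance `dispersion` multiply the
#' weights, bins are dropped out at `dropout_rate`, and `total_reads`
#' reads are then allocated multinomially, so the counts are overdispersed
#' (negative-binomial-like marginals) yet sum exactly to `total_reads`.
#'
#' @param truth A `sample_karyotype` ground truth.
#' @param profile A [source_profile()].
#' @param genome A `genome_bins` from [build_genome()].
#' @param seed Integer seed; identical inputs and seed give bit-identical
#'   counts.
#' @param sample_id Sample identifier stored in the result.
#' @return A `bin_counts` object: list with `sample_id`, `source`,
#'   `counts` (integer per bin, aligned to `genome`), `n_bins`,
#'   `total_reads`.
#' @examples
#' g <- build_genome(scale = 0.05)
#' tri21 <- karyotype("XY", whole_chromosome_event("21", 3, 1, g))
#' s <- simulate_sample(tri21, source_profile("SCM"), g, seed = 1)
#' sum(s$counts) == 2e6
#' @export
simulate_sample <- function(truth, profile, genome, seed,
                            sample_id = "sample") {
  .check_genome(genome)
  stopifnot(inherits(truth, "sample_karyotype"),
            inherits(profile, "source_profile"))
  if (!any(genome$usable)) stop("genome has no usable bins")
  c_frac <- profile$contamination
  if (c_frac < 0 || c_frac > 1) stop("contamination must be in [0, 1]")

  cn_emb <- expected_copy_number(truth, genome)
  cn_xx <- expected_copy_number(karyotype("XX"), genome)
  w <- ((1 - c_frac) * cn_emb / 2 + c_frac * cn_xx / 2) *
    .gc_bias_factor(genome$gc, profile$gc_bias_strength) *
    as.numeric(genome$usable)

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)

  if (profile$dispersion > 0) {
    shape <- 1 / profile$dispersion
    w <- w * rgamma(length(w), shape = shape, rate = shape)
  }
  if (profile$dropout_rate > 0) {
    w[runif(length(w)) < profile$dropout_rate] <- 0
  }
  if (sum(w) <= 0) stop("all bins have zero expected weight")

  counts <- as.integer(rmultinom(1L, size = profile$total_reads,
                                 prob = w / sum(w)))
  structure(list(sample_id = sample_id, source = profile$source,
                 counts = counts, n_bins = length(counts),
                 total_reads = profile$total_reads),
            class = "bin_counts")
}

#' @export
print.bin_counts <- function(x, ...) {
  cat(sprintf("bin_counts '%s' [%s]: %d bins, %d reads (%d zero bins)\n",
              x$sample_id, x$source, x$n_bins, sum(x$counts),
              sum(x$counts == 0L)))
  invisible(x)
}

#' Simulate a euploid reference panel
#'
#' Generates `n_ref` euploid samples (alternating 46,XX / 46,XY by
#' default) used to build the reference normalization panel.
#'
#' @param n_ref Number of panel samples (at least 3).
#' @param profile A [source_profile()] shared by all panel samples.
#' @param genome A `genome_bins`.
#' @param seed Integer seed.
#' @param sexes Optional character vector of length `n_ref` with values
#'   `"XX"`/`"XY"`; default alternates.
#' @return List with `samples` (list of `bin_counts`) and `sexes`.
#' @export
simulate_reference_panel <- function(n_ref, profile, genome, seed,
                                     sexes = NULL) {
  if (n_ref < 3) stop("n_ref must be at least 3 for a usable panel median")
  if (is.null(sexes))
    sexes <- rep(c("XX", "XY"), length.out = n_ref)
  stopifnot(length(sexes) == n_ref, all(sexes %in% c("XX", "XY")))
  samples <- lapply(seq_len(n_ref), function(i) {
    simulate_sample(karyotype(sexes[i]), profile, genome,
                    seed = seed + i,
                    sample_id = sprintf("ref%02d", i))
  })
  list(samples = samples, sexes = sexes)
}

#' Simulate a cohort of embryos with ground truth
#'
#' Each embryo receives one ground-truth karyotype and one `bin_counts`
#' per requested source, all simulated from the same truth. Aneuploid
#' truths carry a single random whole-chromosome autosomal event (gain of
#' one copy or loss of one copy, equiprobable); with probability
#' `mosaic_rate` the event is mosaic with fraction drawn uniformly from
#' `mosaic_m_range`, otherwise full (`m = 1`). The default cohort shape
#' (n = 148, aneuploid rate 47/148) mirrors a published 148-embryo
#' SCM/BF validation cohort in which 101 embryos were euploid and 47
#' aneuploid.
#'
#' @param n Number of embryos (> 0).
#' @param aneuploid_rate Fraction of embryos with an aneuploid truth.
#' @param mosaic_rate Fraction of aneuploid truths that are mosaic.
#' @param profiles Named list of [source_profile()]s, one per source to
#'   simulate (e.g. `list(SCM = source_profile("SCM"))`).
#' @param genome A `genome_bins`.
#' @param seed Integer seed.
#' @param mosaic_m_range Range for mosaic fractions (default c(0.5, 1):
#'   the assay's reportable range).
#' @return List with `truths` (list of `sample_karyotype`) and `counts`
#'   (named list: per source, a list of `bin_counts`).
#' @export
simulate_cohort <- function(n = 148, aneuploid_rate = 47 / 148,
                            mosaic_rate = 0.3,
                            profiles = list(SCM = source_profile("SCM")),
                            genome, seed, mosaic_m_range = c(0.5, 1)) {
  if (n < 1) stop("n must be positive")
  if (aneuploid_rate < 0 || aneuploid_rate > 1 ||
      mosaic_rate < 0 || mosaic_rate > 1)
    stop("rates must lie in [0, 1]")
  stopifnot(length(profiles) >= 1, !is.null(names(profiles)))
  .check_genome(genome)

  old <- .save_rng()
  on.exit(.restore_rng(old))
  set.seed(seed)

  autosomes <- chromosome_names()[1:22]
  truths <- vector("list", n)
  for (i in seq_len(n)) {
    sex <- if (runif(1) < 0.5) "XX" else "XY"
    if (runif(1) < aneuploid_rate) {
      chrom <- sample(autosomes, 1L)
      cn <- if (runif(1) < 0.5) 3L else 1L
      m <- if (runif(1) < mosaic_rate)
        runif(1, mosaic_m_range[1], mosaic_m_range[2]) else 1
      truths[[i]] <- karyotype(sex, whole_chromosome_event(chrom, cn, m,
                                                           genome))
    } else {
      truths[[i]] <- karyotype(sex)
    }
  }
  sample_seeds <- sample.int(.Machine$integer.max %/% 2L,
                             n * length(profiles))
  counts <- vector("list", length(profiles))
  names(counts) <- names(profiles)
  k <- 0L
  for (src in names(profiles)) {
    counts[[src]] <- lapply(seq_len(n), function(i) {
      simulate_sample(truths[[i]], profiles[[src]], genome,
                      seed = sample_seeds[k + i],
                      sample_id = sprintf("embryo%03d", i))
    })
    k <- k + n
  }
  list(truths = truths, counts = counts)
}

#' Truth classification of a karyotype
#'
#' @param truth A `sample_karyotype`.
#' @return `"euploid"` if the truth has no events, else `"aneuploid"`.
#' @export
truth_class <- function(truth) {
  if (nrow(truth$events) == 0L) "euploid" else "aneuploid"
}

#' Karyotype string of a simulation truth
#'
#' @param truth A `sample_karyotype`.
#' @return ISCN-like string, e.g. `"47,XY,+21"` or `"46,XX,+16[0.6]"`.
#' @export
truth_karyotype_string <- function(truth) {
  ev <- truth$events
  count <- 46L
  parts <- character(0)
  if (nrow(ev)) {
    for (k in seq_len(nrow(ev))) {
      sign <- if (ev$cn[k] > 2) "+" else "-"
      tag <- paste0(sign, ev$chrom[k])
      if (ev$m[k] < 1) tag <- sprintf("%s[%.2g]", tag, ev$m[k])
      else count <- count + (ev$cn[k] - 2L)
      parts <- c(parts, tag)
    }
  }
  paste(c(sprintf("%d,%s", count, truth$sex), parts), collapse = ",")
}
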